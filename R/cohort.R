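# Group-level analysis of per-individual fits: Tukey-fence outlier
# exclusion, per-line summaries, a line-effect contrast on log parameters,
# and the between-parameter Pearson correlation matrix.

#' Flag poorly fitted individuals by Tukey fences
#'
#' Per measure, computes the fences `[Q1 - k * IQR, Q3 + k * IQR]`
#' separately for `K` and for `C` on the raw (untransformed) parameter
#' scale, and flags a row when either parameter falls outside its fences.
#' Quartiles use linear interpolation ([stats::quantile()] type 7). Flagged
#' rows are retained with `excluded = TRUE`, never dropped.
#'
#' By default the fences are computed once from all rows (including
#' previously flagged ones), which makes the operation idempotent. With
#' `refit_fences = TRUE` the fences are recomputed from the surviving rows
#' until the flag set stabilizes.
#'
#' @param fits Fit table as produced by [fit_cohort()] (needs `measure`,
#'   `K`, `C`).
#' @param parameters Which parameters the rule inspects (default both).
#' @param k Fence multiplier (default 1.5).
#' @param min_rows Minimum rows per measure for a meaningful IQR; measures
#'   below it are skipped with a warning (default 4).
#' @param refit_fences Recompute fences from non-excluded rows iteratively
#'   (default `FALSE`).
#' @return The fit table with logical `excluded` and character
#'   `exclude_reason` columns.
#' @export
exclude_outliers <- function(fits, parameters = c("K", "C"), k = 1.5,
                             min_rows = 4, refit_fences = FALSE) {
  if (!all(c("measure", parameters) %in% names(fits))) {
    stop("'fits' needs columns measure, ",
         paste(parameters, collapse = ", "), call. = FALSE)
  }
  flag_pass <- function(use) {
    excluded <- rep(FALSE, nrow(fits))
    reason <- rep(NA_character_, nrow(fits))
    for (m in unique(fits$measure)) {
      in_m <- fits$measure == m
      base <- in_m & use
      if (sum(base) < min_rows) {
        warning(sprintf("measure '%s': fewer than %d rows, no exclusion applied",
                        m, min_rows), call. = FALSE)
        next
      }
      for (p in parameters) {
        v <- fits[[p]][base]
        q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
        iqr <- q[2L] - q[1L]
        lo <- q[1L] - k * iqr
        hi <- q[2L] + k * iqr
        out <- in_m & (fits[[p]] < lo | fits[[p]] > hi)
        reason[out] <- ifelse(is.na(reason[out]), p,
                              paste(reason[out], p, sep = ","))
        excluded <- excluded | out
      }
    }
    list(excluded = excluded, reason = reason)
  }

  if (!refit_fences) {
    res <- flag_pass(rep(TRUE, nrow(fits)))
  } else {
    use <- rep(TRUE, nrow(fits))
    res <- flag_pass(use)
    for (it in seq_len(10L)) {
      new_use <- !res$excluded
      if (identical(new_use, use)) break
      use <- new_use
      res <- flag_pass(use)
    }
  }
  fits$excluded <- res$excluded
  fits$exclude_reason <- res$reason
  fits
}

.kv_keep <- function(fits) {
  if ("excluded" %in% names(fits)) fits[!fits$excluded, , drop = FALSE]
  else fits
}

#' Per-line summary of fitted and derived parameters
#'
#' Arithmetic means of `K`, `C`, `T` and `x_inf` within each line x measure
#' cell, over non-excluded rows. `T` and `x_inf` are averaged as
#' per-individual derived values, not recomputed from the mean `K` and mean
#' `C`: the mean of ratios is not the ratio of means, and the per-individual
#' convention is the one that summarizes recovery capacity as a phenotype.
#'
#' @param fits Fit table (after [exclude_outliers()] if exclusion is
#'   wanted); needs `line`, `measure`, `K`, `C`, `T`, `x_inf`.
#' @return Data frame with one row per line x measure: means of the four
#'   quantities and `n`, the number of individuals summarized.
#' @export
summarize_by_line <- function(fits) {
  req <- c("line", "measure", "K", "C", "T", "x_inf")
  if (!all(req %in% names(fits))) {
    stop("'fits' needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  d <- .kv_keep(fits)
  want <- expand.grid(line = unique(fits$line),
                      measure = unique(fits$measure),
                      stringsAsFactors = FALSE)
  empty <- !(paste(want$line, want$measure) %in% paste(d$line, d$measure))
  if (any(empty)) {
    warning("empty line x measure cell(s) after exclusion: ",
            paste(paste(want$line[empty], want$measure[empty], sep = "/"),
                  collapse = ", "), call. = FALSE)
  }
  agg <- stats::aggregate(cbind(K, C, T, x_inf) ~ line + measure, data = d,
                          FUN = mean)
  n <- stats::aggregate(K ~ line + measure, data = d, FUN = length)
  names(n)[3L] <- "n"
  out <- merge(agg, n, by = c("line", "measure"), sort = TRUE)
  out[order(out$measure, out$line), , drop = FALSE]
}

#' Test for a line effect on a fitted parameter
#'
#' Models the log-transformed parameter for one measure with an ordinary
#' linear model, `log(parameter) ~ line * replicate`, then backward-drops
#' non-significant terms at `alpha` (interaction first, then replicate) and
#' refits. Returns the per-line estimated means (back-transformed to the
#' natural scale) and the marginal F-test p-value of the line term in the
#' final model. When only one replicate level is present the replicate term
#' is dropped automatically.
#'
#' @param fits Fit table; rows flagged `excluded` are ignored.
#' @param measure Measure to test.
#' @param parameter `"K"` or `"C"`.
#' @param alpha Threshold for the backward elimination (default 0.05).
#' @return A list of class `"kv_line_test"`: `estimates` (named per-line
#'   geometric-mean-scale estimates), `p_value` (line effect), `formula`,
#'   `n_per_line`, `measure`, `parameter`.
#' @export
line_effect_test <- function(fits, measure, parameter = c("K", "C"),
                             alpha = 0.05) {
  parameter <- match.arg(parameter)
  d <- .kv_keep(fits)
  d <- d[d$measure == measure, , drop = FALSE]
  if (!nrow(d)) stop("no rows for measure '", measure, "'", call. = FALSE)
  d$line <- factor(d$line)
  if (nlevels(d$line) < 2L) {
    stop("need at least two lines to test a line effect", call. = FALSE)
  }
  n_per_line <- table(d$line)
  if (any(n_per_line < 2L)) {
    stop("need at least 2 non-excluded rows per line", call. = FALSE)
  }
  d$y <- log(d[[parameter]])
  has_rep <- "replicate" %in% names(d) && !anyNA(d$replicate) &&
    length(unique(d$replicate)) >= 2L
  if (has_rep) {
    d$replicate <- factor(d$replicate)
    fit <- stats::lm(y ~ line * replicate, data = d)
    a <- stats::anova(fit)
    p_int <- a["line:replicate", "Pr(>F)"]
    if (is.na(p_int) || p_int >= alpha) {
      fit <- stats::lm(y ~ line + replicate, data = d)
      p_rep <- stats::drop1(fit, scope = ~replicate, test = "F")[
        "replicate", "Pr(>F)"]
      if (is.na(p_rep) || p_rep >= alpha) {
        fit <- stats::lm(y ~ line, data = d)
      }
    }
  } else {
    fit <- stats::lm(y ~ line, data = d)
  }
  p_line <- stats::drop1(fit, scope = ~line, test = "F")["line", "Pr(>F)"]
  # per-line estimate: average prediction over the factor grid, back-transformed
  terms_used <- attr(stats::terms(fit), "term.labels")
  grid <- if ("replicate" %in% unlist(strsplit(terms_used, ":"))) {
    expand.grid(line = levels(d$line), replicate = levels(d$replicate))
  } else {
    data.frame(line = levels(d$line))
  }
  pred <- stats::predict(fit, newdata = grid)
  est <- exp(tapply(pred, grid$line, mean))
  structure(list(estimates = est, p_value = unname(p_line),
                 formula = deparse(stats::formula(fit)),
                 n_per_line = n_per_line,
                 measure = measure, parameter = parameter),
            class = "kv_line_test")
}

#' @export
print.kv_line_test <- function(x, ...) {
  cat(sprintf("Line effect on %s (%s), model %s\n",
              x$parameter, x$measure, x$formula))
  print(round(x$estimates, 4))
  cat(sprintf("  line p-value = %.4g\n", x$p_value))
  invisible(x)
}

#' Pearson correlations between fitted parameters
#'
#' Builds the individuals x (measure, parameter) matrix of non-excluded
#' fitted values and computes pairwise-complete Pearson correlations with
#' [stats::cor.test()] p-values. Cells with fewer than `min_pairs` complete
#' pairs are left `NA`.
#'
#' @param fits Fit table; needs `individual_id`, `measure`, `K`, `C`.
#' @param parameters Parameters to cross (default `c("K", "C")`).
#' @param min_pairs Minimum complete pairs per cell (default 3).
#' @return A list of class `"kv_cor_table"`: matrices `r`, `p` and `n`
#'   (complete pairs), with rows/columns named `<measure>_<parameter>`.
#' @export
parameter_correlations <- function(fits, parameters = c("K", "C"),
                                   min_pairs = 3) {
  req <- c("individual_id", "measure", parameters)
  if (!all(req %in% names(fits))) {
    stop("'fits' needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  d <- .kv_keep(fits)
  ids <- sort(unique(fits$individual_id))
  measures <- unique(fits$measure)
  cols <- as.vector(outer(measures, parameters, paste, sep = "_"))
  W <- matrix(NA_real_, length(ids), length(cols),
              dimnames = list(ids, cols))
  for (m in measures) {
    dm <- d[d$measure == m, , drop = FALSE]
    for (p in parameters) {
      W[match(dm$individual_id, ids), paste(m, p, sep = "_")] <- dm[[p]]
    }
  }
  nc <- ncol(W)
  r <- matrix(NA_real_, nc, nc, dimnames = list(cols, cols))
  pm <- matrix(NA_real_, nc, nc, dimnames = list(cols, cols))
  nm <- matrix(0L, nc, nc, dimnames = list(cols, cols))
  for (i in seq_len(nc)) {
    for (j in i:nc) {
      ok <- stats::complete.cases(W[, i], W[, j])
      nm[i, j] <- nm[j, i] <- sum(ok)
      if (i == j) {
        r[i, j] <- 1
        next
      }
      if (sum(ok) >= min_pairs) {
        ct <- stats::cor.test(W[ok, i], W[ok, j], method = "pearson")
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        pm[i, j] <- pm[j, i] <- ct$p.value
      }
    }
  }
  structure(list(r = r, p = pm, n = nm), class = "kv_cor_table")
}

#' @export
print.kv_cor_table <- function(x, ...) {
  cat("Pearson correlations between fitted parameters\n")
  print(round(x$r, 2))
  invisible(x)
}
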