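# Least-squares estimation of (K, C) per series, scored with the modelling
# efficiency statistic. The closed-form solution is evaluated inside the
# objective; positivity is enforced by optimizing on the log scale with a
# multi-start Nelder-Mead simplex.

# Fast closed-form evaluation from rest (x0 = 0), without constructor
# overhead; the optimizer calls this thousands of times.
.kv_xmodel <- function(times, K, C, F_pert, perc, tau1, tau2) {
  m <- perc * F_pert
  rate <- K / C
  x <- numeric(length(times))
  ch <- times >= tau1 & times < tau2
  post <- times >= tau2
  if (any(ch)) x[ch] <- .kv_challenge_x(times[ch] - tau1, K, C, m, 0, 0)
  if (any(post)) {
    x_tau2 <- .kv_challenge_x(tau2 - tau1, K, C, m, 0, 0)
    x[post] <- x_tau2 * exp(-rate * (times[post] - tau2))
  }
  x
}

#' Sum-of-squares objective for a preprocessed series
#'
#' The residual sum of squares between observed values and the closed-form
#' model started from rest (`x0 = 0`), evaluated at the observation times.
#' This is the loss minimized by [fit_series()].
#'
#' @param times,values Observation times (analysis scale) and preprocessed
#'   values, equal length.
#' @param K,C Candidate stiffness and resistance (> 0).
#' @param F_pert,perc,tau1,tau2 Fixed model constants (see [kv_params()]).
#' @return Non-negative scalar.
#' @export
kv_objective <- function(times, values, K, C, F_pert = 0.1, perc = 1,
                         tau1 = 20, tau2 = 60) {
  stopifnot(length(times) == length(values), K > 0, C > 0)
  sum((values - .kv_xmodel(times, K, C, F_pert, perc, tau1, tau2))^2)
}

#' Modelling efficiency (MEF)
#'
#' `MEF = 1 - sum((Y_i - Ymod_i)^2) / sum((Y_i - mean(Y))^2)`. A value of 1
#' indicates a perfect fit; 0 means the model does no better than the
#' observed mean; negative values mean it does worse.
#'
#' @param observed,modeled Numeric vectors of equal length (>= 2).
#' @return Scalar MEF value (at most 1).
#' @examples
#' model_efficiency(c(1, 2, 3), c(1, 2, 3))
#' @export
model_efficiency <- function(observed, modeled) {
  if (length(observed) != length(modeled)) {
    stop("'observed' and 'modeled' must have equal length", call. = FALSE)
  }
  if (length(observed) < 2L) {
    stop("MEF needs at least 2 observations", call. = FALSE)
  }
  denom <- sum((observed - mean(observed))^2)
  if (denom == 0) {
    stop("MEF undefined: observed values are all identical", call. = FALSE)
  }
  1 - sum((observed - modeled)^2) / denom
}

#' Fit stiffness and resistance to one observation series
#'
#' Minimizes [kv_objective()] over `(log K, log C)` with the Nelder-Mead
#' simplex ([stats::optim()]), started from every point of a coarse log-grid
#' (`start_K` crossed with `start_C`) and keeping the best local optimum.
#' The log parameterization enforces positivity; soft bounds keep the search
#' inside a physically plausible box via a quadratic penalty. `F_pert`,
#' `perc` and the challenge window are held fixed, so the fit estimates only
#' `K` and `C`.
#'
#' A series with no variation at all (flat) carries no information about the
#' response amplitude: the stiffness is unidentifiable from above, and the
#' fit is returned flagged `degenerate` with `K_hat` pinned at the upper
#' search bound.
#'
#' @param times,values Observation times (0-100 scale) and preprocessed
#'   values.
#' @param F_pert,perc,tau1,tau2 Fixed constants; defaults 0.1, 1, 20, 60.
#' @param start_K,start_C Multi-start grids on the natural scale.
#' @param reltol Relative convergence tolerance of each simplex run; the
#'   tight default lets noiseless series reach MEF = 1 to high precision.
#' @param maxit Iteration cap per start.
#' @param log_bounds_K,log_bounds_C Soft box bounds on the log scale.
#' @return An object of class `"kv_fit"`: a list with `K_hat`, `C_hat`,
#'   `ssr`, `mef`, `T`, `x_inf`, `x_max`, `converged`, `degenerate`,
#'   `n_obs`, `starts_used` and the fixed constants.
#' @examples
#' p <- kv_params(K = 0.1, C = 2)
#' tt <- c(0, 10, 25, 40, 55, 62, 70, 85, 100)
#' y <- simulate_closed_form(p, tt)$x
#' fit_series(tt, y)
#' @export
fit_series <- function(times, values, F_pert = 0.1, perc = 1,
                       tau1 = 20, tau2 = 60,
                       start_K = c(0.01, 0.1, 1), start_C = c(0.1, 1, 10),
                       reltol = 1e-10, maxit = 2000,
                       log_bounds_K = log(c(1e-4, 1e2)),
                       log_bounds_C = log(c(1e-4, 1e3))) {
  if (length(times) != length(values)) {
    stop("'times' and 'values' must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("at least 2 observation points are required", call. = FALSE)
  }
  .kv_check_times(times)
  if (length(times) < 4L) {
    warning("fewer than 4 observation points; K and C are weakly identified",
            call. = FALSE)
  }

  finish <- function(K_hat, C_hat, converged, degenerate, starts_used) {
    ssr <- kv_objective(times, values, K_hat, C_hat, F_pert, perc, tau1, tau2)
    mod <- .kv_xmodel(times, K_hat, C_hat, F_pert, perc, tau1, tau2)
    mef <- if (stats::var(values) > 0) model_efficiency(values, mod) else NA_real_
    m <- perc * F_pert
    rate <- K_hat / C_hat
    structure(list(
      K_hat = K_hat, C_hat = C_hat, ssr = ssr, mef = mef,
      T = C_hat / K_hat, x_inf = m / K_hat,
      x_max = .kv_challenge_x(tau2 - tau1, K_hat, C_hat, m, 0, 0),
      converged = converged, degenerate = degenerate,
      n_obs = length(times), starts_used = starts_used,
      F_pert = F_pert, perc = perc, tau1 = tau1, tau2 = tau2),
      class = "kv_fit")
  }

  if (diff(range(values)) == 0) {
    return(finish(K_hat = exp(log_bounds_K[2L]), C_hat = 1,
                  converged = FALSE, degenerate = TRUE, starts_used = 0L))
  }

  penalty <- function(par) {
    1e6 * (max(0, par[1L] - log_bounds_K[2L])^2 +
           max(0, log_bounds_K[1L] - par[1L])^2 +
           max(0, par[2L] - log_bounds_C[2L])^2 +
           max(0, log_bounds_C[1L] - par[2L])^2)
  }
  fn <- function(par) {
    kv_objective(times, values, exp(par[1L]), exp(par[2L]),
                 F_pert, perc, tau1, tau2) + penalty(par)
  }

  starts <- expand.grid(K = start_K, C = start_C)
  best <- NULL
  n_starts <- nrow(starts)
  for (i in seq_len(n_starts)) {
    res <- stats::optim(log(c(starts$K[i], starts$C[i])), fn,
                        method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = maxit))
    if (is.null(best) || res$value < best$value) best <- res
  }
  finish(K_hat = exp(best$par[1L]), C_hat = exp(best$par[2L]),
         converged = best$convergence == 0L, degenerate = FALSE,
         starts_used = n_starts)
}

#' @export
print.kv_fit <- function(x, ...) {
  cat("Spring-damper fit\n")
  cat(sprintf("  K = %.4g, C = %.4g  (n_obs = %d, starts = %d)\n",
              x$K_hat, x$C_hat, x$n_obs, x$starts_used))
  cat(sprintf("  T = %.4g, x_inf = %.4g, x_max = %.4g\n",
              x$T, x$x_inf, x$x_max))
  cat(sprintf("  SSR = %.4g, MEF = %.4g, converged = %s%s\n",
              x$ssr, x$mef, x$converged,
              if (isTRUE(x$degenerate)) ", DEGENERATE (flat series)" else ""))
  invisible(x)
}

.kv_fit_row <- function(fit, individual_id, measure, line, replicate) {
  data.frame(individual_id = individual_id, measure = measure,
             line = line, replicate = replicate,
             K = fit$K_hat, C = fit$C_hat,
             T = fit$T, x_inf = fit$x_inf, x_max = fit$x_max,
             ssr = fit$ssr, mef = fit$mef,
             converged = fit$converged, degenerate = fit$degenerate,
             n_obs = fit$n_obs, stringsAsFactors = FALSE)
}

#' Fit every individual x measure series of a cohort
#'
#' Applies [fit_series()] to each individual x measure group of a
#' preprocessed long-format table and assembles the results into the flat
#' fit table consumed by the cohort-level operations.
#'
#' @param data Preprocessed long-format data frame (`individual_id`,
#'   `measure`, `time`, `value`, optional `line`, `replicate`).
#' @param ... Passed on to [fit_series()].
#' @return Data frame with one row per individual x measure: identifiers,
#'   `K`, `C`, `T`, `x_inf`, `x_max`, `ssr`, `mef`, `converged`,
#'   `degenerate`, `n_obs`.
#' @export
fit_cohort <- function(data, ...) {
  req <- c("individual_id", "measure", "time", "value")
  if (!all(req %in% names(data))) {
    stop("'data' needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  key <- interaction(data$individual_id, data$measure, drop = TRUE)
  rows <- lapply(split(data, key), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    fit <- fit_series(d$time, d$value, ...)
    .kv_fit_row(fit, d$individual_id[1L], d$measure[1L],
                if (is.null(d$line)) NA_character_ else d$line[1L],
                if (is.null(d$replicate)) NA_character_ else d$replicate[1L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$measure, out$individual_id), , drop = FALSE]
}

#' Fit the mean temporal pattern of each measure
#'
#' Averages the preprocessed values across individuals at each observation
#' time (per measure) and fits the model to the resulting mean pattern: the
#' standard first look at whether the model can track a measure at all.
#'
#' @inheritParams fit_cohort
#' @return A fit table as in [fit_cohort()] with `individual_id = "mean"`,
#'   one row per measure.
#' @export
fit_mean_pattern <- function(data, ...) {
  req <- c("individual_id", "measure", "time", "value")
  if (!all(req %in% names(data))) {
    stop("'data' needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(split(data, data$measure), function(d) {
    agg <- stats::aggregate(value ~ time, data = d, FUN = mean)
    agg <- agg[order(agg$time), , drop = FALSE]
    fit <- fit_series(agg$time, agg$value, ...)
    .kv_fit_row(fit, "mean", d$measure[1L], NA_character_, NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
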