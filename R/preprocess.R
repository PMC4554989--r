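# Data preparation: fold-change normalization, minimum subtraction, and the
# affine 0-100 time rescaling that places the challenge at [20, 60].
#
# Two working hypotheses underlie these steps: (1) measurement units carry no
# information about the model parameters (only relative change matters), and
# (2) every individual is close to its undisturbed state at some observed
# time point, so the series minimum can anchor x = 0.

#' Fold-change normalization
#'
#' Divides a raw series by a reference mean, turning measures with arbitrary
#' units into dimensionless fold changes of that mean. For cohort data the
#' reference is normally the grand mean of the measure over all individuals
#' and all time points (see [preprocess_cohort()]).
#'
#' @param values Numeric vector of raw measurements.
#' @param reference_mean Positive scalar to divide by.
#' @return Numeric vector of fold changes.
#' @examples
#' normalize_fold_change(c(2, 4, 6), 4)
#' @export
normalize_fold_change <- function(values, reference_mean) {
  if (!is.numeric(values) || length(values) == 0L) {
    stop("'values' must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(reference_mean) || length(reference_mean) != 1L ||
      !is.finite(reference_mean) || reference_mean <= 0) {
    stop("'reference_mean' must be a single positive number", call. = FALSE)
  }
  values / reference_mean
}

#' Shift a series so its minimum is zero
#'
#' Subtracts the series minimum, anchoring the least-disturbed observation at
#' the model's rest state `x = 0`. Idempotent.
#'
#' @param values Numeric vector (normally fold changes).
#' @return Numeric vector with minimum exactly 0.
#' @examples
#' shift_min_zero(c(0.5, 1.0, 1.5))
#' @export
shift_min_zero <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values))) {
    stop("'values' must be a non-empty finite numeric vector", call. = FALSE)
  }
  values - min(values)
}

#' Rescale observation times onto the 0-100 analysis scale
#'
#' Applies the affine map that sends the challenge onset to
#' `challenge_start_scaled` and the challenge end to `challenge_end_scaled`,
#' so studies on different clocks become comparable. The map is only
#' well-defined when the challenge occupies the same fraction of the
#' observation window as on the target scale
#' (`challenge_duration / window_hours == (end - start) / 100`); otherwise a
#' configuration error is raised. For the reference trout design (10-h
#' window from 2 h before a 4-h challenge starting at hour 0), the map is
#' `scaled_t = (t + 2) * 10`.
#'
#' @param times_raw Numeric vector of times in raw units (e.g. hours).
#' @param challenge_onset Challenge start on the raw clock.
#' @param challenge_duration Challenge length in raw units (> 0).
#' @param window_hours Total observation window in raw units (default 10).
#' @param challenge_start_scaled,challenge_end_scaled Challenge bounds on the
#'   target scale (defaults 20 and 60).
#' @return Numeric vector of rescaled times.
#' @examples
#' rescale_time(c(-2, 0, 4, 8), challenge_onset = 0, challenge_duration = 4)
#' @export
rescale_time <- function(times_raw, challenge_onset, challenge_duration,
                         window_hours = 10,
                         challenge_start_scaled = 20,
                         challenge_end_scaled = 60) {
  if (!is.numeric(times_raw)) stop("'times_raw' must be numeric", call. = FALSE)
  if (challenge_duration <= 0) {
    stop("'challenge_duration' must be > 0", call. = FALSE)
  }
  if (challenge_end_scaled <= challenge_start_scaled) {
    stop("scaled challenge end must exceed its start", call. = FALSE)
  }
  prop_raw <- challenge_duration / window_hours
  prop_scaled <- (challenge_end_scaled - challenge_start_scaled) / 100
  if (abs(prop_raw - prop_scaled) > 1e-8) {
    stop(sprintf(paste0("inconsistent design: challenge occupies %.3f of the raw ",
                        "window but %.3f of the 0-100 scale; the affine map would ",
                        "not send the window onto [0, 100]"),
                 prop_raw, prop_scaled), call. = FALSE)
  }
  slope <- (challenge_end_scaled - challenge_start_scaled) / challenge_duration
  challenge_start_scaled + slope * (times_raw - challenge_onset)
}

#' Preprocess a long-format cohort of observation series
#'
#' Runs the two preparation steps on every individual x measure series of a
#' long-format table: fold-change normalization by a per-measure reference
#' mean, then minimum subtraction, optionally preceded by [rescale_time()].
#' The result is model-ready: non-negative, minimum exactly 0, on the
#' fold-change scale.
#'
#' By default the reference for a measure is the grand mean of that measure
#' over all individuals and all time points. Pass `reference_means` (a named
#' vector keyed by measure) to substitute another convention, e.g. a known
#' baseline level.
#'
#' A warning is emitted when a series attains its minimum strictly inside
#' the challenge window, since anchoring `x = 0` there contradicts the
#' assumption that the minimum reflects an undisturbed state.
#'
#' @param data Data frame with columns `individual_id`, `measure`, `time`,
#'   `value`, and optionally `line`, `replicate`.
#' @param reference_means Optional named numeric vector of per-measure
#'   reference means; `NULL` (default) computes grand means from the data.
#' @param time_in_hours If `TRUE`, `time` is first rescaled with
#'   [rescale_time()] using the following arguments.
#' @param challenge_onset,challenge_duration,window_hours Passed to
#'   [rescale_time()] when `time_in_hours` is `TRUE`.
#' @param challenge_window Challenge bounds on the analysis scale, used for
#'   the in-challenge-minimum diagnostic (default `c(20, 60)`).
#' @return The input data frame with `value` replaced by preprocessed values,
#'   `time` on the analysis scale, and a `provenance` column set to
#'   `"preprocessed"`.
#' @export
preprocess_cohort <- function(data, reference_means = NULL,
                              time_in_hours = FALSE,
                              challenge_onset = 0, challenge_duration = 4,
                              window_hours = 10,
                              challenge_window = c(20, 60)) {
  req <- c("individual_id", "measure", "time", "value")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("'data' lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(data$provenance) && any(data$provenance == "preprocessed")) {
    stop("'data' already contains preprocessed rows", call. = FALSE)
  }
  data <- data[order(data$measure, data$individual_id, data$time), ,
               drop = FALSE]
  if (time_in_hours) {
    data$time <- rescale_time(data$time, challenge_onset, challenge_duration,
                              window_hours)
  }

  measures <- unique(data$measure)
  if (is.null(reference_means)) {
    reference_means <- vapply(measures, function(m) {
      mean(data$value[data$measure == m])
    }, numeric(1))
  } else {
    if (is.null(names(reference_means)) ||
        !all(measures %in% names(reference_means))) {
      stop("'reference_means' must be named and cover every measure",
           call. = FALSE)
    }
  }

  key <- interaction(data$individual_id, data$measure, drop = TRUE)
  pieces <- lapply(split(data, key), function(d) {
    ref <- reference_means[[as.character(d$measure[1L])]]
    v <- normalize_fold_change(d$value, ref)
    v <- shift_min_zero(v)
    t_min <- d$time[which.min(v)]
    if (t_min > challenge_window[1L] && t_min < challenge_window[2L]) {
      warning(sprintf(paste0("series %s / %s attains its minimum at t = %g, ",
                             "strictly inside the challenge window; the ",
                             "undisturbed-state anchor may be violated"),
                      d$individual_id[1L], d$measure[1L], t_min),
              call. = FALSE)
    }
    d$value <- v
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$provenance <- "preprocessed"
  attr(out, "reference_means") <- reference_means
  out
}
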