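# Synthetic cohort generator emulating the confinement-challenge study
# design in isogenic rainbow trout: 2 lines x 2 replicates x 4 aquaria,
# four measures (two physiological, two behavioural), sparse observation
# times on the 0-100 scale with a challenge at [20, 60), per-measure
# multiplicative baselines and multiplicative observation noise. Every
# drawn (K, C) pair is recorded, so parameter recovery and group contrasts
# can be checked against known truth.

.kv_default_measures <- c("cortisol_release", "oxygen_consumption",
                          "group_activity", "group_dispersion")

# Per-line, per-measure medians of K and C. Values span the range typical of
# physiological (low-K, slow) and behavioural (high-K, fast-saturating)
# stress responses in the reference confinement design, with the two lines
# contrasted most strongly in the cortisol stiffness.
.kv_default_line_medians <- function() {
  data.frame(
    line    = rep(c("A", "R"), each = 4L),
    measure = rep(.kv_default_measures, times = 2L),
    K = c(0.018, 0.080, 0.120, 0.453,
          0.039, 0.179, 0.126, 0.245),
    C = c(0.302, 1.074, 0.740, 3.871,
          0.537, 1.449, 2.428, 5.791),
    stringsAsFactors = FALSE
  )
}

# Observation designs on the 0-100 scale. Physiological measures are sampled
# sparsely through the challenge; behavioural measures cannot be observed
# during confinement, so their design has no points in [20, 60).
.kv_default_sampling_times <- function(measures) {
  phys <- c(0, 8, 16, 22, 30, 40, 50, 58, 62, 70, 80, 90, 100)
  behav <- c(0, 5, 10, 15, 19, 61, 65, 70, 76, 84, 92, 100)
  st <- lapply(measures, function(m) {
    if (grepl("activity|dispersion|behav", m)) behav else phys
  })
  names(st) <- measures
  st
}

#' Specify a synthetic cohort
#'
#' Collects the design of a synthetic confinement-challenge cohort: group
#' structure, ground-truth parameter medians per line x measure,
#' between-individual dispersion, per-measure raw-scale baselines, noise
#' level and observation designs.
#'
#' Raw values are constructed as
#' `baseline_scale[measure] * (1 + x(t)) * (1 + noise)`, where `x` is the
#' closed-form model response: the model's `x` is a fold-change deviation
#' with rest value 0, so the `+1` offset plus the min-subtraction step of
#' [preprocess_cohort()] makes preprocessing a genuine inverse of
#' generation.
#'
#' @param n_lines,n_replicates,n_individuals_per_cell Group structure;
#'   defaults 2 x 2 x 4 (so 8 statistical individuals per line).
#' @param measures Character vector of measure labels (default the four
#'   trout-style measures; names containing `activity`, `dispersion` or
#'   `behav` are treated as behavioural, i.e. unobservable in-challenge).
#' @param line_medians Data frame `line`, `measure`, `K`, `C` giving the
#'   median of each parameter per cell; must cover `n_lines` lines crossed
#'   with `measures`. Default: built-in two-line medians.
#' @param dispersion Standard deviation of between-individual variation on
#'   the log-parameter scale (default 0.3).
#' @param cross_measure_cor Correlation, across measures within an
#'   individual, of the log-parameter deviations (default 0: independent
#'   draws). Implemented with a shared individual-level latent factor.
#' @param baseline_scale Named numeric vector of per-measure multiplicative
#'   baselines (raw units). Defaults span three orders of magnitude so raw
#'   series genuinely need normalization.
#' @param noise_sigma Multiplicative Gaussian observation noise fraction
#'   (default 0.05).
#' @param sampling_times Named list of per-measure observation times on the
#'   0-100 scale.
#' @param F_pert,perc,tau1,tau2 Model constants used for simulation
#'   (defaults 0.1, 1, 20, 60 - the fitting convention).
#' @param seed Integer seed recorded in the spec (default 1).
#' @return An object of class `"kv_cohort_spec"`.
#' @export
cohort_spec <- function(n_lines = 2, n_replicates = 2,
                        n_individuals_per_cell = 4,
                        measures = .kv_default_measures,
                        line_medians = NULL,
                        dispersion = 0.3,
                        cross_measure_cor = 0,
                        baseline_scale = NULL,
                        noise_sigma = 0.05,
                        sampling_times = NULL,
                        F_pert = 0.1, perc = 1, tau1 = 20, tau2 = 60,
                        seed = 1L) {
  if (n_lines < 1 || n_replicates < 1 || n_individuals_per_cell < 1) {
    stop("all counts must be >= 1", call. = FALSE)
  }
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  if (dispersion < 0) stop("'dispersion' must be >= 0", call. = FALSE)
  if (cross_measure_cor < 0 || cross_measure_cor > 1) {
    stop("'cross_measure_cor' must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(line_medians)) {
    line_medians <- .kv_default_line_medians()
    line_medians <- line_medians[line_medians$measure %in% measures, ,
                                 drop = FALSE]
    line_medians <- line_medians[line_medians$line %in%
                                   utils::head(c("A", "R"), n_lines), ,
                                 drop = FALSE]
  }
  req <- c("line", "measure", "K", "C")
  if (!all(req %in% names(line_medians))) {
    stop("'line_medians' needs columns line, measure, K, C", call. = FALSE)
  }
  lines <- unique(line_medians$line)
  if (length(lines) != n_lines) {
    stop("'line_medians' must define exactly 'n_lines' lines", call. = FALSE)
  }
  want <- expand.grid(line = lines, measure = measures,
                      stringsAsFactors = FALSE)
  have <- paste(line_medians$line, line_medians$measure)
  if (!all(paste(want$line, want$measure) %in% have)) {
    stop("'line_medians' must cover every line x measure cell", call. = FALSE)
  }
  if (any(line_medians$K <= 0) || any(line_medians$C <= 0)) {
    stop("parameter medians must be positive", call. = FALSE)
  }
  if (is.null(baseline_scale)) {
    defaults <- c(cortisol_release = 5, oxygen_consumption = 500,
                  group_activity = 0.5, group_dispersion = 50)
    baseline_scale <- defaults[measures]
    baseline_scale[is.na(baseline_scale)] <- 1
    names(baseline_scale) <- measures
  }
  if (!all(measures %in% names(baseline_scale))) {
    stop("'baseline_scale' must be named and cover every measure",
         call. = FALSE)
  }
  if (is.null(sampling_times)) {
    sampling_times <- .kv_default_sampling_times(measures)
  }
  if (!all(measures %in% names(sampling_times))) {
    stop("'sampling_times' must be named and cover every measure",
         call. = FALSE)
  }
  structure(list(
    n_lines = n_lines, n_replicates = n_replicates,
    n_individuals_per_cell = n_individuals_per_cell,
    measures = measures, lines = lines, line_medians = line_medians,
    dispersion = dispersion, cross_measure_cor = cross_measure_cor,
    baseline_scale = baseline_scale, noise_sigma = noise_sigma,
    sampling_times = sampling_times,
    F_pert = F_pert, perc = perc, tau1 = tau1, tau2 = tau2,
    seed = as.integer(seed)), class = "kv_cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws an individual (K, C) per individual x measure lognormally around
#' the line medians, simulates the closed-form response from rest, converts
#' it to the raw scale as `baseline * (1 + x)`, applies multiplicative
#' observation noise and samples at the per-measure design times.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed controlling all randomness (default `spec$seed`).
#' @return An object of class `"kv_cohort"`: a list with `data` (raw
#'   long-format data frame: `individual_id`, `measure`, `line`,
#'   `replicate`, `time`, `value`), `truth` (one row per individual x
#'   measure with the drawn `K`, `C` and the `baseline` used) and `spec`.
#' @examples
#' co <- generate_cohort(cohort_spec(n_individuals_per_cell = 1), seed = 7)
#' head(co$truth)
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "kv_cohort_spec"))
  set.seed(seed)
  rho <- spec$cross_measure_cor
  med <- spec$line_medians
  data_rows <- list()
  truth_rows <- list()
  k <- 0L
  for (line in spec$lines) {
    for (r in seq_len(spec$n_replicates)) {
      rep_id <- sprintf("rep%d", r)
      for (i in seq_len(spec$n_individuals_per_cell)) {
        id <- sprintf("%s_%s_aq%d", line, rep_id, i)
        zK <- stats::rnorm(1L)
        zC <- stats::rnorm(1L)
        for (m in spec$measures) {
          row <- med[med$line == line & med$measure == m, ][1L, ]
          eK <- stats::rnorm(1L)
          eC <- stats::rnorm(1L)
          logK <- log(row$K) + spec$dispersion *
            (sqrt(rho) * zK + sqrt(1 - rho) * eK)
          logC <- log(row$C) + spec$dispersion *
            (sqrt(rho) * zC + sqrt(1 - rho) * eC)
          K <- exp(logK); C <- exp(logC)
          p <- kv_params(K = K, C = C, F_pert = spec$F_pert,
                         perc = spec$perc, tau1 = spec$tau1,
                         tau2 = spec$tau2)
          st <- spec$sampling_times[[m]]
          x <- simulate_closed_form(p, st)$x
          b <- spec$baseline_scale[[m]]
          noise <- 1 + stats::rnorm(length(st), 0, spec$noise_sigma)
          k <- k + 1L
          data_rows[[k]] <- data.frame(
            individual_id = id, measure = m, line = line,
            replicate = rep_id, time = st,
            value = b * (1 + x) * noise, stringsAsFactors = FALSE)
          truth_rows[[k]] <- data.frame(
            individual_id = id, measure = m, line = line,
            replicate = rep_id, K = K, C = C, baseline = b,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  data <- do.call(rbind, data_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(data) <- rownames(truth) <- NULL
  structure(list(data = data, truth = truth, spec = spec,
                 outliers = NULL, seed = seed),
            class = "kv_cohort")
}

#' Plant extreme responders in a synthetic cohort
#'
#' Multiplies the response deviation of chosen individuals by `magnitude`
#' for one measure (on the raw scale:
#' `value -> baseline * (1 + magnitude * (value/baseline - 1))`), so their
#' fitted parameters land outside the Tukey fences used by
#' [exclude_outliers()]. The planted identities are recorded on the cohort.
#'
#' @param cohort A `kv_cohort` from [generate_cohort()].
#' @param k_outliers Number of individuals to modify (default 1).
#' @param magnitude Amplitude multiplier (default 20; 1 leaves the cohort
#'   unchanged).
#' @param measure Measure to modify (default the first in the spec).
#' @param individuals Optional explicit individual ids; default the first
#'   `k_outliers` ids in sorted order (deterministic).
#' @return The cohort with modified `data` and an `outliers` data frame
#'   (`individual_id`, `measure`, `magnitude`).
#' @export
plant_outliers <- function(cohort, k_outliers = 1, magnitude = 20,
                           measure = NULL, individuals = NULL) {
  stopifnot(inherits(cohort, "kv_cohort"))
  if (is.null(measure)) measure <- cohort$spec$measures[1L]
  ids <- sort(unique(cohort$data$individual_id))
  if (k_outliers > length(ids)) {
    stop("'k_outliers' exceeds the number of individuals", call. = FALSE)
  }
  if (is.null(individuals)) individuals <- ids[seq_len(k_outliers)]
  b <- cohort$spec$baseline_scale[[measure]]
  sel <- cohort$data$measure == measure &
    cohort$data$individual_id %in% individuals
  dev <- cohort$data$value[sel] / b - 1
  cohort$data$value[sel] <- b * (1 + magnitude * dev)
  planted <- data.frame(individual_id = individuals, measure = measure,
                        magnitude = magnitude, stringsAsFactors = FALSE)
  cohort$outliers <- rbind(cohort$outliers, planted)
  cohort
}

#' @export
print.kv_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals x %d measures, %d rows (seed %d)\n",
              length(unique(x$truth$individual_id)),
              length(x$spec$measures), nrow(x$data), x$seed))
  if (!is.null(x$outliers)) {
    cat(sprintf("  planted outliers: %s\n",
                paste(x$outliers$individual_id, collapse = ", ")))
  }
  invisible(x)
}
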