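# One-at-a-time sensitivity sweeps and the K x C interplay grid, each run
# summarized by the robustness quantities x_max, x_inf and T.

.kv_sweep_defaults <- list(
  fixed = list(K = 0.1, C = 2, F_pert = 1, perc = 1, tau1 = 20, tau2 = 60),
  ranges = list(K = c(0.1, 1), C = c(0.5, 20), F_pert = c(1, 10))
)

#' One-at-a-time parameter sweep
#'
#' Varies one of `K`, `C` or `F_pert` while holding the other parameters
#' fixed, and records `x_max`, `x_inf` and `T` for each value. Default
#' ranges and fixed values follow the standard protocol: `K` swept over
#' `[0.1, 1]` with `C = 2`, `F_pert = 1`; `C` over `[0.5, 20]` with
#' `K = 0.1`, `F_pert = 1`; `F_pert` over `[1, 10]` with `K = 0.1`, `C = 2`.
#' Sweep values are log-spaced so hyperbolic relationships are resolved at
#' the low end.
#'
#' @param parameter One of `"K"`, `"C"`, `"F_pert"`.
#' @param values Optional vector of swept values (strictly increasing,
#'   positive). Default: `n` log-spaced points over the standard range.
#' @param fixed Named list overriding the held-fixed configuration.
#' @param n Number of sweep points when `values` is `NULL` (default 50).
#' @return Data frame with columns `parameter`, `value`, `x_max`, `x_inf`,
#'   `T`.
#' @examples
#' sw <- run_sweep("K", n = 5)
#' all.equal(sw$x_inf * sw$value, rep(1, 5))  # x_inf * K = perc * F_pert
#' @export
run_sweep <- function(parameter = c("K", "C", "F_pert"), values = NULL,
                      fixed = list(), n = 50) {
  parameter <- match.arg(parameter)
  base <- utils::modifyList(.kv_sweep_defaults$fixed, fixed)
  if (is.null(values)) {
    r <- .kv_sweep_defaults$ranges[[parameter]]
    values <- exp(seq(log(r[1L]), log(r[2L]), length.out = n))
  }
  if (any(values <= 0) || (length(values) > 1L && any(diff(values) <= 0))) {
    stop("'values' must be positive and strictly increasing", call. = FALSE)
  }
  rows <- lapply(values, function(v) {
    cfg <- base
    cfg[[parameter]] <- v
    p <- kv_params(K = cfg$K, C = cfg$C, F_pert = cfg$F_pert,
                   perc = cfg$perc, tau1 = cfg$tau1, tau2 = cfg$tau2)
    dq <- derive_quantities(p)
    data.frame(parameter = parameter, value = v,
               x_max = dq$x_max, x_inf = dq$x_inf, T = dq$T,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' K x C interplay grid
#'
#' Simulates all combinations of (typically three) stiffness and resistance
#' values on the standard grid, exposing how the impact of `K` on the
#' response depends on `C` (K dominates amplitude when C is low; C shapes
#' the approach to the asymptote).
#'
#' @param K_values,C_values Positive value grids (default three low/mid/high
#'   values each).
#' @param fixed Named list overriding `F_pert`, `perc`, `tau1`, `tau2`
#'   (defaults 1, 1, 20, 60).
#' @param times Evaluation grid (default [kv_grid()]).
#' @return A list with `summary` (data frame `K`, `C`, `x_max`, `x_inf`,
#'   `T`) and `trajectories` (named list of `kv_trajectory` objects,
#'   `"K=<k>,C=<c>"`).
#' @export
run_interplay_grid <- function(K_values = c(0.1, 0.3, 1),
                               C_values = c(0.5, 2, 10),
                               fixed = list(), times = kv_grid()) {
  base <- utils::modifyList(list(F_pert = 1, perc = 1, tau1 = 20, tau2 = 60),
                            fixed)
  grid <- expand.grid(K = K_values, C = C_values)
  trajs <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- kv_params(K = grid$K[i], C = grid$C[i], F_pert = base$F_pert,
                   perc = base$perc, tau1 = base$tau1, tau2 = base$tau2)
    trajs[[i]] <- simulate_closed_form(p, times)
    dq <- derive_quantities(p)
    rows[[i]] <- data.frame(K = grid$K[i], C = grid$C[i],
                            x_max = dq$x_max, x_inf = dq$x_inf, T = dq$T)
  }
  names(trajs) <- sprintf("K=%g,C=%g", grid$K, grid$C)
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, trajectories = trajs)
}
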