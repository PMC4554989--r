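#' Spring-damper model parameters
#'
#' Bundles the physical parameters of the Kelvin-Voigt system used to model
#' an animal's response to an acute challenge: a spring of stiffness `K` and
#' a damper of friction `C` in parallel, pulled between `tau1` and `tau2` by
#' a constant perturbation force `F_pert` modulated by a perception
#' coefficient `perc`. Outside the challenge window the force is negligible
#' and the deformation `x` relaxes as `dx/dt = -(K/C) x`; inside it the
#' system obeys `m x'' + C x' + K x = m` with effective mass
#' `m = perc * F_pert`.
#'
#' All quantities live on the dimensionless fold-change scale produced by
#' [preprocess_cohort()]: `x = 0` is the undisturbed state, and time runs on
#' the 0-100 analysis scale with the challenge at 20-60 by default.
#'
#' @param K Spring stiffness (> 0): the "deformation potential". Small `K`
#'   means a large response amplitude to a given force.
#' @param C Damper friction (> 0): the "resistance", the capacity of the
#'   system to impede deformation. Large `C` slows both onset and recovery.
#' @param F_pert Magnitude of the perturbation force (> 0). Fixed at 0.1 when
#'   fitting field data, where force and response share an arbitrary unit.
#' @param perc Perception coefficient in `[0, 1]` scaling `F_pert` into the
#'   force actually experienced. Default 1 (all individuals perceive the
#'   challenge fully).
#' @param tau1,tau2 Challenge onset and end on the analysis time scale
#'   (`tau2 > tau1`); defaults 20 and 60.
#'
#' @return An object of class `"kv_params"` (a named list).
#' @seealso [derive_quantities()], [simulate_closed_form()],
#'   [simulate_numeric()]
#' @examples
#' p <- kv_params(K = 0.1, C = 2, F_pert = 1)
#' derive_quantities(p)
#' @export
kv_params <- function(K, C, F_pert = 0.1, perc = 1, tau1 = 20, tau2 = 60) {
  vals <- list(K = K, C = C, F_pert = F_pert, perc = perc,
               tau1 = tau1, tau2 = tau2)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  if (K <= 0) stop("'K' must be > 0", call. = FALSE)
  if (C <= 0) stop("'C' must be > 0", call. = FALSE)
  if (F_pert <= 0) stop("'F_pert' must be > 0", call. = FALSE)
  if (perc < 0 || perc > 1) stop("'perc' must lie in [0, 1]", call. = FALSE)
  if (tau2 <= tau1) stop("'tau2' must be greater than 'tau1'", call. = FALSE)
  structure(vals, class = "kv_params")
}

#' @export
print.kv_params <- function(x, ...) {
  cat("Spring-damper parameters\n")
  cat(sprintf("  K = %g, C = %g, F_pert = %g, perc = %g\n",
              x$K, x$C, x$F_pert, x$perc))
  cat(sprintf("  challenge window: [%g, %g)\n", x$tau1, x$tau2))
  dq <- derive_quantities(x)
  cat(sprintf("  derived: T = %g, x_inf = %g, x_max = %g\n",
              dq$T, dq$x_inf, dq$x_max))
  invisible(x)
}

#' Classify the regime active at a time point
#'
#' The model switches vector field at the challenge boundaries: before
#' `tau1` and from `tau2` onwards the force is negligible (first-order
#' relaxation); on the half-open window `[tau1, tau2)` the full second-order
#' system is active.
#'
#' @param t Numeric vector of times.
#' @param params A [kv_params()] object.
#' @return Character vector with elements `"pre"`, `"challenge"` or
#'   `"post"`.
#' @export
classify_regime <- function(t, params) {
  stopifnot(inherits(params, "kv_params"), is.numeric(t))
  ifelse(t < params$tau1, "pre",
         ifelse(t < params$tau2, "challenge", "post"))
}

#' Derived robustness quantities
#'
#' From a fitted or assumed parameter set, computes the three summary
#' quantities used to phenotype a response:
#' \describe{
#'   \item{`T = C/K`}{decay constant of the recovery; the time for the
#'     post-challenge response to shrink by a factor `e`.}
#'   \item{`x_inf = perc * F_pert / K`}{asymptotic deformation if the
#'     perturbation persisted indefinitely.}
#'   \item{`x_max`}{deformation at the end of the finite challenge, i.e. the
#'     observed response peak. Evaluated from the closed-form solution at
#'     `tau2`, not read off a discrete grid.}
#' }
#'
#' @param params A [kv_params()] object.
#' @param x0 Deformation at time 0 (default 0, the undisturbed state).
#' @return A list with elements `T`, `x_inf`, `x_max`.
#' @examples
#' derive_quantities(kv_params(K = 0.1, C = 2, F_pert = 1))
#' @export
derive_quantities <- function(params, x0 = 0) {
  stopifnot(inherits(params, "kv_params"))
  m <- params$perc * params$F_pert
  if (m <= 0) {
    stop("degenerate mass: perc * F_pert must be > 0 to evaluate the challenge regime",
         call. = FALSE)
  }
  rate <- params$K / params$C
  x1 <- x0 * exp(-rate * params$tau1)
  x_max <- .kv_challenge_x(params$tau2 - params$tau1,
                           params$K, params$C, m, x1, -rate * x1)
  list(T = params$C / params$K,
       x_inf = m / params$K,
       x_max = x_max)
}
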