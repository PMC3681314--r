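#' Kinetic parameters for the source-decay mechanism
#'
#' Bundles the four constants of the 1D source-decay model: a morphogen is
#' injected at the distal end (`x = 0`) at rate `J`, diffuses with coefficient
#' `D`, decays everywhere at first-order rate `d`, and cannot leave through
#' the far end at `x = L`.
#'
#' @param D diffusion coefficient, um^2/s. Must be positive.
#' @param d first-order decay rate, 1/s. Non-negative; `d = 0` is allowed for
#'   the parameter bundle itself but most steady-state quantities are then
#'   unbounded and the corresponding calculators signal this.
#' @param J boundary influx, a.u. per second per unit cross-section.
#' @param L system length, um.
#' @return An object of class `"source_decay_params"`.
#' @examples
#' p <- source_decay_params(D = 600, d = 1e-6, J = 1000, L = 3000)
#' characteristic_length(p$D, p$d)
#' @export
source_decay_params <- function(D, d = 1e-6, J = 1000, L = 3000) {
  stopifnot(is.numeric(D), length(D) == 1L, D > 0,
            is.numeric(d), length(d) == 1L, d >= 0,
            is.numeric(J), length(J) == 1L, J >= 0,
            is.numeric(L), length(L) == 1L, L > 0)
  structure(list(D = D, d = d, J = J, L = L), class = "source_decay_params")
}

#' @export
#' @method print source_decay_params
#' @noRd
print.source_decay_params <- function(x, ...) {
  cat("Source-decay parameters\n")
  cat(sprintf("  D = %g um^2/s, d = %g /s, J = %g a.u./s, L = %g um\n",
              x$D, x$d, x$J, x$L))
  if (x$d > 0)
    cat(sprintf("  lambda = %.4g um, C0 = %.4g a.u., Thiele L/lambda = %.3g\n",
                characteristic_length(x$D, x$d),
                max_concentration(x$J, x$D, x$d),
                x$L / characteristic_length(x$D, x$d)))
  invisible(x)
}

#' Characteristic length of a source-decay gradient
#'
#' The distance over which the steady exponential gradient drops to `1/e` of
#' its maximum, `lambda = sqrt(D/d)`.
#'
#' @param D diffusion coefficient, um^2/s (> 0).
#' @param d decay rate, 1/s (> 0; `d = 0` gives an infinite characteristic
#'   length and signals a condition rather than returning a number).
#' @return Characteristic length in um.
#' @examples
#' characteristic_length(600, 1e-6)  # ~2.4e4 um: auxin-like kinetics
#' characteristic_length(600, 0.06)  # 100 um
#' @export
characteristic_length <- function(D, d) {
  stopifnot(is.numeric(D), D > 0, is.numeric(d), d >= 0)
  if (any(d == 0))
    stop("infinite characteristic length: decay rate d is zero, ",
         "the gradient has no finite decay length", call. = FALSE)
  sqrt(D / d)
}

#' Steady-state concentration of the source-decay model
#'
#' Evaluates the finite-domain steady state of diffusion with influx `J` at
#' `x = 0`, first-order decay and a no-flux wall at `x = L`:
#' \deqn{C(x) = \frac{J\lambda}{D}\,
#'   \frac{\cosh((L-x)/\lambda)}{\sinh(L/\lambda)}
#'   = \frac{J\lambda}{D}\,
#'     \frac{e^{-x/\lambda}\,(1 + e^{-2(L-x)/\lambda})}{1 - e^{-2L/\lambda}},}
#' which reduces to `C0 * exp(-x/lambda)` (with `C0 = J/sqrt(D d)`) as soon
#' as the domain is much longer than the characteristic length; only within
#' ~2 lambda of the far wall does the reflected term contribute.
#'
#' @param p a [source_decay_params()] object with `d > 0`.
#' @param x position(s) in um, inside `[0, L]`.
#' @return Concentration(s) in a.u.
#' @examples
#' p <- source_decay_params(D = 600, d = 1e-6, J = 1000, L = 1e6)
#' 100 * (1 - steady_state_concentration(p, 1000) /
#'            steady_state_concentration(p, 0))  # ~4% over the distal 1 mm
#' @export
steady_state_concentration <- function(p, x) {
  stopifnot(inherits(p, "source_decay_params"), is.numeric(x))
  if (any(x < 0 | x > p$L))
    stop("position x outside the domain [0, L]", call. = FALSE)
  lam <- characteristic_length(p$D, p$d)
  ## overflow-safe cosh((L-x)/lam)/sinh(L/lam)
  (p$J * lam / p$D) * exp(-x / lam) * (1 + exp(-2 * (p$L - x) / lam)) /
    (1 - exp(-2 * p$L / lam))
}

#' Maximum steady-state concentration
#'
#' In the long-domain limit the maximum sits at the source and equals
#' `C0 = J * lambda / D = J / sqrt(D * d)`.
#'
#' @param J influx, a.u./s; `D` diffusion um^2/s; `d` decay 1/s (> 0).
#' @param D,d see [characteristic_length()].
#' @return Maximum concentration, a.u.
#' @export
max_concentration <- function(J, D, d) {
  stopifnot(is.numeric(J), J >= 0, is.numeric(D), D > 0, is.numeric(d), d >= 0)
  if (any(d == 0))
    stop("no finite steady maximum: decay rate d is zero, ",
         "concentration grows without bound under constant influx",
         call. = FALSE)
  J / sqrt(D * d)
}

#' Back-engineer the decay rate for a target characteristic length
#'
#' Inverts `lambda = sqrt(D/d)`: the decay rate needed to give a gradient of
#' length `lambda_target` at diffusion `D` is `D / lambda_target^2`.
#'
#' @param D diffusion coefficient, um^2/s (> 0).
#' @param lambda_target desired characteristic length, um (> 0).
#' @return Decay rate, 1/s.
#' @examples
#' back_engineer_decay(600, 100)  # 0.06 /s, i.e. a 12 s half-life
#' @export
back_engineer_decay <- function(D, lambda_target) {
  stopifnot(is.numeric(D), D > 0, is.numeric(lambda_target), lambda_target > 0)
  D / lambda_target^2
}

#' Back-engineer the diffusion coefficient for a target characteristic length
#'
#' @param d decay rate, 1/s (> 0).
#' @param lambda_target desired characteristic length, um (> 0).
#' @return Diffusion coefficient, um^2/s.
#' @examples
#' back_engineer_diffusion(1e-6, 100)  # 0.01 um^2/s
#' @export
back_engineer_diffusion <- function(d, lambda_target) {
  stopifnot(is.numeric(d), d > 0, is.numeric(lambda_target), lambda_target > 0)
  d * lambda_target^2
}

#' Root-mean-square displacement before decay
#'
#' The typical 1D distance a molecule diffuses before it is degraded,
#' `sqrt(2 D / d) = sqrt(2) * lambda`.  Fixing the characteristic length of a
#' source-decay gradient therefore also fixes how far the molecule can carry
#' information.
#'
#' @inheritParams characteristic_length
#' @return RMS displacement, um.
#' @examples
#' rms_displacement(600, 0.06)  # ~141 um
#' @export
rms_displacement <- function(D, d) {
  stopifnot(is.numeric(D), D > 0, is.numeric(d), d >= 0)
  if (any(d == 0))
    stop("unbounded displacement: with d = 0 molecules never decay ",
         "and the RMS travel distance diverges", call. = FALSE)
  sqrt(2 * D / d)
}

#' Diffusive spread after a fixed time
#'
#' The 1D RMS displacement scale of pure diffusion after time `t`,
#' `sqrt(2 D t)`.
#'
#' @param D diffusion coefficient, um^2/s (>= 0).
#' @param t elapsed time, s (>= 0).
#' @return Length scale, um.
#' @examples
#' diffusive_spread(0.01, 3600)  # ~8.5 um in one hour
#' @export
diffusive_spread <- function(D, t) {
  stopifnot(is.numeric(D), D >= 0, is.numeric(t), t >= 0)
  sqrt(2 * D * t)
}

#' Half-life of first-order decay
#'
#' @param d decay rate, 1/s (> 0).
#' @return Half-life in seconds, `log(2)/d`.
#' @examples
#' half_life(1e-6) / 86400  # ~8 days
#' half_life(0.06)          # ~12 s
#' @export
half_life <- function(d) {
  if (!is.numeric(d) || any(d <= 0))
    stop("half_life requires a positive decay rate", call. = FALSE)
  log(2) / d
}

#' Thiele modulus
#'
#' The ratio of system size to characteristic length, `L / lambda` -- a direct
#' indicator of whether a gradient can pattern a tissue of that size: values
#' near or below 1 mean the gradient barely varies over the tissue; very large
#' values mean it collapses within a tiny distal fraction.
#'
#' @param L system length, um (> 0).
#' @param lambda_char characteristic length, um (> 0).
#' @return Dimensionless ratio.
#' @examples
#' thiele_modulus(480, 120)  # fly-embryo-like: 4
#' @export
thiele_modulus <- function(L, lambda_char) {
  stopifnot(is.numeric(L), L > 0, is.numeric(lambda_char), lambda_char > 0)
  L / lambda_char
}

#' Gradient summary for a source-decay parameter set
#'
#' @param p a [source_decay_params()] object with `d > 0`.
#' @return A list with `lambda_char` (um), `C0` (a.u.) and `thiele`
#'   (`L / lambda_char`).
#' @export
gradient_summary <- function(p) {
  stopifnot(inherits(p, "source_decay_params"))
  lam <- characteristic_length(p$D, p$d)
  list(lambda_char = lam,
       C0 = max_concentration(p$J, p$D, p$d),
       thiele = thiele_modulus(p$L, lam))
}

#' Transient 1D simulation of the source-decay model
#'
#' Finite-volume discretisation of diffusion plus linear decay on a uniform
#' grid, with the influx `J` applied as a flux boundary condition at `x = 0`
#' and a zero-flux wall at `x = L`.  Time integration is backward Euler
#' (unconditionally stable and positivity preserving for this operator); the
#' discrete mass balance influx - decay - accumulation is conserved to solver
#' precision at every step.
#'
#' @param p a [source_decay_params()] object.
#' @param grid_spacing node spacing, um.  A warning is emitted when fewer than
#'   10 nodes resolve one characteristic length.
#' @param time_points strictly increasing output times, s (the initial state
#'   at `t = 0` is always included in the output).
#' @param initial initial concentration: scalar or one value per node
#'   (default 0).
#' @param dt time step, s.  Defaults to the spacing between the densest output
#'   times capped at `grid_spacing^2 / D` (accuracy, not stability: the
#'   implicit scheme is stable for any positive `dt`, but a non-positive or
#'   non-finite step is rejected).
#' @return A list with `x` (node centres, um), `times`, `profiles` (matrix,
#'   one row per time), and `mass_balance_error` (max relative defect of the
#'   per-step ledger).
#' @examples
#' p <- source_decay_params(D = 600, d = 0.06, J = 1000, L = 600)
#' out <- simulate_source_decay_1d(p, grid_spacing = 5, time_points = c(60, 300))
#' @export
simulate_source_decay_1d <- function(p, grid_spacing, time_points,
                                     initial = 0, dt = NULL) {
  stopifnot(inherits(p, "source_decay_params"),
            is.numeric(grid_spacing), grid_spacing > 0,
            is.numeric(time_points), all(time_points > 0),
            !is.unsorted(time_points, strictly = TRUE))
  h <- grid_spacing
  n <- max(2L, round(p$L / h))
  h <- p$L / n                        # exact tiling
  x <- (seq_len(n) - 0.5) * h
  if (p$d > 0) {
    lam <- sqrt(p$D / p$d)
    if (h > lam / 10)
      warning(sprintf(paste0("grid spacing %.3g um resolves the characteristic",
                             " length %.3g um with fewer than 10 nodes"),
                      h, lam), call. = FALSE)
  }
  if (is.null(dt)) dt <- min(diff(c(0, time_points)), h^2 / p$D)
  if (!is.finite(dt) || dt <= 0)
    stop("time step must be a positive finite number", call. = FALSE)

  ## A: finite-volume diffusion + decay (per-volume rates); b: influx at node 1
  main <- rep(-2 * p$D / h^2 - p$d, n)
  main[c(1L, n)] <- -p$D / h^2 - p$d
  off <- rep(p$D / h^2, n - 1L)
  A <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                          diagonals = list(off, main, off))
  b <- numeric(n); b[1L] <- p$J / h
  M <- Matrix::Diagonal(n) - dt * A
  fac <- Matrix::lu(M)

  C <- rep_len(initial, n)
  if (any(C < 0)) stop("initial concentrations must be non-negative", call. = FALSE)
  times <- c(0, time_points)
  profiles <- matrix(NA_real_, length(times), n)
  profiles[1L, ] <- C
  t_now <- 0
  max_defect <- 0
  for (k in seq_along(time_points)) {
    t_target <- time_points[k]
    while (t_now < t_target - 1e-12 * t_target) {
      step_dt <- min(dt, t_target - t_now)
      if (abs(step_dt - dt) > 1e-12 * dt) {
        Mk <- Matrix::Diagonal(n) - step_dt * A
        Cn <- as.numeric(Matrix::solve(Mk, C + step_dt * b))
      } else {
        Cn <- as.numeric(Matrix::solve(fac, C + step_dt * b))
      }
      ## ledger: accumulation must equal influx - decay (diffusion is internal)
      acc <- sum(Cn - C) * h
      src <- p$J * step_dt
      dec <- p$d * sum(Cn) * h * step_dt   # implicit endpoint
      scale <- max(abs(src), abs(dec), sum(Cn) * h, 1e-300)
      defect <- abs(acc - (src - dec)) / scale
      max_defect <- max(max_defect, defect)
      if (defect > 1e-6)
        stop(sprintf("mass-balance defect %.3g exceeds 1e-6 per step", defect),
             call. = FALSE)
      C <- Cn
      t_now <- t_now + step_dt
    }
    profiles[k + 1L, ] <- C
  }
  list(x = x, times = times, profiles = profiles,
       mass_balance_error = max_defect)
}

#' Steady state of the discrete 1D source-decay operator
#'
#' Solves the same finite-volume system as [simulate_source_decay_1d()] for
#' its exact steady state (useful as the long-time limit without marching).
#'
#' @inheritParams simulate_source_decay_1d
#' @return A list with `x` and `concentration`.
#' @export
steady_state_source_decay_1d <- function(p, grid_spacing) {
  stopifnot(inherits(p, "source_decay_params"), p$d > 0,
            is.numeric(grid_spacing), grid_spacing > 0)
  h <- grid_spacing
  n <- max(2L, round(p$L / h))
  h <- p$L / n
  main <- rep(-2 * p$D / h^2 - p$d, n)
  main[c(1L, n)] <- -p$D / h^2 - p$d
  off <- rep(p$D / h^2, n - 1L)
  A <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                          diagonals = list(off, main, off))
  b <- numeric(n); b[1L] <- p$J / h
  list(x = (seq_len(n) - 0.5) * h,
       concentration = as.numeric(Matrix::solve(A, -b)))
}
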