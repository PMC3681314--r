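#' Parameters for the unidirectional cell-file transport model
#'
#' A file of `N` cells downstream of a source cell (index 0) held at fixed
#' concentration `C0`.  Every cell leaks morphogen to both neighbours at rate
#' `q`; polar efflux carriers add a rate `p` in the downward direction only
#' (towards the dead end at cell `N`).  An optional first-order decay `d`
#' removes morphogen from every cell except the clamped source.
#'
#' `p` and `q` are first-order exchange rates between cell compartments (a
#' membrane permeability times membrane-area-per-cell-volume absorbed into one
#' constant, so a permeability quoted in um/s divided by a cell length in um).
#' All dimensionless outputs (per-cell ratios, characteristic length in cell
#' lengths) depend only on the ratios `p/q` and `d/q` and are unaffected by
#' that scaling.
#'
#' @param p additional polar efflux rate, downward (>= 0).
#' @param q background leakage rate, both directions (> 0).
#' @param d decay rate, 1/s (>= 0).
#' @param N number of cells beyond the source cell (>= 1).
#' @param C0 fixed concentration of source cell 0, a.u.
#' @param cell_length cell length in um; scalar or one value per cell
#'   (cells 1..N).
#' @return An object of class `"cell_file_params"`.
#' @examples
#' cell_file_params(p = 19, q = 1)
#' @export
cell_file_params <- function(p, q, d = 0, N = 60, C0 = 1, cell_length = 16) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0,
            is.numeric(q), length(q) == 1L, q > 0,
            is.numeric(d), length(d) == 1L, d >= 0,
            is.numeric(N), length(N) == 1L, N >= 1, N == round(N),
            is.numeric(C0), length(C0) == 1L, C0 >= 0,
            is.numeric(cell_length), all(cell_length > 0),
            length(cell_length) %in% c(1L, as.integer(N)))
  structure(list(p = p, q = q, d = d, N = as.integer(N), C0 = C0,
                 cell_length = cell_length),
            class = "cell_file_params")
}

#' @export
#' @method print cell_file_params
#' @noRd
print.cell_file_params <- function(x, ...) {
  cat("Cell-file transport parameters\n")
  cat(sprintf("  p = %g, q = %g, d = %g /s, N = %d, C0 = %g\n",
              x$p, x$q, x$d, x$N, x$C0))
  if (x$p > 0) {
    lam <- characteristic_length_cells(x$p, x$q, x$cell_length[1L])
    cat(sprintf("  per-cell ratio (p+q)/q = %g, lambda = %.3g cells = %.3g um\n",
                equilibrium_ratio(x$p, x$q), lam$cells, lam$um))
  }
  invisible(x)
}

#' Equilibrium concentration ratio between consecutive cells
#'
#' At flux equilibrium with no decay, each cell holds `(p+q)/q` times the
#' concentration of its upstream neighbour: the polar pump wins over back-leak
#' by exactly that factor.
#'
#' @param p polar efflux rate (>= 0).
#' @param q background leakage rate (> 0; `q = 0` is a division by zero and is
#'   signalled).
#' @return Dimensionless ratio `(p+q)/q`.
#' @examples
#' equilibrium_ratio(19, 1)   # 20-fold per cell
#' equilibrium_ratio(3, 17)   # back-engineered shallow gradient
#' @export
equilibrium_ratio <- function(p, q) {
  stopifnot(is.numeric(p), all(p >= 0), is.numeric(q))
  if (any(q <= 0))
    stop("background leakage q must be positive (q = 0 divides by zero)",
         call. = FALSE)
  (p + q) / q
}

#' Characteristic length of the unidirectional gradient
#'
#' The exponential length of the heaped-up profile, `1 / log((p+q)/q)`,
#' expressed in cell lengths and (times `cell_length`) in um.  Depends only on
#' the ratio `p/q`.
#'
#' @inheritParams equilibrium_ratio
#' @param cell_length cell length in um used for the metric conversion.
#' @return A list with elements `cells` and `um`.
#' @examples
#' characteristic_length_cells(19, 1, 16)   # 0.33 cells, ~5 um
#' characteristic_length_cells(3, 17, 16)   # ~6.2 cells, ~100 um
#' @export
characteristic_length_cells <- function(p, q, cell_length = 16) {
  stopifnot(is.numeric(q), all(q > 0), is.numeric(cell_length),
            all(cell_length > 0))
  if (any(p <= 0))
    stop("infinite characteristic length: p = 0 gives a flat profile",
         call. = FALSE)
  lam <- 1 / log((p + q) / q)
  list(cells = lam, um = lam * cell_length)
}

#' Equilibrium profile of the cell file (no decay)
#'
#' `C_n = C0 * ((p+q)/q)^n` for `n = 0..N`: an exponential increase towards
#' the dead end whenever `p > 0`.  Because the ratio to the power `N` easily
#' overflows double precision (a 20-fold ratio exceeds 19 orders of magnitude
#' within 15 cells), the profile is computed and returned in log-space
#' alongside the (possibly `Inf`) linear values.
#'
#' @param params a [cell_file_params()] object.
#' @return A list with `n` (0..N), `log10_concentration` and `concentration`.
#' @examples
#' pr <- equilibrium_profile(cell_file_params(p = 19, q = 1, N = 15))
#' pr$log10_concentration[16] - pr$log10_concentration[1]  # ~19.5 decades
#' @export
equilibrium_profile <- function(params) {
  stopifnot(inherits(params, "cell_file_params"))
  n <- 0:params$N
  lg <- n * log10(equilibrium_ratio(params$p, params$q)) +
    ifelse(params$C0 > 0, log10(params$C0), -Inf)
  list(n = n, log10_concentration = lg, concentration = 10^lg)
}

#' Simulate the cell-file transport dynamics
#'
#' Integrates
#' \deqn{dC_n/dt = (p+q) C_{n-1} + q C_{n+1} - (p + 2q) C_n - d C_n}
#' for `n = 1..N-1`, with the source cell clamped (`dC_0/dt = 0`) and the
#' dead-end row `dC_N/dt = (p+q) C_{N-1} - q C_N - d C_N`.  Uses the stiff
#' `lsoda` integrator from \pkg{deSolve}.
#'
#' @param params a [cell_file_params()] object.
#' @param time_points strictly increasing output times, s.
#' @param initial initial concentrations for cells 0..N: scalar recycled, or a
#'   vector of length `N + 1`.  Cell 0 is reset to `C0` regardless.
#' @return A list of class `"cell_file_trajectory"` with `times`,
#'   `concentrations` (matrix, rows = times, cols = cells 0..N) and `params`.
#' @examples
#' tr <- simulate_cellfile(cell_file_params(p = 3, q = 17, N = 10),
#'                         time_points = c(10, 100))
#' @export
simulate_cellfile <- function(params, time_points, initial = 0) {
  stopifnot(inherits(params, "cell_file_params"),
            is.numeric(time_points), all(time_points > 0),
            !is.unsorted(time_points, strictly = TRUE))
  N <- params$N
  y0 <- rep_len(initial, N + 1L)
  if (any(y0 < 0)) stop("initial concentrations must be non-negative",
                        call. = FALSE)
  y0[1L] <- params$C0
  p <- params$p; q <- params$q; d <- params$d
  rhs <- function(t, y, parms) {
    dy <- numeric(N + 1L)
    if (N >= 2L) {
      n <- 2:N   # interior cells 1..N-1 (1-based offset)
      dy[n] <- (p + q) * y[n - 1L] + q * y[n + 1L] - (p + 2 * q + d) * y[n]
    }
    dy[N + 1L] <- (p + q) * y[N] - (q + d) * y[N + 1L]
    list(dy)
  }
  sol <- deSolve::ode(y = y0, times = c(0, time_points), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1L] < 0)
    stop("stiff integration failed before reaching the requested times",
         call. = FALSE)
  conc <- unname(as.matrix(sol[, -1L, drop = FALSE]))
  structure(list(times = c(0, time_points), concentrations = conc,
                 params = params),
            class = "cell_file_trajectory")
}

#' Steady-state concentration ratios with decay
#'
#' Per-cell ratios `R_n = C_n / C_{n-1}` of the decay-extended cell-file model
#' at steady state, computed by backward recursion from the dead end:
#' `R_N = (p+q)/(q+d)` and
#' `R_n = (p+q) / (p + 2q + d - q R_{n+1})` for `n < N`.
#' With `d = 0` every ratio equals `(p+q)/q`; with decay the file splits into
#' a proximal influx-driven regime where `R_n` sits at the asymptote given by
#' [asymptotic_source_ratio()] and a distal heaping-up regime where `R_n`
#' returns to `(p+q)/q`, with a transition only a few cells wide.
#'
#' @param params a [cell_file_params()] object with `N >= 2`.
#' @return Numeric vector `R_1..R_N` (ratio of cell `n` to cell `n-1`).
#' @examples
#' R <- steady_ratios_with_decay(cell_file_params(p = 19, q = 1, d = 0.5, N = 40))
#' tail(R, 1)   # near the dead end: ~(p+q)/(q+d)
#' head(R, 1)   # far from it: the influx-driven asymptote
#' @export
steady_ratios_with_decay <- function(params) {
  stopifnot(inherits(params, "cell_file_params"), params$N >= 2)
  p <- params$p; q <- params$q; d <- params$d; N <- params$N
  R <- numeric(N)
  R[N] <- (p + q) / (q + d)
  for (n in (N - 1L):1L)
    R[n] <- (p + q) / (p + 2 * q + d - q * R[n + 1L])
  R
}

#' Reconstruct the steady profile from the decay ratios
#'
#' Cumulative product of [steady_ratios_with_decay()] starting at the clamped
#' source, in log-space to avoid overflow.
#'
#' @inheritParams steady_ratios_with_decay
#' @return A list with `n`, `log10_concentration` and `concentration`.
#' @export
steady_profile_with_decay <- function(params) {
  R <- steady_ratios_with_decay(params)
  lg <- c(0, cumsum(log10(R))) +
    ifelse(params$C0 > 0, log10(params$C0), -Inf)
  list(n = 0:params$N, log10_concentration = lg, concentration = 10^lg)
}

#' Asymptotic influx-driven ratio far from the dead end
#'
#' In a long file with decay, the per-cell ratio far from the dead end
#' approaches the fixed point of the steady-state recursion,
#' \deqn{R = \frac{p + d + 2q - \sqrt{(p+d)^2 + 4dq}}{2q},}
#' which for `q << p` simplifies to `p / (p + d)`.
#'
#' @inheritParams equilibrium_ratio
#' @param d decay rate (>= 0).
#' @param simplified if `TRUE`, return the `q << p` approximation `p/(p+d)`.
#' @return Dimensionless ratio (1 when `d = 0`: the influx-driven region is
#'   flat without decay).
#' @export
asymptotic_source_ratio <- function(p, q, d, simplified = FALSE) {
  stopifnot(is.numeric(p), p >= 0, is.numeric(q), q > 0,
            is.numeric(d), d >= 0)
  if (simplified) return(p / (p + d))
  (p + d + 2 * q - sqrt((p + d)^2 + 4 * d * q)) / (2 * q)
}
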