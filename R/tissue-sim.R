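#' Largest stable explicit time step
#'
#' Positivity (and hence stability) of the explicit Euler step is guaranteed
#' while `dt * max(-diag(A)) <= 1`; this returns that bound times a safety
#' factor.
#'
#' @param model a `tissue_model`.
#' @param safety multiplier in (0, 1].
#' @return Time step in seconds.
#' @export
stable_dt <- function(model, safety = 0.9) {
  stopifnot(inherits(model, "tissue_model"), safety > 0, safety <= 1)
  safety / max(-Matrix::diag(model$A))
}

#' Advance a concentration field by one explicit step
#'
#' One forward-Euler step of `dC/dt = A C + b`: intracellular and wall
#' diffusion, membrane carrier fluxes, decay and influx, all applied
#' simultaneously.  The step size must respect the positivity bound of
#' [stable_dt()]; violations raise an error naming the offending compartment
#' rather than producing silent garbage.
#'
#' @param field a `concentration_field`.
#' @param model the `tissue_model` it lives on.
#' @param dt time step, s.
#' @return The advanced `concentration_field` with attributes
#'   `mass_balance_defect` (relative ledger defect of this step).
#' @export
step <- function(field, model, dt) {
  stopifnot(inherits(field, "concentration_field"),
            inherits(model, "tissue_model"),
            length(field$values) == model$n, dt > 0)
  dmax <- max(-Matrix::diag(model$A))
  if (dt * dmax > 1)
    stop(sprintf(paste0("dt = %g violates the stability bound %g set by ",
                        "compartment %d"), dt, 1 / dmax,
                 which.max(-Matrix::diag(model$A))), call. = FALSE)
  C <- field$values
  Cn <- C + dt * (as.numeric(model$A %*% C) + model$b)
  if (any(Cn < 0)) {
    bad <- which.min(Cn)
    stop(sprintf("negative concentration %.3g in compartment %d after step",
                 Cn[bad], bad), call. = FALSE)
  }
  vol <- model$comp$volume
  acc <- sum((Cn - C) * vol)
  src <- sum(model$b * vol) * dt
  dec <- model$params$d * sum(C * vol) * dt
  scale <- max(abs(src), abs(dec), sum(C * vol), .Machine$double.xmin)
  out <- new_field(model, Cn, time = field$time + dt)
  attr(out, "mass_balance_defect") <- abs(acc - (src - dec)) / scale
  out
}

## Backward-Euler stepper with cached LU factorisation.
implicit_stepper <- function(model, dt) {
  M <- Matrix::Diagonal(model$n) - dt * model$A
  fac <- Matrix::lu(M)
  function(C) as.numeric(Matrix::solve(fac, C + dt * model$b))
}

#' Integrate a tissue model to given output times
#'
#' Backward-Euler integration (unconditionally stable and positivity
#' preserving for this operator), used for the transient experiments where
#' explicit stepping would be needlessly expensive.
#'
#' @param model a `tissue_model`.
#' @param field initial `concentration_field` (default all-zero).
#' @param times strictly increasing output times, s (relative to the field's
#'   current time).
#' @param dt implicit step, s (default: 1/20 of the smallest output spacing).
#' @return List of `concentration_field`s, one per output time.
#' @export
simulate_tissue <- function(model, field = NULL, times, dt = NULL) {
  stopifnot(inherits(model, "tissue_model"), is.numeric(times),
            all(times > 0), !is.unsorted(times, strictly = TRUE))
  if (is.null(field)) field <- new_field(model)
  if (is.null(dt)) dt <- min(diff(c(0, times))) / 20
  stopifnot(dt > 0)
  adv <- implicit_stepper(model, dt)
  t0 <- field$time
  C <- field$values
  t_now <- 0
  out <- vector("list", length(times))
  for (k in seq_along(times)) {
    while (t_now < times[k] - 1e-9 * times[k]) {
      h <- min(dt, times[k] - t_now)
      C <- if (abs(h - dt) <= 1e-12 * dt) adv(C) else {
        fac <- Matrix::lu(Matrix::Diagonal(model$n) - h * model$A)
        as.numeric(Matrix::solve(fac, C + h * model$b))
      }
      t_now <- t_now + h
    }
    out[[k]] <- new_field(model, C, time = t0 + t_now)
  }
  out
}

#' Run a tissue model to its steady state
#'
#' Marches `dC/dt = A C + b` to equilibrium with backward-Euler steps of
#' geometrically growing size, declaring convergence when the maximum
#' relative concentration change per simulated minute drops below
#' `tolerance`.  With the default slow decay (1e-6/s) true equilibrium is
#' approached on the 1/d ~ 10^6 s scale, which the growing steps cross in a
#' few dozen solves; `method = "direct"` instead solves `A C = -b` exactly in
#' one factorisation (identical answer for any non-singular operator).
#'
#' @param model a `tissue_model`.
#' @param field optional initial field (default all-zero).
#' @param tolerance maximum relative change per simulated minute
#'   (default 1e-5).
#' @param max_time simulated-time cap, s; exceeding it raises an error with
#'   the last convergence measure (default `1e4 / d`, bounded to at most
#'   1e13 s).
#' @param dt0 first implicit step, s.
#' @param method `"march"` (default) or `"direct"`.
#' @return The steady `concentration_field`; attribute `sim_time` reports the
#'   simulated seconds used (`NA` for the direct solve) and `change_per_min`
#'   the final convergence measure.
#' @export
run_to_steady_state <- function(model, field = NULL, tolerance = 1e-5,
                                max_time = NULL, dt0 = 1,
                                method = c("march", "direct")) {
  stopifnot(inherits(model, "tissue_model"), tolerance > 0)
  method <- match.arg(method)
  if (method == "direct") {
    C <- as.numeric(Matrix::solve(model$A, -model$b))
    if (any(C < -1e-9 * max(abs(C))))
      stop("direct steady-state solve produced negative concentrations; ",
           "the operator may be singular (d = 0 with no outflow)",
           call. = FALSE)
    out <- new_field(model, pmax(C, 0), time = Inf)
    attr(out, "sim_time") <- NA_real_
    attr(out, "change_per_min") <- 0
    return(out)
  }
  if (is.null(max_time))
    max_time <- min(1e4 / max(model$params$d, 1e-9), 1e13)
  if (is.null(field)) field <- new_field(model)
  C <- field$values
  dt <- dt0
  t_sim <- 0
  change <- Inf
  while (t_sim < max_time) {
    adv <- implicit_stepper(model, dt)
    for (k in 1:4) {    # a few steps per factorisation
      Cn <- adv(C)
      t_sim <- t_sim + dt
      floor_c <- 1e-12 * max(Cn, .Machine$double.xmin)
      change <- max(abs(Cn - C) / pmax(Cn, floor_c)) * 60 / dt
      C <- Cn
      if (change < tolerance) break
    }
    if (change < tolerance) break
    dt <- dt * 2
  }
  if (change >= tolerance)
    stop(sprintf(paste0("no steady state within %.3g simulated seconds: ",
                        "relative change still %.3g per simulated minute ",
                        "(tolerance %.3g)"), t_sim, change, tolerance),
         call. = FALSE)
  out <- new_field(model, C, time = field$time + t_sim)
  attr(out, "sim_time") <- t_sim
  attr(out, "change_per_min") <- change
  out
}

#' Per-link fluxes of a concentration field
#'
#' Reconstructs every mass flux (a.u./s) from the concentrations: diffusive
#' fluxes along cytosol and wall links (`g * (C_i - C_j)`, positive from `i`
#' to `j`) and membrane carrier fluxes
#' (`edge * (P_efflux * C_cell - P_influx * C_wall)`, positive out of the
#' cell).  The discrete divergence of these fluxes equals the local rate of
#' concentration change plus decay minus production, which
#' [check_continuity()]-style tests exploit.
#'
#' @inheritParams step
#' @return A list with data frames `diffusion` (`i`, `j`, `flux`) and
#'   `membrane` (`cell`, `side`, `pixel`, `wall`, `flux`).
#' @export
compute_flux_field <- function(field, model) {
  stopifnot(inherits(field, "concentration_field"),
            inherits(model, "tissue_model"))
  C <- field$values
  ld <- model$links$diffusion
  lm_ <- model$links$membrane
  list(diffusion = data.frame(i = ld$i, j = ld$j,
                              flux = ld$g * (C[ld$i] - C[ld$j])),
       membrane = data.frame(cell = lm_$cell, side = lm_$side,
                             pixel = lm_$pixel, wall = lm_$wall,
                             flux = lm_$edge *
                               (lm_$efflux * C[lm_$pixel] -
                                  lm_$influx * C[lm_$wall])))
}

#' Net shootward (axial) flux through each cell
#'
#' Sums the membrane fluxes through the apical and basal faces of every cell
#' into a single net axial transport number (positive = shootward, away from
#' the tip), a compact readout of the circulation pattern.
#'
#' @inheritParams step
#' @return Data frame with `cell`, `type`, `file` and `axial_flux` (a.u./s).
#' @export
axial_cell_flux <- function(field, model) {
  fx <- compute_flux_field(field, model)$membrane
  up <- tapply(ifelse(fx$side == "apical", fx$flux,
                      ifelse(fx$side == "basal", -fx$flux, 0)),
               fx$cell, sum)
  cells <- model$layout$cells
  i <- match(as.integer(names(up)), cells$id)
  data.frame(cell = as.integer(names(up)), type = cells$type[i],
             file = cells$file[i], axial_flux = as.numeric(up))
}
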