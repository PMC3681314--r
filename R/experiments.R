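## Scenario-level experiments: mechanism presets, establishment dynamics,
## influx-cut + QC-ablation, robustness scans, and threshold zonation.

#' Assemble layout, permeability map and parameters for a mechanism
#'
#' Encodes the study conditions of the mechanism comparison: the full
#' minimal-root layout for source-decay and reflux-loop, the reduced
#' (vascular + pericycle + QC) layout for unidirectional transport; influx
#' from the shoot over the proximal vascular boundary for the transported
#' mechanisms and production inside the QC for source-decay.
#'
#' Source-decay variants: `"default"` (auxin kinetics, d = 1e-6/s),
#' `"fast_decay"` (d = 0.06/s; when `match_mass` is `TRUE`, the production is
#' raised by the same factor so the steady total morphogen content J/d stays
#' that of the default), `"slow_diffusion"` (D scaled down to 0.01 um^2/s,
#' wall diffusion scaled with it).
#'
#' @param mechanism `"source_decay"`, `"unidirectional"`,
#'   `"unidirectional_backengineered"` or `"reflux_loop"`.
#' @param layout_config overrides for [build_root_layout()] (the desk-scale
#'   experiments use `segment_length = 1200`).
#' @param variant source-decay variant (see above).
#' @param match_mass scale fast-decay production to conserve total content.
#' @param params optional [transport_params()] overriding the preset.
#' @param ... passed to [assign_pin_map()].
#' @return List with `layout`, `map`, `params` and `mechanism`.
#' @export
mechanism_setup <- function(mechanism,
                            layout_config = list(),
                            variant = c("default", "fast_decay",
                                        "slow_diffusion"),
                            match_mass = TRUE,
                            params = NULL, ...) {
  mechanism <- match.arg(mechanism,
                         c("source_decay", "unidirectional",
                           "unidirectional_backengineered", "reflux_loop"))
  variant <- match.arg(variant)
  if (mechanism %in% c("unidirectional", "unidirectional_backengineered"))
    layout_config <- utils::modifyList(list(reduced = TRUE), layout_config)
  layout <- build_root_layout(layout_config)
  map <- assign_pin_map(layout, mechanism, ...)
  if (is.null(params)) {
    if (mechanism == "source_decay") {
      d0 <- 1e-6; J0 <- 1000
      params <- switch(
        variant,
        default = transport_params(d = d0, J_in = J0,
                                   influx_mode = "qc_source"),
        fast_decay = transport_params(
          d = 0.06, J_in = if (match_mass) J0 * 0.06 / d0 else J0,
          influx_mode = "qc_source"),
        slow_diffusion = transport_params(D_cyt = 0.01, D_wall = 0.01 / 15,
                                          d = d0, J_in = J0,
                                          influx_mode = "qc_source"))
    } else {
      params <- transport_params(influx_mode = "proximal_vascular_boundary")
    }
  }
  list(mechanism = mechanism, layout = layout, map = map, params = params)
}

#' Default exponential-fit window for a gradient profile
#'
#' From two cell lengths above the concentration maximum (excluding the
#' accumulation spike at the QC) down to the detected elbow; when no elbow is
#' found the window extends over the remainder of the profile.
#'
#' @param profile a `longitudinal_profile`.
#' @param cell_length meristem cell length, um.
#' @return `c(from, to)` in um.
#' @export
default_fit_window <- function(profile, cell_length = 16) {
  pos <- profile$position_um
  from <- pos[which.max(profile$concentration_au)] + 2 * cell_length
  distal <- profile[pos >= from & profile$concentration_au > 0, ,
                    drop = FALSE]
  class(distal) <- class(profile)
  elbow <- if (nrow(distal) >= 11) detect_elbow(distal) else NA_real_
  to <- if (is.finite(elbow)) elbow else max(pos)
  if (to <= from) to <- max(pos)
  c(from, to)
}

#' Fit the gradient of a simulated field along a cell file
#'
#' Convenience wrapper: extract the longitudinal profile, choose the default
#' window ([default_fit_window()]) and fit the exponential.
#'
#' @param field,model as in [extract_profile()].
#' @param file_selector cell file (default `"vascular"`).
#' @param window optional explicit window.
#' @return A `gradient_fit` with the profile attached as attribute
#'   `"profile"`.
#' @export
fit_gradient <- function(field, model, file_selector = "vascular",
                         window = NULL) {
  pr <- extract_profile(field, model, file_selector, per_cell = TRUE)
  if (is.null(window))
    window <- default_fit_window(pr, model$layout$config$mz_cell_length)
  fit <- fit_exponential(pr, window)
  attr(fit, "profile") <- pr
  fit
}

#' Define a simulation scenario
#'
#' A mechanism plus layout, parameters, a time-stamped event list and an
#' output schedule -- a fully deterministic description of one experiment.
#'
#' @param mechanism see [mechanism_setup()].
#' @param layout_config,variant,params,... forwarded to [mechanism_setup()].
#' @param init `"zero"` (establishment experiments) or `"steady"`
#'   (perturbation experiments start from the steady state).
#' @param events list of events, each
#'   `list(time =, type =, ...)` with `type` one of `"cut_influx"`,
#'   `"ablate"` (optional `selector`), `"rescale_permeabilities"` (`factor`),
#'   `"set_polarity_ratio"` (`factor`, optional `file_types`).  Must be
#'   sorted by time.
#' @param schedule strictly increasing output times, s (non-empty).
#' @param seed random seed recorded for provenance (the runs themselves are
#'   deterministic).
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(mechanism, layout_config = list(),
                     variant = "default", params = NULL,
                     init = c("zero", "steady"),
                     events = list(), schedule, seed = NULL, ...) {
  init <- match.arg(init)
  if (missing(schedule) || length(schedule) == 0)
    stop("scenario validation: schedule must be a non-empty vector of ",
         "output times", call. = FALSE)
  stopifnot(is.numeric(schedule), all(schedule > 0),
            !is.unsorted(schedule, strictly = TRUE))
  ev_times <- vapply(events, function(e) as.numeric(e$time), numeric(1))
  if (length(events) && is.unsorted(ev_times))
    stop("scenario validation: events must be sorted by time", call. = FALSE)
  ok_types <- c("cut_influx", "ablate", "rescale_permeabilities",
                "set_polarity_ratio")
  for (e in events)
    if (!e$type %in% ok_types)
      stop("scenario validation: unknown event type '", e$type, "'",
           call. = FALSE)
  structure(list(mechanism = mechanism, layout_config = layout_config,
                 variant = variant, params = params, init = init,
                 events = events, schedule = schedule, seed = seed,
                 map_args = list(...)),
            class = "scenario")
}

apply_event <- function(state, e) {
  if (e$type == "cut_influx") {
    state$params$J_in <- 0
  } else if (e$type == "ablate") {
    sel <- if (is.null(e$selector)) "quiescent_centre" else e$selector
    ids <- select_cells(state$layout, sel)
    if (length(ids) == 0)
      stop("ablation event selector matched no cells", call. = FALSE)
    state$layout <- ablate_cells(state$layout, ids)
  } else if (e$type == "rescale_permeabilities") {
    state$map <- scale_permeabilities(state$map, e$factor)
  } else if (e$type == "set_polarity_ratio") {
    ft <- if (is.null(e$file_types))
      c("endodermis", "cortex", "epidermis") else e$file_types
    state$map <- set_polarity_ratio(state$map, e$factor, ft, state$layout)
  }
  state
}

## Carry a field across an operator rebuild (e.g. after ablation) by matching
## compartments on kind and centre coordinates; vanished compartments drop
## their content with the ablated cells.
transfer_field <- function(field, old_model, new_model) {
  key <- function(m) paste0(m$comp$kind, "_", round(m$comp$x, 6), "_",
                            round(m$comp$y, 6))
  i <- match(key(new_model), key(old_model))
  v <- ifelse(is.na(i), 0, field$values[i])
  new_field(new_model, v, time = field$time)
}

#' Run a scenario
#'
#' Builds the mechanism's model, initialises the field (`"zero"` or the
#' computed steady state), applies the events atomically at their times
#' (rebuilding the transport operator when an event changes geometry,
#' permeabilities or influx) and records the field, the vascular -- and where
#' present epidermal -- profiles and the gradient fit at every schedule time.
#' Event validity (e.g. ablation selectors) is checked before any
#' integration starts.
#'
#' @param sc a [scenario()].
#' @param resolution optional override of the layout's grid resolution.
#' @return List of class `"scenario_result"`: `times`, `fields`, `profiles`,
#'   `fits`, `cell_means` (matrix times x cells) and the final `model`.
#' @export
run_scenario <- function(sc, resolution = NULL) {
  stopifnot(inherits(sc, "scenario"))
  setup <- do.call(mechanism_setup,
                   c(list(mechanism = sc$mechanism,
                          layout_config = sc$layout_config,
                          variant = sc$variant, params = sc$params),
                     sc$map_args))
  state <- setup[c("layout", "map", "params")]
  ## validate events against the initial layout before running
  for (e in sc$events)
    if (e$type == "ablate") {
      sel <- if (is.null(e$selector)) "quiescent_centre" else e$selector
      if (length(select_cells(state$layout, sel)) == 0)
        stop("event at t = ", e$time, " references missing cells",
             call. = FALSE)
    }
  model <- build_tissue_model(state$layout, state$map, state$params,
                              resolution)
  field <- if (sc$init == "steady") run_to_steady_state(model)
  else new_field(model)
  field$time <- 0

  ev <- sc$events
  ev_t <- vapply(ev, function(e) as.numeric(e$time), numeric(1))
  out_fields <- vector("list", length(sc$schedule))
  has_epi <- any(state$layout$cells$type == "epidermis")
  t_now <- 0
  for (k in seq_along(sc$schedule)) {
    t_target <- sc$schedule[k]
    repeat {
      nxt <- which(ev_t > t_now + 1e-12 & ev_t <= t_target)
      if (length(nxt) == 0) break
      nxt <- nxt[1L]
      if (ev_t[nxt] > t_now + 1e-9)
        field <- simulate_tissue(model, field,
                                 times = ev_t[nxt] - t_now)[[1L]]
      t_now <- ev_t[nxt]
      old_model <- model
      state <- apply_event(state, ev[[nxt]])
      model <- build_tissue_model(state$layout, state$map, state$params,
                                  resolution)
      field <- transfer_field(field, old_model, model)
      field$time <- t_now
      ev_t[nxt] <- -Inf
    }
    if (t_target > t_now + 1e-9)
      field <- simulate_tissue(model, field, times = t_target - t_now)[[1L]]
    t_now <- t_target
    out_fields[[k]] <- field
  }
  profiles <- lapply(out_fields, extract_profile, model = model,
                     file_selector = "vascular")
  fits <- lapply(out_fields, function(f)
    tryCatch(fit_gradient(f, model), error = function(e) NULL,
             warning = function(w) NULL))
  cm <- t(vapply(out_fields, cell_means, model = model,
                 FUN.VALUE = numeric(length(unique(model$comp$cell[
                   model$comp$kind == "cytosol"])))))
  res <- list(times = sc$schedule, fields = out_fields, profiles = profiles,
              epidermal_profiles = if (has_epi)
                lapply(out_fields, extract_profile, model = model,
                       file_selector = "epidermis") else NULL,
              fits = fits, cell_means = cm, model = model, scenario = sc)
  class(res) <- "scenario_result"
  res
}

#' Influx-cut plus QC-ablation experiment
#'
#' Starts from the steady state of the mechanism, then at `t = 0` stops all
#' influx/production and ablates the QC cells (their area becomes a no-flux
#' obstacle), and follows the response.  The summary reports, per surviving
#' cell, the maximum fold-change of its mean concentration relative to the
#' pre-ablation steady state, and, for mechanisms that show one, the region
#' with fold-change above 1.
#'
#' @param mechanism,variant,layout_config,params,... see [mechanism_setup()].
#' @param time_points output times after the perturbation, s.
#' @param increase_tol relative tolerance above which a cell counts as
#'   showing a post-ablation increase (default 0.01).  At the new dead end
#'   of the unidirectional mechanism the flux balance after ablation is
#'   exactly neutral in the cell-file caricature ((p+q)C[n-1] = qC[n] when
#'   the per-cell ratio is (p+q)/q), so discretised runs equilibrate within
#'   a fraction of a percent of the pre-ablation level in either direction;
#'   the tolerance separates that from genuine replenishment, which in the
#'   reflux loop reaches several-fold.
#' @param resolution optional grid override.
#' @return List of class `"ablation_result"` with `times`, `cell_means`
#'   (times x cells, first row = steady state), `fold_change` (per-cell
#'   maximum over the series), `increased` (cell ids with fold-change > 1),
#'   `total_mass` trace and the post-ablation `model`.
#' @export
run_ablation_experiment <- function(mechanism, variant = "default",
                                    layout_config = list(),
                                    time_points = c(60, 300, 600, 1200),
                                    increase_tol = 0.01,
                                    params = NULL, resolution = NULL, ...) {
  setup <- mechanism_setup(mechanism, layout_config, variant,
                           params = params, ...)
  model0 <- build_tissue_model(setup$layout, setup$map, setup$params,
                               resolution)
  steady <- run_to_steady_state(model0)
  cm0 <- cell_means(steady, model0)

  layout1 <- ablate_cells(setup$layout, "quiescent_centre")
  params1 <- setup$params; params1$J_in <- 0
  model1 <- build_tissue_model(layout1, setup$map, params1, resolution)
  f <- transfer_field(steady, model0, model1)
  f$time <- 0
  series <- simulate_tissue(model1, f, times = time_points)
  cm <- t(vapply(series, cell_means, model = model1,
                 FUN.VALUE = numeric(length(unique(
                   model1$comp$cell[model1$comp$kind == "cytosol"])))))
  base <- cm0[colnames(cm)]
  fold <- apply(cm, 2, max) / base
  masses <- c(total_mass(f, model1),
              vapply(series, total_mass, model = model1, numeric(1)))
  res <- list(mechanism = mechanism, variant = variant,
              times = time_points,
              steady_cell_means = cm0, cell_means = cm,
              fold_change = fold,
              increased = as.integer(names(fold))[fold > 1 + increase_tol],
              total_mass = masses, model = model1)
  class(res) <- "ablation_result"
  res
}

#' @export
#' @method print ablation_result
#' @noRd
print.ablation_result <- function(x, ...) {
  cat(sprintf(paste0("Influx cut + QC ablation (%s, %s): %d cells followed ",
                     "to t = %g s\n  max fold-change %.3g; %d cell(s) with ",
                     "post-ablation increase\n  total morphogen %.4g -> ",
                     "%.4g a.u.\n"),
              x$mechanism, x$variant, length(x$fold_change),
              max(x$times), max(x$fold_change), length(x$increased),
              x$total_mass[1], x$total_mass[length(x$total_mass)]))
  invisible(x)
}

#' Robustness scan of the reflux-loop gradient
#'
#' One steady-state run per multiplicative factor on the chosen knob:
#' `"uniform_permeability"` scales every efflux and influx permeability
#' (the net influx from the shoot is held constant, as the influx rate is
#' prescribed independently of the permeabilities);
#' `"polarity_ratio"` scales the lateral:apical permeability ratio of the
#' ground-tissue files.  Reports the fitted characteristic length and the
#' concentration maximum for each factor.
#'
#' @param factors positive multiplicative factors (1 = the base run).
#' @param knob which parameter axis to scan.
#' @param mechanism,layout_config,params,resolution,... forwarded to
#'   [mechanism_setup()]/[build_tissue_model()].
#' @param file_types ground-tissue files for the polarity knob.
#' @return Data frame of class `"robustness_scan"`, sorted by factor, with
#'   `factor`, `lambda_fit` (um) and `C_max` (a.u.).
#' @export
run_robustness_scan <- function(factors,
                                knob = c("uniform_permeability",
                                         "polarity_ratio"),
                                mechanism = "reflux_loop",
                                layout_config = list(segment_length = 1200),
                                file_types = c("endodermis", "cortex",
                                               "epidermis"),
                                params = NULL, resolution = NULL, ...) {
  knob <- match.arg(knob)
  if (any(factors <= 0))
    stop("scan factors must be positive", call. = FALSE)
  setup <- mechanism_setup(mechanism, layout_config, params = params, ...)
  rows <- lapply(factors, function(f) {
    map <- if (knob == "uniform_permeability")
      scale_permeabilities(setup$map, f)
    else set_polarity_ratio(setup$map, f, file_types, setup$layout)
    model <- build_tissue_model(setup$layout, map, setup$params, resolution)
    st <- run_to_steady_state(model)
    fit <- fit_gradient(st, model)
    data.frame(factor = f, lambda_fit = fit$lambda_fit,
               C_max = max(cell_means(st, model)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$factor), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("robustness_scan", "data.frame")
  out
}

#' Threshold-based zonation of a profile
#'
#' Reads positional information from a monotone gradient: for each threshold
#' (strictly decreasing, a 'high' then progressively 'lower' gene activation
#' levels), the zone boundary is the most proximal position where the
#' concentration still reaches the threshold (linear interpolation between
#' samples).  Thresholds above the profile maximum yield an empty zone
#' (`NA` boundary), not an error.
#'
#' @param profile a `longitudinal_profile` with positive concentrations.
#' @param thresholds strictly decreasing positive thresholds, a.u.
#' @param labels optional zone labels (length = number of thresholds).
#' @return List of class `"zonation_result"` with `thresholds`, `boundaries`
#'   (um, `NA` = empty zone) and `zones` (data frame `label`, `from`, `to`).
#' @examples
#' pr <- longitudinal_profile(seq(0, 200, 2), exp(-seq(0, 200, 2) / 30))
#' threshold_zonation(pr, c(exp(-1), exp(-2)))$boundaries  # 30, 60
#' @export
threshold_zonation <- function(profile, thresholds, labels = NULL) {
  stopifnot(inherits(profile, "longitudinal_profile"),
            all(profile$concentration_au > 0), length(thresholds) >= 1)
  if (is.unsorted(rev(thresholds), strictly = TRUE))
    stop("thresholds must be strictly decreasing", call. = FALSE)
  x <- profile$position_um
  y <- profile$concentration_au
  bound <- vapply(thresholds, function(th) {
    above <- which(y >= th)
    if (length(above) == 0) return(NA_real_)
    k <- max(above)
    if (k == length(x)) return(x[k])
    ## interpolate the crossing between sample k and k+1
    x[k] + (x[k + 1] - x[k]) * (y[k] - th) / (y[k] - y[k + 1])
  }, numeric(1))
  if (is.null(labels)) labels <- paste0("zone", seq_along(thresholds))
  from <- c(min(x), bound[-length(bound)])
  zones <- data.frame(label = labels, from = from, to = bound)
  structure(list(thresholds = thresholds, boundaries = bound, zones = zones),
            class = "zonation_result")
}

#' @export
#' @method print zonation_result
#' @noRd
print.zonation_result <- function(x, ...) {
  cat("Threshold zonation\n")
  for (i in seq_along(x$thresholds))
    cat(sprintf("  threshold %.4g -> boundary %s um\n", x$thresholds[i],
                ifelse(is.na(x$boundaries[i]), "empty",
                       sprintf("%.4g", x$boundaries[i]))))
  invisible(x)
}
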