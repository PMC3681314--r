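# Shared fixtures, memoised so expensive steady states are computed once per
# test run.  Everything is generated in code; no stored data.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Desk-scale (1200 um) steady states for the three mechanisms.
desk_reflux <- function() fixture("desk_reflux", function() {
  s <- mechanism_setup("reflux_loop", list(segment_length = 1200))
  m <- build_tissue_model(s$layout, s$map, s$params)
  list(setup = s, model = m, steady = run_to_steady_state(m))
})

desk_source_decay <- function() fixture("desk_source_decay", function() {
  s <- mechanism_setup("source_decay", list(segment_length = 1200))
  m <- build_tissue_model(s$layout, s$map, s$params)
  list(setup = s, model = m, steady = run_to_steady_state(m))
})

desk_unidirectional <- function() fixture("desk_unidirectional", function() {
  s <- mechanism_setup("unidirectional", list(segment_length = 1200))
  m <- build_tissue_model(s$layout, s$map, s$params)
  list(setup = s, model = m, steady = run_to_steady_state(m))
})

# A small full layout for cheap structural tests.
small_reflux_model <- function() fixture("small_reflux", function() {
  s <- mechanism_setup("reflux_loop", list(segment_length = 300))
  m <- build_tissue_model(s$layout, s$map, s$params)
  list(setup = s, model = m)
})

# Tiny closed two-cell system (no influx, no decay) for conservation and
# membrane-equilibrium tests.
tiny_closed_model <- function(efflux = 5) {
  lay <- build_root_layout(list(
    segment_length = 16, mz_length = 0, reduced = TRUE,
    files_half = data.frame(type = "vascular", width = 10)))
  pm <- assign_pin_map(lay, "source_decay",
                       rules = data.frame(
                         type = "quiescent_centre",
                         side = c("apical", "basal", "lateral_inner",
                                  "lateral_outer"),
                         efflux = efflux))
  par <- transport_params(J_in = 0)
  par$d <- 0
  list(layout = lay, map = pm, model = build_tissue_model(lay, pm, par))
}

# Mirror-image compartment permutation of a model (matches on kind + centre).
mirror_index <- function(model) {
  w <- model$layout$domain$width
  key <- paste0(model$comp$kind, "_", round(model$comp$y, 6), "_",
                round(model$comp$x, 6))
  mkey <- paste0(model$comp$kind, "_", round(model$comp$y, 6), "_",
                 round(w - model$comp$x, 6))
  match(mkey, key)
}
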