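## Tissue-specific PIN permeability maps.  Efflux permeabilities are drawn
## from three levels -- strong PIN expression (20 um/s), weak PIN expression
## (5 um/s) and carrier-free background (1 um/s) -- while influx is apolar
## everywhere (20 um/s, chemiosmotic uptake plus AUX/LAX carriers).  The
## tissue-by-tissue assignment ships as a reconstructed default (observed PIN
## distributions are only described qualitatively) and every entry can be
## overridden through `rules`.

#' Assign a mechanism-specific PIN permeability map to a layout
#'
#' Produces one efflux and one influx permeability per membrane segment of
#' the layout, following the mechanism being modelled:
#'
#' * `reflux_loop` -- basal (rootward) PINs on the vascular and pericycle
#'   files, apical (shootward) PINs on the outer files, lateral inward-facing
#'   PINs across the ground tissue (weak level by default, which reproduces
#'   the tissue-scale gradient length of the reflux loop in this geometry),
#'   apolar PINs in the columella; the QC carries weak apolar expression.
#' * `source_decay` -- strong PIN expression on all sides of every cell, so
#'   polar transport plays no role and exchange is diffusion-like.
#' * `unidirectional` -- basal-only PINs in the vascular and pericycle files
#'   (intended for the reduced layout); everything else at background.
#' * `unidirectional_backengineered` -- as `unidirectional` plus apical PINs
#'   at 85% of the basal strength, the modification needed to flatten the
#'   per-cell ratio to a usable characteristic length.
#'
#' @param layout a [build_root_layout()] layout.
#' @param mechanism one of `"source_decay"`, `"unidirectional"`,
#'   `"unidirectional_backengineered"`, `"reflux_loop"`.
#' @param pin_strong,pin_weak,p_bg,p_aux permeability levels in um/s
#'   (defaults 20, 5, 1 and 20).
#' @param lateral_strength named numeric: lateral inward efflux per
#'   ground-tissue type for the reflux map.  Default
#'   `c(endodermis = pin_weak, cortex = pin_weak, epidermis = pin_weak)`.
#' @param rules optional data frame with `type`, `side`, `efflux` rows applied
#'   last, overriding any default assignment.
#' @return A `pin_map`: data frame with `cell`, `side`, `efflux`, `influx`
#'   (um/s) and attribute `mechanism`.
#' @examples
#' lay <- build_root_layout(list(segment_length = 300))
#' pm <- assign_pin_map(lay, "reflux_loop")
#' subset(pm, side == "basal" & efflux > 1)[1:3, ]
#' @export
assign_pin_map <- function(layout, mechanism,
                           pin_strong = 20, pin_weak = 5,
                           p_bg = 1, p_aux = 20,
                           lateral_strength = NULL, rules = NULL) {
  stopifnot(inherits(layout, "root_layout"))
  mechanism <- match.arg(mechanism,
                         c("source_decay", "unidirectional",
                           "unidirectional_backengineered", "reflux_loop"))
  seg <- membrane_segments(layout)
  type_of <- setNames(layout$cells$type, layout$cells$id)
  seg$type <- type_of[as.character(seg$cell)]
  seg$efflux <- p_bg
  seg$influx <- p_aux
  set <- function(types, sides, value) {
    hit <- seg$type %in% types & seg$side %in% sides
    seg$efflux[hit] <<- value
  }
  if (mechanism == "source_decay") {
    set(cell_types, c("apical", "basal", "lateral_inner", "lateral_outer"),
        pin_strong)
  } else if (mechanism %in% c("unidirectional",
                              "unidirectional_backengineered")) {
    set(c("vascular", "pericycle"), "basal", pin_strong)
    if (mechanism == "unidirectional_backengineered")
      set(c("vascular", "pericycle"), "apical", 0.85 * pin_strong)
  } else { # reflux_loop
    if (is.null(lateral_strength))
      lateral_strength <- c(endodermis = pin_weak, cortex = pin_weak,
                            epidermis = pin_weak)
    set(c("vascular", "pericycle"), "basal", pin_strong)
    set(c("endodermis", "cortex", "epidermis"), "apical", pin_strong)
    for (ty in names(lateral_strength))
      set(ty, "lateral_inner", lateral_strength[[ty]])
    set("columella", c("apical", "basal", "lateral_inner", "lateral_outer"),
        pin_strong)
    set("quiescent_centre",
        c("apical", "basal", "lateral_inner", "lateral_outer"), pin_weak)
  }
  if (!is.null(rules)) {
    stopifnot(all(c("type", "side", "efflux") %in% names(rules)))
    for (i in seq_len(nrow(rules)))
      set(rules$type[i], rules$side[i], rules$efflux[i])
  }
  out <- seg[, c("cell", "side", "length", "neighbour", "efflux", "influx")]
  structure(out, class = c("pin_map", "data.frame"), mechanism = mechanism)
}

#' Scale all permeabilities of a map
#'
#' Multiplies every segment's efflux and influx permeability by the given
#' factors (used by the uniform-permeability robustness scan, where the net
#' influx from the shoot is held constant separately).
#'
#' @param map a `pin_map`.
#' @param factor_efflux,factor_influx positive multipliers.
#' @return The rescaled `pin_map`.
#' @export
scale_permeabilities <- function(map, factor_efflux = 1,
                                 factor_influx = factor_efflux) {
  stopifnot(inherits(map, "pin_map"), factor_efflux > 0, factor_influx > 0)
  map$efflux <- map$efflux * factor_efflux
  map$influx <- map$influx * factor_influx
  map
}

#' Rescale the lateral:apical permeability ratio of the ground tissue
#'
#' Multiplies the lateral inward-facing efflux permeability of the selected
#' ground-tissue files by `lateral_to_apical_factor`, leaving apical/basal
#' values untouched -- i.e. the lateral:apical ratio changes by exactly that
#' factor on those files.  This is the cell-polarity knob that controls the
#' reflux-loop gradient's steepness.
#'
#' @param map a `pin_map`.
#' @param lateral_to_apical_factor positive multiplier.
#' @param file_types cell types to modify (subset of the ground tissue;
#'   default all lateral-PIN-bearing outer files).
#' @param layout the layout the map was built on (needed to resolve types).
#' @return The modified `pin_map`.
#' @export
set_polarity_ratio <- function(map, lateral_to_apical_factor,
                               file_types = c("endodermis", "cortex",
                                              "epidermis"),
                               layout) {
  stopifnot(inherits(map, "pin_map"), lateral_to_apical_factor > 0,
            all(file_types %in% c("endodermis", "cortex", "epidermis")),
            inherits(layout, "root_layout"))
  type_of <- setNames(layout$cells$type, layout$cells$id)
  hit <- type_of[as.character(map$cell)] %in% file_types &
    map$side == "lateral_inner"
  map$efflux[hit] <- map$efflux[hit] * lateral_to_apical_factor
  map
}
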