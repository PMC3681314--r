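test_that("default layout follows the zone rules and carries QC and columella", {
  lay <- build_root_layout(list(segment_length = 600))
  cells <- lay$cells
  # 16 um cells in the meristem, 60 um in the elongation zone, 0.5 um walls
  expect_true(all((cells$y1 - cells$y0)[cells$zone == "MZ"] == 16))
  expect_true(all((cells$y1 - cells$y0)[cells$zone == "EZ"] == 60))
  expect_equal(lay$config$wall_thickness, 0.5)
  expect_setequal(unique(cells$type),
                  c("vascular", "pericycle", "endodermis", "cortex",
                    "epidermis", "quiescent_centre", "columella"))
  # three columella tiers distal to the QC
  expect_equal(length(unique(cells$row[cells$type == "columella"])), 3)
  expect_lt(max(cells$y1[cells$type == "columella"]),
            min(cells$y1[cells$type == "quiescent_centre"]) + 1e-9)
  # footprints tile without overlap: total cell area = domain area
  expect_equal(sum((cells$x1 - cells$x0) * (cells$y1 - cells$y0)),
               lay$domain$width * lay$domain$length)
})

test_that("layout is mirror-symmetric about the root midline", {
  lay <- build_root_layout(list(segment_length = 400))
  cells <- lay$cells
  w <- lay$domain$width
  key <- paste(cells$type, cells$y0, round(cells$x0, 9))
  mirrored <- paste(cells$type, cells$y0, round(w - cells$x1, 9))
  expect_setequal(key, mirrored)
})

test_that("reduced layout keeps only the stele files plus the QC", {
  lay <- build_root_layout(list(segment_length = 300, reduced = TRUE))
  expect_setequal(unique(lay$cells$type),
                  c("vascular", "pericycle", "quiescent_centre"))
  # the QC row is the distal dead end (no columella below)
  expect_equal(min(lay$cells$y0[lay$cells$type == "quiescent_centre"]), 0)
})

test_that("explicit wall mode is rejected, interface mode tolerates coarse grids", {
  expect_error(build_root_layout(list(wall_mode = "explicit", resolution = 4)),
               "interface")
  expect_silent(build_root_layout(list(segment_length = 200, resolution = 4)))
})

test_that("ablation removes exactly the selected cells and keeps the rest", {
  lay <- build_root_layout(list(segment_length = 300))
  n_qc <- sum(lay$cells$type == "quiescent_centre")
  expect_gt(n_qc, 0)
  abl <- ablate_cells(lay)
  expect_equal(nrow(lay$cells) - nrow(abl$cells), n_qc)
  expect_equal(nrow(abl$obstacles), n_qc)
  expect_false(any(abl$cells$type == "quiescent_centre"))
  # the surviving geometry is untouched
  keep <- lay$cells$type != "quiescent_centre"
  expect_identical(abl$cells, lay$cells[keep, ])
  expect_error(ablate_cells(lay, character(0)), "no cells")
  expect_error(ablate_cells(lay, "no_such_type"), "no cells")
})

test_that("layout serialisation round-trips losslessly", {
  lay <- ablate_cells(build_root_layout(list(segment_length = 300)))
  path <- withr::local_tempfile(fileext = ".json")
  write_layout(lay, path)
  back <- read_layout(path)
  expect_identical(back$cells, lay$cells)
  expect_identical(back$obstacles$id, lay$obstacles$id)
  expect_equal(back$config, lay$config, ignore_attr = TRUE,
               tolerance = 0)   # JSON may re-type integers; values are exact
})

test_that("membrane segments cover all four sides of every cell", {
  lay <- build_root_layout(list(segment_length = 300))
  seg <- membrane_segments(lay)
  expect_equal(nrow(seg), 4 * nrow(lay$cells))
  expect_setequal(unique(seg$side),
                  c("apical", "basal", "lateral_inner", "lateral_outer"))
  # vertical neighbours agree on their shared interface length
  expect_true(all(seg$length[seg$side %in% c("apical", "basal")] %in%
                    (lay$files$x1 - lay$files$x0)))
})

test_that("mechanism maps assign every segment with the expected polarity", {
  lay <- build_root_layout(list(segment_length = 400))
  cells <- lay$cells
  for (mech in c("source_decay", "unidirectional",
                 "unidirectional_backengineered", "reflux_loop")) {
    pm <- assign_pin_map(lay, mech)
    expect_equal(nrow(pm), 4 * nrow(cells))   # no background holes
    expect_true(all(pm$efflux > 0))
    expect_true(all(pm$influx == 20))         # apolar influx everywhere
  }
  # source-decay: strong PIN on all sides of every cell
  pm_sd <- assign_pin_map(lay, "source_decay")
  expect_true(all(pm_sd$efflux == 20))
  # reflux: a vascular cell pumps basally at 20 um/s and leaks elsewhere
  pm_rf <- assign_pin_map(lay, "reflux_loop")
  vas <- cells$id[cells$type == "vascular"][1]
  vrows <- pm_rf[pm_rf$cell == vas, ]
  expect_equal(vrows$efflux[vrows$side == "basal"], 20)
  expect_true(all(vrows$efflux[vrows$side != "basal"] == 1))
  # outer files pump apically; ground tissue carries inward lateral PINs
  epi <- cells$id[cells$type == "epidermis"][1]
  erows <- pm_rf[pm_rf$cell == epi, ]
  expect_equal(erows$efflux[erows$side == "apical"], 20)
  expect_gt(erows$efflux[erows$side == "lateral_inner"], 1)
  # columella: apolar strong expression on all sides
  col <- cells$id[cells$type == "columella"][1]
  expect_true(all(pm_rf$efflux[pm_rf$cell == col] == 20))
  # back-engineered unidirectional: apical/basal efflux ratio exactly 0.85
  pm_be <- assign_pin_map(lay, "unidirectional_backengineered")
  brows <- pm_be[pm_be$cell == vas, ]
  expect_equal(brows$efflux[brows$side == "apical"] /
                 brows$efflux[brows$side == "basal"], 0.85)
  expect_error(assign_pin_map(lay, "osmosis"))
})

test_that("mirror symmetry of the layout implies mirror symmetry of every map", {
  lay <- build_root_layout(list(segment_length = 300))
  cells <- lay$cells
  w <- lay$domain$width
  mirror_id <- cells$id[match(paste(cells$y0, round(w - cells$x1, 9)),
                              paste(cells$y0, round(cells$x0, 9)))]
  names(mirror_id) <- cells$id
  for (mech in c("source_decay", "unidirectional", "reflux_loop")) {
    pm <- assign_pin_map(lay, mech)
    key <- paste(pm$cell, pm$side)
    # lateral_inner maps to lateral_inner under mirroring (inner = midline)
    mkey <- paste(mirror_id[as.character(pm$cell)], pm$side)
    expect_equal(pm$efflux, pm$efflux[match(key, mkey)])
  }
})

test_that("permeability rescaling operations compose and invert exactly", {
  lay <- build_root_layout(list(segment_length = 300))
  pm <- assign_pin_map(lay, "reflux_loop")
  expect_identical(scale_permeabilities(pm, 1, 1), pm)
  up <- scale_permeabilities(pm, 1000)
  expect_equal(up$efflux, pm$efflux * 1000)
  expect_equal(up$influx, pm$influx * 1000)
  expect_equal(scale_permeabilities(up, 1 / 1000), pm)
  expect_error(scale_permeabilities(pm, -1))
  # polarity knob: doubles the lateral:apical ratio exactly on chosen files
  pol <- set_polarity_ratio(pm, 2, c("epidermis", "cortex"), lay)
  sel_types <- lay$cells$type[match(pm$cell, lay$cells$id)]
  hit <- sel_types %in% c("epidermis", "cortex") & pm$side == "lateral_inner"
  expect_equal(pol$efflux[hit], 2 * pm$efflux[hit])
  expect_equal(pol$efflux[!hit], pm$efflux[!hit])
  expect_equal(set_polarity_ratio(pol, 0.5, c("epidermis", "cortex"), lay),
               pm)
  expect_identical(set_polarity_ratio(pm, 1, layout = lay), pm)
})
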