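## Minimal-root tissue template: axis-aligned rectangular cells on a global
## row/file grid, mirror-symmetric about the root midline, distal tip at y = 0.
## Cell footprints are half-open intervals so the tiling is exact; the 0.5 um
## apoplast around every cell is represented as sub-grid "interface wall"
## compartments attached to membrane segments (see build_tissue_model).

cell_types <- c("vascular", "pericycle", "endodermis", "cortex", "epidermis",
                "quiescent_centre", "columella")

default_layout_config <- function() {
  list(
    segment_length = 3000,      # um, simulated segment (distal tip at 0)
    resolution = 4,             # um per cytosol pixel (target)
    wall_thickness = 0.5,       # um, nominal apoplast thickness
    wall_mode = "interface",
    mz_length = 350,            # um of meristem above the QC
    mz_cell_length = 16,        # um
    ez_cell_length = 60,        # um
    columella_tiers = 3,
    columella_tier_length = 16, # um
    qc_row_length = 16,         # um
    ## half-root files from the midline outward; mirrored to the full root
    files_half = data.frame(
      type = c("vascular", "pericycle", "endodermis", "cortex", "epidermis"),
      width = c(10, 8, 10, 12, 10)),
    reduced = FALSE             # vascular + pericycle + QC only
  )
}

#' Build the minimal-root tissue layout
#'
#' Generates the cell-resolution root segment used by the tissue simulator: a
#' mirror-symmetric arrangement of longitudinal cell files (vascular,
#' pericycle, endodermis, cortex, epidermis from the midline outward), a
#' quiescent-centre (QC) row capping the central files, and columella tiers
#' distal to the QC.  Cell lengths follow the zone rule: `mz_cell_length`
#' (16 um) in the meristem, `ez_cell_length` (60 um) in the elongation zone;
#' every cell is surrounded by an apoplast of `wall_thickness` (0.5 um),
#' carried as interface compartments rather than raster pixels.
#'
#' @param config named list overriding entries of the default configuration:
#'   `segment_length` (um, default 3000), `resolution` (um per cytosol pixel),
#'   `wall_thickness`, `wall_mode` (`"interface"` only), `mz_length`,
#'   `mz_cell_length`, `ez_cell_length`, `columella_tiers`,
#'   `columella_tier_length`, `qc_row_length`, `files_half` (data frame with
#'   `type`, `width` from the midline outward), and `reduced` (`TRUE` keeps
#'   only vascular and pericycle files plus the QC, the template used for the
#'   unidirectional mechanism).
#' @return An object of class `"root_layout"`: list with `cells` (data frame
#'   of footprints with `id`, `row`, `col`, `type`, `file`, `zone`,
#'   `x0`/`x1`/`y0`/`y1`), `rows`, `files`, `domain`, `obstacles`, and the
#'   resolved `config`.
#' @examples
#' lay <- build_root_layout(list(segment_length = 400))
#' table(lay$cells$type)
#' @export
build_root_layout <- function(config = list()) {
  cfg <- utils::modifyList(default_layout_config(), config)
  ## modifyList merges data frames column-wise; the file table is atomic
  if (!is.null(config$files_half))
    cfg$files_half <- as.data.frame(config$files_half)
  if (!identical(cfg$wall_mode, "interface")) {
    if (cfg$resolution > cfg$wall_thickness)
      stop("resolution coarser than the wall thickness requires the ",
           "interface-wall mode", call. = FALSE)
    stop("explicit wall-pixel mode is not implemented; use wall_mode = ",
         "\"interface\"", call. = FALSE)
  }
  stopifnot(cfg$segment_length > 0, cfg$resolution > 0,
            cfg$wall_thickness > 0, cfg$mz_cell_length > 0,
            cfg$ez_cell_length > 0, cfg$columella_tiers >= 0)
  fh <- cfg$files_half
  if (isTRUE(cfg$reduced))
    fh <- fh[fh$type %in% c("vascular", "pericycle"), , drop = FALSE]
  stopifnot(nrow(fh) >= 1, all(fh$type %in% cell_types), all(fh$width > 0))

  ## files: mirror half-root about the midline
  files <- data.frame(
    col = seq_len(2L * nrow(fh)),
    type = c(rev(fh$type), fh$type),
    width = c(rev(fh$width), fh$width),
    side = rep(c("L", "R"), each = nrow(fh)),
    stringsAsFactors = FALSE)
  files$file <- paste0(files$type, "_", files$side)
  files$x0 <- cumsum(c(0, files$width))[seq_len(nrow(files))]
  files$x1 <- files$x0 + files$width
  width_total <- sum(files$width)

  ## rows from the distal tip upward
  n_col <- if (isTRUE(cfg$reduced)) 0L else as.integer(cfg$columella_tiers)
  kind <- c(rep("columella", n_col), "qc")
  len <- c(rep(cfg$columella_tier_length, n_col), cfg$qc_row_length)
  y_top <- sum(len)
  qc_top <- y_top
  while (y_top < qc_top + cfg$mz_length - 1e-9) {
    kind <- c(kind, "mz"); len <- c(len, cfg$mz_cell_length)
    y_top <- y_top + cfg$mz_cell_length
  }
  while (y_top < cfg$segment_length - 1e-9) {
    kind <- c(kind, "ez"); len <- c(len, cfg$ez_cell_length)
    y_top <- y_top + cfg$ez_cell_length
  }
  rows <- data.frame(row = seq_along(kind), kind = kind, length = len)
  rows$y0 <- cumsum(c(0, len))[seq_len(nrow(rows))]
  rows$y1 <- rows$y0 + rows$length

  ## cells on the row x file grid
  grid <- expand.grid(row = rows$row, col = files$col)
  cells <- data.frame(
    id = seq_len(nrow(grid)),
    row = grid$row, col = grid$col,
    type = files$type[grid$col],
    file = files$file[grid$col],
    zone = c(columella = "columella", qc = "MZ", mz = "MZ",
             ez = "EZ")[rows$kind[grid$row]],
    x0 = files$x0[grid$col], x1 = files$x1[grid$col],
    y0 = rows$y0[grid$row], y1 = rows$y1[grid$row],
    stringsAsFactors = FALSE)
  kind_of <- rows$kind[cells$row]
  cells$type[kind_of == "columella"] <- "columella"
  cells$file[kind_of == "columella"] <-
    paste0("columella_", files$side[cells$col[kind_of == "columella"]])
  central <- cells$type %in% c("vascular", "pericycle")
  qc_sel <- kind_of == "qc" & central
  cells$type[qc_sel] <- "quiescent_centre"
  cells$file[qc_sel] <- paste0("quiescent_centre_",
                               files$side[cells$col[qc_sel]])
  cells$zone[kind_of == "columella"] <- "columella"

  structure(list(cells = cells, rows = rows, files = files,
                 domain = list(width = width_total, length = y_top),
                 obstacles = cells[0, c("id", "x0", "x1", "y0", "y1")],
                 config = cfg),
            class = "root_layout")
}

#' @export
#' @method print root_layout
#' @noRd
print.root_layout <- function(x, ...) {
  cat(sprintf("Minimal-root layout: %d cells (%d files x %d rows), %g x %g um\n",
              nrow(x$cells), nrow(x$files), nrow(x$rows),
              x$domain$width, x$domain$length))
  print(table(x$cells$type))
  if (nrow(x$obstacles))
    cat(sprintf("  %d ablated cell footprint(s) held as no-flux obstacles\n",
                nrow(x$obstacles)))
  invisible(x)
}

#' Plot a root layout as a cell-type map
#'
#' @param x a `root_layout`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.root_layout <- function(x, ...) {
  pal <- c(vascular = "firebrick", pericycle = "orange",
           endodermis = "gold", cortex = "forestgreen",
           epidermis = "steelblue", quiescent_centre = "grey40",
           columella = "cyan3")
  graphics::plot(NA, xlim = c(0, x$domain$width),
                 ylim = c(0, x$domain$length), asp = 1,
                 xlab = "x (um)", ylab = "y (um, distal tip at 0)", ...)
  with(x$cells, graphics::rect(x0, y0, x1, y1, col = pal[type],
                               border = "black", lwd = 0.3))
  if (nrow(x$obstacles))
    with(x$obstacles, graphics::rect(x0, y0, x1, y1, col = "black"))
  invisible(x)
}

#' Select cells of a layout
#'
#' Selector used by [ablate_cells()] and the scenario events: a character
#' vector of cell types and/or file names, a vector of cell ids, or a
#' predicate `function(cells) -> logical`.
#'
#' @param layout a `root_layout`.
#' @param selector the selection (default `"quiescent_centre"`).
#' @return Integer cell ids.
#' @export
select_cells <- function(layout, selector = "quiescent_centre") {
  cells <- layout$cells
  if (is.function(selector)) return(cells$id[which(selector(cells))])
  if (is.character(selector))
    return(cells$id[cells$type %in% selector | cells$file %in% selector])
  if (is.numeric(selector)) return(cells$id[cells$id %in% selector])
  stop("unsupported cell selector", call. = FALSE)
}

#' Ablate cells: turn their footprints into no-flux obstacles
#'
#' Removes the selected cells from the layout and records their footprints as
#' impermeable obstacles: no morphogen can enter or leave the region they
#' occupied (their membrane fluxes vanish; the surrounding apoplast remains).
#' All other geometry is unchanged.
#'
#' @param layout a `root_layout`.
#' @param cell_selector see [select_cells()]; defaults to the QC cells.
#' @return The modified `root_layout`.
#' @examples
#' lay <- build_root_layout(list(segment_length = 300))
#' abl <- ablate_cells(lay)          # removes the QC
#' nrow(lay$cells) - nrow(abl$cells)
#' @export
ablate_cells <- function(layout, cell_selector = "quiescent_centre") {
  stopifnot(inherits(layout, "root_layout"))
  ids <- select_cells(layout, cell_selector)
  if (length(ids) == 0)
    stop("cell selector matched no cells; nothing to ablate", call. = FALSE)
  sel <- layout$cells$id %in% ids
  layout$obstacles <- rbind(layout$obstacles,
                            layout$cells[sel, c("id", "x0", "x1", "y0", "y1")])
  layout$cells <- layout$cells[!sel, , drop = FALSE]
  layout
}

#' Serialise a layout to JSON
#'
#' Writes the resolved configuration plus the ids of any ablated cells; the
#' layout is rebuilt deterministically from these on read, so the round trip
#' is lossless.  The full cell table is embedded alongside for inspection by
#' other tools.
#'
#' @param layout a `root_layout`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "root_layout"))
  cfg <- layout$config
  cfg$files_half <- as.list(cfg$files_half)
  jsonlite::write_json(
    list(format = "rootflux_layout", version = 1L,
         config = cfg, ablated = layout$obstacles$id,
         cells = layout$cells),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a layout written by [write_layout()]
#'
#' @param path JSON file.
#' @return A `root_layout`.
#' @export
read_layout <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(spec$format, "rootflux_layout"))
    stop("not a rootflux layout file: ", path, call. = FALSE)
  cfg <- spec$config
  cfg$files_half <- as.data.frame(cfg$files_half)
  lay <- build_root_layout(cfg)
  if (length(spec$ablated)) lay <- ablate_cells(lay, as.numeric(spec$ablated))
  lay
}

#' Membrane segments of a layout
#'
#' One oriented segment per cell side (`apical` = shootward face, `basal` =
#' rootward face, `lateral_inner` = facing the midline, `lateral_outer` =
#' facing away).  `neighbour` is the adjacent cell id, or `NA` where the side
#' faces the domain boundary or an ablated obstacle.
#'
#' @param layout a `root_layout`.
#' @return Data frame with `cell`, `side`, `length` (um) and `neighbour`.
#' @export
membrane_segments <- function(layout) {
  cells <- layout$cells
  mid <- layout$domain$width / 2
  idx <- matrix(NA_integer_, nrow(layout$rows), nrow(layout$files))
  idx[cbind(cells$row, cells$col)] <- cells$id
  nb <- function(dr, dc) {
    r <- cells$row + dr; c <- cells$col + dc
    ok <- r >= 1 & r <= nrow(idx) & c >= 1 & c <= ncol(idx)
    out <- rep(NA_integer_, nrow(cells))
    out[ok] <- idx[cbind(r[ok], c[ok])]
    out
  }
  inner_right <- (cells$x0 + cells$x1) / 2 < mid   # inner face is the +x side
  seg <- rbind(
    data.frame(cell = cells$id, side = "apical",
               length = cells$x1 - cells$x0, neighbour = nb(1L, 0L)),
    data.frame(cell = cells$id, side = "basal",
               length = cells$x1 - cells$x0, neighbour = nb(-1L, 0L)),
    data.frame(cell = cells$id, side = "lateral_inner",
               length = cells$y1 - cells$y0,
               neighbour = ifelse(inner_right, nb(0L, 1L), nb(0L, -1L))),
    data.frame(cell = cells$id, side = "lateral_outer",
               length = cells$y1 - cells$y0,
               neighbour = ifelse(inner_right, nb(0L, -1L), nb(0L, 1L))))
  rownames(seg) <- NULL
  seg
}
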