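#' Transport parameters for the tissue simulator
#'
#' @param D_cyt intracellular diffusion coefficient, um^2/s (default 600).
#' @param D_wall apoplastic diffusion coefficient, um^2/s (default 40, i.e.
#'   15-fold reduced relative to the cytosol).
#' @param d first-order decay rate, 1/s (default 1e-6, an ~8-day half-life).
#' @param J_in total influx or production rate, a.u./s (default 1000).
#' @param influx_mode where morphogen enters: `"proximal_vascular_boundary"`
#'   distributes `J_in` over the shootward boundary walls of the vascular and
#'   pericycle files (biosynthesis in the shoot, delivery by the stele);
#'   `"qc_source"` produces `J_in` uniformly inside the QC cells (the
#'   localised source of the source-decay mechanism).
#' @return An object of class `"transport_params"`.
#' @export
transport_params <- function(D_cyt = 600, D_wall = 40, d = 1e-6,
                             J_in = 1000,
                             influx_mode = c("proximal_vascular_boundary",
                                             "qc_source")) {
  influx_mode <- match.arg(influx_mode)
  stopifnot(D_cyt > 0, D_wall > 0, d >= 0, J_in >= 0)
  structure(list(D_cyt = D_cyt, D_wall = D_wall, d = d, J_in = J_in,
                 influx_mode = influx_mode),
            class = "transport_params")
}

#' @export
#' @method print transport_params
#' @noRd
print.transport_params <- function(x, ...) {
  cat(sprintf(paste0("Transport parameters: D_cyt = %g, D_wall = %g um^2/s, ",
                     "d = %g /s,\n  J_in = %g a.u./s into %s\n"),
              x$D_cyt, x$D_wall, x$d, x$J_in, x$influx_mode))
  invisible(x)
}

## Pixel grid of one cell: centres, ids, and boundary bookkeeping.
cell_pixels <- function(x0, x1, y0, y1, h, offset) {
  nx <- max(1L, round((x1 - x0) / h))
  ny <- max(1L, round((y1 - y0) / h))
  wx <- (x1 - x0) / nx
  wy <- (y1 - y0) / ny
  idx <- matrix(offset + seq_len(nx * ny), nrow = ny, ncol = nx)
  list(nx = nx, ny = ny, wx = wx, wy = wy, idx = idx,
       x = x0 + (seq_len(nx) - 0.5) * wx,
       y = y0 + (seq_len(ny) - 0.5) * wy)
}

#' Compile a tissue model from layout, permeability map and parameters
#'
#' Discretises the layout into a finite-volume compartment system: every cell
#' interior becomes a grid of cytosol pixels (target spacing `resolution`,
#' diffusion `D_cyt`), every cell-cell or cell-boundary interface becomes one
#' apoplast compartment of nominal `wall_thickness` volume (diffusion
#' `D_wall` between walls meeting at cell corners), and every membrane
#' segment carries the carrier flux law
#' `flux = P_efflux * C_in - P_influx * C_out` from the permeability map.
#' Decay `-d*C` acts in every compartment and the influx enters according to
#' `influx_mode`.  The result is a sparse linear system `dC/dt = A C + b`
#' with a Metzler (positivity-preserving) matrix `A`.
#'
#' Membrane segments of ablated cells are absent, so former cell areas are
#' impermeable obstacles; the walls around them remain part of the apoplast.
#'
#' @param layout a [build_root_layout()] layout.
#' @param pin_map a matching [assign_pin_map()] map (keyed by cell and side;
#'   entries for ablated cells are ignored).
#' @param params a [transport_params()] object.
#' @param resolution cytosol pixel size in um (default: the layout's).
#' @return An object of class `"tissue_model"`; notably `comp` (compartment
#'   table with `kind`, `cell`, `x`, `y`, `volume`), `A`, `b`, and the link
#'   tables used for flux reconstruction.
#' @export
build_tissue_model <- function(layout, pin_map, params, resolution = NULL) {
  stopifnot(inherits(layout, "root_layout"), inherits(pin_map, "pin_map"),
            inherits(params, "transport_params"))
  h <- if (is.null(resolution)) layout$config$resolution else resolution
  stopifnot(h > 0)
  cells <- layout$cells
  t_wall <- layout$config$wall_thickness
  mid <- layout$domain$width / 2

  ## --- cytosol pixels -------------------------------------------------
  px <- vector("list", nrow(cells))
  offset <- 0L
  for (i in seq_len(nrow(cells))) {
    px[[i]] <- cell_pixels(cells$x0[i], cells$x1[i], cells$y0[i], cells$y1[i],
                           h, offset)
    offset <- offset + px[[i]]$nx * px[[i]]$ny
  }
  n_pix <- offset
  pix_x <- numeric(n_pix); pix_y <- numeric(n_pix)
  pix_vol <- numeric(n_pix); pix_cell <- integer(n_pix)
  di <- integer(0); dj <- integer(0); dg <- numeric(0)  # diffusion links
  for (i in seq_len(nrow(cells))) {
    g <- px[[i]]
    ids <- as.vector(g$idx)
    pix_x[ids] <- rep(g$x, each = g$ny)
    pix_y[ids] <- rep(g$y, times = g$nx)
    pix_vol[ids] <- g$wx * g$wy
    pix_cell[ids] <- cells$id[i]
    if (g$nx > 1L) {        # horizontal neighbours
      a <- as.vector(g$idx[, -g$nx, drop = FALSE])
      b2 <- as.vector(g$idx[, -1L, drop = FALSE])
      di <- c(di, a); dj <- c(dj, b2)
      dg <- c(dg, rep(params$D_cyt * g$wy / g$wx, length(a)))
    }
    if (g$ny > 1L) {        # vertical neighbours
      a <- as.vector(g$idx[-g$ny, , drop = FALSE])
      b2 <- as.vector(g$idx[-1L, , drop = FALSE])
      di <- c(di, a); dj <- c(dj, b2)
      dg <- c(dg, rep(params$D_cyt * g$wx / g$wy, length(a)))
    }
  }

  ## --- walls: one compartment per interface ---------------------------
  ## sides facing an ablated obstacle are sealed outright (no wall, no
  ## membrane exchange: the obstacle is a no-flux boundary), while domain
  ## boundary sides keep their apoplast compartment
  seg <- membrane_segments(layout)
  if (nrow(layout$obstacles)) {
    ci <- match(seg$cell, cells$id)
    eps <- t_wall / 2
    probe_x <- (cells$x0[ci] + cells$x1[ci]) / 2
    probe_y <- (cells$y0[ci] + cells$y1[ci]) / 2
    right <- (seg$side == "lateral_inner" &
                (cells$x0[ci] + cells$x1[ci]) / 2 < mid) |
      (seg$side == "lateral_outer" &
         (cells$x0[ci] + cells$x1[ci]) / 2 >= mid)
    probe_y[seg$side == "apical"] <- cells$y1[ci][seg$side == "apical"] + eps
    probe_y[seg$side == "basal"] <- cells$y0[ci][seg$side == "basal"] - eps
    lat <- seg$side %in% c("lateral_inner", "lateral_outer")
    probe_x[lat & right] <- cells$x1[ci][lat & right] + eps
    probe_x[lat & !right] <- cells$x0[ci][lat & !right] - eps
    ob <- layout$obstacles
    sealed <- vapply(seq_len(nrow(seg)), function(s)
      any(probe_x[s] > ob$x0 & probe_x[s] < ob$x1 &
            probe_y[s] > ob$y0 & probe_y[s] < ob$y1), logical(1))
    seg <- seg[!sealed, , drop = FALSE]
  }
  row_of <- match(seg$cell, cells$id)
  seg_key <- ifelse(!is.na(seg$neighbour),
                    paste0("p", pmin(seg$cell, seg$neighbour), "_",
                           pmax(seg$cell, seg$neighbour)),
                    paste0("b", seg$cell, "_", seg$side))
  wall_key <- unique(seg_key)
  n_wall <- length(wall_key)
  wall_of_seg <- match(seg_key, wall_key)
  first_seg <- match(wall_key, seg_key)
  ## geometry of each wall from its first membrane segment
  wseg_cell <- row_of[first_seg]; wseg_side <- seg$side[first_seg]
  inner_right <- (cells$x0 + cells$x1) / 2 < mid
  wall_geom <- function(ci, side) {
    x0 <- cells$x0[ci]; x1 <- cells$x1[ci]
    y0 <- cells$y0[ci]; y1 <- cells$y1[ci]
    right <- (side == "lateral_inner" & inner_right[ci]) |
      (side == "lateral_outer" & !inner_right[ci])
    switch(side,
           apical = c(x0, x1, y1, y1),
           basal = c(x0, x1, y0, y0),
           if (right) c(x1, x1, y0, y1) else c(x0, x0, y0, y1))
  }
  wg <- t(mapply(wall_geom, wseg_cell, wseg_side))
  wall_len <- seg$length[first_seg]
  wall_vol <- wall_len * t_wall
  wall_id <- n_pix + seq_len(n_wall)

  ## wall-wall diffusion through shared junctions (cell corners)
  ep_key <- function(x, y) paste0(round(x, 6), "_", round(y, 6))
  ends <- rbind(data.frame(w = seq_len(n_wall),
                           k = ep_key(wg[, 1], wg[, 3])),
                data.frame(w = seq_len(n_wall),
                           k = ep_key(wg[, 2], wg[, 4])))
  wi <- integer(0); wj <- integer(0); wgc <- numeric(0)
  for (grp in split(ends$w, ends$k)) {
    if (length(grp) < 2L) next
    pr <- utils::combn(grp, 2L)
    wi <- c(wi, pr[1L, ]); wj <- c(wj, pr[2L, ])
    wgc <- c(wgc, params$D_wall * t_wall /
               (0.5 * (wall_len[pr[1L, ]] + wall_len[pr[2L, ]])))
  }

  ## --- membrane links --------------------------------------------------
  pm_key <- paste0(pin_map$cell, "_", pin_map$side)
  pm_eff <- setNames(pin_map$efflux, pm_key)
  pm_inf <- setNames(pin_map$influx, pm_key)
  mp <- integer(0); mw <- integer(0); me <- numeric(0)
  mPe <- numeric(0); mPa <- numeric(0)
  mcell <- integer(0); mside <- character(0)
  for (s in seq_len(nrow(seg))) {
    ci <- row_of[s]; g <- px[[ci]]; side <- seg$side[s]
    right <- (side == "lateral_inner" & inner_right[ci]) |
      (side == "lateral_outer" & !inner_right[ci])
    pid <- switch(side,
                  apical = g$idx[g$ny, ],
                  basal = g$idx[1L, ],
                  if (right) g$idx[, g$nx] else g$idx[, 1L])
    e <- if (side %in% c("apical", "basal")) g$wx else g$wy
    key <- paste0(seg$cell[s], "_", side)
    Pe <- unname(pm_eff[key]); Pa <- unname(pm_inf[key])
    if (is.na(Pe) || is.na(Pa))
      stop("permeability map has no entry for cell ", seg$cell[s],
           " side ", side, call. = FALSE)
    k <- length(pid)
    mp <- c(mp, pid); mw <- c(mw, rep(wall_id[wall_of_seg[s]], k))
    me <- c(me, rep(e, k)); mPe <- c(mPe, rep(Pe, k)); mPa <- c(mPa, rep(Pa, k))
    mcell <- c(mcell, rep(seg$cell[s], k)); mside <- c(mside, rep(side, k))
  }

  ## --- influx ----------------------------------------------------------
  n <- n_pix + n_wall
  vol <- c(pix_vol, wall_vol)
  b <- numeric(n)
  if (params$J_in == 0) {
    ## no influx: nothing to place (in particular after influx-cut events
    ## the source region may no longer exist)
  } else if (params$influx_mode == "qc_source") {
    qc <- cells$id[cells$type == "quiescent_centre"]
    if (length(qc) == 0)
      stop("influx_mode 'qc_source' needs QC cells in the layout",
           call. = FALSE)
    sel <- which(pix_cell %in% qc)
    b[sel] <- params$J_in / sum(pix_vol[sel])  # uniform volumetric production
  } else {
    top <- max(cells$row)
    ok <- seg$side == "apical" & is.na(seg$neighbour) &
      cells$row[row_of] == top &
      cells$type[row_of] %in% c("vascular", "pericycle")
    if (!any(ok))
      stop("no proximal vascular/pericycle boundary found for influx",
           call. = FALSE)
    wsel <- wall_of_seg[ok]
    share <- wall_len[wsel] / sum(wall_len[wsel])
    b[wall_id[wsel]] <- b[wall_id[wsel]] +
      params$J_in * share / wall_vol[wsel]
  }

  ## --- assemble A ------------------------------------------------------
  ii <- c(di, di, dj, dj,
          wall_id[wi], wall_id[wi], wall_id[wj], wall_id[wj],
          mp, mp, mw, mw,
          seq_len(n))
  jj <- c(di, dj, dj, di,
          wall_id[wi], wall_id[wj], wall_id[wj], wall_id[wi],
          mp, mw, mw, mp,
          seq_len(n))
  xx <- c(-dg / vol[di], dg / vol[di], -dg / vol[dj], dg / vol[dj],
          -wgc / vol[wall_id[wi]], wgc / vol[wall_id[wi]],
          -wgc / vol[wall_id[wj]], wgc / vol[wall_id[wj]],
          -me * mPe / vol[mp], me * mPa / vol[mp],
          -me * mPa / vol[mw], me * mPe / vol[mw],
          rep(-params$d, n))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))

  comp <- data.frame(
    id = seq_len(n),
    kind = rep(c("cytosol", "wall"), c(n_pix, n_wall)),
    cell = c(pix_cell, rep(NA_integer_, n_wall)),
    x = c(pix_x, (wg[, 1] + wg[, 2]) / 2),
    y = c(pix_y, (wg[, 3] + wg[, 4]) / 2),
    volume = vol)

  structure(list(
    layout = layout, pin_map = pin_map, params = params, resolution = h,
    n = n, n_pix = n_pix, n_wall = n_wall,
    comp = comp, A = A, b = b,
    pixels = setNames(px, cells$id),
    links = list(
      diffusion = data.frame(i = c(di, wall_id[wi]), j = c(dj, wall_id[wj]),
                             g = c(dg, wgc)),
      membrane = data.frame(pixel = mp, wall = mw, edge = me,
                            efflux = mPe, influx = mPa,
                            cell = mcell, side = mside))),
    class = "tissue_model")
}

#' @export
#' @method print tissue_model
#' @noRd
print.tissue_model <- function(x, ...) {
  cat(sprintf(paste0("Tissue model: %d compartments (%d cytosol pixels at ",
                     "%g um, %d walls),\n  %d nonzeros in the transport ",
                     "operator; influx %g a.u./s (%s)\n"),
              x$n, x$n_pix, x$resolution, x$n_wall,
              Matrix::nnzero(x$A), x$params$J_in, x$params$influx_mode))
  invisible(x)
}

#' Create a concentration field for a model
#'
#' @param model a [build_tissue_model()] model.
#' @param value scalar or per-compartment initial concentration (a.u.).
#' @param time time stamp, s.
#' @return An object of class `"concentration_field"`.
#' @export
new_field <- function(model, value = 0, time = 0) {
  stopifnot(inherits(model, "tissue_model"))
  v <- rep_len(value, model$n)
  if (any(v < 0) || any(!is.finite(v)))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  structure(list(values = v, time = time), class = "concentration_field")
}

#' @export
#' @method print concentration_field
#' @noRd
print.concentration_field <- function(x, ...) {
  cat(sprintf("Concentration field at t = %g s: %d compartments, range [%.4g, %.4g] a.u.\n",
              x$time, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Total morphogen mass of a field
#'
#' @param field a `concentration_field`; `model` its `tissue_model`.
#' @param model the model the field lives on.
#' @return Total mass in a.u. (concentration times compartment volume).
#' @export
total_mass <- function(field, model) {
  sum(field$values * model$comp$volume)
}

#' Per-cell mean concentrations
#'
#' Volume-weighted mean cytosolic concentration of every cell, the summary
#' used for fold-change reports.
#'
#' @inheritParams total_mass
#' @return Named numeric vector (names = cell ids).
#' @export
cell_means <- function(field, model) {
  pix <- model$comp$kind == "cytosol"
  m <- tapply(field$values[pix] * model$comp$volume[pix],
              model$comp$cell[pix], sum)
  v <- tapply(model$comp$volume[pix], model$comp$cell[pix], sum)
  out <- m / v
  setNames(as.numeric(out), names(out))
}
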