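#' Longitudinal profile through a cell file
#'
#' Samples the cytosolic concentration along the midline of one cell file,
#' ordered from the distal tip upward.  The selected column of the layout is
#' followed across zone boundaries, so the profile also traverses the QC and
#' columella rows sitting in that column; wall compartments are excluded.
#'
#' @param field a `concentration_field`.
#' @param model its `tissue_model`.
#' @param file_selector a file name (`"vascular_L"`) or a cell type
#'   (`"vascular"`, which picks the left file of that type).
#' @param per_cell if `TRUE`, collapse the profile to one volume-weighted
#'   mean concentration per cell (at the cell centre), removing the
#'   within-cell sawtooth that polar pumping superimposes on the tissue-scale
#'   gradient; the default keeps the pixel-resolution midline samples.
#' @return A data frame of class `"longitudinal_profile"` with
#'   `position_um` (strictly increasing, distal to proximal),
#'   `concentration_au` and `cell`; attribute `file` records the identity.
#' @export
extract_profile <- function(field, model, file_selector, per_cell = FALSE) {
  stopifnot(inherits(field, "concentration_field"),
            inherits(model, "tissue_model"),
            is.character(file_selector), length(file_selector) == 1L)
  cells <- model$layout$cells
  col <- unique(cells$col[cells$file == file_selector])
  if (length(col) == 0)
    col <- unique(cells$col[cells$type == file_selector])
  if (length(col) == 0)
    stop("unknown cell file: ", file_selector, call. = FALSE)
  col <- min(col)   # the left file when a type names a mirrored pair
  ids <- cells$id[cells$col == col]
  ids <- ids[order(cells$y0[match(ids, cells$id)])]
  pos <- numeric(0); conc <- numeric(0); of_cell <- integer(0)
  for (id in ids) {
    g <- model$pixels[[as.character(id)]]
    if (per_cell) {
      pos <- c(pos, mean(g$y))
      conc <- c(conc, mean(field$values[as.vector(g$idx)]))
      of_cell <- c(of_cell, id)
    } else {
      cmid <- ceiling(g$nx / 2)          # pixel column nearest the midline
      pix <- g$idx[, cmid]
      pos <- c(pos, g$y)
      conc <- c(conc, field$values[pix])
      of_cell <- c(of_cell, rep(id, g$ny))
    }
  }
  out <- data.frame(position_um = pos, concentration_au = conc,
                    cell = of_cell)
  structure(out, class = c("longitudinal_profile", "data.frame"),
            file = file_selector, time = field$time)
}

#' Construct a profile from raw vectors
#'
#' Convenience for synthetic profiles and file import.
#'
#' @param position_um strictly increasing positions, um.
#' @param concentration_au concentrations, a.u. (same length).
#' @param file optional file identity label.
#' @return A `longitudinal_profile`.
#' @export
longitudinal_profile <- function(position_um, concentration_au, file = NA) {
  stopifnot(length(position_um) == length(concentration_au),
            !is.unsorted(position_um, strictly = TRUE))
  structure(data.frame(position_um = position_um,
                       concentration_au = concentration_au,
                       cell = NA_integer_),
            class = c("longitudinal_profile", "data.frame"), file = file)
}

#' Fit an exponential gradient to a profile window
#'
#' Log-linear least squares of `log C` against position over the window:
#' the characteristic length `lambda` is minus the inverse slope, `C0` the
#' back-extrapolated concentration at position 0, and `alpha = 1/lambda` the
#' decay-per-length coefficient (for the reflux loop, the fraction of the
#' shootward stream bent back into the vasculature per um).
#'
#' @param profile a `longitudinal_profile` (decreasing away from the tip over
#'   the fitted window).
#' @param window numeric `c(from, to)` in um; default the whole profile.
#' @return An object of class `"gradient_fit"` with `lambda_fit` (um),
#'   `C0_fit` (a.u.), `alpha` (1/um), `window`, `residual` (RMS log
#'   residual) and `n`.
#' @examples
#' pr <- longitudinal_profile(seq(0, 150, 5), 2 * exp(-seq(0, 150, 5) / 30))
#' fit_exponential(pr)$lambda_fit   # 30
#' @export
fit_exponential <- function(profile, window = NULL) {
  stopifnot(inherits(profile, "longitudinal_profile"))
  x <- profile$position_um
  y <- profile$concentration_au
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    keep <- x >= window[1] & x <= window[2]
    x <- x[keep]; y <- y[keep]
  } else window <- range(x)
  if (length(x) < 5L)
    stop("fit window must contain at least 5 samples", call. = FALSE)
  if (any(y <= 0))
    stop("non-positive concentrations in the fit window", call. = FALSE)
  fit <- stats::lm(log(y) ~ x)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0)
    warning("profile is not decreasing over the window; lambda is negative",
            call. = FALSE)
  structure(list(lambda_fit = -1 / slope,
                 C0_fit = exp(unname(coef(fit)[1L])),
                 alpha = -slope,
                 window = window,
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 n = length(x)),
            class = "gradient_fit")
}

#' @export
#' @method print gradient_fit
#' @noRd
print.gradient_fit <- function(x, ...) {
  cat(sprintf(paste0("Exponential gradient fit: lambda = %.4g um, C0 = %.4g",
                     " a.u.\n  (alpha = %.4g /um; window %g-%g um, n = %d, ",
                     "RMS log residual %.3g)\n"),
              x$lambda_fit, x$C0_fit, x$alpha, x$window[1], x$window[2],
              x$n, x$residual))
  invisible(x)
}

#' @export
coef.gradient_fit <- function(object, ...) {
  c(lambda = object$lambda_fit, C0 = object$C0_fit, alpha = object$alpha)
}

#' Detect the elbow between exponential and flat profile regions
#'
#' Finds the junction between a distal exponential decline and a proximal
#' near-flat, influx-driven region by a two-segment change-point fit on the
#' log-concentration: every admissible breakpoint is scored by the summed
#' residual sum-of-squares of the two local linear fits, and the best one is
#' reported only when the distal slope is negative and exceeds the proximal
#' slope magnitude by `slope_contrast`.  Absence of an elbow is a valid
#' result, reported as `NA` (never 0).
#'
#' @param profile a `longitudinal_profile` with positive concentrations.
#' @param min_segment minimum samples on each side of the breakpoint.
#' @param slope_contrast required ratio of distal to proximal absolute slope.
#' @return Breakpoint position in um, or `NA_real_` when no change-point
#'   passes the contrast threshold; attributes `slope_distal` and
#'   `slope_proximal` carry the fitted log-slopes.
#' @export
detect_elbow <- function(profile, min_segment = 5L, slope_contrast = 4) {
  stopifnot(inherits(profile, "longitudinal_profile"),
            all(profile$concentration_au > 0))
  x <- profile$position_um
  y <- log(profile$concentration_au)
  n <- length(x)
  if (n < 2L * min_segment + 1L) return(NA_real_)
  ks <- seq(min_segment, n - min_segment)
  rss <- vapply(ks, function(k) {
    f1 <- stats::lm.fit(cbind(1, x[1:k]), y[1:k])
    f2 <- stats::lm.fit(cbind(1, x[(k + 1):n]), y[(k + 1):n])
    sum(f1$residuals^2) + sum(f2$residuals^2)
  }, numeric(1))
  k <- ks[which.min(rss)]
  s1 <- stats::lm.fit(cbind(1, x[1:k]), y[1:k])$coefficients[2L]
  s2 <- stats::lm.fit(cbind(1, x[(k + 1):n]), y[(k + 1):n])$coefficients[2L]
  pos <- (x[k] + x[k + 1L]) / 2
  if (!(s1 < 0 && abs(s1) > slope_contrast * abs(s2))) pos <- NA_real_
  structure(pos, slope_distal = unname(s1), slope_proximal = unname(s2))
}

#' Write a profile as a delimited-text table
#'
#' @param profile a `longitudinal_profile`.
#' @param path output file (tab-separated with header
#'   `position_um concentration_au file`).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "longitudinal_profile"))
  df <- data.frame(position_um = profile$position_um,
                   concentration_au = profile$concentration_au,
                   file = attr(profile, "file"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
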