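#' Labeled microscopy image
#'
#' A single 2-D channel with physical pixel size and a role tag so pipeline
#' stages can check they were handed the channel they expect (mitochondrial
#' label, cell fill, or dendrite marker such as MAP2).
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_size um per pixel, > 0.
#' @param channel_role `"mitochondria"`, `"cell_fill"` or `"dendrite_marker"`.
#' @return a `labeled_image`.
#' @export
labeled_image <- function(pixels, pixel_size,
                          channel_role = c("mitochondria", "cell_fill",
                                           "dendrite_marker")) {
  channel_role <- match.arg(channel_role)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (!all(is.finite(pixels))) stop("pixel intensities must be finite")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 channel_role = channel_role),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat("<labeled_image> ", nrow(x$pixels), " x ", ncol(x$pixels), " px (",
      x$pixel_size, " um/px), role: ", x$channel_role, "\n", sep = "")
  invisible(x)
}

#' Set of segmented mitochondria along a reference path
#'
#' Each mitochondrion is reduced to its centroid position along a 1-D
#' reference path (um from the soma end) and its length; `pixel_count` is
#' carried when the set came from an image.
#'
#' @param position_um centroid positions along the path, >= 0.
#' @param length_um per-object lengths, > 0.
#' @param pixel_count optional per-object pixel counts.
#' @param reference free-form description of the reference path or frame.
#' @return a `mitochondrion_set`.
#' @export
mitochondrion_set <- function(position_um, length_um = rep(1, length(position_um)),
                              pixel_count = NULL, reference = "path") {
  position_um <- as.numeric(position_um)
  length_um <- as.numeric(length_um)
  if (length(length_um) == 1) length_um <- rep(length_um, length(position_um))
  if (length(position_um) != length(length_um))
    stop("position_um and length_um must have equal length")
  if (any(position_um < 0)) stop("positions must be >= 0")
  if (any(length_um <= 0)) stop("lengths must be > 0")
  items <- data.frame(position_um = position_um, length_um = length_um)
  if (!is.null(pixel_count)) items$pixel_count <- as.integer(pixel_count)
  structure(list(items = items, reference = reference),
            class = "mitochondrion_set")
}

#' @export
print.mitochondrion_set <- function(x, ...) {
  cat("<mitochondrion_set> ", nrow(x$items), " mitochondria on ",
      x$reference, "\n", sep = "")
  invisible(x)
}

#' @export
length.mitochondrion_set <- function(x) nrow(x$items)

#' Threshold an image channel to a binary mask
#'
#' @param image a `labeled_image` or plain numeric matrix.
#' @param method `"otsu"` (threshold chosen by Otsu's criterion, via EBImage)
#'   or `"fixed"`.
#' @param threshold required intensity cutoff when `method = "fixed"`;
#'   foreground is intensity >= threshold.
#' @return logical matrix of foreground pixels.
#' @export
segment_image <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  if (!is.matrix(px) || !is.numeric(px)) stop("image must be a numeric matrix")
  if (method == "fixed") {
    if (is.null(threshold)) stop("fixed thresholding requires `threshold`")
    return(px >= threshold)
  }
  rng <- range(px)
  if (rng[1] == rng[2])
    stop("constant image: Otsu threshold is undefined, use method = \"fixed\"")
  scaled <- (px - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256)
  px >= rng[1] + th * (rng[2] - rng[1])
}

#' Pixel-shell radial profile of a binary mask (mitochondrial Sholl)
#'
#' Counts foreground pixels per annulus `[k*w, (k+1)*w)` of Euclidean pixel
#' distance from the soma center, out to the farthest foreground pixel.
#' Distances are measured between pixel centers; the soma center may be
#' fractional. The default one-pixel shell width gives the finest radial
#' resolution the image supports.
#'
#' @param mask logical (or 0/1) matrix.
#' @param soma_center numeric `(x, y)` in pixel coordinates (column, row;
#'   pixel centers at integers).
#' @param shell_width shell width in pixels, >= 1.
#' @return a `radial_profile` with `quantity_kind = "pixels"` and pixel units.
#'   An empty mask yields a single shell with count 0.
#' @export
mito_sholl <- function(mask, soma_center, shell_width = 1) {
  if (is.numeric(mask)) mask <- mask > 0
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix")
  if (length(soma_center) != 2 || !all(is.finite(soma_center)))
    stop("soma_center must be finite (x, y) pixel coordinates")
  if (soma_center[1] < 1 || soma_center[1] > ncol(mask) ||
      soma_center[2] < 1 || soma_center[2] > nrow(mask))
    stop("soma_center lies outside the image")
  if (shell_width < 1) stop("shell_width must be >= 1 pixel")

  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0)
    return(radial_profile(c(0, shell_width), 0, "pixels", unit = "pixel"))
  d <- sqrt((fg[, "col"] - soma_center[1])^2 +
            (fg[, "row"] - soma_center[2])^2)
  nshell <- floor(max(d) / shell_width) + 1L
  counts <- tabulate(floor(d / shell_width) + 1L, nbins = nshell)
  radial_profile(seq(0, nshell) * shell_width, counts, "pixels",
                 unit = "pixel")
}

#' Cumulative distribution container
#'
#' Normalized-distance grid in `[0, 1]` with the cumulative fraction of mass
#' within each distance — the mitochondrial probability map (MPM) when built
#' from a mitochondrial radial profile, and the normalized branchpoint
#' distribution behind BP90.
#'
#' @param normalized_distance non-decreasing grid in `[0, 1]`.
#' @param cumulative_fraction non-decreasing values in `[0, 1]`, ending at 1.
#' @return a `cumulative_distribution`.
#' @export
cumulative_distribution <- function(normalized_distance, cumulative_fraction) {
  x <- as.numeric(normalized_distance)
  f <- as.numeric(cumulative_fraction)
  if (length(x) != length(f)) stop("grid and fractions differ in length")
  if (any(diff(x) < 0) || any(diff(f) < -1e-12))
    stop("both axes must be non-decreasing")
  if (any(x < -1e-12 | x > 1 + 1e-12) || any(f < -1e-12 | f > 1 + 1e-9))
    stop("normalized distances and fractions must lie in [0, 1]")
  if (abs(f[length(f)] - 1) > 1e-9)
    stop("cumulative fraction must end at 1")
  structure(list(normalized_distance = pmin(pmax(x, 0), 1),
                 cumulative_fraction = pmin(pmax(f, 0), 1)),
            class = "cumulative_distribution")
}

#' @export
print.cumulative_distribution <- function(x, ...) {
  cat("<cumulative_distribution> ", length(x$normalized_distance),
      " grid points, median at ~", sprintf("%.3f", cdf_quantile(x, 0.5)),
      "\n", sep = "")
  invisible(x)
}

#' Mitochondrial probability map from a radial profile
#'
#' Converts a radial profile into the cumulative fraction of total mass as a
#' function of distance from the soma, with distance normalized by
#' `max_extent` so that the dendritic tip maps to 1. `max_extent` should be
#' the cell's maximum dendritic tip distance (trace mode) or the farthest
#' dendrite-mask pixel (image mode) — a tip reference, not a mitochondrial
#' one.
#'
#' @param profile a `radial_profile` with positive total counts.
#' @param max_extent normalizing distance in the profile's units; must reach
#'   at least the outer edge of the farthest non-empty shell.
#' @return a `cumulative_distribution` evaluated at the shell outer edges.
#' @export
mpm <- function(profile, max_extent) {
  stopifnot(inherits(profile, "radial_profile"))
  total <- sum(profile$counts)
  if (total <= 0) stop("MPM is undefined for a profile with zero total mass")
  outer_edges <- profile$shell_edges[-1]
  nonempty <- which(profile$counts > 0)
  if (max_extent < outer_edges[max(nonempty)])
    stop("max_extent must reach the farthest non-empty shell")
  keep <- outer_edges <= max_extent
  cumulative_distribution(outer_edges[keep] / max_extent,
                          cumsum(profile$counts)[keep] / total)
}

# interpolated quantile of a cumulative_distribution, anchored at (0, 0)
cdf_quantile <- function(cdf, p) {
  x <- c(0, cdf$normalized_distance)
  f <- c(0, cdf$cumulative_fraction)
  i <- which(f >= p)[1]
  if (is.na(i)) return(NA_real_)
  if (f[i] == p || i == 1) return(x[i])
  x[i - 1] + (p - f[i - 1]) / (f[i] - f[i - 1]) * (x[i] - x[i - 1])
}

#' Mito60: normalized position of 60% cumulative mitochondrial mass
#'
#' The smallest normalized distance at which the MPM reaches 0.60, linearly
#' interpolated between grid points (an exact 0.60 at a grid point returns
#' that point). Uniformly distributed mass gives 0.6; proximal accumulation
#' gives smaller values.
#'
#' @param cdf a `cumulative_distribution` (typically from [mpm()]).
#' @param p cumulative mass level, default 0.60.
#' @return a value in (0, 1].
#' @export
mito60 <- function(cdf, p = 0.60) {
  stopifnot(inherits(cdf, "cumulative_distribution"))
  cdf_quantile(cdf, p)
}

#' Mitochondrial index: mito area over dendrite-marker area
#'
#' Ratio of mitochondrial foreground to dendrite-marker (e.g. MAP2)
#' foreground within an optional region of interest. Mitochondrial pixels
#' count only where they overlap the dendrite mask, so somatic or axonal
#' signal inside the ROI does not inflate the index.
#'
#' @param mito_mask,dendrite_mask logical matrices of identical dimension.
#' @param roi optional logical matrix restricting the measurement.
#' @return dimensionless ratio.
#' @export
mitochondrial_index <- function(mito_mask, dendrite_mask, roi = NULL) {
  if (is.numeric(mito_mask)) mito_mask <- mito_mask > 0
  if (is.numeric(dendrite_mask)) dendrite_mask <- dendrite_mask > 0
  if (!identical(dim(mito_mask), dim(dendrite_mask)))
    stop("masks must have identical dimensions")
  if (is.null(roi)) roi <- array(TRUE, dim = dim(mito_mask))
  if (is.numeric(roi)) roi <- roi > 0
  dend <- sum(dendrite_mask & roi)
  if (dend == 0) stop("mitochondrial index undefined: no dendrite area in ROI")
  sum(mito_mask & dendrite_mask & roi) / dend
}

#' Dendritic occupancy gaps
#'
#' Samples a path at `step` intervals (cell midpoints) and marks a sample
#' occupied when a mitochondrial footprint covers it: in set mode the
#' footprint is `centroid +/- length/2` along the path; in mask mode any
#' foreground pixel within `radius` of the sample point. Returns the fraction
#' of dendritic length without mitochondria and the gap segments themselves.
#'
#' @param path either a single path length in um (set mode) or an n x 2
#'   matrix of (x, y) um vertices of a polyline (required for mask mode).
#' @param mitos a `mitochondrion_set`, or a logical mask with `pixel_size`
#'   set for mask mode. An empty set yields fraction 1 with one full-length
#'   gap.
#' @param radius capture radius in um for mask mode (default 0.5, roughly a
#'   mitochondrial radius at the magnifications these images are taken at).
#' @param step sampling interval in um (default 0.1, well below optical
#'   resolution).
#' @param pixel_size um per pixel, mask mode only.
#' @return list with `fraction_unoccupied` and `gap_segments` (data.frame of
#'   `start`, `end` in um along the path).
#' @export
occupancy_gaps <- function(path, mitos, radius = 0.5, step = 0.1,
                           pixel_size = NULL) {
  if (radius <= 0 || step <= 0) stop("radius and step must be > 0")
  if (is.matrix(path)) {
    seg <- sqrt(rowSums(diff(path)^2))
    arclen <- c(0, cumsum(seg))
    path_length <- arclen[length(arclen)]
  } else {
    path_length <- as.numeric(path)
  }
  if (!is.finite(path_length) || path_length <= 0)
    stop("path length must be > 0")

  n_cells <- max(1L, round(path_length / step))
  centers <- (seq_len(n_cells) - 0.5) * (path_length / n_cells)
  occupied <- rep(FALSE, n_cells)

  if (inherits(mitos, "mitochondrion_set")) {
    it <- mitos$items
    for (i in seq_len(nrow(it))) {
      lo <- it$position_um[i] - it$length_um[i] / 2
      hi <- it$position_um[i] + it$length_um[i] / 2
      occupied <- occupied | (centers >= lo & centers <= hi)
    }
  } else {
    mask <- if (is.numeric(mitos)) mitos > 0 else mitos
    if (!is.logical(mask) || !is.matrix(mask))
      stop("mitos must be a mitochondrion_set or a logical mask")
    if (is.null(pixel_size)) stop("mask mode requires pixel_size")
    if (!is.matrix(path)) stop("mask mode requires a polyline path")
    pts <- interpolate_polyline(path, centers)
    fg <- which(mask, arr.ind = TRUE)
    if (nrow(fg) > 0) {
      fx <- fg[, "col"] * pixel_size
      fy <- fg[, "row"] * pixel_size
      for (k in seq_len(n_cells)) {
        d2 <- (fx - pts[k, 1])^2 + (fy - pts[k, 2])^2
        occupied[k] <- any(d2 <= radius^2)
      }
    }
  }

  r <- rle(!occupied)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gap <- which(r$values)
  cell <- path_length / n_cells
  gaps <- data.frame(start = (starts[gap] - 1) * cell, end = ends[gap] * cell)
  list(fraction_unoccupied = mean(!occupied), gap_segments = gaps)
}

# points at given arclength positions along an n x 2 polyline
interpolate_polyline <- function(path, s) {
  seg <- sqrt(rowSums(diff(path)^2))
  arclen <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), arclen[length(arclen)])
  cbind(stats::approx(arclen, path[, 1], xout = s)$y,
        stats::approx(arclen, path[, 2], xout = s)$y)
}

#' Mitochondria per 10 um of axon
#'
#' @param path_length axon length in um, > 0.
#' @param mitos a `mitochondrion_set` (or a plain count).
#' @return count per 10 um.
#' @export
axonal_density <- function(path_length, mitos) {
  if (path_length <= 0) stop("path_length must be > 0")
  n <- if (inherits(mitos, "mitochondrion_set")) length(mitos) else
    as.numeric(mitos)
  10 * n / path_length
}

#' Length-normalized mitochondrial positions
#'
#' Each centroid position divided by the path length, clipped to `[0, 1]`,
#' order preserved — the per-organelle coordinates pooled in
#' length-normalized axon plots.
#'
#' @inheritParams axonal_density
#' @return numeric vector in `[0, 1]`.
#' @export
relative_positions <- function(path_length, mitos) {
  if (path_length <= 0) stop("path_length must be > 0")
  pos <- if (inherits(mitos, "mitochondrion_set")) mitos$items$position_um
  else as.numeric(mitos)
  pmin(pmax(pos / path_length, 0), 1)
}

#' Radial profile of mitochondrial centroid positions
#'
#' Histogram of a `mitochondrion_set`'s centroid positions into shells of the
#' given width — the placement-mode analogue of [mito_sholl()], feeding the
#' same [mpm()] / [mito60()] chain.
#'
#' @param mitos a `mitochondrion_set`.
#' @param shell_width shell width in um.
#' @return a `radial_profile` with `quantity_kind = "pixels"` semantics
#'   (counts of objects per shell).
#' @export
position_profile <- function(mitos, shell_width) {
  stopifnot(inherits(mitos, "mitochondrion_set"))
  if (shell_width <= 0) stop("shell_width must be > 0")
  pos <- mitos$items$position_um
  if (length(pos) == 0)
    return(radial_profile(c(0, shell_width), 0, "pixels"))
  nshell <- floor(max(pos) / shell_width) + 1L
  counts <- tabulate(floor(pos / shell_width) + 1L, nbins = nshell)
  radial_profile(seq(0, nshell) * shell_width, counts, "pixels")
}
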