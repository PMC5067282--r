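#' Kymograph: space-time image along a traced path
#'
#' Rows index position along the path (one sample per pixel of arclength),
#' columns index frames. `soma_end` records which end of the path faces the
#' soma so that displacement signs can be oriented anterograde-positive.
#'
#' @param data numeric matrix, positions x frames.
#' @param pixel_size um per path sample.
#' @param frame_interval seconds between frames.
#' @param soma_end `"low_index"` (path start at the soma, the default) or
#'   `"high_index"`.
#' @return a `kymograph`.
#' @export
kymograph <- function(data, pixel_size, frame_interval,
                      soma_end = c("low_index", "high_index")) {
  soma_end <- match.arg(soma_end)
  if (!is.matrix(data) || ncol(data) < 2)
    stop("kymograph needs a matrix with >= 2 frames (columns)")
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("pixel_size and frame_interval must be > 0")
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval, soma_end = soma_end),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat("<kymograph> ", nrow(x$data), " positions x ", ncol(x$data),
      " frames; ", x$pixel_size, " um/px, ", x$frame_interval,
      " s/frame; soma at ", x$soma_end, "\n", sep = "")
  invisible(x)
}

#' Build a kymograph from a time-lapse stack
#'
#' For every frame, intensity is sampled (bilinear interpolation) at
#' unit-arclength steps along the path; at each step the maximum over
#' `line_width` perpendicular offsets is taken, so organelles that wander a
#' pixel or two off the traced line are still captured.
#'
#' @param stack a list of numeric matrices or a 3-D array (rows x cols x
#'   frames), all frames of equal size.
#' @param path n x 2 matrix of (x, y) pixel coordinates of the traced
#'   process, ordered from its `soma_end`.
#' @param line_width odd integer >= 1, perpendicular averaging width in
#'   pixels.
#' @param pixel_size um per image pixel.
#' @param frame_interval seconds per frame.
#' @param soma_end which end of `path` is proximal.
#' @return a `kymograph`.
#' @export
build_kymograph <- function(stack, path, line_width = 3, pixel_size = 1,
                            frame_interval = 1,
                            soma_end = c("low_index", "high_index")) {
  soma_end <- match.arg(soma_end)
  frames <- as_frame_list(stack)
  if (line_width < 1 || line_width %% 2 != 1)
    stop("line_width must be an odd integer >= 1")
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  if (any(path[, 1] < 1 | path[, 1] > nc | path[, 2] < 1 | path[, 2] > nr))
    stop("path leaves the image bounds")

  seg <- sqrt(rowSums(diff(path)^2))
  total <- sum(seg)
  if (total > sqrt(nr^2 + nc^2) * length(seg))
    stop("path longer than plausible for the image")
  s <- seq(0, total, by = 1)
  pts <- interpolate_polyline(path, s)
  # unit tangent/normal per sample from neighbouring samples
  tang <- rbind(pts[2, ] - pts[1, ],
                (pts[-(1:2), , drop = FALSE] -
                   pts[seq_len(nrow(pts) - 2), , drop = FALSE]) / 2,
                pts[nrow(pts), ] - pts[nrow(pts) - 1, ])
  tlen <- sqrt(rowSums(tang^2)); tlen[tlen == 0] <- 1
  nrm <- cbind(-tang[, 2], tang[, 1]) / tlen
  offsets <- seq(-(line_width - 1) / 2, (line_width - 1) / 2)

  out <- matrix(0, nrow = nrow(pts), ncol = length(frames))
  for (f in seq_along(frames)) {
    vals <- matrix(-Inf, nrow = nrow(pts), ncol = length(offsets))
    for (k in seq_along(offsets)) {
      xo <- pts[, 1] + offsets[k] * nrm[, 1]
      yo <- pts[, 2] + offsets[k] * nrm[, 2]
      vals[, k] <- bilinear_sample(frames[[f]], xo, yo)
    }
    out[, f] <- apply(vals, 1, max)
  }
  kymograph(out, pixel_size = pixel_size, frame_interval = frame_interval,
            soma_end = soma_end)
}

as_frame_list <- function(stack) {
  frames <- if (is.list(stack)) stack
  else if (is.array(stack) && length(dim(stack)) == 3)
    lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  else stop("stack must be a list of matrices or a 3-D array")
  if (length(frames) < 2) stop("need at least 2 frames")
  frames
}

# bilinear interpolation at (x, y) pixel coordinates, clamped to the border
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' A single particle track
#'
#' @param frame integer frame indices, strictly increasing.
#' @param position_um positions along the path in um.
#' @param frame_interval seconds per frame.
#' @param soma_end which end of the path is proximal.
#' @return a `track`.
#' @export
track <- function(frame, position_um, frame_interval,
                  soma_end = c("low_index", "high_index")) {
  soma_end <- match.arg(soma_end)
  frame <- as.integer(frame)
  if (length(frame) < 2) stop("a track needs >= 2 samples")
  if (any(diff(frame) <= 0)) stop("frames must be strictly increasing")
  if (length(frame) != length(position_um)) stop("length mismatch")
  structure(list(samples = data.frame(frame = frame,
                                      position_um = as.numeric(position_um)),
                 frame_interval = frame_interval, soma_end = soma_end),
            class = "track")
}

#' Detect particles and link them into tracks
#'
#' Per-frame 1-D local-maxima detection on the kymograph columns (sub-pixel
#' refinement by parabolic interpolation), then greedy nearest-neighbour
#' linking between consecutive frames: candidate links are consumed in order
#' of increasing distance, links longer than `max_jump` are rejected, and
#' unmatched detections seed new tracks. A track that misses detections for
#' up to `max_gap` consecutive frames stays eligible for relinking — two
#' particles closer than the optical resolution merge into a single peak for
#' a frame or two, and without this tolerance every such encounter would
#' split a trajectory. Tracks shorter than 3 frames are discarded. Greedy
#' linking is adequate at the low particle densities of dendritic
#' organelles; dense or crossing traffic can swap identities.
#'
#' @param kymo a `kymograph`.
#' @param detection_threshold minimum intensity of a local maximum.
#' @param max_jump maximum frame-to-frame displacement in um.
#' @param max_gap frames a track may coast without a detection (default 1).
#' @return list of `track` objects.
#' @export
detect_and_link <- function(kymo, detection_threshold, max_jump,
                            max_gap = 1) {
  stopifnot(inherits(kymo, "kymograph"))
  if (max_jump <= 0) stop("max_jump must be > 0")
  nframes <- ncol(kymo$data)
  detections <- lapply(seq_len(nframes), function(f)
    detect_peaks_1d(kymo$data[, f], detection_threshold) * kymo$pixel_size)

  active <- list()     # each: list(frame=, position_um=)
  done <- list()
  for (f in seq_len(nframes)) {
    det <- detections[[f]]
    linked_det <- rep(FALSE, length(det))
    linked_trk <- rep(FALSE, length(active))
    if (length(active) > 0 && length(det) > 0) {
      last_pos <- vapply(active, function(t) t$position_um[length(t$position_um)],
                         numeric(1))
      dmat <- abs(outer(last_pos, det, "-"))
      repeat {
        i <- which.min(dmat)
        if (length(i) == 0 || !is.finite(dmat[i]) || dmat[i] > max_jump) break
        ti <- (i - 1) %% nrow(dmat) + 1
        di <- (i - 1) %/% nrow(dmat) + 1
        active[[ti]]$frame <- c(active[[ti]]$frame, f)
        active[[ti]]$position_um <- c(active[[ti]]$position_um, det[di])
        linked_trk[ti] <- TRUE; linked_det[di] <- TRUE
        dmat[ti, ] <- Inf; dmat[, di] <- Inf
      }
    }
    # retire tracks that exhausted their gap allowance
    if (length(active) > 0) {
      last_f <- vapply(active, function(t) t$frame[length(t$frame)],
                       numeric(1))
      expired <- !linked_trk & (f - last_f > max_gap)
      done <- c(done, active[expired])
      active <- active[!expired]
    }
    for (di in which(!linked_det))
      active <- c(active, list(list(frame = f, position_um = det[di])))
  }
  done <- c(done, active)
  done <- Filter(function(t) length(t$frame) >= 3, done)
  lapply(done, function(t)
    track(t$frame, t$position_um, frame_interval = kymo$frame_interval,
          soma_end = kymo$soma_end))
}

# local maxima (strictly above the right neighbour, >= the left, above
# threshold) with parabolic sub-pixel refinement; returns positions in pixels
# counted from the first row (0-based so position = (row-1) + offset)
detect_peaks_1d <- function(v, threshold) {
  n <- length(v)
  if (n < 3) return(numeric(0))
  i <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n] &
               v[2:(n - 1)] >= threshold) + 1L
  if (length(i) == 0) return(numeric(0))
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  offset <- ifelse(abs(denom) > .Machine$double.eps,
                   0.5 * (v[i - 1] - v[i + 1]) / denom, 0)
  offset <- pmin(pmax(offset, -0.5), 0.5)
  (i - 1) + offset
}

# net displacement signed anterograde-positive
oriented_displacements <- function(trk) {
  d <- diff(trk$samples$position_um)
  if (trk$soma_end == "high_index") d <- -d
  d
}

#' Classify a track as stationary, anterograde or retrograde
#'
#' Net displacement (last minus first position, signed so positive points
#' away from the soma) at least `displacement_threshold` in magnitude makes
#' the track mobile (ties count as mobile); the sign sets the direction.
#' The default threshold of 2 um over a 2-minute movie is the conventional
#' mobility cutoff in the axonal-transport literature — slower net drift is
#' indistinguishable from stage noise.
#'
#' @param trk a `track`.
#' @param displacement_threshold um, default 2.
#' @return `"stationary"`, `"anterograde"` or `"retrograde"`.
#' @export
classify_motility <- function(trk, displacement_threshold = 2) {
  stopifnot(inherits(trk, "track"))
  net <- sum(oriented_displacements(trk))
  if (abs(net) < displacement_threshold) "stationary"
  else if (net > 0) "anterograde" else "retrograde"
}

#' Per-run velocities of a track
#'
#' Splits the track into runs of consecutive same-direction steps whose
#' per-frame step exceeds `noise_floor` (sub-pixel detection jitter);
#' pauses and dithering below the floor break runs and are excluded. Each
#' run reports `|displacement| / duration`.
#'
#' @param trk a `track`.
#' @param noise_floor um per frame; default one pixel-equivalent (1 um at
#'   1 um/px — pass `pixel_size` of the source kymograph for other scales).
#' @return data.frame with columns `direction`, `velocity_um_s`,
#'   `duration_s`; zero rows for a stationary track.
#' @export
run_velocities <- function(trk, noise_floor = 1) {
  stopifnot(inherits(trk, "track"))
  d <- oriented_displacements(trk)
  dt <- diff(trk$samples$frame) * trk$frame_interval
  state <- ifelse(abs(d) <= noise_floor, 0L, ifelse(d > 0, 1L, -1L))
  runs <- rle(state)
  out <- data.frame(direction = character(0), velocity_um_s = numeric(0),
                    duration_s = numeric(0))
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (runs$values[k] == 0L) next
    sel <- idx_start[k]:idx_end[k]
    disp <- abs(sum(d[sel]))
    dur <- sum(dt[sel])
    out <- rbind(out, data.frame(
      direction = if (runs$values[k] > 0) "anterograde" else "retrograde",
      velocity_um_s = disp / dur, duration_s = dur))
  }
  out
}

#' Summarize motility across tracks
#'
#' Aggregates [classify_motility()] and [run_velocities()] over a set of
#' tracks: percent mobile of all tracks, the anterograde/retrograde split
#' among mobile tracks, and mean run velocity per direction (runs pooled
#' across the mobile tracks of that direction). Velocities are `NA` when no
#' runs exist in a direction — missing, not zero.
#'
#' @param tracks non-empty list of `track` objects.
#' @param displacement_threshold mobility cutoff in um.
#' @param noise_floor run-segmentation floor in um per frame.
#' @return a `motility_summary` (list with `n_tracks`, `percent_mobile`,
#'   `percent_anterograde`, `percent_retrograde`,
#'   `mean_velocity_anterograde`, `mean_velocity_retrograde`).
#' @export
summarize_motility <- function(tracks, displacement_threshold = 2,
                               noise_floor = 1) {
  if (length(tracks) == 0) stop("motility summary undefined for zero tracks")
  classes <- vapply(tracks, classify_motility, character(1),
                    displacement_threshold = displacement_threshold)
  mobile <- classes != "stationary"
  n_mob <- sum(mobile)
  vel <- function(dir) {
    runs <- do.call(rbind, lapply(tracks[mobile][classes[mobile] == dir],
                                  run_velocities, noise_floor = noise_floor))
    runs <- runs[runs$direction == dir, , drop = FALSE]
    if (is.null(runs) || nrow(runs) == 0) NA_real_ else mean(runs$velocity_um_s)
  }
  structure(list(
    n_tracks = length(tracks),
    percent_mobile = 100 * n_mob / length(tracks),
    percent_anterograde = if (n_mob > 0)
      100 * sum(classes == "anterograde") / n_mob else NA_real_,
    percent_retrograde = if (n_mob > 0)
      100 * sum(classes == "retrograde") / n_mob else NA_real_,
    mean_velocity_anterograde = if (n_mob > 0) vel("anterograde") else NA_real_,
    mean_velocity_retrograde = if (n_mob > 0) vel("retrograde") else NA_real_),
    class = "motility_summary")
}

#' @export
print.motility_summary <- function(x, ...) {
  cat("<motility_summary> ", x$n_tracks, " tracks; ",
      sprintf("%.1f%% mobile", x$percent_mobile), sep = "")
  if (!is.na(x$percent_anterograde))
    cat(sprintf(" (%.0f%% antero / %.0f%% retro)", x$percent_anterograde,
                x$percent_retrograde))
  cat("\n")
  if (!is.na(x$mean_velocity_anterograde) || !is.na(x$mean_velocity_retrograde))
    cat(sprintf("  mean run velocity: antero %.3f um/s, retro %.3f um/s\n",
                x$mean_velocity_anterograde, x$mean_velocity_retrograde))
  invisible(x)
}

#' Per-track table for export
#'
#' @param tracks list of `track` objects.
#' @param displacement_threshold mobility cutoff passed to
#'   [classify_motility()].
#' @return data.frame with `track_id`, `frame`, `position_um`, `class`.
#' @export
tracks_table <- function(tracks, displacement_threshold = 2) {
  do.call(rbind, lapply(seq_along(tracks), function(i) {
    cl <- classify_motility(tracks[[i]], displacement_threshold)
    cbind(track_id = i, tracks[[i]]$samples, class = cl)
  }))
}
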