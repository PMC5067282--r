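#' Stochastic dendritic tree model
#'
#' Parameters of the branching-process generator behind [generate_tree()]:
#' primary dendrites leave the soma at roughly even angles, each branch grows
#' in 1-um steps with a direction random walk (`tortuosity` = angular sd per
#' step, radians), branch events occur as a Poisson process along length at
#' `branch_rate` per um (so generated trees carry about `branch_rate`
#' branchpoints per um of cable), and a branch that survives to its drawn
#' segment length (Normal, truncated at 1 um) terminates. Defaults are sized
#' to resemble a cultured hippocampal pyramidal cell at two weeks in vitro:
#' a few thousand um of dendrite carrying a few dozen branchpoints.
#'
#' @param n_primary primary dendrite count.
#' @param branch_rate branch events per um of cable.
#' @param segment_length_mean,segment_length_sd terminal segment length (um).
#' @param max_depth maximum branch order; branching stops beyond it.
#' @param tortuosity direction random-walk sd per 1-um step (radians).
#' @param seed RNG seed for [generate_tree()].
#' @return a `tree_model` parameter list.
#' @export
tree_model <- function(n_primary = 5, branch_rate = 0.015,
                       segment_length_mean = 80, segment_length_sd = 30,
                       max_depth = 7, tortuosity = 0.15, seed = 1) {
  stopifnot(n_primary >= 1, branch_rate >= 0, segment_length_mean > 0,
            segment_length_sd >= 0, max_depth >= 1, tortuosity >= 0)
  structure(list(n_primary = n_primary, branch_rate = branch_rate,
                 segment_length_mean = segment_length_mean,
                 segment_length_sd = segment_length_sd,
                 max_depth = max_depth, tortuosity = tortuosity, seed = seed),
            class = "tree_model")
}

#' Generate a synthetic neuron morphology
#'
#' Planar (z = 0) stochastic binary branching from a single-point soma,
#' reproducible given the model seed. The returned object satisfies every
#' `neuron_morphology` invariant and round-trips through SWC.
#'
#' @param model a [tree_model()].
#' @param structure structure label for the generated cable
#'   (`"dendrite_basal"` by default; use `"axon"` for axon fixtures).
#' @return a `neuron_morphology`.
#' @export
generate_tree <- function(model, structure = "dendrite_basal") {
  stopifnot(inherits(model, "tree_model"))
  set.seed(model$seed)
  step <- 1
  max_nodes <- 1e5

  ids <- 1L
  rows <- list(data.frame(id = 1L, structure = "soma", x = 0, y = 0, z = 0,
                          radius = 5, parent = NA_integer_))
  n_nodes <- 1L

  base <- stats::runif(1, 0, 2 * pi)
  queue <- lapply(seq_len(model$n_primary), function(k) {
    list(parent = 1L, x = 0, y = 0,
         angle = base + 2 * pi * (k - 1) / model$n_primary +
           stats::rnorm(1, 0, 0.2),
         depth = 1L)
  })

  while (length(queue) > 0) {
    br <- queue[[1]]; queue <- queue[-1]
    seg_len <- max(1, stats::rnorm(1, model$segment_length_mean,
                                   model$segment_length_sd))
    t_branch <- if (model$branch_rate > 0 && br$depth < model$max_depth)
      stats::rexp(1, model$branch_rate) else Inf
    grow <- min(seg_len, t_branch)
    branched <- is.finite(t_branch) && t_branch <= seg_len
    nstep <- max(1L, ceiling(grow / step))

    angles <- br$angle + cumsum(stats::rnorm(nstep, 0, model$tortuosity))
    dx <- step * cos(angles); dy <- step * sin(angles)
    xs <- br$x + cumsum(dx); ys <- br$y + cumsum(dy)
    new_ids <- ids + seq_len(nstep)
    ids <- ids + nstep
    n_nodes <- n_nodes + nstep
    if (n_nodes > max_nodes)
      stop("size limit exceeded: tree would have more than 1e5 nodes")
    rows[[length(rows) + 1L]] <- data.frame(
      id = new_ids, structure = structure, x = xs, y = ys, z = 0,
      radius = 0.5, parent = c(br$parent, new_ids[-nstep]))

    if (branched) {
      tip_id <- new_ids[nstep]
      spread <- stats::runif(1, 0.3, 0.7)
      for (s in c(-1, 1))
        queue <- c(queue, list(list(parent = tip_id, x = xs[nstep],
                                    y = ys[nstep],
                                    angle = angles[nstep] + s * spread,
                                    depth = br$depth + 1L)))
    }
  }
  neuron_morphology(do.call(rbind, rows))
}

#' Mitochondrial placement model
#'
#' Linear density of mitochondrial centroids over the normalized
#' proximo-distal axis (soma = 0, tip = 1): `uniform` emulates the
#' homogeneous distribution of healthy dendrites, `truncated_exponential`
#' (density proportional to `exp(-x / tau)` on `[0, 1]`) the proximal
#' accumulation seen when transport fails; smaller `tau` concentrates mass
#' nearer the soma.
#'
#' @param kind `"uniform"` or `"truncated_exponential"`.
#' @param tau normalized length scale of the exponential, > 0.
#' @param n_mitochondria number of placements.
#' @param mito_length mean mitochondrion length, um.
#' @param length_jitter fractional length jitter (uniform in
#'   `mito_length * (1 +/- length_jitter)`).
#' @return a `placement_model`.
#' @export
placement_model <- function(kind = c("uniform", "truncated_exponential"),
                            tau = 0.3, n_mitochondria = 100,
                            mito_length = 1, length_jitter = 0.2) {
  kind <- match.arg(kind)
  stopifnot(tau > 0, n_mitochondria >= 0, mito_length > 0,
            length_jitter >= 0, length_jitter < 1)
  structure(list(kind = kind, tau = tau, n_mitochondria = n_mitochondria,
                 mito_length = mito_length, length_jitter = length_jitter),
            class = "placement_model")
}

# analytic normalized position of cumulative mass p for a placement model
placement_quantile <- function(model, p) {
  if (model$kind == "uniform") return(p)
  tau <- model$tau
  -tau * log(1 - p * (1 - exp(-1 / tau)))
}

#' Place mitochondria along a path or a dendritic tree
#'
#' Draws i.i.d. normalized positions from the placement-model density and
#' maps them to um. On a plain path of length `L` the position is `x * L`.
#' On a morphology, a root-to-tip path is chosen with probability
#' proportional to its tip path distance and the mitochondrion sits at
#' `x` times that tip's distance, so the ground-truth normalized coordinate
#' is exactly density-distributed whatever the topology. The drawn
#' normalized positions are kept in the `norm_position` column for
#' parameter-recovery oracles; spatial coordinates and local direction are
#' kept for rasterization.
#'
#' @param target a path length in um, or a `neuron_morphology`.
#' @param model a [placement_model()].
#' @param seed RNG seed.
#' @return a `mitochondrion_set` whose `items` carry `norm_position`, and
#'   (`x`, `y`, `ux`, `uy`) columns.
#' @export
place_mitochondria <- function(target, model, seed = 1) {
  stopifnot(inherits(model, "placement_model"))
  set.seed(seed)
  n <- model$n_mitochondria
  if (n == 0) {
    out <- mitochondrion_set(numeric(0), numeric(0))
    out$items$norm_position <- numeric(0)
    return(out)
  }
  u <- stats::runif(n)
  x <- if (model$kind == "uniform") u else placement_quantile(model, u)
  len <- model$mito_length *
    (1 + model$length_jitter * stats::runif(n, -1, 1))

  if (inherits(target, "neuron_morphology")) {
    tp <- tip_paths(target)
    if (length(tp$tips) == 0) stop("morphology has no dendritic tips")
    pick <- sample.int(length(tp$tips), n, replace = TRUE,
                       prob = tp$tip_dist)
    pos <- x * tp$tip_dist[pick]
    coords <- t(vapply(seq_len(n), function(i)
      point_on_tip_path(target, tp, pick[i], pos[i]), numeric(4)))
    out <- mitochondrion_set(pos, len, reference = "tree")
    out$items$norm_position <- x
    out$items$x <- coords[, 1]; out$items$y <- coords[, 2]
    out$items$ux <- coords[, 3]; out$items$uy <- coords[, 4]
  } else {
    L <- as.numeric(target)
    if (!is.finite(L) || L <= 0) stop("path length must be > 0")
    out <- mitochondrion_set(x * L, len, reference = "path")
    out$items$norm_position <- x
    out$items$x <- x * L; out$items$y <- 0
    out$items$ux <- 1; out$items$uy <- 0
  }
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  out
}

# root-to-tip chains of a morphology's dendrites: tip row indices, their path
# distances, and the parent chain for interpolation
tip_paths <- function(morph, structures = dendrite_structures()) {
  nd <- morph$nodes
  cc <- child_counts(morph)
  tips <- which(nd$structure %in% structures & cc == 0L)
  pd <- node_path_distances(morph)
  list(tips = tips, tip_dist = pd[tips], path_dist = pd,
       parent_idx = match(nd$parent, nd$id))
}

# coordinates and unit direction at arclength s along the root-to-tip chain
point_on_tip_path <- function(morph, tp, tip_k, s) {
  nd <- morph$nodes
  i <- tp$tips[tip_k]
  chain <- integer(0)
  while (!is.na(i)) { chain <- c(i, chain); i <- tp$parent_idx[i] }
  d <- tp$path_dist[chain]
  s <- min(max(s, 0), d[length(d)])
  j <- findInterval(s, d, rightmost.closed = TRUE)
  j <- min(max(j, 1L), length(chain) - 1L)
  a <- chain[j]; b <- chain[j + 1L]
  f <- if (d[j + 1] > d[j]) (s - d[j]) / (d[j + 1] - d[j]) else 0
  dx <- nd$x[b] - nd$x[a]; dy <- nd$y[b] - nd$y[a]
  nrm <- sqrt(dx^2 + dy^2); if (nrm == 0) nrm <- 1
  c(nd$x[a] + f * dx, nd$y[a] + f * dy, dx / nrm, dy / nrm)
}

#' Rasterize a morphology and its mitochondria into two channels
#'
#' Paints the dendritic cable (at trace radius) into a cell-fill channel and
#' each mitochondrion as a capsule of its length into a mitochondrial
#' channel, then applies a Gaussian point-spread blur and additive Gaussian
#' noise. The pre-blur binary masks are returned as ground truth for
#' segmentation and index oracles.
#'
#' @param morph a `neuron_morphology` (planar; z ignored).
#' @param mitos a `mitochondrion_set` from [place_mitochondria()] (needs the
#'   spatial columns), or `NULL` for a fill-only render.
#' @param pixel_size um per pixel.
#' @param psf_sigma blur sd in um (0 = none).
#' @param noise_sd additive Gaussian noise sd in intensity units.
#' @param mito_radius capsule radius in um.
#' @param amplitude foreground intensity before blur.
#' @return list with `cell_fill` and `mitochondria` (`labeled_image`),
#'   ground-truth `dendrite_mask` and `mito_mask`, and `soma_center_px`
#'   (x, y pixel coordinates of the soma center).
#' @export
rasterize_neuron <- function(morph, mitos = NULL, pixel_size = 0.25,
                             psf_sigma = 0, noise_sd = 0, mito_radius = 0.25,
                             amplitude = 100) {
  stopifnot(inherits(morph, "neuron_morphology"), pixel_size > 0)
  nd <- morph$nodes
  pad <- max(nd$radius, mito_radius) + 2
  x0 <- min(nd$x) - pad; y0 <- min(nd$y) - pad
  W <- ceiling((max(nd$x) + pad - x0) / pixel_size) + 1L
  H <- ceiling((max(nd$y) + pad - y0) / pixel_size) + 1L
  if (as.double(W) * H > 1e8)
    stop("size limit exceeded: field of view over 1e8 pixels")

  to_px <- function(x, y) cbind((x - x0) / pixel_size + 1,
                                (y - y0) / pixel_size + 1)
  dend <- matrix(FALSE, H, W)
  ed <- edge_table(morph)
  for (i in seq_len(nrow(ed))) {
    a <- ed$parent[i]; b <- ed$child[i]
    if (nd$structure[b] == "soma") next
    nstamp <- max(2L, ceiling(ed$length[i] / (pixel_size / 2)) + 1L)
    t <- seq(0, 1, length.out = nstamp)
    px <- to_px(nd$x[a] + t * (nd$x[b] - nd$x[a]),
                nd$y[a] + t * (nd$y[b] - nd$y[a]))
    r_px <- max(1, nd$radius[b] / pixel_size)
    dend <- stamp_disks(dend, px, r_px)
  }

  mito <- matrix(FALSE, H, W)
  if (!is.null(mitos) && length(mitos) > 0) {
    it <- mitos$items
    if (is.null(it$x))
      stop("mitochondrion set lacks spatial coordinates; use place_mitochondria")
    for (i in seq_len(nrow(it))) {
      half <- it$length_um[i] / 2
      t <- seq(-half, half, by = pixel_size / 2)
      if (length(t) < 2) t <- c(-half, half)
      px <- to_px(it$x[i] + t * it$ux[i], it$y[i] + t * it$uy[i])
      inside <- px[, 1] >= 1 & px[, 1] <= W & px[, 2] >= 1 & px[, 2] <= H
      if (any(inside))
        mito <- stamp_disks(mito, px[inside, , drop = FALSE],
                            max(1, mito_radius / pixel_size))
    }
  }

  render <- function(mask, role) {
    img <- amplitude * mask
    if (psf_sigma > 0)
      img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                      sigma = psf_sigma / pixel_size))
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), nrow(img))
    labeled_image(img, pixel_size, role)
  }
  sc <- to_px(morph$soma_center[1], morph$soma_center[2])
  list(cell_fill = render(dend, "cell_fill"),
       mitochondria = render(mito, "mitochondria"),
       dendrite_mask = dend, mito_mask = mito,
       soma_center_px = as.numeric(sc))
}

# set TRUE all pixels within r_px of any of the given (x, y) pixel points
stamp_disks <- function(mask, pts, r_px) {
  H <- nrow(mask); W <- ncol(mask)
  ri <- ceiling(r_px)
  off <- expand.grid(dx = -ri:ri, dy = -ri:ri)
  off <- off[off$dx^2 + off$dy^2 <= r_px^2 + 1e-9, ]
  cx <- round(pts[, 1]); cy <- round(pts[, 2])
  for (k in seq_len(nrow(off))) {
    xs <- cx + off$dx[k]; ys <- cy + off$dy[k]
    ok <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
    mask[cbind(ys[ok], xs[ok])] <- TRUE
  }
  mask
}

#' Organelle motility model
#'
#' Two-state (run / pause) transport along a 1-D path. A particle is mobile
#' with probability `p_mobile`; mobile particles take a direction
#' (anterograde with `p_anterograde`) and a personal speed drawn from
#' `Normal(run_speed_mean, run_speed_sd)`, and alternate runs and pauses
#' with exponential waiting times at `pause_rate` / `resume_rate`. Defaults
#' approximate dendritic mitochondria: ~30% mobile at ~0.4 um/s with
#' frequent pausing.
#'
#' @param p_mobile fraction of mobile particles.
#' @param p_anterograde anterograde fraction among mobile particles.
#' @param run_speed_mean,run_speed_sd run speed distribution, um/s.
#' @param pause_rate,resume_rate state-switch rates, per second.
#' @param seed RNG seed for [simulate_timelapse()].
#' @return a `motility_model`.
#' @export
motility_model <- function(p_mobile = 0.3, p_anterograde = 0.5,
                           run_speed_mean = 0.4, run_speed_sd = 0.05,
                           pause_rate = 0.05, resume_rate = 0.2, seed = 1) {
  stopifnot(p_mobile >= 0, p_mobile <= 1, p_anterograde >= 0,
            p_anterograde <= 1, run_speed_mean > 0, run_speed_sd >= 0,
            pause_rate >= 0, resume_rate >= 0)
  structure(list(p_mobile = p_mobile, p_anterograde = p_anterograde,
                 run_speed_mean = run_speed_mean,
                 run_speed_sd = run_speed_sd, pause_rate = pause_rate,
                 resume_rate = resume_rate, seed = seed),
            class = "motility_model")
}

#' Simulate a time-lapse movie of particles on a 1-D path
#'
#' Renders each frame as a small 2-D image with Gaussian spots on the path
#' row plus additive noise, and returns full ground truth (per-frame
#' positions, assigned class, per-particle speed). Particles reflect at the
#' path ends so the particle count is constant; the soma sits at the
#' low-position end.
#'
#' @param path_length um.
#' @param model a [motility_model()].
#' @param n_frames number of frames, >= 2.
#' @param frame_interval seconds.
#' @param pixel_size um per pixel.
#' @param n_particles particle count.
#' @param noise_sd camera noise sd (intensity units; spot amplitude is 100).
#' @param initial_positions optional fixed starting positions in um
#'   (defaults to uniform placements).
#' @param psf_sigma_px spot Gaussian sd in pixels.
#' @return list: `stack` (list of frames), `path` (2-column pixel polyline
#'   for [build_kymograph()]), `truth` (list with `positions` matrix
#'   particles x frames, `class`, `mobile`, `direction`, `speed`, and
#'   ground-truth `tracks`), plus `pixel_size` and `frame_interval`.
#' @export
simulate_timelapse <- function(path_length, model, n_frames = 60,
                               frame_interval = 2, pixel_size = 0.2,
                               n_particles = 10, noise_sd = 2,
                               initial_positions = NULL, psf_sigma_px = 1.2) {
  stopifnot(inherits(model, "motility_model"), n_frames >= 2,
            path_length > 0)
  set.seed(model$seed)
  n <- n_particles
  pos0 <- if (is.null(initial_positions))
    stats::runif(n, 0.02, 0.98) * path_length else initial_positions
  mobile <- stats::runif(n) < model$p_mobile
  direction <- ifelse(stats::runif(n) < model$p_anterograde, 1, -1)
  direction[!mobile] <- 0
  speed <- pmax(0.01, stats::rnorm(n, model$run_speed_mean,
                                   model$run_speed_sd))
  p_pause <- 1 - exp(-model$pause_rate * frame_interval)
  p_resume <- 1 - exp(-model$resume_rate * frame_interval)

  positions <- matrix(0, n, n_frames)
  positions[, 1] <- pos0
  running <- rep(TRUE, n)
  dir_now <- direction
  for (f in 2:n_frames) {
    switch_off <- running & stats::runif(n) < p_pause
    switch_on <- !running & stats::runif(n) < p_resume
    running <- (running & !switch_off) | switch_on
    step <- ifelse(mobile & running, dir_now * speed * frame_interval, 0)
    p <- positions[, f - 1] + step
    over <- p > path_length; under <- p < 0
    p[over] <- 2 * path_length - p[over]
    p[under] <- -p[under]
    dir_now[over | under] <- -dir_now[over | under]
    positions[, f] <- p
  }

  W <- ceiling(path_length / pixel_size) + 1L
  H <- 5L; row0 <- 3L
  cols <- seq_len(W)
  stack <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    frame <- matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    for (i in seq_len(n)) {
      cx <- positions[i, f] / pixel_size + 1
      lo <- max(1L, floor(cx - 4 * psf_sigma_px))
      hi <- min(W, ceiling(cx + 4 * psf_sigma_px))
      prof <- 100 * exp(-((lo:hi) - cx)^2 / (2 * psf_sigma_px^2))
      for (r in seq_len(H))
        frame[r, lo:hi] <- frame[r, lo:hi] +
          prof * exp(-((r - row0)^2) / (2 * 1.0^2))
    }
    stack[[f]] <- frame
  }

  class_lab <- ifelse(!mobile, "stationary",
                      ifelse(direction > 0, "anterograde", "retrograde"))
  gt_tracks <- lapply(seq_len(n), function(i)
    track(seq_len(n_frames), positions[i, ], frame_interval = frame_interval,
          soma_end = "low_index"))
  list(stack = stack,
       path = cbind(c(1, W), c(row0, row0)),
       truth = list(positions = positions, class = class_lab,
                    mobile = mobile, direction = direction, speed = speed,
                    tracks = gt_tracks),
       pixel_size = pixel_size, frame_interval = frame_interval,
       seed = model$seed)
}
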