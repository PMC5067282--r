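# programmatic fixtures shared across test files

# straight cable of `n` nodes spaced `spacing` um along direction (dx, dy);
# root is the first cable node unless a soma is prepended
make_cable <- function(n = 10, spacing = 5, dx = 1, dy = 0, soma = FALSE,
                       structure = "dendrite_basal") {
  nrm <- sqrt(dx^2 + dy^2)
  ux <- dx / nrm; uy <- dy / nrm
  off <- if (soma) 1L else 0L
  rows <- list()
  if (soma)
    rows[[1]] <- data.frame(id = 1L, structure = "soma", x = 0, y = 0, z = 0,
                            radius = 5, parent = NA_integer_)
  for (i in seq_len(n)) {
    d <- i * spacing
    rows[[length(rows) + 1L]] <- data.frame(
      id = off + i, structure = structure,
      x = if (soma) d * ux else (i - 1) * spacing * ux,
      y = if (soma) d * uy else (i - 1) * spacing * uy,
      z = 0, radius = 0.5,
      parent = if (i == 1L) (if (soma) 1L else NA_integer_) else off + i - 1L)
  }
  neuron_morphology(do.call(rbind, rows))
}

# soma + full binary dendritic tree of the given depth; every internal
# dendrite node has two children, branch arms of length `arm`
make_binary_tree <- function(depth = 3, arm = 10) {
  rows <- list(data.frame(id = 1L, structure = "soma", x = 0, y = 0, z = 0,
                          radius = 2, parent = NA_integer_))
  nid <- 1L
  grow <- function(parent_id, x, y, angle, level) {
    nid <<- nid + 1L
    my_id <- nid
    nx <- x + arm * cos(angle); ny <- y + arm * sin(angle)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = my_id, structure = "dendrite_basal", x = nx, y = ny, z = 0,
      radius = 0.5, parent = parent_id)
    if (level < depth) {
      grow(my_id, nx, ny, angle + 0.4, level + 1L)
      grow(my_id, nx, ny, angle - 0.4, level + 1L)
    }
  }
  grow(1L, 0, 0, 0.1, 1L)
  neuron_morphology(do.call(rbind, rows))
}

# random small tree for oracle tests
random_test_tree <- function(seed) {
  generate_tree(tree_model(n_primary = 3, branch_rate = 0.03,
                           segment_length_mean = 25, segment_length_sd = 8,
                           max_depth = 3, tortuosity = 0.2, seed = seed))
}

# independent Sholl-intersection oracle: dense sampling of the radial
# distance along every edge, counting transitions across each sphere
# (inside = distance < r, so a point exactly at r is outside)
brute_sholl_intersections <- function(morph, step, n_samples = 200) {
  nd <- morph$nodes
  sc <- morph$soma_center
  d_node <- sqrt((nd$x - sc[1])^2 + (nd$y - sc[2])^2 + (nd$z - sc[3])^2)
  dend <- nd$structure %in% c("dendrite_basal", "dendrite_apical")
  maxd <- max(d_node[dend])
  radii <- seq_len(floor(maxd / step)) * step
  counts <- integer(length(radii))
  t <- seq(0, 1, length.out = n_samples)
  for (i in which(!is.na(nd$parent) & dend)) {
    p <- match(nd$parent[i], nd$id)
    xs <- nd$x[p] + t * (nd$x[i] - nd$x[p]) - sc[1]
    ys <- nd$y[p] + t * (nd$y[i] - nd$y[p]) - sc[2]
    zs <- nd$z[p] + t * (nd$z[i] - nd$z[p]) - sc[3]
    d <- sqrt(xs^2 + ys^2 + zs^2)
    for (k in seq_along(radii)) {
      inside <- d < radii[k]
      counts[k] <- counts[k] + sum(inside[-1] != inside[-n_samples])
    }
  }
  counts
}

# independent per-pixel binning oracle for mito_sholl
brute_pixel_shells <- function(mask, center, w = 1) {
  counts <- numeric(0)
  for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    if (!mask[r, cc]) next
    d <- sqrt((cc - center[1])^2 + (r - center[2])^2)
    k <- floor(d / w) + 1
    if (k > length(counts)) counts <- c(counts, rep(0, k - length(counts)))
    counts[k] <- counts[k] + 1
  }
  counts
}

# analytic Mito60 for a truncated-exponential placement density
analytic_mito60 <- function(tau, p = 0.6) -tau * log(1 - p * (1 - exp(-1 / tau)))

# mito60 estimated through the package pipeline from a placed set
pipeline_mito60 <- function(mitos, path_length, shell_width = 1) {
  mito60(mpm(position_profile(mitos, shell_width), path_length))
}
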