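#' Radial profile container
#'
#' Holds a per-shell quantity versus distance from the soma: `shell_edges` are
#' the `n + 1` strictly increasing bin edges and `counts` the quantity in each
#' of the `n` shells `[edge_k, edge_{k+1})`. For `intersections` profiles the
#' count in shell `k` is the number of process crossings of the sphere at the
#' shell's *outer* edge, the classical Sholl convention.
#'
#' @param shell_edges strictly increasing numeric vector (um or pixels).
#' @param counts non-negative quantity per shell; one shorter than the edges.
#' @param quantity_kind one of `"pixels"`, `"branchpoints"`, `"intersections"`.
#' @param unit distance unit label, `"um"` or `"pixel"`.
#' @return a `radial_profile` object.
#' @export
radial_profile <- function(shell_edges, counts,
                           quantity_kind = c("pixels", "branchpoints",
                                             "intersections"),
                           unit = "um") {
  quantity_kind <- match.arg(quantity_kind)
  shell_edges <- as.numeric(shell_edges)
  counts <- as.numeric(counts)
  if (length(counts) != length(shell_edges) - 1L)
    stop("length(counts) must equal length(shell_edges) - 1")
  if (any(diff(shell_edges) <= 0))
    stop("shell_edges must be strictly increasing")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(shell_edges = shell_edges, counts = counts,
                 quantity_kind = quantity_kind, unit = unit),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat("<radial_profile> ", length(x$counts), " shells of ", x$quantity_kind,
      ", reaching ", max(x$shell_edges), " ", x$unit,
      " (total ", sum(x$counts), ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.radial_profile <- function(x, ...) {
  n <- length(x$counts)
  data.frame(shell_start = x$shell_edges[seq_len(n)],
             shell_end = x$shell_edges[seq_len(n) + 1L],
             count = x$counts)
}

#' Total traced length per structure
#'
#' Sums the Euclidean lengths of parent-child edges whose child node belongs
#' to the selected structures. Edges internal to the soma contour are always
#' excluded, so a multi-point soma does not inflate dendritic length.
#'
#' @param morph a `neuron_morphology`.
#' @param structures structure labels to include; defaults to both dendrite
#'   classes.
#' @return total length in um.
#' @export
total_length <- function(morph, structures = dendrite_structures()) {
  stopifnot(inherits(morph, "neuron_morphology"))
  structures <- match_structures(structures)
  ed <- edge_table(morph)
  nd <- morph$nodes
  keep <- nd$structure[ed$child] %in% structures &
    !(nd$structure[ed$child] == "soma" & nd$structure[ed$parent] == "soma")
  sum(ed$length[keep])
}

match_structures <- function(structures) {
  if (length(structures) == 0) stop("empty structure selection")
  bad <- setdiff(structures, swc_structures())
  if (length(bad) > 0)
    stop("unknown structure(s): ", paste(bad, collapse = ", "))
  structures
}

#' Branchpoints and their radial distances
#'
#' A branchpoint is a node of the selected structures with at least two
#' children in those structures; the soma is never a branchpoint (primary
#' dendrites emerging from it are counted by [morphometry_summary()] instead).
#' Distance is Euclidean (radial) from the soma center.
#'
#' @inheritParams total_length
#' @return data.frame with columns `id` and `distance` (um), one row per
#'   branchpoint.
#' @export
branchpoints <- function(morph, structures = dendrite_structures()) {
  stopifnot(inherits(morph, "neuron_morphology"))
  structures <- match_structures(structures)
  nd <- morph$nodes
  cc <- child_counts(morph, structures)
  is_bp <- cc >= 2L & nd$structure %in% structures
  d <- node_radial_distances(morph)
  data.frame(id = nd$id[is_bp], distance = d[is_bp])
}

#' Sholl profile of a traced morphology
#'
#' Concentric spheres centered at the soma at radii `step, 2*step, ...`.
#' With `quantity = "intersections"` each sphere counts the process segments
#' crossing it (a segment whose radial distance passes through the radius;
#' points exactly at a radius belong to the outside, so a tip landing exactly
#' on a sphere still registers the crossing). With `quantity = "branchpoints"`
#' each annulus `[r, r + step)` counts the branchpoints it contains.
#'
#' @inheritParams total_length
#' @param step shell spacing in um; must be positive.
#' @param quantity `"intersections"` or `"branchpoints"`.
#' @param distance `"radial"` (Euclidean from the soma center, the default)
#'   or `"path"` (arclength along the trace); path mode is available for
#'   branchpoint profiles only.
#' @return a `radial_profile`.
#' @export
sholl <- function(morph, step,
                  quantity = c("intersections", "branchpoints"),
                  structures = dendrite_structures(),
                  distance = c("radial", "path")) {
  stopifnot(inherits(morph, "neuron_morphology"))
  quantity <- match.arg(quantity)
  distance <- match.arg(distance)
  structures <- match_structures(structures)
  if (!is.numeric(step) || length(step) != 1 || step <= 0)
    stop("step must be a positive number")

  if (quantity == "branchpoints") {
    bp <- branchpoints(morph, structures)
    if (distance == "path") {
      pd <- node_path_distances(morph)
      bp$distance <- pd[match(bp$id, morph$nodes$id)]
    }
    if (nrow(bp) == 0)
      return(radial_profile(c(0, step), 0, "branchpoints"))
    nshell <- floor(max(bp$distance) / step) + 1L
    idx <- floor(bp$distance / step) + 1L      # half-open [r, r+step)
    counts <- tabulate(idx, nbins = nshell)
    return(radial_profile(seq(0, nshell) * step, counts, "branchpoints"))
  }

  if (distance == "path")
    stop("path distance is only defined for branchpoint profiles")
  ed <- edge_table(morph)
  nd <- morph$nodes
  keep <- nd$structure[ed$child] %in% structures &
    !(nd$structure[ed$child] == "soma" & nd$structure[ed$parent] == "soma")
  ed <- ed[keep, , drop = FALSE]
  d <- node_radial_distances(morph)
  maxd <- max(d[nd$structure %in% structures], 0)
  nshell <- floor(maxd / step)
  if (nshell < 1L)
    return(radial_profile(c(0, step), 0, "intersections"))
  radii <- seq_len(nshell) * step

  counts <- integer(nshell)
  sc <- morph$soma_center
  for (i in seq_len(nrow(ed))) {
    a <- c(nd$x[ed$parent[i]], nd$y[ed$parent[i]], nd$z[ed$parent[i]]) - sc
    b <- c(nd$x[ed$child[i]], nd$y[ed$child[i]], nd$z[ed$child[i]]) - sc
    counts <- counts + segment_sphere_crossings(a, b, radii)
  }
  radial_profile(c(0, radii), counts, "intersections")
}

# Number of crossings of the segment a->b (soma at origin) with each sphere
# radius. The radial distance along the segment is unimodal with a single
# minimum; on each monotone piece a sphere of radius r is crossed iff
# min(d) < r <= max(d) (points exactly at r count as outside the open ball).
segment_sphere_crossings <- function(a, b, radii) {
  v <- b - a
  vv <- sum(v * v)
  tstar <- if (vv > 0) max(0, min(1, -sum(a * v) / vv)) else 0
  da <- sqrt(sum(a^2))
  db <- sqrt(sum((a + v)^2))
  dm <- sqrt(sum((a + tstar * v)^2))
  (pmin(dm, da) < radii & radii <= pmax(dm, da)) +
    (pmin(dm, db) < radii & radii <= pmax(dm, db))
}

# path (arclength) distance from the root for every node
node_path_distances <- function(morph) {
  nd <- morph$nodes
  ed <- edge_table(morph)
  d <- rep(NA_real_, nrow(nd))
  d[is.na(nd$parent)] <- 0
  # nodes are not guaranteed topologically sorted; iterate until settled
  remaining <- ed
  while (nrow(remaining) > 0) {
    ready <- !is.na(d[remaining$parent])
    if (!any(ready)) stop("internal error: disconnected edges")
    d[remaining$child[ready]] <- d[remaining$parent[ready]] +
      remaining$length[ready]
    remaining <- remaining[!ready, , drop = FALSE]
  }
  d
}

#' Size-normalized branchpoint position (BP90)
#'
#' Divides each branchpoint's radial distance by the cell's maximum radial
#' tip distance (tip = 1) and returns the 0.90 empirical quantile of the
#' normalized distances, linearly interpolated between order statistics.
#' Values near 1 mean branching reaches the periphery; proximal-shifted
#' arbors give smaller values. Invariant under rigid motion and uniform
#' scaling of the trace.
#'
#' @inheritParams total_length
#' @param probs quantile level; 0.90 for the headline statistic.
#' @return a value in (0, 1].
#' @export
bp90 <- function(morph, structures = dendrite_structures(), probs = 0.90) {
  stopifnot(inherits(morph, "neuron_morphology"))
  structures <- match_structures(structures)
  bp <- branchpoints(morph, structures)
  if (nrow(bp) == 0)
    stop("bp90 is undefined for a morphology with no branchpoints")
  nd <- morph$nodes
  cc <- child_counts(morph)                 # tips: no children at all
  sel <- nd$structure %in% structures
  tips <- sel & cc == 0L
  if (!any(tips)) stop("no terminal tips in the selected structures")
  d <- node_radial_distances(morph)
  max_tip <- max(d[tips])
  if (max_tip <= 0) stop("degenerate morphology: all tips at the soma center")
  unname(stats::quantile(bp$distance / max_tip, probs = probs, type = 7))
}

#' Maximum dendritic tip distance of a cell
#'
#' The size-normalization reference used by BP90 and the MPM: the largest
#' distance from the soma to a terminal tip of the selected structures,
#' either radial (Euclidean) or along the path (arclength) — use the mode
#' matching the coordinate of the quantity being normalized.
#'
#' @inheritParams total_length
#' @param mode `"radial"` or `"path"`.
#' @return distance in um.
#' @export
max_tip_distance <- function(morph, structures = dendrite_structures(),
                             mode = c("radial", "path")) {
  stopifnot(inherits(morph, "neuron_morphology"))
  mode <- match.arg(mode)
  structures <- match_structures(structures)
  nd <- morph$nodes
  tips <- nd$structure %in% structures & child_counts(morph) == 0L
  if (!any(tips)) stop("no terminal tips in the selected structures")
  d <- if (mode == "radial") node_radial_distances(morph)
  else node_path_distances(morph)
  max(d[tips])
}

#' Whole-cell morphometry summary
#'
#' @inheritParams total_length
#' @param sholl_step shell spacing passed through to [bp90()]'s companion
#'   profile consumers; not used in the scalar summary itself.
#' @return data.frame with one row: total dendritic and axonal length (um),
#'   branchpoint count, primary dendrite count, and BP90 (NA when the cell
#'   has no branchpoints).
#' @export
morphometry_summary <- function(morph, structures = dendrite_structures()) {
  stopifnot(inherits(morph, "neuron_morphology"))
  nd <- morph$nodes
  parent_struct <- nd$structure[match(nd$parent, nd$id)]
  n_primary <- sum(nd$structure %in% dendrite_structures() &
                     !is.na(parent_struct) & parent_struct == "soma")
  bp <- branchpoints(morph, structures)
  data.frame(
    total_dendritic_length = total_length(morph, dendrite_structures()),
    total_axonal_length = if ("axon" %in% nd$structure)
      total_length(morph, "axon") else 0,
    n_branchpoints = nrow(bp),
    n_primary_dendrites = n_primary,
    bp90 = if (nrow(bp) > 0) bp90(morph, structures) else NA_real_
  )
}
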