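#' Neuron morphology objects
#'
#' A `neuron_morphology` is a validated rooted tree of traced nodes in
#' micrometers, the in-memory form of an SWC reconstruction. Nodes carry a
#' structure label (`soma`, `axon`, `dendrite_basal`, `dendrite_apical`),
#' 3-D coordinates, a radius and a parent reference; the soma center is the
#' centroid of the soma-labelled nodes unless overridden.
#'
#' @param nodes data.frame with columns `id`, `structure`, `x`, `y`, `z`,
#'   `radius`, `parent` (`NA` for the root). Coordinates and radii in um.
#' @param soma_center optional numeric length-3 override of the soma centroid,
#'   useful for single-point somas traced away from the arbor's visual center.
#' @return an object of class `neuron_morphology`.
#' @export
neuron_morphology <- function(nodes, soma_center = NULL) {
  required <- c("id", "structure", "x", "y", "z", "radius", "parent")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes)))
    stop("`nodes` must be a data.frame with columns ",
         paste(required, collapse = ", "))
  nodes <- nodes[, required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$structure <- as.character(nodes$structure)

  bad <- setdiff(unique(nodes$structure), swc_structures())
  if (length(bad) > 0)
    stop("unknown structure label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids")
  if (!all(is.finite(nodes$x) & is.finite(nodes$y) & is.finite(nodes$z)))
    stop("all coordinates must be finite")
  if (any(!is.finite(nodes$radius) | nodes$radius < 0))
    stop("radius must be finite and >= 0")

  roots <- which(is.na(nodes$parent))
  if (length(roots) != 1L)
    stop("morphology must have exactly one root, found ", length(roots))
  missing_parent <- setdiff(nodes$parent[!is.na(nodes$parent)], nodes$id)
  if (length(missing_parent) > 0)
    stop("parent id(s) not present in node table: ",
         paste(missing_parent, collapse = ", "))

  # connectivity + acyclicity: every node must reach the root by parent links
  idx <- match(nodes$parent, nodes$id)
  n <- nrow(nodes)
  depth <- rep(NA_integer_, n)
  depth[roots] <- 0L
  frontier <- roots
  while (length(frontier) > 0) {
    children <- which(idx %in% frontier & is.na(depth))
    depth[children] <- 1L
    frontier <- children
  }
  if (anyNA(depth))
    stop("morphology is not a single connected tree (cycle or orphan subtree)")

  if (is.null(soma_center)) {
    soma <- nodes[nodes$structure == "soma", c("x", "y", "z")]
    if (nrow(soma) == 0) {
      root_row <- nodes[is.na(nodes$parent), c("x", "y", "z")]
      soma_center <- as.numeric(root_row[1, ])
    } else {
      soma_center <- colMeans(soma)
    }
  }
  soma_center <- as.numeric(soma_center)
  stopifnot(length(soma_center) == 3, all(is.finite(soma_center)))

  structure(list(nodes = nodes, soma_center = soma_center),
            class = "neuron_morphology")
}

swc_structures <- function() c("soma", "axon", "dendrite_basal", "dendrite_apical")

dendrite_structures <- function() c("dendrite_basal", "dendrite_apical")

#' @export
print.neuron_morphology <- function(x, ...) {
  tab <- table(factor(x$nodes$structure, levels = swc_structures()))
  cat("<neuron_morphology> ", nrow(x$nodes), " nodes (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n",
      sep = "")
  cat("  soma center: (", paste(sprintf("%.2f", x$soma_center), collapse = ", "),
      ") um\n", sep = "")
  invisible(x)
}

#' Parse an SWC reconstruction
#'
#' Reads the standard 7-column SWC dialect (id, type, x, y, z, radius, parent;
#' `#` comments; parent -1 for the root). Type codes map 1 -> soma, 2 -> axon,
#' 3 -> basal dendrite, 4 -> apical dendrite; any other code is treated as
#' basal dendrite with a warning, so undefined custom codes do not silently
#' drop tracing.
#'
#' @param x path to an SWC file, or a character vector of SWC lines.
#' @param soma_center optional soma-center override passed to
#'   [neuron_morphology()].
#' @return a `neuron_morphology`.
#' @export
parse_swc <- function(x, soma_center = NULL) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    readLines(x) else unlist(strsplit(x, "\n"))
  lines_raw <- lines
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0) stop("no SWC records found")

  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  nfield <- lengths(fields)
  if (any(nfield != 7L)) {
    bad <- keep[which(nfield != 7L)[1]]
    stop("malformed SWC line ", bad, " (expected 7 columns): ",
         trimws(lines_raw[bad]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    bad <- keep[which(rowSums(is.na(m)) > 0)[1]]
    stop("non-numeric field on SWC line ", bad, ": ", trimws(lines_raw[bad]))
  }

  type_code <- as.integer(m[, 2])
  structure_lab <- rep("dendrite_basal", nrow(m))
  structure_lab[type_code == 1] <- "soma"
  structure_lab[type_code == 2] <- "axon"
  structure_lab[type_code == 4] <- "dendrite_apical"
  unknown <- !(type_code %in% 1:4)
  if (any(unknown))
    warning(sum(unknown), " node(s) with unknown SWC type code mapped to ",
            "dendrite_basal")

  nodes <- data.frame(
    id = as.integer(m[, 1]),
    structure = structure_lab,
    x = m[, 3], y = m[, 4], z = m[, 5],
    radius = m[, 6],
    parent = ifelse(m[, 7] < 0, NA_integer_, as.integer(m[, 7]))
  )
  neuron_morphology(nodes, soma_center = soma_center)
}

#' Write a morphology to SWC
#'
#' @param morph a `neuron_morphology`.
#' @param file path to write; with `file = NULL` the SWC lines are returned
#'   as a character vector.
#' @return the SWC lines, invisibly when written to a file.
#' @export
write_swc <- function(morph, file = NULL) {
  stopifnot(inherits(morph, "neuron_morphology"))
  nd <- morph$nodes
  code <- match(nd$structure, swc_structures())
  lines <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                   nd$id, code, nd$x, nd$y, nd$z, nd$radius,
                   ifelse(is.na(nd$parent), -1L, nd$parent))
  lines <- c("# id type x y z radius parent", lines)
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

# radial (Euclidean) distance of every node from the soma center
node_radial_distances <- function(morph) {
  nd <- morph$nodes
  sc <- morph$soma_center
  sqrt((nd$x - sc[1])^2 + (nd$y - sc[2])^2 + (nd$z - sc[3])^2)
}

# per-node count of children restricted to the given structures
child_counts <- function(morph, structures = NULL) {
  nd <- morph$nodes
  keep <- !is.na(nd$parent)
  if (!is.null(structures)) keep <- keep & nd$structure %in% structures
  counts <- integer(nrow(nd))
  if (any(keep)) {
    tab <- table(factor(nd$parent[keep], levels = nd$id))
    counts <- as.integer(tab)
  }
  counts
}

# edge table: child row index, parent row index, Euclidean length
edge_table <- function(morph) {
  nd <- morph$nodes
  child <- which(!is.na(nd$parent))
  parent <- match(nd$parent[child], nd$id)
  len <- sqrt((nd$x[child] - nd$x[parent])^2 +
              (nd$y[child] - nd$y[parent])^2 +
              (nd$z[child] - nd$z[parent])^2)
  data.frame(child = child, parent = parent, length = len)
}
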