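#' Two-group comparison (Welch t or Mann-Whitney)
#'
#' The Mann-Whitney branch computes the exact two-sided permutation p-value
#' by full enumeration of group assignments when the pooled sample is small
#' (n1 + n2 <= 20; ties handled through midranks), and otherwise the normal
#' approximation with tie correction. The t branch is the Welch unequal-
#' variance form via [stats::t.test()].
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param test `"t_test"` or `"mann_whitney"`.
#' @param labels group labels for reporting.
#' @return a `group_comparison` list: `statistic_name`, `statistic`
#'   (t, or Mann-Whitney U of the first group), `p_value`, `test`,
#'   `group_labels`, `per_cell_values`.
#' @export
compare_groups <- function(a, b, test = c("t_test", "mann_whitney"),
                           labels = c("A", "B")) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")

  if (test == "t_test") {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    stat <- unname(ht$statistic); p <- ht$p.value; name <- "t"
  } else {
    n1 <- length(a); n2 <- length(b)
    r <- rank(c(a, b))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    name <- "U"; stat <- U
    if (n1 + n2 <= 20) {
      p <- mw_exact_p(r, n1)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                correct = TRUE))
      p <- ht$p.value
    }
  }
  structure(list(group_labels = labels, per_cell_values = list(a, b),
                 statistic_name = name, statistic = stat,
                 p_value = min(1, p), test = test),
            class = "group_comparison")
}

# exact two-sided Mann-Whitney p by enumeration of all group-1 assignments;
# works with ties because the observed midranks define the permutation null
mw_exact_p <- function(r, n1) {
  n <- length(r)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  Us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$group_labels[1], " (n=",
      length(x$per_cell_values[[1]]), ") vs ", x$group_labels[2], " (n=",
      length(x$per_cell_values[[2]]), "): ", x$test, "\n  ",
      x$statistic_name, " = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Percent change of a test group relative to a reference
#'
#' `100 * (reference_mean - test_mean) / reference_mean`: positive values are
#' decreases relative to the reference, negative values increases.
#'
#' @param reference_mean reference group mean (non-zero).
#' @param test_mean test group mean.
#' @return percent change.
#' @export
percent_change <- function(reference_mean, test_mean) {
  if (!is.finite(reference_mean) || reference_mean == 0)
    stop("reference mean must be finite and non-zero")
  100 * (reference_mean - test_mean) / reference_mean
}

#' Batch morphometry over SWC files
#'
#' Parses each file, computes the per-cell summary and a branchpoint Sholl
#' profile, and averages the profiles on a common radius grid. Unparseable
#' files are skipped with a warning; the call errors only if none parse.
#'
#' @param swc_files character vector of SWC paths (or a list of
#'   `neuron_morphology` objects).
#' @param sholl_step Sholl shell spacing in um.
#' @param structures structures analyzed.
#' @param out_dir optional directory to write `cells.csv` and `sholl.csv`.
#' @return list: `cells` (one summary row per cell), `sholl` (data.frame
#'   `radius`, per-cell columns, `mean`).
#' @export
run_morphometry <- function(swc_files, sholl_step = 10,
                            structures = dendrite_structures(),
                            out_dir = NULL) {
  if (length(swc_files) == 0) stop("no input cells given")
  cells <- list(); profiles <- list(); names_used <- character(0)
  for (i in seq_along(swc_files)) {
    f <- swc_files[[i]]
    m <- tryCatch(if (inherits(f, "neuron_morphology")) f else parse_swc(f),
                  error = function(e) {
                    warning("skipping cell ", i, ": ", conditionMessage(e))
                    NULL
                  })
    if (is.null(m)) next
    nm <- if (is.character(f)) basename(f) else paste0("cell_", i)
    cells[[length(cells) + 1L]] <- cbind(cell = nm,
                                         morphometry_summary(m, structures))
    profiles[[length(profiles) + 1L]] <- sholl(m, sholl_step, "branchpoints",
                                               structures)
    names_used <- c(names_used, nm)
  }
  if (length(cells) == 0) stop("no SWC file could be parsed")
  cells <- do.call(rbind, cells)

  nmax <- max(vapply(profiles, function(p) length(p$counts), integer(1)))
  radius <- (seq_len(nmax) - 0.5) * sholl_step
  mat <- vapply(profiles, function(p) {
    c(p$counts, rep(0, nmax - length(p$counts)))
  }, numeric(nmax))
  mat <- matrix(mat, nrow = nmax)
  shl <- data.frame(radius = radius, mat, mean = rowMeans(mat))
  names(shl) <- c("radius", names_used, "mean")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(shl, file.path(out_dir, "sholl.csv"), row.names = FALSE)
  }
  list(cells = cells, sholl = shl)
}

#' Group-average MPM curves on a common normalized grid
#'
#' Per-cell MPMs are first interpolated onto a shared normalized-distance
#' grid (piecewise-linear, anchored at (0, 0)), then averaged pointwise;
#' averaging preserves monotonicity and the endpoint at 1.
#'
#' @param cdfs list of `cumulative_distribution` objects.
#' @param grid common normalized grid, default 0..1 by 0.01.
#' @return data.frame `normalized_distance`, `mean`, and one column per cell.
#' @export
average_mpm <- function(cdfs, grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(cdfs) >= 1)
  mat <- vapply(cdfs, function(cdf) {
    stats::approx(x = c(0, cdf$normalized_distance, 1),
                  y = c(0, cdf$cumulative_fraction, 1),
                  xout = grid, ties = "ordered", rule = 2)$y
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  out <- data.frame(normalized_distance = grid, mean = rowMeans(mat))
  cbind(out, as.data.frame(mat))
}

#' Mitochondrial-distribution statistics for a cohort of cells
#'
#' Placement mode: each cell is a list with a `mitos` `mitochondrion_set`
#' and a `max_extent` (um, the cell's tip reference). Image mode: each cell
#' is a list with `mito_image` and `dendrite_image` (`labeled_image` or
#' matrix), a `soma_center` in pixel coordinates, and optionally fixed
#' thresholds. Produces per-cell Mito60 (and index, gaps and density where
#' the inputs allow) plus the group-average MPM.
#'
#' @param cells list of per-cell input lists (see details above).
#' @param shell_width shell width for the radial profile (um in placement
#'   mode, pixels in image mode).
#' @param gap_radius,gap_step occupancy-gap parameters, um.
#' @param out_dir optional directory for `mitomap_cells.csv` /
#'   `mpm_curves.csv`.
#' @return list: `cells` (per-cell statistics), `mpm` (curves from
#'   [average_mpm()]).
#' @export
run_mitomap <- function(cells, shell_width = 1, gap_radius = 0.5,
                        gap_step = 0.1, out_dir = NULL) {
  if (length(cells) == 0) stop("no input cells given")
  rows <- list(); cdfs <- list()
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    if (!is.null(cell$mitos)) {
      if (is.null(cell$max_extent))
        stop("placement mode needs max_extent for cell ", i)
      prof <- position_profile(cell$mitos, shell_width)
      cdf <- mpm(prof, cell$max_extent)
      gaps <- occupancy_gaps(cell$max_extent, cell$mitos,
                             radius = gap_radius, step = gap_step)
      rows[[i]] <- data.frame(
        cell = i, mito60 = mito60(cdf),
        fraction_unoccupied = gaps$fraction_unoccupied,
        density_per_10um = axonal_density(cell$max_extent, cell$mitos),
        mito_index = NA_real_)
    } else {
      if (is.null(cell$soma_center))
        stop("image mode needs soma_center for cell ", i)
      mito_mask <- segment_image(cell$mito_image,
                                 if (is.null(cell$mito_threshold)) "otsu"
                                 else "fixed", cell$mito_threshold)
      dend_mask <- segment_image(cell$dendrite_image,
                                 if (is.null(cell$dendrite_threshold)) "otsu"
                                 else "fixed", cell$dendrite_threshold)
      prof <- mito_sholl(mito_mask, cell$soma_center)
      dend_prof <- mito_sholl(dend_mask, cell$soma_center)
      max_extent <- max(dend_prof$shell_edges)
      cdf <- mpm(prof, max_extent)
      rows[[i]] <- data.frame(
        cell = i, mito60 = mito60(cdf),
        fraction_unoccupied = NA_real_, density_per_10um = NA_real_,
        mito_index = mitochondrial_index(mito_mask, dend_mask, cell$roi))
    }
    cdfs[[i]] <- cdf
  }
  tab <- do.call(rbind, rows)
  curves <- average_mpm(cdfs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "mitomap_cells.csv"),
                     row.names = FALSE)
    utils::write.csv(curves, file.path(out_dir, "mpm_curves.csv"),
                     row.names = FALSE)
  }
  list(cells = tab, mpm = curves)
}
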