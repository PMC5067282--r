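#' Read a (multi-frame) TIFF stack
#'
#' @param path TIFF file.
#' @param pixel_size um per pixel to attach to the frames.
#' @return list of numeric matrices (one per frame).
#' @export
read_stack <- function(path, pixel_size = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]   # drop extra channels
    storage.mode(f) <- "double"
    f
  })
}

#' Write a stack (or single image) to TIFF
#'
#' Intensities are rescaled to `[0, 1]` jointly across frames, as the TIFF
#' writer requires.
#'
#' @param x matrix, list of matrices, or `kymograph` / `labeled_image`.
#' @param path output file.
#' @export
write_stack <- function(x, path) {
  if (inherits(x, "kymograph")) x <- x$data
  if (inherits(x, "labeled_image")) x <- x$pixels
  frames <- if (is.list(x)) x else list(x)
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  rng <- if (hi > lo) hi - lo else 1
  frames <- lapply(frames, function(f) (f - lo) / rng)
  tiff::writeTIFF(frames, path)
  invisible(path)
}

#' Read a 2-column (x, y) coordinate CSV as a path polyline
#'
#' Accepts plain `x,y` tables (with or without header), e.g. point lists
#' exported from ImageJ ROIs.
#'
#' @param path CSV file.
#' @return n x 2 numeric matrix.
#' @export
read_path_csv <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^[0-9.+-]", trimws(strsplit(first, ",")[[1]][1]))
  tab <- utils::read.csv(path, header = has_header)
  m <- as.matrix(tab[, 1:2])
  colnames(m) <- c("x", "y")
  storage.mode(m) <- "double"
  m
}

#' Export a radial profile as CSV
#'
#' @param profile a `radial_profile`.
#' @param path output CSV.
#' @export
write_profile_csv <- function(profile, path) {
  df <- as.data.frame(profile)
  names(df) <- c(paste0("shell_start_", profile$unit),
                 paste0("shell_end_", profile$unit), "count")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a mitochondrion set as CSV
#'
#' @param mitos a `mitochondrion_set`.
#' @param path output CSV.
#' @export
write_mitos_csv <- function(mitos, path) {
  df <- data.frame(mito_id = seq_len(length(mitos)),
                   position_um = mitos$items$position_um,
                   length_um = mitos$items$length_um)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
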