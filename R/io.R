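## On-disk formats: clips and traces round-trip bit-exactly through RDS;
## event tables and point sets are plain CSV; voxel masks are multi-page TIFF.

#' Read and write stimulus clips and traces
#'
#' Clips and traces are stored as RDS (bit-exact round trip); the event table
#' of a clip can additionally be exported as CSV with columns
#' `label,start_s,end_s` for use outside R.
#'
#' @param x a [StimulusClip-class] or [EpochedTrace-class].
#' @param file path.
#' @return the object (readers), invisibly the path (writers).
#' @name clip-io
NULL

#' @rdname clip-io
#' @export
writeClip <- function(x, file) {
  stopifnot(methods::is(x, "StimulusClip"))
  saveRDS(x, file)
  invisible(file)
}

#' @rdname clip-io
#' @export
readClip <- function(file) {
  x <- readRDS(file)
  stopifnot(methods::is(x, "StimulusClip"))
  x
}

#' @rdname clip-io
#' @export
writeTrace <- function(x, file) {
  stopifnot(methods::is(x, "EpochedTrace") ||
              (is.list(x) && all(vapply(x, methods::is, logical(1),
                                        "EpochedTrace"))))
  saveRDS(x, file)
  invisible(file)
}

#' @rdname clip-io
#' @export
readTrace <- function(file) readRDS(file)

#' @rdname clip-io
#' @export
writeEventsCsv <- function(x, file) {
  ev <- if (methods::is(x, "data.frame")) x else events(x)
  utils::write.csv(ev, file, row.names = FALSE)
  invisible(file)
}

#' @rdname clip-io
#' @export
readEventsCsv <- function(file)
  utils::read.csv(file, stringsAsFactors = FALSE)

#' Read and write voxel masks and puncta
#'
#' Masks go through multi-page TIFF (one page per z-slice, x along rows);
#' puncta and 2D point sets through CSV with micrometre coordinates.
#'
#' @param mask 3D logical array `(x, y, z)`.
#' @param file path.
#' @name anatomy-io
NULL

#' @rdname anatomy-io
#' @export
writeMask <- function(mask, file) {
  pages <- lapply(seq_len(dim(mask)[3]), function(k) mask[, , k] * 1)
  tiff::writeTIFF(pages, file)
  invisible(file)
}

#' @rdname anatomy-io
#' @export
readMask <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(FALSE, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) out[, , k] <- pages[[k]] > 0.5
  out
}

#' @rdname anatomy-io
#' @param points matrix with micrometre coordinates (2 or 3 columns).
#' @export
writePointsCsv <- function(points, file) {
  df <- as.data.frame(points)
  names(df) <- c("x_um", "y_um", "z_um")[seq_len(ncol(df))]
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname anatomy-io
#' @export
readPointsCsv <- function(file)
  as.matrix(utils::read.csv(file, stringsAsFactors = FALSE))
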