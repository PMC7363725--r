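#' Hounsfield-unit voxel volume
#'
#' Container for a 3-D scalar grid of Hounsfield units (HU) together with
#' its voxel spacing and world origin. World coordinates are millimetres;
#' voxel `[i, j, k]` has its centre at `origin_mm + (c(i, j, k) - 1) *
#' spacing_mm`, with axes ordered x (left to right), y (posterior to
#' anterior), z (inferior to superior).
#'
#' @param data numeric 3-D array of HU values (finite).
#' @param spacing_mm positive numeric triple, voxel edge lengths in mm.
#' @param origin_mm numeric triple, world position of voxel `[1,1,1]`.
#' @return an object of class `hu_volume`.
#' @export
hu_volume <- function(data, spacing_mm = c(0.3, 0.3, 0.3),
                      origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (length(data) == 0L) stop("empty volume")
  if (!all(is.finite(data))) stop("HU values must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be a strictly positive triple")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be a finite triple")
  structure(list(data = data, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hu_volume> %d x %d x %d voxels, spacing %s mm, HU [%g, %g]\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_mm), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Binary voxel mask
#'
#' A boolean grid sharing the geometry (spacing, origin) of the volume it
#' was derived from. `provenance` accumulates a human-readable record of
#' the threshold and morphological operations that produced the mask.
#'
#' @param data logical 3-D array.
#' @param spacing_mm,origin_mm geometry, as in [hu_volume()].
#' @param provenance character vector of applied operations.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing_mm = c(0.3, 0.3, 0.3),
                        origin_mm = c(0, 0, 0), provenance = character()) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop("`data` must be a logical 3-D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be a strictly positive triple")
  structure(list(data = data, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm),
                 provenance = as.character(provenance)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$data), 100 * mean(x$data)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Integer offsets of a discrete ball (Euclidean radius r, in voxels).
ball_offsets <- function(radius) {
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be >= 0")
  g <- expand.grid(i = -radius:radius, j = -radius:radius, k = -radius:radius)
  g <- g[g$i^2 + g$j^2 + g$k^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Write / read a volume as a raw grid with JSON sidecar
#'
#' The voxel data are stored as little-endian doubles in `<path>.raw.gz`
#' (gzip-compressed) and geometry metadata (shape, spacing, origin) in
#' `<path>.json`. This is the scan interchange format used by the
#' command-line tools in place of a DICOM series.
#'
#' @param vol an [hu_volume()].
#' @param path basename (without extension) for the two files.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   an [hu_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "hu_volume"))
  meta <- list(shape = dim(vol$data), spacing_mm = vol$spacing_mm,
               origin_mm = vol$origin_mm, dtype = "float64_le")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  con <- gzfile(paste0(path, ".raw.gz"), "wb")
  on.exit(close(con))
  writeBin(as.vector(vol$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  con <- gzfile(paste0(path, ".raw.gz"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = prod(shape), size = 8,
                  endian = "little")
  if (length(vals) != prod(shape)) stop("raw grid truncated")
  hu_volume(array(vals, dim = shape), meta$spacing_mm, meta$origin_mm)
}
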