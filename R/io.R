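#' Read an image file as an RGB array
#'
#' Reads PNG/TIFF (via the png and tiff packages) or JPEG (via EBImage)
#' into an `M x N x 3` array in `[0, 1]`, row/column oriented as base R
#' matrices. Grayscale input is replicated across channels; an alpha
#' channel is dropped.
#'
#' @param path File path; format inferred from the extension.
#' @return `M x N x 3` numeric array in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      img <- EBImage::readImage(path)
      a <- EBImage::imageData(img)
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    },
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 1L) x <- array(rep(x, 3L), c(dim(x)[1:2], 3L))
  x
}

#' Write an image array to disk
#'
#' Writes 8-bit PNG or TIFF depending on the file extension. Values are
#' clamped to `[0, 1]` and rounded to 8-bit levels, so an image already on
#' the 8-bit lattice round-trips without level loss (the 0-255 integer
#' levels are preserved exactly).
#'
#' @param x Image matrix or array with values in `[0, 1]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  x <- pmin(pmax(x, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  invisible(path)
}

#' Export an attention map
#'
#' Writes the overlap-averaged attention map either as a 16-bit grayscale
#' TIFF (values scaled from `[0, 1]`) or as a plain-text array readable
#' with [read_ram_txt()].
#'
#' @param ram An [attention_map] (see [build_ram()]).
#' @param path Output path; `.tif`/`.tiff` for 16-bit image export,
#'   anything else for whitespace-delimited text.
#' @return `path`, invisibly.
#' @export
export_ram <- function(ram, path) {
  stopifnot(inherits(ram, "attention_map"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pmin(pmax(ram$averaged, 0), 1), path, bits.per.sample = 16L)
  } else {
    utils::write.table(ram$averaged, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_ram
#' @export
read_ram_txt <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}
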