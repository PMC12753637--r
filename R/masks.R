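#' Label masks
#'
#' Throughout the package a segmentation mask is an integer matrix (rows = y,
#' columns = x, origin top-left, y increasing downward) holding per-pixel
#' class labels: 0 background, 1 PD-L1-positive intact tumour cell,
#' 2 PD-L1-negative intact tumour cell. These helpers validate masks and
#' read/write them as single-channel 8-bit PNG files carrying the literal
#' byte values 0/1/2.
#'
#' @param mask integer matrix with values in \{0, 1, 2\}.
#' @return `validate_mask()` returns the mask invisibly (storage mode
#'   integer), or signals an error describing the violation.
#' @export
validate_mask <- function(mask) {
  if (!is.matrix(mask)) {
    stop("mask must be a matrix (rows = y, columns = x)", call. = FALSE)
  }
  storage.mode(mask) <- "integer"
  bad <- setdiff(unique(as.vector(mask)), c(0L, 1L, 2L))
  if (length(bad) > 0) {
    stop("mask contains out-of-range labels: ",
         paste(bad, collapse = ", "),
         " (allowed: 0 background, 1 positive, 2 negative)", call. = FALSE)
  }
  invisible(mask)
}

#' @rdname validate_mask
#' @param path file path of an 8-bit single-channel PNG.
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] > 1L && any(raw[, , 1] != raw[, , min(2L, dim(raw)[3])])) {
      stop("mask PNG must be single-channel: ", path, call. = FALSE)
    }
    raw <- raw[, , 1]
  }
  mask <- matrix(as.integer(round(raw * 255)), nrow(raw), ncol(raw))
  validate_mask(mask)
  mask
}

#' @rdname validate_mask
#' @export
write_mask <- function(mask, path) {
  mask <- validate_mask(mask)
  png::writePNG(mask / 255, target = path)
  invisible(path)
}

#' Read and write RGB patch images
#'
#' Images are numeric arrays `H x W x 3` with channel intensities in
#' \[0, 1\] (the convention of the png package). 8-bit inputs on the 0-255
#' scale are rescaled on read. PNG and TIFF are supported, chosen by file
#' extension.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_image()` returns an `H x W x 3` array in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "': ", path, call. = FALSE)
  )
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), c(dim(img), 3L))
  }
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @param image numeric `H x W x 3` array in \[0, 1\].
#' @export
write_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L)
  image <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(image, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(image, where = path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "': ", path, call. = FALSE)
  )
  invisible(path)
}

#' Rescale 0-255 pixel data to the unit interval
#'
#' Affine input normalisation used by the segmenter: byte-scale intensities
#' are mapped to \[0, 1\]; data already in \[0, 1\] pass through unchanged.
#'
#' @param image numeric array.
#' @return array of the same shape with values in \[0, 1\].
#' @export
normalize_image <- function(image) {
  if (max(image) > 1) image <- image / 255
  pmin(pmax(image, 0), 1)
}

# run RNG-dependent code under a temporary seed, restoring global RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic expansion of one master seed into n substream seeds
expand_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
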