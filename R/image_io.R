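#' Read and write 8-bit grayscale slice images
#'
#' The pipeline stores converted slices as 8-bit grayscale images with
#' matching stems under `images/` and `masks/`.  PNG is used when the
#' \pkg{png} package is installed; otherwise images are written as plain-text
#' PGM (P2), a portable format any image tool can open.  Masks are stored
#' with their raw class identifiers (0, 1, 2) as pixel values, not rescaled,
#' so a mask file round-trips exactly.
#'
#' @param x integer matrix with values in 0..255 (rows = image height).
#' @param path output path; the extension (`.png` or `.pgm`) picks the codec.
#' @return `write_gray` returns `path` invisibly; `read_gray` an integer
#'   matrix.
#' @examples
#' p <- tempfile(fileext = ".pgm")
#' m <- matrix(0:249, 25, 10)
#' write_gray(m, p)
#' stopifnot(identical(read_gray(p), m))
#' @export
write_gray <- function(x, path) {
  if (!is.matrix(x)) stop("`x` must be a matrix", call. = FALSE)
  x <- round(x)
  if (any(x < 0 | x > 255)) stop("pixel values must lie in [0, 255]", call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG requires the `png` package; use a .pgm path instead",
           call. = FALSE)
    png::writePNG(x / 255, path)
  } else {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(x), nrow(x)), "255"), con)
    # one image row per line; readers accept arbitrary whitespace
    writeLines(apply(x, 1L, paste, collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_gray
#' @export
read_gray <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the `png` package", call. = FALSE)
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(matrix(as.integer(round_half_up(img * 255)), nrow(img), ncol(img)))
  }
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (txt[1L] != "P2") stop("not a plain PGM (P2) file: ", path, call. = FALSE)
  w <- as.integer(txt[2L]); h <- as.integer(txt[3L])
  vals <- as.integer(txt[-(1:4)])
  if (length(vals) != h * w) stop("truncated PGM file: ", path, call. = FALSE)
  matrix(vals, h, w, byrow = TRUE)
}

# extension for the preferred available codec
gray_ext <- function(format = c("auto", "png", "pgm")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (requireNamespace("png", quietly = TRUE)) "png" else "pgm"
  paste0(".", format)
}
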