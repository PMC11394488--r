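# Plain-text image I/O. Toy slides and masks travel as ASCII netpbm files
# (P3 for RGB, P2 for gray, P1 for bitmaps) so every fixture stays a text file.

#' Write / read an RGB image as ASCII PPM (P3)
#'
#' @param img `h x w x 3` numeric array with values in 0-255.
#' @param path Destination file.
#' @export
write_ppm <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  vals <- round(aperm(img, c(3, 2, 1)))  # channel fastest, then x, then y
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(as.integer(vals), collapse = " "), con)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  assert_that(toks[1] == "P3", "expected ASCII PPM (P3) in %s", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  assert_that(length(vals) == w * h * 3, "truncated PPM payload in %s", path)
  aperm(array(vals, dim = c(3, w, h)), c(3, 2, 1))
}

#' Write / read a binary mask as ASCII PGM (P2, values 0/255)
#'
#' @param mask 0/1 integer matrix.
#' @param path Destination file.
#' @export
write_mask_pgm <- function(mask, path) {
  h <- nrow(mask); w <- ncol(mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(w, h), "255"), con)
  writeLines(paste(as.integer(t(mask) * 255L), collapse = " "), con)
  invisible(path)
}

#' @rdname write_mask_pgm
#' @export
read_mask_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  assert_that(toks[1] == "P2", "expected ASCII PGM (P2) in %s", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  matrix(as.integer(vals > 127L), nrow = h, ncol = w, byrow = TRUE)
}

# Nearest-neighbour downsample of an RGB array by an integer factor — stands in
# for reading a thumbnail level from a slide pyramid.
downsample_image <- function(img, factor) {
  stopifnot(factor >= 1, factor == floor(factor))
  if (factor == 1) return(img)
  rows <- seq(1, dim(img)[1], by = factor)
  cols <- seq(1, dim(img)[2], by = factor)
  img[rows, cols, , drop = FALSE]
}
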