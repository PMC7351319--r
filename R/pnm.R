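#' Lossless plain-text NetPBM image input/output
#'
#' Annotation maps and white-light frames are stored losslessly as ASCII
#' NetPBM files: PGM (P2) for 8-bit grayscale annotation images and PPM
#' (P3) for RGB frames.  Comment lines are not emitted and not supported on
#' read.
#'
#' @param img For `write_pgm`, an integer matrix (values 0..maxval, row =
#'   image row); for `write_ppm`, an H x W x 3 numeric array in [0, 1].
#' @param path File path.
#' @param maxval Maximum sample value.
#' @name pnm
NULL

#' @rdname pnm
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  img <- unclass(img)
  stopifnot(is.matrix(img), all(img >= 0), all(img <= maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  utils::write.table(img, con, row.names = FALSE, col.names = FALSE)
}

#' @rdname pnm
#' @export
read_pgm <- function(path) {
  header <- readLines(path, n = 3L)
  if (header[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  dims <- as.integer(strsplit(trimws(header[2]), "\\s+")[[1]])
  vals <- scan(path, what = integer(), skip = 3, quiet = TRUE)
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}

#' @rdname pnm
#' @export
write_ppm <- function(img, path, maxval = 255L) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  h <- dim(img)[1]; w <- dim(img)[2]
  # interleave channels: r g b per pixel, row-major
  flat <- matrix(0L, nrow = h, ncol = 3L * w)
  flat[, seq(1, 3 * w, 3)] <- q[, , 1]
  flat[, seq(2, 3 * w, 3)] <- q[, , 2]
  flat[, seq(3, 3 * w, 3)] <- q[, , 3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), as.character(maxval)), con)
  utils::write.table(flat, con, row.names = FALSE, col.names = FALSE)
}

#' @rdname pnm
#' @export
read_ppm <- function(path) {
  header <- readLines(path, n = 3L)
  if (header[1] != "P3") stop("not an ASCII PPM (P3) file: ", path)
  dims <- as.integer(strsplit(trimws(header[2]), "\\s+")[[1]])
  maxval <- as.integer(header[3])
  vals <- scan(path, what = integer(), skip = 3, quiet = TRUE)
  w <- dims[1]; h <- dims[2]
  flat <- matrix(vals, nrow = h, ncol = 3L * w, byrow = TRUE)
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- flat[, seq(1, 3 * w, 3)]
  img[, , 2] <- flat[, seq(2, 3 * w, 3)]
  img[, , 3] <- flat[, seq(3, 3 * w, 3)]
  img / maxval
}
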