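#' Read a grayscale image from PNG, TIFF or PGM
#'
#' PNG and TIFF are decoded with the png and tiff packages; values are scaled
#' from `[0, 1]` to `[0, L]` and rounded. RGB(A) inputs are converted with the
#' BT.601 luma combination (alpha ignored). PGM (both plain `P2` and binary
#' `P5`, maxval <= 255) is parsed directly.
#'
#' @param path file path; format chosen by extension (.png, .tif/.tiff,
#'   .pgm).
#' @param L target maximum gray level (8-bit sources are scaled to `[0, L]`).
#' @return integer gray-level matrix.
#' @export
read_gray_image <- function(path, L = 255L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path)
  } else if (ext == "pgm") {
    return(.read_pgm(path, L))
  } else {
    stop(sprintf("unsupported image format '.%s'", ext))
  }
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) {
      return(to_grayscale(a[, , 1:3] * L, L))
    }
    a <- a[, , 1]
  }
  g <- round(a * L)
  storage.mode(g) <- "integer"
  g
}

#' Write a grayscale image to PNG, TIFF or PGM
#'
#' @inheritParams as_gray_image
#' @param path destination; format chosen by extension.
#' @export
write_gray_image <- function(img, path, L = 255L) {
  img <- as_gray_image(img, L)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / L, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img / L, path)
  } else if (ext == "pgm") {
    .write_pgm(img, path, L)
  } else {
    stop(sprintf("unsupported image format '.%s'", ext))
  }
  invisible(path)
}

#' Write a binary mask as a 0/255 single-channel image
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param path destination (.png, .tif/.tiff or .pgm).
#' @export
write_mask <- function(mask, path) {
  if (!is.logical(mask)) stop("mask must be logical")
  img <- matrix(0L, nrow(mask), ncol(mask))
  img[mask] <- 255L
  write_gray_image(img, path, 255L)
}

#' Read a binary mask: nonzero pixels are foreground
#'
#' @param path image path.
#' @export
read_mask <- function(path) {
  read_gray_image(path, 255L) > 0L
}

#' @keywords internal
.read_pgm <- function(path, L = 255L) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # header tokens: magic, width, height, maxval; '#' starts a comment
  while (length(tok) < 4L) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PGM header")
    line <- sub("#.*$", "", line)
    tok <- c(tok, strsplit(trimws(line), "[[:space:]]+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  magic <- tok[1]
  w <- as.integer(tok[2]); ht <- as.integer(tok[3]); maxval <- as.integer(tok[4])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (expected P2 or P5)")
  if (maxval > 255L) stop("only maxval <= 255 PGM supported")
  n <- w * ht
  if (magic == "P5") {
    v <- as.integer(readBin(con, "raw", n = n))
  } else {
    v <- scan(con, what = integer(), n = n, comment.char = "#", quiet = TRUE)
  }
  if (length(v) < n) stop("truncated PGM data")
  g <- round(v / maxval * L)
  out <- matrix(as.integer(g), nrow = ht, ncol = w, byrow = TRUE)
  out
}

#' @keywords internal
.write_pgm <- function(img, path, L = 255L) {
  v <- as.integer(round(img / L * 255))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(img), nrow(img)), "255"), con)
  writeBin(as.raw(as.vector(t(matrix(v, nrow(img), ncol(img))))), con)
  invisible(path)
}
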