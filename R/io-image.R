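#' Read and write images
#'
#' Images are exchanged as numeric arrays (`rows x cols x 3`, values 0-255)
#' and masks as logical matrices. PNG is handled through the \pkg{png}
#' package; plain-text Netpbm (`.ppm` P3 / `.pgm` P2) is supported so that
#' small fixtures can live in version control as text.
#'
#' @param path File path; the extension (`.png`, `.ppm`, `.pgm`) selects the
#'   format.
#' @param img A `rows x cols x 3` numeric array with values in 0-255.
#' @return `read_image()` returns an RGB array; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
    return(a * 255)
  }
  if (ext %in% c("ppm", "pgm")) return(read_pnm(path))
  rlang::abort(sprintf("unsupported image format: '%s'", ext))
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  assert_rgb(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(clip255(img) / 255, path)
  } else if (ext == "ppm") {
    write_pnm(img, path)
  } else {
    rlang::abort(sprintf("unsupported image format: '%s'", ext))
  }
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks are written as 8-bit single-channel images with foreground = 255.
#'
#' @param mask Logical matrix.
#' @param path File path (`.png` or `.pgm`).
#' @return `read_mask()` returns a logical matrix; `write_mask()` returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(mask * 1, path)
  } else if (ext == "pgm") {
    write_pnm(mask * 255, path)
  } else {
    rlang::abort(sprintf("unsupported mask format: '%s'", ext))
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1]
    a * 255
  } else if (ext == "pgm") {
    read_pnm(path)
  } else {
    rlang::abort(sprintf("unsupported mask format: '%s'", ext))
  }
  if (is.array(m) && length(dim(m)) == 3L) m <- m[, , 1]
  m > 127
}

# Plain-text Netpbm: P2 (grayscale) for matrices, P3 (RGB) for arrays.
write_pnm <- function(img, path) {
  if (is.matrix(img)) {
    vals <- round(t(clip255(img)))  # row-major order
    header <- c("P2", paste(ncol(img), nrow(img)), "255")
    writeLines(c(header, paste(as.vector(vals), collapse = " ")), path)
  } else {
    assert_rgb(img)
    nr <- dim(img)[1]; nc <- dim(img)[2]
    vals <- round(clip255(img))
    # interleave channels pixel by pixel, row-major
    flat <- as.vector(aperm(vals, c(3, 2, 1)))
    header <- c("P3", paste(nc, nr), "255")
    writeLines(c(header, paste(flat, collapse = " ")), path)
  }
  invisible(path)
}

read_pnm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  toks <- scan(text = paste(txt, collapse = " "), what = character(),
               quiet = TRUE)
  magic <- toks[1]
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (magic == "P2") {
    matrix(vals, nr, nc, byrow = TRUE)
  } else if (magic == "P3") {
    a <- aperm(array(vals, c(3, nc, nr)), c(3, 2, 1))
    a
  } else {
    rlang::abort(sprintf("unsupported Netpbm magic '%s'", magic))
  }
}
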