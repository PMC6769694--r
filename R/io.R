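#' @name pnm
#' @title Read and write portable anymap rasters
#'
#' @description
#' Raster I/O uses the portable anymap family: PPM (P3 ASCII / P6 binary)
#' for RGB fields and PGM (P2 / P5) for single-channel label masks. These
#' formats are self-describing, dependency-free and have an ASCII variant
#' suitable for text-only fixtures; any common converter (ImageMagick,
#' netpbm, Pillow) turns PNG/TIFF/JPEG microscope exports into PPM
#' losslessly (JPEG sources carry compression artifacts — convert once,
#' upstream).
#'
#' @param path file path.
#' @param image an [rgb_image()] (for `write_ppm`).
#' @param mask integer matrix (for `write_pgm`).
#' @param ascii write the ASCII variant (P3/P2) instead of binary (P6/P5).
#' @param maxval maximum sample value declared in the header.
#' @return `read_ppm` returns an [rgb_image()]; `read_pgm` an integer
#'   matrix. The writers return the path, invisibly.
NULL

# Tokenize a PNM header from raw bytes; returns tokens and the offset of
# the first pixel byte (for binary variants).
pnm_header <- function(raw, n_tokens) {
  tokens <- character(0)
  i <- 1L
  n <- length(raw)
  while (length(tokens) < n_tokens) {
    if (i > n) stop("truncated PNM header")
    ch <- rawToChar(raw[i])
    if (ch == "#") {
      while (i <= n && rawToChar(raw[i]) != "\n") i <- i + 1L
    } else if (grepl("[[:space:]]", ch)) {
      i <- i + 1L
    } else {
      start <- i
      while (i <= n && !grepl("[[:space:]]", rawToChar(raw[i]))) i <- i + 1L
      tokens <- c(tokens, rawToChar(raw[start:(i - 1L)]))
    }
  }
  # exactly one whitespace byte separates the header from binary pixel data
  list(tokens = tokens, data_offset = i + 1L)
}

read_pnm <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 2L) stop("not a PNM file: ", path)
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop("unsupported raster format in '", path,
         "' (expected PPM/PGM, magic P2/P3/P5/P6)")
  }
  hd <- pnm_header(raw, 4L)
  w <- as.integer(hd$tokens[2])
  h <- as.integer(hd$tokens[3])
  maxval <- as.integer(hd$tokens[4])
  if (is.na(w) || is.na(h) || is.na(maxval) || w < 1L || h < 1L) {
    stop("corrupt PNM header in '", path, "'")
  }
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L
  n_samples <- w * h * channels
  data <- if (magic %in% c("P2", "P3")) {
    txt <- rawToChar(raw[hd$data_offset:length(raw)])
    vals <- scan(text = txt, what = integer(), quiet = TRUE, comment.char = "#")
    if (length(vals) < n_samples) stop("truncated pixel data in '", path, "'")
    vals[seq_len(n_samples)]
  } else {
    if (maxval > 255) stop("16-bit PNM not supported")
    bytes <- raw[hd$data_offset:length(raw)]
    if (length(bytes) < n_samples) stop("truncated pixel data in '", path, "'")
    as.integer(bytes[seq_len(n_samples)])
  }
  list(data = data, width = w, height = h, channels = channels,
       maxval = maxval)
}

#' @rdname pnm
#' @export
read_ppm <- function(path) {
  p <- read_pnm(path)
  if (p$channels != 3L) {
    stop("'", path, "' is a grayscale PGM, not a color PPM")
  }
  rgb_image(aperm(array(p$data, c(3L, p$width, p$height)), c(3, 2, 1)))
}

#' @rdname pnm
#' @export
write_ppm <- function(image, path, ascii = FALSE) {
  image <- as_rgb_image(image)
  d <- dim(image)
  stream <- as.vector(aperm(unclass(image), c(3, 2, 1)))
  if (ascii) {
    con <- file(path, "wb")  # binary mode keeps \n exact across platforms
    on.exit(close(con))
    writeLines(c("P3", paste(d[2], d[1]), "255",
                 paste(stream, collapse = " ")), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P6", paste(d[2], d[1]), "255"), con)
    writeBin(as.raw(stream), con)
  }
  invisible(path)
}

#' @rdname pnm
#' @export
read_pgm <- function(path) {
  p <- read_pnm(path)
  if (p$channels != 1L) stop("'", path, "' is a color PPM, not a PGM")
  matrix(p$data, p$height, p$width, byrow = TRUE)
}

#' @rdname pnm
#' @export
write_pgm <- function(mask, path, maxval = max(3L, max(mask)), ascii = FALSE) {
  stopifnot(is.matrix(mask))
  stream <- as.vector(t(mask))
  if (any(stream < 0 | stream > maxval)) stop("mask values exceed maxval")
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(mask), nrow(mask)), as.character(maxval),
                 paste(stream, collapse = " ")), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(ncol(mask), nrow(mask)), as.character(maxval)), con)
    writeBin(as.raw(stream), con)
  }
  invisible(path)
}

#' Write a segmentation overlay image
#'
#' Renders a three-class label mask as a color overlay in the conventional
#' legend: green = reaction, yellow = tissue without reaction, black =
#' background. Binary reaction masks (logical matrices) are drawn green on
#' black.
#'
#' @param mask integer label matrix in `{1,2,3}`, or a logical reaction mask.
#' @param path output PPM path.
#' @return The path, invisibly.
#' @export
write_overlay <- function(mask, path) {
  if (is.logical(mask)) mask <- ifelse(mask, 1L, 3L)
  stopifnot(is.matrix(mask), all(mask %in% 1:3))
  d <- dim(mask)
  px <- array(0L, c(d[1], d[2], 3))
  px[, , 1][mask == 2L] <- 255L
  px[, , 2][mask %in% 1:2] <- 255L
  write_ppm(rgb_image(px), path)
}
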