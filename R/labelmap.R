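#' Label map and grayscale image containers
#'
#' A `label_map` is a 2-D integer raster in which 0 is background and values
#' 1..32 index the FDI permanent-tooth classes of an [fdi_schema()]. A
#' `gray_image` is a single-channel intensity raster. Both use the standard
#' raster convention: 0-based pixel coordinates, origin at the top-left,
#' row index increasing downward.
#'
#' @param pixels Integer matrix (rows x cols) of class values.
#' @param schema An [fdi_schema()] describing the tooth classes.
#' @param image_id Identifier carried through to measurement records.
#' @return A `label_map` object (integer matrix with attributes).
#' @export
label_map <- function(pixels, schema = fdi_schema(), image_id = "image") {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "integer"
  validate_classes(pixels, schema)
  structure(pixels, class = "label_map", schema = schema,
            image_id = as.character(image_id))
}

validate_classes <- function(pixels, schema) {
  bad <- setdiff(unique(as.vector(pixels)), c(0L, schema$class_index))
  if (length(bad) > 0) {
    stop("class out of schema: pixel value(s) ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' @rdname label_map
#' @export
gray_image <- function(pixels, image_id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix")
  }
  structure(pixels, class = "gray_image", image_id = as.character(image_id))
}

#' @export
print.label_map <- function(x, ...) {
  k <- setdiff(unique(as.vector(x)), 0L)
  cat(sprintf("<label_map '%s'> %d x %d px, %d tooth class(es)\n",
              attr(x, "image_id"), nrow(x), ncol(x), length(k)))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image '%s'> %d x %d px, range [%.3g, %.3g]\n",
              attr(x, "image_id"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# ---- raster I/O -------------------------------------------------------------

#' Read a tooth-class label map from a raster file
#'
#' Accepts single-channel 8- or 16-bit PNG or portable graymap (PGM, plain
#' `P2` or binary `P5`). Pixel values are interpreted directly as class
#' indices and validated against the schema; any value outside
#' \{0, 1, ..., 32\} is an error.
#'
#' @param path Path to a `.png` or `.pgm`/`.pnm` file.
#' @param schema An [fdi_schema()].
#' @param image_id Identifier; defaults to the file name without extension.
#' @return A [label_map()].
#' @export
read_labelmap <- function(path, schema = fdi_schema(),
                          image_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(image_id)) {
    image_id <- sub("\\.[^.]+$", "", basename(path))
  }
  px <- read_raster_int(path)
  label_map(px, schema = schema, image_id = image_id)
}

#' Write a label map to a raster file
#'
#' Writes an 8-bit single-channel PNG or a plain-text `P2` PGM depending on
#' the file extension. Reading the file back reproduces the pixel array
#' bit-exactly.
#'
#' @param map A [label_map()].
#' @param path Output path ending in `.png` or `.pgm`.
#' @export
write_labelmap <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  ext <- tolower(tools::file_ext(path))
  px <- unclass(map)
  attributes(px) <- list(dim = dim(map))
  if (ext == "png") {
    png::writePNG(px / 255, target = path)
  } else if (ext %in% c("pgm", "pnm")) {
    write_pgm(px, path, maxval = 255L)
  } else {
    stop("unsupported extension '", ext, "' (use png or pgm)")
  }
  invisible(path)
}

#' Read a grayscale panoramic image
#'
#' @param path Path to a single-channel PNG or PGM file.
#' @param image_id Identifier; defaults to the file name without extension.
#' @return A [gray_image()] with intensities in `[0, 1]`.
#' @export
read_gray <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(image_id)) image_id <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) != 2L) stop("multi-channel input: expected grayscale")
  } else if (ext %in% c("pgm", "pnm")) {
    r <- read_pgm(path)
    px <- r$pixels / r$maxval
  } else {
    stop("unsupported extension '", ext, "'")
  }
  gray_image(px, image_id = image_id)
}

read_raster_int <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    if (length(dim(px)) != 2L) {
      stop("multi-channel input: label maps must be single-channel")
    }
    depth <- attr(px, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    out <- round(px * (2^depth - 1))
    storage.mode(out) <- "integer"
    attributes(out) <- list(dim = dim(px))
    out
  } else if (ext %in% c("pgm", "pnm")) {
    read_pgm(path)$pixels
  } else {
    stop("unsupported extension '", ext, "'")
  }
}

# Portable graymap (P2 plain / P5 binary), maxval <= 65535. No installed R
# package reads PNM, and the plain variant gives a text-only fixture format.
write_pgm <- function(pixels, path, maxval = 255L, binary = FALSE) {
  stopifnot(is.matrix(pixels), all(pixels >= 0), all(pixels <= maxval))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(ncol(pixels), nrow(pixels)), as.character(maxval)),
               con)
    v <- as.integer(t(pixels))  # row-major per PNM
    if (maxval < 256) {
      writeBin(as.raw(v), con)
    } else {
      writeBin(writeBin(as.integer(v), raw(), size = 2, endian = "big"), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(pixels), nrow(pixels)), as.character(maxval)),
               con)
    apply(pixels, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_pnm_token(con)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (magic ", magic, ")")
  w <- as.integer(read_pnm_token(con))
  h <- as.integer(read_pnm_token(con))
  maxval <- as.integer(read_pnm_token(con))
  n <- w * h
  if (magic == "P2") {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    v <- as.integer(strsplit(trimws(txt), "\\s+")[[1]])
  } else {
    size <- if (maxval < 256) 1L else 2L
    v <- readBin(con, "integer", n = n, size = size, signed = FALSE,
                 endian = "big")
  }
  if (length(v) < n) stop("truncated PGM: expected ", n, " samples")
  px <- matrix(v[seq_len(n)], nrow = h, ncol = w, byrow = TRUE)
  list(pixels = px, maxval = maxval)
}

# single whitespace-delimited token, skipping '#' comments
read_pnm_token <- function(con) {
  tok <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0) stop("unexpected end of PNM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
      next
    }
    if (grepl("\\s", ch)) {
      if (length(tok) > 0) break else next
    }
    tok <- c(tok, ch)
  }
  paste(tok, collapse = "")
}

# ---- preprocessing ----------------------------------------------------------

#' Preprocess a raster to the working resolution
#'
#' Resamples the input to a fixed 512 x 1024 (rows x cols) working grid.
#' Grayscale images are resampled with bilinear interpolation and then
#' min-max normalized to `[0, 1]`; label maps are resampled with
#' nearest-neighbor interpolation only, which guarantees that no class value
#' absent from the input is ever introduced. A constant grayscale image has
#' a degenerate normalization and is returned as all zeros with a warning.
#'
#' Inputs already on the target grid are not resampled (the interpolation
#' identity), which makes preprocessing idempotent.
#'
#' @param x A [gray_image()], [label_map()], or bare numeric matrix
#'   (treated as a grayscale image).
#' @param shape Target `(rows, cols)`; default `c(512, 1024)`.
#' @param ... Unused.
#' @return An object of the same class as `x`, resampled to `shape`.
#' @export
preprocess <- function(x, shape = c(512L, 1024L), ...) {
  UseMethod("preprocess")
}

#' @export
preprocess.matrix <- function(x, shape = c(512L, 1024L), ...) {
  preprocess(gray_image(x), shape = shape, ...)
}

#' @export
preprocess.gray_image <- function(x, shape = c(512L, 1024L), ...) {
  if (length(x) == 0) stop("zero-size input")
  px <- resample_raster(unclass_matrix(x), shape, "bilinear")
  rng <- range(px)
  if (rng[1] == rng[2]) {
    warning("constant image: normalization degenerate, returning all zeros")
    px[] <- 0
  } else {
    px <- (px - rng[1]) / (rng[2] - rng[1])
  }
  gray_image(px, image_id = attr(x, "image_id"))
}

#' @export
preprocess.label_map <- function(x, shape = c(512L, 1024L), ...) {
  if (length(x) == 0) stop("zero-size input")
  px <- resample_raster(unclass_matrix(x), shape, "none")
  storage.mode(px) <- "integer"
  label_map(px, schema = attr(x, "schema"), image_id = attr(x, "image_id"))
}

unclass_matrix <- function(x) {
  d <- dim(x)
  x <- as.vector(x)
  dim(x) <- d
  x
}

resample_raster <- function(px, shape, filter) {
  if (all(dim(px) == shape)) return(px)
  out <- EBImage::resize(EBImage::Image(px), w = shape[1], h = shape[2],
                         filter = filter)
  EBImage::imageData(out)
}
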