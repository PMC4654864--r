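# Reading, normalizing and writing the image and table formats the pipeline
# touches. Pixel intensities are held as plain numeric matrices in [0,1],
# first index = row; RGB images as row x col x 3 arrays in R,G,B order.

#' Read a microscopy image and normalize it to [0,1]
#'
#' Supported formats: TIFF, PNG, JPEG (via EBImage) and uncompressed BMP
#' (built-in reader). 8-bit values are divided by 255 and 16-bit values by
#' 65535, so the dtype maximum always maps to 1. JPEG input triggers a
#' warning because lossy compression distorts intensity statistics.
#'
#' @param path path to a TIFF/PNG/JPEG/BMP file.
#' @return a numeric matrix in [0,1] for grayscale input, or a
#'   rows x cols x 3 array (R,G,B) for colour input.
#' @export
readIntensityImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff", "png", "jpg", "jpeg")) {
    if (ext %in% c("jpg", "jpeg"))
      warning("JPEG is lossy; intensity statistics may be distorted: ", path)
    img <- try(EBImage::readImage(path), silent = TRUE)
    if (inherits(img, "try-error"))
      stop("unreadable image file: ", path, call. = FALSE)
    x <- EBImage::imageData(img)
  } else if (ext == "bmp") {
    x <- readBMP(path)
  } else {
    stop("unsupported image format '", ext, "' (need TIFF/PNG/JPEG/BMP)",
         call. = FALSE)
  }
  # EBImage stores images x-major; transpose to row = vertical position
  if (length(dim(x)) == 2) {
    x <- t(x)
  } else if (length(dim(x)) == 3) {
    x <- aperm(x, c(2, 1, 3))
    if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE] # drop alpha
  } else {
    stop("unsupported image layout in ", path, call. = FALSE)
  }
  if (any(dim(x)[1:2] < 1)) stop("zero-size image: ", path, call. = FALSE)
  clip01(x)
}

# Minimal reader for uncompressed BMP (8-bit palette/grayscale and 24-bit).
readBMP <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readBin(con, "raw", 2)
  if (!identical(as.integer(sig), c(0x42L, 0x4DL)))
    stop("not a BMP file: ", path, call. = FALSE)
  invisible(readBin(con, "raw", 8))
  dataOffset <- readBin(con, "integer", 1, size = 4, endian = "little")
  headerSize <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (headerSize < 40) stop("unsupported BMP header", call. = FALSE)
  width <- readBin(con, "integer", 1, size = 4, endian = "little")
  height <- readBin(con, "integer", 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", 1, size = 2, endian = "little")) # planes
  bpp <- readBin(con, "integer", 1, size = 2, endian = "little")
  compression <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (compression != 0)
    stop("compressed BMP is not supported", call. = FALSE)
  if (!bpp %in% c(8L, 24L))
    stop("only 8-bit and 24-bit BMP are supported", call. = FALSE)
  topDown <- height < 0
  height <- abs(height)
  palette <- NULL
  if (bpp == 8L) {
    seek(con, 14 + headerSize)
    nPal <- (dataOffset - 14 - headerSize) %/% 4
    if (nPal <= 0) nPal <- 256
    pal <- readBin(con, "raw", nPal * 4)
    pm <- matrix(as.integer(pal), nrow = 4) # B,G,R,reserved
    palette <- pm[3:1, , drop = FALSE] / 255 # R,G,B rows
  }
  seek(con, dataOffset)
  rowBytes <- ((bpp / 8 * width + 3) %/% 4) * 4
  raw <- readBin(con, "raw", rowBytes * height)
  rows <- matrix(as.integer(raw), nrow = rowBytes)[seq_len(bpp / 8 * width), ,
                                                   drop = FALSE]
  order <- if (topDown) seq_len(height) else rev(seq_len(height))
  if (bpp == 8L) {
    idx <- rows[, order, drop = FALSE] + 1L          # width x height
    r <- matrix(palette[1, idx], width, height)
    g <- matrix(palette[2, idx], width, height)
    b <- matrix(palette[3, idx], width, height)
    if (all(r == g) && all(g == b)) return(r)
    return(array(c(r, g, b), dim = c(width, height, 3)))
  }
  b <- rows[seq(1, by = 3, length.out = width), order, drop = FALSE] / 255
  g <- rows[seq(2, by = 3, length.out = width), order, drop = FALSE] / 255
  r <- rows[seq(3, by = 3, length.out = width), order, drop = FALSE] / 255
  array(c(r, g, b), dim = c(width, height, 3))
}

#' Split an RGB image into nuclei and foci channels
#'
#' By convention nuclei carry the DNA stain imaged in blue and foci the
#' antibody signal imaged in green, so the defaults map blue to nuclei and
#' green to foci.
#'
#' @param rgb rows x cols x 3 array in R,G,B order (from
#'   \code{\link{readIntensityImage}}).
#' @param nucleiChannel,fociChannel one of \code{"R"}, \code{"G"},
#'   \code{"B"}; they must differ.
#' @param sourceId text label attached to the result.
#' @return a \linkS4class{ChannelPair}.
#' @export
splitChannels <- function(rgb, nucleiChannel = "B", fociChannel = "G",
                          sourceId = "") {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("rgb must be a rows x cols x 3 array", call. = FALSE)
  chan <- c(R = 1L, G = 2L, B = 3L)
  if (!nucleiChannel %in% names(chan) || !fociChannel %in% names(chan))
    stop("channels must be 'R', 'G' or 'B'", call. = FALSE)
  if (nucleiChannel == fociChannel)
    stop("nuclei and foci channels must differ", call. = FALSE)
  ChannelPair(nuclei = rgb[, , chan[nucleiChannel]],
              foci = rgb[, , chan[fociChannel]],
              sourceId = sourceId)
}

#' Read a field of view as a ChannelPair
#'
#' Either a single RGB file (channels split with the blue-to-nuclei,
#' green-to-foci defaults) or a pair of grayscale files.
#'
#' @param path RGB image path, or the nuclei image path when
#'   \code{fociPath} is given.
#' @param fociPath optional path of a separate grayscale foci image.
#' @param ... passed to \code{\link{splitChannels}}.
#' @return a \linkS4class{ChannelPair}.
#' @export
readChannelPair <- function(path, fociPath = NULL, ...) {
  if (is.null(fociPath)) {
    x <- readIntensityImage(path)
    if (length(dim(x)) != 3)
      stop("single-file input must be RGB; provide fociPath for grayscale pairs",
           call. = FALSE)
    return(splitChannels(x, sourceId = basename(path), ...))
  }
  nuc <- readIntensityImage(path)
  foc <- readIntensityImage(fociPath)
  if (length(dim(nuc)) == 3) nuc <- nuc[, , 3]
  if (length(dim(foc)) == 3) foc <- foc[, , 2]
  if (!identical(dim(nuc), dim(foc)))
    stop("nuclei and foci images must have identical dimensions", call. = FALSE)
  ChannelPair(nuclei = nuc, foci = foc, sourceId = basename(path))
}

#' Write an intensity image (grayscale or RGB) to PNG or TIFF
#'
#' @param x matrix or rows x cols x 3 array in [0,1].
#' @param path output path; format chosen from the extension (png/tif/tiff).
#' @param bitsPerSample 8 or 16 (TIFF only).
#' @return the path, invisibly.
#' @export
writeIntensityImage <- function(x, path, bitsPerSample = 8) {
  ext <- tolower(tools::file_ext(path))
  if (length(dim(x)) == 2) {
    img <- EBImage::Image(t(x), colormode = "Grayscale")
  } else {
    img <- EBImage::Image(aperm(x, c(2, 1, 3)), colormode = "Color")
  }
  if (ext %in% c("tif", "tiff")) {
    EBImage::writeImage(img, path, type = "tiff",
                        bits.per.sample = as.integer(bitsPerSample))
  } else if (ext == "png") {
    EBImage::writeImage(img, path, type = "png")
  } else {
    stop("unsupported output format '", ext, "' (use png or tiff)",
         call. = FALSE)
  }
  invisible(path)
}

#' Mark detected foci with square frames on an image
#'
#' Draws a one-pixel-wide square ring of half-width \code{frameHalfWidth}
#' around each detection; pixels outside the rings are left untouched.
#' Frames are clipped at the image border. This mirrors the visual feedback
#' of marking identified foci with red frames (detections) or blue frames
#' (simulator ground truth).
#'
#' @param x grayscale matrix or RGB array in [0,1].
#' @param centers n x 2 matrix of (row, col) positions; they must lie inside
#'   the image.
#' @param frameHalfWidth half-width of the square frame in pixels.
#' @param color \code{"red"} or \code{"blue"}.
#' @return rows x cols x 3 RGB array with the frames drawn.
#' @export
markFoci <- function(x, centers, frameHalfWidth = 4, color = c("red", "blue")) {
  color <- match.arg(color)
  if (length(dim(x)) == 2) {
    rgb <- array(rep(x, 3), dim = c(dim(x), 3))
  } else {
    rgb <- x
  }
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  centers <- asCenterMatrix(centers)
  if (nrow(centers) == 0) return(rgb)
  rc <- round(centers)
  if (any(rc[, 1] < 1 | rc[, 1] > nr | rc[, 2] < 1 | rc[, 2] > nc))
    stop("focus centre outside the image", call. = FALSE)
  val <- if (color == "red") c(1, 0, 0) else c(0, 0, 1)
  w <- as.integer(frameHalfWidth)
  for (i in seq_len(nrow(rc))) {
    r <- rc[i, 1]; c <- rc[i, 2]
    rr <- max(1, r - w):min(nr, r + w)
    cc <- max(1, c - w):min(nc, c + w)
    for (ch in 1:3) {
      # top/bottom edges (if not clipped away), then left/right edges
      if (r - w >= 1) rgb[r - w, cc, ch] <- val[ch]
      if (r + w <= nr) rgb[r + w, cc, ch] <- val[ch]
      if (c - w >= 1) rgb[rr, c - w, ch] <- val[ch]
      if (c + w <= nc) rgb[rr, c + w, ch] <- val[ch]
    }
  }
  rgb
}

asCenterMatrix <- function(centers) {
  if (is.null(centers)) return(matrix(numeric(), 0, 2))
  if (is.data.frame(centers)) centers <- as.matrix(centers[, c("cr", "cc")])
  if (!is.matrix(centers)) centers <- matrix(centers, ncol = 2, byrow = TRUE)
  if (nrow(centers) > 0 && ncol(centers) != 2)
    stop("centers must be an n x 2 matrix of (row, col)", call. = FALSE)
  centers
}

#' Write an annotated overlay image
#'
#' @param x original grayscale matrix or RGB array.
#' @param detections a \linkS4class{FociCount}, or an n x 2 matrix of
#'   (row, col) centres.
#' @param path output PNG or TIFF path.
#' @param frameHalfWidth,color passed to \code{\link{markFoci}}.
#' @return the path, invisibly.
#' @export
writeOverlay <- function(x, detections, path, frameHalfWidth = 4,
                         color = "red") {
  if (is(detections, "FociCount")) detections <- detections(detections)
  rgb <- markFoci(x, detections, frameHalfWidth = frameHalfWidth,
                  color = color)
  writeIntensityImage(rgb, path)
}

#' Write per-nucleus foci counts and per-image summaries to CSV
#'
#' One row per nucleus (record type \code{"nucleus"}) followed by one
#' summary row per image (record type \code{"summary"}) carrying the
#' nucleus count, the mean foci number per nucleus and its standard error
#' (SEM; 0 for a single nucleus, empty when an image has no nuclei).
#'
#' @param results named list of \linkS4class{FociCount} objects; names are
#'   the image ids.
#' @param path output CSV path.
#' @return the written data.frame, invisibly.
#' @export
writeResultsTable <- function(results, path) {
  if (is(results, "FociCount")) results <- list(image = results)
  ids <- names(results)
  if (is.null(ids)) ids <- paste0("image", seq_along(results))
  rows <- list()
  for (i in seq_along(results)) {
    res <- results[[i]]
    cnt <- fociPerNucleus(res)
    if (length(cnt) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        image_id = ids[i], record = "nucleus",
        nucleus_label = as.integer(names(cnt)), foci_count = as.integer(cnt),
        n_nuclei = NA_integer_, mean_foci = NA_real_, sem = NA_real_)
    }
    n <- nucleusCount(res)
    rows[[length(rows) + 1]] <- data.frame(
      image_id = ids[i], record = "summary", nucleus_label = NA_integer_,
      foci_count = NA_integer_, n_nuclei = n,
      mean_foci = if (n > 0) meanFoci(res) else NA_real_,
      sem = if (n > 0) semFoci(res) else NA_real_)
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}
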