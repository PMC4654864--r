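# Internal helpers shared by the segmentation and detection pipelines.

# symmetric (half-sample) reflection indices for padding by `p` pixels
.reflectIdx <- function(n, p) {
  idx <- seq.int(1 - p, n + p)
  idx <- ifelse(idx < 1, 1 - idx, idx)
  ifelse(idx > n, 2 * n + 1 - idx, idx)
}

# pad a matrix by p pixels on every side with mirrored values
padReflect <- function(x, p) {
  if (p <= 0) return(x)
  x[.reflectIdx(nrow(x), p), .reflectIdx(ncol(x), p), drop = FALSE]
}

unpad <- function(x, p, nr, nc) {
  x[p + seq_len(nr), p + seq_len(nc), drop = FALSE]
}

# discrete disk: offsets (di, dj) with di^2 + dj^2 <= r^2
discBrush <- function(r) {
  r <- as.integer(round(r))
  d <- seq.int(-r, r)
  k <- outer(d^2, d^2, "+") <= r^2
  storage.mode(k) <- "integer"
  k
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stopifnotIntensity <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 1 || ncol(x) < 1)
    stop(what, " must have positive dimensions", call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 1)
    stop(what, " intensities must lie in [0,1]", call. = FALSE)
  invisible(TRUE)
}

# grayscale erosion/dilation with reflect padding (EBImage pads with extremes
# at the border otherwise); kern is a 0/1 matrix
erodePad <- function(x, kern) {
  p <- (nrow(kern) - 1L) %/% 2L
  unpad(EBImage::erode(padReflect(x, p), kern), p, nrow(x), ncol(x))
}

dilatePad <- function(x, kern) {
  p <- (nrow(kern) - 1L) %/% 2L
  unpad(EBImage::dilate(padReflect(x, p), kern), p, nrow(x), ncol(x))
}

# Gaussian smoothing with reflect padding
gaussSmooth <- function(x, sigma) {
  r <- max(2L, as.integer(ceiling(3 * sigma)))
  p <- r + 1L
  xp <- padReflect(x, p)
  sm <- EBImage::gblur(xp, sigma = sigma, radius = 2L * r + 1L)
  unpad(as.matrix(sm), p, nrow(x), ncol(x))
}

# binary 3x3 median = majority vote over the 9-pixel neighbourhood
binaryMedian3 <- function(mask) {
  p <- 1L
  mp <- padReflect(mask * 1.0, p)
  s <- as.matrix(EBImage::filter2(mp, matrix(1, 3, 3), boundary = "replicate"))
  out <- unpad(s, p, nrow(mask), ncol(mask)) >= 5
  out * 1L
}

# labelled bounding boxes / centroids / areas of an integer label matrix
labelRecords <- function(lab) {
  labs <- sort(unique(as.vector(lab)))
  labs <- labs[labs > 0]
  if (length(labs) == 0)
    return(data.frame(label = integer(), area = integer(),
                      r0 = integer(), r1 = integer(),
                      c0 = integer(), c1 = integer(),
                      cr = numeric(), cc = numeric()))
  recs <- lapply(labs, function(l) {
    w <- which(lab == l, arr.ind = TRUE)
    data.frame(label = l, area = nrow(w),
               r0 = min(w[, 1]), r1 = max(w[, 1]),
               c0 = min(w[, 2]), c1 = max(w[, 2]),
               cr = mean(w[, 1]), cc = mean(w[, 2]))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# repack positive labels to consecutive 1..K (scan order of first occurrence)
repackLabels <- function(lab) {
  labs <- unique(as.vector(lab))
  labs <- labs[labs > 0]
  if (length(labs) == 0) return(lab)
  map <- integer(max(labs))
  map[sort(labs)] <- seq_along(labs)
  out <- lab
  pos <- out > 0
  out[pos] <- map[out[pos]]
  out
}
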