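# Nuclei segmentation: threshold -> clean -> close bays -> watershed ->
# final opening. The output is an integer-labelled mask with one label per
# nucleus; foci are only counted inside it.

#' Huang's fuzzy-entropy threshold
#'
#' Automatic threshold minimizing Huang & Wang's measure of fuzziness in its
#' Shannon-entropy form over a 256-bin histogram. For every candidate
#' threshold the pixels are split into background/foreground classes; each
#' gray level g gets a class membership
#' \eqn{u(g) = 1 / (1 + |g - mu|/C)} (mu = its class mean, C = the occupied
#' gray-level range), and the fuzziness is the histogram-weighted Shannon
#' entropy \eqn{-u log u - (1-u) log(1-u)} summed over levels. The returned
#' threshold is the upper edge of the optimal background bin.
#'
#' @param img numeric intensity matrix in [0,1] with at least two distinct
#'   values.
#' @return threshold in (min(img), max(img)).
#' @export
huangThreshold <- function(img) {
  stopifnotIntensity(img)
  v <- as.vector(img)
  if (max(v) == min(v))
    stop("constant image: threshold is undefined", call. = FALSE)
  nbins <- 256L
  bin <- pmin(floor(v * nbins), nbins - 1L) # 0-based bin index
  h <- tabulate(bin + 1L, nbins)
  g <- (seq_len(nbins) - 0.5) / nbins       # bin centres
  occ <- which(h > 0)
  C <- g[max(occ)] - g[min(occ)]
  W <- cumsum(h * g); N <- cumsum(h)
  Wtot <- W[nbins]; Ntot <- N[nbins]
  shannon <- function(u) {
    s <- numeric(length(u))
    ok <- u > 0 & u < 1
    s[ok] <- -u[ok] * log(u[ok]) - (1 - u[ok]) * log(1 - u[ok])
    s
  }
  # candidate thresholds between occupied min and max bins
  cand <- seq.int(min(occ), max(occ) - 1L)
  best <- Inf; bestT <- cand[1]
  for (t in cand) {
    mu0 <- W[t] / N[t]
    mu1 <- (Wtot - W[t]) / (Ntot - N[t])
    u <- numeric(nbins)
    lo <- seq_len(t); hi <- seq.int(t + 1L, nbins)
    u[lo] <- 1 / (1 + abs(g[lo] - mu0) / C)
    u[hi] <- 1 / (1 + abs(g[hi] - mu1) / C)
    E <- sum(h * shannon(u))
    if (E < best) { best <- E; bestT <- t }
  }
  bestT / nbins # upper edge of background bin t (1-based) = t/nbins
}

# binary opening by reconstruction: erosion with a disk, then reconstruction
# by dilation under the original mask (8-connected); survivors keep their
# exact original shape
openByReconstruction <- function(mask, r) {
  kern <- discBrush(r)
  er <- erodePad(mask * 1.0, kern) > 0.5
  if (!any(er)) return(mask * 0L)
  lab <- cpp_label8(mask > 0)
  keep <- unique(lab[er])
  keep <- keep[keep > 0]
  matrix((lab %in% keep) * 1L, nrow(mask), ncol(mask))
}

#' Primary nuclear mask
#'
#' Binarizes the nuclei channel (Huang's method or a manual threshold),
#' fills holes, applies a 3x3 median filter and performs morphological
#' opening by reconstruction with a disk of radius \code{openRadius}:
#' objects that cannot contain the disk are removed while survivors keep
#' their exact shape.
#'
#' @param img nuclei-channel intensity matrix in [0,1].
#' @param params a \linkS4class{NucleiParams}.
#' @return 0/1 integer matrix.
#' @export
makePrimaryMask <- function(img, params = NucleiParams()) {
  thr <- if (params@thresholdMethod == "manual") params@manualThreshold
         else huangThreshold(img)
  mask <- (img > thr) * 1L
  mask <- as.matrix(EBImage::fillHull(mask))
  mask <- binaryMedian3(mask)
  openByReconstruction(mask, params@openRadius)
}

#' Close bay-shaped indentations of a binary mask
#'
#' Dilates \code{n} times with a 3x3 square structuring element, fills
#' holes, then erodes \code{n} times with the same element. Concavities
#' whose mouth closes during dilation become holes and are filled, so bays
#' inside nuclei disappear.
#'
#' @param mask 0/1 matrix.
#' @param n number of dilation/erosion iterations (default 3).
#' @return 0/1 integer matrix.
#' @export
closeBays <- function(mask, n = 3) {
  k3 <- matrix(1L, 3, 3)
  m <- mask * 1.0
  for (i in seq_len(n)) m <- dilatePad(m, k3)
  m <- as.matrix(EBImage::fillHull((m > 0.5) * 1L))
  m <- m * 1.0
  for (i in seq_len(n)) m <- erodePad(m, k3)
  (m > 0.5) * 1L
}

#' Separate touching nuclei by a distance-transform watershed
#'
#' Computes the Euclidean distance transform of the foreground, smooths it
#' lightly (Gaussian sigma = 1 px, so plateau fragmentation does not seed
#' spurious basins), and floods the negated map from its regional maxima
#' (maxima closer than 1 intensity unit of distance are merged). Touching
#' blobs are separated by one-pixel-wide background lines; output regions
#' are 8-connected and labelled 1..K.
#'
#' @param mask 0/1 matrix.
#' @return integer label matrix.
#' @export
watershedSplit <- function(mask) {
  if (!any(mask > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- as.matrix(EBImage::distmap(mask > 0))
  ds <- gaussSmooth(d, 1)
  ds[mask == 0] <- 0
  lab <- as.matrix(EBImage::watershed(EBImage::Image(ds), tolerance = 1,
                                      ext = 1))
  storage.mode(lab) <- "integer"
  # impose 1-px background separation lines: clear pixels of the larger
  # label that touch (8-neighbourhood) a smaller positive label
  nr <- nrow(lab); nc <- ncol(lab)
  if (max(lab) > 1) {
    clear <- matrix(FALSE, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
      ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
      nb <- matrix(0L, nr, nc)
      nb[ok_r, ok_c] <- lab[rs[ok_r], cs[ok_c]]
      clear <- clear | (lab > 0 & nb > 0 & nb < lab)
    }
    lab[clear] <- 0L
  }
  repackLabels(lab)
}

#' Final per-nucleus opening and border exclusion
#'
#' Opens every labelled region with a disk of radius \code{r} (removing
#' watershed debris and smoothing boundaries), drops regions eliminated by
#' the opening, optionally drops regions touching the image border, and
#' repacks labels to 1..K. The operation is idempotent.
#'
#' @param lab integer label matrix.
#' @param r disk radius in pixels (default 10).
#' @param excludeBorder drop border-touching nuclei (default TRUE).
#' @return a \linkS4class{NucleusSet}.
#' @export
finalizeNuclei <- function(lab, r = 10, excludeBorder = TRUE) {
  nr <- nrow(lab); nc <- ncol(lab)
  kern <- discBrush(r)
  p <- (nrow(kern) - 1L) %/% 2L
  out <- matrix(0L, nr, nc)
  labs <- sort(unique(as.vector(lab))); labs <- labs[labs > 0]
  for (l in labs) {
    w <- which(lab == l, arr.ind = TRUE)
    r0 <- max(1, min(w[, 1]) - p - 1L); r1 <- min(nr, max(w[, 1]) + p + 1L)
    c0 <- max(1, min(w[, 2]) - p - 1L); c1 <- min(nc, max(w[, 2]) + p + 1L)
    sub <- (lab[r0:r1, c0:c1, drop = FALSE] == l) * 1.0
    # plain opening on a zero-padded crop: regions are isolated, so padding
    # with background is exact
    pad <- p + 1L
    subp <- matrix(0, nrow(sub) + 2 * pad, ncol(sub) + 2 * pad)
    subp[pad + seq_len(nrow(sub)), pad + seq_len(ncol(sub))] <- sub
    op <- as.matrix(EBImage::opening(subp, kern))
    op <- op[pad + seq_len(nrow(sub)), pad + seq_len(ncol(sub)), drop = FALSE]
    sel <- op > 0.5
    if (!any(sel)) next
    idx <- which(sel, arr.ind = TRUE)
    out[cbind(idx[, 1] + r0 - 1L, idx[, 2] + c0 - 1L)] <- l
  }
  if (excludeBorder) {
    edge <- unique(c(out[1, ], out[nr, ], out[, 1], out[, nc]))
    edge <- edge[edge > 0]
    if (length(edge)) out[out %in% edge] <- 0L
  }
  out <- repackLabels(out)
  new("NucleusSet", labels = out, records = labelRecords(out))
}

#' Segment nuclei from the DNA-stain channel
#'
#' Full nuclei pipeline: threshold (Huang or manual), fill holes, 3x3
#' median filter, opening by reconstruction, bay closing
#' (dilate/fill/erode), distance-transform watershed separation of touching
#' nuclei, and a final per-nucleus opening that removes non-nucleus
#' elements.
#'
#' @param img nuclei-channel intensity matrix in [0,1].
#' @param params a \linkS4class{NucleiParams}.
#' @return a \linkS4class{NucleusSet}.
#' @export
segmentNuclei <- function(img, params = NucleiParams()) {
  mask <- makePrimaryMask(img, params)
  mask <- closeBays(mask, params@morphIterations)
  lab <- watershedSplit(mask)
  finalizeNuclei(lab, r = params@openRadius,
                 excludeBorder = params@excludeBorder)
}

#' Treat a whole frame as a single nucleus
#'
#' Used for simulated single-nucleus foci images, where no nuclei channel
#' exists and every image corresponds to one nucleus by construction.
#'
#' @param dims (rows, cols) of the image.
#' @return a \linkS4class{NucleusSet} with one label covering the frame.
#' @export
fullFrameNucleus <- function(dims) {
  lab <- matrix(1L, dims[1], dims[2])
  new("NucleusSet", labels = lab, records = labelRecords(lab))
}
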