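# Foci detection: adaptive median filter -> white top-hat -> H-maxima with
# an Otsu-derived height -> regional maxima -> final intensity threshold ->
# per-nucleus counting.

#' Adaptive median filter
#'
#' Classic two-level adaptive median filter for impulse-noise removal: for
#' every pixel the window grows from 3x3 until the window median is strictly
#' between the window minimum and maximum (level A); the original pixel is
#' then kept if it is itself strictly between minimum and maximum, otherwise
#' replaced by the median (level B). If the window reaches \code{sMax}
#' without level A passing, the median of the largest window is returned.
#' Borders are handled by reflection.
#'
#' @param img intensity matrix in [0,1].
#' @param sMax maximum window size, odd and >= 3 (default 7).
#' @return filtered intensity matrix.
#' @export
adaptiveMedianFilter <- function(img, sMax = 7) {
  stopifnotIntensity(img)
  cpp_adaptive_median(img, as.integer(sMax))
}

#' White top-hat transform
#'
#' Image minus its grayscale opening by a disk of radius \code{r}: isolates
#' bright structures smaller than the disk and flattens slowly varying
#' background and non-uniform illumination.
#'
#' @param img intensity matrix in [0,1].
#' @param r disk radius in pixels (default 3).
#' @return non-negative matrix, pointwise \code{<= img}.
#' @export
topHat <- function(img, r = 3) {
  stopifnotIntensity(img)
  kern <- discBrush(r)
  op <- dilatePad(erodePad(img, kern), kern)
  out <- img - op
  out[out < 0] <- 0
  out
}

#' Otsu's threshold
#'
#' 256-bin threshold maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}. Used here as the height
#' parameter of the H-maxima transform, so peak suppression adapts to the
#' intensity distribution of the background-corrected image.
#'
#' @param img intensity matrix in [0,1] with at least two distinct values.
#' @return threshold in (min(img), max(img)).
#' @export
otsuThreshold <- function(img) {
  stopifnotIntensity(img)
  v <- as.vector(img)
  if (max(v) == min(v))
    stop("constant image: threshold is undefined", call. = FALSE)
  nbins <- 256L
  h <- tabulate(pmin(floor(v * nbins), nbins - 1L) + 1L, nbins)
  g <- (seq_len(nbins) - 0.5) / nbins
  N <- cumsum(h); W <- cumsum(h * g)
  Ntot <- N[nbins]; Wtot <- W[nbins]
  occ <- which(h > 0)
  cand <- seq.int(min(occ), max(occ) - 1L)
  w0 <- N[cand] / Ntot
  w1 <- 1 - w0
  mu0 <- W[cand] / N[cand]
  mu1 <- (Wtot - W[cand]) / (Ntot - N[cand])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  cand[which.max(bcv)] / nbins # upper edge of the optimal background bin
}

#' H-maxima transform
#'
#' Suppresses all regional maxima whose height above their surroundings is
#' less than \code{h}, computed as the grayscale morphological
#' reconstruction by dilation of \code{img - h} under \code{img}
#' (8-connected). The output satisfies
#' \code{img - h <= hMaxima(img, h) <= img} pointwise, and \code{h = 0}
#' returns the input unchanged.
#'
#' @param img intensity matrix.
#' @param h non-negative suppression height.
#' @return transformed matrix.
#' @export
hMaxima <- function(img, h) {
  if (h < 0) stop("h must be >= 0", call. = FALSE)
  cpp_reconstruct_dilation(img - h, img)
}

#' Regional maxima
#'
#' 8-connected plateaus of constant intensity strictly greater than all
#' neighbouring pixels. A constant image is one single plateau covering the
#' frame (callers downstream treat such degenerate plateaus as background).
#'
#' @param img intensity matrix.
#' @return logical matrix marking maximal plateaus.
#' @export
regionalMaxima <- function(img) {
  cpp_regional_maxima(img)
}

#' Detect and count foci per nucleus
#'
#' Pipeline on the foci channel: adaptive median filter, white top-hat with
#' a disk of radius \code{tophatRadius}, H-maxima with height equal to
#' Otsu's threshold of the top-hat image, regional maxima of the result,
#' then a final intensity screening: each 8-connected maxima plateau is one
#' candidate focus and survives when its mean top-hat intensity is at least
#' \code{finalThreshold}. Screening whole plateaus (rather than individual
#' pixels) keeps the detected count monotone non-increasing in both the
#' H-maxima height and the final threshold. The intensity-weighted centroid
#' of a surviving plateau assigns it to the nucleus label at that position;
#' plateaus falling on background are discarded, and degenerate plateaus
#' covering more than 25\% of their nucleus are treated as background (this
#' makes blank images count zero foci instead of erroring).
#'
#' @param img foci-channel intensity matrix in [0,1].
#' @param nuclei a \linkS4class{NucleusSet} (for simulated single-nucleus
#'   images use \code{\link{fullFrameNucleus}}).
#' @param params a \linkS4class{FociParams}.
#' @return a \linkS4class{FociCount}.
#' @export
detectFoci <- function(img, nuclei, params = FociParams()) {
  stopifnotIntensity(img)
  lab <- labelMatrix(nuclei)
  if (!identical(dim(img), dim(lab)))
    stop("foci image and nuclei mask must have identical dimensions",
         call. = FALSE)
  recs <- nucleusRecords(nuclei)
  nNuc <- nrow(recs)
  emptyDet <- data.frame(cr = numeric(), cc = numeric(), nucleus = integer(),
                         peakIntensity = numeric(), area = integer())
  emptyResult <- function() {
    cnt <- rep(0L, nNuc)
    names(cnt) <- if (nNuc) as.character(recs$label) else character()
    new("FociCount", detections = emptyDet, perNucleusCounts = cnt,
        nNuclei = as.integer(nNuc),
        meanPerNucleus = if (nNuc) 0 else NA_real_,
        sem = if (nNuc) 0 else NA_real_)
  }
  filtered <- adaptiveMedianFilter(img, params@medianMaxWindow)
  th <- topHat(filtered, params@tophatRadius)
  if (max(th) - min(th) < 1 / 256) return(emptyResult()) # flat: blank control
  h <- otsuThreshold(th)
  hm <- hMaxima(th, h)
  rm <- regionalMaxima(hm)
  if (!any(rm)) return(emptyResult())
  comp <- cpp_label8(rm)
  pos <- which(comp > 0L)
  byComp <- split(pos, comp[pos])
  det <- vector("list", length(byComp))
  areas <- recs$area
  names(areas) <- as.character(recs$label)
  nrImg <- nrow(img)
  for (k in seq_along(byComp)) {
    idx <- byComp[[k]]
    wt <- th[idx]
    if (mean(wt) < params@finalThreshold) next # plateau-level screening
    rr <- ((idx - 1L) %% nrImg) + 1L
    cc <- ((idx - 1L) %/% nrImg) + 1L
    if (sum(wt) <= 0) wt <- rep(1, length(idx))
    crd <- sum(rr * wt) / sum(wt)
    ccd <- sum(cc * wt) / sum(wt)
    ri <- min(max(1L, as.integer(round(crd))), nrow(img))
    ci <- min(max(1L, as.integer(round(ccd))), ncol(img))
    nl <- lab[ri, ci]
    if (nl == 0) next
    if (length(idx) > 0.25 * areas[as.character(nl)]) next # degenerate plateau
    det[[k]] <- data.frame(cr = crd, cc = ccd, nucleus = as.integer(nl),
                           peakIntensity = max(th[idx]), area = length(idx))
  }
  det <- do.call(rbind, det)
  if (is.null(det)) det <- emptyDet
  cnt <- integer(nNuc)
  names(cnt) <- as.character(recs$label)
  if (nrow(det) > 0) {
    tb <- table(det$nucleus)
    cnt[names(tb)] <- as.integer(tb)
  }
  s <- summarizeCounts(cnt)
  new("FociCount", detections = det, perNucleusCounts = cnt,
      nNuclei = as.integer(nNuc), meanPerNucleus = s[["mean"]],
      sem = s[["sem"]])
}

#' Mean and SEM of per-nucleus foci counts
#'
#' @param counts integer vector of per-nucleus foci counts.
#' @return named numeric vector with elements \code{mean} and \code{sem}
#'   (SEM = sample sd / sqrt(n); 0 for a single nucleus, NA for none).
#' @export
summarizeCounts <- function(counts) {
  n <- length(counts)
  if (n == 0) return(c(mean = NA_real_, sem = NA_real_))
  m <- mean(counts)
  s <- if (n > 1) sd(counts) / sqrt(n) else 0
  c(mean = m, sem = s)
}

#' Count foci on a two-channel field of view
#'
#' Convenience wrapper: segments nuclei from the nuclei channel, then
#' detects and counts foci per nucleus in the foci channel.
#'
#' @param pair a \linkS4class{ChannelPair}.
#' @param nucleiParams a \linkS4class{NucleiParams}.
#' @param fociParams a \linkS4class{FociParams}.
#' @return list with elements \code{nuclei} (\linkS4class{NucleusSet}) and
#'   \code{foci} (\linkS4class{FociCount}).
#' @export
countFoci <- function(pair, nucleiParams = NucleiParams(),
                      fociParams = FociParams()) {
  nuc <- segmentNuclei(pair@nuclei, nucleiParams)
  res <- detectFoci(pair@foci, nuc, fociParams)
  list(nuclei = nuc, foci = res)
}
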