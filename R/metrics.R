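# Evaluation statistics: RelDiff1 (reliability against simulated ground
# truth), RelDiff2 (robustness to artificial out-of-focus background), the
# circular-averaging blur protocol, and outlier screening of per-image means.

#' Relative difference against a reference count (RelDiff1)
#'
#' \code{(nAuto - nRef) / nRef * 100} in percent. Positive values indicate
#' overestimation, negative values underestimation of the reference foci
#' number. For an image set both arguments are set-level means (mean
#' automatic count per image vs mean pre-defined count per image).
#'
#' @param nAuto mean automatic foci count.
#' @param nRef mean reference (ground-truth) foci count, > 0.
#' @return signed percentage.
#' @export
relDiff1 <- function(nAuto, nRef) {
  if (nRef <= 0) stop("reference count must be > 0", call. = FALSE)
  (nAuto - nRef) / nRef * 100
}

#' Relative difference under artificial background (RelDiff2)
#'
#' \code{|nBase - nArt| / nBase * 100} in percent, comparing the mean foci
#' count on a base image with the count on the same image after adding an
#' artificial out-of-focus background. Lower values mean the detector is
#' more robust to out-of-focus signal.
#'
#' @param nBase mean foci per nucleus on the base image, > 0.
#' @param nArt mean foci per nucleus on the composite image.
#' @return non-negative percentage.
#' @export
relDiff2 <- function(nBase, nArt) {
  if (nBase <= 0) stop("base count must be > 0", call. = FALSE)
  abs(nBase - nArt) / nBase * 100
}

#' Pillbox (circular averaging) convolution kernel
#'
#' Normalized uniform disk of radius \code{f} with area-weighted fractional
#' coverage at the rim, so the blur strength varies smoothly with the
#' radius. The kernel sums to 1.
#'
#' @param f radius in pixels (>= 1).
#' @return square numeric matrix.
#' @export
pillboxKernel <- function(f) {
  if (f < 1) stop("radius must be >= 1", call. = FALSE)
  r <- as.integer(ceiling(f))
  d <- seq.int(-r, r)
  k <- matrix(0, length(d), length(d))
  sub <- 16L # sub-pixel sampling per axis for rim coverage
  off <- (seq_len(sub) - 0.5) / sub - 0.5
  for (i in seq_along(d)) for (j in seq_along(d)) {
    if (sqrt(d[i]^2 + d[j]^2) <= f - 0.71) { k[i, j] <- 1; next }
    if (sqrt(d[i]^2 + d[j]^2) >= f + 0.71) next
    px <- outer(d[i] + off, rep(1, sub))
    py <- outer(rep(1, sub), d[j] + off)
    k[i, j] <- mean(px^2 + py^2 <= f^2)
  }
  k / sum(k)
}

#' Blur an image with a circular averaging filter
#'
#' Convolution with the normalized pillbox kernel of radius \code{f}
#' (reflect padding). Mimics out-of-focus light: the larger the radius, the
#' stronger the blur.
#'
#' @param img intensity matrix.
#' @param f pillbox radius in pixels.
#' @return blurred matrix of the same size.
#' @export
circularAverage <- function(img, f) {
  k <- pillboxKernel(f)
  p <- (nrow(k) - 1L) %/% 2L
  xp <- padReflect(img, p)
  out <- as.matrix(EBImage::filter2(xp, k, boundary = "replicate"))
  unpad(out, p, nrow(img), ncol(img))
}

#' Composite image with artificial out-of-focus background
#'
#' Adds the circularly blurred foci channel of a neighbouring focal plane
#' to the base foci channel and clips to [0,1] (saturation, as on a
#' detector; no rescaling, so base-image foci intensities are untouched).
#'
#' @param base base foci-channel matrix.
#' @param neighbor neighbouring-plane foci-channel matrix, same size.
#' @param f pillbox blur radius in pixels.
#' @return composite matrix in [0,1].
#' @export
outOfFocusComposite <- function(base, neighbor, f) {
  if (!identical(dim(base), dim(neighbor)))
    stop("base and neighbor images must have identical dimensions",
         call. = FALSE)
  clip01(base + circularAverage(neighbor, f))
}

#' Blur-robustness protocol
#'
#' Counts foci on the base image, then for each blur radius adds the
#' blurred neighbour channel and re-counts with identical parameters,
#' reporting RelDiff2 per radius.
#'
#' @param base base foci-channel matrix.
#' @param neighbor neighbouring-plane foci-channel matrix.
#' @param nuclei a \linkS4class{NucleusSet}; defaults to treating the whole
#'   frame as one nucleus (simulated single-nucleus images).
#' @param params a \linkS4class{FociParams}.
#' @param radii blur radii in pixels (default 1:6).
#' @return data.frame with columns \code{f}, \code{nBase}, \code{nArt},
#'   \code{relDiff2}.
#' @export
blurRobustness <- function(base, neighbor, nuclei = NULL,
                           params = FociParams(), radii = 1:6) {
  if (any(radii < 1)) stop("blur radii must be >= 1", call. = FALSE)
  if (is.null(nuclei)) nuclei <- fullFrameNucleus(dim(base))
  nBase <- meanFoci(detectFoci(base, nuclei, params))
  if (is.na(nBase) || nBase <= 0)
    stop("base image must contain at least one countable focus",
         call. = FALSE)
  rows <- lapply(radii, function(f) {
    comp <- outOfFocusComposite(base, neighbor, f)
    nArt <- meanFoci(detectFoci(comp, nuclei, params))
    data.frame(f = f, nBase = nBase, nArt = nArt,
               relDiff2 = relDiff2(nBase, nArt))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag outliers among per-image mean counts
#'
#' Tukey's fences: values outside \code{[Q1 - k IQR, Q3 + k IQR]} are
#' flagged (k = 1.5 by default). With fewer than 4 values the fences are
#' not meaningful and everything is kept with a warning.
#'
#' @param x numeric vector of per-image mean foci counts.
#' @param k fence multiplier (default 1.5).
#' @return list with elements \code{kept}, \code{flagged} and
#'   \code{fences}.
#' @export
flagOutliers <- function(x, k = 1.5) {
  if (length(x) < 4) {
    warning("fewer than 4 values: outlier fences not applied")
    return(list(kept = x, flagged = numeric(), fences = c(-Inf, Inf)))
  }
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  out <- x < fences[1] | x > fences[2]
  list(kept = x[!out], flagged = x[out], fences = fences)
}

#' Set-level reliability benchmark (RelDiff1) on simulated images
#'
#' Runs the detector with the given parameters over a list of simulated
#' images (each treated as one nucleus), and compares the set-level mean
#' automatic count to the set-level mean ground-truth count.
#'
#' @param sims list of \linkS4class{SimulatedFoci} from
#'   \code{\link{simulateFociSet}}.
#' @param params a \linkS4class{FociParams}.
#' @return list with \code{nAuto}, \code{nRef}, \code{relDiff1},
#'   \code{perImage} (data.frame of automatic vs true counts).
#' @export
relDiff1Benchmark <- function(sims, params = FociParams()) {
  counts <- vapply(sims, function(s) {
    nuc <- fullFrameNucleus(dim(pixelMatrix(s)))
    as.numeric(sum(fociPerNucleus(detectFoci(pixelMatrix(s), nuc, params))))
  }, numeric(1))
  truth <- vapply(sims, trueFociCount, integer(1))
  nAuto <- mean(counts)
  nRef <- mean(truth)
  list(nAuto = nAuto, nRef = nRef, relDiff1 = relDiff1(nAuto, nRef),
       perImage = data.frame(image = seq_along(sims), auto = counts,
                             truth = truth))
}
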