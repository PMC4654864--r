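#' @import methods
#' @importFrom stats median quantile rnorm runif sd
#' @importFrom utils read.csv write.csv packageVersion
#' @useDynLib fociQuant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Parameters for nuclei segmentation
#'
#' The nuclei pipeline exposes three scientific parameters: the threshold
#' (method or manual value), the radius of the disk structuring element used
#' for opening by reconstruction and for the final per-nucleus opening
#' (\code{openRadius}), and the number of 3x3 dilation/erosion iterations
#' used to close bay regions (\code{morphIterations}).
#'
#' @slot thresholdMethod \code{"huang"} (fuzzy-entropy automatic threshold)
#'   or \code{"manual"}.
#' @slot manualThreshold intensity in [0,1]; used only when
#'   \code{thresholdMethod == "manual"}.
#' @slot openRadius disk radius in pixels (default 10).
#' @slot morphIterations number of 3x3 dilate/erode iterations (default 3).
#' @slot excludeBorder drop nuclei touching the image border (default TRUE).
#' @export
setClass("NucleiParams",
  representation(
    thresholdMethod = "character",
    manualThreshold = "numeric",
    openRadius = "numeric",
    morphIterations = "numeric",
    excludeBorder = "logical"
  ),
  prototype(
    thresholdMethod = "huang",
    manualThreshold = 0.5,
    openRadius = 10,
    morphIterations = 3,
    excludeBorder = TRUE
  )
)

setValidity("NucleiParams", function(object) {
  msg <- NULL
  if (!object@thresholdMethod %in% c("huang", "manual"))
    msg <- c(msg, "thresholdMethod must be 'huang' or 'manual'")
  if (object@manualThreshold < 0 || object@manualThreshold > 1)
    msg <- c(msg, "manualThreshold must lie in [0,1]")
  if (object@openRadius < 1)
    msg <- c(msg, "openRadius must be >= 1")
  if (object@morphIterations < 0)
    msg <- c(msg, "morphIterations must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Parameters for foci detection
#'
#' Foci detection exposes two scientific parameters: the radius of the disk
#' used by the white top-hat transform (\code{tophatRadius}, default 3) and
#' the final intensity threshold applied to the top-hat image at the regional
#' maxima (\code{finalThreshold}, default 0.07). The maximum window of the
#' adaptive median filter (\code{medianMaxWindow}) is an advanced setting.
#'
#' @slot tophatRadius disk radius in pixels (default 3).
#' @slot finalThreshold intensity in [0,1] (default 0.07).
#' @slot medianMaxWindow odd window size >= 3 for the adaptive median
#'   filter (default 7).
#' @export
setClass("FociParams",
  representation(
    tophatRadius = "numeric",
    finalThreshold = "numeric",
    medianMaxWindow = "numeric"
  ),
  prototype(tophatRadius = 3, finalThreshold = 0.07, medianMaxWindow = 7)
)

setValidity("FociParams", function(object) {
  msg <- NULL
  if (object@tophatRadius < 1) msg <- c(msg, "tophatRadius must be >= 1")
  if (object@finalThreshold < 0 || object@finalThreshold > 1)
    msg <- c(msg, "finalThreshold must lie in [0,1]")
  w <- object@medianMaxWindow
  if (w < 3 || w %% 2 != 1) msg <- c(msg, "medianMaxWindow must be odd and >= 3")
  if (is.null(msg)) TRUE else msg
})

#' Configuration of the synthetic foci-image simulator
#'
#' @slot imageSize (rows, cols) in pixels.
#' @slot nFociRange inclusive [low, high] range of the true foci number.
#' @slot minSeparation minimum distance in pixels between ground-truth foci
#'   placed by different template draws.
#' @slot backgroundLevel constant background intensity.
#' @slot pixelNoiseSd standard deviation of per-pixel Gaussian noise.
#' @slot inhomAmplitude standard deviation of the low-frequency
#'   (out-of-focus-like) background field.
#' @slot inhomScale Gaussian blur sigma (pixels) of the low-frequency field.
#' @slot amplitudeRange [low, high] range of per-template peak amplitudes.
#' @slot seed integer seed recorded with the configuration (NA = unset).
#' @export
setClass("SimulationConfig",
  representation(
    imageSize = "numeric",
    nFociRange = "numeric",
    minSeparation = "numeric",
    backgroundLevel = "numeric",
    pixelNoiseSd = "numeric",
    inhomAmplitude = "numeric",
    inhomScale = "numeric",
    amplitudeRange = "numeric",
    seed = "numeric"
  ),
  prototype(
    imageSize = c(300, 300),
    nFociRange = c(5, 8),
    minSeparation = 8,
    backgroundLevel = 0.05,
    pixelNoiseSd = 0.02,
    inhomAmplitude = 0.04,
    inhomScale = 40,
    amplitudeRange = c(0.3, 0.7),
    seed = NA_real_
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  if (length(object@imageSize) != 2 || any(object@imageSize < 1))
    msg <- c(msg, "imageSize must be two positive integers")
  if (length(object@nFociRange) != 2 ||
      object@nFociRange[1] > object@nFociRange[2] || object@nFociRange[1] < 0)
    msg <- c(msg, "nFociRange must be 0 <= low <= high")
  if (object@minSeparation < 1) msg <- c(msg, "minSeparation must be >= 1")
  for (s in c("backgroundLevel", "pixelNoiseSd", "inhomAmplitude")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, paste(s, "must lie in [0,1]"))
  }
  ar <- object@amplitudeRange
  if (length(ar) != 2 || ar[1] > ar[2] || ar[1] < 0 || ar[2] > 1)
    msg <- c(msg, "amplitudeRange must be 0 <= low <= high <= 1")
  if (is.null(msg)) TRUE else msg
})

#' A focus template used by the simulator
#'
#' A small additive intensity patch with unit peak amplitude, together with
#' the ground-truth peak offsets it contributes (one for single templates,
#' two for paired templates).
#'
#' @slot patch numeric matrix of non-negative values.
#' @slot nFoci 1 or 2.
#' @slot gtOffsets nFoci x 2 matrix of (row, col) offsets relative to the
#'   patch centre.
#' @slot shapeTag "round", "elliptical" or "paired".
#' @export
setClass("FocusTemplate",
  representation(
    patch = "matrix",
    nFoci = "integer",
    gtOffsets = "matrix",
    shapeTag = "character"
  )
)

setValidity("FocusTemplate", function(object) {
  msg <- NULL
  if (any(object@patch < 0)) msg <- c(msg, "patch values must be >= 0")
  if (!object@nFoci %in% c(1L, 2L)) msg <- c(msg, "nFoci must be 1 or 2")
  if (nrow(object@gtOffsets) != object@nFoci)
    msg <- c(msg, "gtOffsets must have nFoci rows")
  if (is.null(msg)) TRUE else msg
})

#' Paired nuclei and foci channels of one field of view
#'
#' @slot nuclei intensity matrix in [0,1] (DNA-stain channel).
#' @slot foci intensity matrix in [0,1] (foci channel), same dimensions.
#' @slot sourceId text label identifying the source image.
#' @export
setClass("ChannelPair",
  representation(nuclei = "matrix", foci = "matrix", sourceId = "character")
)

setValidity("ChannelPair", function(object) {
  if (!identical(dim(object@nuclei), dim(object@foci)))
    return("nuclei and foci channels must have identical dimensions")
  TRUE
})

#' Labeled nuclei of one image
#'
#' Integer label matrix (0 = background, labels 1..K, each region
#' 8-connected) plus one record per nucleus.
#'
#' @slot labels integer matrix of nucleus labels.
#' @slot records data.frame with columns label, area, r0, r1, c0, c1
#'   (bounding box) and cr, cc (centroid).
#' @export
setClass("NucleusSet",
  representation(labels = "matrix", records = "data.frame")
)

setValidity("NucleusSet", function(object) {
  k <- nrow(object@records)
  labs <- sort(unique(as.vector(object@labels)))
  labs <- labs[labs > 0]
  if (k > 0 && !identical(as.integer(labs), seq_len(k)))
    return("labels must be consecutive integers 1..K")
  TRUE
})

#' Per-nucleus foci detections of one image
#'
#' @slot detections data.frame with one row per detected focus: cr, cc
#'   (intensity-weighted centroid), nucleus (label), peakIntensity, area.
#' @slot perNucleusCounts named integer vector, one entry per nucleus label.
#' @slot nNuclei number of nuclei considered.
#' @slot meanPerNucleus mean foci per nucleus.
#' @slot sem standard error of the mean (0 for a single nucleus).
#' @export
setClass("FociCount",
  representation(
    detections = "data.frame",
    perNucleusCounts = "integer",
    nNuclei = "integer",
    meanPerNucleus = "numeric",
    sem = "numeric"
  )
)

setValidity("FociCount", function(object) {
  if (sum(object@perNucleusCounts) != nrow(object@detections))
    return("per-nucleus counts must sum to the number of detections")
  if (object@nNuclei > 0 &&
      abs(object@meanPerNucleus - sum(object@perNucleusCounts) / object@nNuclei) > 1e-9)
    return("meanPerNucleus must equal total count / nNuclei")
  TRUE
})

#' A simulated single-nucleus foci image with ground truth
#'
#' @slot image intensity matrix in [0,1].
#' @slot gtCoordinates n x 2 matrix of true focus positions (row, col).
#' @slot nFociTrue number of true foci.
#' @slot config the \linkS4class{SimulationConfig} used.
#' @export
setClass("SimulatedFoci",
  representation(
    image = "matrix",
    gtCoordinates = "matrix",
    nFociTrue = "integer",
    config = "SimulationConfig"
  )
)

setValidity("SimulatedFoci", function(object) {
  msg <- NULL
  if (object@nFociTrue != nrow(object@gtCoordinates))
    msg <- c(msg, "nFociTrue must equal the number of ground-truth coordinates")
  rng <- object@config@nFociRange
  if (object@nFociTrue < rng[1] || object@nFociTrue > rng[2])
    msg <- c(msg, "nFociTrue must lie within the configured nFociRange")
  if (is.null(msg)) TRUE else msg
})

# ---- constructors -----------------------------------------------------------

#' @rdname NucleiParams-class
#' @param thresholdMethod,manualThreshold,openRadius,morphIterations,excludeBorder
#'   see the corresponding slots.
#' @return a \code{NucleiParams} object.
#' @export
NucleiParams <- function(thresholdMethod = "huang", manualThreshold = 0.5,
                         openRadius = 10, morphIterations = 3,
                         excludeBorder = TRUE) {
  new("NucleiParams", thresholdMethod = thresholdMethod,
      manualThreshold = manualThreshold, openRadius = openRadius,
      morphIterations = morphIterations, excludeBorder = excludeBorder)
}

#' @rdname FociParams-class
#' @param tophatRadius,finalThreshold,medianMaxWindow see the corresponding
#'   slots.
#' @return a \code{FociParams} object.
#' @export
FociParams <- function(tophatRadius = 3, finalThreshold = 0.07,
                       medianMaxWindow = 7) {
  new("FociParams", tophatRadius = tophatRadius,
      finalThreshold = finalThreshold, medianMaxWindow = medianMaxWindow)
}

#' @rdname SimulationConfig-class
#' @param imageSize,nFociRange,minSeparation,backgroundLevel,pixelNoiseSd,inhomAmplitude,inhomScale,amplitudeRange,seed
#'   see the corresponding slots.
#' @return a \code{SimulationConfig} object.
#' @export
SimulationConfig <- function(imageSize = c(300, 300), nFociRange = c(5, 8),
                             minSeparation = 8, backgroundLevel = 0.05,
                             pixelNoiseSd = 0.02, inhomAmplitude = 0.04,
                             inhomScale = 40, amplitudeRange = c(0.3, 0.7),
                             seed = NA) {
  new("SimulationConfig", imageSize = as.numeric(imageSize),
      nFociRange = as.numeric(nFociRange), minSeparation = minSeparation,
      backgroundLevel = backgroundLevel, pixelNoiseSd = pixelNoiseSd,
      inhomAmplitude = inhomAmplitude, inhomScale = inhomScale,
      amplitudeRange = as.numeric(amplitudeRange), seed = as.numeric(seed))
}

#' @rdname ChannelPair-class
#' @param nuclei,foci,sourceId see the corresponding slots.
#' @return a \code{ChannelPair} object.
#' @export
ChannelPair <- function(nuclei, foci, sourceId = "") {
  new("ChannelPair", nuclei = nuclei, foci = foci, sourceId = sourceId)
}

# ---- show methods -----------------------------------------------------------

setMethod("show", "NucleusSet", function(object) {
  cat("NucleusSet:", nrow(object@records), "nuclei,",
      paste(dim(object@labels), collapse = " x "), "pixels\n")
  if (nrow(object@records) > 0) {
    cat("  areas (px):", paste(object@records$area, collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "FociCount", function(object) {
  cat("FociCount:", nrow(object@detections), "foci in", object@nNuclei,
      "nuclei\n")
  if (object@nNuclei > 0)
    cat(sprintf("  mean foci/nucleus = %.3f (SEM %.3f)\n",
                object@meanPerNucleus, object@sem))
  invisible(NULL)
})

setMethod("show", "SimulatedFoci", function(object) {
  cat("SimulatedFoci:", paste(dim(object@image), collapse = " x "),
      "pixels,", object@nFociTrue, "ground-truth foci\n")
  invisible(NULL)
})

setMethod("show", "ChannelPair", function(object) {
  cat("ChannelPair", if (nzchar(object@sourceId))
    paste0("[", object@sourceId, "]") else "",
    ":", paste(dim(object@nuclei), collapse = " x "), "pixels\n")
  invisible(NULL)
})
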