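# Synthetic single-nucleus foci images with known ground truth. Each image
# is built by additively placing focus templates (with a minimum separation
# between placements), then adding a constant background, a low-frequency
# inhomogeneous field and per-pixel Gaussian noise.

gauss2d <- function(size, center, sigmaR, sigmaC = sigmaR, theta = 0) {
  d <- seq_len(size)
  rr <- outer(d - center[1], rep(1, size))
  cc <- outer(rep(1, size), d - center[2])
  u <- cos(theta) * rr + sin(theta) * cc
  v <- -sin(theta) * rr + cos(theta) * cc
  exp(-(u^2 / (2 * sigmaR^2) + v^2 / (2 * sigmaC^2)))
}

makeTemplate <- function(nFoci, offsets, sigmas, thetas, shapeTag) {
  reach <- max(abs(offsets)) + ceiling(3 * max(unlist(sigmas)))
  size <- 2L * as.integer(reach) + 1L
  ctr <- (size + 1) / 2
  patch <- matrix(0, size, size)
  for (i in seq_len(nrow(offsets))) {
    s <- sigmas[[i]]
    patch <- patch + gauss2d(size, ctr + offsets[i, ],
                             sigmaR = s[1], sigmaC = s[length(s)],
                             theta = thetas[i])
  }
  new("FocusTemplate", patch = patch, nFoci = as.integer(nFoci),
      gtOffsets = offsets, shapeTag = shapeTag)
}

#' Build the bank of focus templates
#'
#' Nine templates emulating the variety of real foci: isotropic Gaussian
#' spots (sigma 1.0, 1.5, 2.0 px), elliptical Gaussian spots (axis ratios
#' 1.5-2 at three orientations), and paired spots (two sigma = 1.2
#' Gaussians at 3-5 px separation) that probe the detector's ability to
#' split adjacent foci. Every template records the offsets of its true
#' peak(s); paired templates contribute two ground-truth foci.
#'
#' @return list of \linkS4class{FocusTemplate} objects.
#' @export
buildTemplateBank <- function() {
  bank <- list()
  add <- function(t) bank[[length(bank) + 1L]] <<- t
  for (s in c(1.0, 1.5, 2.0))
    add(makeTemplate(1, matrix(c(0, 0), 1), list(s), 0, "round"))
  ell <- list(c(2.25, 1.5, 0), c(2.625, 1.5, pi / 4), c(3.0, 1.5, pi / 2))
  for (e in ell)
    add(makeTemplate(1, matrix(c(0, 0), 1), list(e[1:2]), e[3], "elliptical"))
  pairs <- list(rbind(c(0, -1), c(0, 2)),    # separation 3
                rbind(c(-2, 0), c(2, 0)),    # separation 4
                rbind(c(-2, -2), c(1, 2)))   # separation 5
  for (p in pairs)
    add(makeTemplate(2, p, list(1.2, 1.2), c(0, 0), "paired"))
  bank
}

#' Bank restricted to single-focus templates
#'
#' Convenience for experiments that require all ground-truth foci to respect
#' the configured minimum separation (paired templates place two peaks
#' closer than that by design).
#'
#' @return list of \linkS4class{FocusTemplate} objects with one focus each.
#' @export
singleFocusBank <- function() {
  Filter(function(t) t@nFoci == 1L, buildTemplateBank())
}

#' Simulate one single-nucleus foci image
#'
#' Draws the target focus number uniformly from \code{nFociRange}, places
#' templates at uniformly random positions by rejection sampling (enforcing
#' \code{minSeparation} between foci of different placements and a border
#' margin of the patch radius), scales each placement by an amplitude drawn
#' from \code{amplitudeRange}, then adds the constant background, the
#' Gaussian-blurred low-frequency noise field (standardized to
#' \code{inhomAmplitude} standard deviation) and per-pixel Gaussian noise,
#' and clips to [0,1].
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param bank template list from \code{\link{buildTemplateBank}}.
#' @param seed optional integer seed; a given seed reproduces the image
#'   bit-exactly.
#' @return a \linkS4class{SimulatedFoci}.
#' @export
simulateFociImage <- function(config = SimulationConfig(),
                              bank = buildTemplateBank(), seed = NULL) {
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  nr <- as.integer(config@imageSize[1]); nc <- as.integer(config@imageSize[2])
  rng <- as.integer(config@nFociRange)
  target <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
  img <- matrix(0, nr, nc)
  coords <- matrix(numeric(), 0, 2)
  placed <- 0L
  maxAttempts <- 10000L
  while (placed < target) {
    ok <- FALSE
    cand <- Filter(function(t) t@nFoci <= target - placed, bank)
    if (length(cand) == 0) stop("no usable template", call. = FALSE)
    for (att in seq_len(maxAttempts)) {
      tpl <- cand[[sample.int(length(cand), 1)]]
      size <- nrow(tpl@patch)
      margin <- (size - 1L) %/% 2L
      if (nr - 2 * margin < 1 || nc - 2 * margin < 1)
        stop("image too small for template placement", call. = FALSE)
      pr <- sample.int(nr - 2L * margin, 1) + margin
      pc <- sample.int(nc - 2L * margin, 1) + margin
      newc <- sweep(tpl@gtOffsets, 2, c(pr, pc), "+")
      if (nrow(coords) > 0) {
        dmin <- min(sqrt(outer(newc[, 1], coords[, 1], "-")^2 +
                         outer(newc[, 2], coords[, 2], "-")^2))
        if (dmin < config@minSeparation) next
      }
      amp <- runif(1, config@amplitudeRange[1], config@amplitudeRange[2])
      rs <- (pr - margin):(pr + margin)
      cs <- (pc - margin):(pc + margin)
      img[rs, cs] <- img[rs, cs] + amp * tpl@patch
      coords <- rbind(coords, newc)
      placed <- placed + tpl@nFoci
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place focus after ", maxAttempts,
           " attempts; image capacity exceeded", call. = FALSE)
  }
  img <- img + config@backgroundLevel
  if (config@inhomAmplitude > 0) {
    w <- matrix(rnorm(nr * nc), nr, nc)
    ws <- gaussSmooth(w, config@inhomScale)
    s <- sd(as.vector(ws))
    if (s > 0) img <- img + (ws - mean(ws)) / s * config@inhomAmplitude
  }
  if (config@pixelNoiseSd > 0)
    img <- img + matrix(rnorm(nr * nc, sd = config@pixelNoiseSd), nr, nc)
  img <- clip01(img)
  cfg <- config
  if (!is.null(seed)) cfg@seed <- as.numeric(seed)
  new("SimulatedFoci", image = img, gtCoordinates = coords,
      nFociTrue = as.integer(nrow(coords)), config = cfg)
}

#' Preset simulator configurations
#'
#' \code{"irradiated"} emulates images of cells shortly after irradiation
#' (57-69 foci per image); \code{"control"} emulates non-irradiated cells
#' (5-8 foci per image). Both use the default 300 x 300 frame and noise
#' model.
#'
#' @param preset \code{"irradiated"} or \code{"control"}.
#' @return a \linkS4class{SimulationConfig}.
#' @export
presetConfig <- function(preset = c("irradiated", "control")) {
  preset <- match.arg(preset)
  if (preset == "irradiated") SimulationConfig(nFociRange = c(57, 69))
  else SimulationConfig(nFociRange = c(5, 8))
}

#' Simulate a set of foci images
#'
#' Generates \code{nImages} independent images with per-image seeds derived
#' from the master seed, so a fixed master seed reproduces the whole set
#' bit-exactly. Optionally writes 8-bit grayscale images, blue-frame
#' annotated copies and a ground-truth CSV (image id, focus index, row,
#' col) to \code{outputDir}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param nImages number of images (>= 1).
#' @param seed master seed.
#' @param bank template list (default \code{\link{buildTemplateBank}}).
#' @param outputDir optional directory for image/CSV output.
#' @param format \code{"png"} or \code{"tiff"} for written images.
#' @param annotate also write blue-frame annotated copies.
#' @return list of \linkS4class{SimulatedFoci} (invisibly carries the
#'   ground-truth table as attribute \code{"groundTruth"}).
#' @export
simulateFociSet <- function(config = SimulationConfig(), nImages = 50,
                            seed = 1, bank = buildTemplateBank(),
                            outputDir = NULL, format = "png",
                            annotate = FALSE) {
  if (nImages < 1) stop("nImages must be >= 1", call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nImages)
  out <- vector("list", nImages)
  gt <- list()
  for (i in seq_len(nImages)) {
    sim <- simulateFociImage(config, bank, seed = seeds[i])
    out[[i]] <- sim
    co <- groundTruth(sim)
    gt[[i]] <- data.frame(image_id = sprintf("sim_%03d", i),
                          focus = seq_len(nrow(co)),
                          row = co[, 1], col = co[, 2])
  }
  gtTab <- do.call(rbind, gt)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nImages)) {
      id <- sprintf("sim_%03d", i)
      writeIntensityImage(pixelMatrix(out[[i]]),
                          file.path(outputDir, paste0(id, ".", format)))
      if (annotate)
        writeOverlay(pixelMatrix(out[[i]]), groundTruth(out[[i]]),
                     file.path(outputDir, paste0(id, "_gt.png")),
                     color = "blue")
    }
    write.csv(gtTab, file.path(outputDir, "ground_truth.csv"),
              row.names = FALSE)
  }
  attr(out, "groundTruth") <- gtTab
  out
}
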