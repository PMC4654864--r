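# Batch entry points tying the modules into reproducible runs. Each run
# writes a provenance JSON (full configuration, seed, package version) next
# to its outputs; deterministic modes reproduce bit-exactly from it.

writeProvenance <- function(outputDir, mode, config, seed = NULL) {
  prov <- list(mode = mode, config = config, seed = seed,
               package = "fociQuant",
               version = as.character(packageVersion("fociQuant")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(outputDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(prov)
}

paramsToList <- function(p) {
  sl <- slotNames(class(p))
  out <- lapply(sl, function(s) slot(p, s))
  names(out) <- sl
  out
}

#' Count foci in a batch of images
#'
#' Processes every input image (RGB: blue = nuclei, green = foci), writes a
#' CSV result table with per-nucleus counts and per-image summaries, and
#' optionally per-image overlay PNGs with detected foci framed in red.
#' Unreadable images are skipped with a warning; an empty batch is an
#' error.
#'
#' @param inputs character vector of image paths, or a directory.
#' @param outputDir output directory (created if missing).
#' @param nucleiParams a \linkS4class{NucleiParams}.
#' @param fociParams a \linkS4class{FociParams}.
#' @param overlay write overlay images (default TRUE).
#' @return the result table, invisibly.
#' @export
runCount <- function(inputs, outputDir, nucleiParams = NucleiParams(),
                     fociParams = FociParams(), overlay = TRUE) {
  if (length(inputs) == 1 && dir.exists(inputs))
    inputs <- list.files(inputs, pattern = "\\.(tif|tiff|png|jpe?g|bmp)$",
                         ignore.case = TRUE, full.names = TRUE)
  if (length(inputs) == 0) stop("empty input batch", call. = FALSE)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (path in inputs) {
    res <- try({
      x <- readIntensityImage(path)
      pair <- if (length(dim(x)) == 3)
        splitChannels(x, sourceId = basename(path))
      else ChannelPair(nuclei = x, foci = x, sourceId = basename(path))
      countFoci(pair, nucleiParams, fociParams)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("skipping unreadable/unprocessable image: ", path)
      next
    }
    results[[basename(path)]] <- res$foci
    if (overlay && nrow(detections(res$foci)) >= 0) {
      out <- file.path(outputDir,
                       paste0(tools::file_path_sans_ext(basename(path)),
                              "_overlay.png"))
      writeOverlay(x, res$foci, out)
    }
  }
  if (length(results) == 0) stop("no image could be processed", call. = FALSE)
  tab <- writeResultsTable(results, file.path(outputDir, "foci_counts.csv"))
  writeProvenance(outputDir, "count",
                  list(nuclei = paramsToList(nucleiParams),
                       foci = paramsToList(fociParams),
                       inputs = inputs))
  invisible(tab)
}

#' Simulate and write an image set
#'
#' @param preset \code{"irradiated"} (57-69 foci) or \code{"control"}
#'   (5-8 foci), or a \linkS4class{SimulationConfig}.
#' @param nImages number of images (default 50).
#' @param seed master seed.
#' @param outputDir output directory.
#' @param annotate write blue-frame annotated copies (default TRUE).
#' @return list of \linkS4class{SimulatedFoci}, invisibly.
#' @export
runSimulate <- function(preset = "control", nImages = 50, seed = 1,
                        outputDir, annotate = TRUE) {
  config <- if (is(preset, "SimulationConfig")) preset
            else presetConfig(preset)
  sims <- simulateFociSet(config, nImages = nImages, seed = seed,
                          outputDir = outputDir, annotate = annotate)
  writeProvenance(outputDir, "simulate",
                  list(preset = if (is.character(preset)) preset else "custom",
                       config = paramsToList(config), nImages = nImages),
                  seed = seed)
  truth <- vapply(sims, trueFociCount, integer(1))
  message(sprintf("simulated %d images, %d-%d true foci (mean %.2f)",
                  nImages, min(truth), max(truth), mean(truth)))
  invisible(sims)
}

#' Reliability benchmark: simulate a set and report set-level RelDiff1
#'
#' @param preset \code{"irradiated"}, \code{"control"} or a
#'   \linkS4class{SimulationConfig}.
#' @param nImages number of images (default 50).
#' @param seed master seed.
#' @param fociParams a \linkS4class{FociParams}.
#' @param outputDir optional; writes \code{reldiff1.json} and a per-image
#'   CSV when given.
#' @return list with \code{nAuto}, \code{nRef}, \code{relDiff1},
#'   \code{perImage}.
#' @export
runBenchmarkRelDiff1 <- function(preset = "irradiated", nImages = 50,
                                 seed = 1, fociParams = FociParams(),
                                 outputDir = NULL) {
  config <- if (is(preset, "SimulationConfig")) preset
            else presetConfig(preset)
  sims <- simulateFociSet(config, nImages = nImages, seed = seed)
  rep <- relDiff1Benchmark(sims, fociParams)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(relDiff1 = rep$relDiff1, nAuto = rep$nAuto, nRef = rep$nRef,
           nImages = nImages, seed = seed),
      file.path(outputDir, "reldiff1.json"), auto_unbox = TRUE, digits = NA)
    write.csv(rep$perImage, file.path(outputDir, "reldiff1_per_image.csv"),
              row.names = FALSE)
    writeProvenance(outputDir, "benchmark-reldiff1",
                    list(preset = if (is.character(preset)) preset else "custom",
                         config = paramsToList(config), nImages = nImages,
                         foci = paramsToList(fociParams)), seed = seed)
  }
  rep
}

#' Robustness benchmark: blur protocol on a simulated base/neighbour pair
#'
#' Simulates two independent images from the same configuration, treats one
#' as the base and one as the neighbouring focal plane, and runs the
#' circular-averaging blur protocol for the given radii.
#'
#' @param preset \code{"irradiated"}, \code{"control"} or a
#'   \linkS4class{SimulationConfig}.
#' @param seed master seed.
#' @param radii blur radii (default 1:6).
#' @param fociParams a \linkS4class{FociParams}.
#' @param outputDir optional; writes \code{reldiff2.csv} when given.
#' @return data.frame from \code{\link{blurRobustness}}.
#' @export
runBenchmarkBlur <- function(preset = "irradiated", seed = 1, radii = 1:6,
                             fociParams = FociParams(), outputDir = NULL) {
  config <- if (is(preset, "SimulationConfig")) preset
            else presetConfig(preset)
  sims <- simulateFociSet(config, nImages = 2, seed = seed)
  tab <- blurRobustness(pixelMatrix(sims[[1]]), pixelMatrix(sims[[2]]),
                        params = fociParams, radii = radii)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tab, file.path(outputDir, "reldiff2.csv"), row.names = FALSE)
    writeProvenance(outputDir, "benchmark-blur",
                    list(preset = if (is.character(preset)) preset else "custom",
                         config = paramsToList(config), radii = radii,
                         foci = paramsToList(fociParams)), seed = seed)
  }
  tab
}

#' Read a run configuration from YAML (or JSON)
#'
#' The file may set any of the five scientific parameters
#' (\code{nuclei.threshold_method}, \code{nuclei.manual_threshold},
#' \code{nuclei.open_radius}, \code{nuclei.morph_iterations},
#' \code{foci.tophat_radius}, \code{foci.final_threshold}) and an
#' \code{advanced} section (adaptive-median window, simulator settings).
#' Values not present keep their defaults.
#'
#' @param path YAML or JSON file.
#' @return list with elements \code{nucleiParams}, \code{fociParams},
#'   \code{seed}, \code{raw}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  np <- NucleiParams()
  fp <- FociParams()
  n <- raw$nuclei
  if (!is.null(n$threshold_method)) np@thresholdMethod <- n$threshold_method
  if (!is.null(n$manual_threshold)) np@manualThreshold <- n$manual_threshold
  if (!is.null(n$open_radius)) np@openRadius <- n$open_radius
  if (!is.null(n$morph_iterations)) np@morphIterations <- n$morph_iterations
  if (!is.null(n$exclude_border)) np@excludeBorder <- n$exclude_border
  f <- raw$foci
  if (!is.null(f$tophat_radius)) fp@tophatRadius <- f$tophat_radius
  if (!is.null(f$final_threshold)) fp@finalThreshold <- f$final_threshold
  if (!is.null(raw$advanced$median_max_window))
    fp@medianMaxWindow <- raw$advanced$median_max_window
  validObject(np); validObject(fp)
  list(nucleiParams = np, fociParams = fp,
       seed = if (!is.null(raw$seed)) raw$seed else 1, raw = raw)
}
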