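# Image and table input/output: normalization, round trips, channel
# splitting, overlays, result tables.

test_that("normalization maps dtype extremes to 0 and 1 and 16-bit scales by 65535", {
  tmp <- tempfile(fileext = ".png")
  x <- matrix(c(0, 255, 128, 64) / 255, 2, 2)
  writeIntensityImage(x, tmp)
  y <- readIntensityImage(tmp)
  expect_equal(min(y), 0)
  expect_equal(max(y), 1)
  expect_equal(y, x, tolerance = 1e-12)

  tmp16 <- tempfile(fileext = ".tif")
  x16 <- matrix(c(0, 32768, 65535, 1) / 65535, 2, 2)
  writeIntensityImage(x16, tmp16, bitsPerSample = 16)
  y16 <- readIntensityImage(tmp16)
  expect_equal(y16[1, 2], 65535 / 65535)
  expect_equal(y16[2, 1], 32768 / 65535, tolerance = 1e-9) # 0.50000763
  expect_equal(y16[2, 2], 1 / 65535, tolerance = 1e-12)
  unlink(c(tmp, tmp16))
})

test_that("lossless round trip preserves 8-bit pixel values exactly", {
  set.seed(11)
  x <- matrix(sample(0:255, 40 * 30, replace = TRUE) / 255, 40, 30)
  for (ext in c(".png", ".tif")) {
    tmp <- tempfile(fileext = ext)
    writeIntensityImage(x, tmp)
    y <- readIntensityImage(tmp)
    expect_equal(round(y * 255), round(x * 255))
    unlink(tmp)
  }
})

test_that("JPEG input is accepted with a lossy-compression warning", {
  tmp <- tempfile(fileext = ".jpg")
  img <- EBImage::Image(matrix(0.5, 16, 16))
  EBImage::writeImage(img, tmp, type = "jpeg")
  expect_warning(y <- readIntensityImage(tmp), "lossy")
  expect_equal(dim(y), c(16L, 16L))
  unlink(tmp)
})

test_that("unsupported formats and missing files are rejected", {
  expect_error(readIntensityImage(tempfile(fileext = ".png")), "not found")
  tmp <- tempfile(fileext = ".xyz")
  writeLines("x", tmp)
  expect_error(readIntensityImage(tmp), "unsupported")
  unlink(tmp)
})

test_that("BMP reader recovers 8-bit grayscale and 24-bit colour pixels", {
  set.seed(5)
  g <- matrix(sample(0:255, 12 * 17, replace = TRUE), 12, 17)
  tmp <- tempfile(fileext = ".bmp")
  writeBMP8(g, tmp)
  y <- readIntensityImage(tmp)
  expect_equal(y, g / 255, tolerance = 1e-12)
  unlink(tmp)

  rgb <- array(sample(0:255, 9 * 7 * 3, replace = TRUE), dim = c(9, 7, 3))
  writeBMP24(rgb, tmp)
  z <- readIntensityImage(tmp)
  expect_equal(dim(z), c(9L, 7L, 3L))
  expect_equal(z, rgb / 255, tolerance = 1e-12)
  unlink(tmp)
})

test_that("splitChannels maps blue to nuclei and green to foci by default", {
  rgb <- array(0, dim = c(5, 5, 3))
  rgb[, , 2] <- 0.4
  rgb[, , 3] <- 0.7
  cp <- splitChannels(rgb)
  expect_equal(unique(as.vector(cp@nuclei)), 0.7)
  expect_equal(unique(as.vector(cp@foci)), 0.4)

  red <- array(0, dim = c(5, 5, 3)); red[, , 1] <- 1
  cp2 <- splitChannels(red)
  expect_true(all(cp2@nuclei == 0) && all(cp2@foci == 0))

  expect_error(splitChannels(rgb, nucleiChannel = "G", fociChannel = "G"),
               "differ")
})

test_that("overlay with no detections is pixel-identical and frames clip at borders", {
  x <- matrix(runif(25), 5, 5)
  out <- markFoci(x, NULL)
  expect_equal(out[, , 1], x)
  expect_equal(out[, , 2], x)
  expect_equal(out[, , 3], x)

  # frame ring at (10,10), half-width 3: square ring rows/cols 7..13
  x2 <- matrix(0.5, 20, 20)
  fr <- markFoci(x2, matrix(c(10, 10), 1), frameHalfWidth = 3)
  red <- fr[, , 1] == 1 & fr[, , 2] == 0
  expect_true(all(red[7, 7:13]) && all(red[13, 7:13]))
  expect_true(all(red[7:13, 7]) && all(red[7:13, 13]))
  expect_equal(sum(red), 24) # ring only, interior untouched
  expect_equal(fr[10, 10, 1], 0.5)

  # clipping at the corner: no error, partial ring drawn
  fr2 <- markFoci(x2, matrix(c(1, 1), 1), frameHalfWidth = 3)
  expect_equal(sum(fr2[, , 1] == 1 & fr2[, , 2] == 0), 7)
  expect_error(markFoci(x2, matrix(c(0, 5), 1)), "outside")
})

test_that("results table reports per-nucleus rows plus mean and SEM summaries", {
  mk <- function(counts) {
    det <- data.frame(cr = numeric(0), cc = numeric(0), nucleus = integer(0),
                      peakIntensity = numeric(0), area = integer(0))
    if (sum(counts) > 0)
      det <- do.call(rbind, lapply(seq_along(counts), function(i)
        if (counts[i] > 0) data.frame(cr = 1, cc = 1, nucleus = i,
                                      peakIntensity = 0.5, area = 1)[rep(1, counts[i]), ]))
    cnt <- as.integer(counts); names(cnt) <- seq_along(counts)
    s <- summarizeCounts(cnt)
    new("FociCount", detections = det, perNucleusCounts = cnt,
        nNuclei = length(counts), meanPerNucleus = s[["mean"]], sem = s[["sem"]])
  }
  tmp <- tempfile(fileext = ".csv")
  tab <- writeResultsTable(list(a = mk(c(3, 5)), b = mk(7)), tmp)
  expect_true(file.exists(tmp))
  sa <- tab[tab$image_id == "a" & tab$record == "summary", ]
  expect_equal(sa$mean_foci, 4)   # (3+5)/2
  expect_equal(sa$sem, 1)         # sd = sqrt(2), sem = sd/sqrt(2) = 1
  sb <- tab[tab$image_id == "b" & tab$record == "summary", ]
  expect_equal(sb$sem, 0)         # single-nucleus convention
  expect_equal(sum(tab$record == "nucleus"), 3)
  unlink(tmp)
})
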