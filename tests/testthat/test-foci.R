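# Foci detection: adaptive median, top-hat, Otsu, H-maxima, regional
# maxima, end-to-end counting, summaries.

test_that("adaptive median leaves constants alone and removes salt impulses", {
  const <- matrix(0.5, 20, 20)
  expect_equal(adaptiveMedianFilter(const, 7), const)

  salt <- const; salt[10, 12] <- 1.0
  out <- adaptiveMedianFilter(salt, 7)
  expect_equal(out[10, 12], 0.5)
  expect_equal(out, const)
})

test_that("top-hat is zero on constants and preserves isolated peak amplitude", {
  expect_true(all(topHat(matrix(0.3, 15, 15), 3) == 0))

  img <- matrix(0.2, 21, 21); img[11, 11] <- 0.8
  th <- topHat(img, 3)
  expect_equal(th[11, 11], 0.6)
  expect_equal(sum(th), 0.6) # everything else exactly zero

  # smooth ramp + small bright spot: ramp removed, spot amplitude kept
  ramp <- outer(seq(0, 0.3, length.out = 41), rep(1, 41))
  spot <- addGaussianSpot(ramp, c(21, 21), 1.2, 0.4)
  th2 <- topHat(spot, 3)
  interior <- matrix(FALSE, 41, 41)
  interior[5:37, 1:10] <- TRUE # away from borders and from the spot
  expect_lt(max(th2[interior]), 1e-9)             # pure-ramp area flattened
  expect_gt(th2[21, 21], 0.3)                     # spot survives
})

test_that("Otsu threshold matches the exhaustive between-class-variance scan", {
  x <- matrix(rep(c(0.2, 0.8), each = 32), 8, 8)
  thr <- otsuThreshold(x)
  expect_gt(thr, 0.2); expect_lt(thr, 0.8)

  set.seed(7)
  x2 <- matrix(runif(64 * 64), 64, 64)
  expect_equal(otsuThreshold(x2), oracleOtsu(x2))

  # independent cross-check against EBImage's Otsu (same 256-bin setup)
  expect_lt(abs(otsuThreshold(x2) -
                EBImage::otsu(EBImage::Image(x2), range = c(0, 1),
                              levels = 256)), 1.5 / 256)

  expect_error(otsuThreshold(matrix(0.5, 4, 4)), "constant")
})

test_that("H-maxima obeys the sandwich bounds, identity at h=0 and the 1D example", {
  set.seed(9)
  img <- matrix(runif(30 * 30), 30, 30)
  expect_equal(hMaxima(img, 0), img)

  for (h in c(0.1, 0.4)) {
    hm <- hMaxima(img, h)
    expect_true(all(hm <= img + 1e-12))
    expect_true(all(hm >= img - h - 1e-12))
  }

  # 1D profile: small peak suppressed, tall peak lowered by h
  prof <- matrix(c(0, 0.3, 0, 0.6, 0), 1, 5)
  hm <- hMaxima(prof, 0.4)
  expect_equal(hm, oracleReconstruct(prof - 0.4, prof))
  expect_equal(hm[1, 4], 0.2)        # retained at height h below the peak
  expect_equal(hm[1, 2], 0)          # suppressed into the surroundings
  rm1 <- regionalMaxima(hm)
  expect_equal(which(rm1), 4L)       # one surviving maximum

  # h at least the dynamic range leaves a single global plateau
  flatish <- hMaxima(img, diff(range(img)))
  rmf <- regionalMaxima(flatish)
  expect_equal(max(fociQuant:::cpp_label8(rmf)), 1)
})

test_that("regional maxima of a single-peak image is one plateau; constants are one plateau", {
  img <- addGaussianSpot(matrix(0, 21, 21), c(11, 11), 2, 1)
  rm <- regionalMaxima(img)
  expect_equal(max(fociQuant:::cpp_label8(rm)), 1)
  expect_true(rm[11, 11])

  const <- matrix(0.2, 9, 9)
  expect_true(all(regionalMaxima(const)))
})

test_that("noise-free spots are counted exactly and out-of-mask foci are dropped", {
  img <- matrix(0.05, 120, 120)
  centers <- list(c(20, 20), c(20, 60), c(20, 100), c(60, 20), c(60, 60),
                  c(60, 100), c(100, 20), c(100, 60))
  for (ctr in centers) img <- addGaussianSpot(img, ctr, 1.5, 0.5)
  img <- pmin(img, 1)
  res <- detectFoci(img, fullFrameNucleus(dim(img)))
  expect_equal(sum(fociPerNucleus(res)), 8)
  expect_equal(nrow(detections(res)), 8)

  # restrict the nuclear mask so one spot falls on background
  lab3 <- matrix(1L, 120, 120)
  lab3[95:120, 1:40] <- 0L # spot at (100,20) on background
  ns <- new("NucleusSet", labels = lab3, records = fociQuant:::labelRecords(lab3))
  res3 <- detectFoci(img, ns)
  expect_equal(sum(fociPerNucleus(res3)), 7)
})

test_that("blank foci channels give zero foci without errors", {
  res <- detectFoci(matrix(0.05, 80, 80), fullFrameNucleus(c(80, 80)))
  expect_equal(sum(fociPerNucleus(res)), 0)
  expect_equal(meanFoci(res), 0)
  expect_equal(semFoci(res), 0)
})

test_that("count summaries follow the mean and SEM conventions", {
  expect_equal(summarizeCounts(c(3, 5)), c(mean = 4, sem = 1))
  expect_equal(summarizeCounts(7), c(mean = 7, sem = 0))
  expect_equal(summarizeCounts(c(0, 0, 0)), c(mean = 0, sem = 0))
  expect_true(all(is.na(summarizeCounts(integer(0)))))
})

test_that("per-nucleus counts always sum to the number of detections", {
  set.seed(13)
  cfg <- SimulationConfig(nFociRange = c(10, 15))
  for (i in 1:5) {
    s <- simulateFociImage(cfg, seed = 100 + i)
    img <- pixelMatrix(s)
    # split the frame into two nuclei
    lab <- matrix(1L, nrow(img), ncol(img))
    lab[, seq_len(ncol(img) / 2)] <- 2L
    ns <- new("NucleusSet", labels = lab,
              records = fociQuant:::labelRecords(lab))
    res <- detectFoci(img, ns)
    expect_equal(sum(fociPerNucleus(res)), nrow(detections(res)))
    expect_false(any(duplicated(
      detections(res)[, c("cr", "cc")])))
  }
})
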