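# Nuclei segmentation: thresholding, mask construction, bay closing,
# watershed separation, final opening, full pipeline.

test_that("Huang threshold separates two-valued images and matches the exhaustive scan", {
  x <- matrix(rep(c(0.1, 0.9), each = 50), 10, 10)
  thr <- huangThreshold(x)
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.9)

  # bimodal Gaussian mixture, modes 0.2 / 0.8 with equal mass
  set.seed(21)
  v <- c(rnorm(500, 0.2, 0.05), rnorm(500, 0.8, 0.05))
  x2 <- matrix(pmin(pmax(v, 0), 1), 25, 40)
  expect_equal(huangThreshold(x2), oracleHuang(x2))

  expect_error(huangThreshold(matrix(0.4, 5, 5)), "constant")
})

test_that("primary mask fills holes, removes small objects and despeckles", {
  img <- drawDisk(100, 100, c(50, 50), 30, 0.8) + 0.05
  img[50, 50] <- 0.05; img[50, 51] <- 0.05; img[51, 50] <- 0.05 # 3-px hole
  img <- pmin(img, 1)
  p <- NucleiParams(thresholdMethod = "manual", manualThreshold = 0.4)
  m <- makePrimaryMask(img, p)
  expect_equal(m[50, 50], 1L)               # hole filled
  # area preserved up to median-filter nibbling of the discrete boundary
  expect_gte(sum(m), sum(drawDisk(100, 100, c(50, 50), 30)) - 30)

  # object smaller than the opening disk disappears entirely
  img2 <- drawDisk(60, 60, c(30, 30), 4, 0.8) + 0.05
  expect_equal(sum(makePrimaryMask(pmin(img2, 1), p)), 0)

  # isolated salt pixel removed by the median step, disk area preserved
  img3 <- drawDisk(80, 80, c(40, 40), 30, 0.8) + 0.05
  img3[5, 5] <- 0.9
  m3 <- makePrimaryMask(pmin(img3, 1), p)
  expect_equal(m3[5, 5], 0L)
  ref <- sum(drawDisk(80, 80, c(40, 40), 30))
  expect_true(abs(sum(m3) - ref) <= 30) # boundary-band nibbling only
})

test_that("closeBays fills a bay and matches a step-by-step dilation/erosion oracle", {
  # disk with a 4-pixel-wide bay cut from the boundary to the centre
  mask <- drawDisk(60, 60, c(30, 30), 20)
  mask[28:31, 10:30] <- 0
  closed <- closeBays(mask, 3)
  expect_equal(closed[30, 20], 1L) # bay interior filled
  expect_true(all(closed[mask == 1] == 1)) # superset of input

  # oracle: three explicit dilations, fill via the package is not used --
  # on a bay (not a hole) erosion of the dilated mask must already close it
  d <- mask
  for (i in 1:3) d <- oracleDilate3(d)
  expect_equal(d[30, 20], 1L) # mouth closed after 3 dilations

  # n = 0 reduces to hole filling only
  holed <- drawDisk(40, 40, c(20, 20), 12)
  holed[20, 20] <- 0
  f0 <- closeBays(holed, 0)
  expect_equal(f0[20, 20], 1L)
  expect_equal(sum(f0), sum(drawDisk(40, 40, c(20, 20), 12)))
})

test_that("watershed separates overlapping disks but never splits a convex disk", {
  # two radius-20 disks, centres 30 px apart
  m <- pmax(drawDisk(100, 120, c(50, 45), 20), drawDisk(100, 120, c(50, 75), 20))
  lab <- watershedSplit(m)
  expect_equal(max(lab), 2)
  # separation line is background
  expect_true(any(m == 1 & lab == 0))

  single <- drawDisk(80, 80, c(40, 40), 25)
  lab1 <- watershedSplit(single)
  expect_equal(max(lab1), 1)
  expect_equal(sum(lab1 > 0), sum(single)) # nothing removed from a convex blob

  empty <- matrix(0L, 30, 30)
  expect_equal(max(watershedSplit(empty)), 0)
})

test_that("finalizeNuclei drops debris and border-touching regions and is idempotent", {
  lab <- matrix(0L, 100, 100)
  lab[drawDisk(100, 100, c(40, 40), 30) > 0] <- 1L
  lab[drawDisk(100, 100, c(80, 80), 5) > 0] <- 2L  # debris, radius 5 < 10
  ns <- finalizeNuclei(lab, r = 10, excludeBorder = FALSE)
  expect_equal(nucleusCount(ns), 1)
  expect_true(all(sort(unique(as.vector(labelMatrix(ns)))) %in% c(0L, 1L)))

  # idempotency of the final opening
  ns2 <- finalizeNuclei(labelMatrix(ns), r = 10, excludeBorder = FALSE)
  expect_equal(labelMatrix(ns2), labelMatrix(ns))

  # border exclusion
  labB <- matrix(0L, 60, 60)
  labB[drawDisk(60, 60, c(1, 30), 15) > 0] <- 1L   # touches row 1
  labB[drawDisk(60, 60, c(40, 30), 14) > 0] <- 2L
  nsB <- finalizeNuclei(labB, r = 10, excludeBorder = TRUE)
  expect_equal(nucleusCount(nsB), 1)
  expect_equal(nucleusRecords(nsB)$label, 1L) # labels repacked to 1..K
})

test_that("full nuclei pipeline segments blurred disks including touching ones", {
  img <- matrix(0.03, 220, 220)
  for (ctr in list(c(60, 60), c(60, 130), c(160, 160))) # two touching, one apart
    img[drawDisk(220, 220, ctr, 40) > 0] <- img[drawDisk(220, 220, ctr, 40) > 0] + 0.7
  img <- pmin(img, 1)
  img <- as.matrix(EBImage::gblur(img, sigma = 2))
  ns <- segmentNuclei(pmin(pmax(img, 0), 1), NucleiParams())
  expect_equal(nucleusCount(ns), 3)

  # blank image yields zero nuclei (degenerate threshold propagates as error,
  # manual threshold on blank gives empty mask)
  blank <- matrix(0.02, 120, 120)
  nsb <- segmentNuclei(blank, NucleiParams(thresholdMethod = "manual",
                                           manualThreshold = 0.5))
  expect_equal(nucleusCount(nsb), 0)

  # disk with internal hole and a boundary bay -> one nucleus, hole/bay filled
  img3 <- drawDisk(140, 140, c(70, 70), 45, 0.8) + 0.03
  img3[65:75, 65:75] <- 0.03        # hole
  img3[68:72, 25:70] <- 0.03        # bay to the boundary
  ns3 <- segmentNuclei(pmin(img3, 1),
                       NucleiParams(thresholdMethod = "manual",
                                    manualThreshold = 0.4))
  expect_equal(nucleusCount(ns3), 1)
  expect_equal(labelMatrix(ns3)[70, 70], 1L) # hole filled
})

test_that("watershed labels are consecutive and never fewer than the components", {
  set.seed(33)
  for (i in 1:5) {
    m <- matrix(0L, 90, 90)
    for (k in 1:3) {
      ctr <- sample(20:70, 2)
      m <- pmax(m, drawDisk(90, 90, ctr, sample(8:16, 1)))
    }
    ncomp <- max(fociQuant:::cpp_label8(m > 0))
    lab <- watershedSplit(m)
    expect_gte(max(lab), ncomp)
    labs <- sort(unique(as.vector(lab))); labs <- labs[labs > 0]
    expect_equal(labs, seq_along(labs)) # consecutive 1..K
  }
})
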