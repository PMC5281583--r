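# Agreement metrics and the semi-automated thresholding baseline.

test_that("Dice index follows the overlap formula and its conventions", {
  d <- c(4L, 4L, 1L)
  a <- array(FALSE, d); a[1:2, 1:2, 1] <- TRUE
  b <- array(FALSE, d); b[2:3, 1:2, 1] <- TRUE
  expect_equal(diceIndex(a, b), 2 * 2 / (4 + 4))   # overlap 2 of 4 and 4
  expect_equal(diceIndex(a, a), 1)
  disj <- array(FALSE, d); disj[4, 4, 1] <- TRUE
  expect_equal(diceIndex(a, disj), 0)
  expect_equal(diceIndex(a, b), diceIndex(b, a))   # symmetry
  expect_message(dd <- diceIndex(array(FALSE, d), array(FALSE, d)), "empty")
  expect_equal(dd, 1)
  expect_error(diceIndex(a, array(FALSE, c(3, 3, 1))), "differ")
})

test_that("lesion volume is count times voxel volume and additive", {
  m <- array(FALSE, c(20L, 20L, 2L)); m[1:10, 1:10, 1] <- TRUE
  expect_equal(lesionVolume(m, c(0.12, 0.12, 0.50)), 100 * 0.0072)  # 0.72
  expect_equal(lesionVolume(array(FALSE, c(4, 4, 1)), c(1, 1, 1)), 0)
  expect_equal(lesionVolume(m, c(0.12, 0.12, 1.0)),
               2 * lesionVolume(m, c(0.12, 0.12, 0.5)))
  m2 <- array(FALSE, c(20L, 20L, 2L)); m2[11:15, 1:4, 2] <- TRUE
  expect_equal(lesionVolume(m | m2, c(1, 1, 1)),
               lesionVolume(m, c(1, 1, 1)) + lesionVolume(m2, c(1, 1, 1)))
  expect_error(lesionVolume(m, c(0, 1, 1)), "positive")
})

test_that("ICC(A,1) matches a two-way ANOVA mean-squares oracle", {
  # 6-case table, two methods
  x <- c(12.1, 30.4, 45.2, 18.9, 51.7, 26.3)
  y <- c(14.0, 28.8, 47.9, 17.5, 55.0, 27.1)
  got <- iccAbsoluteAgreement(cbind(x, y))
  # independent oracle: mean squares from a two-way aov decomposition
  df <- data.frame(score = c(x, y),
                   case = factor(rep(1:6, 2)),
                   method = factor(rep(1:2, each = 6)))
  ms <- summary(aov(score ~ case + method, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 2
  want <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(got, want, tolerance = 1e-9)
  expect_equal(iccAbsoluteAgreement(cbind(x, x)), 1)
  # absolute agreement penalizes a constant bias
  expect_lt(iccAbsoluteAgreement(cbind(x, x + 10)),
            iccAbsoluteAgreement(cbind(x, x)))
  expect_error(iccAbsoluteAgreement(cbind(rep(1, 4), rep(1, 4))),
               "degenerate")
  expect_error(iccAbsoluteAgreement(cbind(x[1:2], y[1:2])), "at least 3")
})

test_that("ICC decreases as measurement noise grows", {
  medianIcc <- function(noiseSd) {
    vapply(1:20, function(s) {
      set.seed(1000 + s)
      x <- runif(12, 10, 80)
      iccAbsoluteAgreement(cbind(x, x + rnorm(12, 0, noiseSd)))
    }, numeric(1))
  }
  m1 <- median(medianIcc(1)); m2 <- median(medianIcc(8))
  m3 <- median(medianIcc(25))
  expect_true(m1 > m2 && m2 > m3)
})

test_that("the contralateral threshold is mean plus two sample sds", {
  expect_equal(contralateralThreshold(c(48, 50, 52)), 54)  # sd(n-1) = 2
  expect_equal(contralateralThreshold(c(50, 50, 50)), 50)
  v <- rnorm(10, 50, 5)
  expect_equal(contralateralThreshold(v), mean(v) + 2 * sd(v))
  expect_error(contralateralThreshold(50), "at least 2")
})

test_that("threshold masks are strict and domain-restricted", {
  a <- array(c(40, 50, 60, 70), c(2, 2, 1))
  expect_equal(sum(thresholdMask(a, 100)), 0)
  expect_equal(sum(thresholdMask(a, 0)), 4)
  # equality excluded
  expect_identical(as.vector(thresholdMask(a, 60)),
                   c(FALSE, FALSE, FALSE, TRUE))
  dom <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  expect_identical(as.vector(thresholdMask(a, 45, dom)),
                   c(FALSE, TRUE, FALSE, FALSE))
})

test_that("the semi-automated baseline mirrors the observer workflow", {
  ph <- generatePhantom(phantomSpec(dim = c(64L, 64L, 10L),
                                    lesionVolume = 12, seed = 7L))
  t2 <- ph$t2
  atlas <- ph$truthAtlas
  healthyRoi <- atlasMask(atlas, "CBH") & !atlasMask(atlas, "CV") &
    !atlasMask(atlas, "PVZ")
  # this animal's contralateral ROI mean sits at the healthy tissue mean
  expect_equal(roiMean(t2, healthyRoi), 40, tolerance = 1)
  # group threshold from per-animal ROI means (animals differ more than
  # voxels within one animal do)
  roiMeans <- c(37.5, 42.8, 40.1, 44.0, 39.0, roiMean(t2, healthyRoi))
  thr <- contralateralThreshold(roiMeans)
  excl <- atlasMask(atlas, "IV") | atlasMask(atlas, "CV") |
    atlasMask(atlas, "PVZ")
  base <- semiAutomatedLesion(t2, thr, domain = atlasMask(atlas, "WB"),
                              exclusion = excl)
  expect_gt(diceIndex(base$mask & atlasMask(atlas, "IBH"), ph$lesion), 0.5)
  expect_equal(base$volume,
               lesionVolume(base$mask, voxelSpacing(t2)))
})

test_that("agreement reports summarise Dice, volumes and ICC", {
  set.seed(77)
  d <- c(16L, 16L, 4L)
  masks1 <- lapply(1:4, function(i) {
    m <- array(FALSE, d); m[2:(4 + 2 * i), 3:10, 2:3] <- TRUE; m
  })
  masks2 <- lapply(masks1, function(m) {
    m2 <- m
    m2[2, , ] <- FALSE                      # small systematic difference
    m2
  })
  rep <- agreementReport(masks1, masks2, c(0.12, 0.12, 0.5))
  expect_equal(nrow(rep$perCase), 4)
  expect_true(all(rep$perCase$dice > 0.5 & rep$perCase$dice < 1))
  expect_true(is.finite(rep$icc))
  expect_equal(rep$meanAbsVolDiff, mean(rep$perCase$absVolDiff))
})
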