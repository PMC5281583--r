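# Level-set engine: gradient map, energy bookkeeping, evolution contracts.

test_that("gradient map matches the hand-composed formula", {
  set.seed(11)
  img <- array(runif(16, 0, 1), c(4, 4, 1))
  cv <- array(c(rep(TRUE, 4), rep(FALSE, 12)), c(4, 4, 1))
  g <- voxelData(gradientMap(img, cv))
  # independent computation
  v <- img[cv]
  mu <- mean(v); s <- max(sqrt(mean((v - mu)^2)), 1e-3)
  ev <- -dnorm(img, mu, s, log = TRUE)
  ev <- (ev - min(ev)) / (max(ev) - min(ev))
  expect_equal(g, 1 - ev^2, tolerance = 1e-12)
  expect_true(all(g >= 0 & g <= 1))
  # the minimum-energy voxel gets g = 1, the maximum-energy voxel g = 0
  expect_equal(g[which.max(-dnorm(img, mu, s, log = TRUE))], 0)
  expect_equal(g[which.min(-dnorm(img, mu, s, log = TRUE))], 1)
})

test_that("gradient map of a constant image is identically 1", {
  img <- array(0.5, c(4, 4, 2))
  g <- voxelData(gradientMap(img, array(TRUE, c(4, 4, 2))))
  expect_true(all(g == 1))
})

test_that("energy bookkeeping matches brute-force summation", {
  set.seed(21)
  for (rep in 1:5) {
    img <- array(runif(36), c(6, 6, 1))
    obj <- array(runif(36) > 0.5, c(6, 6, 1))
    mObj <- gaussModel(runif(1, 0.4, 0.8), runif(1, 0.05, 0.2))
    mBg <- gaussModel(runif(1, 0.1, 0.4), runif(1, 0.05, 0.2))
    alpha <- runif(1, 0, 3); mu <- runif(1, 0, 2)
    p <- stageParams("stroke", alpha = alpha, mu = mu)
    got <- levelSetEnergy(obj, img, mObj, mBg, p)
    want <- bruteEnergy(obj, img, mObj, mBg, alpha, mu)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("energy of an empty object is the background sum; mu adds area", {
  set.seed(22)
  img <- array(runif(24), c(4, 3, 2))
  mObj <- gaussModel(0.7, 0.1); mBg <- gaussModel(0.3, 0.1)
  p0 <- stageParams("stroke", alpha = 0, mu = 0)
  eEmpty <- levelSetEnergy(array(FALSE, c(4, 3, 2)), img, mObj, mBg, p0)
  expect_equal(eEmpty, -sum(logProb(mBg, img)), tolerance = 1e-12)
  obj <- array(c(rep(TRUE, 10), rep(FALSE, 14)), c(4, 3, 2))
  e0 <- levelSetEnergy(obj, img, mObj, mBg, p0)
  e2 <- levelSetEnergy(obj, img, mObj, mBg,
                       stageParams("stroke", alpha = 0, mu = 1.7))
  expect_equal(e2 - e0, 1.7 * sum(obj), tolerance = 1e-12)
  # a checkerboard object on a 6x6x1 grid against the brute-force oracle
  co <- coordArrays(c(6L, 6L, 1L))
  chk <- array((co$X + co$Y) %% 2 == 0, c(6, 6, 1))
  img6 <- array(runif(36), c(6, 6, 1))
  p <- stageParams("stroke", alpha = 1.3, mu = 0.4)
  expect_equal(levelSetEnergy(chk, img6, mObj, mBg, p),
               bruteEnergy(chk, img6, mObj, mBg, 1.3, 0.4),
               tolerance = 1e-9)
})

test_that("a uniform gradient map reduces Length to the plain perimeter", {
  set.seed(23)
  img <- array(runif(36), c(6, 6, 1))
  obj <- array(runif(36) > 0.5, c(6, 6, 1))
  p <- stageParams("ventricles", alpha = 2, mu = 0)
  mObj <- gaussModel(0.7, 0.1); mBg <- gaussModel(0.3, 0.1)
  eNoG <- levelSetEnergy(obj, img, mObj, mBg, p)
  eOnes <- levelSetEnergy(obj, img, mObj, mBg, p, g = array(1, c(6, 6, 1)))
  expect_identical(eNoG, eOnes)
})

test_that("evolution reaches per-voxel ML classification on separated populations", {
  tp <- twoPopImage()
  obj <- gaussModel(0.7, 0.04); bg <- gaussModel(0.3, 0.04)
  p <- stageParams("stroke", alpha = 0, mu = 0, nIter = 200L,
                   objectModel = "gaussian", backgroundModel = "gaussian",
                   objectFixed = TRUE, backgroundFixed = TRUE)
  init <- array(FALSE, dim(tp$img)); init[1:20, , ] <- TRUE
  res <- evolveLevelSet(tp$img, init, obj, bg, p)
  ml <- logProb(obj, tp$img) > logProb(bg, tp$img)
  far <- abs(signedDistance(tp$truth)) > 1
  expect_equal(sum((res != ml) & far), 0)
})

test_that("an exact initialization with exact models is stationary", {
  tp <- twoPopImage(d = c(32L, 32L, 4L), seed = 9)
  obj <- gaussModel(0.7, 0.04); bg <- gaussModel(0.3, 0.04)
  p <- stageParams("stroke", alpha = 0, mu = 0, nIter = 50L,
                   objectModel = "gaussian", backgroundModel = "gaussian",
                   objectFixed = TRUE, backgroundFixed = TRUE)
  ml <- logProb(obj, tp$img) >= logProb(bg, tp$img)
  dim(ml) <- dim(tp$img)
  res <- evolveLevelSet(tp$img, ml, obj, bg, p)
  expect_equal(as.vector(res), as.vector(ml))
})

test_that("evolution is deterministic and respects the domain", {
  tp <- twoPopImage(d = c(32L, 32L, 4L), seed = 13)
  obj <- gaussModel(0.7, 0.04); bg <- gaussModel(0.3, 0.04)
  p <- stageParams("stroke", alpha = 0.5, mu = 0.2, nIter = 60L,
                   objectModel = "gaussian", backgroundModel = "gaussian",
                   objectFixed = TRUE, backgroundFixed = TRUE)
  domain <- array(FALSE, dim(tp$img)); domain[5:28, 5:28, ] <- TRUE
  init <- tp$truth & domain
  r1 <- evolveLevelSet(tp$img, init, obj, bg, p, domain = domain)
  r2 <- evolveLevelSet(tp$img, init, obj, bg, p, domain = domain)
  expect_identical(as.vector(r1), as.vector(r2))
  expect_equal(sum(r1 & !domain), 0)       # mask stays inside the domain
  expect_error(evolveLevelSet(tp$img, array(FALSE, dim(tp$img)), obj, bg, p),
               "empty-initialization")
})

test_that("swapping the models yields the complementary segmentation", {
  tp <- twoPopImage(d = c(32L, 32L, 4L), seed = 17)
  obj <- gaussModel(0.7, 0.04); bg <- gaussModel(0.3, 0.04)
  p <- stageParams("stroke", alpha = 0, mu = 0, nIter = 120L,
                   objectModel = "gaussian", backgroundModel = "gaussian",
                   objectFixed = TRUE, backgroundFixed = TRUE)
  init <- array(FALSE, dim(tp$img)); init[10:22, 10:22, 2:3] <- TRUE
  r1 <- evolveLevelSet(tp$img, init, obj, bg, p)
  r2 <- evolveLevelSet(tp$img, !init, bg, obj, p)
  expect_equal(as.vector(r2), as.vector(!r1))
})

test_that("with fixed models and no regularization the energy never increases", {
  set.seed(31)
  for (rep in 1:10) {
    d <- c(12L, 10L, 3L)
    img <- array(runif(prod(d)), d)
    obj <- gaussModel(runif(1, 0.5, 0.9), runif(1, 0.05, 0.2))
    bg <- gaussModel(runif(1, 0.1, 0.5), runif(1, 0.05, 0.2))
    init <- array(runif(prod(d)) > 0.5, d)
    if (!any(init)) init[1, 1, 1] <- TRUE
    p <- stageParams("stroke", alpha = 0, mu = 0, nIter = 40L,
                     objectModel = "gaussian", backgroundModel = "gaussian",
                     objectFixed = TRUE, backgroundFixed = TRUE)
    res <- evolveLevelSet(img, init, obj, bg, p, traceEnergy = TRUE)
    e <- c(levelSetEnergy(init, img, obj, bg, p), attr(res, "energy"))
    expect_true(all(diff(e) <= 1e-9))
  }
})

test_that("single-bin histograms exert no data force", {
  set.seed(33)
  d <- c(16L, 16L, 2L)
  img <- array(runif(prod(d)), d)
  m1 <- fitHistogramModel(img, array(TRUE, d), nBins = 1L, fixed = TRUE)
  init <- array(FALSE, d); init[4:12, 4:12, ] <- TRUE
  p <- stageParams("stroke", alpha = 0, mu = 0, nIter = 50L,
                   objectFixed = TRUE, backgroundFixed = TRUE)
  res <- evolveLevelSet(img, init, m1, m1, p)
  expect_equal(as.vector(res), as.vector(init))
})

test_that("stage parameter defaults reproduce the published table", {
  wb <- stageParams("wholeBrain")
  expect_equal(c(wb@alpha, wb@mu, wb@nIter), c(5, 2, 80))
  expect_identical(c(wb@objectModel, wb@backgroundModel),
                   c("gaussian", "gaussian"))
  expect_identical(wb@inputImage, "echo4")
  expect_false(wb@useGradientMap)
  cv <- stageParams("contralateralVentricle")
  expect_equal(c(cv@alpha, cv@mu, cv@nIter), c(0.1, 0, 120))
  vv <- stageParams("ventricles")
  expect_equal(c(vv@alpha, vv@mu, vv@nIter), c(2, 1.5, 120))
  expect_true(vv@useGradientMap && vv@objectFixed && !vv@backgroundFixed)
  st <- stageParams("stroke")
  expect_equal(c(st@alpha, st@mu, st@nIter), c(0.3, 0, 80))
  expect_true(st@backgroundFixed && !st@objectFixed)
  expect_identical(c(st@objectModel, st@backgroundModel),
                   c("histogram", "histogram"))
})
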