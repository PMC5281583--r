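# Synthetic phantom generator: determinism, volume targeting, tissue
# statistics, echo synthesis.

test_that("the same seed reproduces the phantom bit for bit", {
  a <- generatePhantom(phantomSpec(seed = 4L))
  b <- generatePhantom(phantomSpec(seed = 4L))
  expect_identical(voxelData(a$t2), voxelData(b$t2))
  expect_identical(a$lesion, b$lesion)
  expect_identical(encodeAtlas(a$templateAtlas),
                   encodeAtlas(b$templateAtlas))
  expect_identical(voxelData(a$echoes[[4]]), voxelData(b$echoes[[4]]))
  c <- generatePhantom(phantomSpec(seed = 5L))
  expect_false(identical(voxelData(a$t2), voxelData(c$t2)))
})

test_that("the lesion hits the requested volume within 5%", {
  for (vol in c(20, 30)) {
    ph <- generatePhantom(phantomSpec(lesionVolume = vol, seed = 2L))
    got <- sum(ph$lesion) * prod(voxelSpacing(ph$t2))
    expect_lt(abs(got - vol) / vol, 0.05)
  }
  expect_error(generatePhantom(phantomSpec(lesionVolume = 5000, seed = 1L)),
               "infeasible")
})

test_that("phantom structure satisfies the atlas and hemisphere contracts", {
  ph <- generatePhantom(phantomSpec(seed = 6L))
  expect_true(validObject(ph$truthAtlas))
  expect_true(validObject(ph$templateAtlas))
  # no lesion voxels on the contralateral side
  expect_equal(sum(ph$lesion & atlasMask(ph$truthAtlas, "CBH")), 0)
  expect_true(all(ph$lesion | !ph$lesion))
  expect_true(all(!ph$lesion | atlasMask(ph$truthAtlas, "IBH")))
  # lesion T2 stochastically dominates healthy tissue T2
  t2 <- voxelData(ph$t2)
  healthy <- atlasMask(ph$truthAtlas, "WB") & !ph$lesion &
    !atlasMask(ph$truthAtlas, "IV") & !atlasMask(ph$truthAtlas, "CV")
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(quantile(t2[ph$lesion], qs) > quantile(t2[healthy], qs)))
})

test_that("a lesion-free phantom has exchangeable hemispheres", {
  ph <- generatePhantom(phantomSpec(archetype = "none", seed = 8L))
  expect_equal(sum(ph$lesion), 0)
  t2 <- voxelData(ph$t2)
  ibh <- atlasMask(ph$truthAtlas, "IBH") & !atlasMask(ph$truthAtlas, "IV")
  cbh <- atlasMask(ph$truthAtlas, "CBH") & !atlasMask(ph$truthAtlas, "CV")
  expect_equal(mean(t2[ibh]), mean(t2[cbh]), tolerance = 0.01)
  expect_equal(sd(t2[ibh]), sd(t2[cbh]), tolerance = 0.05)
})

test_that("noiseless echoes decay log-linearly and recover T2", {
  d <- c(10L, 10L, 2L)
  t2 <- ScalarVolume(array(runif(prod(d), 25, 85), d))
  pd <- ScalarVolume(array(1, d))
  echoes <- synthesizeEchoes(t2, pd, te = 9, nEchoes = 12L, noiseSd = 0)
  n <- 1:12
  # per-voxel log-linear fit: slope = -TE / T2
  for (idx in list(c(1, 1, 1), c(5, 7, 2), c(10, 10, 1))) {
    y <- log(vapply(echoes, function(e)
      voxelData(e)[idx[1], idx[2], idx[3]], numeric(1)))
    slope <- coef(lm(y ~ n))[["n"]]
    t2hat <- -9 / slope
    expect_equal(t2hat, voxelData(t2)[idx[1], idx[2], idx[3]],
                 tolerance = 0.01)
  }
  # TE -> 0 limit: echo 1 approaches proton density
  e1 <- synthesizeEchoes(t2, pd, te = 1e-6, nEchoes = 1L, noiseSd = 0)[[1]]
  expect_equal(voxelData(e1), voxelData(pd), tolerance = 1e-6)
  # two-tissue noiseless phantom: echo 4 takes exactly two values
  tt <- array(40, d); tt[1:5, , ] <- 80
  e4 <- synthesizeEchoes(ScalarVolume(tt), pd, te = 9, nEchoes = 4L,
                         noiseSd = 0)[[4]]
  expect_equal(length(unique(as.vector(voxelData(e4)))), 2L)
  expect_error(synthesizeEchoes(ScalarVolume(array(-1, d)), pd),
               "non-positive")
})

test_that("template perturbation stays within the stated amplitude", {
  ph <- generatePhantom(phantomSpec(seed = 9L))
  # warped whole-brain boundary stays within a 2-voxel (in-plane) band of
  # the truth: eroding truth by 3 must stay inside the template mask
  shrunk <- strokeseg:::.erodeInPlane(atlasMask(ph$truthAtlas, "WB"), 3L)
  expect_true(all(!shrunk | atlasMask(ph$templateAtlas, "WB")))
  expect_gt(diceIndex(atlasMask(ph$templateAtlas, "WB"),
                      atlasMask(ph$truthAtlas, "WB")), 0.9)
  # perfect labels when the amplitude is zero
  pf <- generatePhantom(phantomSpec(templatePerturb = 0, seed = 9L))
  expect_identical(encodeAtlas(pf$templateAtlas), encodeAtlas(pf$truthAtlas))
})
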