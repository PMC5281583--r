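# Cropping, rescaling, reference-slice selection, per-slice CDF matching,
# echo summation.

test_that("crop box is the tight bounding box of the mask", {
  d <- c(16L, 12L, 6L)
  img <- array(rnorm(prod(d)), d)
  m <- array(FALSE, d)
  m[4:11, 6:10, 2:5] <- TRUE
  cr <- cropToLabelBbox(ScalarVolume(img), m)
  expect_equal(dim(cr$volume), c(8L, 5L, 4L))
  expect_equal(cr$report$box, c(3L, 11L, 5L, 10L, 1L, 5L))
  expect_equal(voxelData(cr$volume), img[4:11, 6:10, 2:5])
  # full-volume mask: identity crop
  crf <- cropToLabelBbox(ScalarVolume(img), array(TRUE, d))
  expect_equal(voxelData(crf$volume), img)
  # brute-force oracle: scan all set voxels on a random mask
  set.seed(5)
  mr <- array(runif(prod(d)) > 0.9, d)
  mr[8, 6, 3] <- TRUE
  w <- which(mr, arr.ind = TRUE)
  want <- c(min(w[, 1]) - 1L, max(w[, 1]), min(w[, 2]) - 1L, max(w[, 2]),
            min(w[, 3]) - 1L, max(w[, 3]))
  expect_equal(cropToLabelBbox(ScalarVolume(img), mr)$report$box,
               as.integer(want))
  expect_error(cropToLabelBbox(ScalarVolume(img), array(FALSE, d)), "empty")
})

test_that("cropping then zero-padding back preserves interior values", {
  d <- c(10L, 9L, 4L)
  img <- array(rnorm(prod(d)), d)
  m <- array(FALSE, d); m[3:8, 2:7, 2:3] <- TRUE
  cr <- cropToLabelBbox(ScalarVolume(img), m)
  back <- undoCrop(cr$volume, cr$report)
  expect_equal(back[3:8, 2:7, 2:3], img[3:8, 2:7, 2:3])
  expect_true(all(back[1, , ] == 0))
})

test_that("unit rescaling is linear, idempotent and degenerate-safe", {
  v <- rescaleUnit(array(c(2, 4, 6, 2, 2, 2, 4, 4), c(2, 2, 2)))
  expect_equal(sort(unique(as.vector(voxelData(v)))), c(0, 0.5, 1))
  # already exactly spanning the unit interval: unchanged
  a <- array(c(0, 1, runif(6)), c(2, 2, 2))
  expect_equal(voxelData(rescaleUnit(a)), a)
  expect_equal(voxelData(rescaleUnit(rescaleUnit(a))), a)
  expect_true(all(voxelData(rescaleUnit(array(7, c(2, 2, 2)))) == 0))
})

test_that("reference slice maximizes the Shannon histogram entropy", {
  d <- c(16L, 16L, 3L)
  a <- array(0.5, d)
  # slice 2 uniformly covers all 64 bins; others constant
  a[, , 2] <- rep(seq(1 / 128, 1 - 1 / 128, length.out = 64), 4)
  idx <- selectReferenceSlice(a)
  expect_equal(as.integer(idx), 2L)
  ent <- attr(idx, "entropy")
  # independent -sum(p log p) for each slice after unit rescale
  ar <- voxelData(rescaleUnit(a))
  want <- sapply(1:3, function(z) {
    p <- tabulate(pmin(pmax(floor(ar[, , z] * 64) + 1, 1), 64), nbins = 64)
    p <- p[p > 0] / sum(p)
    -sum(p * log(p))
  })
  expect_equal(as.vector(ent), want, tolerance = 1e-12)
  expect_equal(ent[[1]], 0)                # constant slice has zero entropy
  expect_equal(ent[[2]], log(64), tolerance = 1e-12)
})

test_that("CDF matching removes a constant shift and keeps ranks", {
  set.seed(19)
  d <- c(24L, 24L, 3L)
  base <- matrix(rnorm(576, 10, 2), 24, 24)
  a <- array(0, d)
  a[, , 1] <- base
  a[, , 2] <- base + 5          # shifted copy of the reference
  a[, , 3] <- matrix(rnorm(576, 12, 3), 24, 24)
  out <- voxelData(perSliceCdfNormalize(a, refSlice = 1L))
  expect_equal(out[, , 1], a[, , 1])      # reference slice untouched
  # shift removed: two-sample KS distance between matched slice and ref
  ks <- function(x, y) {
    g <- sort(c(x, y))
    max(abs(ecdf(x)(g) - ecdf(y)(g)))
  }
  expect_lt(ks(as.vector(out[, , 2]), as.vector(base)), 0.05)
  expect_equal(median(out[, , 2]), median(base), tolerance = 0.2)
  # monotone: rank order within each slice preserved
  for (z in 2:3) {
    o <- order(a[, , z])
    expect_true(all(diff(out[, , z][o]) >= 0))
  }
})

test_that("echo summation is exact and matches the relaxation closed form", {
  d <- c(8L, 8L, 2L)
  one <- ScalarVolume(array(runif(prod(d)), d))
  expect_equal(voxelData(sumEchoes(list(one))), voxelData(one))
  expect_equal(voxelData(sumEchoes(list(one, one))), 2 * voxelData(one))
  expect_error(sumEchoes(list(one, ScalarVolume(array(0, c(4, 4, 2))))),
               "differ")
  # 16 noiseless synthetic echoes: sum equals PD * sum_n exp(-n TE / T2)
  t2 <- ScalarVolume(array(runif(prod(d), 20, 90), d))
  pd <- ScalarVolume(array(runif(prod(d), 0.5, 1), d))
  echoes <- synthesizeEchoes(t2, pd, te = 9, nEchoes = 16L, noiseSd = 0)
  s <- voxelData(sumEchoes(echoes))
  want <- voxelData(pd) * Reduce(`+`, lapply(1:16, function(n)
    exp(-n * 9 / voxelData(t2))))
  expect_equal(s, want, tolerance = 1e-9)
})
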