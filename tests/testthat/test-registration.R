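# NCC registration, transform application, label propagation, transform I/O.

makeBlobVolume <- function(d = c(40L, 40L, 8L), seed = 2) {
  set.seed(seed)
  co <- coordArrays(d)
  a <- exp(-(((co$X - 18)^2) / 80 + ((co$Y - 22)^2) / 60 +
               ((co$Z - 4)^2) / 6)) +
    0.5 * exp(-(((co$X - 28)^2) / 30 + ((co$Y - 12)^2) / 40 +
                  ((co$Z - 5)^2) / 4)) +
    array(rnorm(prod(d), 0, 0.01), d)
  ScalarVolume(a, spacing = c(0.12, 0.12, 0.5))
}

test_that("self-registration recovers the identity", {
  v <- makeBlobVolume()
  tf <- registerNCC(v, v, stages = "rigid", maxit = 150L)
  expect_gt(attr(tf, "ncc"), 0.999)
  expect_lt(max(abs(tf@translation / voxelSpacing(v))), 0.1)
  expect_lt(max(abs(tf@matrix - diag(3))), 0.02)
})

test_that("a known integer translation is recovered within half a voxel", {
  v <- makeBlobVolume()
  shift <- c(3, -2, 1) * voxelSpacing(v)
  # moving(x) = fixed(x + shift); the fixed-to-moving map is then -shift
  moving <- resampleVolume(v, affineTransform(diag(3), shift))
  tf <- registerNCC(moving, v, stages = "rigid", maxit = 200L)
  err <- abs((tf@translation + shift) / voxelSpacing(v))
  expect_lt(max(err), 0.5)
})

test_that("NCC is invariant under linear intensity rescaling", {
  v <- makeBlobVolume()
  v2 <- ScalarVolume(3.7 * voxelData(v) + 11, spacing = voxelSpacing(v))
  tf1 <- registerNCC(v, v, stages = "rigid", maxit = 60L)
  tf2 <- registerNCC(v2, v, stages = "rigid", maxit = 60L)
  expect_equal(attr(tf1, "ncc"), attr(tf2, "ncc"), tolerance = 1e-6)
  expect_error(registerNCC(ScalarVolume(array(1, c(8, 8, 2))), v),
               "constant")
})

smallAtlas <- function(d = c(24L, 24L, 6L)) {
  co <- coordArrays(d)
  wb <- ((co$X - 12)^2 / 81 + (co$Y - 12)^2 / 64 +
           (co$Z - 3.5)^2 / 5) <= 1
  ibh <- wb & co$X > 12
  cbh <- wb & co$X <= 12
  iv <- ibh & abs(co$X - 15) <= 1 & abs(co$Y - 12) <= 3 & co$Z %in% 3:4
  cv <- cbh & abs(co$X - 9) <= 1 & abs(co$Y - 12) <= 3 & co$Z %in% 3:4
  pvz <- wb & !iv & !cv & abs(co$Y - 12) <= 4 &
    (abs(co$X - 15) <= 2 | abs(co$X - 9) <= 2) & co$Z %in% 2:5
  LabelAtlas(wb, ibh, cbh, iv, cv, pvz)
}

test_that("label propagation under the identity is the identity", {
  at <- smallAtlas()
  out <- propagateLabels(at, affineTransform(), dim(at@wb))
  for (lb in c("WB", "IBH", "CBH", "IV", "CV", "PVZ"))
    expect_identical(atlasMask(out, lb), atlasMask(at, lb))
})

test_that("integer-voxel translation shifts labels exactly", {
  at <- smallAtlas()
  sp <- c(0.12, 0.12, 0.5)
  tf <- affineTransform(diag(3), c(2, -1, 1) * sp)
  out <- propagateLabels(at, tf, dim(at@wb), targetSpacing = sp,
                         atlasSpacing = sp)
  d <- dim(at@wb)
  # independent index-shift oracle: out[i] = wb[i + (2,-1,1)]
  want <- array(FALSE, d)
  want[1:(d[1] - 2), 2:d[2], 1:(d[3] - 1)] <-
    at@wb[3:d[1], 1:(d[2] - 1), 2:d[3]]
  expect_identical(atlasMask(out, "WB"), want)
  # nearest-neighbour warping introduces no new label values
  expect_true(all(encodeAtlas(out) %in% unique(as.vector(encodeAtlas(at)))))
})

test_that("propagating with a transform and its inverse restores labels", {
  at <- smallAtlas()
  sp <- c(0.12, 0.12, 0.5)
  R <- diag(3)
  th <- 0.06
  R[1:2, 1:2] <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  tf <- affineTransform(R, c(0.2, -0.15, 0.3),
                        center = (dim(at@wb) - 1) / 2 * sp)
  fwd <- propagateLabels(at, tf, dim(at@wb), targetSpacing = sp,
                         atlasSpacing = sp)
  back <- propagateLabels(fwd, invertTransform(tf), dim(at@wb),
                          targetSpacing = sp, atlasSpacing = sp)
  for (lb in c("WB", "IBH", "CBH"))
    expect_gt(diceIndex(atlasMask(back, lb), atlasMask(at, lb)), 0.95)
  expect_error(propagateLabels(at, affineTransform(diag(3), c(100, 0, 0)),
                               dim(at@wb), targetSpacing = sp,
                               atlasSpacing = sp),
               "propagation-failed")
})

test_that("affine and displacement-field transforms round-trip via files", {
  tf <- affineTransform(matrix(c(1.02, 0.01, 0, -0.02, 0.98, 0.01,
                                 0, 0, 1.01), 3, 3),
                        c(0.3, -0.2, 0.5), center = c(1, 2, 3))
  f <- tempfile(fileext = ".txt")
  writeAffineTransform(tf, f)
  tf2 <- readAffineTransform(f)
  # the file stores the center folded into the translation: same mapping
  pts <- matrix(rnorm(15), 3)
  expect_equal(strokeseg:::.mapPoints(tf2, pts),
               strokeseg:::.mapPoints(tf, pts), tolerance = 1e-12)
  d <- c(6L, 5L, 4L)
  u <- array(rnorm(prod(d) * 3, 0, 0.1), c(d, 3L))
  ff <- tempfile(fileext = ".nii.gz")
  im <- RNifti::asNifti(u)
  RNifti::writeNifti(im, ff)
  df <- readDisplacementField(ff)
  expect_s4_class(df, "SpatialTransform")
  expect_equal(df@field, u, tolerance = 1e-6)
})
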