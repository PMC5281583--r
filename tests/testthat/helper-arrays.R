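# shared helpers for building small deterministic volumes and masks

coordArrays <- function(d) {
  list(X = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
       Y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
       Z = array(rep(seq_len(d[3]), each = d[1] * d[2]), d))
}

# two-population image: Gaussian intensities inside/outside an ellipsoidal
# truth region, well separated so per-voxel ML classification is decisive
twoPopImage <- function(d = c(64L, 64L, 8L), meanIn = 0.7, meanOut = 0.3,
                        sd = 0.04, seed = 7) {
  set.seed(seed)
  co <- coordArrays(d)
  truth <- ((co$X - d[1] / 2)^2 / (0.28 * d[1])^2 +
            (co$Y - d[2] / 2 + 2)^2 / (0.23 * d[2])^2 +
            (co$Z - (d[3] + 1) / 2)^2 / (0.38 * d[3])^2) <= 1
  img <- array(rnorm(prod(d), meanOut, sd), d)
  img[truth] <- rnorm(sum(truth), meanIn, sd)
  list(img = img, truth = truth)
}

gaussModel <- function(mean, sd, fixed = TRUE)
  new("GaussianModel", mean = mean, sd = sd, fixed = fixed)

# independent brute-force evaluation of the level-set energy: loops over
# voxels and 6-neighbour faces, never calls levelSetEnergy
bruteEnergy <- function(obj, img, mObj, mBg, alpha, mu, g = NULL,
                        domain = NULL) {
  d <- dim(img)
  if (is.null(domain)) domain <- array(TRUE, d)
  if (is.null(g)) g <- array(1, d)
  e <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!domain[i, j, k]) next
    v <- img[i, j, k]
    if (obj[i, j, k]) {
      e <- e - logProb(mObj, v) + mu
      for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))) {
        ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 ||
            kk > d[3]) next
        if (!obj[ii, jj, kk]) e <- e + alpha * g[i, j, k]
      }
    } else {
      e <- e - logProb(mBg, v)
    }
  }
  e
}

# brute-force dense-area filter oracle for one slice: exhaustive
# neighbourhood counting with integer arithmetic
bruteDenseSlice <- function(sl) {
  d <- dim(sl)
  dense <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!sl[i, j]) next
    cnt <- 0L; tot <- 0L
    for (dx in -4:4) for (dy in -4:4) {
      if (dx == 0 && dy == 0) next
      if (dx * dx + dy * dy > 16) next
      ii <- i + dx; jj <- j + dy
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2]) next
      tot <- tot + 1L
      if (sl[ii, jj]) cnt <- cnt + 1L
    }
    dense[i, j] <- 4L * cnt >= 3L * tot
  }
  dense
}
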