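#' Specify a synthetic tMCAo mouse brain phantom
#'
#' Defaults follow the acquisition geometry of a 7T multi-slice multi-echo
#' protocol (96 x 96 x 16 grid at 0.12 x 0.12 x 0.50 mm, TE 9 ms, 20
#' echoes) and tissue T2 statistics chosen to reproduce the difficulty of
#' real lesion data: healthy tissue 40 +- 3 ms, CSF/ventricle 90 +- 8 ms,
#' lesion 65 +- 6 ms, so that lesion and ventricle T2 distributions
#' partially overlap and the lesion cannot be isolated by a plain
#' threshold.
#'
#' @param dim integer(3) grid size
#' @param spacing numeric(3) voxel size in mm
#' @param t2Healthy,t2Ventricle,t2Lesion,t2Head,t2Background numeric(2) T2
#'   mean/sd in ms per tissue (`t2Head`: extracerebral head tissue filling
#'   the field of view around the brain)
#' @param archetype lesion shape: `"striatal"`, `"corticostriatal"`,
#'   `"fragmented"`, `"large-edema"` or `"none"`
#' @param lesionVolume target lesion volume in mm^3
#' @param noiseSd additive measurement noise on the T2 map (ms)
#' @param echoTime TE in ms
#' @param nEchoes echoes per train
#' @param echoNoiseSd additive noise on synthesized echoes (a.u.)
#' @param sliceGainSd sd of the per-slice multiplicative echo gain
#'   (emulates coil/slice-profile inhomogeneity)
#' @param templatePerturb max amplitude of the smooth random warp applied
#'   to the template labels, in in-plane voxels; the physical (mm)
#'   amplitude is isotropic, so thick-slice axes are perturbed by
#'   proportionally fewer voxels (0 = perfect labels)
#' @param seed random seed (same seed, same phantom)
#' @return a [PhantomSpec-class]
#' @export
phantomSpec <- function(dim = c(96L, 96L, 16L),
                        spacing = c(0.12, 0.12, 0.50),
                        t2Healthy = c(40, 3), t2Ventricle = c(90, 8),
                        t2Lesion = c(65, 6), t2Head = c(20, 3),
                        t2Background = c(3, 1),
                        archetype = "corticostriatal", lesionVolume = 30,
                        noiseSd = 1.5, echoTime = 9, nEchoes = 20L,
                        echoNoiseSd = 0.01, sliceGainSd = 0.05,
                        templatePerturb = 2, seed = 1L) {
  new("PhantomSpec", dim = as.integer(dim), spacing = as.numeric(spacing),
      t2Healthy = t2Healthy, t2Ventricle = t2Ventricle,
      t2Lesion = t2Lesion, t2Head = t2Head, t2Background = t2Background,
      archetype = archetype, lesionVolume = lesionVolume,
      noiseSd = noiseSd, echoTime = echoTime, nEchoes = as.integer(nEchoes),
      echoNoiseSd = echoNoiseSd, sliceGainSd = sliceGainSd,
      templatePerturb = templatePerturb, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %s, %s archetype, lesion %.1f mm^3, seed %d\n",
              paste(object@dim, collapse = " x "), object@archetype,
              object@lesionVolume, object@seed))
})

#' Generate a synthetic brain phantom
#'
#' Builds an ellipsoidal brain (flattened along z so that coronal
#' cross-sections stay comparable across the slice stack, as in a real
#' mouse brain) split by a midline plane into ipsilateral (stroke-bearing)
#' and contralateral hemispheres, surrounded by extracerebral head tissue,
#' with a curved lateral ventricle pair, a periventricular shell, and a
#' lesion of the requested archetype in the ipsilateral hemisphere, scaled
#' to the target volume (within 5%). Voxel T2 values are tissue mean plus
#' Gaussian tissue texture plus additive measurement noise; echo images
#' additionally carry a per-slice multiplicative gain. The template atlas is
#' the truth atlas warped by a smooth random displacement (max amplitude
#' `templatePerturb` voxels), emulating residual label-propagation error.
#' The contralateral hemisphere never contains lesion voxels, and with
#' `archetype = "none"` the hemispheres are statistically exchangeable.
#'
#' @param spec a [PhantomSpec-class]
#' @return list with `t2` ([ScalarVolume-class], ms), `pd` (proton-density
#'   [ScalarVolume-class], a.u.), `echoes` (list of [ScalarVolume-class]),
#'   `truthAtlas` and `templateAtlas` ([LabelAtlas-class]) and `lesion`
#'   (logical truth mask)
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  set.seed(spec@seed)
  d <- spec@dim
  geo <- .phantomGeometry(d)
  lesion <- .drawLesion(spec, geo)

  t2 <- array(rnorm(prod(d), spec@t2Background[1], spec@t2Background[2]), d)
  t2[geo$muscle] <- rnorm(sum(geo$muscle), spec@t2Head[1], spec@t2Head[2])
  # cortical bone: short T2, little signal
  t2[geo$skull] <- rnorm(sum(geo$skull), 6, 1.5)
  nWB <- sum(geo$wb)
  t2[geo$wb] <- rnorm(nWB, spec@t2Healthy[1], spec@t2Healthy[2])
  if (any(lesion))
    t2[lesion] <- rnorm(sum(lesion), spec@t2Lesion[1], spec@t2Lesion[2])
  vent <- geo$iv | geo$cv
  t2[vent] <- rnorm(sum(vent), spec@t2Ventricle[1], spec@t2Ventricle[2])
  if (spec@noiseSd > 0) t2 <- t2 + rnorm(prod(d), 0, spec@noiseSd)
  t2 <- pmax(t2, 0.5)
  dim(t2) <- d

  pd <- array(0.02, d)
  pd[geo$muscle] <- 1
  pd[geo$skull] <- 0.08
  pd[geo$wb] <- 1

  truth <- LabelAtlas(geo$wb, geo$ibh, geo$cbh, geo$iv, geo$cv, geo$pvz,
                      enforce = FALSE)
  # perturbation amplitude is isotropic in mm (registration error is
  # physical): templatePerturb in-plane voxels, converted per axis
  template <- if (spec@templatePerturb > 0)
    .perturbAtlas(truth,
                  spec@templatePerturb * min(spec@spacing) / spec@spacing)
  else truth

  t2v <- ScalarVolume(t2, spacing = spec@spacing)
  pdv <- ScalarVolume(pd, spacing = spec@spacing)
  echoes <- synthesizeEchoes(t2v, pdv, te = spec@echoTime,
                             nEchoes = spec@nEchoes,
                             noiseSd = spec@echoNoiseSd)
  if (spec@sliceGainSd > 0) {
    # per-slice multiplicative gain, shared by all echoes of a slice
    gain <- 1 + rnorm(d[3], 0, spec@sliceGainSd)
    echoes <- lapply(echoes, function(e) {
      a <- voxelData(e)
      a <- sweep(a, 3L, gain, `*`)
      ScalarVolume(a, spacing = spec@spacing)
    })
  }
  list(t2 = t2v, pd = pdv, echoes = echoes, truthAtlas = truth,
       templateAtlas = template, lesion = lesion, spec = spec)
}

#' Synthesize a multi-echo train from a T2 map
#'
#' Echo n (1-based) has expected signal `PD * exp(-n * TE / T2)` plus
#' optional additive Gaussian noise: the inverse of the multi-echo T2
#' fitting that produces quantitative maps on the scanner.
#'
#' @param t2 T2 map ([ScalarVolume-class], ms); must be positive wherever
#'   `brainMask` is `TRUE`
#' @param pd proton density map ([ScalarVolume-class], a.u.)
#' @param te echo spacing in ms
#' @param nEchoes number of echoes
#' @param noiseSd additive Gaussian noise sd (a.u.); 0 for noiseless
#' @param brainMask optional mask in which T2 must be positive (defaults
#'   to the whole grid)
#' @return list of `nEchoes` [ScalarVolume-class] volumes
#' @export
synthesizeEchoes <- function(t2, pd, te = 9, nEchoes = 20L, noiseSd = 0,
                             brainMask = NULL) {
  a <- .asArray(t2)
  p <- .asArray(pd)
  .stopIfIncongruent(a, p)
  check <- if (is.null(brainMask)) array(TRUE, dim(a)) else .asMask(brainMask)
  if (any(a[check] <= 0))
    stop("non-positive T2 inside the brain; cannot synthesize echoes")
  sp <- if (is(t2, "ScalarVolume")) t2@spacing else c(1, 1, 1)
  lapply(seq_len(nEchoes), function(n) {
    s <- p * exp(-n * te / a)
    if (noiseSd > 0) s <- s + rnorm(length(s), 0, noiseSd)
    ScalarVolume(array(s, dim(a)), spacing = sp)
  })
}

# --- geometry --------------------------------------------------------------

.phantomGeometry <- function(d) {
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  ax <- 0.40 * d[1]; ay <- 0.32 * d[2]; az <- 0.46 * d[3]
  x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  # superellipsoid flattened along z: coronal cross-sections stay
  # comparable across the slice stack, as in a real mouse brain
  rho2 <- ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^6
  wb <- rho2 <= 1
  # head tissue spans the whole slice stack (the mouse head extends well
  # beyond the brain), so every slice contains comparable extracerebral
  # content
  head <- (((X - cx) / (1.22 * ax))^2 + ((Y - cy) / (1.32 * ay))^2 +
             ((Z - cz) / (0.62 * d[3]))^6) <= 1 & !wb
  skull <- head & .dilateInPlane(wb, 2L)   # dark gap between brain and head
  muscle <- head & !skull
  ibh <- wb & (X > cx)       # stroke-bearing (right) hemisphere
  cbh <- wb & (X <= cx)
  scl <- d[1] / 96           # ventricle geometry scales with the grid
  vent <- function(side) {
    m <- array(FALSE, d)
    tpar <- seq(0, 1, length.out = 48)
    vx <- cx + side * (4 + 3 * sin(pi * tpar)) * scl
    vy <- cy + (-14 + 28 * tpar) * (d[2] / 96)
    zmid <- cz; zr <- 0.22 * d[3]
    for (zi in z) {
      dz <- abs(zi - zmid)
      if (dz > zr) next
      rz <- 2.5 * scl * sqrt(max(0, 1 - (dz / zr)^2))
      if (rz < 0.8) next
      sl <- matrix(FALSE, d[1], d[2])
      for (k in seq_along(tpar)) {
        dx2 <- outer((x - vx[k])^2, (y - vy[k])^2, `+`)
        sl <- sl | (dx2 <= rz^2)
      }
      m[, , zi] <- sl
    }
    m & wb
  }
  iv <- vent(+1) & ibh
  cv <- vent(-1) & cbh
  # periventricular shell: in-plane dilation of the ventricles by 3 voxels
  pvz <- .dilateInPlane(iv | cv, ceiling(3 * scl)) & wb & !(iv | cv)
  list(wb = wb, head = head, skull = skull, muscle = muscle,
       ibh = ibh, cbh = cbh, iv = iv, cv = cv,
       pvz = pvz, X = X, Y = Y, Z = Z, cx = cx, cy = cy, cz = cz, ax = ax,
       ay = ay, az = az, rho2 = rho2)
}

.erodeInPlane <- function(mask, r) {
  !.dilateInPlane(!mask, r)
}

.dilateInPlane <- function(mask, r) {
  out <- array(FALSE, dim(mask))
  offs <- rbind(c(0L, 0L), .diskOffsets(r))
  for (k in seq_len(nrow(offs))) {
    sh <- .shiftPad(.shiftPad(mask, 1L, offs[k, 1], FALSE),
                    2L, offs[k, 2], FALSE)
    out <- out | sh
  }
  out
}

# candidate lesion shape at linear scale k, per archetype; the shape is
# clipped to the ipsilateral hemisphere minus ventricles
.lesionShape <- function(spec, geo, k) {
  d <- spec@dim
  X <- geo$X; Y <- geo$Y; Z <- geo$Z
  sx <- d[1] / 96; sy <- d[2] / 96; sz <- d[3] / 16
  ell <- function(c0, r0) {
    ((X - (geo$cx + c0[1] * sx)) / (r0[1] * k * sx))^2 +
    ((Y - (geo$cy + c0[2] * sy)) / (r0[2] * k * sy))^2 +
    ((Z - (geo$cz + c0[3] * sz)) / (r0[3] * k * sz))^2 <= 1
  }
  shape <- switch(spec@archetype,
    none = array(FALSE, d),
    striatal = ell(c(21, 0, 0), c(9, 11, 3)),
    corticostriatal = {
      zfall <- 1 - ((Z - geo$cz) / (3.8 * k * sz))^2
      zfall[zfall < 0] <- 0
      ell(c(21, -2, 0), c(9, 11, 3)) |
        (geo$rho2 >= (0.74)^2 & geo$rho2 <= 1 & X > geo$cx + 12 * sx &
           abs(Y - geo$cy) <= 16 * k * sy * sqrt(zfall))
    },
    fragmented = ell(c(18, -13, -1.2), c(7.5, 8.5, 2.9)) |
      ell(c(25, 13, 1.2), c(6.5, 7, 2.6)),
    `large-edema` = ell(c(14, 0, 0), c(14, 15, 4.2))
  )
  keep <- geo$ibh & !(geo$iv | geo$cv)
  if (spec@archetype %in% c("striatal", "corticostriatal", "fragmented"))
    keep <- keep & !geo$pvz
  shape & keep
}

.drawLesion <- function(spec, geo) {
  if (spec@archetype == "none") return(array(FALSE, spec@dim))
  targetVox <- spec@lesionVolume / prod(spec@spacing)
  lo <- 0.2; hi <- 2.6
  best <- NULL; bestErr <- Inf
  for (it in 1:40) {
    k <- (lo + hi) / 2
    shape <- .lesionShape(spec, geo, k)
    n <- sum(shape)
    err <- abs(n - targetVox) / targetVox
    if (err < bestErr) { best <- shape; bestErr <- err }
    if (n < targetVox) lo <- k else hi <- k
    if (hi - lo < 1e-4) break
  }
  if (bestErr > 0.05)
    stop(sprintf(
      "infeasible lesion volume: %.1f mm^3 requested, best %.1f mm^3",
      spec@lesionVolume, sum(best) * prod(spec@spacing)))
  best
}

# smooth random warp of the truth labels: coarse iid Gaussian displacement
# grids upsampled trilinearly, scaled to the requested max amplitude
.perturbAtlas <- function(atlas, amplitude) {
  d <- dim(atlas@wb)
  amplitude <- rep_len(amplitude, 3L)   # per-axis amplitude in voxels
  coarse <- c(5L, 5L, 3L)
  up1 <- function() {
    g <- array(rnorm(prod(coarse)), coarse)
    pts <- rbind(
      1 + (as.vector(slice.index(array(0, d), 1)) - 1) /
        (d[1] - 1) * (coarse[1] - 1),
      1 + (as.vector(slice.index(array(0, d), 2)) - 1) /
        (d[2] - 1) * (coarse[2] - 1),
      1 + (as.vector(slice.index(array(0, d), 3)) - 1) /
        (d[3] - 1) * (coarse[3] - 1))
    array(.sampleTrilinear(g, pts), d)
  }
  ux <- up1(); uy <- up1(); uz <- up1()
  mx <- max(abs(c(ux, uy, uz)))
  ux <- ux * amplitude[1] / mx
  uy <- uy * amplitude[2] / mx
  uz <- uz * amplitude[3] / mx
  X <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  Y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  pts <- rbind(as.vector(X + ux), as.vector(Y + uy), as.vector(Z + uz))
  warp1 <- function(m) array(as.logical(.sampleNearest(m, pts,
                                                       fill = FALSE)), d)
  LabelAtlas(warp1(atlas@wb), warp1(atlas@ibh), warp1(atlas@cbh),
             warp1(atlas@iv), warp1(atlas@cv), warp1(atlas@pvz),
             enforce = TRUE)
}
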