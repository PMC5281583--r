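# Multi-resolution rigid/affine registration by normalized correlation.
# Transforms map fixed-image world coordinates (mm, origin at voxel (1,1,1),
# i.e. w = (index - 1) * spacing) to moving-image world coordinates.

#' Create an affine/rigid spatial transform
#' @param matrix 3x3 linear part
#' @param translation numeric(3) in mm
#' @param center rotation center in mm (fixed-image world coordinates)
#' @param kind `"rigid"` or `"affine"`
#' @return a [SpatialTransform-class]
#' @export
affineTransform <- function(matrix = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0), kind = "affine") {
  new("SpatialTransform", kind = kind, matrix = matrix,
      translation = as.numeric(translation), center = as.numeric(center),
      field = array(0, c(0, 0, 0, 0)), fieldSpacing = c(1, 1, 1))
}

#' Create a dense displacement-field transform
#' @param field (nx, ny, nz, 3) array of mm displacements on the target grid
#' @param spacing numeric(3) spacing of the field grid
#' @return a [SpatialTransform-class]
#' @export
displacementFieldTransform <- function(field, spacing = c(1, 1, 1)) {
  new("SpatialTransform", kind = "field", matrix = diag(3),
      translation = c(0, 0, 0), center = c(0, 0, 0), field = field,
      fieldSpacing = as.numeric(spacing))
}

setMethod("show", "SpatialTransform", function(object) {
  if (object@kind == "field") {
    cat("SpatialTransform: dense displacement field on a",
        paste(dim(object@field)[1:3], collapse = " x "), "grid\n")
  } else {
    cat("SpatialTransform:", object@kind, "\n")
    cat("  matrix:\n")
    print(round(object@matrix, 5))
    cat("  translation (mm):", round(object@translation, 4), "\n")
  }
})

# map fixed world coordinates (3 x n matrix) to moving world coordinates
.mapPoints <- function(transform, pts) {
  if (transform@kind == "field")
    stop("point mapping of a dense field requires the target grid")
  transform@matrix %*% (pts - transform@center) +
    transform@center + transform@translation
}

# world coordinates (3 x n) of every voxel of a grid
.gridWorld <- function(dims, spacing) {
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                               z = seq_len(dims[3])))
  t((idx - 1) * rep(spacing, each = nrow(idx)))
}

# trilinear sampling of array `a` at continuous voxel coordinates (3 x n,
# 1-based); outside points return NA
.sampleTrilinear <- function(a, pts) {
  d <- dim(a)
  x <- pts[1, ]; y <- pts[2, ]; z <- pts[3, ]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), max(d[3] - 1L, 1L))
  if (d[3] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- if (d[3] == 1L) 0 else z - z0
  z1 <- pmin(z0 + 1, d[3])
  at <- function(i, j, k) a[cbind(i, j, k)]
  v000 <- at(x0, y0, z0);     v100 <- at(x0 + 1, y0, z0)
  v010 <- at(x0, y0 + 1, z0); v110 <- at(x0 + 1, y0 + 1, z0)
  v001 <- at(x0, y0, z1);     v101 <- at(x0 + 1, y0, z1)
  v011 <- at(x0, y0 + 1, z1); v111 <- at(x0 + 1, y0 + 1, z1)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  out[ok] <- v0 * (1 - fz) + v1 * fz
  out
}

# nearest-neighbour sampling; outside points return `fill`
.sampleNearest <- function(a, pts, fill = 0) {
  d <- dim(a)
  i <- round(pts[1, ]); j <- round(pts[2, ]); k <- round(pts[3, ])
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(fill, ncol(pts))
  out[ok] <- a[cbind(i[ok], j[ok], k[ok])]
  out
}

# continuous moving-volume voxel coordinates of every target-grid voxel
.targetToMovingVoxels <- function(transform, targetDim, targetSpacing,
                                  movingSpacing) {
  w <- .gridWorld(targetDim, targetSpacing)
  if (transform@kind == "field") {
    fd <- dim(transform@field)[1:3]
    if (!identical(as.integer(fd), as.integer(targetDim)))
      stop("displacement field grid must match the target grid")
    u <- matrix(aperm(transform@field, c(4, 1, 2, 3)), nrow = 3)
    wm <- w + u
  } else {
    wm <- .mapPoints(transform, w)
  }
  wm / movingSpacing + 1
}

#' Resample a moving volume onto a target grid through a transform
#' @param moving a [ScalarVolume-class]
#' @param transform a [SpatialTransform-class] (fixed-to-moving mapping)
#' @param targetDim integer(3) target grid size
#' @param targetSpacing numeric(3) target spacing in mm
#' @param fill value for voxels mapping outside the moving volume
#' @return a [ScalarVolume-class] on the target grid
#' @export
resampleVolume <- function(moving, transform, targetDim = dim(moving),
                           targetSpacing = voxelSpacing(moving), fill = 0) {
  vox <- .targetToMovingVoxels(transform, targetDim, targetSpacing,
                               voxelSpacing(moving))
  v <- .sampleTrilinear(voxelData(moving), vox)
  v[is.na(v)] <- fill
  ScalarVolume(array(v, targetDim), spacing = targetSpacing)
}

# --- NCC and the optimizer -------------------------------------------------

.ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 16) return(NA_real_)
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

# smooth (1-2-1 separable) and decimate by 2, anisotropy-aware: an axis is
# only halved while its spacing is within a factor 2 of the finest axis
# (thick-slice stacks keep their z resolution at coarse levels)
.pyrDown <- function(a, sp) {
  sm <- function(x, axis) (.shift1(x, axis, 1) + 2 * x +
                             .shift1(x, axis, -1)) / 4
  d <- dim(a)
  halve <- sp <= 2 * min(sp) & d >= 8L
  if (!any(halve)) halve <- d >= 8L
  idx <- lapply(1:3, function(ax) {
    if (halve[ax]) seq(1L, d[ax], by = 2L) else seq_len(d[ax])
  })
  for (ax in which(halve)) a <- sm(a, ax)
  list(arr = a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       sp = sp * ifelse(halve, 2, 1))
}

.rotationMatrix <- function(rx, ry, rz) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

.paramsToTransform <- function(par, kind, center) {
  if (kind == "rigid") {
    affineTransform(.rotationMatrix(par[1], par[2], par[3]), par[4:6],
                    center = center, kind = "rigid")
  } else {
    affineTransform(diag(3) + matrix(par[1:9], 3, 3), par[10:12],
                    center = center, kind = "affine")
  }
}

.transformToParams <- function(tf, kind) {
  if (kind == "rigid") {
    R <- tf@matrix
    ry <- asin(max(-1, min(1, -R[3, 1])))
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
    c(rx, ry, rz, tf@translation)
  } else {
    c(as.vector(tf@matrix - diag(3)), tf@translation)
  }
}

#' Rigid + affine registration by normalized correlation
#'
#' Coarse-to-fine intensity-based registration: a Gaussian image pyramid
#' with four resolutions for the rigid stage and two for the affine stage;
#' at each level the Normalized Correlation Coefficient between the fixed
#' image and the resampled moving image is maximised with a gradient-free
#' (Nelder-Mead) search. The recovered transform maps fixed-image world
#' coordinates to moving-image world coordinates, with rotation about the
#' fixed-volume center.
#'
#' @param moving,fixed [ScalarVolume-class] objects
#' @param stages character vector, subset of `c("rigid", "affine")`, run in
#'   that order
#' @param rigidLevels,affineLevels pyramid depths
#' @param maxit Nelder-Mead iteration budget per level
#' @return a [SpatialTransform-class] with the final NCC attached as
#'   attribute `"ncc"`
#' @export
registerNCC <- function(moving, fixed, stages = c("rigid", "affine"),
                        rigidLevels = 4L, affineLevels = 2L, maxit = 300L) {
  stages <- match.arg(stages, c("rigid", "affine"), several.ok = TRUE)
  fArr0 <- voxelData(fixed)
  if (max(fArr0) == min(fArr0) ||
      max(voxelData(moving)) == min(voxelData(moving)))
    stop("non-finite NCC: constant image cannot be registered")
  center <- (dim(fixed) - 1) / 2 * voxelSpacing(fixed)
  tf <- affineTransform(center = center, kind = "rigid")

  for (stage in stages) {
    nlev <- if (stage == "rigid") rigidLevels else affineLevels
    # pyramids, coarsest first
    fPyr <- list(list(arr = fArr0, sp = voxelSpacing(fixed)))
    mPyr <- list(list(arr = voxelData(moving), sp = voxelSpacing(moving)))
    for (l in seq_len(nlev - 1L)) {
      prevF <- fPyr[[1]]; prevM <- mPyr[[1]]
      if (min(dim(prevF$arr)[1:2]) < 16) break
      fPyr <- c(list(.pyrDown(prevF$arr, prevF$sp)), fPyr)
      mPyr <- c(list(.pyrDown(prevM$arr, prevM$sp)), mPyr)
    }
    par <- .transformToParams(tf, stage)
    scale <- if (stage == "rigid")
      c(rep(0.05, 3), rep(2 * max(voxelSpacing(fixed)), 3))
    else c(rep(0.05, 9), rep(2 * max(voxelSpacing(fixed)), 3))
    for (l in seq_along(fPyr)) {
      fArr <- fPyr[[l]]$arr; fSp <- fPyr[[l]]$sp
      mArr <- mPyr[[l]]$arr; mSp <- mPyr[[l]]$sp
      objective <- function(p) {
        tfl <- .paramsToTransform(p, stage, center)
        vox <- .targetToMovingVoxels(tfl, dim(fArr), fSp, mSp)
        v <- .sampleTrilinear(mArr, vox)
        nOK <- sum(!is.na(v))
        if (nOK < 0.25 * length(v)) return(1)
        cc <- .ncc(fArr, array(v, dim(fArr)))
        if (!is.finite(cc)) return(1)
        -cc
      }
      if (stage == "rigid" && l == 1L) {
        # coarse-level exhaustive translation search: a cheap global
        # initializer that keeps Nelder-Mead out of rotation-compensated
        # local optima
        tIdx <- if (stage == "rigid") 4:6 else 10:12
        steps <- as.matrix(expand.grid(x = -4:4, y = -4:4, z = -2:2))
        best <- objective(par)
        bestPar <- par
        for (r in seq_len(nrow(steps))) {
          cand <- par
          cand[tIdx] <- cand[tIdx] + steps[r, ] * fSp
          val <- objective(cand)
          if (val < best) { best <- val; bestPar <- cand }
        }
        par <- bestPar
      }
      # most of the search happens at the coarse levels; fine levels only
      # polish, so their iteration budget shrinks
      lmaxit <- max(60L, as.integer(maxit / 2^(l - 1L)))
      opt <- optim(par, objective, method = "Nelder-Mead",
                   control = list(maxit = lmaxit, parscale = scale,
                                  reltol = 1e-9))
      par <- opt$par
    }
    tf <- .paramsToTransform(par, stage, center)
  }
  finalVox <- .targetToMovingVoxels(tf, dim(fixed), voxelSpacing(fixed),
                                    voxelSpacing(moving))
  v <- .sampleTrilinear(voxelData(moving), finalVox)
  attr(tf, "ncc") <- .ncc(fArr0, array(v, dim(fixed)))
  tf
}

#' Propagate template labels to a subject grid
#'
#' Warps all six atlas masks with nearest-neighbour interpolation through a
#' transform (the fixed/subject to moving/template mapping from
#' [registerNCC()], or an external dense displacement field) and
#' re-enforces the atlas invariants by masking.
#'
#' @param atlas a [LabelAtlas-class] on the template grid
#' @param transform a [SpatialTransform-class]
#' @param targetDim integer(3) subject grid size
#' @param targetSpacing numeric(3) subject spacing (mm)
#' @param atlasSpacing numeric(3) template spacing (mm)
#' @return a [LabelAtlas-class] on the subject grid
#' @export
propagateLabels <- function(atlas, transform, targetDim,
                            targetSpacing = c(1, 1, 1),
                            atlasSpacing = targetSpacing) {
  vox <- .targetToMovingVoxels(transform, targetDim, targetSpacing,
                               atlasSpacing)
  warp1 <- function(m) {
    out <- .sampleNearest(m, vox, fill = FALSE)
    array(as.logical(out), targetDim)
  }
  out <- LabelAtlas(wb = warp1(atlas@wb), ibh = warp1(atlas@ibh),
                    cbh = warp1(atlas@cbh), iv = warp1(atlas@iv),
                    cv = warp1(atlas@cv), pvz = warp1(atlas@pvz),
                    enforce = TRUE)
  if (!any(out@wb))
    stop("propagation-failed: warped whole-brain mask is empty")
  out
}

#' Invert an affine/rigid transform
#' @param transform an affine or rigid [SpatialTransform-class]
#' @return the inverse [SpatialTransform-class]
#' @export
invertTransform <- function(transform) {
  if (transform@kind == "field")
    stop("dense displacement fields are not analytically invertible")
  Minv <- solve(transform@matrix)
  affineTransform(Minv, -Minv %*% transform@translation,
                  center = transform@center, kind = transform@kind)
}
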