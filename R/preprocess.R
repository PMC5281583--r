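#' Crop a volume to the bounding box of a brain mask
#'
#' Computes the smallest axis-aligned box containing `brainMask` and crops
#' the image to it. The returned report carries the box so that the same
#' crop can be applied to companion volumes and label masks with
#' [applyCrop()], and a cropped volume can be zero-padded back with
#' [undoCrop()].
#'
#' @param image a [ScalarVolume-class] or 3D array
#' @param brainMask nonempty logical mask congruent with `image`
#' @return list with `volume` (cropped [ScalarVolume-class]) and `report`
#'   (list with `box`, a 6-vector `(x0, x1, y0, y1, z0, z1)` of 0-based
#'   half-open bounds, and `originalDim`)
#' @export
cropToLabelBbox <- function(image, brainMask) {
  a <- .asArray(image)
  m <- .asMask(brainMask)
  .stopIfIncongruent(a, m)
  if (!any(m)) stop("empty mask: nothing to crop to")
  box <- .maskBbox(m)
  sp <- if (is(image, "ScalarVolume")) image@spacing else c(1, 1, 1)
  list(volume = ScalarVolume(.cropBox(a, box), spacing = sp),
       report = list(box = box, originalDim = dim(a)))
}

# 0-based half-open bounding box (x0, x1, y0, y1, z0, z1) of TRUE voxels
.maskBbox <- function(m) {
  w <- which(m, arr.ind = TRUE)
  as.integer(c(min(w[, 1]) - 1L, max(w[, 1]), min(w[, 2]) - 1L, max(w[, 2]),
               min(w[, 3]) - 1L, max(w[, 3])))
}

.cropBox <- function(a, box) {
  a[(box[1] + 1L):box[2], (box[3] + 1L):box[4], (box[5] + 1L):box[6],
    drop = FALSE]
}

#' Apply a previously computed crop to a companion volume or mask
#' @param x a [ScalarVolume-class], 3D array or logical mask
#' @param report the report returned by [cropToLabelBbox()]
#' @return object of the same kind, cropped
#' @export
applyCrop <- function(x, report) {
  if (is(x, "ScalarVolume"))
    return(ScalarVolume(.cropBox(x@values, report$box),
                        spacing = x@spacing))
  if (is(x, "LabelAtlas")) {
    return(new("LabelAtlas",
               wb = .cropBox(x@wb, report$box),
               ibh = .cropBox(x@ibh, report$box),
               cbh = .cropBox(x@cbh, report$box),
               iv = .cropBox(x@iv, report$box),
               cv = .cropBox(x@cv, report$box),
               pvz = .cropBox(x@pvz, report$box)))
  }
  .cropBox(.asArray(x), report$box)
}

#' Zero-pad a cropped array back to the original grid
#' @param x cropped [ScalarVolume-class] or array
#' @param report the report returned by [cropToLabelBbox()]
#' @param fill value for voxels outside the crop box
#' @return array on the original grid
#' @export
undoCrop <- function(x, report, fill = 0) {
  a <- .asArray(x)
  out <- array(fill, report$originalDim)
  box <- report$box
  out[(box[1] + 1L):box[2], (box[3] + 1L):box[4], (box[5] + 1L):box[6]] <- a
  out
}

#' Rescale intensities to the unit interval
#'
#' Maps intensities linearly so that the minimum becomes 0 and the maximum
#' 1; a constant image maps to all zeros. Idempotent after the first
#' application.
#'
#' @param image a [ScalarVolume-class] or 3D array
#' @return a [ScalarVolume-class]
#' @export
rescaleUnit <- function(image) {
  a <- .asArray(image)
  rng <- range(a)
  sp <- if (is(image, "ScalarVolume")) image@spacing else c(1, 1, 1)
  if (rng[2] - rng[1] <= 0)
    return(ScalarVolume(array(0, dim(a)), spacing = sp))
  ScalarVolume((a - rng[1]) / (rng[2] - rng[1]), spacing = sp)
}

#' Select the maximum-entropy reference slice
#'
#' Returns the z-index of the slice whose 64-bin intensity histogram has
#' maximal Shannon entropy (ties broken by the lowest index). Entropy is
#' computed after unit rescaling of the whole volume, with bins spanning
#' the unit interval.
#'
#' @param image a [ScalarVolume-class] or 3D array with at least one slice
#' @return integer slice index (1-based), with the per-slice entropies
#'   (nats) attached as attribute `"entropy"`
#' @export
selectReferenceSlice <- function(image) {
  a <- voxelData(rescaleUnit(image))
  nz <- dim(a)[3]
  ent <- vapply(seq_len(nz), function(z) {
    p <- tabulate(.binIndex(a[, , z], c(0, 1), 64L), nbins = 64L)
    p <- p / sum(p)
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  idx <- which.max(ent)          # which.max returns the first maximum
  attr(idx, "entropy") <- ent
  idx
}

#' Per-slice intensity normalization by CDF matching
#'
#' Histogram-matches every slice of an echo image to a reference slice by
#' mapping each slice's empirical cumulative intensity distribution onto
#' the inverse CDF of the reference (monotone quantile mapping on 256
#' quantile levels). When a mask is supplied (the pipeline passes the
#' propagated brain mask), the map is estimated from mask voxels only -
#' the slice content inside the volume of interest is comparable across
#' slices, while air/head fractions are not - and applied to the whole
#' slice, extending linearly beyond the estimation range. Applied to echo
#' images only, never to the quantitative T2 map.
#'
#' @param image a [ScalarVolume-class] or 3D array
#' @param refSlice 1-based reference slice index, e.g. from
#'   [selectReferenceSlice()]
#' @param nLevels number of quantile levels of the mapping
#' @param mask optional logical mask on which the per-slice CDFs are
#'   estimated (default: the full slice)
#' @param clampRange optional numeric(2): clamp the mapped intensities to
#'   this range (the pipeline passes the unit interval, where preprocessed
#'   intensities live)
#' @return a [ScalarVolume-class]
#' @export
perSliceCdfNormalize <- function(image, refSlice, nLevels = 256L,
                                 mask = NULL, clampRange = NULL) {
  a <- .asArray(image)
  nz <- dim(a)[3]
  if (refSlice < 1L || refSlice > nz) stop("invalid reference slice")
  if (!is.null(mask)) {
    mask <- .asMask(mask)
    .stopIfIncongruent(a, mask)
  }
  probs <- seq(0, 1, length.out = nLevels)
  sliceVals <- function(z) {
    if (is.null(mask)) return(as.vector(a[, , z]))
    v <- a[, , z][mask[, , z]]
    if (length(v) < 8L) as.vector(a[, , z]) else v
  }
  refQ <- quantile(sliceVals(refSlice), probs = probs, names = FALSE,
                   type = 7)
  out <- a
  for (z in seq_len(nz)) {
    if (z == refSlice) next
    sliceQ <- quantile(sliceVals(z), probs = probs, names = FALSE, type = 7)
    # monotone map: slice quantiles -> reference quantiles
    out[, , z] <- .monotoneMap(a[, , z], sliceQ, refQ)
  }
  if (!is.null(clampRange))
    out <- array(pmin(pmax(out, clampRange[1]), clampRange[2]), dim(a))
  sp <- if (is(image, "ScalarVolume")) image@spacing else c(1, 1, 1)
  ScalarVolume(out, spacing = sp)
}

# piecewise-linear monotone interpolation from src quantiles to dst
# quantiles; duplicated knots (constant stretches) are collapsed and the
# end segments are extended linearly outside the knot range
.monotoneMap <- function(v, srcQ, dstQ) {
  keep <- !duplicated(srcQ)
  srcQ <- srcQ[keep]
  dstQ <- dstQ[keep]
  n <- length(srcQ)
  if (n == 1L) return(array(dstQ, dim(v)))
  m <- approx(srcQ, dstQ, xout = v, rule = 2)$y
  # tails: extend with the robust inter-decile slope of the map (a gain
  # estimate insensitive to the noisy extreme quantiles)
  i1 <- max(1L, floor(0.1 * n)); i2 <- min(n, ceiling(0.9 * n))
  s <- if (srcQ[i2] > srcQ[i1])
    (dstQ[i2] - dstQ[i1]) / (srcQ[i2] - srcQ[i1]) else 1
  lo <- v < srcQ[1]
  if (any(lo)) m[lo] <- dstQ[1] + s * (v[lo] - srcQ[1])
  hi <- v > srcQ[n]
  if (any(hi)) m[hi] <- dstQ[n] + s * (v[hi] - srcQ[n])
  dim(m) <- dim(v)
  m
}

#' Voxelwise sum of an echo train
#'
#' The echo-sum image is used as the registration target: it accumulates
#' signal over the whole train and has higher SNR than any single echo.
#'
#' @param echoes list of congruent [ScalarVolume-class] objects or arrays
#' @return a [ScalarVolume-class]
#' @export
sumEchoes <- function(echoes) {
  if (length(echoes) < 1L) stop("need at least one echo")
  arrs <- lapply(echoes, .asArray)
  do.call(.stopIfIncongruent, arrs)
  s <- Reduce(`+`, arrs)
  sp <- if (is(echoes[[1]], "ScalarVolume")) echoes[[1]]@spacing
        else c(1, 1, 1)
  ScalarVolume(s, spacing = sp)
}
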