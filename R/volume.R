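#' Create a ScalarVolume
#'
#' @param values 3D numeric array (a 2D matrix is promoted to a single-slice
#'   volume).
#' @param spacing numeric(3) voxel size (dx, dy, dz) in mm.
#' @return a [ScalarVolume-class]
#' @examples
#' v <- ScalarVolume(array(rnorm(8 * 8 * 2), c(8, 8, 2)),
#'                   spacing = c(0.12, 0.12, 0.5))
#' voxelSpacing(v)
#' @export
ScalarVolume <- function(values, spacing = c(1, 1, 1)) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  storage.mode(values) <- "double"
  new("ScalarVolume", values = values, spacing = as.numeric(spacing))
}

#' @rdname voxelData
#' @export
setMethod("voxelData", "ScalarVolume", function(x) x@values)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ScalarVolume", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "SegmentationBundle", function(x) x@spacing)

#' @describeIn ScalarVolume dimensions of the voxel grid
#' @param x a ScalarVolume
#' @export
setMethod("dim", "ScalarVolume", function(x) dim(x@values))

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ScalarVolume %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(object@values),
              max(object@values)))
})

setMethod("show", "SegmentationBundle", function(object) {
  cat("SegmentationBundle on a", paste(dim(object@rWB), collapse = " x "),
      "grid\n")
  vv <- prod(object@spacing)
  for (nm in c("rWB", "rIBH", "rCBH", "rCV", "rV", "rSInit", "rStroke"))
    cat(sprintf("  %-8s %7d voxels  %9.2f mm^3\n", sub("^r", "R_", nm),
                sum(slot(object, nm)), sum(slot(object, nm)) * vv))
})

setMethod("show", "GaussianModel", function(object) {
  cat(sprintf("GaussianModel mean %.4g sd %.4g%s\n", object@mean, object@sd,
              if (object@fixed) " (fixed)" else ""))
})

setMethod("show", "HistogramModel", function(object) {
  cat(sprintf("HistogramModel %d bins on [%.3g, %.3g]%s\n",
              length(object@mass), min(object@breaks), max(object@breaks),
              if (object@fixed) " (fixed)" else ""))
})

setMethod("show", "StageParams", function(object) {
  cat(sprintf(
    "StageParams: I=%s obj=%s%s bg=%s%s alpha=%g mu=%g nIter=%d g=%s\n",
    object@inputImage, object@objectModel,
    if (object@objectFixed) "(fixed)" else "",
    object@backgroundModel, if (object@backgroundFixed) "(fixed)" else "",
    object@alpha, object@mu, object@nIter,
    if (object@useGradientMap) "+" else "-"))
})

setMethod("show", "LabelAtlas", function(object) {
  cat("LabelAtlas on a", paste(dim(object@wb), collapse = " x "), "grid\n")
  for (nm in c("wb", "ibh", "cbh", "iv", "cv", "pvz"))
    cat(sprintf("  M_%-4s %7d voxels\n", toupper(nm), sum(slot(object, nm))))
})

# --- internal array helpers ------------------------------------------------

# resolve a ScalarVolume or bare array argument to a numeric array
.asArray <- function(x) {
  if (is(x, "ScalarVolume")) return(x@values)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!(is.array(x) && length(dim(x)) == 3L))
    stop("expected a ScalarVolume or a 3D array")
  x
}

.asMask <- function(x) {
  m <- .asArray(x)
  if (!is.logical(m)) {
    m2 <- array(as.logical(m != 0), dim(m))
    m <- m2
  }
  m
}

.stopIfIncongruent <- function(...) {
  dims <- lapply(list(...), function(x) dim(.asArray(x)))
  for (d in dims[-1])
    if (!identical(d, dims[[1]])) stop("volume dimensions differ")
  invisible(TRUE)
}

# shift a 3D array by one voxel along an axis, replicating the boundary
.shift1 <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]] - by
  i[i < 1L] <- 1L
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# zero-padded shift (values moved by `by`, vacated voxels set to `fill`)
.shiftPad <- function(a, axis, by, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- lapply(d, seq_len)
  dst <- lapply(d, seq_len)
  if (by >= 0) {
    dst[[axis]] <- (1L + by):n
    src[[axis]] <- 1L:(n - by)
  } else {
    dst[[axis]] <- 1L:(n + by)
    src[[axis]] <- (1L - by):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
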