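.SD_FLOOR <- 1e-3
.HIST_FLOOR <- 1e-8

#' Fit a Gaussian region model
#'
#' Maximum-likelihood Gaussian fit (divide-by-n variance) to the image
#' intensities inside `region`. The standard deviation is clamped from below
#' at `sdFloor` so that degenerate (constant) regions still yield finite
#' log-densities.
#'
#' @param image a [ScalarVolume-class] or 3D array
#' @param region logical mask congruent with `image`; must be nonempty
#' @param fixed should the model be frozen during level-set evolution?
#' @param sdFloor lower bound for the fitted sd
#' @return a [GaussianModel-class]
#' @examples
#' img <- ScalarVolume(array(c(0.2, 0.4, 0.6, 0), c(2, 2, 1)))
#' m <- fitGaussianModel(img, array(c(TRUE, TRUE, TRUE, FALSE), c(2, 2, 1)))
#' m
#' @export
fitGaussianModel <- function(image, region, fixed = FALSE,
                             sdFloor = .SD_FLOOR) {
  a <- .asArray(image)
  region <- .asMask(region)
  .stopIfIncongruent(a, region)
  v <- a[region]
  if (length(v) == 0L) stop("empty-region-model: region has no voxels")
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2))           # ML (divide-by-n) estimator
  new("GaussianModel", mean = mu, sd = max(s, sdFloor), fixed = fixed)
}

#' Fit a histogram region model
#'
#' Equal-width histogram over `limits` (default the unit interval used for
#' preprocessed intensities). Per-bin mass is count/total, floored at 1e-8
#' and renormalised; values outside `limits` are counted in the edge bins.
#'
#' @param image a [ScalarVolume-class] or 3D array
#' @param region logical mask congruent with `image`; must be nonempty
#' @param nBins number of bins (default 64)
#' @param limits numeric(2) intensity range covered by the bins
#' @param fixed should the model be frozen during level-set evolution?
#' @return a [HistogramModel-class]
#' @export
fitHistogramModel <- function(image, region, nBins = 64L, limits = c(0, 1),
                              fixed = FALSE) {
  a <- .asArray(image)
  region <- .asMask(region)
  .stopIfIncongruent(a, region)
  nBins <- as.integer(nBins)
  if (nBins < 1L) stop("nBins must be >= 1")
  v <- a[region]
  if (length(v) == 0L) stop("empty-region-model: region has no voxels")
  breaks <- seq(limits[1], limits[2], length.out = nBins + 1L)
  idx <- .binIndex(v, limits, nBins)
  cnt <- tabulate(idx, nbins = nBins)
  mass <- cnt / sum(cnt)
  mass <- pmax(mass, .HIST_FLOOR)
  mass <- mass / sum(mass)
  new("HistogramModel", breaks = breaks, mass = mass, fixed = fixed)
}

# bin index with edge clipping; values exactly at internal edges fall into
# the right bin (left-closed bins), the last bin is closed on both sides
.binIndex <- function(v, limits, nBins) {
  idx <- floor((v - limits[1]) / (limits[2] - limits[1]) * nBins) + 1L
  idx[idx < 1L] <- 1L
  idx[idx > nBins] <- nBins
  as.integer(idx)
}

#' @rdname logProb
#' @export
setMethod("logProb", "GaussianModel", function(model, values) {
  dnorm(values, mean = model@mean, sd = model@sd, log = TRUE)
})

#' @rdname logProb
#' @export
setMethod("logProb", "HistogramModel", function(model, values) {
  nb <- length(model@mass)
  lims <- c(model@breaks[1], model@breaks[nb + 1L])
  lm <- log(model@mass)[.binIndex(values, lims, nb)]
  if (is.array(values)) dim(lm) <- dim(values)
  lm
})

#' @rdname modelFixed
#' @export
setMethod("modelFixed", "RegionModel", function(x) x@fixed)

#' Voxelwise log-probability map
#'
#' Evaluates a region model at every voxel of an image, returning the
#' log-probability field used by the level-set data terms
#' \eqn{-\log P(I(x);\Omega_O) - \log P(I(x);\Omega_B)}.
#'
#' @param model a [RegionModel-class]
#' @param image a [ScalarVolume-class] or 3D array
#' @return a [ScalarVolume-class] of log-probabilities (finite everywhere)
#' @export
logProbMap <- function(model, image) {
  a <- .asArray(image)
  lp <- logProb(model, a)
  sp <- if (is(image, "ScalarVolume")) image@spacing else c(1, 1, 1)
  ScalarVolume(array(lp, dim(a)), spacing = sp)
}

# dispatch-free model fit used by the evolution loop
.fitModel <- function(kind, image, region, fixed, limits) {
  if (kind == "gaussian") fitGaussianModel(image, region, fixed = fixed)
  else fitHistogramModel(image, region, limits = limits, fixed = fixed)
}
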