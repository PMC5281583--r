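#' ScalarVolume: a 3D intensity grid with voxel spacing
#'
#' Container for a single 3D image volume: a quantitative T2 map (values in
#' ms), an individual echo image (arbitrary units) or any derived scalar
#' field. Axis order is (x, y, z) with z the slice index.
#'
#' @slot values 3D numeric array of voxel intensities; all values finite.
#' @slot spacing numeric(3), voxel size (dx, dy, dz) in mm; strictly positive.
#'
#' @seealso [ScalarVolume()], [voxelData()], [voxelSpacing()]
#' @export
setClass("ScalarVolume",
  representation(values = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@values)
    if (length(d) != 3L)
      msg <- c(msg, "'values' must be a 3D array")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "all voxel values must be finite")
    if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 strictly positive numbers")
    if (length(msg)) msg else TRUE
  }
)

#' RegionModel: per-intensity probability model of a masked region
#'
#' Virtual parent of [GaussianModel-class] and [HistogramModel-class]. A
#' region model summarises the intensity distribution of a region and is
#' evaluated voxelwise as a log-probability during level-set evolution. A
#' model flagged `fixed` is never re-estimated while the contour evolves.
#'
#' @slot fixed logical; if `TRUE` the model is frozen during evolution.
#' @export
setClass("RegionModel", representation("VIRTUAL", fixed = "logical"))

#' Gaussian region model
#'
#' Maximum-likelihood Gaussian intensity model (divide-by-n variance); the
#' standard deviation is clamped from below at `sdFloor` (default 1e-3 of
#' the unit intensity range) to keep log-densities finite on degenerate
#' regions.
#'
#' @slot mean numeric(1) ML mean.
#' @slot sd numeric(1) ML standard deviation after clamping.
#' @export
setClass("GaussianModel", contains = "RegionModel",
  representation(mean = "numeric", sd = "numeric"),
  validity = function(object) {
    if (length(object@mean) != 1L || !is.finite(object@mean))
      return("'mean' must be a single finite number")
    if (length(object@sd) != 1L || !is.finite(object@sd) || object@sd <= 0)
      return("'sd' must be a single positive number")
    TRUE
  }
)

#' Histogram region model
#'
#' Equal-width binned intensity model over a stated range. Per-bin
#' probability mass is count/total, floored at `1e-8` and renormalised;
#' intensities outside the range are assigned to the edge bins.
#'
#' @slot breaks numeric vector of bin edges (length nbins + 1, increasing).
#' @slot mass numeric vector of per-bin probability mass, sums to 1.
#' @export
setClass("HistogramModel", contains = "RegionModel",
  representation(breaks = "numeric", mass = "numeric"),
  validity = function(object) {
    nb <- length(object@mass)
    if (nb < 1L) return("at least one bin required")
    if (length(object@breaks) != nb + 1L)
      return("'breaks' must have length(mass) + 1 entries")
    if (any(diff(object@breaks) <= 0))
      return("'breaks' must be strictly increasing")
    if (any(object@mass < 0) || abs(sum(object@mass) - 1) > 1e-9)
      return("'mass' must be non-negative and sum to 1 (within 1e-9)")
    TRUE
  }
)

#' StageParams: parameters of one level-set segmentation stage
#'
#' One column of the stage parameter table: which input image the stage
#' reads, the object/background model families and whether each is held
#' fixed, the length weight `alpha`, the area weight `mu`, the iteration
#' budget `nIter`, and whether the gradient map g(x) weights the length
#' term.
#'
#' @slot inputImage `"echo4"` or `"t2map"`.
#' @slot objectModel,backgroundModel `"gaussian"` or `"histogram"`.
#' @slot objectFixed,backgroundFixed logical; frozen vs re-estimated models.
#' @slot alpha non-negative length (boundary) weight.
#' @slot mu area weight.
#' @slot nIter positive integer iteration budget.
#' @slot useGradientMap logical; weight the length term by g(x).
#' @seealso [stageParams()]
#' @export
setClass("StageParams",
  representation(inputImage = "character", objectModel = "character",
                 backgroundModel = "character", objectFixed = "logical",
                 backgroundFixed = "logical", alpha = "numeric",
                 mu = "numeric", nIter = "integer",
                 useGradientMap = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@inputImage %in% c("echo4", "t2map"))
      msg <- c(msg, "inputImage must be 'echo4' or 't2map'")
    for (m in c(object@objectModel, object@backgroundModel))
      if (!m %in% c("gaussian", "histogram"))
        msg <- c(msg, "model kinds must be 'gaussian' or 'histogram'")
    if (!is.finite(object@alpha) || object@alpha < 0)
      msg <- c(msg, "alpha must be >= 0")
    if (!is.finite(object@mu))
      msg <- c(msg, "mu must be finite")
    if (object@nIter < 1L)
      msg <- c(msg, "nIter must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' LabelAtlas: the six template/propagated anatomical masks
#'
#' Boolean masks on one grid: whole brain (WB), ipsilateral and
#' contralateral brain hemispheres (IBH, CBH), ipsilateral and contralateral
#' ventricles (IV, CV) and the periventricular zone (PVZ). Invariants:
#' hemispheres are disjoint subsets of the whole brain, each ventricle lies
#' in its hemisphere.
#'
#' @slot wb,ibh,cbh,iv,cv,pvz logical 3D arrays, all of identical dimension.
#' @seealso [LabelAtlas()], [atlasMask()]
#' @export
setClass("LabelAtlas",
  representation(wb = "array", ibh = "array", cbh = "array",
                 iv = "array", cv = "array", pvz = "array"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@wb)
    masks <- list(object@wb, object@ibh, object@cbh, object@iv, object@cv,
                  object@pvz)
    if (length(d) != 3L) msg <- c(msg, "masks must be 3D arrays")
    for (m in masks) {
      if (!is.logical(m)) msg <- c(msg, "masks must be logical")
      if (!identical(dim(m), d)) msg <- c(msg, "masks must share one grid")
    }
    if (!length(msg)) {
      if (any(object@ibh & object@cbh))
        msg <- c(msg, "hemispheres must be disjoint")
      if (any((object@ibh | object@cbh) & !object@wb))
        msg <- c(msg, "hemispheres must lie inside the whole brain")
      if (any(object@iv & !object@ibh))
        msg <- c(msg, "ipsilateral ventricle must lie in IBH")
      if (any(object@cv & !object@cbh))
        msg <- c(msg, "contralateral ventricle must lie in CBH")
    }
    if (length(msg)) msg else TRUE
  }
)

#' SpatialTransform: rigid/affine mapping or dense displacement field
#'
#' Maps fixed-image world coordinates (mm) to moving-image world
#' coordinates. Affine transforms act as `A %*% (p - center) + center + t`;
#' displacement-field transforms as `p + u(p)` with `u` sampled on the
#' target grid.
#'
#' @slot kind `"rigid"`, `"affine"` or `"field"`.
#' @slot matrix 3x3 matrix (ignored for fields).
#' @slot translation numeric(3) in mm.
#' @slot center numeric(3) rotation center in mm.
#' @slot field 4D array (nx, ny, nz, 3) of mm displacements, or empty.
#' @slot fieldSpacing numeric(3) spacing of the field grid.
#' @export
setClass("SpatialTransform",
  representation(kind = "character", matrix = "matrix",
                 translation = "numeric", center = "numeric",
                 field = "array", fieldSpacing = "numeric"),
  prototype(kind = "affine", matrix = diag(3), translation = c(0, 0, 0),
            center = c(0, 0, 0), field = array(0, c(0, 0, 0, 0)),
            fieldSpacing = c(1, 1, 1)),
  validity = function(object) {
    if (!object@kind %in% c("rigid", "affine", "field"))
      return("kind must be 'rigid', 'affine' or 'field'")
    if (object@kind != "field") {
      if (!all(dim(object@matrix) == c(3, 3)))
        return("matrix must be 3x3")
      if (abs(det(object@matrix)) < 1e-12)
        return("matrix must be invertible")
    } else {
      if (length(dim(object@field)) != 4L || dim(object@field)[4] != 3L)
        return("field must be a (nx, ny, nz, 3) array")
    }
    TRUE
  }
)

#' SegmentationBundle: all regions derived by the segmentation cascade
#'
#' Holds the whole-brain region and the hemisphere split, the ventricle
#' regions, the stroke initialization and the final lesion mask, all on the
#' cropped grid, plus a provenance log of stage parameters and convergence.
#'
#' @slot rWB,rIBH,rCBH,rCV,rV,rSInit,rStroke logical 3D masks.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot provenance list of per-stage parameter/convergence records.
#' @seealso [runPipeline()], [bundleMask()]
#' @export
setClass("SegmentationBundle",
  representation(rWB = "array", rIBH = "array", rCBH = "array",
                 rCV = "array", rV = "array", rSInit = "array",
                 rStroke = "array", spacing = "numeric",
                 provenance = "list"),
  validity = function(object) {
    d <- dim(object@rWB)
    masks <- list(object@rIBH, object@rCBH, object@rCV, object@rV,
                  object@rSInit, object@rStroke)
    for (m in masks)
      if (!identical(dim(m), d)) return("all masks must be congruent")
    if (any(object@rCV & !object@rCBH))
      return("R_CV must lie inside R_CBH")
    if (any(object@rV & !object@rWB))
      return("R_V must lie inside R_WB")
    TRUE
  }
)

#' PhantomSpec: parameters of the synthetic brain phantom
#'
#' Describes a synthetic tMCAo mouse brain: grid geometry (default
#' 96 x 96 x 16 voxels at 0.12 x 0.12 x 0.50 mm), tissue T2 statistics in
#' ms, the lesion archetype and its target volume, measurement noise, the
#' multi-echo acquisition (TE 9 ms, 20 echoes) and the random seed. Tissue
#' defaults place the lesion between healthy tissue and CSF so that lesion
#' and ventricle intensities partially overlap.
#'
#' @slot dim integer(3) grid size.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot t2Healthy,t2Ventricle,t2Lesion,t2Head,t2Background numeric(2)
#'   mean/sd (ms); `t2Head` is the extracerebral head tissue (muscle/skull)
#'   filling the field of view around the brain.
#' @slot archetype one of `"striatal"`, `"corticostriatal"`, `"fragmented"`,
#'   `"large-edema"`, `"none"`.
#' @slot lesionVolume target lesion volume in mm^3.
#' @slot noiseSd additive measurement noise on the T2 map (ms).
#' @slot echoTime echo spacing TE in ms.
#' @slot nEchoes number of echoes in the train.
#' @slot echoNoiseSd additive noise on synthesized echoes (a.u.).
#' @slot sliceGainSd sd of the per-slice multiplicative gain applied to the
#'   echo images (coil/slice-profile inhomogeneity; what the per-slice
#'   normalization corrects).
#' @slot templatePerturb max amplitude (voxels) of the smooth random warp
#'   applied to the template labels; 0 gives perfect labels.
#' @slot seed integer random seed; same seed, same phantom.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", spacing = "numeric",
                 t2Healthy = "numeric", t2Ventricle = "numeric",
                 t2Lesion = "numeric", t2Head = "numeric",
                 t2Background = "numeric",
                 archetype = "character", lesionVolume = "numeric",
                 noiseSd = "numeric", echoTime = "numeric",
                 nEchoes = "integer", echoNoiseSd = "numeric",
                 sliceGainSd = "numeric",
                 templatePerturb = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@dim) != 3L || any(object@dim < c(16L, 16L, 4L)))
      msg <- c(msg, "grid must be at least 16 x 16 x 4")
    if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
    for (t in list(object@t2Healthy, object@t2Ventricle, object@t2Lesion,
                   object@t2Head, object@t2Background))
      if (length(t) != 2L || t[1] <= 0 || t[2] < 0)
        msg <- c(msg, "tissue T2 must be (mean > 0, sd >= 0)")
    if (!object@archetype %in% c("striatal", "corticostriatal", "fragmented",
                                 "large-edema", "none"))
      msg <- c(msg, "unknown lesion archetype")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@echoTime <= 0 || object@nEchoes < 1L)
      msg <- c(msg, "echo train must have TE > 0 and >= 1 echo")
    if (object@templatePerturb < 0)
      msg <- c(msg, "templatePerturb must be >= 0")
    if (length(msg)) msg else TRUE
  }
)
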