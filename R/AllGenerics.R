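#' Extract voxel data from a volume
#' @param x a [ScalarVolume-class]
#' @return the 3D numeric array of intensities
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Voxel spacing of a volume or bundle
#' @param x a [ScalarVolume-class] or [SegmentationBundle-class]
#' @return numeric(3) voxel size in mm
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Is a region model frozen during evolution?
#' @param x a [RegionModel-class]
#' @return logical(1)
#' @export
setGeneric("modelFixed", function(x) standardGeneric("modelFixed"))

#' Voxelwise log-probability under a region model
#'
#' Evaluates log P(I(x)) for every value of `values` under the model:
#' the Gaussian log-density for [GaussianModel-class], the log bin mass for
#' [HistogramModel-class]. Always finite (histogram masses are floored,
#' Gaussian sd is clamped).
#'
#' @param model a [RegionModel-class]
#' @param values numeric vector or array of intensities
#' @return numeric of the same shape as `values`
#' @export
setGeneric("logProb", function(model, values) standardGeneric("logProb"))

#' Extract one mask from a label atlas
#' @param x a [LabelAtlas-class]
#' @param label one of `"WB"`, `"IBH"`, `"CBH"`, `"IV"`, `"CV"`, `"PVZ"`
#' @return logical 3D array
#' @export
setGeneric("atlasMask", function(x, label) standardGeneric("atlasMask"))

#' Extract one region from a segmentation bundle
#' @param x a [SegmentationBundle-class]
#' @param name one of `"WB"`, `"IBH"`, `"CBH"`, `"CV"`, `"V"`, `"SInit"`,
#'   `"stroke"`
#' @return logical 3D array
#' @export
setGeneric("bundleMask", function(x, name) standardGeneric("bundleMask"))

#' Final lesion mask of a segmentation bundle
#' @param x a [SegmentationBundle-class]
#' @return logical 3D array
#' @export
setGeneric("lesionMask", function(x) standardGeneric("lesionMask"))
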