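# The four level-set segmentation stages. All stage inputs are expected on
# the cropped grid with unit-rescaled intensities (see runPipeline), and
# all intermediate regions are plain logical arrays.

#' Whole-brain segmentation (stage A2.a)
#'
#' Minimises the level-set energy on the (preprocessed) fourth echo image
#' starting from the propagated whole-brain mask, then applies per-slice
#' hole filling, per-slice morphological opening with a radius-2 disk, and
#' keeps the largest 26-connected component.
#'
#' @param echo4 preprocessed fourth echo ([ScalarVolume-class] or array)
#' @param atlas propagated [LabelAtlas-class] on the same grid
#' @param params stage parameters (default `stageParams("wholeBrain")`:
#'   Gaussian object/background, alpha 5, mu 2, 80 iterations, full-grid
#'   domain)
#' @return logical mask R_WB with evolution metadata in attributes
#' @export
segmentWholeBrain <- function(echo4, atlas,
                              params = stageParams("wholeBrain")) {
  res <- evolveLevelSet(echo4, atlasMask(atlas, "WB"), params = params)
  meta <- attributes(res)
  out <- largestComponent(openBySlice(fillHolesBySlice(res), radius = 2L))
  out <- fillHolesBySlice(out)
  if (!any(out)) stop("brain-not-found: whole-brain segmentation is empty")
  attr(out, "iterations") <- meta$iterations
  attr(out, "converged") <- meta$converged
  out
}

#' Contralateral-ventricle segmentation (stage A2.b)
#'
#' Evolves the level set on the T2 map inside the contralateral hemisphere
#' `R_CBH = R_WB \ M_IBH`, starting from the propagated contralateral
#' ventricle label.
#'
#' @param t2 preprocessed T2 map
#' @param atlas propagated [LabelAtlas-class]
#' @param rWB whole-brain region from [segmentWholeBrain()]
#' @param params stage parameters (default
#'   `stageParams("contralateralVentricle")`)
#' @return logical mask R_CV
#' @export
segmentContralateralVentricle <- function(t2, atlas, rWB,
    params = stageParams("contralateralVentricle")) {
  rCBH <- rWB & !atlasMask(atlas, "IBH")
  init <- atlasMask(atlas, "CV") & rCBH
  if (!any(init))
    stop("cv-not-found: contralateral ventricle label misses the domain")
  res <- evolveLevelSet(t2, init, params = params, domain = rCBH)
  if (!any(res))
    stop("cv-not-found: contralateral ventricle segmentation is empty")
  res
}

#' Ventricle segmentation (stage A2.c)
#'
#' Segments both ventricles on the T2 map inside R_WB. The object model is
#' a histogram fitted on the segmented contralateral ventricle and kept
#' fixed; the background histogram adapts. The gradient map derived from
#' the contralateral-ventricle Gaussian energy weights the length term so
#' the contour does not leak into lesion tissue touching the ventricles.
#' If evolution empties the region, the propagated ventricle labels are
#' used as a fallback (with a warning).
#'
#' @param t2 preprocessed T2 map
#' @param atlas propagated [LabelAtlas-class]
#' @param rWB whole-brain region
#' @param rCV contralateral ventricle region
#' @param params stage parameters (default `stageParams("ventricles")`)
#' @return logical mask R_V with attribute `"fallback"` when the label
#'   fallback was used
#' @export
segmentVentricles <- function(t2, atlas, rWB, rCV,
                              params = stageParams("ventricles")) {
  init <- (atlasMask(atlas, "IV") | atlasMask(atlas, "CV")) & rWB
  if (!any(init)) init <- rCV & rWB
  obj <- fitHistogramModel(t2, rCV, fixed = TRUE)
  g <- gradientMap(t2, rCV)
  res <- tryCatch(
    evolveLevelSet(t2, init, object = obj, params = params, domain = rWB,
                   g = g),
    error = function(e) NULL)
  if (is.null(res) || !any(res)) {
    warning("ventricle segmentation empty; falling back to propagated labels")
    res <- init
    attr(res, "fallback") <- TRUE
  }
  res
}

#' Dense-area filter for the stroke initialization
#'
#' A voxel of the mask is "dense" when at least 75% of its in-slice
#' neighbours inside a disk of radius 4 (49-voxel disk, center excluded)
#' also belong to the mask; at the volume border the fraction is taken
#' over in-bounds neighbours only. Returns the union of the mask's
#' 26-connected components that contain at least one dense voxel. The 75%
#' rule is evaluated in exact integer arithmetic.
#'
#' @param mask logical 3D array
#' @return filtered logical mask, with the dense-voxel mask attached as
#'   attribute `"dense"`
#' @export
denseAreaFilter <- function(mask) {
  m <- .asMask(mask)
  d <- dim(m)
  offs <- .diskOffsets(4L)
  cnt <- array(0L, d)
  inb <- array(0L, d)
  mi <- array(as.integer(m), d)
  ones <- array(1L, d)
  for (k in seq_len(nrow(offs))) {
    cnt <- cnt + .shiftPad(.shiftPad(mi, 1L, offs[k, 1], 0L),
                           2L, offs[k, 2], 0L)
    inb <- inb + .shiftPad(.shiftPad(ones, 1L, offs[k, 1], 0L),
                           2L, offs[k, 2], 0L)
  }
  dense <- m & (4L * cnt >= 3L * inb)
  lab <- .cpp_label26(m, d)
  keepLabels <- unique(lab[dense])
  keepLabels <- keepLabels[keepLabels > 0L]
  out <- array(lab %in% keepLabels, d)
  attr(out, "dense") <- dense
  out
}

# in-plane integer offsets within a disk of given radius, center excluded
.diskOffsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= r^2 & !(g$dx == 0 & g$dy == 0), ]
  as.matrix(g)
}

#' Stroke initialization mask (stage A3, initialization)
#'
#' Fits histogram models on the whole brain and on the contralateral
#' hemisphere, both with the ventricles and the periventricular zone
#' excluded, and selects the ipsilateral voxels where the whole-brain
#' model probability strictly exceeds the contralateral-model probability:
#' \deqn{R_{s_{init}} = P(I(x); R_{WB}\setminus(R_V \cup M_{PVZ})) >
#'   P(I(x); R_{CBH}\setminus(R_V \cup M_{PVZ}))}
#' evaluated on \eqn{R_{IBH}\setminus(R_V \cup M_{PVZ})}. Components not
#' intersecting dense areas are then filtered out ([denseAreaFilter()]).
#'
#' @param t2 preprocessed T2 map
#' @param atlas propagated [LabelAtlas-class]
#' @param rWB,rV whole-brain and ventricle regions
#' @param filter apply the dense-area filter (default `TRUE`)
#' @return logical mask (possibly empty), with the unfiltered mask as
#'   attribute `"raw"`
#' @export
initStrokeMask <- function(t2, atlas, rWB, rV, filter = TRUE) {
  excl <- rV | atlasMask(atlas, "PVZ")
  rIBH <- rWB & atlasMask(atlas, "IBH")
  rCBH <- rWB & !atlasMask(atlas, "IBH")
  regWB <- rWB & !excl
  regCBH <- rCBH & !excl
  a <- .asArray(t2)
  if (!any(regWB) || !any(regCBH)) return(array(FALSE, dim(a)))
  mWB <- fitHistogramModel(a, regWB)
  mCBH <- fitHistogramModel(a, regCBH)
  sel <- (logProb(mWB, a) > logProb(mCBH, a)) & rIBH & !excl
  dim(sel) <- dim(a)
  raw <- sel
  if (filter) sel <- denseAreaFilter(sel)
  attr(sel, "raw") <- raw
  sel
}

#' Stroke segmentation (stage A3)
#'
#' Evolves the level set on the T2 map from the filtered stroke
#' initialization, restricted to the ipsilateral hemisphere without the
#' ventricles and the periventricular zone. The background histogram is
#' fitted on the contralateral hemisphere and kept fixed; the object
#' histogram adapts. An empty initialization yields an empty lesion (no
#' lesion detected).
#'
#' @param t2 preprocessed T2 map
#' @param atlas propagated [LabelAtlas-class]
#' @param rWB,rV whole-brain and ventricle regions
#' @param rSInit filtered stroke initialization ([initStrokeMask()])
#' @param params stage parameters (default `stageParams("stroke")`)
#' @return logical mask R_stroke (subset of the stroke domain), with
#'   attribute `"note"` set to `"no-lesion-detected"` when empty
#' @export
segmentStroke <- function(t2, atlas, rWB, rV, rSInit,
                          params = stageParams("stroke")) {
  excl <- rV | atlasMask(atlas, "PVZ")
  rIBH <- rWB & atlasMask(atlas, "IBH")
  rCBH <- rWB & !atlasMask(atlas, "IBH")
  domain <- rIBH & !excl
  init <- rSInit & domain
  if (!any(init)) {
    out <- array(FALSE, dim(rWB))
    attr(out, "note") <- "no-lesion-detected"
    return(out)
  }
  bg <- fitHistogramModel(t2, rCBH, fixed = TRUE)
  evolveLevelSet(t2, init, background = bg, params = params,
                 domain = domain)
}
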