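#' Run the full automated lesion-segmentation pipeline
#'
#' Executes, in order: optional registration and label propagation (when a
#' template is given instead of subject-space labels), cropping to the
#' propagated whole-brain bounding box, unit intensity rescaling (plus
#' per-slice CDF normalization of the echo images), the four level-set
#' stages (whole brain, contralateral ventricle, both ventricles, stroke)
#' and lesion volume quantification. The pipeline is deterministic and
#' never consults truth labels.
#'
#' @param t2 quantitative T2 map ([ScalarVolume-class], values in ms)
#' @param echoes list of echo images ([ScalarVolume-class]), 1-based echo
#'   order; at least four echoes (the fourth drives brain segmentation)
#' @param atlas a [LabelAtlas-class] already in subject space, or `NULL`
#'   when `template` is given
#' @param template optional list with `image` ([ScalarVolume-class]) and
#'   `atlas` ([LabelAtlas-class]) on the template grid; the subject
#'   echo-sum is registered to the template image and the labels are
#'   propagated
#' @param transform optional externally computed [SpatialTransform-class]
#'   (e.g. from [readAffineTransform()] or [readDisplacementField()]);
#'   skips the built-in registration
#' @param config optional named list (or YAML/JSON file path) overriding
#'   stage parameters, keyed by stage name (`wholeBrain`,
#'   `contralateralVentricle`, `ventricles`, `stroke`), each a list of
#'   [stageParams()] fields
#' @return list with `bundle` (a [SegmentationBundle-class] on the cropped
#'   grid), `report` (volumes in mm^3, stage parameters, convergence), and
#'   `context` (preprocessed inputs, reusable by [resegmentStroke()])
#' @seealso [segmentWholeBrain()], [segmentStroke()], [resegmentStroke()]
#' @export
runPipeline <- function(t2, echoes, atlas = NULL, template = NULL,
                        transform = NULL, config = NULL) {
  cfg <- .resolveConfig(config)
  if (is.null(atlas)) {
    if (is.null(template))
      stop("registration: either subject-space labels or a template is required")
    echoSum <- sumEchoes(echoes)
    if (is.null(transform))
      transform <- registerNCC(moving = template$image, fixed = echoSum)
    atlas <- propagateLabels(template$atlas, transform, dim(t2),
                             targetSpacing = voxelSpacing(t2),
                             atlasSpacing = voxelSpacing(template$image))
  }

  # preprocessing: crop to the propagated brain bbox, rescale, normalize
  cropped <- cropToLabelBbox(t2, atlasMask(atlas, "WB"))
  report <- cropped$report
  t2c <- rescaleUnit(cropped$volume)
  atlasC <- applyCrop(atlas, report)
  echo4raw <- applyCrop(echoes[[min(4L, length(echoes))]], report)
  ref <- selectReferenceSlice(echo4raw)
  # CDF maps are estimated on the propagated brain mask eroded by the
  # nominal label-propagation error margin, so that boundary label error
  # cannot pull extracerebral intensities into the per-slice estimates
  maskNorm <- .erodeInPlane(atlasMask(atlasC, "WB"), 3L)
  if (!any(maskNorm)) maskNorm <- atlasMask(atlasC, "WB")
  echo4 <- perSliceCdfNormalize(rescaleUnit(echo4raw), ref,
                                mask = maskNorm, clampRange = c(0, 1))

  ctx <- list(t2 = t2c, echo4 = echo4, atlas = atlasC, crop = report,
              spacing = voxelSpacing(t2), refSlice = as.integer(ref),
              config = cfg)
  .runStages(ctx)
}

.resolveConfig <- function(config) {
  if (is.null(config)) return(list())
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.stageParamsFromConfig <- function(stage, cfg) {
  ov <- cfg[[stage]]
  if (is.null(ov)) return(stageParams(stage))
  # accept the flat key set (alpha, mu, n_iter, object_model, ...) too
  map <- c(n_iter = "nIter", object_model = "objectModel",
           background_model = "backgroundModel", object_fixed = "objectFixed",
           background_fixed = "backgroundFixed",
           use_gradient_map = "useGradientMap", input_image = "inputImage")
  names(ov) <- ifelse(names(ov) %in% names(map), map[names(ov)], names(ov))
  do.call(stageParams, c(list(stage = stage), ov))
}

.runStages <- function(ctx) {
  cfg <- ctx$config
  prov <- list(refSlice = ctx$refSlice, crop = ctx$crop$box)

  pWB <- .stageParamsFromConfig("wholeBrain", cfg)
  rWB <- withCallingHandlers(
    segmentWholeBrain(ctx$echo4, ctx$atlas, pWB),
    error = function(e) stop("stage whole-brain: ", conditionMessage(e)))
  prov$wholeBrain <- list(params = .paramsRecord(pWB),
                          iterations = attr(rWB, "iterations"))

  pCV <- .stageParamsFromConfig("contralateralVentricle", cfg)
  rCV <- tryCatch(
    segmentContralateralVentricle(ctx$t2, ctx$atlas, rWB, pCV),
    error = function(e)
      stop("stage contralateral-ventricle: ", conditionMessage(e)))
  prov$contralateralVentricle <- list(params = .paramsRecord(pCV),
                                      iterations = attr(rCV, "iterations"))

  pV <- .stageParamsFromConfig("ventricles", cfg)
  rV <- segmentVentricles(ctx$t2, ctx$atlas, rWB, rCV, pV)
  prov$ventricles <- list(params = .paramsRecord(pV),
                          iterations = attr(rV, "iterations"),
                          fallback = isTRUE(attr(rV, "fallback")))

  rSInit <- initStrokeMask(ctx$t2, ctx$atlas, rWB, rV)

  pS <- .stageParamsFromConfig("stroke", cfg)
  rStroke <- segmentStroke(ctx$t2, ctx$atlas, rWB, rV, rSInit, pS)
  prov$stroke <- list(params = .paramsRecord(pS),
                      iterations = attr(rStroke, "iterations"),
                      note = attr(rStroke, "note"))

  ibh <- atlasMask(ctx$atlas, "IBH")
  bundle <- new("SegmentationBundle",
                rWB = .strip(rWB), rIBH = .strip(rWB & ibh),
                rCBH = .strip(rWB & !ibh), rCV = .strip(rCV),
                rV = .strip(rV), rSInit = .strip(rSInit),
                rStroke = .strip(rStroke),
                spacing = ctx$spacing, provenance = prov)
  list(bundle = bundle, report = pipelineReport(bundle), context = ctx)
}

.strip <- function(m) { attributes(m) <- list(dim = dim(m)); m }

.paramsRecord <- function(p) {
  list(input_image = p@inputImage, object_model = p@objectModel,
       background_model = p@backgroundModel, object_fixed = p@objectFixed,
       background_fixed = p@backgroundFixed, alpha = p@alpha, mu = p@mu,
       n_iter = p@nIter, use_gradient_map = p@useGradientMap)
}

#' Volume report of a segmentation bundle
#' @param bundle a [SegmentationBundle-class]
#' @return list of per-region volumes (mm^3) plus the provenance log
#' @export
pipelineReport <- function(bundle) {
  vv <- prod(bundle@spacing)
  vols <- list(
    wholeBrain = sum(bundle@rWB) * vv,
    ipsilateralHemisphere = sum(bundle@rIBH) * vv,
    contralateralHemisphere = sum(bundle@rCBH) * vv,
    contralateralVentricle = sum(bundle@rCV) * vv,
    ventricles = sum(bundle@rV) * vv,
    strokeInit = sum(bundle@rSInit) * vv,
    lesion = sum(bundle@rStroke) * vv)
  list(volumes_mm3 = vols, provenance = bundle@provenance)
}

#' Re-run only the stroke stage with different parameters
#'
#' Reuses the preprocessed inputs and the whole-brain/ventricle regions of
#' a finished [runPipeline()] result and repeats stroke initialization and
#' evolution with new stage parameters. This is the workhorse of the
#' parameter sensitivity analysis, where only the stroke-stage parameters
#' are perturbed.
#'
#' @param result the list returned by [runPipeline()]
#' @param params a [StageParams-class] for the stroke stage
#' @return list with `bundle` and `report` (as in [runPipeline()])
#' @export
resegmentStroke <- function(result, params = stageParams("stroke")) {
  ctx <- result$context
  b <- result$bundle
  rSInit <- initStrokeMask(ctx$t2, ctx$atlas, b@rWB, b@rV)
  rStroke <- segmentStroke(ctx$t2, ctx$atlas, b@rWB, b@rV, rSInit, params)
  prov <- b@provenance
  prov$stroke <- list(params = .paramsRecord(params),
                      iterations = attr(rStroke, "iterations"),
                      note = attr(rStroke, "note"))
  bundle <- new("SegmentationBundle",
                rWB = b@rWB, rIBH = b@rIBH, rCBH = b@rCBH, rCV = b@rCV,
                rV = b@rV, rSInit = .strip(rSInit),
                rStroke = .strip(rStroke), spacing = b@spacing,
                provenance = prov)
  list(bundle = bundle, report = pipelineReport(bundle))
}

#' @rdname bundleMask
#' @export
setMethod("bundleMask", "SegmentationBundle", function(x, name) {
  nm <- c(WB = "rWB", IBH = "rIBH", CBH = "rCBH", CV = "rCV", V = "rV",
          SInit = "rSInit", stroke = "rStroke")
  key <- nm[match(tolower(name), tolower(names(nm)))]
  if (is.na(key)) stop("unknown region '", name, "'")
  slot(x, key)
})

#' @rdname lesionMask
#' @export
setMethod("lesionMask", "SegmentationBundle", function(x) x@rStroke)

#' Parameter sensitivity of the stroke stage
#'
#' Perturbs each stroke-stage parameter (`alpha`, `mu`, `nIter`) in turn by
#' a relative factor (default plus/minus 50%) on a set of finished pipeline
#' results, re-runs only the stroke stage, and summarises how the mean
#' absolute volume difference against reference volumes and the mean Dice
#' index change relative to the unperturbed run.
#'
#' @param results list of [runPipeline()] results (one per case)
#' @param truthLesions list of truth lesion masks on each cropped grid
#' @param delta relative perturbation (default 0.5)
#' @return data.frame with one row per (parameter, direction): the
#'   perturbed mean absolute volume difference (mm^3), its relative change
#'   (%) against baseline, the mean Dice, and the Dice change
#' @export
strokeSensitivity <- function(results, truthLesions, delta = 0.5) {
  base <- .suiteMetrics(lapply(results, function(r) r$bundle@rStroke),
                        results, truthLesions)
  rows <- list()
  for (parName in c("alpha", "mu", "nIter")) {
    for (dir in c(-1, 1)) {
      p0 <- stageParams("stroke")
      val <- slot(p0, parName)
      newVal <- val * (1 + dir * delta)
      if (parName == "nIter") newVal <- max(1L, as.integer(round(newVal)))
      pp <- do.call(stageParams,
                    c(list(stage = "stroke"), setNames(list(newVal), parName)))
      masks <- lapply(results, function(r)
        resegmentStroke(r, pp)$bundle@rStroke)
      met <- .suiteMetrics(masks, results, truthLesions)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = parName, direction = dir, value = newVal,
        meanAbsVolDiff = met$mavd,
        volDiffChangePct = 100 * abs(met$mavd - base$mavd) /
          max(base$mavd, .Machine$double.eps),
        meanDice = met$dice, diceChange = abs(met$dice - base$dice))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- base
  out
}

.suiteMetrics <- function(masks, results, truthLesions) {
  vv <- vapply(results, function(r) prod(r$bundle@spacing), numeric(1))
  volsA <- vapply(seq_along(masks), function(i) sum(masks[[i]]) * vv[i],
                  numeric(1))
  volsT <- vapply(seq_along(masks), function(i)
    sum(truthLesions[[i]]) * vv[i], numeric(1))
  dice <- vapply(seq_along(masks), function(i)
    diceIndex(masks[[i]], truthLesions[[i]]), numeric(1))
  list(mavd = mean(abs(volsA - volsT)), dice = mean(dice),
       volumes = volsA, truthVolumes = volsT)
}
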