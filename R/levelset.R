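.STAGE_DEFAULTS <- list(
  wholeBrain = list(inputImage = "echo4", objectModel = "gaussian",
                    backgroundModel = "gaussian", objectFixed = FALSE,
                    backgroundFixed = FALSE, alpha = 5, mu = 2, nIter = 80L,
                    useGradientMap = FALSE),
  contralateralVentricle = list(inputImage = "t2map",
                    objectModel = "gaussian", backgroundModel = "gaussian",
                    objectFixed = FALSE, backgroundFixed = FALSE,
                    alpha = 0.1, mu = 0, nIter = 120L,
                    useGradientMap = FALSE),
  ventricles = list(inputImage = "t2map", objectModel = "histogram",
                    backgroundModel = "histogram", objectFixed = TRUE,
                    backgroundFixed = FALSE, alpha = 2, mu = 1.5,
                    nIter = 120L, useGradientMap = TRUE),
  stroke = list(inputImage = "t2map", objectModel = "histogram",
                backgroundModel = "histogram", objectFixed = FALSE,
                backgroundFixed = TRUE, alpha = 0.3, mu = 0, nIter = 80L,
                useGradientMap = FALSE)
)

#' Stage parameters for the segmentation cascade
#'
#' Returns the parameter set of one of the four segmentation stages
#' (whole brain: Gaussian/Gaussian, alpha 5, mu 2, 80 iterations;
#' contralateral ventricle: Gaussian/Gaussian, alpha 0.1, mu 0, 120;
#' ventricles: fixed-object histogram, alpha 2, mu 1.5, 120, gradient map
#' on; stroke: fixed-background histogram, alpha 0.3, mu 0, 80). Any field
#' can be overridden through `...`.
#'
#' @param stage one of `"wholeBrain"`, `"contralateralVentricle"`,
#'   `"ventricles"`, `"stroke"`
#' @param ... named overrides of individual fields (`alpha`, `mu`, `nIter`,
#'   `objectModel`, `backgroundModel`, `objectFixed`, `backgroundFixed`,
#'   `useGradientMap`, `inputImage`)
#' @return a [StageParams-class]
#' @examples
#' stageParams("stroke")
#' stageParams("stroke", alpha = 0.45)
#' @export
stageParams <- function(stage = c("wholeBrain", "contralateralVentricle",
                                  "ventricles", "stroke"), ...) {
  stage <- match.arg(stage)
  p <- .STAGE_DEFAULTS[[stage]]
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown stage parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  new("StageParams", inputImage = p$inputImage,
      objectModel = p$objectModel, backgroundModel = p$backgroundModel,
      objectFixed = p$objectFixed, backgroundFixed = p$backgroundFixed,
      alpha = as.numeric(p$alpha), mu = as.numeric(p$mu),
      nIter = as.integer(p$nIter), useGradientMap = p$useGradientMap)
}

#' Gradient map from the contralateral ventricle model
#'
#' Computes \eqn{g(x) = 1 - e_v^2(x)} where
#' \eqn{e_v(x) = -\log P_{Gaussian}(I(x); R_{CV})} is the Gaussian energy of
#' the contralateral-ventricle region, min-max scaled to the unit interval
#' over the whole volume. The map is close to 1 at CSF-like intensities and
#' drops toward 0 at intensities far from the ventricle model, so that the
#' length term brakes the ventricle contour before it leaks into the
#' lesion.
#'
#' @param image a [ScalarVolume-class] or 3D array
#' @param cvRegion nonempty logical mask of the contralateral ventricle
#' @return a [ScalarVolume-class] with values in the unit interval; a
#'   constant image yields g identically 1
#' @export
gradientMap <- function(image, cvRegion) {
  a <- .asArray(image)
  model <- fitGaussianModel(image, cvRegion)
  ev <- -logProb(model, a)
  rng <- range(ev)
  if (rng[2] - rng[1] <= 0) {
    g <- array(1, dim(a))
  } else {
    ev <- (ev - rng[1]) / (rng[2] - rng[1])
    g <- 1 - ev^2
  }
  sp <- if (is(image, "ScalarVolume")) image@spacing else c(1, 1, 1)
  ScalarVolume(g, spacing = sp)
}

#' Level-set energy of a segmentation state
#'
#' Evaluates the region-based energy
#' \deqn{E(\phi) = \alpha \, g(x) \, \mathrm{Length}(\partial\Omega_O)
#'   + \mu \, \mathrm{Area}(\Omega_O)
#'   - \sum_{\Omega_O} \log P(I(x);\Omega_O)
#'   - \sum_{\Omega_B} \log P(I(x);\Omega_B)}
#' for a binary object/background partition. The data terms are sums of
#' negative log-probabilities over the object and background voxels inside
#' the evolution domain. Length is the (optionally g-weighted) perimeter of
#' the object: the number of 6-neighbour voxel faces between an in-domain
#' object voxel and a background voxel, each weighted by g at the object
#' voxel. Area is the in-domain object voxel count. Both are in voxel
#' units; physical units enter only in final volume reporting.
#'
#' @param state logical object mask, or a signed field whose non-negative
#'   part is the object (`phi >= 0` counts as object)
#' @param image a [ScalarVolume-class] or 3D array
#' @param object,background [RegionModel-class] objects
#' @param params a [StageParams-class] supplying `alpha` and `mu`
#' @param g optional gradient map (defaults to 1 everywhere)
#' @param domain optional logical evolution-domain mask (defaults to the
#'   full grid)
#' @return a finite scalar
#' @export
levelSetEnergy <- function(state, image, object, background, params,
                           g = NULL, domain = NULL) {
  a <- .asArray(image)
  st <- .asArray(state)
  .stopIfIncongruent(a, st)
  obj <- if (is.logical(st)) st else st >= 0
  dim(obj) <- dim(a)
  if (is.null(domain)) domain <- array(TRUE, dim(a)) else {
    domain <- .asMask(domain); .stopIfIncongruent(a, domain)
  }
  gArr <- if (is.null(g)) array(1, dim(a)) else .asArray(g)
  .stopIfIncongruent(a, gArr)

  lpO <- logProb(object, a)
  lpB <- logProb(background, a)
  eData <- -sum(lpO[obj & domain]) - sum(lpB[!obj & domain])

  eArea <- params@mu * sum(obj & domain)

  eLen <- 0
  if (params@alpha > 0) {
    per <- array(0, dim(a))
    for (axis in 1:3) for (s in c(-1L, 1L)) {
      nb <- .shiftPad(obj, axis, s, fill = FALSE)   # neighbour label
      inb <- .shiftPad(array(TRUE, dim(a)), axis, s, fill = FALSE)
      per <- per + (obj & domain & inb & !nb)
    }
    eLen <- params@alpha * sum(gArr * per)
  }
  eLen + eArea + eData
}

# clamp for the data force (log-likelihood-ratio): the histogram floor
# already bounds histogram forces at log(1/eps); Gaussian forces are
# clamped to the same scale so both model families share one bounded
# force range and the CFL time step is not stalled by astronomical
# Gaussian tail ratios (air vs brain)
.FORCE_CLAMP <- -log(1e-8)
.PHI_CLAMP <- 3
.STOP_FRAC <- 1e-4
.STOP_WINDOW <- 10L   # consecutive low-change iterations before stopping
.REINIT_EVERY <- 20L
.CFL <- 0.45

#' Evolve a region-based level set
#'
#' Minimises the energy of [levelSetEnergy()] by explicit gradient descent
#' on a clamped signed-distance field: the update at each voxel is
#' \eqn{\phi \mathrel{+}= dt\,[\,\alpha( g\kappa + \nabla g \cdot
#' \nabla\phi/|\nabla\phi| ) - \mu + \log P_O(I) - \log P_B(I)\,]} with the
#' data force clamped to the histogram-floor bound `log(1e8)` (about 18.4,
#' the same scale that bounds histogram forces) and the time step set by a
#' CFL-like
#' bound (max voxel displacement 0.45 per iteration). Non-fixed models are
#' re-estimated from the current partition every iteration. Evolution runs
#' for at most `nIter` iterations and stops early once fewer than 0.01% of
#' domain voxels change label between consecutive iterations, sustained
#' over ten consecutive iterations (the CFL step caps front speed, so a
#' single still iteration does not imply convergence). Voxels
#' outside `domain` never change label. The field is reinitialised to a
#' signed distance every 20 iterations while the length term is active
#' (`alpha > 0`); with `alpha == 0` the update is purely local and the
#' field is only kept clamped.
#'
#' @param image a [ScalarVolume-class] or 3D array (the stage input image)
#' @param init logical initialization mask, or a signed field (`>= 0` is
#'   object); must be nonempty inside `domain`
#' @param object,background initial [RegionModel-class] objects, or `NULL`
#'   to fit them from the initial partition using the model kinds in
#'   `params`
#' @param params a [StageParams-class]
#' @param domain optional logical evolution-domain mask
#' @param g optional gradient map ([gradientMap()]); used when
#'   `params@useGradientMap` is `TRUE`
#' @param limits intensity range for histogram models
#' @param traceEnergy if `TRUE`, attach the per-iteration energy (computed
#'   with the stage's alpha/mu) as attribute `"energy"`
#' @return logical object mask restricted to `domain`, with attributes
#'   `"iterations"` (number performed) and `"converged"` (early stop)
#' @export
evolveLevelSet <- function(image, init, object = NULL, background = NULL,
                           params, domain = NULL, g = NULL,
                           limits = c(0, 1), traceEnergy = FALSE) {
  a <- .asArray(image)
  d <- dim(a)
  initArr <- .asArray(init)
  .stopIfIncongruent(a, initArr)
  obj0 <- if (is.logical(initArr)) initArr else initArr >= 0
  dim(obj0) <- d
  if (is.null(domain)) domain <- array(TRUE, d) else {
    domain <- .asMask(domain); .stopIfIncongruent(a, domain)
  }
  obj0 <- obj0 & domain
  if (!any(obj0)) stop("empty-initialization: no object voxels inside domain")

  useG <- isTRUE(params@useGradientMap) && !is.null(g)
  gArr <- if (useG) .asArray(g) else NULL

  if (is.null(object))
    object <- .fitModel(params@objectModel, a, obj0, params@objectFixed,
                        limits)
  if (is.null(background)) {
    bg0 <- domain & !obj0
    if (!any(bg0)) bg0 <- !obj0
    background <- .fitModel(params@backgroundModel, a, bg0,
                            params@backgroundFixed, limits)
  }
  objFixed <- isTRUE(params@objectFixed) || modelFixed(object)
  bgFixed <- isTRUE(params@backgroundFixed) || modelFixed(background)

  phi <- .cpp_signed_distance(obj0, d)
  phi[phi > .PHI_CLAMP] <- .PHI_CLAMP
  phi[phi < -.PHI_CLAMP] <- -.PHI_CLAMP
  obj <- obj0
  nDomain <- sum(domain)
  energies <- if (traceEnergy) numeric(params@nIter) else NULL
  iters <- 0L
  converged <- FALSE
  lowChange <- 0L

  for (it in seq_len(params@nIter)) {
    # model re-estimation from the current partition (adaptive models only)
    if (!objFixed && any(obj))
      object <- .fitModel(params@objectModel, a, obj, FALSE, limits)
    if (!bgFixed && any(domain & !obj))
      background <- .fitModel(params@backgroundModel, a, domain & !obj,
                              FALSE, limits)

    force <- logProb(object, a) - logProb(background, a)
    force[force > .FORCE_CLAMP] <- .FORCE_CLAMP
    force[force < -.FORCE_CLAMP] <- -.FORCE_CLAMP
    force <- force - params@mu

    if (params@alpha > 0) {
      reg <- .curvatureForce(phi, gArr)
      reg[reg > 2] <- 2; reg[reg < -2] <- -2
      force <- force + params@alpha * reg
    }

    fmax <- max(abs(force[domain]))
    if (!is.finite(fmax) || fmax == 0) { converged <- TRUE; break }
    dt <- .CFL / fmax
    phi[domain] <- phi[domain] + dt * force[domain]
    phi[phi > .PHI_CLAMP] <- .PHI_CLAMP
    phi[phi < -.PHI_CLAMP] <- -.PHI_CLAMP

    newObj <- (phi >= 0) & domain
    dim(newObj) <- d
    changed <- sum(newObj != obj)
    obj <- newObj
    iters <- it
    if (traceEnergy)
      energies[it] <- levelSetEnergy(obj, a, object, background, params,
                                     g = if (useG) gArr else NULL,
                                     domain = domain)
    # convergence: fewer than stop_frac of domain voxels changing label,
    # sustained over a window (a single still iteration can just be the
    # front spooling up, since the CFL step caps per-iteration movement)
    lowChange <- if (changed < .STOP_FRAC * nDomain) lowChange + 1L else 0L
    if (lowChange >= .STOP_WINDOW) { converged <- TRUE; break }
    if (params@alpha > 0 && it %% .REINIT_EVERY == 0L) {
      phi <- .cpp_signed_distance(obj, d)
      phi[phi > .PHI_CLAMP] <- .PHI_CLAMP
      phi[phi < -.PHI_CLAMP] <- -.PHI_CLAMP
    }
  }
  res <- obj
  attr(res, "iterations") <- iters
  attr(res, "converged") <- converged
  if (traceEnergy) attr(res, "energy") <- energies[seq_len(iters)]
  res
}

# alpha-term of the descent: div(g * grad(phi)/|grad(phi)|)
#   = g * kappa + grad(g) . grad(phi)/|grad(phi)|
# central differences; kappa clamped to [-1, 1] for stability
.curvatureForce <- function(phi, g = NULL) {
  eps <- 1e-8
  px <- (.shift1(phi, 1, -1) - .shift1(phi, 1, 1)) / 2
  py <- (.shift1(phi, 2, -1) - .shift1(phi, 2, 1)) / 2
  pz <- (.shift1(phi, 3, -1) - .shift1(phi, 3, 1)) / 2
  pxx <- .shift1(phi, 1, -1) - 2 * phi + .shift1(phi, 1, 1)
  pyy <- .shift1(phi, 2, -1) - 2 * phi + .shift1(phi, 2, 1)
  pzz <- .shift1(phi, 3, -1) - 2 * phi + .shift1(phi, 3, 1)
  pxy <- (.shift1(.shift1(phi, 1, -1), 2, -1) -
          .shift1(.shift1(phi, 1, -1), 2, 1) -
          .shift1(.shift1(phi, 1, 1), 2, -1) +
          .shift1(.shift1(phi, 1, 1), 2, 1)) / 4
  pxz <- (.shift1(.shift1(phi, 1, -1), 3, -1) -
          .shift1(.shift1(phi, 1, -1), 3, 1) -
          .shift1(.shift1(phi, 1, 1), 3, -1) +
          .shift1(.shift1(phi, 1, 1), 3, 1)) / 4
  pyz <- (.shift1(.shift1(phi, 2, -1), 3, -1) -
          .shift1(.shift1(phi, 2, -1), 3, 1) -
          .shift1(.shift1(phi, 2, 1), 3, -1) +
          .shift1(.shift1(phi, 2, 1), 3, 1)) / 4
  g2 <- px^2 + py^2 + pz^2
  kappa <- (pxx * (py^2 + pz^2) + pyy * (px^2 + pz^2) +
            pzz * (px^2 + py^2) -
            2 * (px * py * pxy + px * pz * pxz + py * pz * pyz)) /
           (g2^1.5 + eps)
  kappa[kappa > 1] <- 1
  kappa[kappa < -1] <- -1
  if (is.null(g)) return(kappa)
  gx <- (.shift1(g, 1, -1) - .shift1(g, 1, 1)) / 2
  gy <- (.shift1(g, 2, -1) - .shift1(g, 2, 1)) / 2
  gz <- (.shift1(g, 3, -1) - .shift1(g, 3, 1)) / 2
  gn <- sqrt(g2) + eps
  g * kappa + (gx * px + gy * py + gz * pz) / gn
}
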