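#' Dice overlap index
#'
#' `2 |A intersect B| / (|A| + |B|)`, in the unit interval. Two empty
#' masks are defined to agree perfectly (value 1, with a message).
#'
#' @param r1,r2 congruent logical masks
#' @return numeric(1)
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
#' b <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1))
#' diceIndex(a, b)
#' @export
diceIndex <- function(r1, r2) {
  m1 <- .asMask(r1); m2 <- .asMask(r2)
  .stopIfIncongruent(m1, m2)
  s <- sum(m1) + sum(m2)
  if (s == 0L) {
    message("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(m1 & m2) / s
}

#' Lesion volume in mm^3
#' @param mask logical mask
#' @param spacing numeric(3) voxel size in mm
#' @return voxel count times voxel volume
#' @examples
#' lesionVolume(array(TRUE, c(10, 10, 1)), c(0.12, 0.12, 0.50))
#' @export
lesionVolume <- function(mask, spacing) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  sum(.asMask(mask)) * prod(spacing)
}

#' Intraclass correlation, two-way model, absolute agreement
#'
#' Single-measure ICC for absolute agreement under a two-way model
#' (McGraw-Wong ICC(A,1)), computed from the two-way ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' with n cases (rows) and k raters/methods (columns). Used to compare
#' lesion volumes between the observer mean and the automated method.
#'
#' @param ratings numeric matrix, cases in rows, methods in columns
#'   (at least 3 cases and 2 columns)
#' @return numeric(1) in `[-1, 1]`
#' @export
iccAbsoluteAgreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L || k < 2L) stop("need at least 3 cases and 2 methods")
  if (any(!is.finite(ratings))) stop("ratings must be finite")
  grand <- mean(ratings)
  rowM <- rowMeans(ratings)
  colM <- colMeans(ratings)
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst <= 0) stop("degenerate-ratings: zero total variance")
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Group threshold from contralateral ROI means
#'
#' The semi-automated baseline's threshold: the mean plus two standard
#' deviations (sample sd, n-1) of a vector of per-animal average T2 values
#' measured in a contralateral-hemisphere ROI, pooled per animal group.
#'
#' @param roiMeans numeric vector of per-animal contralateral ROI mean T2
#'   values (ms); length at least 2
#' @return threshold in ms
#' @examples
#' contralateralThreshold(c(48, 50, 52))   # 50 + 2 * 2 = 54
#' @export
contralateralThreshold <- function(roiMeans) {
  if (length(roiMeans) < 2L) stop("need at least 2 ROI means")
  mean(roiMeans) + 2 * sd(roiMeans)
}

#' Mean intensity within a region of interest
#' @param image a [ScalarVolume-class] or 3D array
#' @param roi nonempty logical mask
#' @return numeric(1)
#' @export
roiMean <- function(image, roi) {
  a <- .asArray(image)
  m <- .asMask(roi)
  .stopIfIncongruent(a, m)
  if (!any(m)) stop("empty ROI")
  mean(a[m])
}

#' Threshold mask (semi-automated step M2)
#'
#' All voxels strictly above the threshold, inside the domain.
#'
#' @param image T2 map ([ScalarVolume-class] or array, ms)
#' @param threshold threshold in ms
#' @param domain optional logical mask (defaults to the full grid)
#' @return logical mask
#' @export
thresholdMask <- function(image, threshold, domain = NULL) {
  a <- .asArray(image)
  m <- a > threshold
  if (!is.null(domain)) {
    dm <- .asMask(domain)
    .stopIfIncongruent(a, dm)
    m <- m & dm
  }
  dim(m) <- dim(a)
  m
}

#' Semi-automated lesion segmentation baseline (M1-M4)
#'
#' Thresholding baseline: threshold at the group value (M1, from
#' [contralateralThreshold()]), mask all voxels above it (M2), remove
#' confounding regions (M3 - the manual edit is represented by an
#' exclusion mask standing in for the observer), and quantify the volume
#' (M4).
#'
#' @param t2 T2 map ([ScalarVolume-class], ms)
#' @param threshold group threshold in ms
#' @param domain optional mask restricting the search (e.g. the brain)
#' @param exclusion optional mask of confounding regions removed by the
#'   observer (ventricles, periventricular tissue)
#' @return list with `mask` and `volume` (mm^3)
#' @export
semiAutomatedLesion <- function(t2, threshold, domain = NULL,
                                exclusion = NULL) {
  m <- thresholdMask(t2, threshold, domain)
  if (!is.null(exclusion)) m <- m & !.asMask(exclusion)
  sp <- if (is(t2, "ScalarVolume")) t2@spacing else c(1, 1, 1)
  list(mask = m, volume = lesionVolume(m, sp))
}

#' Agreement report between two segmentation methods
#'
#' Per-case Dice and volumes for two sets of masks, the absolute volume
#' differences, and the two-way absolute-agreement ICC of the volumes.
#'
#' @param masks1,masks2 lists of congruent logical masks (same length)
#' @param spacing numeric(3) voxel size in mm
#' @return list with `perCase` (data.frame: dice, volume1, volume2,
#'   absVolDiff) and `icc` (NA with fewer than 3 cases), plus mean/sd
#'   summaries
#' @export
agreementReport <- function(masks1, masks2, spacing) {
  stopifnot(length(masks1) == length(masks2))
  dice <- mapply(diceIndex, masks1, masks2)
  v1 <- vapply(masks1, lesionVolume, numeric(1), spacing = spacing)
  v2 <- vapply(masks2, lesionVolume, numeric(1), spacing = spacing)
  perCase <- data.frame(dice = dice, volume1 = v1, volume2 = v2,
                        absVolDiff = abs(v1 - v2))
  icc <- if (length(masks1) >= 3L)
    tryCatch(iccAbsoluteAgreement(cbind(v1, v2)), error = function(e) NA_real_)
  else NA_real_
  list(perCase = perCase, icc = icc,
       meanDice = mean(dice), sdDice = sd(dice),
       meanAbsVolDiff = mean(perCase$absVolDiff),
       sdAbsVolDiff = sd(perCase$absVolDiff))
}
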