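#' Create a LabelAtlas
#'
#' @param wb,ibh,cbh,iv,cv,pvz logical 3D masks on one grid: whole brain,
#'   ipsilateral/contralateral hemisphere, ipsilateral/contralateral
#'   ventricle, periventricular zone.
#' @param enforce if `TRUE` (default), invariants are re-enforced by
#'   masking (hemispheres clipped to the brain and made disjoint with
#'   ipsilateral priority, ventricles clipped to their hemisphere) instead
#'   of failing validity; use after warping.
#' @return a [LabelAtlas-class]
#' @export
LabelAtlas <- function(wb, ibh, cbh, iv, cv, pvz, enforce = TRUE) {
  wb <- .asMask(wb); ibh <- .asMask(ibh); cbh <- .asMask(cbh)
  iv <- .asMask(iv); cv <- .asMask(cv); pvz <- .asMask(pvz)
  if (enforce) {
    ibh <- ibh & wb
    cbh <- cbh & wb & !ibh
    iv <- iv & ibh
    cv <- cv & cbh
    pvz <- pvz & wb
  }
  new("LabelAtlas", wb = wb, ibh = ibh, cbh = cbh, iv = iv, cv = cv,
      pvz = pvz)
}

.ATLAS_LABELS <- c(WB = "wb", IBH = "ibh", CBH = "cbh", IV = "iv",
                   CV = "cv", PVZ = "pvz")

#' @rdname atlasMask
#' @export
setMethod("atlasMask", "LabelAtlas", function(x, label) {
  label <- toupper(label)
  if (!label %in% names(.ATLAS_LABELS))
    stop("unknown label '", label, "'; use one of ",
         paste(names(.ATLAS_LABELS), collapse = ", "))
  slot(x, .ATLAS_LABELS[[label]])
})

#' Encode a label atlas as one integer-coded volume
#'
#' Codes: 1 whole-brain only, 2 ipsilateral hemisphere, 3 contralateral
#' hemisphere, 4 ipsilateral ventricle, 5 contralateral ventricle, 6
#' periventricular zone. Higher codes take priority at overlapping voxels
#' except that ventricle codes (4, 5) beat the periventricular code (6).
#' Note the coded format cannot record which hemisphere a periventricular
#' voxel belongs to; [decodeAtlas()] therefore leaves code-6 voxels out of
#' the hemisphere masks. Round-tripping is exact for WB, IV, CV and PVZ,
#' and exact for the hemispheres only where they do not overlap the PVZ;
#' use the six-volume format when that matters.
#'
#' @param atlas a [LabelAtlas-class]
#' @return integer 3D array of codes 0..6
#' @export
encodeAtlas <- function(atlas) {
  code <- array(0L, dim(atlas@wb))
  code[atlas@wb] <- 1L
  code[atlas@ibh] <- 2L
  code[atlas@cbh] <- 3L
  code[atlas@pvz] <- 6L
  code[atlas@iv] <- 4L
  code[atlas@cv] <- 5L
  code
}

#' Decode an integer-coded atlas volume
#' @param code integer 3D array of codes 0..6 (see [encodeAtlas()])
#' @return a [LabelAtlas-class]
#' @export
decodeAtlas <- function(code) {
  code <- .asArray(code)
  LabelAtlas(wb = code >= 1L,
             ibh = code == 2L | code == 4L,
             cbh = code == 3L | code == 5L,
             iv = code == 4L,
             cv = code == 5L,
             pvz = code == 6L,
             enforce = TRUE)
}
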