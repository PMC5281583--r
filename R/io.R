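# NIfTI and plain-text I/O. All image files go through RNifti.

#' Read a 3D NIfTI volume as a ScalarVolume
#' @param path NIfTI file (.nii or .nii.gz)
#' @return a [ScalarVolume-class]
#' @export
readScalarVolume <- function(path) {
  im <- RNifti::readNifti(path)
  a <- array(as.numeric(im), dim(im))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
  if (length(dim(a)) != 3L) stop("expected a 3D volume in ", path)
  sp <- RNifti::pixdim(im)[1:3]
  ScalarVolume(a, spacing = sp)
}

#' Write a ScalarVolume (or mask) to NIfTI
#' @param x a [ScalarVolume-class], or 3D array with `spacing` given
#' @param path output file
#' @param spacing voxel size, used when `x` is a bare array
#' @export
writeScalarVolume <- function(x, path, spacing = c(1, 1, 1)) {
  if (is(x, "ScalarVolume")) {
    a <- x@values
    spacing <- x@spacing
  } else {
    a <- .asArray(x)
    storage.mode(a) <- "double"
  }
  im <- RNifti::asNifti(a)
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a 4D multi-echo NIfTI stack as a list of ScalarVolumes
#' @param path NIfTI file with a 4D (x, y, z, echo) image
#' @return list of [ScalarVolume-class], one per echo (1-based echo order)
#' @export
readEchoStack <- function(path) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4L) stop("expected a 4D echo stack in ", path)
  sp <- RNifti::pixdim(im)[1:3]
  lapply(seq_len(d[4]), function(e)
    ScalarVolume(array(as.numeric(im[, , , e]), d[1:3]), spacing = sp))
}

#' Write a list of echo volumes as one 4D NIfTI stack
#' @param echoes list of congruent [ScalarVolume-class] objects
#' @param path output file
#' @export
writeEchoStack <- function(echoes, path) {
  arrs <- lapply(echoes, .asArray)
  a <- array(unlist(arrs), c(dim(arrs[[1]]), length(arrs)))
  im <- RNifti::asNifti(a)
  RNifti::pixdim(im) <- c(voxelSpacing(echoes[[1]]), 1)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a label atlas from NIfTI
#'
#' Accepts either a single integer-coded volume (codes 1..6, see
#' [encodeAtlas()]) or six separate binary volumes.
#'
#' @param path one coded NIfTI file, or a character vector of six files in
#'   the order WB, IBH, CBH, IV, CV, PVZ
#' @return a [LabelAtlas-class]
#' @export
readLabelAtlas <- function(path) {
  if (length(path) == 6L) {
    vols <- lapply(path, function(p) voxelData(readScalarVolume(p)) > 0)
    return(LabelAtlas(vols[[1]], vols[[2]], vols[[3]], vols[[4]],
                      vols[[5]], vols[[6]], enforce = TRUE))
  }
  v <- readScalarVolume(path)
  decodeAtlas(array(as.integer(round(v@values)), dim(v@values)))
}

#' Write a label atlas as one coded NIfTI volume
#' @param atlas a [LabelAtlas-class]
#' @param path output file
#' @param spacing voxel size in mm
#' @export
writeLabelAtlas <- function(atlas, path, spacing = c(1, 1, 1)) {
  writeScalarVolume(array(as.numeric(encodeAtlas(atlas)), dim(atlas@wb)),
                    path, spacing = spacing)
}

#' Read an affine transform from a plain-text file
#'
#' The file holds a homogeneous 4x4 matrix, row-major, mm units, acting on
#' fixed-image world coordinates (rotation center already folded in).
#'
#' @param path text file with 16 whitespace-separated numbers (4 rows)
#' @return a [SpatialTransform-class] (kind `"affine"`, center 0)
#' @export
readAffineTransform <- function(path) {
  vals <- scan(path, quiet = TRUE)
  if (length(vals) != 16L) stop("expected a 4x4 matrix in ", path)
  A <- matrix(vals, 4, 4, byrow = TRUE)
  affineTransform(A[1:3, 1:3], A[1:3, 4], center = c(0, 0, 0),
                  kind = "affine")
}

#' Write an affine transform to a plain-text file
#' @param transform an affine or rigid [SpatialTransform-class]
#' @param path output file
#' @export
writeAffineTransform <- function(transform, path) {
  if (transform@kind == "field")
    stop("use writeScalarVolume for displacement fields")
  M <- transform@matrix
  # fold the rotation center into the translation column
  t <- as.numeric(transform@center - M %*% transform@center +
                    transform@translation)
  A <- rbind(cbind(M, t), c(0, 0, 0, 1))
  writeLines(apply(A, 1, function(r) paste(format(r, digits = 17),
                                           collapse = " ")), path)
  invisible(path)
}

#' Read a dense displacement field from a 4D NIfTI
#' @param path NIfTI file with a (nx, ny, nz, 3) volume of mm displacements
#' @return a [SpatialTransform-class] of kind `"field"`
#' @export
readDisplacementField <- function(path) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 3-component displacement field in ", path)
  displacementFieldTransform(array(as.numeric(im), d),
                             spacing = RNifti::pixdim(im)[1:3])
}
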