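# NIfTI input/output via RNifti. Volumes carry spacing through pixdim;
# world origin is stored in the qform translation (axis-aligned grids only).

#' Write a volume to NIfTI
#'
#' @param vol a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(is_volume_grid(vol))
  img <- RNifti::asNifti(vol$values)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  xf <- diag(c(vol$spacing, 1))
  xf[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file with a 3D scalar image.
#' @return A [volume_grid()].
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vals)) != 3L)
    stop("expected a 3D NIfTI volume")
  xf <- RNifti::xform(img)
  volume_grid(vals, spacing = RNifti::pixdim(img)[1:3], origin = xf[1:3, 4])
}

#' Write a displacement field to 4D NIfTI
#'
#' The 4th dimension holds the three displacement components, in mm.
#'
#' @param field a [displacement_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field_nifti <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  img <- RNifti::asNifti(field$u)
  img <- RNifti::`pixdim<-`(img, c(field$spacing, 1))
  xf <- diag(c(field$spacing, 1))
  xf[1:3, 4] <- field$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a displacement field from 4D NIfTI
#'
#' @param path NIfTI file with a 4D array whose 4th dimension has length 3.
#' @return A [displacement_field()].
#' @export
read_field_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  u <- array(as.numeric(img), dim = dim(img))
  if (length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("expected a 4D NIfTI with 3 vector components")
  xf <- RNifti::xform(img)
  displacement_field(u, spacing = RNifti::pixdim(img)[1:3],
                     origin = xf[1:3, 4])
}

# Run a block of code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
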