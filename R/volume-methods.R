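#' @include AllClasses.R
NULL

#' Construct an ImageVolume
#'
#' @param values 3-D numeric array (logical arrays are coerced).
#' @param spacing per-axis voxel size in mm.
#' @param origin physical coordinate (mm) of the first voxel centre.
#' @param orientation permutation of \code{c("LR","AP","SI")} naming the
#'   anatomical direction of each array axis.
#' @return An \code{ImageVolume}.
#' @export
ImageVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        orientation = c("LR", "AP", "SI")) {
  storage.mode(values) <- "double"
  new("ImageVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' Construct a BinaryMask
#'
#' @inheritParams ImageVolume
#' @return A \code{BinaryMask}.
#' @export
BinaryMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       orientation = c("LR", "AP", "SI")) {
  storage.mode(values) <- "double"
  new("BinaryMask", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' Construct a ProbabilityMap
#'
#' @inheritParams ImageVolume
#' @return A \code{ProbabilityMap}.
#' @export
ProbabilityMap <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           orientation = c("LR", "AP", "SI")) {
  storage.mode(values) <- "double"
  new("ProbabilityMap", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' Construct a RegionAtlas
#'
#' @inheritParams ImageVolume
#' @param labelTable data.frame with columns \code{region}, \code{side},
#'   \code{label} mapping each named region per hemisphere to its integer
#'   label in \code{values}.
#' @return A \code{RegionAtlas}.
#' @export
RegionAtlas <- function(values, labelTable, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0),
                        orientation = c("LR", "AP", "SI")) {
  storage.mode(values) <- "double"
  new("RegionAtlas", values = values, labelTable = labelTable,
      spacing = as.numeric(spacing), origin = as.numeric(origin),
      orientation = orientation)
}

#' Construct a RigidTransform
#'
#' @param rotation angles (radians) about the x, y, z grid axes; the
#'   rotation matrix is \code{Rz Ry Rx}.
#' @param translation mm.
#' @param center rotation centre, mm.
#' @return A \code{RigidTransform}.
#' @export
RigidTransform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform", rotation = as.numeric(rotation),
      translation = as.numeric(translation), center = as.numeric(center))
}

# ---- accessors --------------------------------------------------------------

#' @rdname ImageVolume-accessors
#' @name ImageVolume-accessors
#' @title Accessors for ImageVolume objects
#' @param x an \code{ImageVolume} (or subclass).
#' @return \code{imageData}: the 3-D array; \code{voxelSpacing},
#'   \code{volumeOrigin}: numeric 3-vectors; \code{orientation}: character
#'   triple; \code{lrAxis}: the array axis index running left-right.
NULL

#' @rdname ImageVolume-accessors
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
#' @rdname ImageVolume-accessors
#' @export
setMethod("imageData", "ImageVolume", function(x) x@values)

#' @rdname ImageVolume-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname ImageVolume-accessors
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)

#' @rdname ImageVolume-accessors
#' @export
setGeneric("volumeOrigin", function(x) standardGeneric("volumeOrigin"))
#' @rdname ImageVolume-accessors
#' @export
setMethod("volumeOrigin", "ImageVolume", function(x) x@origin)

#' @rdname ImageVolume-accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))
#' @rdname ImageVolume-accessors
#' @export
setMethod("orientation", "ImageVolume", function(x) x@orientation)

#' @rdname ImageVolume-accessors
#' @export
setGeneric("lrAxis", function(x) standardGeneric("lrAxis"))
#' @rdname ImageVolume-accessors
#' @export
setMethod("lrAxis", "ImageVolume", function(x) which(x@orientation == "LR"))

#' @rdname ImageVolume-accessors
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))
#' @rdname ImageVolume-accessors
#' @export
setMethod("labelTable", "RegionAtlas", function(x) x@labelTable)

#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@values))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s %dx%dx%d, spacing %s mm, origin (%s), axes %s\n",
              class(object), d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = "x"),
              paste(signif(object@origin, 4), collapse = ", "),
              paste(object@orientation, collapse = "/")))
  v <- object@values
  cat(sprintf("  intensity range [%.3g, %.3g], mean %.3g\n",
              min(v), max(v), mean(v)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryMask %dx%dx%d, spacing %s mm, %d positive voxels\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = "x"),
              sum(object@values)))
})

setMethod("show", "RegionAtlas", function(object) {
  d <- dim(object@values)
  cat(sprintf("RegionAtlas %dx%dx%d, %d regions, %d labelled voxels\n",
              d[1], d[2], d[3], nrow(object@labelTable),
              sum(object@values != 0)))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf(
    "RigidTransform: rot (%s) deg, trans (%s) mm, centre (%s) mm\n",
    paste(signif(object@rotation * 180 / pi, 4), collapse = ", "),
    paste(signif(object@translation, 4), collapse = ", "),
    paste(signif(object@center, 4), collapse = ", ")))
})

setMethod("show", "PhantomCase", function(object) {
  cat(sprintf("PhantomCase %s (group %s): %s grid, lesion %d voxels\n",
              object@id, object@group,
              paste(dim(object@cta@values), collapse = "x"),
              sum(object@lesionMask@values)))
})

setMethod("show", "RegionContingency", function(object) {
  cat(sprintf("RegionContingency: TN %d, TP %d, FN %d, FP %d\n",
              object@tn, object@tp, object@fn, object@fp))
})

# ---- grid helpers -----------------------------------------------------------

#' Test whether two volumes share the same grid
#'
#' Same array shape, spacing, origin (within 1e-6 mm) and orientation.
#' @param a,b \code{ImageVolume} objects.
#' @return logical.
#' @export
gridCongruent <- function(a, b) {
  identical(dim(a@values), dim(b@values)) &&
    max(abs(a@spacing - b@spacing)) < 1e-6 &&
    max(abs(a@origin - b@origin)) < 1e-6 &&
    identical(a@orientation, b@orientation)
}

.stopIfNotCongruent <- function(a, b, what = "volumes") {
  if (!gridCongruent(a, b))
    stop(sprintf("%s are not grid-congruent", what), call. = FALSE)
  invisible(TRUE)
}

# Replace the voxel array of a volume, keeping class and geometry.
.withValues <- function(vol, values) {
  storage.mode(values) <- "double"
  out <- vol
  out@values <- values
  validObject(out)
  out
}

# ---- NIfTI IO ---------------------------------------------------------------

#' Read a volume from a NIfTI file
#'
#' Spacing is taken from the NIfTI pixdim and the origin from the sform/qform
#' translation. Axes are assumed already in the package's canonical order
#' (axis 1 left-right, 2 anterior-posterior, 3 superior-inferior), the
#' convention in which \code{\link{writeVolume}} writes.
#'
#' @param file path to a .nii or .nii.gz file.
#' @param class one of \code{"ImageVolume"}, \code{"BinaryMask"},
#'   \code{"ProbabilityMap"}.
#' @return the requested volume object.
#' @export
readVolume <- function(file, class = c("ImageVolume", "BinaryMask",
                                       "ProbabilityMap")) {
  class <- match.arg(class)
  img <- RNifti::readNifti(file)
  vals <- array(as.numeric(img), dim = dim(img))
  sp <- attr(img, "pixdim")[seq_len(3)]
  xf <- RNifti::xform(img)
  orig <- xf[seq_len(3), 4]
  fun <- switch(class, ImageVolume = ImageVolume, BinaryMask = BinaryMask,
                ProbabilityMap = ProbabilityMap)
  fun(vals, spacing = sp, origin = orig)
}

#' Write a volume to a NIfTI file
#'
#' @param vol an \code{ImageVolume} (or subclass).
#' @param file output path (.nii or .nii.gz).
#' @return \code{file}, invisibly.
#' @export
writeVolume <- function(vol, file) {
  img <- RNifti::asNifti(vol@values)
  RNifti::pixdim(img) <- vol@spacing
  aff <- diag(4)
  diag(aff)[seq_len(3)] <- vol@spacing
  aff[seq_len(3), 4] <- vol@origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}
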