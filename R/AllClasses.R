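#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib ctastroke, .registration = TRUE
NULL

.axisLabels <- c("LR", "AP", "SI")

#' ImageVolume: a 3-D scalar grid with physical geometry
#'
#' The carrier for all volumetric data in the package: CTA-like and
#' NCCT-like channels, derived channels, and (through subclasses) masks,
#' probability maps and region atlases. Physical coordinates of voxel
#' \code{(i,j,k)} (1-based) are \code{origin + (c(i,j,k)-1) * spacing};
#' the origin is the centre of the first voxel.
#'
#' @slot values 3-D numeric array.
#' @slot spacing per-axis voxel size in mm (positive).
#' @slot origin physical coordinate (mm) of the first voxel centre.
#' @slot orientation character triple, a permutation of \code{"LR"},
#'   \code{"AP"}, \code{"SI"} naming the anatomical direction of each array
#'   axis; the \code{"LR"} entry fixes the sagittal-flip axis.
#' @export
setClass("ImageVolume", representation(
  values = "array",
  spacing = "numeric",
  origin = "numeric",
  orientation = "character"
), prototype(
  spacing = c(1, 1, 1),
  origin = c(0, 0, 0),
  orientation = c("LR", "AP", "SI")
))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be a finite 3-vector")
  if (length(object@orientation) != 3L ||
      !setequal(object@orientation, .axisLabels))
    msg <- c(msg, "orientation must be a permutation of LR, AP, SI")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a \{0,1\} grid on an ImageVolume geometry
#'
#' Used for brain masks, lesion masks and thresholded predictions.
#' @export
setClass("BinaryMask", contains = "ImageVolume")

setValidity("BinaryMask", function(object) {
  if (!all(object@values %in% c(0, 1)))
    "mask values must be 0 or 1" else TRUE
})

#' ProbabilityMap: per-voxel confidence in [0,1]
#'
#' The network's output; values outside the intracranial mask are zero.
#' @export
setClass("ProbabilityMap", contains = "ImageVolume")

setValidity("ProbabilityMap", function(object) {
  v <- object@values
  if (any(v < 0) || any(v > 1)) "probabilities must lie in [0,1]" else TRUE
})

#' RegionAtlas: ASPECTS-analog region labels
#'
#' Integer label volume with 0 background and labels 1..20 covering the ten
#' ASPECTS regions (M1-M6, insular ribbon I, lentiform nucleus L, caudate C,
#' internal capsule IC) in each hemisphere, plus the table mapping
#' region x side to the integer label.
#'
#' @slot labelTable data.frame with columns \code{region}, \code{side},
#'   \code{label}.
#' @export
setClass("RegionAtlas", contains = "ImageVolume",
         representation(labelTable = "data.frame"))

setValidity("RegionAtlas", function(object) {
  msg <- character()
  lab <- unique(as.vector(object@values))
  lab <- lab[lab != 0]
  if (any(lab != round(lab)) || any(lab < 0))
    msg <- c(msg, "labels must be non-negative integers")
  need <- c("region", "side", "label")
  if (!all(need %in% names(object@labelTable)))
    msg <- c(msg, "labelTable needs columns region, side, label")
  else if (!all(lab %in% object@labelTable$label))
    msg <- c(msg, "label volume contains labels missing from labelTable")
  if (length(msg)) msg else TRUE
})

#' RigidTransform: a 6-DOF spatial map
#'
#' Maps a physical point p to \code{R (p - center) + center + translation},
#' with \code{R = Rz(g) Ry(b) Rx(a)} built from the \code{rotation} angles
#' \code{c(a, b, g)} (radians). Used as a resampling transform: applying it
#' to a volume samples the volume at the mapped points.
#'
#' @slot rotation angles (radians) about the x, y, z grid axes.
#' @slot translation mm.
#' @slot center rotation centre, mm.
#' @export
setClass("RigidTransform", representation(
  rotation = "numeric", translation = "numeric", center = "numeric"
), prototype(rotation = c(0, 0, 0), translation = c(0, 0, 0),
             center = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  if (length(object@rotation) != 3L || length(object@translation) != 3L ||
      length(object@center) != 3L ||
      any(!is.finite(c(object@rotation, object@translation, object@center))))
    "rotation, translation and center must be finite 3-vectors" else TRUE
})

#' PhantomSpec: parameters of one synthetic head phantom
#'
#' Describes a bilaterally near-symmetric head phantom: skull shell,
#' intracranial cavity with parenchyma/CSF contrast, symmetric aging
#' confounders (periventricular hypoattenuation, widened cortical sulci),
#' and optionally a unilateral hypoattenuated lesion ellipsoid. Intensities
#' are pseudo-HU arbitrary units (parenchyma 35, CSF 5, skull 100); the
#' lesion interior is parenchyma scaled by \code{1 - lesionContrast}.
#'
#' @slot gridShape voxels per axis.
#' @slot spacingMm per-axis voxel size, mm.
#' @slot lesionPresent logical.
#' @slot lesionSide \code{"left"} or \code{"right"}.
#' @slot lesionRadiusMm base semi-axis of the lesion ellipsoid, mm.
#' @slot lesionContrast fractional intensity drop inside the lesion, (0,1).
#' @slot confounderPeriventricular severity in [0,1].
#' @slot confounderSulcal severity in [0,1].
#' @slot noiseSd additive Gaussian noise SD, intensity units.
#' @slot posePerturbation c(max rotation deg, max translation mm) of a random
#'   rigid head-pose perturbation applied to all channels in unison.
#' @slot seed integer RNG seed; identical spec + seed gives bit-identical
#'   volumes.
#' @export
setClass("PhantomSpec", representation(
  gridShape = "integer", spacingMm = "numeric",
  lesionPresent = "logical", lesionSide = "character",
  lesionRadiusMm = "numeric", lesionContrast = "numeric",
  confounderPeriventricular = "numeric", confounderSulcal = "numeric",
  noiseSd = "numeric", posePerturbation = "numeric", seed = "integer"
), prototype(
  gridShape = c(96L, 96L, 64L), spacingMm = c(1.2, 1.2, 1.6),
  lesionPresent = TRUE, lesionSide = "left",
  lesionRadiusMm = 12, lesionContrast = 0.35,
  confounderPeriventricular = 0.5, confounderSulcal = 0.5,
  noiseSd = 2, posePerturbation = c(2, 2), seed = 1L
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 32L))
    msg <- c(msg, "gridShape must be >= 32 voxels per axis")
  if (any(object@spacingMm <= 0)) msg <- c(msg, "spacing must be positive")
  if (!object@lesionSide %in% c("left", "right"))
    msg <- c(msg, "lesionSide must be 'left' or 'right'")
  if (object@lesionContrast <= 0 || object@lesionContrast >= 1)
    msg <- c(msg, "lesionContrast must lie in (0,1)")
  if (object@confounderPeriventricular < 0 || object@confounderPeriventricular > 1 ||
      object@confounderSulcal < 0 || object@confounderSulcal > 1)
    msg <- c(msg, "confounder severities must lie in [0,1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@posePerturbation) != 2L || any(object@posePerturbation < 0))
    msg <- c(msg, "posePerturbation must be c(deg, mm) >= 0")
  if (length(msg)) msg else TRUE
})

#' PhantomCase: one synthetic subject
#'
#' Grid-congruent CTA and NCCT channels, ground-truth lesion and brain
#' masks, the region atlas, and the group label: \code{"A"} (lesioned) or
#' \code{"B"} (confounders only).
#' @export
setClass("PhantomCase", representation(
  id = "character", group = "character",
  cta = "ImageVolume", ncct = "ImageVolume",
  lesionMask = "BinaryMask", brainMask = "BinaryMask",
  atlas = "RegionAtlas", spec = "PhantomSpec"
))

setValidity("PhantomCase", function(object) {
  msg <- character()
  if (!object@group %in% c("A", "B")) msg <- c(msg, "group must be 'A' or 'B'")
  d <- dim(object@cta@values)
  for (s in c("ncct", "lesionMask", "brainMask", "atlas"))
    if (!identical(dim(slot(object, s)@values), d))
      msg <- c(msg, paste0(s, " grid not congruent with cta"))
  nles <- sum(object@lesionMask@values)
  if (object@group == "B" && nles > 0)
    msg <- c(msg, "group B case must have an empty lesion mask")
  if (object@group == "A" && nles == 0)
    msg <- c(msg, "group A case must have a nonempty lesion mask")
  if (length(msg)) msg else TRUE
})

#' RegionContingency: region-level 2x2 counts
#'
#' TN/TP/FN/FP counts of ASPECTS-region positivity calls accumulated over
#' cases; \code{tn+tp+fn+fp} equals 20 x number of cases.
#' @export
setClass("RegionContingency", representation(
  tn = "numeric", tp = "numeric", fn = "numeric", fp = "numeric"
), prototype(tn = 0, tp = 0, fn = 0, fp = 0))

setValidity("RegionContingency", function(object) {
  v <- c(object@tn, object@tp, object@fn, object@fp)
  if (any(v < 0) || any(v != round(v)))
    "counts must be non-negative integers" else TRUE
})
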