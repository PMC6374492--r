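#' @include volume-methods.R
NULL

#' Create a PreprocessConfig
#'
#' Parameters of the input-conditioning chain: isotropic resampling target,
#' interpolation modes, and the rigid-registration settings used when
#' building the hemispheric comparison channel (multi-resolution pyramid of
#' Gaussian smoothing levels, mean-squared-difference metric over the fixed
#' brain mask, derivative-free optimizer with fixed iteration caps).
#'
#' @param targetSpacingMm isotropic output voxel size in mm. Default 1.0
#'   for desk-scale phantoms; set 0.5 to match clinical-resolution use.
#' @param imageInterpolation interpolation for intensity images.
#' @param maskInterpolation interpolation for masks and label volumes.
#' @param pyramidSigmasMm Gaussian smoothing (mm) per pyramid level, coarse
#'   to fine; 0 means no smoothing.
#' @param pyramidMaxIter optimizer iteration cap per level.
#' @param pyramidStride metric point subsampling stride per level.
#' @param tolerance relative convergence tolerance of the optimizer.
#' @param maxMetricPoints cap on mask points entering the metric.
#' @param cropMarginVoxels margin added around the brain bounding box.
#' @param normalizeBeforeComparison if \code{TRUE} (default) the
#'   hemispheric comparison channel is derived from the already-normalized
#'   CTA; if \code{FALSE} it is built from the raw CTA and the CTA's
#'   normalization map applied afterwards.
#' @return object of class \code{PreprocessConfig} (a validated list).
#' @export
preprocessConfig <- function(targetSpacingMm = 1.0,
                             imageInterpolation = c("linear", "nearest"),
                             maskInterpolation = c("nearest", "linear"),
                             pyramidSigmasMm = c(2, 1, 0),
                             pyramidMaxIter = c(500L, 400L, 400L),
                             pyramidStride = c(4L, 2L, 1L),
                             tolerance = 1e-6,
                             maxMetricPoints = 12000L,
                             cropMarginVoxels = 4L,
                             normalizeBeforeComparison = TRUE) {
  if (targetSpacingMm <= 0) stop("targetSpacingMm must be positive")
  nl <- length(pyramidSigmasMm)
  stopifnot(length(pyramidMaxIter) == nl, length(pyramidStride) == nl)
  structure(list(
    targetSpacingMm = targetSpacingMm,
    imageInterpolation = match.arg(imageInterpolation),
    maskInterpolation = match.arg(maskInterpolation),
    pyramidSigmasMm = pyramidSigmasMm,
    pyramidMaxIter = as.integer(pyramidMaxIter),
    pyramidStride = as.integer(pyramidStride),
    tolerance = tolerance,
    maxMetricPoints = as.integer(maxMetricPoints),
    cropMarginVoxels = as.integer(cropMarginVoxels),
    normalizeBeforeComparison = normalizeBeforeComparison
  ), class = "PreprocessConfig")
}

# ---- rigid transforms -------------------------------------------------------

# Rotation matrix Rz(g) Ry(b) Rx(a) for angles c(a, b, g) in radians.
.rotationMatrix <- function(angles) {
  a <- angles[1]; b <- angles[2]; g <- angles[3]
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Euler angles (Rz Ry Rx convention) of a rotation matrix.
.eulerFromMatrix <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(b)) > 1e-8) {
    a <- atan2(R[3, 2], R[3, 3])
    g <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock: fold everything into a
    a <- atan2(-R[2, 3], R[2, 2])
    g <- 0
  }
  c(a, b, g)
}

#' Affine form of a rigid transform
#'
#' Returns the 3x3 matrix \code{M} and offset \code{t0} such that the
#' transform maps a point p to \code{M p + t0}.
#'
#' @param transform a \code{RigidTransform}.
#' @return list with elements \code{M} and \code{t0}.
#' @export
transformMatrix <- function(transform) {
  R <- .rotationMatrix(transform@rotation)
  t0 <- transform@center + transform@translation -
    as.vector(R %*% transform@center)
  list(M = R, t0 = t0)
}

#' Invert a rigid transform
#'
#' @param transform a \code{RigidTransform}.
#' @return the \code{RigidTransform} mapping each point back, i.e.
#'   composing the two maps any point to itself (within numerical
#'   tolerance).
#' @export
invertRigid <- function(transform) {
  R <- .rotationMatrix(transform@rotation)
  Rt <- t(R)
  RigidTransform(rotation = .eulerFromMatrix(Rt),
                 translation = -as.vector(Rt %*% transform@translation),
                 center = transform@center)
}

#' Resample a volume through a rigid transform
#'
#' The output voxel at physical point p takes the input volume's value at
#' the transformed point T(p) (pull-back resampling). The output grid is
#' that of \code{reference} (default: the input's own grid). Points mapping
#' outside the input get \code{background}.
#'
#' @param vol volume to resample.
#' @param transform a \code{RigidTransform}.
#' @param interpolation \code{"linear"} or \code{"nearest"}; use nearest
#'   for masks and label volumes so the value set is preserved.
#' @param reference volume supplying the output grid.
#' @param background fill value outside the input.
#' @return resampled volume of the same class as \code{vol}.
#' @export
applyTransform <- function(vol, transform,
                           interpolation = c("linear", "nearest"),
                           reference = vol, background = 0) {
  interpolation <- match.arg(interpolation)
  mt <- transformMatrix(transform)
  arr <- cpp_resample_affine(vol@values, dim(vol@values), vol@spacing,
                             vol@origin, mt$M, mt$t0,
                             dim(reference@values), reference@spacing,
                             reference@origin,
                             if (interpolation == "linear") 0L else 1L,
                             background, 0L)
  out <- vol
  out@values <- arr
  out@spacing <- reference@spacing
  out@origin <- reference@origin
  validObject(out)
  out
}

#' Resample a volume to a target voxel size
#'
#' Preserves the physical field of view within one voxel; output voxel
#' centres are placed so the first voxel edges of input and output grids
#' coincide. Nearest interpolation preserves the input value set and is
#' used for masks and delineations.
#'
#' @param vol volume to resample.
#' @param targetSpacingMm scalar (isotropic) or 3-vector target spacing.
#' @param interpolation \code{"linear"} or \code{"nearest"}.
#' @return resampled volume of the same class as \code{vol}.
#' @export
resampleVolume <- function(vol, targetSpacingMm,
                           interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  target <- rep_len(as.numeric(targetSpacingMm), 3)
  if (any(target <= 0)) stop("target spacing must be positive")
  d <- dim(vol@values)
  outDim <- pmax(1L, as.integer(round(d * vol@spacing / target)))
  outOrigin <- vol@origin - vol@spacing / 2 + target / 2
  arr <- cpp_resample_affine(vol@values, d, vol@spacing, vol@origin,
                             diag(3), c(0, 0, 0), outDim, target, outOrigin,
                             if (interpolation == "linear") 0L else 1L, 0,
                             1L)
  out <- vol
  out@values <- arr
  out@spacing <- target
  out@origin <- outOrigin
  validObject(out)
  out
}

#' Flip a volume along its left-right axis
#'
#' Reverses the voxel array along the axis whose orientation label is
#' \code{"LR"}; geometry is unchanged, so the flip mirrors the anatomy
#' about the grid's midsagittal plane. Applying it twice restores the
#' input bit-exactly.
#'
#' @param vol an \code{ImageVolume} (or subclass).
#' @return flipped volume, same class.
#' @export
sagittalFlip <- function(vol) {
  ax <- which(vol@orientation == "LR")
  idx <- rep(list(quote(expr = )), 3)
  idx[[ax]] <- rev(seq_len(dim(vol@values)[ax]))
  arr <- do.call(`[`, c(list(vol@values), idx, list(drop = FALSE)))
  out <- vol
  out@values <- arr
  out
}

# ---- brain mask -------------------------------------------------------------

#' Estimate the intracranial mask from a skull-bearing volume
#'
#' Identifies the largest connected low-to-mid-intensity component fully
#' enclosed by the bright skull shell (a component of the sub-threshold
#' voxels that does not touch the volume border), then fills internal
#' holes. The bright threshold is placed between the volume's median and
#' its upper intensity tail.
#'
#' @param vol raw (un-normalized) volume containing a bright skull shell.
#' @return a \code{BinaryMask} on \code{vol}'s grid.
#' @export
estimateBrainMask <- function(vol) {
  v <- vol@values
  d <- dim(v)
  hi <- stats::quantile(v, 0.999, names = FALSE)
  med <- stats::median(v)
  thr <- med + 0.55 * (hi - med)
  dark <- array(as.integer(v < thr), dim = d)
  lab <- cpp_label_components(dark, d, 6L)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border != 0]
  counts <- tabulate(lab)
  counts[border] <- 0
  if (!length(counts) || all(counts == 0))
    stop("no enclosed intracranial component found: empty brain mask",
         call. = FALSE)
  keep <- which.max(counts)
  mask <- lab == keep
  # fill internal holes: complement components not reaching the border
  inv <- array(as.integer(!mask), dim = d)
  ilab <- cpp_label_components(inv, d, 6L)
  iborder <- unique(c(ilab[c(1, d[1]), , ], ilab[, c(1, d[2]), ],
                      ilab[, , c(1, d[3])]))
  iborder <- iborder[iborder != 0]
  hole <- ilab != 0 & !(ilab %in% iborder)
  mask <- mask | hole
  BinaryMask(array(as.numeric(mask), dim = d), spacing = vol@spacing,
             origin = vol@origin, orientation = vol@orientation)
}

#' Standardize intensities within a mask
#'
#' Applies the affine map \code{x -> (x - m) / s} to the whole volume,
#' where m and s are the mean and (population) standard deviation of the
#' in-mask voxels, so in-mask intensities have zero mean and unit variance.
#'
#' @param vol volume to standardize.
#' @param mask \code{BinaryMask}, grid-congruent with \code{vol}.
#' @return the standardized volume, with the map's centre m and scale s in
#'   attributes \code{"center"} and \code{"scale"}.
#' @export
normalizeInMask <- function(vol, mask) {
  .stopIfNotCongruent(vol, mask, "volume and mask")
  inm <- mask@values == 1
  if (!any(inm)) stop("mask is empty", call. = FALSE)
  x <- vol@values[inm]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s < 1e-12)
    stop("degenerate in-mask variance: intensities are constant",
         call. = FALSE)
  out <- .withValues(vol, (vol@values - m) / s)
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

#' Crop a volume to the brain bounding box
#'
#' @param vol volume to crop.
#' @param mask nonempty \code{BinaryMask} defining the region to keep.
#' @param marginVoxels bounding-box dilation per axis, clipped to the grid.
#' @return cropped volume; the origin is updated so physical coordinates of
#'   retained voxels are unchanged.
#' @export
cropToBrain <- function(vol, mask, marginVoxels = 0L) {
  .stopIfNotCongruent(vol, mask, "volume and mask")
  if (!any(mask@values == 1)) stop("mask is empty", call. = FALSE)
  d <- dim(vol@values)
  idx <- which(mask@values == 1)
  ijk <- arrayInd(idx, d)
  lo <- pmax(1L, apply(ijk, 2, min) - marginVoxels)
  hi <- pmin(d, apply(ijk, 2, max) + marginVoxels)
  arr <- vol@values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- vol
  out@values <- arr
  out@origin <- vol@origin + (lo - 1) * vol@spacing
  validObject(out)
  out
}

# ---- rigid registration -----------------------------------------------------

#' Rigid registration by mean-squared intensity difference
#'
#' Finds the 6-DOF transform T minimizing the mean squared difference
#' between the fixed volume and the moving volume sampled at T(p), over
#' physical points p drawn from the fixed brain mask, using a
#' multi-resolution pyramid of Gaussian smoothing levels and a
#' derivative-free simplex optimizer with fixed iteration caps. Suitable
#' for same-modality alignment such as matching the flipped CTA back onto
#' the original.
#'
#' If the optimized metric is no better than the identity transform's, the
#' identity is returned, so registration never degrades alignment.
#'
#' @param moving volume to align.
#' @param fixed reference volume.
#' @param config a \code{\link{preprocessConfig}}.
#' @param mask optional \code{BinaryMask} on the fixed grid; default uses
#'   the whole fixed volume.
#' @return a \code{RigidTransform} with attributes \code{metric} (final
#'   mean squared difference), \code{metricIdentity}, and \code{converged}.
#'   Warns if the optimizer hit its iteration cap on the finest level.
#' @export
rigidRegister <- function(moving, fixed, config = preprocessConfig(),
                          mask = NULL) {
  dF <- dim(fixed@values)
  if (is.null(mask)) {
    inm <- rep(TRUE, prod(dF))
  } else {
    .stopIfNotCongruent(fixed, mask, "fixed volume and mask")
    inm <- mask@values == 1
    if (!any(inm)) stop("mask is empty", call. = FALSE)
  }
  idx <- which(inm)
  if (length(idx) > config$maxMetricPoints)
    idx <- idx[seq(1L, length(idx),
                   length.out = config$maxMetricPoints)]
  ijk <- arrayInd(idx, dF)
  pts <- t(sweep(ijk - 1, 2, fixed@spacing, `*`) +
             matrix(fixed@origin, nrow(ijk), 3, byrow = TRUE))
  center <- rowMeans(pts)
  par <- rep(0, 6)  # c(rot deg, trans mm)
  metricAt <- function(par, movVals, fixVals, pick) {
    tf <- RigidTransform(par[1:3] * pi / 180, par[4:6], center)
    mt <- transformMatrix(tf)
    r <- cpp_msd_metric(fixVals[pick], pts[, pick, drop = FALSE],
                        movVals, dim(moving@values), moving@spacing,
                        moving@origin, mt$M, mt$t0)
    if (r[2] < max(10, 0.25 * sum(pick))) 1e10 else r[1]
  }
  converged <- TRUE
  for (lev in seq_along(config$pyramidSigmasMm)) {
    sig <- config$pyramidSigmasMm[lev]
    movVals <- if (sig > 0)
      cpp_gauss_blur(moving@values, dim(moving@values), sig / moving@spacing)
    else moving@values
    fixBlur <- if (sig > 0)
      cpp_gauss_blur(fixed@values, dF, sig / fixed@spacing)
    else fixed@values
    fixVals <- fixBlur[idx]
    pick <- seq(1L, length(idx)) %% config$pyramidStride[lev] == 0L
    if (!any(pick)) pick <- rep(TRUE, length(idx))
    opt <- stats::optim(par, metricAt, movVals = movVals, fixVals = fixVals,
                        pick = pick, method = "Nelder-Mead",
                        control = list(maxit = config$pyramidMaxIter[lev],
                                       reltol = config$tolerance))
    par <- opt$par
    converged <- opt$convergence == 0
  }
  finest <- length(config$pyramidSigmasMm)
  movVals <- moving@values
  fixVals <- fixed@values[idx]
  pickAll <- rep(TRUE, length(idx))
  mFinal <- metricAt(par, movVals, fixVals, pickAll)
  mIdent <- metricAt(rep(0, 6), movVals, fixVals, pickAll)
  if (mFinal > mIdent) {
    par <- rep(0, 6)
    mFinal <- mIdent
  }
  if (!converged)
    warning(sprintf(
      "rigid registration hit its iteration cap; final metric %.6g", mFinal))
  out <- RigidTransform(par[1:3] * pi / 180, par[4:6], center)
  attr(out, "metric") <- mFinal
  attr(out, "metricIdentity") <- mIdent
  attr(out, "converged") <- converged
  out
}

#' Build the hemispheric comparison channel
#'
#' Flips the CTA left-right and rigidly registers the flipped volume back
#' onto the original, giving each voxel its approximate contralateral
#' homolog as an extra input channel. For a perfectly symmetric head the
#' result equals the input up to noise; in a lesioned head the comparison
#' channel is brighter than the original inside the lesion (the healthy
#' homolog shows no hypoattenuation).
#'
#' @param cta the (typically normalized) CTA volume.
#' @param mask intracranial \code{BinaryMask} on the CTA grid.
#' @param config a \code{\link{preprocessConfig}}.
#' @return the comparison \code{ImageVolume}, with the registration
#'   \code{RigidTransform} in attribute \code{"registration"}.
#' @export
makeHemisphericComparison <- function(cta, mask,
                                      config = preprocessConfig()) {
  flipped <- sagittalFlip(cta)
  tf <- rigidRegister(flipped, cta, config, mask)
  comp <- applyTransform(flipped, tf, "linear", reference = cta)
  attr(comp, "registration") <- tf
  comp
}

# ---- whole-case chain -------------------------------------------------------

#' Preprocess a phantom case for network training and inference
#'
#' The full input-conditioning chain: estimate the intracranial mask from
#' the raw CTA, crop all channels to the brain bounding box (plus margin),
#' resample to the isotropic target spacing (linear for images, nearest for
#' masks and the atlas), standardize intensities inside the brain mask, and
#' construct the hemispheric comparison channel from the normalized CTA
#' (configurable). All outputs are grid-congruent.
#'
#' @param case a \code{PhantomCase}.
#' @param config a \code{\link{preprocessConfig}}.
#' @param useTrueBrainMask use the phantom's ground-truth brain mask
#'   instead of the estimate (default \code{FALSE}).
#' @return a list of class \code{PreprocessedCase}: \code{id},
#'   \code{group}, channels \code{cta}, \code{flip}, \code{ncct}
#'   (normalized, grid-congruent), \code{brainMask}, \code{lesionMask},
#'   \code{atlas}, and \code{log} (per-case registration metric and
#'   convergence lines).
#' @export
preprocessCase <- function(case, config = preprocessConfig(),
                           useTrueBrainMask = FALSE) {
  log <- character()
  brain <- if (useTrueBrainMask) case@brainMask else
    estimateBrainMask(case@cta)
  m <- config$cropMarginVoxels
  cta <- cropToBrain(case@cta, brain, m)
  ncct <- cropToBrain(case@ncct, brain, m)
  lesion <- cropToBrain(case@lesionMask, brain, m)
  atlas <- cropToBrain(case@atlas, brain, m)
  brainC <- cropToBrain(brain, brain, m)
  ts <- config$targetSpacingMm
  cta <- resampleVolume(cta, ts, config$imageInterpolation)
  ncct <- resampleVolume(ncct, ts, config$imageInterpolation)
  lesion <- resampleVolume(lesion, ts, config$maskInterpolation)
  atlas <- resampleVolume(atlas, ts, config$maskInterpolation)
  brainC <- resampleVolume(brainC, ts, config$maskInterpolation)
  normC <- normalizeInMask(cta, brainC)
  normN <- normalizeInMask(ncct, brainC)
  if (config$normalizeBeforeComparison) {
    flip <- makeHemisphericComparison(normC, brainC, config)
  } else {
    raw <- makeHemisphericComparison(cta, brainC, config)
    flip <- .withValues(raw, (raw@values - attr(normC, "center")) /
                          attr(normC, "scale"))
    attr(flip, "registration") <- attr(raw, "registration")
  }
  tf <- attr(flip, "registration")
  log <- c(log, sprintf(
    "case=%s registration metric=%.6g identity=%.6g converged=%s",
    case@id, attr(tf, "metric"), attr(tf, "metricIdentity"),
    attr(tf, "converged")))
  structure(list(id = case@id, group = case@group,
                 cta = normC, flip = flip, ncct = normN,
                 brainMask = brainC, lesionMask = lesion, atlas = atlas,
                 log = log),
            class = "PreprocessedCase")
}
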