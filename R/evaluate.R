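#' @include volume-methods.R
NULL

#' Threshold a probability map
#'
#' A voxel is positive iff its probability is greater than or equal to the
#' threshold (ties at the threshold are positive).
#'
#' @param p a \code{ProbabilityMap}.
#' @param t threshold in [0, 1]; 0.5 is the conservative default used for
#'   labelling voxels as lesion-positive.
#' @return a \code{BinaryMask} on the same grid.
#' @export
thresholdMap <- function(p, t = 0.5) {
  stopifnot(t >= 0, t <= 1)
  BinaryMask(array(as.numeric(p@values >= t), dim(p@values)),
             spacing = p@spacing, origin = p@origin,
             orientation = p@orientation)
}

#' Voxel-wise overlap metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and Dice coefficient
#' 2TP/(2TP+FP+FN), counted over the voxels inside \code{mask} only.
#' With an empty truth the sensitivity is undefined (\code{NaN}, with a
#' \code{reason} attribute) and the DSC is 1 if the prediction is also
#' empty, else 0.
#'
#' @param pred,truth \code{BinaryMask}s.
#' @param mask evaluation region \code{BinaryMask}.
#' @return list with \code{sensitivity}, \code{specificity}, \code{dsc}
#'   and the voxel counts \code{tp}, \code{tn}, \code{fp}, \code{fn}.
#' @export
voxelMetrics <- function(pred, truth, mask) {
  .stopIfNotCongruent(pred, truth, "pred and truth")
  .stopIfNotCongruent(pred, mask, "pred and mask")
  inm <- mask@values == 1
  p <- pred@values[inm] == 1
  g <- truth@values[inm] == 1
  tp <- sum(p & g); fp <- sum(p & !g)
  fn <- sum(!p & g); tn <- sum(!p & !g)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    s <- NaN; attr(s, "reason") <- "empty truth: no positive voxels"; s
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else NaN
  dsc <- if (tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  list(sensitivity = sens, specificity = spec, dsc = dsc,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' ROC curve over a threshold sweep
#'
#' Sweeps all distinct probability values (plus 0 and 1) with the same
#' >= tie rule as \code{\link{thresholdMap}}, over in-mask voxels, and
#' integrates the area under the curve by the trapezoidal rule. The curve
#' includes the (0,0) and (1,1) endpoints and its FPR is non-decreasing.
#'
#' @param p a \code{ProbabilityMap}.
#' @param truth ground-truth \code{BinaryMask}.
#' @param mask evaluation region \code{BinaryMask}.
#' @return list with \code{fpr}, \code{tpr}, \code{thresholds},
#'   \code{auc}.
#' @export
rocCurve <- function(p, truth, mask) {
  .stopIfNotCongruent(p, truth, "map and truth")
  .stopIfNotCongruent(p, mask, "map and mask")
  inm <- mask@values == 1
  s <- p@values[inm]
  g <- truth@values[inm] == 1
  nP <- sum(g); nN <- sum(!g)
  if (nP == 0 || nN == 0)
    stop("ROC needs at least one positive and one negative voxel in mask",
         call. = FALSE)
  ord <- order(s, decreasing = TRUE)
  sSort <- s[ord]; gSort <- g[ord]
  cumTp <- cumsum(gSort); cumFp <- cumsum(!gSort)
  # one operating point per distinct score t: positives are voxels >= t
  last <- cumsum(rle(sSort)$lengths)
  thrPts <- sSort[last]
  tpr <- cumTp[last] / nP
  fpr <- cumFp[last] / nN
  # endpoints: a threshold above every score (empty positive set, also the
  # t = 1 sweep point when max(s) < 1) and t = 0 (everything positive)
  fpr <- c(0, fpr); tpr <- c(0, tpr); thr <- c(1, thrPts)
  if (fpr[length(fpr)] != 1 || tpr[length(tpr)] != 1) {
    fpr <- c(fpr, 1); tpr <- c(tpr, 1); thr <- c(thr, 0)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc)
}

#' Region-level positivity calls
#'
#' A region is stroke-positive iff at least one predicted-positive voxel
#' carries that region's atlas label. Regions whose label is absent from
#' the atlas volume are reported negative with a warning.
#'
#' @param pred a \code{BinaryMask}.
#' @param atlas a \code{RegionAtlas}.
#' @return named logical vector, one entry per labelTable row (20 for the
#'   standard ASPECTS-analog atlas), ordered as the label table.
#' @export
regionPositivity <- function(pred, atlas) {
  .stopIfNotCongruent(pred, atlas, "pred and atlas")
  lt <- atlas@labelTable
  present <- unique(as.vector(atlas@values))
  missing <- setdiff(lt$label, present)
  if (length(missing))
    warning(sprintf("atlas labels absent from volume: %s",
                    paste(missing, collapse = ", ")))
  labAt <- atlas@values[pred@values == 1]
  pos <- lt$label %in% labAt
  names(pos) <- paste(lt$side, lt$region, sep = ".")
  pos
}

#' Construct / accumulate a region contingency table
#'
#' Element-wise 2x2 tally of predicted vs true region positivity,
#' accumulated over cases.
#'
#' @param predRegions,truthRegions logical vectors (or equal-shaped
#'   matrices/lists of per-case vectors).
#' @return a \code{RegionContingency}.
#' @export
regionContingency <- function(predRegions, truthRegions) {
  if (is.list(predRegions)) predRegions <- do.call(c, predRegions)
  if (is.list(truthRegions)) truthRegions <- do.call(c, truthRegions)
  p <- as.logical(predRegions); g <- as.logical(truthRegions)
  if (length(p) != length(g))
    stop("prediction and truth region vectors differ in length",
         call. = FALSE)
  new("RegionContingency",
      tp = sum(p & g), fp = sum(p & !g),
      fn = sum(!p & g), tn = sum(!p & !g))
}

#' Counts accessor
#' @param x a \code{RegionContingency}.
#' @return named numeric vector tn/tp/fn/fp.
#' @export
contingencyCounts <- function(x) {
  c(tn = x@tn, tp = x@tp, fn = x@fn, fp = x@fp)
}

# Half-up rounding to 2 decimals, the convention used when comparing with
# printed values.
.round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Metrics from a region contingency table
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and region-count Dice
#' 2TP/(2TP+FP+FN). Metrics with zero denominator are \code{NaN} with a
#' reason attribute. Values are reported at full precision together with
#' the half-up 2-decimal rounding used for comparison against printed
#' tables.
#'
#' @param x a \code{RegionContingency} (or anything accepted by
#'   \code{\link{regionContingency}} pairs via \code{tn,tp,fn,fp}
#'   arguments).
#' @return list with \code{sensitivity}, \code{specificity}, \code{dsc}
#'   and \code{rounded} (the three metrics rounded to 2 decimals).
#' @export
metricsFromContingency <- function(x) {
  stopifnot(is(x, "RegionContingency"))
  mk <- function(num, den, what) {
    if (den > 0) num / den else {
      v <- NaN; attr(v, "reason") <- paste0(what, ": zero denominator"); v
    }
  }
  sens <- mk(x@tp, x@tp + x@fn, "sensitivity")
  spec <- mk(x@tn, x@tn + x@fp, "specificity")
  dsc <- mk(2 * x@tp, 2 * x@tp + x@fp + x@fn, "dsc")
  list(sensitivity = sens, specificity = spec, dsc = dsc,
       rounded = c(sensitivity = .round2(sens), specificity = .round2(spec),
                   dsc = .round2(dsc)))
}

#' Combined Dice over lesioned and lesion-free groups
#'
#' Pools the lesioned-group contingency with the false positives
#' contributed by the lesion-free group (which adds only TN/FP regions):
#' DSC = 2TP / (2TP + FP_A + FP_B + FN).
#'
#' @param contingencyA \code{RegionContingency} of the lesioned group.
#' @param fpGroupB false-positive region count of the lesion-free group.
#' @return list with \code{dsc} and its 2-decimal rounding.
#' @export
combinedDsc <- function(contingencyA, fpGroupB) {
  stopifnot(fpGroupB >= 0)
  den <- 2 * contingencyA@tp + contingencyA@fp + fpGroupB + contingencyA@fn
  if (den == 0) {
    v <- NaN; attr(v, "reason") <- "zero denominator"
    return(list(dsc = v, rounded = NaN))
  }
  d <- 2 * contingencyA@tp / den
  list(dsc = d, rounded = .round2(d))
}

#' ASPECTS score from region positivity
#'
#' Ten points per hemisphere minus the number of stroke-positive regions in
#' that hemisphere; the reported score is the minimum (worst) hemisphere.
#'
#' @param regionPositives 20-entry logical vector ordered as the standard
#'   label table (left regions 1-10, right 11-20).
#' @return integer score, 0-10.
#' @export
aspectsScore <- function(regionPositives) {
  stopifnot(length(regionPositives) == 20)
  left <- sum(regionPositives[1:10])
  right <- sum(regionPositives[11:20])
  as.integer(min(10 - left, 10 - right))
}

#' Largest connected lesion component volume
#'
#' Labels the mask's connected components (26-neighbourhood) and returns
#' the physical volume of the largest, in cm^3; 0 for an empty mask.
#'
#' @param mask a \code{BinaryMask} with known voxel spacing.
#' @return volume in cm^3.
#' @export
largestComponentVolume <- function(mask) {
  m <- array(as.integer(mask@values == 1), dim(mask@values))
  if (!any(m == 1)) return(0)
  lab <- cpp_label_components(m, dim(m), 26L)
  counts <- tabulate(lab)
  max(counts) * prod(mask@spacing) / 1000
}

#' Evaluate one predicted case at both levels
#'
#' Voxel-wise metrics at the given threshold, the region positivity
#' vectors (prediction and truth), ASPECTS scores, and the
#' largest-component volume of the thresholded prediction.
#'
#' @param prob a \code{ProbabilityMap}.
#' @param truth lesion \code{BinaryMask}.
#' @param mask intracranial \code{BinaryMask}.
#' @param atlas a \code{RegionAtlas}.
#' @param threshold probability threshold (default 0.5).
#' @return list with \code{voxel} (see \code{\link{voxelMetrics}}),
#'   \code{predRegions}, \code{truthRegions}, \code{aspectsPred},
#'   \code{aspectsTruth}, \code{volumeCm3}.
#' @export
evaluateCase <- function(prob, truth, mask, atlas, threshold = 0.5) {
  pred <- thresholdMap(prob, threshold)
  vox <- voxelMetrics(pred, truth, mask)
  pr <- regionPositivity(pred, atlas)
  tr <- regionPositivity(truth, atlas)
  list(voxel = vox, predRegions = pr, truthRegions = tr,
       aspectsPred = aspectsScore(pr), aspectsTruth = aspectsScore(tr),
       volumeCm3 = largestComponentVolume(pred))
}
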