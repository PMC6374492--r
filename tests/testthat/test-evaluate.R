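# Brute-force oracles used to check the evaluation implementations on
# random instances.
bruteVoxelCounts <- function(pred, truth, mask) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  d <- dim(imageData(pred))
  for (i in seq_len(prod(d))) {
    if (imageData(mask)[i] != 1) next
    p <- imageData(pred)[i] == 1
    g <- imageData(truth)[i] == 1
    if (p && g) tp <- tp + 1 else if (p) fp <- fp + 1
    else if (g) fn <- fn + 1 else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Pairwise-ranking (concordance) AUC with ties counted half.
concordanceAuc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

test_that("threshold tie rule marks values at the threshold positive", {
  p <- ProbabilityMap(array(c(0.49, 0.5, 0.51, 0, 1, 0.2, 0.8, 0.5),
                            c(2, 2, 2)))
  m <- thresholdMap(p, 0.5)
  expect_identical(as.vector(imageData(m)), c(0, 1, 1, 0, 1, 0, 1, 1))
  expect_true(all(imageData(thresholdMap(p, 0)) == 1))
  pm <- ProbabilityMap(array(0.9, c(2, 2, 2)))
  expect_true(all(imageData(thresholdMap(pm, 1)) == 0))
})

test_that("voxel metrics equal a brute-force recount on random masks", {
  d <- c(20, 20, 20)
  for (seed in 1:3) {
    pred <- randomMask(d, 0.3, seed)
    truth <- randomMask(d, 0.2, seed + 10)
    mask <- randomMask(d, 0.8, seed + 20)
    vm <- voxelMetrics(pred, truth, mask)
    cnt <- bruteVoxelCounts(pred, truth, mask)
    expect_equal(c(tp = vm$tp, fp = vm$fp, fn = vm$fn, tn = vm$tn), cnt)
    expect_equal(vm$sensitivity, cnt["tp"] / (cnt["tp"] + cnt["fn"]),
                 ignore_attr = TRUE)
    expect_equal(vm$specificity, cnt["tn"] / (cnt["tn"] + cnt["fp"]),
                 ignore_attr = TRUE)
    expect_equal(vm$dsc,
                 2 * cnt["tp"] / (2 * cnt["tp"] + cnt["fp"] + cnt["fn"]),
                 ignore_attr = TRUE)
  }
})

test_that("voxel metric edge conventions: identical, disjoint, empty truth", {
  d <- c(6, 6, 6)
  all1 <- BinaryMask(array(1, d))
  a <- randomMask(d, 0.4, 1)
  expect_equal(voxelMetrics(a, a, all1)$dsc, 1)
  b <- BinaryMask(array(1 - imageData(a), d))
  expect_equal(voxelMetrics(a, b, all1)$dsc, 0)
  empty <- BinaryMask(array(0, d))
  vm <- voxelMetrics(a, empty, all1)
  expect_true(is.nan(vm$sensitivity))
  expect_match(attr(vm$sensitivity, "reason"), "empty truth")
  expect_equal(vm$dsc, 0)
  expect_equal(voxelMetrics(empty, empty, all1)$dsc, 1)
})

test_that("ROC agrees with the concordance oracle and handles edge shapes", {
  d <- c(8, 8, 8)
  mask <- BinaryMask(array(1, d))
  set.seed(42)
  for (rep in 1:3) {
    s <- array(round(runif(prod(d)), 2), d)   # ties on purpose
    g <- array(rbinom(prod(d), 1, 0.3), d)
    roc <- rocCurve(ProbabilityMap(s), BinaryMask(g), mask)
    expect_equal(roc$auc, concordanceAuc(as.vector(s), as.vector(g) == 1),
                 tolerance = 1e-9)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[length(roc$fpr)], 1)
    expect_equal(roc$tpr[length(roc$tpr)], 1)
  }
  # probabilities equal to the labels give AUC 1
  g <- array(rbinom(prod(d), 1, 0.4), d)
  expect_equal(rocCurve(ProbabilityMap(g), BinaryMask(g), mask)$auc, 1)
  # label-independent probabilities give AUC ~ 0.5 (permutation oracle)
  s <- array(runif(prod(d)), d)
  aucs <- replicate(20, {
    gp <- array(sample(as.vector(g)), d)
    rocCurve(ProbabilityMap(s), BinaryMask(gp), mask)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # single-class truth errors
  expect_error(rocCurve(ProbabilityMap(s), BinaryMask(array(1, d)), mask),
               "positive and .* negative")
})

test_that("ROC AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  d <- c(10, 10, 10)
  set.seed(7)
  s <- array(runif(prod(d)), d)
  g <- array(rbinom(prod(d), 1, 0.25), d)
  mine <- rocCurve(ProbabilityMap(s), BinaryMask(g),
                   BinaryMask(array(1, d)))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(as.vector(g), as.vector(s),
                                        quiet = TRUE, direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("region positivity matches per-label brute force and is monotone", {
  cs <- smallLesioned()
  atlas <- cs@atlas
  d <- dim(imageData(atlas))
  pred <- randomMask(d, 0.002, 99)
  pred@spacing <- voxelSpacing(atlas)
  pos <- regionPositivity(pred, atlas)
  lt <- labelTable(atlas)
  for (k in seq_len(nrow(lt))) {
    expected <- any(imageData(pred)[imageData(atlas) == lt$label[k]] == 1)
    expect_identical(unname(pos[k]), expected)
  }
  # empty prediction: all 20 negative
  emptyP <- BinaryMask(array(0, d), spacing = voxelSpacing(atlas))
  expect_false(any(regionPositivity(emptyP, atlas)))
  # single voxel in a known region flags exactly that region
  lab <- lt$label[lt$region == "M3" & lt$side == "left"]
  i <- which(imageData(atlas) == lab)[1]
  oneP <- array(0, d); oneP[i] <- 1
  pos1 <- regionPositivity(BinaryMask(oneP, spacing = voxelSpacing(atlas)),
                           atlas)
  expect_equal(unname(which(pos1)), which(lt$label == lab))
  # monotone: adding voxels never clears a region
  more <- imageData(pred); more[i] <- 1
  pos2 <- regionPositivity(BinaryMask(more, spacing = voxelSpacing(atlas)),
                           atlas)
  expect_true(all(pos2[pos]))
})

test_that("contingency tallies accumulate and error on length mismatch", {
  set.seed(3)
  pred <- lapply(1:5, function(i) runif(20) < 0.3)
  truth <- lapply(1:5, function(i) runif(20) < 0.3)
  ct <- regionContingency(pred, truth)
  p <- unlist(pred); g <- unlist(truth)
  expect_equal(contingencyCounts(ct),
               c(tn = sum(!p & !g), tp = sum(p & g),
                 fn = sum(!p & g), fp = sum(p & !g)))
  expect_equal(sum(contingencyCounts(ct)), 100)
  # identical vectors: TP = k, no errors
  k <- sum(truth[[1]])
  ct2 <- regionContingency(truth[1], truth[1])
  expect_equal(contingencyCounts(ct2),
               c(tn = 20 - k, tp = k, fn = 0, fp = 0))
  # all-negative truth with j positive predictions gives FP = j
  j <- sum(pred[[1]])
  ct3 <- regionContingency(pred[1], list(rep(FALSE, 20)))
  expect_equal(contingencyCounts(ct3)[["fp"]], j)
  expect_error(regionContingency(list(rep(TRUE, 20)), list(rep(TRUE, 19))),
               "length")
})

test_that("contingency metrics reproduce the published region counts", {
  # printed counts for the three input-feature experiments
  rows <- list(
    list(tn = 78, tp = 99, fn = 6, fp = 117, fpB = 92,
         sens = 0.94, spec = 0.40, dsc = 0.62, comb = 0.48),
    list(tn = 158, tp = 98, fn = 7, fp = 37, fpB = 46,
         sens = 0.93, spec = 0.81, dsc = 0.82, comb = 0.69),
    list(tn = 159, tp = 98, fn = 7, fp = 36, fpB = 34,
         sens = 0.93, spec = 0.82, dsc = 0.82, comb = 0.72))
  for (r in rows) {
    ct <- new("RegionContingency", tn = r$tn, tp = r$tp, fn = r$fn,
              fp = r$fp)
    m <- metricsFromContingency(ct)
    expect_equal(unname(m$rounded["sensitivity"]), r$sens)
    expect_equal(unname(m$rounded["specificity"]), r$spec)
    expect_equal(unname(m$rounded["dsc"]), r$dsc)
    expect_equal(combinedDsc(ct, r$fpB)$rounded, r$comb)
    # counts cover 15 subjects x 20 regions
    expect_identical(sum(contingencyCounts(ct)), 300)
  }
  # reduction: no group-B false positives leaves the group-A DSC
  ct <- new("RegionContingency", tn = 158, tp = 98, fn = 7, fp = 37)
  expect_equal(combinedDsc(ct, 0)$dsc, metricsFromContingency(ct)$dsc)
  # undefined metrics are flagged
  ct0 <- new("RegionContingency", tn = 300, tp = 0, fn = 0, fp = 0)
  m0 <- metricsFromContingency(ct0)
  expect_equal(m0$specificity, 1)
  expect_true(is.nan(m0$sensitivity))
})

test_that("ASPECTS scoring follows the worst-hemisphere rule", {
  none <- rep(FALSE, 20)
  expect_identical(aspectsScore(none), 10L)
  left3 <- none; left3[c(1, 5, 9)] <- TRUE
  expect_identical(aspectsScore(left3), 7L)
  expect_identical(aspectsScore(rep(TRUE, 20)), 0L)
  # weakly decreasing as positives accumulate
  v <- none; prev <- 10L
  for (i in sample(1:20)) {
    v[i] <- TRUE
    s <- aspectsScore(v)
    expect_lte(s, prev)
    prev <- s
  }
  expect_identical(prev, 0L)
})

test_that("largest-component volume matches an independent flood fill", {
  cube <- array(0, c(20, 20, 20))
  cube[5:14, 5:14, 5:14] <- 1
  expect_equal(largestComponentVolume(BinaryMask(cube)), 1.0)
  # two components: only the larger counts
  two <- array(0, c(30, 10, 10))
  two[1:5, 1:4, 1:5] <- 1    # 100 voxels
  two[20:24, 1:2, 1:5] <- 1  # 50 voxels
  expect_equal(largestComponentVolume(BinaryMask(two)), 100 / 1000)
  expect_equal(largestComponentVolume(BinaryMask(array(0, c(5, 5, 5)))), 0)
  # random blob field vs a brute-force BFS flood fill (26-connectivity)
  set.seed(31)
  d <- c(12, 12, 12)
  m <- array(rbinom(prod(d), 1, 0.25), d)
  floodLargest <- function(m) {
    d <- dim(m); seen <- array(FALSE, d); best <- 0
    for (s in which(m == 1)) {
      if (seen[s]) next
      stack <- s; seen[s] <- TRUE; size <- 0
      while (length(stack)) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        size <- size + 1
        ijk <- arrayInd(cur, d)
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          n <- ijk + c(dx, dy, dz)
          if (any(n < 1) || any(n > d)) next
          li <- n[1] + d[1] * (n[2] - 1 + d[2] * (n[3] - 1))
          if (m[li] == 1 && !seen[li]) { seen[li] <- TRUE
            stack <- c(stack, li) }
        }
      }
      best <- max(best, size)
    }
    best
  }
  expect_equal(largestComponentVolume(BinaryMask(m, spacing = c(1, 1, 1))),
               floodLargest(m) / 1000)
})

test_that("evaluateCase ties the levels together on a phantom", {
  pp <- smallLesionedPP()
  # a synthetic probability map: the truth blurred, plus noise
  set.seed(5)
  tr <- imageData(pp$lesionMask)
  pr <- 0.9 * tr + 0.05
  ev <- evaluateCase(ProbabilityMap(array(pr, dim(tr)),
                                    spacing = voxelSpacing(pp$lesionMask),
                                    origin = volumeOrigin(pp$lesionMask)),
                     pp$lesionMask, pp$brainMask, pp$atlas)
  expect_equal(ev$voxel$dsc, 1)
  expect_identical(ev$predRegions, ev$truthRegions)
  expect_identical(ev$aspectsPred, ev$aspectsTruth)
  expect_lte(ev$aspectsTruth, 10L)
})
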