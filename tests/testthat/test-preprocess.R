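test_that("estimated brain mask matches the phantom ground truth", {
  cs <- smallLesioned()
  est <- estimateBrainMask(cs@cta)
  inter <- sum(imageData(est) * imageData(cs@brainMask))
  dsc <- 2 * inter / (sum(imageData(est)) + sum(imageData(cs@brainMask)))
  expect_gte(dsc, 0.95)
  # single connected component
  lab <- ctastroke:::cpp_label_components(
    array(as.integer(imageData(est)), dim(imageData(est))),
    dim(imageData(est)), 6L)
  expect_identical(max(lab), 1L)
})

test_that("a volume without an enclosed cavity gives an empty-mask error", {
  flat <- ImageVolume(array(0, c(40, 40, 40)))
  expect_error(estimateBrainMask(flat), "empty")
})

test_that("in-mask standardization has zero mean, unit variance, idempotence", {
  cs <- smallLesioned()
  mask <- cs@brainMask
  norm <- normalizeInMask(cs@cta, mask)
  x <- imageData(norm)[imageData(mask) == 1]
  expect_lt(abs(mean(x)), 1e-6)
  expect_lt(abs(mean(x^2) - 1), 1e-6)
  # idempotence
  norm2 <- normalizeInMask(norm, mask)
  expect_equal(imageData(norm2), imageData(norm), tolerance = 1e-9)
  # hand-computed oracle: values {1,3} equally frequent -> x -> (x - 2) / 1
  v <- ImageVolume(array(c(1, 3), c(4, 4, 2)))
  m <- BinaryMask(array(1, c(4, 4, 2)))
  out <- normalizeInMask(v, m)
  expect_equal(imageData(out), imageData(v) - 2, tolerance = 1e-12)
  # constant intensities are degenerate
  expect_error(normalizeInMask(ImageVolume(array(7, c(4, 4, 2))), m),
               "degenerate")
})

test_that("resampling preserves identity, constants and ramp endpoints", {
  cs <- smallLesioned()
  same <- resampleVolume(cs@cta, voxelSpacing(cs@cta))
  expect_equal(imageData(same), imageData(cs@cta), tolerance = 1e-9)
  const <- ImageVolume(array(3, c(20, 20, 20)), spacing = c(2, 2, 2))
  down <- resampleVolume(const, 1.5)
  expect_true(all(abs(imageData(down) - 3) < 1e-9))
  # linear ramp: output values must equal the analytic interpolation of the
  # ramp at the new sample positions (clamped at the edges)
  n <- 20
  ramp <- ImageVolume(array(rep(seq_len(n), times = n * n), c(n, n, n)),
                      spacing = c(2, 2, 2))
  res <- resampleVolume(ramp, c(1.25, 2, 2))
  pos <- (volumeOrigin(res)[1] + (seq_len(dim(res)[1]) - 1) * 1.25) / 2 + 1
  expected <- pmin(pmax(pos, 1), n)
  expect_equal(imageData(res)[, 1, 1], expected, tolerance = 1e-9)
  expect_equal(imageData(res)[1, 1, 1], 1, tolerance = 1e-9)
  expect_equal(imageData(res)[dim(res)[1], 1, 1], n, tolerance = 1e-9)
  # nearest mode preserves the binary value set
  resM <- resampleVolume(cs@lesionMask, 1.1, "nearest")
  expect_true(all(imageData(resM) %in% c(0, 1)))
  expect_error(resampleVolume(cs@cta, -1), "positive")
})

test_that("sagittal flip is an exact involution with the index map i -> n+1-i", {
  cs <- smallLesioned()
  expect_identical(imageData(sagittalFlip(sagittalFlip(cs@cta))),
                   imageData(cs@cta))
  v <- imageData(cs@cta)
  f <- imageData(sagittalFlip(cs@cta))
  n <- dim(v)[1]
  i <- 7L
  expect_identical(f[i, , ], v[n + 1L - i, , ])
})

test_that("rigid transforms compose, invert and round-trip", {
  tf <- RigidTransform(rotation = c(0.03, -0.02, 0.05),
                       translation = c(4, -2, 1), center = c(10, 20, 30))
  inv <- invertRigid(tf)
  mt <- transformMatrix(tf); mi <- transformMatrix(inv)
  p <- c(33, -12, 7)
  q <- mi$M %*% (mt$M %*% p + mt$t0) + mi$t0
  expect_equal(as.vector(q), p, tolerance = 1e-12)
  # identity transform resampling is exact up to interpolation
  cs <- smallLesioned()
  idt <- applyTransform(cs@cta, RigidTransform())
  expect_equal(imageData(idt), imageData(cs@cta), tolerance = 1e-9)
  # t then t^-1 returns the original within interpolation tolerance; use a
  # smooth field so the oracle is dominated by transform error rather than
  # edge blurring
  set.seed(4)
  smooth <- ctastroke:::cpp_gauss_blur(array(rnorm(40^3), c(40, 40, 40)),
                                       c(40L, 40L, 40L), c(2, 2, 2))
  sv <- ImageVolume(smooth * (10 / sd(smooth)))
  moved <- applyTransform(sv, tf)
  back <- applyTransform(moved, inv)
  core <- as.logical(seq_len(40^3) * 0); dim(core) <- c(40, 40, 40)
  core[8:32, 8:32, 8:32] <- TRUE  # interior, unaffected by background fill
  err <- (imageData(back) - imageData(sv))[core]
  expect_lt(sqrt(mean(err^2)), 0.1 * 10)
  # nearest mode preserves label sets
  atl <- applyTransform(cs@atlas, tf, "nearest")
  expect_true(all(imageData(atl) %in% 0:20))
})

test_that("registration recovers a known rigid perturbation within 1 deg / 1 mm", {
  cs <- fixture("regPhantom", function()
    generatePhantom(PhantomSpec(posePerturbation = c(0, 0), seed = 17L)))
  truth <- cs@brainMask
  ctr <- colMeans(which(imageData(truth) == 1, arr.ind = TRUE) - 1) *
    voxelSpacing(truth)
  tf <- RigidTransform(rotation = c(0, 0, 3 * pi / 180),
                       translation = c(4, 0, 0), center = ctr)
  moved <- applyTransform(cs@cta, tf)
  rec <- suppressWarnings(
    rigidRegister(moved, cs@cta, preprocessConfig(), mask = truth))
  # the recovered transform must equal the inverse of the applied one
  expected <- invertRigid(tf)
  mr <- transformMatrix(rec); me <- transformMatrix(expected)
  relRot <- mr$M %*% t(me$M)
  angleErr <- acos(pmin(1, (sum(diag(relRot)) - 1) / 2)) * 180 / pi
  expect_lt(angleErr, 1)
  pts <- which(imageData(truth) == 1, arr.ind = TRUE)[c(1, 5000, 20000), ] - 1
  pts <- sweep(pts, 2, voxelSpacing(truth), `*`)
  errs <- apply(pts, 1, function(p)
    sqrt(sum((mr$M %*% p + mr$t0 - (me$M %*% p + me$t0))^2)))
  expect_lt(max(errs), 1)
  # optimizer contract: final metric no worse than identity
  expect_lte(attr(rec, "metric"), attr(rec, "metricIdentity"))
})

test_that("registering a volume to itself stays at the identity", {
  cs <- smallLesioned()
  rec <- suppressWarnings(rigidRegister(cs@cta, cs@cta, smallPreprocConfig(),
                                        mask = cs@brainMask))
  expect_lt(max(abs(rec@rotation)) * 180 / pi, 0.5)
  expect_lt(max(abs(rec@translation)), 0.75)  # half a 1.5 mm voxel
})

test_that("hemispheric comparison equals the original for a symmetric head", {
  pp <- smallHealthyPP()
  inm <- imageData(pp$brainMask) == 1
  d <- (imageData(pp$flip) - imageData(pp$cta))[inm]
  noiseSd <- 2 / attr(pp$cta, "scale")  # phantom noise in normalized units
  expect_lt(sqrt(mean(d^2)), sqrt(2) * noiseSd)
})

test_that("hemispheric comparison is brighter than the CTA inside the lesion", {
  pp <- smallLesionedPP()
  les <- imageData(pp$lesionMask) == 1
  expect_gt(mean(imageData(pp$flip)[les]), mean(imageData(pp$cta)[les]))
})

test_that("comparing the comparison approximately restores the CTA", {
  pp <- smallHealthyPP()
  again <- suppressWarnings(
    makeHemisphericComparison(pp$flip, pp$brainMask, smallPreprocConfig()))
  inm <- imageData(pp$brainMask) == 1
  d <- (imageData(again) - imageData(pp$cta))[inm]
  noiseSd <- 2 / attr(pp$cta, "scale")
  expect_lt(sqrt(mean(d^2)), 2 * noiseSd)
})

test_that("cropping preserves physical coordinates and handles edge cases", {
  cs <- smallLesioned()
  full <- BinaryMask(array(1, dim(imageData(cs@cta))),
                     spacing = voxelSpacing(cs@cta))
  same <- cropToBrain(cs@cta, full, 0L)
  expect_identical(imageData(same), imageData(cs@cta))
  one <- array(0, dim(imageData(cs@cta)))
  one[10, 12, 14] <- 1
  single <- BinaryMask(one, spacing = voxelSpacing(cs@cta))
  crop <- cropToBrain(cs@cta, single, 0L)
  expect_identical(dim(imageData(crop)), c(1L, 1L, 1L))
  expect_equal(volumeOrigin(crop),
               (c(10, 12, 14) - 1) * voxelSpacing(cs@cta))
  expect_identical(imageData(crop)[1, 1, 1], imageData(cs@cta)[10, 12, 14])
  empty <- BinaryMask(array(0, dim(imageData(cs@cta))),
                      spacing = voxelSpacing(cs@cta))
  expect_error(cropToBrain(cs@cta, empty), "empty")
})

test_that("preprocessing yields grid-congruent, deterministic outputs", {
  pp <- smallLesionedPP()
  for (nm in c("flip", "ncct"))
    expect_true(gridCongruent(pp$cta, pp[[nm]]))
  for (nm in c("brainMask", "lesionMask", "atlas"))
    expect_true(gridCongruent(pp$cta, pp[[nm]]))
  again <- suppressWarnings(preprocessCase(smallLesioned(),
                                           smallPreprocConfig()))
  expect_identical(imageData(pp$cta), imageData(again$cta))
  expect_identical(imageData(pp$flip), imageData(again$flip))
  expect_match(pp$log, "registration metric", all = FALSE)
})
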