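test_that("network construction is seed-deterministic with softmax outputs", {
  cfg <- tinyNetConfig()
  m1 <- buildNetwork(cfg, seed = 5)
  m2 <- buildNetwork(cfg, seed = 5)
  expect_identical(m1@params, m2@params)
  m3 <- buildNetwork(cfg, seed = 6)
  expect_false(identical(m1@params, m3@params))
  set.seed(1)
  nb <- 3
  normal <- array(rnorm(cfg$patchNormal^3 * 2 * nb),
                  c(rep(cfg$patchNormal, 3), 2, nb))
  context <- array(rnorm(cfg$patchContext^3 * 2 * nb),
                   c(rep(cfg$patchContext, 3), 2, nb))
  probs <- ctastroke:::.cnnForward(m1, normal, context)$probs
  expect_lt(max(abs(apply(probs, c(1, 2, 3, 5), sum) - 1)), 1e-6)
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("misconfigured networks and channel mismatches are rejected", {
  expect_error(networkConfig(outputSize = 8L), "odd|multiple")
  expect_error(networkConfig(outputSize = 5L, downsampleFactor = 3L),
               "multiple")
  cfg1 <- tinyNetConfig(1L)
  m <- buildNetwork(cfg1, 1)
  pp <- smallLesionedPP()
  expect_error(
    predictVolume(m, list(cta = pp$cta, flip = pp$flip), pp$brainMask),
    "expects 1 channel")
  expect_error(
    trainNetwork(m, list(pp), trainingConfig(), c("cta", "flip")),
    "channel count")
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- networkConfig(nInputChannels = 2, convFilters = c(3, 4),
                       hiddenFilters = 5, outputSize = 3)
  m <- buildNetwork(cfg, seed = 42)
  set.seed(9)
  nb <- 2
  normal <- array(rnorm(cfg$patchNormal^3 * 2 * nb),
                  c(rep(cfg$patchNormal, 3), 2, nb))
  context <- array(rnorm(cfg$patchContext^3 * 2 * nb),
                   c(rep(cfg$patchContext, 3), 2, nb))
  labels <- array(rbinom(27 * nb, 1, 0.4), c(3, 3, 3, nb))
  fwd <- ctastroke:::.cnnForward(m, normal, context, keepActs = TRUE)
  bwd <- ctastroke:::.cnnBackward(m, fwd, labels)
  lossAt <- function(params) {
    m2 <- m; m2@params <- params
    f <- ctastroke:::.cnnForward(m2, normal, context)
    -mean(labels * log(f$probs[, , , 2, ] + 1e-12) +
            (1 - labels) * log(f$probs[, , , 1, ] + 1e-12))
  }
  for (nm in names(m@params)) {
    g <- bwd$grads[[nm]]
    i <- which.max(abs(g))
    eps <- 1e-5
    pa <- m@params; pa[[nm]][i] <- pa[[nm]][i] + eps
    pb <- m@params; pb[[nm]][i] <- pb[[nm]][i] - eps
    num <- (lossAt(pa) - lossAt(pb)) / (2 * eps)
    expect_lt(abs(num - g[i]) / max(1e-8, abs(num) + abs(g[i])), 1e-5)
  }
})

test_that("one optimizer step matches the hand-computed update rule", {
  # two scalar parameters, known gradients: verify
  #   r <- rho r + (1-rho) g^2 ; step <- -lr g / sqrt(r + eps)
  #   v <- mu v + step ; w <- w + mu v + step
  cfg <- trainingConfig(l1 = 0, l2 = 0, rmsRho = 0.9, rmsEpsilon = 1e-4,
                        momentum = 0.6)
  params <- list(a.b = 2, b.b = -1)   # .b so no weight penalty applies
  grads <- list(a.b = 0.5, b.b = -0.25)
  state <- list(r = list(a.b = 0.04, b.b = 0), v = list(a.b = 0.1, b.b = 0))
  up <- ctastroke:::.optimStep(params, grads, state, lr = 0.001, cfg)
  for (nm in c("a.b", "b.b")) {
    r <- 0.9 * state$r[[nm]] + 0.1 * grads[[nm]]^2
    s <- -0.001 * grads[[nm]] / sqrt(r + 1e-4)
    v <- 0.6 * state$v[[nm]] + s
    w <- params[[nm]] + 0.6 * v + s
    expect_equal(up$params[[nm]], w, tolerance = 1e-12)
    expect_equal(up$state$r[[nm]], r, tolerance = 1e-12)
    expect_equal(up$state$v[[nm]], v, tolerance = 1e-12)
  }
  # L1/L2 penalties enter the gradient of weight arrays
  cfgReg <- trainingConfig(l1 = 0.01, l2 = 0.1)
  w0 <- list(x.W = array(2, c(1, 1, 1, 1, 1)))
  g0 <- list(x.W = array(0, c(1, 1, 1, 1, 1)))
  st0 <- list(r = list(x.W = 0), v = list(x.W = 0))
  up2 <- ctastroke:::.optimStep(w0, g0, st0, lr = 0.001, cfgReg)
  gEff <- 0.01 * sign(2) + 0.1 * 2
  r <- 0.1 * gEff^2
  s <- -0.001 * gEff / sqrt(r + 1e-4)
  expect_equal(as.numeric(up2$params$x.W), 2 + 0.6 * s + s,
               tolerance = 1e-12)
})

test_that("learning rate schedule halves at each configured epoch", {
  cfg <- trainingConfig()
  expect_equal(learningRate(cfg, 1), 0.001)
  expect_equal(learningRate(cfg, 16), 0.001)
  for (k in seq_along(cfg$lrHalvingEpochs)) {
    e <- cfg$lrHalvingEpochs[k]
    expect_equal(learningRate(cfg, e), 0.001 * 0.5^k)
    expect_equal(learningRate(cfg, e), learningRate(cfg, e - 1) / 2)
  }
  expect_equal(learningRate(cfg, 35), 0.001 / 256)
})

test_that("batch sampling respects masks and the foreground fraction", {
  ppL <- smallLesionedPP()
  ppN <- smallHealthyPP()
  net <- tinyNetConfig()
  # foreground fraction 1: every patch centre is a lesion voxel
  cfg1 <- trainingConfig(batchSize = 8L, fgFraction = 1, seed = 2L)
  b <- sampleTrainingBatch(list(ppL), cfg1, net)
  o <- net$outputSize
  mid <- (o + 1) / 2
  expect_true(all(b$labels[mid, mid, mid, ] == 1))
  expect_true(all(b$fgCentred))
  # all-negative cohort: all label patches are zero, with a warning
  cfg5 <- trainingConfig(batchSize = 6L, fgFraction = 0.5, seed = 3L)
  expect_warning(b0 <- sampleTrainingBatch(list(ppN), cfg5, net),
                 "uniform")
  expect_true(all(b0$labels == 0))
  # empirical foreground fraction over many draws matches the setting
  cfgHalf <- trainingConfig(batchSize = 50L, fgFraction = 0.5, seed = 4L)
  hits <- 0; draws <- 20
  set.seed(77)
  for (i in seq_len(draws)) {
    bi <- sampleTrainingBatch(list(ppL, ppN), cfgHalf, net)
    hits <- hits + sum(bi$fgCentred)
  }
  n <- draws * 50
  phat <- hits / n
  ci <- 3 * sqrt(0.25 / n)
  expect_lt(abs(phat - 0.5), ci)
})

test_that("reflection augmentation is an involution that swaps channel roles", {
  pp <- smallLesionedPP()
  net <- tinyNetConfig()
  cfg <- trainingConfig(batchSize = 4L, seed = 6L)
  b <- sampleTrainingBatch(list(pp), cfg, net)
  once <- augmentReflection(b)
  twice <- augmentReflection(once)
  expect_identical(twice$normal, b$normal)
  expect_identical(twice$context, b$context)
  expect_identical(twice$labels, b$labels)
  # channels swapped and arrays reflected
  expect_identical(once$normal[, , , 1, ],
                   b$normal[rev(seq_len(dim(b$normal)[1])), , , 2, ])
  # single channel: plain reflection
  net1 <- tinyNetConfig(1L)
  b1 <- sampleTrainingBatch(list(pp), cfg, net1, channels = "cta")
  r1 <- augmentReflection(b1)
  expect_identical(r1$normal[, , , 1, ],
                   b1$normal[rev(seq_len(dim(b1$normal)[1])), , , 1, ])
  # on a symmetric phantom the augmented stack is close to the original
  ppSym <- smallHealthyPP()
  set.seed(8)
  bs <- sampleTrainingBatch(list(ppSym), trainingConfig(batchSize = 6L,
                                                        fgFraction = 0,
                                                        seed = 9L), net)
  ra <- augmentReflection(bs)
  noiseSd <- 2 / attr(ppSym$cta, "scale")
  # patches are not mirror-aligned voxel-by-voxel (centres are off-midline),
  # so compare channel means, which mirror symmetry does preserve
  expect_lt(max(abs(apply(ra$normal, 4:5, mean) -
                      apply(bs$normal, 4:5, mean))), 5 * noiseSd)
})

test_that("a short training run reduces the loss on phantoms", {
  pp <- list(smallLesionedPP(), smallHealthyPP())
  net <- tinyNetConfig()
  m <- buildNetwork(net, seed = 3)
  cfg <- trainingConfig(nEpochs = 2L, subepochsPerEpoch = 3L,
                        batchesPerSubepoch = 4L, batchSize = 8L,
                        lrHalvingEpochs = 2, initialLr = 0.002, seed = 10L)
  tr <- trainNetwork(m, pp, cfg)
  expect_identical(nrow(tr@trace), 6L)
  expect_lt(tail(tr@trace$loss, 1), tr@trace$loss[1])
  expect_true(all(is.finite(tr@trace$loss)))
  expect_identical(unique(tr@trace$lr), c(0.002, 0.001))
  # training is seed-deterministic
  tr2 <- trainNetwork(buildNetwork(net, seed = 3), pp, cfg)
  expect_identical(tr@params, tr2@params)
  expect_match(trainingLog(tr)[1], "epoch=1")
})

test_that("prediction is masked, bounded and equals single-pass on one tile", {
  pp <- smallLesionedPP()
  net <- tinyNetConfig()
  m <- buildNetwork(net, seed = 4)
  prob <- predictVolume(m, list(cta = pp$cta, flip = pp$flip), pp$brainMask)
  v <- imageData(prob)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(v[imageData(pp$brainMask) == 0] == 0))
  # tiling equivalence: a mask spanning exactly one output tile
  d <- dim(imageData(pp$cta))
  o <- net$outputSize
  s <- c(15L, 15L, 10L)
  mk <- array(0, d)
  mk[s[1]:(s[1] + o - 1), s[2]:(s[2] + o - 1), s[3]:(s[3] + o - 1)] <- 1
  oneTile <- BinaryMask(mk, spacing = voxelSpacing(pp$cta),
                        origin = volumeOrigin(pp$cta))
  pTiled <- predictVolume(m, list(cta = pp$cta, flip = pp$flip), oneTile,
                          tileBatch = 1L)
  # independent single pass through the network at the same tile centre
  cen <- s + (o - 1L) %/% 2L
  f <- net$downsampleFactor
  hN <- (net$patchNormal - 1L) %/% 2L
  hC <- (net$patchContext - 1L) %/% 2L
  chan <- list(imageData(pp$cta), imageData(pp$flip))
  chanDs <- lapply(chan, function(a)
    ctastroke:::cpp_downsample_mean(a, dim(a), f))
  normal <- array(0, c(rep(net$patchNormal, 3), 2, 1))
  context <- array(0, c(rep(net$patchContext, 3), 2, 1))
  cenDs <- (cen - 1L) %/% f + 1L
  for (j in 1:2) {
    normal[, , , j, 1] <- ctastroke:::.extractPatch(chan[[j]], cen, hN)
    context[, , , j, 1] <- ctastroke:::.extractPatch(chanDs[[j]], cenDs, hC)
  }
  direct <- ctastroke:::.cnnForward(m, normal, context)$probs[, , , 2, 1]
  got <- imageData(pTiled)[s[1]:(s[1] + o - 1), s[2]:(s[2] + o - 1),
                           s[3]:(s[3] + o - 1)]
  expect_equal(got, direct, tolerance = 1e-12)
})

test_that("an augmentation-trained model is statistically mirror-consistent", {
  # predicting a mirrored case and mirroring back should approximately
  # reproduce the prediction on the original
  pp <- smallLesionedPP()
  ppN <- smallHealthyPP()
  net <- tinyNetConfig()
  cfg <- trainingConfig(nEpochs = 4L, subepochsPerEpoch = 3L,
                        batchesPerSubepoch = 4L, batchSize = 8L,
                        lrHalvingEpochs = c(3, 4), initialLr = 0.002,
                        seed = 10L)
  m <- trainNetwork(buildNetwork(net, 3), list(pp, ppN), cfg)
  p1 <- predictVolume(m, list(cta = pp$cta, flip = pp$flip), pp$brainMask)
  p2 <- sagittalFlip(predictVolume(
    m, list(cta = sagittalFlip(pp$cta), flip = sagittalFlip(pp$flip)),
    sagittalFlip(pp$brainMask)))
  inm <- imageData(pp$brainMask) == 1
  expect_lt(mean(abs(imageData(p1) - imageData(p2))[inm]), 0.05)
  expect_gt(cor(imageData(p1)[inm], imageData(p2)[inm]), 0.7)
})

test_that("model checkpoints round-trip", {
  m <- buildNetwork(tinyNetConfig(), seed = 12)
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, f)
  back <- loadModel(f)
  expect_identical(back@params, m@params)
  expect_identical(back@config, m@config)
  expect_identical(back@seed, m@seed)
})
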