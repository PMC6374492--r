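#' @include preprocess.R
NULL

#' Create a NetworkConfig
#'
#' Configuration of the dual-pathway, multi-scale, patch-based 3-D
#' segmentation network. The normal-resolution pathway sees a small patch
#' at full resolution; the context pathway sees a patch of the same volume
#' mean-pooled by \code{downsampleFactor}, covering a larger physical
#' extent, and its feature maps are upsampled back before the two pathways
#' are concatenated and passed through 1x1x1 hidden and classification
#' layers (softmax over two classes per output voxel). All convolutions are
#' unpadded, so each pathway's input patch size is fixed by the output
#' segment size and the number of convolution layers.
#'
#' The default is a desk-scale network (depth 6: four 3x3x3 convolution
#' layers per pathway, one hidden layer, one classification layer). The
#' full-scale 11-layer variant is reachable with eight convolution layers
#' and two hidden layers.
#'
#' @param nInputChannels 1, 2 or 3 image channels.
#' @param convFilters filter counts of the 3x3x3 convolution layers
#'   (shared between the two pathways).
#' @param hiddenFilters filter counts of the 1x1x1 hidden layers after
#'   concatenation.
#' @param outputSize edge length of the cubic output segment (odd, and a
#'   multiple of \code{downsampleFactor}).
#' @param downsampleFactor integer context down-sampling factor.
#' @param kernelSize convolution kernel edge (default 3).
#' @return object of class \code{NetworkConfig} with derived fields
#'   \code{patchNormal}, \code{patchContext} and \code{depth}.
#' @export
networkConfig <- function(nInputChannels = 2L, convFilters = c(8, 8, 12, 12),
                          hiddenFilters = 16, outputSize = 9L,
                          downsampleFactor = 3L, kernelSize = 3L) {
  if (!nInputChannels %in% 1:3) stop("nInputChannels must be 1, 2 or 3")
  outputSize <- as.integer(outputSize)
  f <- as.integer(downsampleFactor)
  k <- as.integer(kernelSize)
  L <- length(convFilters)
  if (outputSize %% 2L == 0L) stop("outputSize must be odd")
  if (outputSize %% f != 0L)
    stop("configuration error: outputSize must be a multiple of the ",
         "context downsample factor so the pathway outputs align")
  patchNormal <- outputSize + L * (k - 1L)
  patchContext <- outputSize %/% f + L * (k - 1L)
  if (patchContext < k)
    stop("configuration error: receptive field exceeds the context patch")
  structure(list(nInputChannels = as.integer(nInputChannels),
                 convFilters = as.integer(convFilters),
                 hiddenFilters = as.integer(hiddenFilters),
                 outputSize = outputSize, downsampleFactor = f,
                 kernelSize = k, patchNormal = patchNormal,
                 patchContext = patchContext,
                 depth = L + length(hiddenFilters) + 1L),
            class = "NetworkConfig")
}

#' Create a TrainingConfig
#'
#' Defaults are the published training recipe: batch size 10, L1 1e-6,
#' L2 1e-4, RMSprop (rho 0.9, epsilon 1e-4) with Nesterov momentum 0.6,
#' 35 epochs of 15 sub-epochs, initial learning rate 0.001 halved at eight
#' predefined epochs, sagittal-reflection augmentation on.
#'
#' @param batchSize segments per gradient step.
#' @param l1,l2 regularization coefficients on the weights.
#' @param rmsRho,rmsEpsilon RMSprop decay and damping.
#' @param momentum Nesterov momentum.
#' @param nEpochs,subepochsPerEpoch,batchesPerSubepoch training schedule;
#'   \code{batchesPerSubepoch} sets the desk-scale sub-epoch length.
#' @param initialLr initial learning rate.
#' @param lrHalvingEpochs epochs at which the rate is halved (the exact
#'   epochs are unpublished; the default follows the late-phase halving
#'   convention of this network family).
#' @param augmentReflection sagittal-reflection augmentation (all channels
#'   and labels mirrored in unison).
#' @param reflectionSwapRoles additionally swap the cta and
#'   hemispheric-comparison channel roles when reflecting. Off by default:
#'   because the mirror of the comparison channel approximately reproduces
#'   the CTA itself, reflecting and swapping together nearly restores the
#'   original stack while the labels are mirrored, which teaches the
#'   network to mark the healthy contralateral homolog of a lesion
#'   (observed as contralateral false-positive regions). Plain unison
#'   reflection already removes left-right directional dependence.
#' @param fgFraction fraction of training patches centred on lesion voxels
#'   (class-imbalance control; unpublished, default 0.5).
#' @param seed RNG seed for sampling, augmentation and initialization of
#'   the optimizer state.
#' @return object of class \code{TrainingConfig}.
#' @export
trainingConfig <- function(batchSize = 10L, l1 = 1e-6, l2 = 1e-4,
                           rmsRho = 0.9, rmsEpsilon = 1e-4,
                           momentum = 0.6, nEpochs = 35L,
                           subepochsPerEpoch = 15L,
                           batchesPerSubepoch = 10L,
                           initialLr = 0.001,
                           lrHalvingEpochs = c(17, 19, 21, 23, 25, 27, 29, 31),
                           augmentReflection = TRUE,
                           reflectionSwapRoles = FALSE, fgFraction = 0.5,
                           seed = 1L) {
  stopifnot(batchSize >= 1, l1 >= 0, l2 >= 0, rmsRho >= 0, rmsRho < 1,
            rmsEpsilon > 0, momentum >= 0, momentum < 1, nEpochs >= 1,
            subepochsPerEpoch >= 1, batchesPerSubepoch >= 1,
            initialLr > 0, fgFraction >= 0, fgFraction <= 1)
  structure(list(batchSize = as.integer(batchSize), l1 = l1, l2 = l2,
                 rmsRho = rmsRho, rmsEpsilon = rmsEpsilon,
                 momentum = momentum, nEpochs = as.integer(nEpochs),
                 subepochsPerEpoch = as.integer(subepochsPerEpoch),
                 batchesPerSubepoch = as.integer(batchesPerSubepoch),
                 initialLr = initialLr,
                 lrHalvingEpochs = sort(as.numeric(lrHalvingEpochs)),
                 augmentReflection = augmentReflection,
                 reflectionSwapRoles = reflectionSwapRoles,
                 fgFraction = fgFraction, seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Learning rate at a given epoch
#'
#' Initial rate halved once for every halving epoch reached.
#' @param cfg a \code{\link{trainingConfig}}.
#' @param epoch epoch index (1-based).
#' @return numeric learning rate.
#' @export
learningRate <- function(cfg, epoch) {
  cfg$initialLr * 0.5^sum(cfg$lrHalvingEpochs <= epoch)
}

#' StrokeCNN: the dual-pathway segmentation network
#'
#' Weights, configuration and the training trace of a patch-based 3-D
#' segmentation network; build with \code{\link{buildNetwork}}, train with
#' \code{\link{trainNetwork}}, apply with \code{\link{predictVolume}}.
#' @export
setClass("StrokeCNN", representation(
  config = "list", params = "list", seed = "integer", trace = "data.frame"
))

setMethod("show", "StrokeCNN", function(object) {
  np <- sum(vapply(object@params, length, 0L))
  cat(sprintf(paste0("StrokeCNN: depth %d, %d channels, patch %d^3 -> ",
                     "output %d^3, %d parameters, %d training steps\n"),
              object@config$depth, object@config$nInputChannels,
              object@config$patchNormal, object@config$outputSize,
              np, nrow(object@trace)))
})

#' Build (initialize) the network
#'
#' He-style Gaussian weight initialization, seed-deterministic; biases
#' start at zero.
#'
#' @param config a \code{\link{networkConfig}}.
#' @param seed integer seed.
#' @return a \code{StrokeCNN}.
#' @export
buildNetwork <- function(config, seed = 1L) {
  stopifnot(inherits(config, "NetworkConfig"))
  k <- config$kernelSize
  .withSeed(seed, {
    params <- list()
    mk <- function(kd, cin, cout) {
      sd <- sqrt(2 / (kd^3 * cin))
      array(stats::rnorm(kd^3 * cin * cout, 0, sd),
            dim = c(kd, kd, kd, cin, cout))
    }
    for (p in c("n", "c")) {
      cin <- config$nInputChannels
      for (i in seq_along(config$convFilters)) {
        cout <- config$convFilters[i]
        params[[paste0(p, i, ".W")]] <- mk(k, cin, cout)
        params[[paste0(p, i, ".b")]] <- numeric(cout)
        cin <- cout
      }
    }
    cin <- 2L * utils::tail(config$convFilters, 1)
    for (i in seq_along(config$hiddenFilters)) {
      cout <- config$hiddenFilters[i]
      params[[paste0("h", i, ".W")]] <- mk(1L, cin, cout)
      params[[paste0("h", i, ".b")]] <- numeric(cout)
      cin <- cout
    }
    params[["out.W"]] <- mk(1L, cin, 2L)
    params[["out.b"]] <- numeric(2L)
    new("StrokeCNN", config = unclass(config), params = params,
        seed = as.integer(seed),
        trace = data.frame(epoch = integer(), subepoch = integer(),
                           lr = numeric(), loss = numeric()))
  })
}

# ---- forward / backward -----------------------------------------------------

.concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

# Forward pass on a batch. normal: (Pn,Pn,Pn,C,n); context: (Pc,Pc,Pc,C,n).
# Returns per-voxel two-class probabilities and, if keepActs, every
# intermediate needed by the backward pass.
.cnnForward <- function(model, normal, context, keepActs = FALSE) {
  cfg <- model@config
  p <- model@params
  acts <- list()
  runPath <- function(x, prefix) {
    for (i in seq_along(cfg$convFilters)) {
      nm <- paste0(prefix, i)
      if (keepActs) acts[[paste0(nm, ".in")]] <<- x
      z <- cpp_conv3d_fw(x, dim(x), p[[paste0(nm, ".W")]],
                         dim(p[[paste0(nm, ".W")]]), p[[paste0(nm, ".b")]])
      if (keepActs) acts[[paste0(nm, ".z")]] <<- z
      x <- z * (z > 0)
    }
    x
  }
  an <- runPath(normal, "n")
  ac <- runPath(context, "c")
  acUp <- cpp_upsample3(ac, dim(ac), cfg$downsampleFactor)
  if (!identical(dim(acUp)[1:3], dim(an)[1:3]))
    stop("pathway outputs do not align; check networkConfig")
  x <- .concatChannels(an, acUp)
  for (i in seq_along(cfg$hiddenFilters)) {
    nm <- paste0("h", i)
    if (keepActs) acts[[paste0(nm, ".in")]] <- x
    z <- cpp_conv3d_fw(x, dim(x), p[[paste0(nm, ".W")]],
                       dim(p[[paste0(nm, ".W")]]), p[[paste0(nm, ".b")]])
    if (keepActs) acts[[paste0(nm, ".z")]] <- z
    x <- z * (z > 0)
  }
  if (keepActs) acts[["out.in"]] <- x
  logits <- cpp_conv3d_fw(x, dim(x), p[["out.W"]], dim(p[["out.W"]]),
                          p[["out.b"]])
  d <- dim(logits)
  l1 <- logits[, , , 1, , drop = FALSE]
  l2 <- logits[, , , 2, , drop = FALSE]
  mx <- pmax(l1, l2)
  e1 <- exp(l1 - mx); e2 <- exp(l2 - mx)
  s <- e1 + e2
  probs <- array(0, d)
  probs[, , , 1, ] <- e1 / s
  probs[, , , 2, ] <- e2 / s
  list(probs = probs, acts = if (keepActs) acts else NULL)
}

# Backward pass: voxel-wise two-class cross-entropy. labels: (o,o,o,n) in
# {0,1} (1 = lesion, class 2). Returns loss (data term) and named grads.
.cnnBackward <- function(model, fwd, labels) {
  cfg <- model@config
  p <- model@params
  probs <- fwd$probs
  acts <- fwd$acts
  d <- dim(probs)
  n <- prod(d[c(1:3, 5)])
  y2 <- labels
  p2 <- probs[, , , 2, ]
  p1 <- probs[, , , 1, ]
  eps <- 1e-12
  loss <- -mean(y2 * log(p2 + eps) + (1 - y2) * log(p1 + eps))
  g <- array(0, d)
  g[, , , 1, ] <- ((1 - y2) * (p1 - 1) + y2 * p1) / n
  g[, , , 2, ] <- (y2 * (p2 - 1) + (1 - y2) * p2) / n
  grads <- list()
  convBw <- function(nm, gradOut) {
    x <- acts[[paste0(nm, ".in")]]
    W <- p[[paste0(nm, ".W")]]
    bw <- cpp_conv3d_bw(x, dim(x), W, dim(W), gradOut)
    grads[[paste0(nm, ".W")]] <<- bw$weights
    grads[[paste0(nm, ".b")]] <<- bw$bias
    bw$input
  }
  gx <- convBw("out", g)
  for (i in rev(seq_along(cfg$hiddenFilters))) {
    nm <- paste0("h", i)
    gx <- gx * (acts[[paste0(nm, ".z")]] > 0)
    gx <- convBw(nm, gx)
  }
  nf <- utils::tail(cfg$convFilters, 1)
  gn <- gx[, , , seq_len(nf), , drop = FALSE]
  gcUp <- gx[, , , nf + seq_len(nf), , drop = FALSE]
  gc <- cpp_upsample3_bw(gcUp, dim(gcUp), cfg$downsampleFactor)
  pathBw <- function(gradOut, prefix) {
    for (i in rev(seq_along(cfg$convFilters))) {
      nm <- paste0(prefix, i)
      gradOut <- gradOut * (acts[[paste0(nm, ".z")]] > 0)
      gradOut <- convBw(nm, gradOut)
    }
    gradOut
  }
  pathBw(gn, "n")
  pathBw(gc, "c")
  list(loss = loss, grads = grads)
}

# One optimizer step: RMSprop-scaled gradient with Nesterov momentum,
#   r <- rho r + (1-rho) g^2
#   step <- -lr g / sqrt(r + eps)
#   v <- mu v + step
#   w <- w + mu v + step
# L1/L2 penalties are added to the gradient of weight (not bias) arrays.
.optimStep <- function(params, grads, state, lr, cfg) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (endsWith(nm, ".W"))
      g <- g + cfg$l1 * sign(params[[nm]]) + cfg$l2 * params[[nm]]
    r <- cfg$rmsRho * state$r[[nm]] + (1 - cfg$rmsRho) * g * g
    step <- -lr * g / sqrt(r + cfg$rmsEpsilon)
    v <- cfg$momentum * state$v[[nm]] + step
    params[[nm]] <- params[[nm]] + cfg$momentum * v + step
    state$r[[nm]] <- r
    state$v[[nm]] <- v
  }
  list(params = params, state = state)
}

# ---- patch sampling ---------------------------------------------------------

.extractPatch <- function(arr, center, half) {
  d <- dim(arr)
  size <- 2L * half + 1L
  out <- array(0, c(size, size, size))
  lo <- center - half; hi <- center + half
  sLo <- pmax(lo, 1L); sHi <- pmin(hi, d)
  if (any(sLo > sHi)) return(out)
  dLo <- sLo - lo + 1L; dHi <- dLo + (sHi - sLo)
  out[dLo[1]:dHi[1], dLo[2]:dHi[2], dLo[3]:dHi[3]] <-
    arr[sLo[1]:sHi[1], sLo[2]:sHi[2], sLo[3]:sHi[3]]
  out
}

# Precompute per-case arrays for sampling/inference: ordered channel
# arrays, their mean-pooled versions, and brain/lesion voxel indices.
.prepareCase <- function(pcase, netCfg, channels) {
  chan <- lapply(channels, function(ch) pcase[[ch]]@values)
  names(chan) <- channels
  f <- netCfg$downsampleFactor
  chanDs <- lapply(chan, function(a)
    cpp_downsample_mean(a, dim(a), f))
  list(id = pcase$id, group = pcase$group, chan = chan, chanDs = chanDs,
       labels = pcase$lesionMask@values,
       brainIdx = which(pcase$brainMask@values == 1),
       lesionIdx = which(pcase$lesionMask@values == 1),
       dim = dim(pcase$cta@values))
}

#' Sample a training batch of patches
#'
#' Draws \code{batchSize} training segments from the preprocessed cases:
#' patch centres lie inside the brain masks, and the configured fraction of
#' patches is centred on lesion-positive voxels when any case carries
#' lesion voxels (with a warned fall-back to uniform sampling otherwise).
#' Each segment provides the normal-resolution patch stack, the
#' mean-pooled context patch stack, and the label patch aligned to the
#' network's output grid.
#'
#' @param cases list of \code{PreprocessedCase} (see
#'   \code{\link{preprocessCase}}).
#' @param trainCfg a \code{\link{trainingConfig}}.
#' @param netCfg a \code{\link{networkConfig}}.
#' @param channels character vector naming the input channels, in order,
#'   from \code{"cta"}, \code{"flip"}, \code{"ncct"}.
#' @return list with arrays \code{normal} (Pn^3 x channels x batch),
#'   \code{context} (Pc^3 x channels x batch), \code{labels}
#'   (o^3 x batch), and \code{fgCentred} (logical per segment).
#' @export
sampleTrainingBatch <- function(cases, trainCfg, netCfg,
                                channels = c("cta", "flip")) {
  if (length(channels) != netCfg$nInputChannels)
    stop("channel count does not match the network configuration")
  prepared <- if (!is.null(cases[[1]]$chan)) cases
  else lapply(cases, .prepareCase, netCfg = netCfg, channels = channels)
  .sampleBatchPrepared(prepared, trainCfg, netCfg, channels)
}

.sampleBatchPrepared <- function(prepared, trainCfg, netCfg, channels) {
  nb <- trainCfg$batchSize
  nc <- length(channels)
  Pn <- netCfg$patchNormal; Pc <- netCfg$patchContext
  o <- netCfg$outputSize
  hN <- (Pn - 1L) %/% 2L; hC <- (Pc - 1L) %/% 2L; hO <- (o - 1L) %/% 2L
  f <- netCfg$downsampleFactor
  normal <- array(0, c(Pn, Pn, Pn, nc, nb))
  context <- array(0, c(Pc, Pc, Pc, nc, nb))
  labels <- array(0, c(o, o, o, nb))
  fgCentred <- logical(nb)
  hasLesion <- which(vapply(prepared, function(x) length(x$lesionIdx) > 0,
                            TRUE))
  if (!length(hasLesion) && trainCfg$fgFraction > 0)
    warning("no lesion voxels in the cohort; falling back to uniform ",
            "patch sampling")
  for (i in seq_len(nb)) {
    wantFg <- stats::runif(1) < trainCfg$fgFraction && length(hasLesion)
    ci <- if (wantFg) hasLesion[sample.int(length(hasLesion), 1)]
    else sample.int(length(prepared), 1)
    cs <- prepared[[ci]]
    pool <- if (wantFg) cs$lesionIdx else cs$brainIdx
    cen <- arrayInd(pool[sample.int(length(pool), 1)], cs$dim)[1, ]
    fgCentred[i] <- wantFg && cs$labels[cen[1], cen[2], cen[3]] == 1
    cenDs <- (cen - 1L) %/% f + 1L
    for (j in seq_len(nc)) {
      normal[, , , j, i] <- .extractPatch(cs$chan[[j]], cen, hN)
      context[, , , j, i] <- .extractPatch(cs$chanDs[[j]], cenDs, hC)
    }
    labels[, , , i] <- .extractPatch(cs$labels, cen, hO)
  }
  list(normal = normal, context = context, labels = labels,
       fgCentred = fgCentred, channels = channels)
}

#' Sagittal-reflection augmentation of a patch batch
#'
#' Reflects all channels and the label patches along the left-right axis in
#' unison. When both the primary CTA and the hemispheric-comparison channel
#' are present, the two additionally swap roles: reflecting a channel that
#' is itself a flipped-and-registered copy reproduces (up to registration
#' error) the other channel. Applying the operation twice restores the
#' batch bit-exactly.
#'
#' @param batch a batch as returned by \code{\link{sampleTrainingBatch}}.
#' @param channelRoles character vector naming each channel's role
#'   (default: the batch's own \code{channels}).
#' @param swapRoles logical; set \code{FALSE} to disable the cta/flip
#'   channel-role swap.
#' @param which indices of the segments to reflect (default: all).
#' @return the augmented batch.
#' @export
augmentReflection <- function(batch, channelRoles = batch$channels,
                              swapRoles = TRUE, which = NULL) {
  flipx <- function(a) {
    idx <- rep(list(quote(expr = )), length(dim(a)))
    idx[[1]] <- rev(seq_len(dim(a)[1]))
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  sel <- if (is.null(which)) seq_len(dim(batch$normal)[5]) else which
  if (!length(sel)) return(batch)
  perm <- seq_along(channelRoles)
  if (swapRoles && all(c("cta", "flip") %in% channelRoles)) {
    i1 <- match("cta", channelRoles); i2 <- match("flip", channelRoles)
    perm[c(i1, i2)] <- c(i2, i1)
  }
  batch$normal[, , , , sel] <- flipx(batch$normal)[, , , perm, sel]
  batch$context[, , , , sel] <- flipx(batch$context)[, , , perm, sel]
  batch$labels[, , , sel] <- flipx(batch$labels)[, , , sel]
  batch
}

#' Train the network
#'
#' Voxel-wise two-class cross-entropy with L1 and L2 penalties, optimized
#' by RMSprop with Nesterov momentum on the configured epoch/sub-epoch
#' schedule with stepwise learning-rate halving. Sagittal-reflection
#' augmentation (with cta/flip role swap) is applied to a random half of
#' each batch when enabled. Fully seed-deterministic.
#'
#' @param model a \code{StrokeCNN}.
#' @param cases list of \code{PreprocessedCase}.
#' @param trainCfg a \code{\link{trainingConfig}}.
#' @param channels input channel names, in order.
#' @return the trained \code{StrokeCNN}; the per-sub-epoch loss trace is in
#'   \code{@trace}.
#' @export
trainNetwork <- function(model, cases, trainCfg,
                         channels = c("cta", "flip")) {
  stopifnot(length(cases) >= 1)
  cfg <- model@config
  if (length(channels) != cfg$nInputChannels)
    stop("channel count does not match the network configuration")
  prepared <- lapply(cases, .prepareCase, netCfg = cfg, channels = channels)
  params <- model@params
  zero <- lapply(params, function(x) array(0, dim = if (is.null(dim(x)))
    length(x) else dim(x)))
  state <- list(r = zero, v = zero)
  trace <- model@trace
  .withSeed(trainCfg$seed, {
    for (epoch in seq_len(trainCfg$nEpochs)) {
      lr <- learningRate(trainCfg, epoch)
      for (sub in seq_len(trainCfg$subepochsPerEpoch)) {
        lossAcc <- 0
        for (b in seq_len(trainCfg$batchesPerSubepoch)) {
          batch <- .sampleBatchPrepared(prepared, trainCfg, cfg, channels)
          if (trainCfg$augmentReflection) {
            refl <- which(stats::runif(trainCfg$batchSize) < 0.5)
            batch <- augmentReflection(
              batch, channels,
              swapRoles = isTRUE(trainCfg$reflectionSwapRoles),
              which = refl)
          }
          mTmp <- model; mTmp@params <- params
          fwd <- .cnnForward(mTmp, batch$normal, batch$context,
                             keepActs = TRUE)
          bwd <- .cnnBackward(mTmp, fwd, batch$labels)
          if (!is.finite(bwd$loss))
            stop(sprintf(paste0("non-finite training loss at epoch %d ",
                                "sub-epoch %d batch %d (lr %.3g)"),
                         epoch, sub, b, lr))
          up <- .optimStep(params, bwd$grads, state, lr, trainCfg)
          params <- up$params
          state <- up$state
          lossAcc <- lossAcc + bwd$loss
        }
        trace <- rbind(trace, data.frame(
          epoch = epoch, subepoch = sub, lr = lr,
          loss = lossAcc / trainCfg$batchesPerSubepoch))
      }
    }
  })
  model@params <- params
  model@trace <- trace
  model
}

#' Format the training trace as log lines
#'
#' @param model a trained \code{StrokeCNN}.
#' @return character vector, one "epoch sub-epoch lr loss" line per
#'   sub-epoch.
#' @export
trainingLog <- function(model) {
  with(model@trace, sprintf("epoch=%d subepoch=%d lr=%.6g loss=%.6g",
                            epoch, subepoch, lr, loss))
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the network configuration, seed, weights and
#' training trace.
#' @param model a \code{StrokeCNN}.
#' @param file checkpoint path.
#' @return \code{saveModel}: \code{file}, invisibly; \code{loadModel}: the
#'   restored \code{StrokeCNN}.
#' @export
saveModel <- function(model, file) {
  saveRDS(list(config = model@config, params = model@params,
               seed = model@seed, trace = model@trace), file)
  invisible(file)
}

#' @rdname saveModel
#' @export
loadModel <- function(file) {
  x <- readRDS(file)
  new("StrokeCNN", config = x$config, params = x$params, seed = x$seed,
      trace = x$trace)
}

#' Whole-volume tiled inference
#'
#' Predicts a lesion probability map by tiling the brain bounding box with
#' disjoint output segments, assembling each segment's input patches (zero
#' padded at the volume edge) and stitching the segment predictions;
#' because output tiles are disjoint on the output grid, the stitched map
#' is seam-free and identical to single-pass inference where the volume
#' fits one tile. Probabilities outside the intracranial mask are zero.
#'
#' @param model a trained \code{StrokeCNN}.
#' @param channels named list of grid-congruent \code{ImageVolume}s, in the
#'   network's channel order.
#' @param mask intracranial \code{BinaryMask}.
#' @param tileBatch tiles evaluated per forward pass.
#' @return a \code{ProbabilityMap} on the input grid.
#' @export
predictVolume <- function(model, channels, mask, tileBatch = 16L) {
  cfg <- model@config
  if (length(channels) != cfg$nInputChannels)
    stop(sprintf("model expects %d channel(s), got %d",
                 cfg$nInputChannels, length(channels)))
  for (i in seq_along(channels))
    if (!gridCongruent(channels[[i]], mask))
      stop(sprintf("channel '%s' is not grid-congruent with the mask",
                   if (!is.null(names(channels))) names(channels)[i]
                   else as.character(i)))
  d <- dim(mask@values)
  o <- cfg$outputSize
  f <- cfg$downsampleFactor
  hN <- (cfg$patchNormal - 1L) %/% 2L
  hC <- (cfg$patchContext - 1L) %/% 2L
  chan <- lapply(channels, function(v) v@values)
  chanDs <- lapply(chan, function(a) cpp_downsample_mean(a, dim(a), f))
  idx <- which(mask@values == 1)
  out <- array(0, d)
  if (length(idx)) {
    ijk <- arrayInd(idx, d)
    lo <- apply(ijk, 2, min); hi <- apply(ijk, 2, max)
    starts <- expand.grid(x = seq(lo[1], hi[1], by = o),
                          y = seq(lo[2], hi[2], by = o),
                          z = seq(lo[3], hi[3], by = o))
    nT <- nrow(starts)
    nc <- length(chan)
    for (g in split(seq_len(nT), ceiling(seq_len(nT) / tileBatch))) {
      nb <- length(g)
      normal <- array(0, c(rep(cfg$patchNormal, 3), nc, nb))
      context <- array(0, c(rep(cfg$patchContext, 3), nc, nb))
      for (bi in seq_len(nb)) {
        s <- as.integer(starts[g[bi], ])
        cen <- s + (o - 1L) %/% 2L
        cenDs <- (cen - 1L) %/% f + 1L
        for (j in seq_len(nc)) {
          normal[, , , j, bi] <- .extractPatch(chan[[j]], cen, hN)
          context[, , , j, bi] <- .extractPatch(chanDs[[j]], cenDs, hC)
        }
      }
      probs <- .cnnForward(model, normal, context)$probs
      for (bi in seq_len(nb)) {
        s <- as.integer(starts[g[bi], ])
        e <- pmin(s + o - 1L, d)
        n <- e - s + 1L
        out[s[1]:e[1], s[2]:e[2], s[3]:e[3]] <-
          probs[1:n[1], 1:n[2], 1:n[3], 2, bi]
      }
    }
  }
  out <- out * (mask@values == 1)
  out <- pmin(pmax(out, 0), 1)
  ProbabilityMap(array(out, d), spacing = mask@spacing,
                 origin = mask@origin, orientation = mask@orientation)
}
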