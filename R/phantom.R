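#' @include volume-methods.R
NULL

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-case seed from a cohort seed and case index (fixed affine
# integer mix modulo 2^31-1; exact in double arithmetic).
.caseSeed <- function(cohortSeed, index) {
  as.integer(((as.numeric(cohortSeed) %% 2147483647) * 48271 +
                index * 16807) %% 2147483646 + 1)
}

#' Create a PhantomSpec
#'
#' All arguments default to the package's reference phantom: a
#' 96 x 96 x 64 grid at 1.2 x 1.2 x 1.6 mm (anisotropic, mimicking an
#' acquisition that preprocessing resamples to isotropic), moderate
#' symmetric confounders, and a unilateral lesion.
#'
#' @param gridShape voxels per axis (>= 32 each).
#' @param spacingMm per-axis voxel size in mm.
#' @param lesionPresent logical; \code{FALSE} gives a confounder-only
#'   (group B style) phantom.
#' @param lesionSide \code{"left"} or \code{"right"} (array-left, i.e. low
#'   indices along the L-R axis).
#' @param lesionRadiusMm base semi-axis of the lesion ellipsoid (the
#'   ellipsoid has semi-axes \code{r * c(1, 1.2, 0.85)}).
#' @param lesionContrast fractional intensity drop inside the lesion, (0,1).
#' @param confounderPeriventricular,confounderSulcal severities in [0,1].
#' @param noiseSd additive Gaussian noise SD (intensity units; parenchyma
#'   is 35, CSF 5, skull 100).
#' @param posePerturbation \code{c(max_deg, max_mm)} random rigid head-pose
#'   perturbation; \code{c(0, 0)} keeps the phantom exactly grid-aligned.
#' @param seed integer RNG seed.
#' @return A \code{PhantomSpec}.
#' @export
PhantomSpec <- function(gridShape = c(96L, 96L, 64L),
                        spacingMm = c(1.2, 1.2, 1.6),
                        lesionPresent = TRUE, lesionSide = "left",
                        lesionRadiusMm = 12, lesionContrast = 0.35,
                        confounderPeriventricular = 0.5,
                        confounderSulcal = 0.5, noiseSd = 2,
                        posePerturbation = c(2, 2), seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacingMm = as.numeric(spacingMm), lesionPresent = lesionPresent,
      lesionSide = lesionSide, lesionRadiusMm = lesionRadiusMm,
      lesionContrast = lesionContrast,
      confounderPeriventricular = confounderPeriventricular,
      confounderSulcal = confounderSulcal, noiseSd = noiseSd,
      posePerturbation = as.numeric(posePerturbation),
      seed = as.integer(seed))
}

#' Standard label table for the ASPECTS-analog atlas
#'
#' Ten regions per hemisphere: the six middle-cerebral-artery cortical
#' segments M1-M6, insular ribbon I, lentiform nucleus L, caudate C and
#' internal capsule IC. Left labels 1-10, right labels 11-20.
#'
#' @return data.frame with columns \code{region}, \code{side}, \code{label}.
#' @export
aspectsLabelTable <- function() {
  regions <- c("M1", "M2", "M3", "M4", "M5", "M6", "I", "L", "C", "IC")
  data.frame(region = rep(regions, 2),
             side = rep(c("left", "right"), each = 10),
             label = 1:20)
}

# Phantom geometry shared by the generator and its tests: voxel-centre
# offsets from the grid midpoint and the skull/cavity semi-axes. The grid
# midpoint is (n+1)/2 in 1-based index, so mirroring index i -> n+1-i about
# the L-R axis is an exact voxel-to-voxel map and symmetric structures are
# mirror-symmetric by construction.
.phantomGeometry <- function(spec) {
  d <- spec@gridShape; sp <- spec@spacingMm
  half <- d * sp / 2
  ctr <- (d + 1) / 2
  axOffsets <- lapply(1:3, function(a) ((seq_len(d[a])) - ctr[a]) * sp[a])
  outer <- c(0.88, 0.93, 0.86) * half
  inner <- pmax(outer - 4, outer * 0.5)
  list(dim = d, spacing = sp, centerIndex = ctr,
       centerPhys = (ctr - 1) * sp, axOffsets = axOffsets,
       outerSemi = outer, innerSemi = inner)
}

# Squared normalized ellipsoid radius field for semi-axes a and per-axis
# centre offsets (cx, cy, cz) in mm relative to the grid midpoint.
.ellipField <- function(geo, a, c0 = c(0, 0, 0)) {
  dx <- (geo$axOffsets[[1]] - c0[1]) / a[1]
  dy <- (geo$axOffsets[[2]] - c0[2]) / a[2]
  dz <- (geo$axOffsets[[3]] - c0[3]) / a[3]
  outer(outer(dx^2, dy^2, "+"), dz^2, "+")
}

# Build the noise-free symmetric anatomy (no lesion): intensity volume plus
# cavity mask and the coordinate fields needed downstream.
.phantomAnatomy <- function(spec) {
  geo <- .phantomGeometry(spec)
  d <- geo$dim
  eOut <- .ellipField(geo, geo$outerSemi)
  eIn <- .ellipField(geo, geo$innerSemi)
  cavity <- eIn < 1
  v <- array(0, dim = d)
  v[eOut < 1 & !cavity] <- 100            # skull shell
  v[cavity] <- 35                          # parenchyma
  rho <- sqrt(eIn)
  # subarachnoid CSF rim along the inner skull surface
  csf <- cavity & rho > 0.96
  # widened cortical sulci: radial grooves in the cortical band, defined in
  # |x| so they are mirror-symmetric about the midsagittal plane
  sev <- spec@confounderSulcal
  absX <- abs(geo$axOffsets[[1]])
  phi <- array(0, dim = d)
  for (k in seq_len(d[3]))
    phi[, , k] <- atan2(matrix(geo$axOffsets[[2]], d[1], d[2], byrow = TRUE),
                        matrix(absX, d[1], d[2]))
  grooves <- seq(-1.35, 1.35, length.out = 7)
  width <- 0.04 + 0.14 * sev
  depth <- 0.04 + 0.18 * sev
  inGroove <- array(FALSE, dim = d)
  for (g in grooves) inGroove <- inGroove | abs(phi - g) < width / 2
  sulci <- cavity & rho > 0.96 - depth & rho <= 0.96 & inGroove
  # lateral ventricles, mirror pair
  iv <- geo$innerSemi
  ventSemi <- c(0.11, 0.30, 0.22) * iv
  ventOff <- c(0.22 * iv[1], 0.08 * iv[2], 0.05 * iv[3])
  eVentL <- .ellipField(geo, ventSemi, c(-ventOff[1], ventOff[2], ventOff[3]))
  eVentR <- .ellipField(geo, ventSemi, c(+ventOff[1], ventOff[2], ventOff[3]))
  vent <- (eVentL < 1 | eVentR < 1) & cavity
  # periventricular white-matter hypoattenuation: symmetric rim around the
  # ventricles, severity-scaled intensity drop
  pv <- spec@confounderPeriventricular
  pvRim <- ((eVentL < 2.1 & eVentL >= 1) | (eVentR < 2.1 & eVentR >= 1)) &
    cavity & !vent
  v[pvRim] <- pmin(v[pvRim], 35 - 18 * pv)
  v[csf | sulci] <- 5
  v[vent] <- 5
  list(geo = geo, v = v, cavity = cavity, rho = rho, eIn = eIn)
}

# Rasterize the lesion ellipsoid for a candidate centre; returns NULL if it
# violates the single-hemisphere / inside-cavity constraints.
.tryLesion <- function(anat, spec, center) {
  geo <- anat$geo
  semi <- spec@lesionRadiusMm * c(1, 1.2, 0.85)
  eLes <- .ellipField(geo, semi, center)
  les <- eLes < 1
  if (!any(les)) return(NULL)
  sideSign <- if (spec@lesionSide == "left") -1 else 1
  xOff <- array(geo$axOffsets[[1]], dim = geo$dim)
  if (any(les & sideSign * xOff <= 0)) return(NULL)     # crosses midline
  if (any(les & anat$rho > 0.955)) return(NULL)         # leaves the brain
  les
}

#' Generate one synthetic head phantom
#'
#' Builds a bilaterally near-symmetric head phantom with skull shell,
#' parenchyma, ventricular and sulcal CSF, symmetric aging confounders and
#' (for group A) a unilateral hypoattenuated lesion ellipsoid, then renders
#' a CTA-like channel (sharp, noisy) and an NCCT-like channel (lower
#' contrast, heavier through-plane blur), the ground-truth lesion and brain
#' masks, and the ASPECTS-analog region atlas. A random rigid head-pose
#' perturbation is applied to all channels in unison (masks and atlas via
#' nearest-neighbour resampling). Identical spec (including seed) gives
#' bit-identical output.
#'
#' @param spec a \code{\link{PhantomSpec}}.
#' @param id case identifier stored in the result.
#' @return A \code{PhantomCase}.
#' @export
generatePhantom <- function(spec, id = "phantom") {
  validObject(spec)
  .withSeed(spec@seed, {
    anat <- .phantomAnatomy(spec)
    geo <- anat$geo
    d <- geo$dim; sp <- geo$spacing
    v <- anat$v
    les <- array(FALSE, dim = d)
    if (spec@lesionPresent) {
      sideSign <- if (spec@lesionSide == "left") -1 else 1
      semiX <- spec@lesionRadiusMm
      lo <- semiX + 1.5
      hi <- geo$innerSemi[1] * 0.9 - semiX
      if (hi < lo)
        stop(sprintf(paste0("lesionRadiusMm = %g cannot fit inside one ",
                            "hemisphere (inner semi-axis %.1f mm)"),
                     spec@lesionRadiusMm, geo$innerSemi[1]), call. = FALSE)
      found <- FALSE
      for (try in seq_len(200)) {
        ctr <- c(sideSign * stats::runif(1, lo, hi),
                 stats::runif(1, -0.45, 0.45) * geo$innerSemi[2],
                 stats::runif(1, -0.35, 0.35) * geo$innerSemi[3])
        cand <- .tryLesion(anat, spec, ctr)
        if (!is.null(cand)) { les <- cand; found <- TRUE; break }
      }
      if (!found)
        stop(sprintf(paste0("could not place a lesion of radius %g mm ",
                            "inside the %s hemisphere"),
                     spec@lesionRadiusMm, spec@lesionSide), call. = FALSE)
      lesVal <- 35 * (1 - spec@lesionContrast)
      v[les] <- pmin(v[les], lesVal)
    }
    # render channels: light blur for CTA, strong anisotropic blur and
    # compressed contrast for NCCT (thick-slice acquisition analogue)
    dimI <- as.integer(d)
    ctaV <- cpp_gauss_blur(v, dimI, 0.5 / sp)
    ncctV <- cpp_gauss_blur(v, dimI, c(1.2, 1.2, 3.0) / sp)
    ncctV <- 18 + 0.5 * (ncctV - 18)
    n <- prod(d)
    ctaV <- ctaV + array(stats::rnorm(n, 0, spec@noiseSd), dim = d)
    ncctV <- ncctV + array(stats::rnorm(n, 0, 0.8 * spec@noiseSd), dim = d)
    atlasV <- .buildAtlas(anat)
    pose <- spec@posePerturbation
    geomArgs <- list(spacing = sp, origin = c(0, 0, 0))
    mk <- function(fun, vals) do.call(fun, c(list(vals), geomArgs))
    cta <- mk(ImageVolume, ctaV)
    ncct <- mk(ImageVolume, ncctV)
    lesionMask <- mk(BinaryMask, array(as.numeric(les), dim = d))
    brainMask <- mk(BinaryMask, array(as.numeric(anat$cavity), dim = d))
    atlas <- RegionAtlas(atlasV, aspectsLabelTable(), spacing = sp,
                         origin = c(0, 0, 0))
    if (any(pose > 0)) {
      rot <- stats::runif(3, -pose[1], pose[1]) * pi / 180
      tra <- stats::runif(3, -pose[2], pose[2])
      tf <- RigidTransform(rot, tra, center = geo$centerPhys)
      cta <- applyTransform(cta, tf, "linear")
      ncct <- applyTransform(ncct, tf, "linear")
      lesionMask <- applyTransform(lesionMask, tf, "nearest")
      brainMask <- applyTransform(brainMask, tf, "nearest")
      atlas <- applyTransform(atlas, tf, "nearest")
    }
    new("PhantomCase", id = id,
        group = if (spec@lesionPresent) "A" else "B",
        cta = cta, ncct = ncct, lesionMask = lesionMask,
        brainMask = brainMask, atlas = atlas, spec = spec)
  })
}

# Assign every cavity voxel one of the 20 ASPECTS-analog labels.
# Deep structures (normalized radius < 0.5) go to the nearest of four
# prototype centres (I, L, C, IC) per hemisphere; the cortical shell is
# split into basal (M1-M3) and supraventricular (M4-M6) bands and three
# anterior/middle/posterior sectors.
.buildAtlas <- function(anat) {
  geo <- anat$geo
  d <- geo$dim
  idx <- which(anat$cavity)
  ijk <- arrayInd(idx, d)
  dx <- geo$axOffsets[[1]][ijk[, 1]]
  dy <- geo$axOffsets[[2]][ijk[, 2]]
  dz <- geo$axOffsets[[3]][ijk[, 3]]
  rho <- anat$rho[idx]
  iv <- geo$innerSemi
  right <- dx > 0
  ax <- abs(dx)
  lab <- integer(length(idx))
  deep <- rho < 0.5
  proto <- rbind(I = c(0.45, 0.00, -0.05), L = c(0.30, 0.05, 0.00),
                 C = c(0.18, 0.20, 0.15), IC = c(0.24, 0.12, 0.08))
  protoMm <- sweep(proto, 2, iv, `*`)
  dd <- sapply(seq_len(4), function(k)
    (ax - protoMm[k, 1])^2 + (dy - protoMm[k, 2])^2 + (dz - protoMm[k, 3])^2)
  deepRegion <- c(7L, 8L, 9L, 10L)[max.col(-dd[deep, , drop = FALSE])]
  lab[deep] <- deepRegion
  phi <- atan2(dy, ax)
  sector <- ifelse(phi > 0.45, 0L, ifelse(phi < -0.45, 2L, 1L))
  band <- ifelse(dz <= 0, 0L, 3L)
  lab[!deep] <- 1L + sector[!deep] + band[!deep]
  lab[right] <- lab[right] + 10L
  out <- array(0, dim = d)
  out[idx] <- lab
  out
}

#' Generate a phantom cohort
#'
#' \code{nPositive} lesioned (group A) cases with randomized lesion side,
#' size and contrast, plus \code{nNegative} confounder-only (group B)
#' cases. Confounder severities, noise and pose are randomized per case
#' within the given ranges. Per-case seeds are derived deterministically
#' from the cohort seed, so the cohort is reproducible and individual cases
#' can be regenerated in isolation.
#'
#' @param nPositive,nNegative case counts (>= 0).
#' @param baseSpec \code{\link{PhantomSpec}} supplying grid, spacing, noise
#'   and pose defaults.
#' @param seed cohort seed.
#' @param ranges list of randomization ranges: \code{radiusMm} (default
#'   scaled to the phantom brain so the largest lesion still fits one
#'   hemisphere), \code{contrast}, \code{periventricular}, \code{sulcal}.
#' @return list of \code{PhantomCase} (group A cases first).
#' @export
generateCohort <- function(nPositive, nNegative, baseSpec = PhantomSpec(),
                           seed = 1L, ranges = list()) {
  stopifnot(nPositive >= 0, nNegative >= 0)
  geo <- .phantomGeometry(baseSpec)
  def <- list(radiusMm = c(0.20, 0.38) * geo$innerSemi[1],
              contrast = c(0.25, 0.45),
              periventricular = c(0.2, 0.8), sulcal = c(0.2, 0.8))
  ranges <- utils::modifyList(def, ranges)
  total <- nPositive + nNegative
  if (total == 0) return(list())
  cases <- vector("list", total)
  for (i in seq_len(total)) {
    caseSeed <- .caseSeed(seed, i)
    positive <- i <= nPositive
    pars <- .withSeed(caseSeed, list(
      side = if (stats::runif(1) < 0.5) "left" else "right",
      radius = stats::runif(1, ranges$radiusMm[1], ranges$radiusMm[2]),
      contrast = stats::runif(1, ranges$contrast[1], ranges$contrast[2]),
      pv = stats::runif(1, ranges$periventricular[1], ranges$periventricular[2]),
      su = stats::runif(1, ranges$sulcal[1], ranges$sulcal[2])))
    spec <- baseSpec
    spec@lesionPresent <- positive
    spec@lesionSide <- pars$side
    spec@lesionRadiusMm <- pars$radius
    spec@lesionContrast <- pars$contrast
    spec@confounderPeriventricular <- pars$pv
    spec@confounderSulcal <- pars$su
    spec@seed <- .caseSeed(caseSeed, 1000L)
    id <- sprintf("%s%02d", if (positive) "A" else "B",
                  if (positive) i else i - nPositive)
    cases[[i]] <- generatePhantom(spec, id = id)
  }
  cases
}

#' Write a phantom case to disk as NIfTI files
#'
#' Writes \code{cta.nii.gz}, \code{ncct.nii.gz}, \code{lesion.nii.gz},
#' \code{brain.nii.gz} and \code{atlas.nii.gz} into \code{dir}.
#'
#' @param case a \code{PhantomCase}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCase <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(case@cta, file.path(dir, "cta.nii.gz"))
  writeVolume(case@ncct, file.path(dir, "ncct.nii.gz"))
  writeVolume(case@lesionMask, file.path(dir, "lesion.nii.gz"))
  writeVolume(case@brainMask, file.path(dir, "brain.nii.gz"))
  writeVolume(case@atlas, file.path(dir, "atlas.nii.gz"))
  invisible(dir)
}

#' Write a cohort with a plain-text manifest
#'
#' Each case goes into \code{dir/<id>/} via \code{\link{writeCase}}; the
#' manifest \code{dir/manifest.tsv} records id, group, lesion parameters
#' and per-case seed.
#'
#' @param cases list of \code{PhantomCase}.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cases, function(cs) {
    sp <- cs@spec
    data.frame(id = cs@id, group = cs@group,
               lesion_present = sp@lesionPresent,
               lesion_side = if (sp@lesionPresent) sp@lesionSide else NA,
               lesion_radius_mm = if (sp@lesionPresent) sp@lesionRadiusMm else NA,
               lesion_contrast = if (sp@lesionPresent) sp@lesionContrast else NA,
               confounder_periventricular = sp@confounderPeriventricular,
               confounder_sulcal = sp@confounderSulcal,
               noise_sd = sp@noiseSd, seed = sp@seed)
  })
  manifest <- do.call(rbind, rows)
  for (cs in cases) writeCase(cs, file.path(dir, cs@id))
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
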