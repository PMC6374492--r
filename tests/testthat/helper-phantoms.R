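# Shared fixtures, generated once per test run and cached. Unit tests use
# small grids; the phantom defaults themselves are exercised in
# test-phantom.R.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A small, grid-aligned (no pose perturbation) phantom spec for unit tests;
# any PhantomSpec argument can be overridden.
smallSpec <- function(...) {
  args <- utils::modifyList(
    list(gridShape = c(48L, 48L, 36L), spacingMm = c(1.5, 1.5, 1.8),
         lesionRadiusMm = 8, posePerturbation = c(0, 0)),
    list(...))
  do.call(PhantomSpec, args)
}

smallLesioned <- function() fixture("smallLesioned", function()
  generatePhantom(smallSpec(seed = 11L), id = "les"))

smallHealthy <- function() fixture("smallHealthy", function()
  generatePhantom(smallSpec(lesionPresent = FALSE, seed = 12L), id = "neg"))

# Preprocessed versions (estimated mask, 1.5 mm target to keep tests fast).
smallPreprocConfig <- function()
  preprocessConfig(targetSpacingMm = 1.5, maxMetricPoints = 6000L)

smallLesionedPP <- function() fixture("smallLesionedPP", function()
  suppressWarnings(preprocessCase(smallLesioned(), smallPreprocConfig())))

smallHealthyPP <- function() fixture("smallHealthyPP", function()
  suppressWarnings(preprocessCase(smallHealthy(), smallPreprocConfig())))

# Tiny network configuration used across network tests.
tinyNetConfig <- function(nInputChannels = 2L)
  networkConfig(nInputChannels = nInputChannels, convFilters = c(4, 6),
                hiddenFilters = 8, outputSize = 3L, downsampleFactor = 3L)

# Random binary mask helper on a simple unit grid.
randomMask <- function(dim, p, seed) {
  set.seed(seed)
  BinaryMask(array(rbinom(prod(dim), 1, p), dim))
}
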