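#' @import methods
NULL

#' Mesh-cap collection efficiency curve
#'
#' Tabulated size-dependent collection efficiency of the perforated mesh cap
#' that covers the sampler stub: the fraction of approaching particles of a
#' given aerodynamic diameter that penetrate the conical holes and deposit.
#' Queried by [meshEfficiency()], which interpolates linearly between knots
#' and clamps to the end values outside the tabulated range.
#'
#' @slot diameters Numeric, aerodynamic diameters (micrometres), strictly
#'   increasing.
#' @slot efficiencies Numeric in `[0, 1]`, one value per diameter.
#' @slot label Character scalar identifying the curve's provenance.
#'
#' @seealso [efficiencyCurve()], [defaultEfficiencyCurve()],
#'   [readEfficiencyCurve()]
#' @exportClass EfficiencyCurve
setClass("EfficiencyCurve",
  representation(
    diameters = "numeric",
    efficiencies = "numeric",
    label = "character"
  )
)

setValidity("EfficiencyCurve", function(object) {
  msg <- character()
  if (length(object@diameters) < 1L)
    msg <- c(msg, "curve needs at least one knot")
  if (length(object@diameters) != length(object@efficiencies))
    msg <- c(msg, "diameters and efficiencies must have equal length")
  if (any(!is.finite(object@diameters)) || any(object@diameters <= 0))
    msg <- c(msg, "diameters must be finite and positive")
  if (is.unsorted(object@diameters, strictly = TRUE))
    msg <- c(msg, "diameters must be strictly increasing")
  if (any(!is.finite(object@efficiencies)) ||
      any(object@efficiencies < 0) || any(object@efficiencies > 1))
    msg <- c(msg, "efficiencies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an efficiency curve
#'
#' @param diameters Aerodynamic diameters (micrometres), strictly increasing.
#' @param efficiencies Collection efficiencies in `[0, 1]`, same length.
#' @param label Short provenance label stored with the curve.
#' @return An [EfficiencyCurve-class] object.
#' @examples
#' efficiencyCurve(c(0.5, 1, 10), c(1, 0.9, 0.5))
#' @export
efficiencyCurve <- function(diameters, efficiencies, label = "user") {
  new("EfficiencyCurve",
      diameters = as.numeric(diameters),
      efficiencies = as.numeric(efficiencies),
      label = label)
}

#' Sampler physics and analysis configuration
#'
#' Bundles every physical constant and model choice of the analysis chain:
#' shape factors and particle density used to convert projected areas to
#' aerodynamic diameters and masses, the air state entering the Cunningham
#' slip correction and Stokes settling, the deposition-velocity model, the
#' mesh-cap collection-efficiency curve, the PM fraction convention, and the
#' image-processing parameters (pixel scale, area filters, connectivity,
#' polarity, count-adequacy warning thresholds).
#'
#' The volume shape factor follows the convention `V = f_V * d_pa^3` with
#' `d_pa` the projected-area diameter; the default 1.6 is only meaningful
#' under this convention. Defaults: `f_V = 1.6`, dynamic shape factor
#' `chi = 1.4`, particle density 2.0 g cm^-3, a 12 mm stub, 0.64 um pixels,
#' area filters 0.41-10000 um^2.
#'
#' @slot volumeShapeFactor Dimensionless, `V = f_V * d_pa^3` (default 1.6).
#' @slot dynamicShapeFactor Dimensionless drag ratio chi >= 1 (default 1.4).
#' @slot particleDensity Particle density, g cm^-3 (default 2.0).
#' @slot referenceDensity Unit density defining aerodynamic diameter,
#'   g cm^-3 (1.0).
#' @slot airTemperature K (default 293).
#' @slot airPressure kPa (default 101.3).
#' @slot airViscosity Pa s (default 1.81e-5).
#' @slot meanFreePath Gas mean free path, um (default 0.0665).
#' @slot depositionModel `"settling_plus_diffusion"` or `"settling_only"`.
#' @slot boundaryLayer Diffusive boundary-layer thickness, mm (default 1).
#' @slot efficiencyCurve An [EfficiencyCurve-class].
#' @slot stubDiameter Stub diameter, mm (default 12).
#' @slot pmConvention `"sharp"` (inclusive cut) or `"smooth"` (lognormal
#'   penetration around the cut).
#' @slot pmCuts Named numeric, PM cut diameters um, default
#'   `c(pm25 = 2.5, pm10 = 10)`.
#' @slot pixelSide Image pixel side, um (default 0.64).
#' @slot minArea,maxArea Particle area filters, um^2 (0.41, 10000).
#' @slot connectivity 8 or 4 for component labelling.
#' @slot foregroundPolarity `"bright"` (backscatter default) or `"dark"`.
#' @slot minClassContrast Minimum foreground-background mean grey-level
#'   separation for a tile to count as containing particles (default 30).
#' @slot countWarning Named numeric, minimum adequate particle counts per
#'   fraction, default `c(pm25 = 55, pm10 = 71)`.
#' @slot normArea `"analyzed"`, `"stub"`, or a number (mm^2): the area that
#'   normalises deposited mass into concentration.
#' @slot configId Character scalar; deterministic fingerprint of all other
#'   slots, stamped onto every result row.
#'
#' @seealso [samplerConfig()], [validateConfig()]
#' @exportClass SamplerConfig
setClass("SamplerConfig",
  representation(
    volumeShapeFactor = "numeric",
    dynamicShapeFactor = "numeric",
    particleDensity = "numeric",
    referenceDensity = "numeric",
    airTemperature = "numeric",
    airPressure = "numeric",
    airViscosity = "numeric",
    meanFreePath = "numeric",
    depositionModel = "character",
    boundaryLayer = "numeric",
    efficiencyCurve = "EfficiencyCurve",
    stubDiameter = "numeric",
    pmConvention = "character",
    pmCuts = "numeric",
    pixelSide = "numeric",
    minArea = "numeric",
    maxArea = "numeric",
    connectivity = "numeric",
    foregroundPolarity = "character",
    minClassContrast = "numeric",
    countWarning = "numeric",
    normArea = "ANY",
    configId = "character"
  )
)

setValidity("SamplerConfig", function(object) {
  msg <- character()
  pos <- function(x) length(x) == 1L && is.finite(x) && x > 0
  if (!pos(object@volumeShapeFactor))
    msg <- c(msg, "volumeShapeFactor must be a positive scalar")
  if (!(length(object@dynamicShapeFactor) == 1L &&
        is.finite(object@dynamicShapeFactor) &&
        object@dynamicShapeFactor >= 1))
    msg <- c(msg, "dynamicShapeFactor must be >= 1")
  if (!pos(object@particleDensity))
    msg <- c(msg, "particleDensity must be positive")
  if (!pos(object@referenceDensity))
    msg <- c(msg, "referenceDensity must be positive")
  for (sl in c("airTemperature", "airPressure", "airViscosity",
               "meanFreePath", "boundaryLayer", "stubDiameter",
               "pixelSide")) {
    if (!pos(slot(object, sl))) msg <- c(msg, paste(sl, "must be positive"))
  }
  if (!object@depositionModel %in%
      c("settling_plus_diffusion", "settling_only"))
    msg <- c(msg, "unknown depositionModel")
  if (!object@pmConvention %in% c("sharp", "smooth"))
    msg <- c(msg, "pmConvention must be 'sharp' or 'smooth'")
  if (length(object@pmCuts) < 1L || any(object@pmCuts <= 0))
    msg <- c(msg, "pmCuts must be positive")
  if (!(object@minArea >= 0 && object@maxArea > object@minArea))
    msg <- c(msg, "area filters need 0 <= minArea < maxArea")
  if (!object@connectivity %in% c(4, 8))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (!object@foregroundPolarity %in% c("bright", "dark"))
    msg <- c(msg, "foregroundPolarity must be 'bright' or 'dark'")
  if (is.character(object@normArea)) {
    if (!object@normArea %in% c("analyzed", "stub"))
      msg <- c(msg, "normArea must be 'analyzed', 'stub', or mm^2")
  } else if (!(is.numeric(object@normArea) && pos(object@normArea))) {
    msg <- c(msg, "numeric normArea must be a positive scalar")
  }
  if (length(msg)) msg else TRUE
})

#' One SEM tile image
#'
#' A single grey-level raster tile from the microscopy capture of a sampler
#' stub, together with its physical pixel scale and provenance.
#'
#' @slot pixels Integer matrix of grey levels (0-255 for 8-bit imagery).
#' @slot pixelSide Pixel side length, um.
#' @slot tileIndex Integer tile number within the stub capture.
#' @slot stubId Character identifier of the stub.
#' @seealso [SemTile()], [extractParticles()]
#' @exportClass SemTile
setClass("SemTile",
  representation(
    pixels = "matrix",
    pixelSide = "numeric",
    tileIndex = "integer",
    stubId = "character"
  )
)

setValidity("SemTile", function(object) {
  msg <- character()
  if (length(object@pixels) == 0L)
    msg <- c(msg, "pixel grid must be non-empty")
  if (!(length(object@pixelSide) == 1L && is.finite(object@pixelSide) &&
        object@pixelSide > 0))
    msg <- c(msg, "pixelSide must be positive")
  if (any(object@pixels < 0, na.rm = TRUE))
    msg <- c(msg, "grey levels must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a SEM tile
#'
#' @param pixels Numeric or integer matrix of grey levels.
#' @param pixelSide Pixel side length in micrometres (default 0.64).
#' @param tileIndex Tile number within the stub capture.
#' @param stubId Stub identifier.
#' @return A [SemTile-class] object.
#' @export
SemTile <- function(pixels, pixelSide = 0.64, tileIndex = 1L,
                    stubId = "stub") {
  storage.mode(pixels) <- "integer"
  new("SemTile", pixels = pixels, pixelSide = pixelSide,
      tileIndex = as.integer(tileIndex), stubId = stubId)
}

#' A full stub capture: tiles plus (optionally) simulation truth
#'
#' The set of non-overlapping tiles that together cover the analysed area of
#' one stub. When produced by [renderTiles()] it also carries the ground
#' truth table of deposited particles and the seed that generated them.
#'
#' @slot tiles List of [SemTile-class] objects sharing `stubId` and scale.
#' @slot stubId Character identifier.
#' @slot pixelSide Pixel side, um.
#' @slot truth `data.frame` of deposited-particle truth (may have 0 rows for
#'   real imagery).
#' @slot seed Integer seed that generated the stub (`NA` for real imagery).
#' @seealso [StubImageSet()], [collectStub()]
#' @exportClass StubImageSet
setClass("StubImageSet",
  representation(
    tiles = "list",
    stubId = "character",
    pixelSide = "numeric",
    truth = "data.frame",
    seed = "integer"
  )
)

setValidity("StubImageSet", function(object) {
  msg <- character()
  if (!all(vapply(object@tiles, is, logical(1), class2 = "SemTile")))
    msg <- c(msg, "tiles must all be SemTile objects")
  if (length(object@tiles)) {
    ids <- vapply(object@tiles, function(t) t@stubId, character(1))
    if (!all(ids == object@stubId))
      msg <- c(msg, "all tiles must share the stub's stubId")
    px <- vapply(object@tiles, function(t) t@pixelSide, numeric(1))
    if (!all(abs(px - object@pixelSide) < 1e-12))
      msg <- c(msg, "all tiles must share the stub's pixelSide")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a stub image set
#'
#' @param tiles List of [SemTile-class] objects.
#' @param stubId Stub identifier (defaults to the first tile's).
#' @param truth Optional truth table from the generator.
#' @param seed Optional generator seed.
#' @return A [StubImageSet-class] object.
#' @export
StubImageSet <- function(tiles, stubId = NULL, truth = NULL, seed = NA) {
  if (is.null(stubId)) {
    stubId <- if (length(tiles)) tiles[[1L]]@stubId else "stub"
  }
  px <- if (length(tiles)) tiles[[1L]]@pixelSide else 0.64
  if (is.null(truth)) truth <- data.frame()
  new("StubImageSet", tiles = tiles, stubId = stubId, pixelSide = px,
      truth = truth, seed = as.integer(seed))
}

#' Ground-truth deposition scenario for the synthetic generator
#'
#' Describes an airborne aerosol and a sampling occasion from which the
#' generator deposits particles: a lognormal aerodynamic size distribution
#' carrying a stated mass concentration, the exposure duration, the deposited
#' area and its tiling, handling contamination, and the image noise model.
#' Defaults emulate a coarse-dominated inorganic mining dust sampled on a
#' full 12 mm stub.
#'
#' @slot trueConcentration Total airborne mass concentration, mg m^-3.
#' @slot cmd Count median aerodynamic diameter, um.
#' @slot gsd Geometric standard deviation (> 1).
#' @slot durationHours Exposure duration, h.
#' @slot depositionArea Deposited (tiled) area, mm^2; default the full
#'   12 mm stub disc, 113.10 mm^2.
#' @slot nTiles Number of tiles covering the area (default 36).
#' @slot contaminationRate Expected handling-contamination particles per
#'   stub (Poisson mean), default 40.
#' @slot noiseMean,noiseSd Background grey-level mean and sd (30, 3).
#' @slot particleGrey,particleGreySd Foreground grey-level mean and sd
#'   (210, 8).
#' @slot seed Integer RNG seed; all stub-level randomness derives from it.
#' @seealso [truthScenario()], [samplePopulation()], [renderTiles()]
#' @exportClass TruthScenario
setClass("TruthScenario",
  representation(
    trueConcentration = "numeric",
    cmd = "numeric",
    gsd = "numeric",
    durationHours = "numeric",
    depositionArea = "numeric",
    nTiles = "integer",
    contaminationRate = "numeric",
    noiseMean = "numeric",
    noiseSd = "numeric",
    particleGrey = "numeric",
    particleGreySd = "numeric",
    seed = "integer"
  )
)

setValidity("TruthScenario", function(object) {
  msg <- character()
  if (object@trueConcentration < 0)
    msg <- c(msg, "trueConcentration must be >= 0")
  if (object@gsd <= 1) msg <- c(msg, "gsd must be > 1")
  if (object@cmd <= 0) msg <- c(msg, "cmd must be > 0")
  if (object@durationHours <= 0) msg <- c(msg, "duration must be > 0")
  if (object@depositionArea <= 0) msg <- c(msg, "depositionArea must be > 0")
  if (object@nTiles < 1L) msg <- c(msg, "nTiles must be >= 1")
  if (object@contaminationRate < 0)
    msg <- c(msg, "contaminationRate must be >= 0")
  if (object@noiseSd < 0 || object@particleGreySd < 0)
    msg <- c(msg, "noise standard deviations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a truth scenario
#'
#' @param trueConcentration Airborne mass concentration, mg m^-3.
#' @param cmd Count median aerodynamic diameter, um.
#' @param gsd Geometric standard deviation, > 1.
#' @param durationHours Exposure duration, h.
#' @param depositionArea Deposited area, mm^2 (default 113.10, the full
#'   12 mm stub disc).
#' @param nTiles Tiles covering the area (default 36).
#' @param contaminationRate Expected contamination particles per stub.
#' @param noiseMean,noiseSd Background grey-level model.
#' @param particleGrey,particleGreySd Foreground grey-level model.
#' @param seed Integer RNG seed.
#' @return A [TruthScenario-class] object.
#' @examples
#' sc <- truthScenario(0.05, seed = 7, depositionArea = 1, nTiles = 4)
#' @export
truthScenario <- function(trueConcentration, cmd = 3, gsd = 1.5,
                          durationHours = 24, depositionArea = 113.0973,
                          nTiles = 36L, contaminationRate = 40,
                          noiseMean = 30, noiseSd = 3,
                          particleGrey = 210, particleGreySd = 8,
                          seed = 1L) {
  new("TruthScenario",
      trueConcentration = trueConcentration, cmd = cmd, gsd = gsd,
      durationHours = durationHours, depositionArea = depositionArea,
      nTiles = as.integer(nTiles), contaminationRate = contaminationRate,
      noiseMean = noiseMean, noiseSd = noiseSd, particleGrey = particleGrey,
      particleGreySd = particleGreySd, seed = as.integer(seed))
}

#' Optical particle counter spectrum
#'
#' Bin number concentrations from an optical particle counter covering
#' (by default) 0.3-10 um aerodynamic diameter, plus the density assumed
#' when converting counts to mass.
#'
#' @slot binEdges Increasing bin edges, um (length = bins + 1).
#' @slot numberConcentrations Particles per m^3 in each bin, >= 0.
#' @slot density Conversion density, g cm^-3 (default 2.0).
#' @seealso [opcSpectrum()], [opcToPm()]
#' @exportClass OpcSpectrum
setClass("OpcSpectrum",
  representation(
    binEdges = "numeric",
    numberConcentrations = "numeric",
    density = "numeric"
  )
)

setValidity("OpcSpectrum", function(object) {
  msg <- character()
  if (length(object@binEdges) != length(object@numberConcentrations) + 1L)
    msg <- c(msg, "need length(binEdges) == length(concentrations) + 1")
  if (is.unsorted(object@binEdges, strictly = TRUE))
    msg <- c(msg, "binEdges must be strictly increasing")
  if (any(object@binEdges <= 0))
    msg <- c(msg, "binEdges must be positive")
  if (any(object@numberConcentrations < 0))
    msg <- c(msg, "number concentrations must be >= 0")
  if (!(length(object@density) == 1L && object@density > 0))
    msg <- c(msg, "density must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct an OPC spectrum
#'
#' @param binEdges Increasing bin edges, um.
#' @param numberConcentrations Particles per m^3 per bin.
#' @param density Conversion density, g cm^-3 (default 2.0).
#' @return An [OpcSpectrum-class] object.
#' @examples
#' opcSpectrum(c(0.3, 0.5, 1, 2.5, 5, 10), c(1e7, 5e6, 1e6, 2e5, 1e4))
#' @export
opcSpectrum <- function(binEdges, numberConcentrations, density = 2.0) {
  new("OpcSpectrum", binEdges = as.numeric(binEdges),
      numberConcentrations = as.numeric(numberConcentrations),
      density = density)
}
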