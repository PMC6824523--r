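#' @describeIn SemTile-class Compact display.
#' @param object A `SemTile`.
#' @export
setMethod("show", "SemTile", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SemTile '%s' #%d: %d x %d px @ %.3g um/px (%.3g mm^2)\n",
              object@stubId, object@tileIndex, d[1L], d[2L],
              object@pixelSide,
              prod(d) * object@pixelSide^2 / 1e6))
})

#' @describeIn StubImageSet-class Compact display.
#' @param object A `StubImageSet`.
#' @export
setMethod("show", "StubImageSet", function(object) {
  cat(sprintf("StubImageSet '%s': %d tiles @ %.3g um/px",
              object@stubId, length(object@tiles), object@pixelSide))
  if (nrow(object@truth))
    cat(sprintf(", %d truth particles (seed %d)",
                nrow(object@truth), object@seed))
  cat("\n")
})

#' @describeIn SamplerConfig-class Compact display.
#' @param object A `SamplerConfig`.
#' @export
setMethod("show", "SamplerConfig", function(object) {
  cat(sprintf(
    paste0("SamplerConfig [%s]\n",
           "  shape factors f_V = %.3g, chi = %.3g; rho_p = %.3g g/cm^3\n",
           "  deposition model: %s; efficiency curve: %s (%d knots)\n",
           "  pixel %.3g um; area filter [%.3g, %.3g] um^2; ",
           "connectivity %d; PM convention: %s\n"),
    object@configId, object@volumeShapeFactor, object@dynamicShapeFactor,
    object@particleDensity, object@depositionModel,
    object@efficiencyCurve@label, length(object@efficiencyCurve@diameters),
    object@pixelSide, object@minArea, object@maxArea,
    as.integer(object@connectivity), object@pmConvention))
})

#' @describeIn TruthScenario-class Compact display.
#' @param object A `TruthScenario`.
#' @export
setMethod("show", "TruthScenario", function(object) {
  cat(sprintf(
    paste0("TruthScenario: C = %.4g mg/m^3, lognormal(CMD %.3g um, ",
           "GSD %.3g), %s h\n  area %.4g mm^2 in %d tiles; ",
           "contamination %.3g/stub; seed %d\n"),
    object@trueConcentration, object@cmd, object@gsd,
    format(object@durationHours), object@depositionArea, object@nTiles,
    object@contaminationRate, object@seed))
})

#' @describeIn OpcSpectrum-class Compact display.
#' @param object An `OpcSpectrum`.
#' @export
setMethod("show", "OpcSpectrum", function(object) {
  cat(sprintf(
    "OpcSpectrum: %d bins over [%.3g, %.3g] um, density %.3g g/cm^3\n",
    length(object@numberConcentrations), min(object@binEdges),
    max(object@binEdges), object@density))
})

#' @describeIn EfficiencyCurve-class Compact display.
#' @param object An `EfficiencyCurve`.
#' @export
setMethod("show", "EfficiencyCurve", function(object) {
  cat(sprintf(
    "EfficiencyCurve '%s': %d knots over [%.3g, %.3g] um, eta in [%.3g, %.3g]\n",
    object@label, length(object@diameters), min(object@diameters),
    max(object@diameters), min(object@efficiencies),
    max(object@efficiencies)))
})
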