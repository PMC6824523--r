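#' Gravimetric impactor concentration
#'
#' Converts duplicate pre/post filter weighings and start/end flow checks
#' into a mass concentration: the blank-corrected mass gain
#' `mean(post) - mean(pre) - blankMean` divided by the sampled air volume
#' `mean(flowStart, flowEnd) * duration`. Flows outside the configured
#' tolerance band around the nominal flow produce a warning; the result is
#' still computed.
#'
#' @param preWeights Two pre-sampling filter weights, mg.
#' @param postWeights Two post-sampling filter weights, mg.
#' @param flowStart,flowEnd Measured flows, L min^-1.
#' @param durationMin Sampling duration, minutes.
#' @param blankMean Mean transport-blank mass change, mg (default 0).
#' @param nominalFlow Nominal pump flow, L min^-1 (default 10).
#' @param flowTolerance Accepted deviation from nominal, L min^-1
#'   (default 0.5).
#' @return Concentration, mg m^-3.
#' @examples
#' impactorConcentration(c(100, 100), c(101, 101), 10, 10, 1440)  # 0.0694
#' @export
impactorConcentration <- function(preWeights, postWeights, flowStart,
                                  flowEnd, durationMin, blankMean = 0,
                                  nominalFlow = 10, flowTolerance = 0.5) {
  stopifnot(length(preWeights) == 2L, length(postWeights) == 2L)
  if (durationMin <= 0) stop("duration must be positive")
  flows <- c(flowStart, flowEnd)
  off <- abs(flows - nominalFlow) > flowTolerance
  if (any(off))
    warning(sprintf(
      "flow check %s L/min outside %g +/- %g L/min; result flagged",
      paste(format(flows[off]), collapse = ", "), nominalFlow,
      flowTolerance))
  dm <- mean(postWeights) - mean(preWeights) - blankMean
  volume_m3 <- mean(flows) * durationMin / 1000      # L -> m^3
  dm / volume_m3
}

## Representative diameter of a bin
.binDiameter <- function(lo, hi, mode = c("geometric", "arithmetic")) {
  mode <- match.arg(mode)
  if (mode == "geometric") sqrt(lo * hi) else (lo + hi) / 2
}

#' Convert an OPC spectrum to PM mass concentrations
#'
#' Each bin's number concentration is converted to mass assuming spheres of
#' the bin's representative diameter (geometric mean of the edges by
#' default) and the spectrum's density. Cumulative fractions PM0.5, PM1.0,
#' PM2.5, PM5.0 and PM10 sum the mass of all bins whose upper edge does not
#' exceed the cut. PM0.75, a proxy for the optically resolvable fine
#' fraction, is defined as the mean of PM0.5 and PM1.0.
#'
#' @param spec An [OpcSpectrum-class].
#' @param representativeDiameter `"geometric"` (default) or
#'   `"arithmetic"` bin-centre convention; the choice is recorded in the
#'   result's attributes since the instrument's internal algorithm is
#'   proprietary.
#' @param cuts Cumulative cut diameters, um.
#' @return Named numeric of mass concentrations (mg m^-3): one element per
#'   cut (named `pm0.5`, `pm1`, ...) plus `pm0.75`. Attribute
#'   `representativeDiameter` records the bin-centre convention.
#' @examples
#' sp <- opcSpectrum(c(0.3, 0.5, 1, 2.5, 5, 10), c(2e8, 2e7, 1e6, 5e4, 1e3))
#' opcToPm(sp)
#' @export
opcToPm <- function(spec, representativeDiameter = "geometric",
                    cuts = c(0.5, 1.0, 2.5, 5.0, 10)) {
  stopifnot(is(spec, "OpcSpectrum"))
  lo <- utils::head(spec@binEdges, -1L)
  hi <- utils::tail(spec@binEdges, -1L)
  dRep <- .binDiameter(lo, hi, representativeDiameter)
  # N (m^-3) * pi/6 d^3 (um^3) * rho (g/cm^3): um^3 -> cm^3 is 1e-12,
  # g -> mg is 1e3  =>  mg m^-3 factor 1e-9
  binMass <- spec@numberConcentrations * (pi / 6) * dRep^3 *
    spec@density * 1e-9
  pm <- vapply(cuts, function(x) sum(binMass[hi <= x]), numeric(1))
  names(pm) <- paste0("pm", vapply(cuts, function(x)
    sub("\\.0$", "", as.character(x)), character(1)))
  out <- c(pm, pm0.75 = unname((pm[["pm0.5"]] + pm[["pm1"]]) / 2))
  ord <- order(c(cuts, 0.75))
  out <- out[ord]
  attr(out, "representativeDiameter") <- representativeDiameter
  out
}

#' Fine-fraction ratios from OPC PM masses
#'
#' Percentage of PM2.5 and PM10 mass carried by particles below 0.75 um
#' (PM0.75 / PM2.5 and PM0.75 / PM10), the proxy used to bound how much of
#' a sampler's undercounting could stem from particles too small to
#' resolve in the microscope. Zero denominators yield `NA` (reported as
#' missing).
#'
#' @param pm Named numeric from [opcToPm()] (needs `pm0.75`, `pm2.5`,
#'   `pm10`).
#' @return Named numeric, percent: `pm0.75_over_pm2.5`,
#'   `pm0.75_over_pm10`.
#' @export
fineFractionRatios <- function(pm) {
  stopifnot(all(c("pm0.75", "pm2.5", "pm10") %in% names(pm)))
  ratio <- function(den) {
    if (pm[[den]] <= 0) NA_real_ else 100 * pm[["pm0.75"]] / pm[[den]]
  }
  c(pm0.75_over_pm2.5 = ratio("pm2.5"),
    pm0.75_over_pm10 = ratio("pm10"))
}
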