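## Physical constants (SI)
.kBoltzmann <- 1.380649e-23   # J/K
.gravity <- 9.80665           # m/s^2

## Allen-Raabe slip-correction constants for solid particles
.slipA <- 1.142
.slipB <- 0.558
.slipC <- 0.999

#' Projected-area equivalent diameter
#'
#' Diameter of the circle with the same area as the particle's 2-D image:
#' `d_pa = sqrt(4 A / pi)`.
#'
#' @param area Projected area(s), um^2, strictly positive.
#' @return Diameter(s), um.
#' @examples
#' projectedAreaDiameter(pi / 4)   # 1 um
#' @export
projectedAreaDiameter <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop("projected area must be positive and finite")
  sqrt(4 * area / pi)
}

#' Particle mass from projected-area diameter
#'
#' Applies the volume shape factor convention `V = f_V * d_pa^3` and the
#' configured particle density. With `f_V = pi/6` and unit density this
#' reduces to the mass of a sphere of diameter `d_pa`.
#'
#' @param dPa Projected-area diameter(s), um.
#' @param cfg A [SamplerConfig-class].
#' @return Mass(es) in nanograms.
#' @examples
#' cfg <- samplerConfig()
#' particleMass(1, cfg)   # 1.6 um^3 * 2.0 g/cm^3 = 3.2e-3 ng
#' @export
particleMass <- function(dPa, cfg) {
  if (any(dPa <= 0)) stop("d_pa must be positive")
  volume_um3 <- cfg@volumeShapeFactor * dPa^3
  # 1 um^3 = 1e-12 cm^3; 1 g = 1e9 ng  =>  ng = g/cm^3 * um^3 * 1e-3
  cfg@particleDensity * volume_um3 * 1e-3
}

#' Cunningham slip correction factor
#'
#' `C_c = 1 + Kn (a + b exp(-c / Kn))` with `Kn = 2 lambda / d` and the
#' Allen-Raabe solid-particle constants a = 1.142, b = 0.558, c = 0.999.
#' The mean free path comes from the configured air state (default
#' 0.0665 um at 101.3 kPa, 293 K).
#'
#' @param d Particle diameter(s), um.
#' @param cfg A [SamplerConfig-class] (supplies the mean free path).
#' @return Dimensionless slip correction(s), >= 1.
#' @export
cunninghamFactor <- function(d, cfg) {
  if (any(d <= 0)) stop("diameter must be positive")
  kn <- 2 * cfg@meanFreePath / d
  1 + kn * (.slipA + .slipB * exp(-.slipC / kn))
}

#' Volume-equivalent diameter from projected-area diameter
#'
#' Under the `V = f_V * d_pa^3` convention the sphere with equal volume has
#' `d_ve = (6 f_V / pi)^(1/3) d_pa`.
#'
#' @inheritParams particleMass
#' @return Volume-equivalent diameter(s), um.
#' @export
volumeEquivalentDiameter <- function(dPa, cfg) {
  (6 * cfg@volumeShapeFactor / pi)^(1 / 3) * dPa
}

## Solve x^2 Cc(x) = K for x by damped fixed point from start value x0:
## x <- sqrt(K / Cc(x)). Vectorised over K.
.solveSlipSquare <- function(K, x0, cfg, tol = 1e-9, maxit = 100L) {
  x <- x0
  for (i in seq_len(maxit)) {
    xn <- sqrt(K / cunninghamFactor(x, cfg))
    rel <- abs(xn - x) / x
    x <- xn
    if (all(rel < tol)) return(x)
  }
  stop(sprintf(
    "slip-corrected diameter iteration did not converge (max rel step %.3g after %d iterations)",
    max(rel), maxit))
}

#' Aerodynamic diameter from projected-area diameter
#'
#' Converts via the volume-equivalent diameter and solves the
#' slip-corrected impossibility-of-distinguishing condition
#' `d_ae^2 C_c(d_ae) rho_0 = d_ve^2 C_c(d_ve) rho_p / chi`
#' by damped fixed-point iteration started at the no-slip solution
#' (relative tolerance 1e-9, at most 100 iterations). In the sphere limit
#' (`f_V = pi/6`, `chi = 1`, `rho_p = rho_0`) the identity `d_ae = d_pa`
#' holds to numerical precision.
#'
#' @inheritParams particleMass
#' @return Aerodynamic diameter(s), um.
#' @examples
#' cfg <- samplerConfig()
#' aerodynamicDiameter(1, cfg)
#' @export
aerodynamicDiameter <- function(dPa, cfg) {
  if (any(dPa <= 0)) stop("d_pa must be positive")
  dVe <- volumeEquivalentDiameter(dPa, cfg)
  K <- dVe^2 * cunninghamFactor(dVe, cfg) * cfg@particleDensity /
    (cfg@dynamicShapeFactor * cfg@referenceDensity)
  x0 <- dVe * sqrt(cfg@particleDensity /
                     (cfg@dynamicShapeFactor * cfg@referenceDensity))
  .solveSlipSquare(K, x0, cfg)
}

#' Projected-area diameter from aerodynamic diameter
#'
#' Exact inverse of [aerodynamicDiameter()], solving the same implicit
#' slip-corrected condition for the volume-equivalent diameter.
#'
#' @param dAe Aerodynamic diameter(s), um.
#' @param cfg A [SamplerConfig-class].
#' @return Projected-area diameter(s), um.
#' @export
projectedFromAerodynamic <- function(dAe, cfg) {
  if (any(dAe <= 0)) stop("d_ae must be positive")
  K <- dAe^2 * cunninghamFactor(dAe, cfg) * cfg@dynamicShapeFactor *
    cfg@referenceDensity / cfg@particleDensity
  x0 <- dAe * sqrt(cfg@dynamicShapeFactor * cfg@referenceDensity /
                     cfg@particleDensity)
  dVe <- .solveSlipSquare(K, x0, cfg)
  dVe / (6 * cfg@volumeShapeFactor / pi)^(1 / 3)
}

#' Deposition velocity
#'
#' Effective deposition velocity of the sampler for a particle of given
#' aerodynamic diameter. The default `"settling_plus_diffusion"` model sums
#' gravitational settling of the unit-density aerodynamic sphere,
#' `v_s = rho_0 g d_ae^2 C_c(d_ae) / (18 mu)`, and a Brownian term
#' `v_d = D / delta` with `D` from Stokes-Einstein and `delta` the
#' configured boundary-layer thickness (default 1 mm). The alternative
#' `"settling_only"` model uses `v_s` alone.
#'
#' @param dAe Aerodynamic diameter(s), um.
#' @param cfg A [SamplerConfig-class].
#' @return Deposition velocity (m s^-1).
#' @examples
#' cfg <- samplerConfig(particleDensity = 1, dynamicShapeFactor = 1,
#'                      volumeShapeFactor = pi / 6)
#' depositionVelocity(10, cfg)   # ~3e-3 m/s for a 10 um unit-density sphere
#' @export
depositionVelocity <- function(dAe, cfg) {
  if (any(dAe <= 0)) stop("d_ae must be positive")
  d_m <- dAe * 1e-6
  rho0 <- cfg@referenceDensity * 1000        # g/cm^3 -> kg/m^3
  cc <- cunninghamFactor(dAe, cfg)
  vs <- rho0 * .gravity * d_m^2 * cc / (18 * cfg@airViscosity)
  if (cfg@depositionModel == "settling_only") return(vs)
  D <- .kBoltzmann * cfg@airTemperature * cc /
    (3 * pi * cfg@airViscosity * d_m)
  vd <- D / (cfg@boundaryLayer * 1e-3)
  vs + vd
}

#' Mesh-cap collection efficiency
#'
#' Monotone piecewise-linear interpolation of an [EfficiencyCurve-class] at
#' the requested aerodynamic diameters; outside the tabulated range the end
#' values are used. Results are clamped to `[0, 1]`.
#'
#' @param dAe Aerodynamic diameter(s), um.
#' @param curve An [EfficiencyCurve-class].
#' @return Efficiency value(s) in `[0, 1]`.
#' @examples
#' cv <- efficiencyCurve(c(0.5, 1.0), c(0.4, 0.8))
#' meshEfficiency(0.75, cv)   # 0.6
#' @export
meshEfficiency <- function(dAe, curve) {
  if (!is(curve, "EfficiencyCurve") || length(curve@diameters) == 0L)
    stop("empty or invalid efficiency curve")
  if (length(curve@diameters) == 1L)
    return(rep(curve@efficiencies, length(dAe)))
  y <- stats::approx(curve@diameters, curve@efficiencies, xout = dAe,
                     method = "linear", rule = 2)$y
  pmin(pmax(y, 0), 1)
}

#' Default placeholder efficiency curve
#'
#' A documented placeholder with a logistic-shaped decline from full
#' efficiency below 1 um toward larger sizes,
#' `eta(d) = 1 / (1 + (d / 10)^2)` tabulated on log-spaced knots. The
#' published mesh-cap curves for the sampler are not reproduced here; for
#' fidelity to a given cap, load the appropriate tabulated curve with
#' [readEfficiencyCurve()] or [efficiencyCurve()].
#'
#' @return An [EfficiencyCurve-class].
#' @export
defaultEfficiencyCurve <- function() {
  d <- c(0.1, 0.3, 0.5, 1, 2, 3.2, 5, 7, 10, 15, 20)
  efficiencyCurve(d, 1 / (1 + (d / 10)^2), label = "placeholder_logistic")
}

#' Unit efficiency curve
#'
#' Collection efficiency 1 at every size (an ideally transmitting cap).
#' @return An [EfficiencyCurve-class].
#' @export
unitEfficiencyCurve <- function() {
  efficiencyCurve(c(0.1, 100), c(1, 1), label = "unit")
}

#' Read an efficiency curve from a two-column CSV
#'
#' @param path CSV with columns `d_um` and `efficiency`.
#' @return An [EfficiencyCurve-class] labelled with the file name.
#' @export
readEfficiencyCurve <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("d_um", "efficiency") %in% names(tab)))
    stop("efficiency curve CSV needs columns 'd_um' and 'efficiency'")
  efficiencyCurve(tab$d_um, tab$efficiency, label = basename(path))
}

#' Attach diameters and masses to detected particles
#'
#' Adds projected-area, volume-equivalent and aerodynamic diameters and the
#' shape-factor mass to a particle table produced by [extractParticles()] or
#' [collectStub()].
#'
#' @param particles `data.frame` with an `area_um2` column.
#' @param cfg A [SamplerConfig-class].
#' @return The table with columns `d_pa_um`, `d_ve_um`, `d_ae_um`,
#'   `mass_ng` appended.
#' @export
sizeParticles <- function(particles, cfg) {
  stopifnot(is.data.frame(particles), "area_um2" %in% names(particles))
  if (nrow(particles) == 0L) {
    particles$d_pa_um <- particles$d_ve_um <-
      particles$d_ae_um <- particles$mass_ng <- numeric(0)
    return(particles)
  }
  dPa <- projectedAreaDiameter(particles$area_um2)
  particles$d_pa_um <- dPa
  particles$d_ve_um <- volumeEquivalentDiameter(dPa, cfg)
  particles$d_ae_um <- aerodynamicDiameter(dPa, cfg)
  particles$mass_ng <- particleMass(dPa, cfg)
  particles
}
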