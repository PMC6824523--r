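## Independent RNG streams derived from one scenario seed (kept < 2^31).
.derivedSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 48611 * 37199 + stream * 7919 + 11) %%
               2147483629)
}

## Tile geometry implied by a scenario: square tiles whose total area is as
## close as the pixel grid allows to the requested deposition area. The
## effective (rendered) area is used consistently by the flux model and the
## renderer so that generation and analysis normalise over the same area.
.scenarioGeometry <- function(scenario, cfg) {
  target_um2 <- scenario@depositionArea * 1e6 / scenario@nTiles
  side <- max(8L, as.integer(round(sqrt(target_um2) / cfg@pixelSide)))
  list(tilePixels = side,
       effectiveArea = scenario@nTiles * (side * cfg@pixelSide)^2 / 1e6)
}

## Log-spaced aerodynamic size classes spanning +/- 5 geometric sds of the
## number distribution, with the mass fraction each class carries. The
## mass-weighted distribution of a lognormal number distribution is again
## lognormal with the same GSD and median cmd * exp(3 ln^2 gsd).
.sizeGrid <- function(scenario, nClasses = 160L) {
  lg <- log(scenario@gsd)
  edges <- exp(seq(log(scenario@cmd) - 5 * lg, log(scenario@cmd) + 5 * lg,
                   length.out = nClasses + 1L))
  mmd <- scenario@cmd * exp(3 * lg^2)
  massFrac <- diff(stats::plnorm(edges, meanlog = log(mmd), sdlog = lg))
  list(lower = utils::head(edges, -1L), upper = utils::tail(edges, -1L),
       mid = sqrt(utils::head(edges, -1L) * utils::tail(edges, -1L)),
       massFrac = massFrac)
}

#' Mass fraction and true PM concentration of a scenario
#'
#' Under the sharp-cut convention, the true concentration of the PM
#' fraction below `cut` implied by a scenario's lognormal size
#' distribution.
#'
#' @param scenario A [TruthScenario-class].
#' @param cut Aerodynamic cut diameter, um.
#' @return Concentration, mg m^-3.
#' @export
truePmConcentration <- function(scenario, cut) {
  lg <- log(scenario@gsd)
  mmd <- scenario@cmd * exp(3 * lg^2)
  scenario@trueConcentration *
    stats::plnorm(cut, meanlog = log(mmd), sdlog = lg)
}

#' Expected deposition per size class
#'
#' The analytic Poisson means the generator samples from: for each
#' aerodynamic size class, the expected number of deposited particles is
#' `lambda = C * massFraction / m(d) * eta(d) * v_dep(d) * A * t`, i.e. the
#' airborne number concentration in the class times the mesh-cap
#' efficiency, the deposition velocity, the deposited area, and the
#' duration. Particle mass follows the same shape-factor chain the
#' analysis inverts.
#'
#' @param scenario A [TruthScenario-class].
#' @param cfg A [SamplerConfig-class].
#' @return `data.frame` with `d_ae_um` (class geometric mid), `lower`,
#'   `upper`, `massFraction`, `mass_ng`, `lambda`.
#' @export
expectedDeposition <- function(scenario, cfg) {
  g <- .scenarioGeometry(scenario, cfg)
  sg <- .sizeGrid(scenario)
  dPa <- projectedFromAerodynamic(sg$mid, cfg)
  mass_mg <- particleMass(dPa, cfg) * 1e-6
  eta <- meshEfficiency(sg$mid, cfg@efficiencyCurve)
  vdep <- depositionVelocity(sg$mid, cfg)
  if (any(!is.finite(vdep)))
    stop("non-finite deposition velocity in the scenario size range; scenario rejected")
  lambda <- scenario@trueConcentration * sg$massFrac / mass_mg *
    eta * vdep * (g$effectiveArea * 1e-6) *
    (scenario@durationHours * 3600)
  data.frame(d_ae_um = sg$mid, lower = sg$lower, upper = sg$upper,
             massFraction = sg$massFrac, mass_ng = mass_mg * 1e6,
             lambda = lambda)
}

## Draw particle geometry (position, shape) for given aerodynamic diameters
.particleGeometry <- function(dAe, scenario, cfg, source) {
  n <- length(dAe)
  g <- .scenarioGeometry(scenario, cfg)
  dPa <- if (n) projectedFromAerodynamic(dAe, cfg) else numeric(0)
  area <- pi / 4 * dPa^2
  aspect <- stats::runif(n, 1, 3)
  data.frame(
    particle = seq_len(n),
    tile = if (n) sample.int(scenario@nTiles, n, replace = TRUE)
           else integer(0),
    x_px = stats::runif(n, 0, g$tilePixels),
    y_px = stats::runif(n, 0, g$tilePixels),
    d_ae_um = dAe,
    d_pa_um = dPa,
    area_um2 = area,
    mass_ng = if (n) particleMass(dPa, cfg) else numeric(0),
    aspect = aspect,
    theta = stats::runif(n, 0, pi),
    source = rep_len(source, n),
    stringsAsFactors = FALSE)
}

#' Sample a deposited particle population
#'
#' Draws the ground-truth particles deposited on one stub: per size class
#' the count is Poisson with the mean given by [expectedDeposition()], and
#' each particle receives an aerodynamic diameter (log-uniform within its
#' class), a tile, a position (complete spatial randomness: the air was
#' still in the emulated campaign), an ellipse aspect ratio drawn from
#' U(1, 3) and an orientation. The rendered projected area is the exact
#' inverse image of the segmentation-to-diameter chain, so the pipeline
#' can recover the truth.
#'
#' All randomness is derived from the scenario seed (stream-split so that
#' population, contamination and rendering draw independently).
#'
#' @param scenario A [TruthScenario-class].
#' @param cfg A [SamplerConfig-class].
#' @return Truth `data.frame` (possibly 0 rows): `particle`, `tile`,
#'   `x_px`, `y_px`, `d_ae_um`, `d_pa_um`, `area_um2`, `mass_ng`,
#'   `aspect`, `theta`, `source`.
#' @export
samplePopulation <- function(scenario, cfg = samplerConfig()) {
  stopifnot(is(scenario, "TruthScenario"))
  if (scenario@trueConcentration == 0)
    return(.particleGeometry(numeric(0), scenario, cfg, "deposited"))
  ed <- expectedDeposition(scenario, cfg)
  set.seed(.derivedSeed(scenario@seed, 1L))
  counts <- stats::rpois(nrow(ed), ed$lambda)
  dAe <- exp(stats::runif(sum(counts),
                          rep(log(ed$lower), counts),
                          rep(log(ed$upper), counts)))
  .particleGeometry(dAe, scenario, cfg, "deposited")
}

#' Sample handling-contamination particles
#'
#' Contamination deposited during mounting/dismantling rather than from
#' the sampled air: Poisson count with mean `contaminationRate`, sizes
#' drawn from the scenario's number distribution (not deposition-weighted,
#' since contamination does not pass the cap by settling).
#'
#' @inheritParams samplePopulation
#' @return Truth `data.frame` with `source = "contamination"`.
#' @export
sampleContamination <- function(scenario, cfg = samplerConfig()) {
  set.seed(.derivedSeed(scenario@seed, 2L))
  n <- stats::rpois(1L, scenario@contaminationRate)
  dAe <- stats::rlnorm(n, meanlog = log(scenario@cmd),
                       sdlog = log(scenario@gsd))
  .particleGeometry(dAe, scenario, cfg, "contamination")
}

#' Render deposited particles onto SEM-like tiles
#'
#' Draws each particle as a filled bright ellipse (grey level
#' `N(particleGrey, particleGreySd)`, clipped to 8 bits) on a noisy darker
#' background (`N(noiseMean, noiseSd)`), on the tile containing its
#' centre; ellipse portions beyond the tile edge are clipped. A pixel
#' belongs to a particle when its centre falls inside the ellipse.
#' Particles whose pixels land on another particle's are flagged
#' `merged = TRUE` in the returned truth table (the pipeline will see one
#' component where the truth has two); this is logged, not an error.
#'
#' @param particles Truth table from [samplePopulation()] /
#'   [sampleContamination()] (rows may be concatenated).
#' @param scenario The [TruthScenario-class] that produced them.
#' @param cfg A [SamplerConfig-class].
#' @param stubId Identifier for the rendered stub.
#' @return A [StubImageSet-class] whose `truth` table is `particles` with
#'   `rendered_px` (pixels actually painted) and `merged` appended.
#' @export
renderTiles <- function(particles, scenario, cfg = samplerConfig(),
                        stubId = "sim") {
  g <- .scenarioGeometry(scenario, cfg)
  S <- g$tilePixels
  set.seed(.derivedSeed(scenario@seed, 3L))
  grey <- pmin(255, pmax(0, round(stats::rnorm(
    nrow(particles), scenario@particleGrey, scenario@particleGreySd))))
  particles$rendered_px <- rep(0L, nrow(particles))
  particles$merged <- rep(FALSE, nrow(particles))
  tilesOut <- vector("list", scenario@nTiles)
  for (ti in seq_len(scenario@nTiles)) {
    bg <- matrix(pmin(255, pmax(0, round(stats::rnorm(
      S * S, scenario@noiseMean, scenario@noiseSd)))), S, S)
    owner <- matrix(0L, S, S)
    rows <- which(particles$tile == ti)
    for (k in rows) {
      a <- sqrt(particles$area_um2[k] * particles$aspect[k] / pi) /
        cfg@pixelSide
      b <- a / particles$aspect[k]
      x0 <- particles$x_px[k]
      y0 <- particles$y_px[k]
      jr <- max(1L, floor(x0 - a)):min(S, ceiling(x0 + a))
      ir <- max(1L, floor(y0 - a)):min(S, ceiling(y0 + a))
      dx <- outer(rep(1, length(ir)), jr - 0.5 - x0)
      dy <- outer(ir - 0.5 - y0, rep(1, length(jr)))
      ct <- cos(particles$theta[k]); st <- sin(particles$theta[k])
      inside <- ((dx * ct + dy * st) / a)^2 +
        ((-dx * st + dy * ct) / b)^2 <= 1
      if (!any(inside)) next
      ii <- which(inside, arr.ind = TRUE)
      ri <- ir[ii[, 1L]]; ci <- jr[ii[, 2L]]
      idx <- cbind(ri, ci)
      prev <- owner[idx]
      hit <- prev != 0L
      if (any(hit)) {
        particles$merged[unique(prev[hit])] <- TRUE
        particles$merged[k] <- TRUE
      }
      owner[idx] <- k
      bg[idx] <- pmax(bg[idx], grey[k])
      particles$rendered_px[k] <- sum(inside)
    }
    tilesOut[[ti]] <- SemTile(bg, pixelSide = cfg@pixelSide,
                              tileIndex = ti, stubId = stubId)
  }
  StubImageSet(tilesOut, stubId = stubId, truth = particles,
               seed = scenario@seed)
}

#' Simulate a complete stub
#'
#' Convenience wrapper: deposited population plus handling contamination,
#' rendered into a [StubImageSet-class]. A scenario with zero
#' concentration and positive `contaminationRate` yields a field-blank
#' stub whose only particles are contamination.
#'
#' @inheritParams samplePopulation
#' @param stubId Identifier for the stub.
#' @return A [StubImageSet-class] with the combined truth table.
#' @export
simulateStub <- function(scenario, cfg = samplerConfig(), stubId = "sim") {
  pop <- samplePopulation(scenario, cfg)
  con <- sampleContamination(scenario, cfg)
  con$particle <- con$particle + nrow(pop)
  renderTiles(rbind(pop, con), scenario, cfg, stubId = stubId)
}

#' Fabricate matching reference observations
#'
#' Builds the active-sampling observations an impactor and an optical
#' particle counter would have recorded alongside the scenario: impactor
#' filter mass gains equal to the true sharp-cut PM-fraction concentration
#' times the sampled volume (flow 10 L min^-1 over the scenario duration),
#' with optional Gaussian gravimetric noise (default none), and OPC bin
#' number concentrations implied by the size distribution integrated over
#' the instrument's bins.
#'
#' @inheritParams samplePopulation
#' @param gravimetricNoiseSd Sd of weighing noise per filter weight, mg
#'   (default 0).
#' @param flow Impactor flow, L min^-1 (default 10).
#' @param opcEdges OPC bin edges, um (default the 0.3-10 um six-channel
#'   layout `c(0.3, 0.5, 1, 2.5, 5, 10)`).
#' @param tareWeight Nominal clean-filter weight, mg.
#' @return List with `impactor` (`data.frame`: one row per fraction with
#'   duplicate pre/post weights, flows, duration, and the true
#'   concentration) and `opc` (an [OpcSpectrum-class]).
#' @export
fabricateReferences <- function(scenario, cfg = samplerConfig(),
                                gravimetricNoiseSd = 0, flow = 10,
                                opcEdges = c(0.3, 0.5, 1, 2.5, 5, 10),
                                tareWeight = 120) {
  durMin <- scenario@durationHours * 60
  volume_m3 <- flow * durMin / 1000
  set.seed(.derivedSeed(scenario@seed, 4L))
  imp <- do.call(rbind, lapply(c(pm25 = 2.5, pm10 = 10)[c("pm25", "pm10")],
                               function(cut) {
    cTrue <- truePmConcentration(scenario, cut)
    gain <- cTrue * volume_m3
    noise <- stats::rnorm(4, 0, gravimetricNoiseSd)
    data.frame(pre1 = tareWeight + noise[1L],
               pre2 = tareWeight + noise[2L],
               post1 = tareWeight + gain + noise[3L],
               post2 = tareWeight + gain + noise[4L],
               flow_start = flow, flow_end = flow,
               duration_min = durMin, true_concentration = cTrue)
  }))
  imp <- cbind(fraction = c("pm25", "pm10"), imp)
  rownames(imp) <- NULL

  sg <- .sizeGrid(scenario, nClasses = 400L)
  dPa <- projectedFromAerodynamic(sg$mid, cfg)
  mass_mg <- particleMass(dPa, cfg) * 1e-6
  numberConc <- scenario@trueConcentration * sg$massFrac / mass_mg
  lo <- utils::head(opcEdges, -1L)
  hi <- utils::tail(opcEdges, -1L)
  binConc <- vapply(seq_along(lo), function(b) {
    sum(numberConc[sg$mid > lo[b] & sg$mid <= hi[b]])
  }, numeric(1))
  list(impactor = imp,
       opc = opcSpectrum(opcEdges, binConc, density = cfg@particleDensity))
}
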