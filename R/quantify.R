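## GSD of the optional smooth penetration convention around each cut.
.smoothCutGsd <- 1.5

#' PM fraction weight of a particle
#'
#' Weight with which a particle of given aerodynamic diameter counts toward
#' a PM fraction. The default sharp-cut convention is boundary-inclusive:
#' weight 1 for `d_ae <= cut`, else 0. The `"smooth"` convention replaces
#' the step by a lognormal penetration curve centred on the cut (GSD 1.5),
#' mimicking a sampling-convention-style soft cut. Both are non-increasing
#' in diameter.
#'
#' @param dAe Aerodynamic diameter(s), um.
#' @param cfg A [SamplerConfig-class].
#' @param fraction `"pm25"` or `"pm10"` (a name of `cfg@pmCuts`).
#' @return Weight(s) in `[0, 1]`.
#' @examples
#' cfg <- samplerConfig()
#' pmWeight(2.5, cfg, "pm25")   # 1: the boundary is inclusive
#' pmWeight(3, cfg, "pm25")     # 0
#' @export
pmWeight <- function(dAe, cfg, fraction = "pm25") {
  if (any(dAe <= 0)) stop("d_ae must be positive")
  if (!fraction %in% names(cfg@pmCuts))
    stop("unknown fraction '", fraction, "'")
  cut <- cfg@pmCuts[[fraction]]
  if (cfg@pmConvention == "sharp") {
    as.numeric(dAe <= cut)
  } else {
    stats::pnorm(-(log(dAe) - log(cut)) / log(.smoothCutGsd))
  }
}

## Normalising area in mm^2 for one stub
.normArea <- function(cfg, analyzedArea) {
  if (is.numeric(cfg@normArea)) return(cfg@normArea)
  switch(cfg@normArea,
         analyzed = analyzedArea,
         stub = pi * (cfg@stubDiameter / 2)^2)
}

#' Air concentration from one stub's sized particles
#'
#' Inverts deposited particle masses into an airborne mass concentration
#' per PM fraction: each particle's mass is divided by the mesh-cap
#' collection efficiency and the deposition velocity at its aerodynamic
#' diameter, summed with its fraction weight, and normalised by the
#' analysed area and the exposure duration:
#' `C = sum_i m_i w_i / (eta_i v_i) / (A t)`, reported in mg m^-3.
#'
#' Particles whose efficiency or deposition velocity is zero cannot be
#' inverted; the function stops naming the first such particle. Fraction
#' particle counts below the configured adequacy thresholds (defaults 55
#' for PM2.5, 71 for PM10) trigger a warning but results are still
#' produced.
#'
#' @param particles Sized particle table from [sizeParticles()] (columns
#'   `d_ae_um`, `mass_ng`; optionally `stub_id`).
#' @param analyzedArea Analysed stub area, mm^2.
#' @param occasion One-row `data.frame` or list with at least
#'   `occasion_id` and `duration_h`; `surface` and `role` are carried
#'   through when present.
#' @param cfg A [SamplerConfig-class].
#' @return One-row `data.frame`: `occasion_id`, `stub_id`, `surface`,
#'   `role`, `pm25`, `pm10` (mg m^-3), `pm25_count`, `pm10_count`,
#'   `analyzed_area_mm2`, `duration_h`, `blank_corrected`, `config_id`.
#' @export
stubConcentration <- function(particles, analyzedArea, occasion, cfg) {
  stopifnot(is.data.frame(particles))
  occ <- as.list(occasion)
  if (is.null(occ$duration_h) || occ$duration_h <= 0)
    stop("occasion duration must be positive")
  if (analyzedArea <= 0) stop("analyzed area must be positive")
  area <- .normArea(cfg, analyzedArea)
  res <- data.frame(
    occasion_id = occ$occasion_id %||% NA_character_,
    stub_id = particles$stub_id[1L] %||% NA_character_,
    surface = occ$surface %||% NA_character_,
    role = occ$role %||% "sample",
    pm25 = 0, pm10 = 0, pm25_count = 0L, pm10_count = 0L,
    analyzed_area_mm2 = area, duration_h = occ$duration_h,
    blank_corrected = FALSE, config_id = cfg@configId,
    stringsAsFactors = FALSE)
  if (nrow(particles) == 0L) return(res)
  stopifnot(all(c("d_ae_um", "mass_ng") %in% names(particles)))
  dAe <- particles$d_ae_um
  eta <- meshEfficiency(dAe, cfg@efficiencyCurve)
  vdep <- depositionVelocity(dAe, cfg)
  w25 <- pmWeight(dAe, cfg, "pm25")
  w10 <- pmWeight(dAe, cfg, "pm10")
  bad <- which((w25 > 0 | w10 > 0) & (eta == 0 | vdep == 0))
  if (length(bad))
    stop(sprintf(
      "particle %s (d_ae = %.3g um) has zero %s; cannot invert to concentration",
      paste(particles$particle[bad[1L]] %||% bad[1L]),
      dAe[bad[1L]],
      if (eta[bad[1L]] == 0) "collection efficiency" else "deposition velocity"))
  # mass ng -> mg (1e-6); area mm^2 -> m^2 (1e-6); duration h -> s (3600)
  denom <- area * 1e-6 * occ$duration_h * 3600
  flux <- particles$mass_ng * 1e-6 / (eta * vdep)
  res$pm25 <- sum(flux * w25) / denom
  res$pm10 <- sum(flux * w10) / denom
  res$pm25_count <- sum(dAe <= cfg@pmCuts[["pm25"]])
  res$pm10_count <- sum(dAe <= cfg@pmCuts[["pm10"]])
  for (fr in c("pm25", "pm10")) {
    thr <- cfg@countWarning[[fr]]
    n <- res[[paste0(fr, "_count")]]
    if (n < thr)
      warning(sprintf(
        "occasion %s: only %d %s particles (< %g); counting statistics may be inadequate",
        res$occasion_id, n, toupper(fr), thr))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Field-blank correction
#'
#' Computes the arithmetic mean field-blank concentration per collection
#' surface type (pooling field blanks across locations) and per PM
#' fraction, and subtracts it from every sample and field-blank result of
#' that surface. Negative corrected values are retained unchanged:
#' excluding or truncating them would bias campaign means and blank
#' variation estimates. Transport blanks are reported descriptively and are
#' neither used in the blank mean nor corrected.
#'
#' @param results Concentration table: rows from [stubConcentration()]
#'   (columns `surface`, `role`, `pm25`, `pm10` required).
#' @param requireBlanks If `TRUE` (default), a surface type that has sample
#'   results but no field blank is an error; if `FALSE` it is left
#'   uncorrected with a warning.
#' @return A list with `results` (corrected table, `blank_corrected` set)
#'   and `blankStats`, a `data.frame` of per-surface/fraction field-blank
#'   `mean`, `sd`, and `n`.
#' @export
blankCorrect <- function(results, requireBlanks = TRUE) {
  stopifnot(is.data.frame(results),
            all(c("surface", "role", "pm25", "pm10") %in% names(results)))
  surfaces <- unique(results$surface)
  stats <- do.call(rbind, lapply(surfaces, function(s) {
    fb <- results[results$surface == s & results$role == "field_blank", ]
    do.call(rbind, lapply(c("pm25", "pm10"), function(fr) {
      data.frame(surface = s, fraction = fr,
                 mean = if (nrow(fb)) mean(fb[[fr]]) else NA_real_,
                 sd = if (nrow(fb) > 1L) stats::sd(fb[[fr]]) else NA_real_,
                 n = nrow(fb), stringsAsFactors = FALSE)
    }))
  }))
  for (s in surfaces) {
    rows <- results$surface == s & results$role != "transport_blank"
    m25 <- stats$mean[stats$surface == s & stats$fraction == "pm25"]
    m10 <- stats$mean[stats$surface == s & stats$fraction == "pm10"]
    if (is.na(m25)) {
      msg <- sprintf("no field blank for surface '%s'", s)
      if (requireBlanks) stop(msg, "; use requireBlanks = FALSE to skip")
      warning(msg, "; results for this surface left uncorrected")
      next
    }
    results$pm25[rows] <- results$pm25[rows] - m25
    results$pm10[rows] <- results$pm10[rows] - m10
    results$blank_corrected[rows] <- TRUE
  }
  list(results = results, blankStats = stats)
}

#' Duration-weighted mean concentration
#'
#' Mean of per-occasion concentrations weighted by each occasion's
#' duration, so occasions of unequal length contribute in proportion to
#' the time they cover; equal durations reduce to the arithmetic mean.
#'
#' @param results Concentration table with `pm25`, `pm10`, and
#'   `duration_h` columns (as produced by [stubConcentration()]).
#' @return Named numeric `c(pm25 = , pm10 = )` in mg m^-3.
#' @examples
#' r <- data.frame(pm25 = c(1, 3), pm10 = c(1, 3), duration_h = c(8, 16))
#' timeWeightedMean(r)   # both 7/3
#' @export
timeWeightedMean <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("pm25", "pm10", "duration_h") %in% names(results)))
  if (nrow(results) == 0L) stop("no results to average")
  if (any(results$duration_h <= 0)) stop("durations must be positive")
  w <- results$duration_h
  c(pm25 = sum(results$pm25 * w) / sum(w),
    pm10 = sum(results$pm10 * w) / sum(w))
}

#' Sampler-to-reference concentration ratio
#'
#' The passive sampler's time-averaged concentration as a percentage of a
#' reference (impactor) concentration.
#'
#' @param samplerMean Sampler concentration, mg m^-3.
#' @param referenceMean Reference concentration, mg m^-3; must be positive.
#' @return Percentage (100 = parity).
#' @export
samplerVsReferenceRatio <- function(samplerMean, referenceMean) {
  if (any(!is.finite(referenceMean)) || any(referenceMean <= 0))
    stop("reference concentration must be positive")
  100 * samplerMean / referenceMean
}

#' Build a sampling-occasion table
#'
#' Small constructor for campaign metadata rows. Durations are computed
#' from `start`/`end` timestamps when supplied, or given directly.
#'
#' @param occasion_id Character ids.
#' @param surface Collection surface per occasion (`"PC"` or `"CT"`).
#' @param role `"sample"`, `"field_blank"`, or `"transport_blank"`.
#' @param location Free-text location labels.
#' @param start,end Optional `POSIXct` timestamps (end must exceed start).
#' @param duration_h Durations in hours (required if no timestamps).
#' @return `data.frame` of occasions.
#' @export
samplingOccasions <- function(occasion_id, surface, role = "sample",
                              location = "", start = NULL, end = NULL,
                              duration_h = NULL) {
  n <- length(occasion_id)
  if (!is.null(start)) {
    if (any(as.numeric(end) <= as.numeric(start)))
      stop("occasion end must be after start")
    duration_h <- as.numeric(difftime(end, start, units = "hours"))
  }
  if (is.null(duration_h)) stop("supply start/end or duration_h")
  data.frame(occasion_id = occasion_id,
             location = rep_len(location, n),
             surface = rep_len(surface, n),
             role = rep_len(role, n),
             duration_h = rep_len(duration_h, n),
             stringsAsFactors = FALSE)
}
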