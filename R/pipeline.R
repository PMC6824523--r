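#' Simulate a stub campaign element and write it to disk
#'
#' Runs the synthetic generator for one scenario and writes the rendered
#' tiles, the truth table, the scenario file, and the fabricated reference
#' observations (impactor weighings and OPC bin concentrations) into an
#' output directory. Deterministic for a given scenario seed.
#'
#' @param scenario A [TruthScenario-class] or the path to a scenario YAML
#'   (see [readScenario()]).
#' @param cfg A [SamplerConfig-class].
#' @param outdir Output directory.
#' @param stubId Identifier for the simulated stub.
#' @param format Tile image format, `"png"` or `"tiff"`.
#' @param references Also fabricate reference observations (default TRUE).
#' @return Invisibly, a list with the `stub` ([StubImageSet-class]) and
#'   `references`.
#' @export
runSimulate <- function(scenario, cfg = samplerConfig(), outdir,
                        stubId = "sim", format = "png",
                        references = TRUE) {
  if (is.character(scenario)) scenario <- readScenario(scenario)
  stopifnot(is(scenario, "TruthScenario"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stub <- simulateStub(scenario, cfg, stubId = stubId)
  writeStubImageSet(stub, outdir, format = format)
  writeScenario(scenario, file.path(outdir,
                                    paste0(stubId, "_scenario.yaml")))
  refs <- NULL
  if (references) {
    refs <- fabricateReferences(scenario, cfg)
    utils::write.csv(refs$impactor,
                     file.path(outdir, paste0(stubId, "_impactor.csv")),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(bin_lower_um = utils::head(refs$opc@binEdges, -1L),
                 bin_upper_um = utils::tail(refs$opc@binEdges, -1L),
                 number_per_m3 = refs$opc@numberConcentrations),
      file.path(outdir, paste0(stubId, "_opc.csv")), row.names = FALSE)
  }
  invisible(list(stub = stub, references = refs))
}

#' Run the full analysis pipeline over a campaign
#'
#' Segments every stub, inverts particles into per-occasion PM2.5/PM10
#' concentrations, applies field-blank correction (optional), computes
#' duration-weighted means per collection surface over the sample
#' occasions, and, when reference concentrations are supplied, the
#' sampler-to-reference percentage ratios. A failing stub does not abort
#' the campaign: the failure is recorded and the remaining occasions are
#' processed.
#'
#' @param occasions Occasion table (see [samplingOccasions()]): columns
#'   `occasion_id`, `surface`, `role`, `duration_h`, optionally
#'   `location`.
#' @param stubs Named list mapping `occasion_id` to a
#'   [StubImageSet-class], a list of [SemTile-class] tiles, a directory
#'   path readable by [readStubImageSet()], or a zero-argument function
#'   returning one of these (lazy generation: each stub is materialised
#'   only while processed, keeping campaign memory flat).
#' @param cfg A [SamplerConfig-class].
#' @param references Optional `data.frame` with columns `fraction`
#'   (`"pm25"`/`"pm10"`) and `concentration` (mg m^-3).
#' @param blankCorrection Apply field-blank correction (default TRUE);
#'   `FALSE` reproduces the uncorrected sensitivity reporting mode.
#' @param outdir Optional directory; when given, per-occasion results,
#'   blank statistics, time-weighted means and ratios are written as CSV.
#' @return List with `results` (per-occasion concentrations, stamped with
#'   `config_id` and `software_version`), `blankStats` (or `NULL`),
#'   `timeWeighted` (per surface), `ratios` (or `NULL`), `failures`.
#' @export
runPipeline <- function(occasions, stubs, cfg = samplerConfig(),
                        references = NULL, blankCorrection = TRUE,
                        outdir = NULL) {
  stopifnot(is.data.frame(occasions),
            all(c("occasion_id", "surface", "role", "duration_h") %in%
                  names(occasions)))
  missing <- setdiff(occasions$occasion_id, names(stubs))
  if (length(missing))
    stop("no stub mapped to occasion(s): ", paste(missing, collapse = ", "))
  rows <- list()
  failures <- data.frame(occasion_id = character(0), error = character(0))
  for (i in seq_len(nrow(occasions))) {
    occ <- occasions[i, ]
    res <- tryCatch({
      s <- stubs[[occ$occasion_id]]
      if (is.function(s)) s <- s()
      if (is.character(s)) s <- readStubImageSet(s)
      col <- collectStub(s, cfg)
      sized <- sizeParticles(col$particles, cfg)
      stubConcentration(sized, col$analyzedArea, occ, cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(occasion_id = occ$occasion_id,
                                   error = conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("every occasion failed; first error: ",
                          failures$error[1L])
  results <- do.call(rbind, rows)
  blankStats <- NULL
  if (blankCorrection) {
    bc <- blankCorrect(results)
    results <- bc$results
    blankStats <- bc$blankStats
  }
  results$software_version <-
    as.character(utils::packageVersion("pasam"))
  samples <- results[results$role == "sample", , drop = FALSE]
  tw <- do.call(rbind, lapply(split(samples, samples$surface),
                              function(d) {
    m <- timeWeightedMean(d)
    data.frame(surface = d$surface[1L], pm25 = m[["pm25"]],
               pm10 = m[["pm10"]], config_id = cfg@configId)
  }))
  rownames(tw) <- NULL
  ratios <- NULL
  if (!is.null(references)) {
    stopifnot(all(c("fraction", "concentration") %in% names(references)))
    ratios <- do.call(rbind, lapply(seq_len(nrow(tw)), function(j) {
      do.call(rbind, lapply(c("pm25", "pm10"), function(fr) {
        ref <- references$concentration[references$fraction == fr]
        if (!length(ref)) return(NULL)
        data.frame(surface = tw$surface[j], fraction = fr,
                   sampler = tw[[fr]][j], reference = ref,
                   ratio_percent = samplerVsReferenceRatio(tw[[fr]][j], ref))
      }))
    }))
  }
  out <- list(results = results, blankStats = blankStats,
              timeWeighted = tw, ratios = ratios, failures = failures)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    names(results)[names(results) %in% c("pm25", "pm10")] <-
      c("pm25_mg_per_m3", "pm10_mg_per_m3")
    utils::write.csv(results, file.path(outdir, "concentrations.csv"),
                     row.names = FALSE)
    if (!is.null(blankStats))
      utils::write.csv(blankStats, file.path(outdir, "blank_stats.csv"),
                       row.names = FALSE)
    tw2 <- tw
    names(tw2)[names(tw2) %in% c("pm25", "pm10")] <-
      c("pm25_mg_per_m3", "pm10_mg_per_m3")
    utils::write.csv(tw2, file.path(outdir, "time_weighted_means.csv"),
                     row.names = FALSE)
    if (!is.null(ratios))
      utils::write.csv(ratios, file.path(outdir, "ratios.csv"),
                       row.names = FALSE)
    if (nrow(failures))
      utils::write.csv(failures, file.path(outdir, "failures.csv"),
                       row.names = FALSE)
  }
  out
}
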