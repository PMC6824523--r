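## Deterministic fingerprint of a config: 31-bit polynomial hash over the
## deparsed slot values. Not cryptographic; only needs to distinguish
## configurations within a campaign.
.fingerprint <- function(parts) {
  bytes <- utf8ToInt(paste(parts, collapse = "|"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("cfg-%08x", as.integer(h))
}

#' Construct a sampler configuration
#'
#' Builds a [SamplerConfig-class] carrying every physical constant and
#' model choice of the chain. All arguments have the package defaults
#' described in [SamplerConfig-class]; any can be overridden. The resulting
#' object carries a deterministic `configId` fingerprint so every output
#' row is traceable to the physics that produced it.
#'
#' @param volumeShapeFactor `f_V` in `V = f_V d_pa^3` (default 1.6).
#' @param dynamicShapeFactor Drag ratio `chi >= 1` (default 1.4).
#' @param particleDensity g cm^-3 (default 2.0).
#' @param referenceDensity g cm^-3 (default 1.0).
#' @param airTemperature K (default 293).
#' @param airPressure kPa (default 101.3).
#' @param airViscosity Pa s (default 1.81e-5).
#' @param meanFreePath um (default 0.0665).
#' @param depositionModel `"settling_plus_diffusion"` (default) or
#'   `"settling_only"`.
#' @param boundaryLayer Diffusive boundary layer, mm (default 1).
#' @param efficiencyCurve An [EfficiencyCurve-class]; default
#'   [defaultEfficiencyCurve()].
#' @param stubDiameter mm (default 12).
#' @param pmConvention `"sharp"` or `"smooth"`.
#' @param pmCuts Named cut diameters, um.
#' @param pixelSide um (default 0.64).
#' @param minArea,maxArea Area filters, um^2 (0.41, 10000).
#' @param connectivity 8 (default) or 4.
#' @param foregroundPolarity `"bright"` (default) or `"dark"`.
#' @param minClassContrast Minimum grey-level class separation (default 30).
#' @param countWarning Named adequacy thresholds, default
#'   `c(pm25 = 55, pm10 = 71)`.
#' @param normArea `"analyzed"` (default), `"stub"`, or a number in mm^2.
#' @return A validated [SamplerConfig-class].
#' @examples
#' cfg <- samplerConfig()
#' configId(cfg)
#' @export
samplerConfig <- function(volumeShapeFactor = 1.6,
                          dynamicShapeFactor = 1.4,
                          particleDensity = 2.0,
                          referenceDensity = 1.0,
                          airTemperature = 293,
                          airPressure = 101.3,
                          airViscosity = 1.81e-5,
                          meanFreePath = 0.0665,
                          depositionModel = "settling_plus_diffusion",
                          boundaryLayer = 1,
                          efficiencyCurve = defaultEfficiencyCurve(),
                          stubDiameter = 12,
                          pmConvention = "sharp",
                          pmCuts = c(pm25 = 2.5, pm10 = 10),
                          pixelSide = 0.64,
                          minArea = 0.41,
                          maxArea = 10000,
                          connectivity = 8,
                          foregroundPolarity = "bright",
                          minClassContrast = 30,
                          countWarning = c(pm25 = 55, pm10 = 71),
                          normArea = "analyzed") {
  id <- .fingerprint(c(
    volumeShapeFactor, dynamicShapeFactor, particleDensity,
    referenceDensity, airTemperature, airPressure, airViscosity,
    meanFreePath, depositionModel, boundaryLayer,
    efficiencyCurve@label, efficiencyCurve@diameters,
    efficiencyCurve@efficiencies, stubDiameter, pmConvention, pmCuts,
    pixelSide, minArea, maxArea, connectivity, foregroundPolarity,
    minClassContrast, countWarning, normArea))
  new("SamplerConfig",
      volumeShapeFactor = volumeShapeFactor,
      dynamicShapeFactor = dynamicShapeFactor,
      particleDensity = particleDensity,
      referenceDensity = referenceDensity,
      airTemperature = airTemperature,
      airPressure = airPressure,
      airViscosity = airViscosity,
      meanFreePath = meanFreePath,
      depositionModel = depositionModel,
      boundaryLayer = boundaryLayer,
      efficiencyCurve = efficiencyCurve,
      stubDiameter = stubDiameter,
      pmConvention = pmConvention,
      pmCuts = pmCuts,
      pixelSide = pixelSide,
      minArea = minArea,
      maxArea = maxArea,
      connectivity = connectivity,
      foregroundPolarity = foregroundPolarity,
      minClassContrast = minClassContrast,
      countWarning = countWarning,
      normArea = normArea,
      configId = id)
}

## Mapping from flat config-file keys to samplerConfig() arguments.
.configKeyMap <- c(
  volume_shape_factor = "volumeShapeFactor",
  dynamic_shape_factor = "dynamicShapeFactor",
  particle_density = "particleDensity",
  reference_density = "referenceDensity",
  air_temperature_k = "airTemperature",
  air_pressure_kpa = "airPressure",
  air_viscosity_pas = "airViscosity",
  mean_free_path_um = "meanFreePath",
  deposition_model = "depositionModel",
  boundary_layer_mm = "boundaryLayer",
  stub_diameter_mm = "stubDiameter",
  pm_convention = "pmConvention",
  pixel_side_um = "pixelSide",
  min_area_um2 = "minArea",
  max_area_um2 = "maxArea",
  connectivity = "connectivity",
  foreground_polarity = "foregroundPolarity",
  min_class_contrast = "minClassContrast",
  count_warning_pm25 = NA,   # folded into countWarning
  count_warning_pm10 = NA,
  efficiency_curve_csv = NA, # loaded into efficiencyCurve
  norm_area = "normArea"
)

#' Validate and normalise a key-value configuration
#'
#' Turns a flat named list (typically parsed from a YAML config file) into
#' a [SamplerConfig-class], filling in every package default, warning on
#' unknown keys, and rejecting out-of-range values with the offending key
#' named. An empty list yields the full default configuration.
#'
#' Recognised keys: `volume_shape_factor`, `dynamic_shape_factor`,
#' `particle_density`, `reference_density`, `air_temperature_k`,
#' `air_pressure_kpa`, `air_viscosity_pas`, `mean_free_path_um`,
#' `deposition_model`, `boundary_layer_mm`, `stub_diameter_mm`,
#' `pm_convention`, `pixel_side_um`, `min_area_um2`, `max_area_um2`,
#' `connectivity`, `foreground_polarity`, `min_class_contrast`,
#' `count_warning_pm25`, `count_warning_pm10`, `efficiency_curve_csv`,
#' `norm_area`.
#'
#' @param config Named list of configuration values, or a path to a YAML
#'   file containing one.
#' @return A validated [SamplerConfig-class].
#' @examples
#' validateConfig(list())                       # all defaults
#' validateConfig(list(pixel_side_um = 0.32))
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(.configKeyMap))
  if (length(unknown))
    warning("ignoring unknown config keys: ",
            paste(unknown, collapse = ", "))
  args <- list()
  for (key in intersect(names(config), names(.configKeyMap))) {
    arg <- .configKeyMap[[key]]
    if (!is.na(arg)) args[[arg]] <- config[[key]]
  }
  cw <- c(pm25 = 55, pm10 = 71)
  if (!is.null(config$count_warning_pm25))
    cw["pm25"] <- config$count_warning_pm25
  if (!is.null(config$count_warning_pm10))
    cw["pm10"] <- config$count_warning_pm10
  args$countWarning <- cw
  if (!is.null(config$efficiency_curve_csv))
    args$efficiencyCurve <- readEfficiencyCurve(config$efficiency_curve_csv)
  cfg <- try(do.call(samplerConfig, args), silent = TRUE)
  if (inherits(cfg, "try-error"))
    stop("invalid configuration: ",
         sub("^.*invalid class [^:]+: *", "", attr(cfg, "condition")$message))
  cfg
}

#' Dump a configuration as a flat key-value list
#'
#' Inverse of [validateConfig()] for the scalar keys; useful for writing a
#' config file documenting exactly which physics produced a result set.
#'
#' @param cfg A [SamplerConfig-class].
#' @return Named list using the config-file key names.
#' @export
dumpConfig <- function(cfg) {
  list(
    volume_shape_factor = cfg@volumeShapeFactor,
    dynamic_shape_factor = cfg@dynamicShapeFactor,
    particle_density = cfg@particleDensity,
    reference_density = cfg@referenceDensity,
    air_temperature_k = cfg@airTemperature,
    air_pressure_kpa = cfg@airPressure,
    air_viscosity_pas = cfg@airViscosity,
    mean_free_path_um = cfg@meanFreePath,
    deposition_model = cfg@depositionModel,
    boundary_layer_mm = cfg@boundaryLayer,
    stub_diameter_mm = cfg@stubDiameter,
    pm_convention = cfg@pmConvention,
    pixel_side_um = cfg@pixelSide,
    min_area_um2 = cfg@minArea,
    max_area_um2 = cfg@maxArea,
    connectivity = cfg@connectivity,
    foreground_polarity = cfg@foregroundPolarity,
    min_class_contrast = cfg@minClassContrast,
    count_warning_pm25 = unname(cfg@countWarning["pm25"]),
    count_warning_pm10 = unname(cfg@countWarning["pm10"]),
    norm_area = cfg@normArea
  )
}
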