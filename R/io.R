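#' Read one SEM tile image
#'
#' Reads an 8-bit grayscale TIFF or PNG tile (by file extension) into a
#' [SemTile-class]. Multi-channel images are averaged to grey.
#'
#' @param path Image file path.
#' @param pixelSide Pixel side, um (default 0.64).
#' @param tileIndex Tile number.
#' @param stubId Stub identifier (default: file name stem).
#' @return A [SemTile-class].
#' @export
readSemTile <- function(path, pixelSide = 0.64, tileIndex = 1L,
                        stubId = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  if (is.null(stubId))
    stubId <- sub("_tile[0-9]+$", "", tools::file_path_sans_ext(basename(path)))
  SemTile(round(img * 255), pixelSide = pixelSide,
          tileIndex = tileIndex, stubId = stubId)
}

#' Write a stub image set to disk
#'
#' Writes each tile as an 8-bit grayscale image
#' (`<stubId>_tile###.<ext>`), the simulation truth table (if any) as
#' `<stubId>_truth.csv`, and a `<stubId>_meta.yaml` with the stub id,
#' pixel scale and generator seed.
#'
#' @param stub A [StubImageSet-class].
#' @param dir Output directory (created if needed).
#' @param format `"png"` (default) or `"tiff"`.
#' @return Invisibly, the vector of tile file paths.
#' @export
writeStubImageSet <- function(stub, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(stub@tiles))
  for (i in seq_along(stub@tiles)) {
    t <- stub@tiles[[i]]
    paths[i] <- file.path(dir, sprintf("%s_tile%03d.%s", stub@stubId,
                                       t@tileIndex,
                                       if (format == "png") "png" else "tif"))
    img <- t@pixels / 255
    if (format == "png") png::writePNG(img, paths[i])
    else tiff::writeTIFF(img, paths[i], bits.per.sample = 8L)
  }
  if (nrow(stub@truth))
    utils::write.csv(stub@truth,
                     file.path(dir, paste0(stub@stubId, "_truth.csv")),
                     row.names = FALSE)
  yaml::write_yaml(list(stub_id = stub@stubId, pixel_side_um = stub@pixelSide,
                        seed = if (is.na(stub@seed)) NULL else stub@seed),
                   file.path(dir, paste0(stub@stubId, "_meta.yaml")))
  invisible(paths)
}

#' Read a stub image set from disk
#'
#' Counterpart of [writeStubImageSet()]: reads `<stubId>_tile###` images,
#' the truth table and the metadata file from a directory.
#'
#' @param dir Directory containing one stub's files.
#' @param stubId Stub identifier; default: inferred from the single
#'   `*_meta.yaml` present.
#' @return A [StubImageSet-class].
#' @export
readStubImageSet <- function(dir, stubId = NULL) {
  if (is.null(stubId)) {
    metas <- list.files(dir, pattern = "_meta\\.yaml$")
    if (length(metas) != 1L)
      stop("cannot infer stubId: found ", length(metas), " meta files in ", dir)
    stubId <- sub("_meta\\.yaml$", "", metas)
  }
  meta <- yaml::read_yaml(file.path(dir, paste0(stubId, "_meta.yaml")))
  tilePaths <- sort(list.files(
    dir, pattern = paste0("^", stubId, "_tile[0-9]+\\.(png|tif|tiff)$"),
    full.names = TRUE))
  if (!length(tilePaths)) stop("no tile images for stub '", stubId, "' in ", dir)
  tl <- lapply(seq_along(tilePaths), function(i) {
    readSemTile(tilePaths[i], pixelSide = meta$pixel_side_um,
                tileIndex = i, stubId = stubId)
  })
  truthPath <- file.path(dir, paste0(stubId, "_truth.csv"))
  truth <- if (file.exists(truthPath)) utils::read.csv(truthPath)
           else data.frame()
  StubImageSet(tl, stubId = stubId, truth = truth,
               seed = meta$seed %||% NA)
}

## Scenario file keys <-> truthScenario() arguments
.scenarioKeyMap <- c(
  true_concentration = "trueConcentration",
  cmd_um = "cmd",
  gsd = "gsd",
  duration_h = "durationHours",
  deposition_area_mm2 = "depositionArea",
  n_tiles = "nTiles",
  contamination_rate = "contaminationRate",
  noise_mean = "noiseMean",
  noise_sd = "noiseSd",
  particle_grey = "particleGrey",
  particle_grey_sd = "particleGreySd",
  seed = "seed"
)

#' Read a truth scenario from a YAML file
#'
#' Keys: `true_concentration` (required, mg m^-3), `cmd_um`, `gsd`,
#' `duration_h`, `deposition_area_mm2`, `n_tiles`, `contamination_rate`,
#' `noise_mean`, `noise_sd`, `particle_grey`, `particle_grey_sd`, `seed`.
#' Unknown keys are an error naming the key.
#'
#' @param path YAML file path.
#' @return A [TruthScenario-class].
#' @export
readScenario <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(.scenarioKeyMap))
  if (length(unknown))
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "))
  if (is.null(vals$true_concentration))
    stop("scenario is missing required key 'true_concentration'")
  args <- stats::setNames(vals, .scenarioKeyMap[names(vals)])
  do.call(truthScenario, args)
}

#' Write a truth scenario to a YAML file
#'
#' @param scenario A [TruthScenario-class].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
writeScenario <- function(scenario, path) {
  yaml::write_yaml(list(
    true_concentration = scenario@trueConcentration,
    cmd_um = scenario@cmd,
    gsd = scenario@gsd,
    duration_h = scenario@durationHours,
    deposition_area_mm2 = scenario@depositionArea,
    n_tiles = scenario@nTiles,
    contamination_rate = scenario@contaminationRate,
    noise_mean = scenario@noiseMean,
    noise_sd = scenario@noiseSd,
    particle_grey = scenario@particleGrey,
    particle_grey_sd = scenario@particleGreySd,
    seed = scenario@seed), path)
  invisible(path)
}
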