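## Pipeline orchestration: config-driven wrappers tying the generator,
## instrument, calibration, reconstruction and statistics together, each
## writing a manifest sufficient to reproduce its outputs. The thin
## command-line entry point in inst/scripts/polpipe.R calls these.

readRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

writeManifest <- function(outDir, config, extra = list()) {
  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(config, cfgPath)
  manifest <- c(list(config_md5 = unname(tools::md5sum(cfgPath)),
                     seed = config$seed,
                     r_version = as.character(getRversion()),
                     package_version =
                       as.character(utils::packageVersion("muellerpol"))),
                extra)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

buildInstrumentFromConfig <- function(config) {
  buildInstrument(idealSchedule(),
                  psg_errors = config$instrument$psg_errors,
                  psa_errors = config$instrument$psa_errors)
}

#' Simulate one phantom acquisition plus calibration references
#'
#' Builds the ring phantom and instrument from the config, forward-acquires
#' the 48-frame stack and the reference set, and writes: `stack.tif(.yaml)`,
#' per-map ground-truth TIFFs under `truth/`, reference intensity matrices
#' under `refs/` (CSV + `refs.yaml` nominals), `instrument_true.json`,
#' `config.yaml` and `manifest.json`.
#'
#' @param config YAML path or list; recognised blocks: `seed`, `phantom`
#'   (overrides for [ringPhantomSpec()]), `instrument` (`psg_errors`,
#'   `psa_errors`), `acquire` (`gain`, `bitDepth`, `noise`).
#' @param outDir output directory.
#' @return invisibly, the manifest list.
#' @export
runSimulate <- function(config, outDir) {
  config <- readRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  spec <- do.call(ringPhantomSpec,
                  c(config$phantom %||% list(), list(seed = config$seed)))
  ph <- makeRingPhantom(spec)
  inst <- buildInstrumentFromConfig(config)
  acq <- config$acquire %||% list()
  stack <- forwardAcquire(ph@mueller, inst, gain = acq$gain %||% 1,
                          noise = acq$noise,
                          bitDepth = acq$bitDepth %||% "float",
                          seed = config$seed)
  writeIntensityStack(stack, file.path(outDir, "stack.tif"))
  tmaps <- ph@truth[c("delta_deg", "DeltaC", "DeltaL", "psi_deg", "D")]
  writeParameterMaps(tmaps, file.path(outDir, "truth"))
  writeInstrumentModel(inst, file.path(outDir, "instrument_true.json"))
  refs <- makeReferenceAcquisitions(inst, noise = acq$ref_noise,
                                    gain = acq$gain %||% 1,
                                    seed = config$seed)
  refDir <- file.path(outDir, "refs")
  dir.create(refDir, showWarnings = FALSE)
  utils::write.csv(refs$b0, file.path(refDir, "air.csv"), row.names = FALSE)
  nominals <- list()
  for (i in seq_along(refs$refs)) {
    fn <- sprintf("ref_%02d.csv", i)
    utils::write.csv(refs$refs[[i]]$b, file.path(refDir, fn),
                     row.names = FALSE)
    nominals[[fn]] <- refs$refs[[i]]$nominal
  }
  yaml::write_yaml(nominals, file.path(refDir, "refs.yaml"))
  geo <- ph@geometry
  yaml::write_yaml(geo, file.path(outDir, "geometry.yaml"))
  invisible(writeManifest(outDir, config,
                          list(outputs = c("stack.tif", "truth/", "refs/"))))
}

#' Calibrate the instrument from a simulated run directory
#'
#' Reads the reference CSVs written by [runSimulate()], runs the eigenvalue
#' calibration and writes `calibration.json`.
#'
#' @param runDir directory produced by [runSimulate()].
#' @return invisibly, the [CalibrationResult-class].
#' @export
runCalibrate <- function(runDir) {
  refDir <- file.path(runDir, "refs")
  if (!dir.exists(refDir)) stop("no refs/ directory under ", runDir)
  nominals <- yaml::read_yaml(file.path(refDir, "refs.yaml"))
  b0 <- as.matrix(utils::read.csv(file.path(refDir, "air.csv")))
  dimnames(b0) <- NULL
  rl <- lapply(names(nominals), function(fn) {
    b <- as.matrix(utils::read.csv(file.path(refDir, fn)))
    dimnames(b) <- NULL
    list(nominal = nominals[[fn]], b = b)
  })
  cal <- calibrate(referenceAcquisitionSet(b0, rl))
  writeInstrumentModel(cal, file.path(runDir, "calibration.json"))
  invisible(cal)
}

#' Analyze a simulated run: maps, mask, ROI summary, radial profile
#'
#' Requires `calibration.json` (run [runCalibrate()] first). Writes the
#' parameter maps under `maps/`, the tissue mask, `sample_table.csv` and
#' `profile_delta.csv`.
#'
#' @param runDir directory produced by [runSimulate()].
#' @param mask_on map used for the scaled-MAD mask (default `"Delta"`).
#' @return invisibly, the one-row sample table.
#' @export
runAnalyze <- function(runDir, mask_on = "Delta") {
  calPath <- file.path(runDir, "calibration.json")
  if (!file.exists(calPath))
    stop("missing calibration file: ", calPath, " (run runCalibrate first)")
  inst <- readInstrumentModel(calPath)
  stack <- readIntensityStack(file.path(runDir, "stack.tif"))
  mi <- reconstructMueller(stack, inst)
  maps <- polarimetricMaps(mi)
  writeParameterMaps(maps, file.path(runDir, "maps"))
  mask <- madMask(paramMap(maps, mask_on))
  writePagedTiff(array(mask * 1, c(dim(mask), 1)),
                 file.path(runDir, "mask.tif"))
  row <- roiSummary(maps, mask = mask, sample_id = basename(runDir))
  writeSampleTable(row, file.path(runDir, "sample_table.csv"))
  geo <- yaml::read_yaml(file.path(runDir, "geometry.yaml"))
  prof <- radialProfile(paramMap(maps, "delta_deg"), unlist(geo$center),
                        geo$innerRadius_um, geo$width_um, geo$pitch_um,
                        mask = mask)
  writeProfile(prof, file.path(runDir, "profile_delta.csv"))
  invisible(row)
}

#' Orientation analysis of a fiber volume
#'
#' Either reads `volume.tif` from `config$volume` or synthesizes one from
#' the `fibers` block; writes `orientation.csv` and `dispersion.json`.
#'
#' @param config YAML path or list: `seed`, optional `volume` (TIFF path),
#'   optional `fibers` (overrides for [makeFiberVolume()]), optional
#'   `subvolume_size`, `step`, `sv_max`.
#' @param outDir output directory.
#' @return invisibly, the dispersion summary list.
#' @export
runShg <- function(config, outDir) {
  config <- readRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  vol <- if (!is.null(config$volume)) readFiberVolume(config$volume)
    else do.call(makeFiberVolume,
                 c(config$fibers %||% list(), list(seed = config$seed)))
  of <- estimateOrientations(vol,
          subvolume_size = config$subvolume_size %||% 32,
          step = config$step %||% ((config$subvolume_size %||% 32) / 2))
  writeOrientationField(of, file.path(outDir, "orientation.csv"))
  ds <- dispersionSummary(of, sv_max = config$sv_max %||% 0.4)
  jsonlite::write_json(ds, file.path(outDir, "dispersion.json"),
                       auto_unbox = TRUE, digits = NA)
  writeManifest(outDir, config)
  invisible(ds)
}

#' End-to-end analysis of a synthetic cohort
#'
#' For every cohort sample: render its ring phantom, forward-acquire,
#' reconstruct with the given instrument, compute parameter maps, mask, and
#' take the masked ROI summary. Returns the sample table together with the
#' Spearman battery and group tests on the linear-retardance means.
#'
#' @param cohort result of [makeCohort()].
#' @param instrument an [InstrumentModel-class] (default ideal).
#' @param noise,gain,bitDepth acquisition settings (default noise-free).
#' @param test_param column for [groupTests()]
#'   (default `"mean_delta_deg"`).
#' @return list with `table`, `spearman`, `tests`, `truth`.
#' @export
analyzeCohort <- function(cohort, instrument = buildInstrument(),
                          noise = NULL, gain = 1, bitDepth = "float",
                          test_param = "mean_delta_deg") {
  rows <- lapply(seq_along(cohort$samples), function(i) {
    s <- cohort$samples[[i]]
    ph <- makeRingPhantom(s$spec)
    st <- forwardAcquire(ph@mueller, instrument, gain = gain, noise = noise,
                         bitDepth = bitDepth, seed = s$spec$seed)
    mi <- reconstructMueller(st, instrument)
    maps <- polarimetricMaps(mi)
    inside <- ph@truth$inside
    dmap <- paramMap(maps, "Delta")
    dmap[!inside] <- NA_real_          # mask within the tissue only
    mask <- madMask(dmap) & inside
    roiSummary(maps, mask = mask, sample_id = s$meta$sample_id,
               batch_id = s$meta$batch_id, day = s$meta$day,
               group = s$meta$group)
  })
  table <- do.call(rbind, rows)
  list(table = table,
       spearman = spearmanBattery(table),
       tests = groupTests(table, test_param),
       truth = cohort$truth)
}
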