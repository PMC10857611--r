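# File-oriented pipeline front end: run configurations, result CSV/JSON
# serialization, and run manifests.

#' Read and validate a run configuration
#'
#' Structured YAML with a closed key list; unknown keys are errors (they are
#' usually dimension-file typos).
#'
#' @param file YAML path.
#' @return validated configuration list.
#' @export
readRunConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  known <- c("model", "source_file", "phantom", "preset", "histories",
             "electron_histories", "seed", "workers", "secondaries",
             "fluorescence", "rayleigh", "primary_only", "particles",
             "out_dir", "kerma_estimator", "kerma_radii")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown configuration key: ", unknown[1])
  cfg$histories <- cfg$histories %||% 1e5
  cfg$seed <- cfg$seed %||% 1
  cfg$workers <- cfg$workers %||% 1
  cfg$preset <- cfg$preset %||% "desk"
  cfg$particles <- cfg$particles %||% "both"
  if (cfg$histories < 1) stop("histories must be >= 1")
  cfg
}

.presetSpec <- function(preset, scoreMode = "dose") {
  switch(preset,
         paper = paperBinSpec(scoreMode = scoreMode),
         desk = deskBinSpec(scoreMode = scoreMode),
         stop("unknown preset: ", preset))
}

.manifest <- function(path, extra = list()) {
  fx <- c(list.files(.extdata("physics"), full.names = TRUE),
          list.files(.extdata("spectra"), full.names = TRUE))
  man <- c(list(package = "brachyMC",
                version = as.character(utils::packageVersion("brachyMC")),
                timestamp = format(Sys.time(), tz = "UTC"),
                fixture_hashes = as.list(tools::md5sum(fx))),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

#' Write / read a dose-rate table as CSV
#'
#' Columns carry their units in the header names: r_cm, theta_deg,
#' dose_Gy_per_Bq_s, se_Gy_per_Bq_s.
#'
#' @param table a [DoseRateTable-class].
#' @param file CSV path.
#' @export
writeDoseTable <- function(table, file) {
  df <- doseTableFrame(table)
  names(df) <- c("r_cm", "theta_deg", "dose_Gy_per_Bq_s", "se_Gy_per_Bq_s")
  df$mode <- table@mode
  df$source_kind <- table@sourceKind
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeDoseTable
#' @return for `readDoseTable`, a [DoseRateTable-class].
#' @export
readDoseTable <- function(file) {
  df <- read.csv(file)
  need <- c("r_cm", "theta_deg", "dose_Gy_per_Bq_s", "se_Gy_per_Bq_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("dose table file lacks column: ", miss[1])
  rC <- sort(unique(df$r_cm)); thC <- sort(unique(df$theta_deg))
  v <- matrix(NA_real_, length(rC), length(thC))
  s <- v
  ir <- match(df$r_cm, rC); it <- match(df$theta_deg, thC)
  v[cbind(ir, it)] <- df$dose_Gy_per_Bq_s
  s[cbind(ir, it)] <- df$se_Gy_per_Bq_s
  new("DoseRateTable", rCenters = rC, thCenters = thC, value = v, se = s,
      mode = df$mode[1] %||% "dose",
      sourceKind = df$source_kind[1] %||% "combined",
      particlesPerBq = 1, meta = list(file = file))
}

#' Run the dose-simulation pipeline
#'
#' Transports photon and/or electron histories for the configured source in
#' the 40 cm water sphere, writes the per-decay photon-source,
#' electron-source and combined dose tables as CSV, and a JSON manifest with
#' seeds, toggles and fixture hashes.
#'
#' @param config list from [readRunConfig()] (or an equivalent list).
#' @param outDir output directory.
#' @return invisibly, a list with the three tables and the file paths.
#' @export
runDoseSimulation <- function(config, outDir = config$out_dir %||% ".") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  model <- buildSourceModel(config$model %||% "mHDR-v2r",
                            file = config$source_file)
  tc <- transportConfig(secondaries = config$secondaries %||% TRUE,
                        fluorescence = config$fluorescence %||% TRUE,
                        rayleigh = config$rayleigh %||% TRUE,
                        primaryOnly = config$primary_only %||% FALSE)
  spec <- .presetSpec(config$preset %||% "desk")
  out <- list(); paths <- character()
  nph <- config$histories
  nel <- config$electron_histories %||% max(1, round(nph / 10))
  run1 <- function(kind, n) {
    g <- runHistories(model, loadSpectrum(kind), spec, n, config$seed, tc,
                      config$workers %||% 1)
    finalizeDose(g)
  }
  parts <- config$particles %||% "both"
  if (parts %in% c("photon", "both")) {
    out$photon <- run1("photon", nph)
    paths["photon"] <- file.path(outDir, "dose_photon.csv")
    writeDoseTable(out$photon, paths["photon"])
  }
  if (parts %in% c("electron", "both")) {
    out$electron <- run1("electron", nel)
    paths["electron"] <- file.path(outDir, "dose_electron.csv")
    writeDoseTable(out$electron, paths["electron"])
  }
  if (parts == "both") {
    out$combined <- combineDoseTables(out$photon, out$electron)
    paths["combined"] <- file.path(outDir, "dose_combined.csv")
    writeDoseTable(out$combined, paths["combined"])
  }
  win <- if (spec@window) {
    list(mode = "window", dr_cm = unique(spec@rHalf),
         dtheta_deg = unique(spec@thHalf))
  } else {
    list(mode = "contiguous", r_edges = spec@rEdges, th_edges = spec@thEdges)
  }
  .manifest(file.path(outDir, "manifest_dose.json"),
            list(task = "dose", model = model@name, seed = config$seed,
                 histories = nph, electron_histories = nel,
                 preset = config$preset %||% "desk", window = win,
                 toggles = list(secondaries = tc@secondaries,
                                fluorescence = tc@fluorescence,
                                rayleigh = tc@rayleigh,
                                primary_only = tc@primaryOnly),
                 workers = config$workers %||% 1))
  invisible(c(out, list(paths = paths)))
}

#' Run the air-kerma pipeline
#'
#' Photon-only transport through the 1 mm air shells (10 to 120 cm, vacuum
#' elsewhere), writing the 12-point kerma series CSV and manifest.
#'
#' @inheritParams runDoseSimulation
#' @return invisibly, the [KermaSeries-class] and file path.
#' @export
runKermaSimulation <- function(config, outDir = config$out_dir %||% ".") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  model <- buildSourceModel(config$model %||% "mHDR-v2r",
                            file = config$source_file)
  radii <- config$kerma_radii %||% seq(10, 120, by = 10)
  ks <- simulateAirKermaSeries(model, config$histories, config$seed,
                               radii = radii,
                               estimator = config$kerma_estimator %||% "track",
                               workers = config$workers %||% 1)
  path <- file.path(outDir, "kerma_series.csv")
  write.csv(data.frame(r_cm = ks@r_cm, kerma_Gy_per_Bq_s = ks@kerma,
                       se_Gy_per_Bq_s = ks@se), path, row.names = FALSE)
  .manifest(file.path(outDir, "manifest_kerma.json"),
            list(task = "kerma", model = model@name, seed = config$seed,
                 histories = config$histories, radii = radii,
                 shell_thickness_cm = 0.1,
                 estimator = config$kerma_estimator %||% "track"))
  invisible(list(series = ks, path = path))
}

#' Extract the TG-43 dataset from pipeline outputs
#'
#' @param doseFile combined dose-table CSV.
#' @param kermaFile kerma-series CSV.
#' @param L active length, cm.
#' @param outDir output directory.
#' @return invisibly, the [TG43Dataset-class] and file paths.
#' @export
runTG43Extract <- function(doseFile, kermaFile, L, outDir = ".") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dose <- readDoseTable(doseFile)
  kf <- read.csv(kermaFile)
  miss <- setdiff(c("r_cm", "kerma_Gy_per_Bq_s", "se_Gy_per_Bq_s"), names(kf))
  if (length(miss)) stop("kerma series file lacks column: ", miss[1])
  ks <- new("KermaSeries", r_cm = kf$r_cm, kerma = kf$kerma_Gy_per_Bq_s,
            se = kf$se_Gy_per_Bq_s, meta = list(file = kermaFile))
  ds <- tg43Dataset(dose, ks, L,
                    meta = list(dose_file = doseFile, kerma_file = kermaFile))
  write.csv(ds@gL, file.path(outDir, "tg43_gL.csv"), row.names = FALSE)
  Fw <- ds@F
  write.csv(Fw, file.path(outDir, "tg43_F.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(L_cm = ds@L, SK_uGy_m2_per_Bq_s = ds@SK, SK_se = ds@SKse,
         Lambda_cGy_per_h_U = ds@Lambda, Lambda_se = ds@Lambdase),
    file.path(outDir, "tg43_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(dataset = ds,
                 paths = file.path(outDir, c("tg43_gL.csv", "tg43_F.csv",
                                             "tg43_summary.json"))))
}

#' Read a TG-43 dataset written by [runTG43Extract()]
#'
#' @param dir directory containing tg43_gL.csv, tg43_F.csv,
#'   tg43_summary.json.
#' @return a [TG43Dataset-class].
#' @export
readTG43Dataset <- function(dir) {
  js <- jsonlite::read_json(file.path(dir, "tg43_summary.json"))
  gl <- read.csv(file.path(dir, "tg43_gL.csv"))
  Ft <- read.csv(file.path(dir, "tg43_F.csv"))
  new("TG43Dataset", L = js$L_cm, SK = js$SK_uGy_m2_per_Bq_s,
      SKse = js$SK_se, Lambda = js$Lambda_cGy_per_h_U,
      Lambdase = js$Lambda_se, gL = gl, F = Ft,
      meta = list(dir = dir))
}

#' Write a percent-difference report for two datasets
#'
#' Anisotropy-function percent differences in a wide layout (rows r,
#' columns theta), plus the long-format table with combined SEs.
#'
#' @param A,B [TG43Dataset-class] objects.
#' @param outDir output directory.
#' @return invisibly, the comparison list from [compareDatasets()].
#' @export
runCompare <- function(A, B, outDir = ".") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cmp <- compareDatasets(A, B)
  long <- cmp$F
  write.csv(long, file.path(outDir, "compare_F_long.csv"), row.names = FALSE)
  wide <- stats::reshape(long[c("r_cm", "theta_deg", "pct")],
                         idvar = "r_cm", timevar = "theta_deg",
                         direction = "wide")
  names(wide) <- sub("^pct\\.", "theta_", names(wide))
  write.csv(wide, file.path(outDir, "compare_F_wide.csv"), row.names = FALSE)
  write.csv(cmp$gL, file.path(outDir, "compare_gL.csv"), row.names = FALSE)
  invisible(cmp)
}
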