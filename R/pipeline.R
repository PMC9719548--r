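# Pipeline orchestration: configuration, the simulate / process / report
# commands, run manifests and the thin command-line front end
# (inst/scripts/ssfm.R). Exit codes: 0 ok, 2 config, 3 validation, 4 I/O.

#' Pipeline configuration
#'
#' Resolved configuration for a full run. Precedence when assembled through
#' [load_pipeline_config()]: explicit override > config file > built-in
#' default.
#'
#' @param laser_nm Excitation line (nm).
#' @param normal_reference_nm Reference for blue-shift reporting (nm).
#' @param preprocess List of [preprocess_config()] arguments.
#' @param calibration A [calibration_table()] or a JSON file path.
#' @param bands A [class_bands()] or a JSON file path
#'   (`[{"label":..., "lo_nm":..., "hi_nm":...}]`).
#' @param ramp A [color_ramp()] or a JSON file path.
#' @param noise List of [noise_model()] arguments (simulation only).
#' @param seed Integer RNG seed (simulation only).
#' @param upscale Integer upscale factor for rendered images.
#' @param spatial_median Apply the 3x3 modal label filter.
#' @param extrapolate_calibration Allow concentration lookup outside the
#'   anchor span.
#' @return A `pipeline_config` list with all components resolved to objects.
#' @export
pipeline_config <- function(laser_nm = SSFM_LASER_NM,
                            normal_reference_nm = SSFM_NORMAL_REFERENCE_NM,
                            preprocess = list(),
                            calibration = NULL, bands = NULL, ramp = NULL,
                            noise = list(), seed = 1, upscale = 8,
                            spatial_median = FALSE,
                            extrapolate_calibration = FALSE) {
  pp <- do.call(preprocess_config,
                modifyList(list(laser_nm = laser_nm), preprocess))
  calibration <- if (is.null(calibration)) default_calibration()
    else if (is.character(calibration)) calibration_from_file(calibration)
    else calibration
  bands <- if (is.null(bands)) default_bands()
    else if (is.character(bands)) class_bands(jsonlite::fromJSON(bands))
    else bands
  ramp <- if (is.null(ramp)) default_spectral_ramp()
    else if (is.character(ramp)) ramp_from_file(ramp)
    else ramp
  nm <- do.call(noise_model, noise)
  if (laser_nm >= min(bands$lo_nm))
    stop_config("laser line must lie below the lowest classification band")
  structure(list(laser_nm = laser_nm,
                 normal_reference_nm = normal_reference_nm,
                 preprocess = pp, calibration = calibration, bands = bands,
                 ramp = ramp, noise = nm, seed = as.integer(seed),
                 upscale = as.integer(upscale),
                 spatial_median = isTRUE(spatial_median),
                 extrapolate_calibration = isTRUE(extrapolate_calibration)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path Config file (`.yml`/`.yaml`/`.json`) or `NULL` for pure
#'   defaults.
#' @param overrides Named list overriding file values (e.g. parsed CLI
#'   flags); highest precedence.
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path = NULL, overrides = list()) {
  base <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config(sprintf("no such config file: %s", path))
    ext <- tolower(tools::file_ext(path))
    base <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
            else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (!is.list(base)) stop_config(sprintf("malformed config file: %s", path))
  }
  args <- modifyList(base, overrides)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(args), known)
  if (length(bad))
    stop_config(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  do.call(pipeline_config, args)
}

config_as_list <- function(cfg) {
  list(laser_nm = cfg$laser_nm,
       normal_reference_nm = cfg$normal_reference_nm,
       preprocess = cfg$preprocess[c("dichroic_cutoff_nm", "smooth_sigma_nm",
                                     "rician_sigma")],
       calibration = list(anchors = cfg$calibration$anchors,
                          intensity_params = as.list(cfg$calibration$intensity_params),
                          interpolation = cfg$calibration$interpolation),
       bands = as.data.frame(cfg$bands),
       noise = unclass(cfg$noise), seed = cfg$seed, upscale = cfg$upscale,
       spatial_median = cfg$spatial_median,
       extrapolate_calibration = cfg$extrapolate_calibration)
}

write_manifest <- function(out_dir, cfg, extra = list()) {
  manifest <- c(list(tool = "ssfm",
                     version = as.character(packageVersion("ssfm")),
                     r_version = as.character(getRversion()),
                     seed = cfg$seed,
                     config = config_as_list(cfg)),
                extra)
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Simulate a phantom scan and write its cube and ground truth
#'
#' @param phantom A [phantom_spec()] or a JSON/YAML phantom file path.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param classes Class table for the simulator.
#' @return Invisible list of written paths (`cube`, truth maps, manifest).
#' @export
ssfm_simulate <- function(phantom = phantom_spec(), config = pipeline_config(),
                          out_dir, classes = default_class_table()) {
  if (is.character(phantom)) phantom <- phantom_spec_from_file(phantom)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- make_phantom(phantom)
  sim <- simulate_cube(labels, classes = classes, noise = config$noise,
                       seed = config$seed,
                       dichroic_cutoff_nm = config$preprocess$dichroic_cutoff_nm,
                       pixel_um = phantom$pixel_um,
                       laser_nm = config$laser_nm)
  paths <- list(cube = file.path(out_dir, "cube.json"),
                truth_wavelength = file.path(out_dir, "truth_wavelength.csv"),
                truth_intensity = file.path(out_dir, "truth_intensity.csv"),
                truth_concentration = file.path(out_dir, "truth_concentration.csv"),
                truth_labels = file.path(out_dir, "truth_labels.csv"))
  write_cube(sim$cube, paths$cube, "container")
  write_map_csv(sim$truth$wavelength, paths$truth_wavelength)
  write_map_csv(sim$truth$intensity, paths$truth_intensity)
  write_map_csv(sim$truth$concentration, paths$truth_concentration)
  lab_dt <- data.frame(i = rep(seq_len(nrow(labels)), times = ncol(labels)),
                       j = rep(seq_len(ncol(labels)), each = nrow(labels)),
                       label = as.vector(labels))
  data.table::fwrite(lab_dt[order(lab_dt$i, lab_dt$j), ], paths$truth_labels)
  paths$manifest <- write_manifest(out_dir, config,
                                   list(command = "simulate",
                                        phantom = unclass(phantom)[c("m", "n",
                                          "pixel_um", "background")]))
  invisible(paths)
}

#' Run the full processing pipeline on a cube
#'
#' preprocess -> peak maps -> shift maps -> calibration -> classification
#' -> summary -> renders. Writes the wavelength/intensity/concentration/
#' shift maps (CSV), the per-class summary (CSV + JSON), the per-pixel
#' scatter table (CSV), four rendered micrographs (PNG) and a run manifest.
#'
#' @param cube A [spectral_cube()] or a cube file path.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param verbose Log per-stage progress to stderr.
#' @return Invisible list with the in-memory results (`maps`, `labels`,
#'   `summary`, `scatter`) and `paths` of everything written.
#' @export
ssfm_process <- function(cube, config = pipeline_config(), out_dir,
                         verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) if (verbose)
    message(sprintf("[ssfm %7.2fs] ", proc.time()[["elapsed"]] - t0),
            sprintf(fmt, ...))
  if (is.character(cube)) { say("reading %s", cube); cube <- read_cube(cube) }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(cube$data)
  say("cube %d x %d x %d", d[1], d[2], d[3])
  maps <- build_maps(cube, config$preprocess)
  n_missing <- sum(is.na(maps$wavelength))
  say("peak maps built, %d missing pixel(s)", n_missing)
  maps <- apply_k(maps, k_operator("table", table = config$calibration),
                  extrapolate = config$extrapolate_calibration)
  say("calibration applied, %d pixel(s) out of span",
      attr(maps$concentration, "out_of_span") %||% 0L)
  labels <- classify_map(maps, config$bands,
                         spatial_median = config$spatial_median)
  summary <- summarize_classes(labels, maps, laser_nm = config$laser_nm)
  scatter <- export_scatter(labels, maps)
  say("classified: %s", paste(sprintf("%s=%d", summary$label, summary$count),
                              collapse = " "))
  paths <- list(
    wavelength_map = file.path(out_dir, "wavelength_map.csv"),
    intensity_map = file.path(out_dir, "intensity_map.csv"),
    concentration_map = file.path(out_dir, "concentration_map.csv"),
    shift_map = file.path(out_dir, "shift_map.csv"),
    summary_csv = file.path(out_dir, "class_summary.csv"),
    summary_json = file.path(out_dir, "class_summary.json"),
    scatter = file.path(out_dir, "scatter.csv"),
    img_intensity = file.path(out_dir, "micrograph_intensity.png"),
    img_shift = file.path(out_dir, "micrograph_shift.png"),
    img_concentration = file.path(out_dir, "micrograph_concentration.png"),
    img_labels = file.path(out_dir, "micrograph_labels.png"))
  write_map_csv(maps$wavelength, paths$wavelength_map)
  write_map_csv(maps$intensity, paths$intensity_map)
  write_map_csv(maps$concentration, paths$concentration_map)
  write_map_csv(shift_map(maps), paths$shift_map)
  data.table::fwrite(summary, paths$summary_csv)
  jsonlite::write_json(summary, paths$summary_json, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  data.table::fwrite(scatter, paths$scatter)
  for (mode in c("intensity", "shift", "concentration", "labels"))
    write_image(render_map(maps, mode = mode, labels = labels,
                           ramp = config$ramp,
                           calibration = config$calibration,
                           bands = config$bands, upscale = config$upscale),
                paths[[paste0("img_", mode)]])
  paths$manifest <- write_manifest(out_dir, config,
                                   list(command = "process",
                                        n_pixels = d[1] * d[2],
                                        n_missing = n_missing))
  say("artifacts written to %s", out_dir)
  invisible(list(maps = maps, labels = labels, summary = summary,
                 scatter = scatter, paths = paths))
}

#' Render a class summary as a markdown report
#'
#' @param summary A summary data.frame from [summarize_classes()] or the
#'   path of a `class_summary.csv`/`.json` written by [ssfm_process()].
#' @param out_path Optional path to write the report to.
#' @return The report, as a character vector of lines (invisibly when
#'   written to a file).
#' @export
ssfm_report <- function(summary, out_path = NULL) {
  if (is.character(summary)) {
    if (!file.exists(summary)) stop_io(sprintf("no such file: %s", summary))
    ext <- tolower(tools::file_ext(summary))
    summary <- tryCatch(
      if (ext == "json") jsonlite::fromJSON(summary)
      else as.data.frame(data.table::fread(summary)),
      error = function(e) stop_io(sprintf("malformed summary: %s",
                                          conditionMessage(e))))
  }
  need <- c("label", "count", "fraction", "mean_nm", "min_nm", "max_nm",
            "width_nm", "modal_shift_nm", "typ_conc_uM")
  if (!all(need %in% names(summary)))
    stop_io("malformed summary: missing columns")
  fmt <- function(x, dg = 2) ifelse(is.na(x), "-", formatC(x, digits = dg,
                                                           format = "f"))
  lines <- c(
    "# SSFM class summary", "",
    "| class | pixels | fraction | lambda range (nm) | width (nm) | shift (nm) | conc (uM) |",
    "|---|---|---|---|---|---|---|",
    vapply(seq_len(nrow(summary)), function(r) {
      s <- summary[r, ]
      sprintf("| %s%s | %d | %s | %s - %s | %s | %s | %s |",
              s$label, if (s$count == 0) " (absent)" else "",
              s$count, fmt(s$fraction, 3), fmt(s$min_nm), fmt(s$max_nm),
              fmt(s$width_nm), fmt(s$modal_shift_nm, 0),
              fmt(s$typ_conc_uM, 1))
    }, character(1)))
  if (!is.null(out_path)) {
    writeLines(lines, out_path)
    return(invisible(lines))
  }
  lines
}

# --- command-line front end -------------------------------------------------

parse_flags <- function(args) {
  flags <- list(); positional <- character()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        flags[[key]] <- TRUE; i <- i + 1
      } else {
        flags[[key]] <- args[i + 1]; i <- i + 2
      }
    } else { positional <- c(positional, a); i <- i + 1 }
  }
  list(flags = flags, positional = positional)
}

cli_usage <- function() c(
  "usage: ssfm.R <simulate|process|report> [flags]",
  "",
  "  simulate --phantom <spec.json|yaml> --out <dir> [--config <file>]",
  "           [--seed N] [--noise none|gaussian|rician] [--sigma X] [--relative]",
  "  process  --cube <cube.json|csv> --out <dir> [--config <file>]",
  "           [--laser-nm X] [--calibration <json>] [--bands <json>]",
  "           [--ramp <json>] [--cutoff-nm X] [--smooth-nm X] [--rician-sigma X]",
  "           [--upscale N] [--spatial-median] [--verbose]",
  "  report   --summary <class_summary.csv|json> [--out <file>]")

build_cli_config <- function(fl) {
  overrides <- list()
  if (!is.null(fl$`laser-nm`)) overrides$laser_nm <- as.numeric(fl$`laser-nm`)
  if (!is.null(fl$`normal-reference-nm`))
    overrides$normal_reference_nm <- as.numeric(fl$`normal-reference-nm`)
  if (!is.null(fl$seed)) overrides$seed <- as.integer(fl$seed)
  if (!is.null(fl$upscale)) overrides$upscale <- as.integer(fl$upscale)
  if (!is.null(fl$calibration)) overrides$calibration <- fl$calibration
  if (!is.null(fl$bands)) overrides$bands <- fl$bands
  if (!is.null(fl$ramp)) overrides$ramp <- fl$ramp
  if (isTRUE(fl$`spatial-median`)) overrides$spatial_median <- TRUE
  pp <- list()
  if (!is.null(fl$`cutoff-nm`)) pp$dichroic_cutoff_nm <- as.numeric(fl$`cutoff-nm`)
  if (!is.null(fl$`smooth-nm`)) pp$smooth_sigma_nm <- as.numeric(fl$`smooth-nm`)
  if (!is.null(fl$`rician-sigma`)) pp$rician_sigma <- as.numeric(fl$`rician-sigma`)
  if (length(pp)) overrides$preprocess <- pp
  nz <- list()
  if (!is.null(fl$noise)) nz$kind <- fl$noise
  if (!is.null(fl$sigma)) nz$sigma <- as.numeric(fl$sigma)
  if (isTRUE(fl$relative)) nz$relative <- TRUE
  if (length(nz)) overrides$noise <- nz
  load_pipeline_config(fl$config, overrides)
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `process` and `report` subcommands for the
#' thin `Rscript` wrapper shipped at `inst/scripts/ssfm.R`. Flag precedence:
#' command-line flag > `--config` file > built-in default.
#'
#' @param args Character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code: 0 ok, 2 configuration error, 3 validation
#'   error, 4 I/O error.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { writeLines(cli_usage(), con = stderr()); return(2L) }
  cmd <- args[1]
  p <- parse_flags(args[-1])
  fl <- p$flags
  code <- tryCatch({
    if (cmd == "simulate") {
      if (is.null(fl$out)) stop_config("simulate needs --out <dir>")
      cfg <- build_cli_config(fl)
      phantom <- if (is.null(fl$phantom)) phantom_spec()
                 else phantom_spec_from_file(fl$phantom)
      ssfm_simulate(phantom, cfg, fl$out)
      message("cube and ground truth written to ", fl$out)
    } else if (cmd == "process") {
      if (is.null(fl$cube) || is.null(fl$out))
        stop_config("process needs --cube <file> and --out <dir>")
      cfg <- build_cli_config(fl)
      ssfm_process(fl$cube, cfg, fl$out, verbose = isTRUE(fl$verbose))
      message("pipeline artifacts written to ", fl$out)
    } else if (cmd == "report") {
      if (is.null(fl$summary)) stop_config("report needs --summary <file>")
      lines <- ssfm_report(fl$summary, out_path = fl$out)
      if (is.null(fl$out)) writeLines(lines)
    } else {
      writeLines(cli_usage(), con = stderr())
      stop_config(sprintf("unknown command '%s'", cmd))
    }
    0L
  },
  ssfm_config_error = function(e) { message("config error: ", conditionMessage(e)); 2L },
  ssfm_validation_error = function(e) { message("validation error: ", conditionMessage(e)); 3L },
  ssfm_io_error = function(e) { message("I/O error: ", conditionMessage(e)); 4L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  code
}
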