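#' Validated pipeline configuration
#'
#' Collects every stage parameter of the simulate--extract--detect--match
#' chain into one validated list that serializes to YAML/JSON and re-parses
#' to an identical value set.  A single root `seed` drives all noise
#' generators; per-trace seeds are derived from it by fixed offsets, so
#' adding a stage never perturbs the noise of earlier stages.
#'
#' @param preset Preset name (see [tds_preset()]).
#' @param snr Detector amplitude signal-to-noise ratio.
#' @param seed Root integer seed.
#' @param concentration_g_ml Solute concentration for solution presets.
#' @param window,pad_factor,anchor_band_thz,floor_db Extraction settings
#'   (`NULL` = use the preset's recommended values).
#' @param min_prominence_frac,baseline,baseline_window_thz,smooth_thz Peak
#'   detection settings (`NULL` = preset recommendation).
#' @param tolerance_one_to_one_thz,tolerance_many_to_one_thz Matching
#'   tolerances.
#' @param concentrations_g_ml Concentration grid for the series stage.
#' @return An object of class `tds_config` (a named list incl. `version`).
#' @examples
#' cfg <- tds_config("mannitol_solid")
#' cfg2 <- parse_config(unparse_config(cfg))
#' identical(cfg[order(names(cfg))], cfg2[order(names(cfg2))])
#' @export
tds_config <- function(preset = "mannitol_solid", snr = 1000, seed = 42,
                       concentration_g_ml = 1.0,
                       window = NULL, pad_factor = NULL,
                       anchor_band_thz = NULL, floor_db = NULL,
                       min_prominence_frac = NULL, baseline = NULL,
                       baseline_window_thz = NULL, smooth_thz = NULL,
                       tolerance_one_to_one_thz = 0.10,
                       tolerance_many_to_one_thz = 0.15,
                       concentrations_g_ml = seq(0.2, 1.0, by = 0.2)) {
  p <- tds_preset(preset, concentration_g_ml = concentration_g_ml)
  ex <- p$extraction
  pick <- function(user, key) if (is.null(user)) ex[[key]] else user
  cfg <- list(
    preset = preset, snr = snr, seed = as.integer(seed),
    concentration_g_ml = concentration_g_ml,
    window = pick(window, "window"),
    pad_factor = pick(pad_factor, "pad_factor"),
    anchor_band_thz = as.numeric(pick(anchor_band_thz, "anchor_band_thz")),
    floor_db = pick(floor_db, "floor_db"),
    min_prominence_frac = pick(min_prominence_frac, "min_prominence_frac"),
    baseline = pick(baseline, "baseline"),
    baseline_window_thz = {
      v <- pick(baseline_window_thz, "baseline_window_thz")
      if (is.null(v)) 0.4 else v
    },
    smooth_thz = pick(smooth_thz, "smooth_thz"),
    tolerance_one_to_one_thz = tolerance_one_to_one_thz,
    tolerance_many_to_one_thz = tolerance_many_to_one_thz,
    concentrations_g_ml = as.numeric(concentrations_g_ml),
    version = as.character(utils::packageVersion("teraspec")))
  validate_config(cfg)
  class(cfg) <- c("tds_config", "list")
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, what)
    if (!ok) tds_stop("invalid_config", sprintf("invalid config: %s", what))
  chk(is.character(cfg$preset), "preset")
  chk(is.numeric(cfg$snr) && cfg$snr > 0, "snr must be positive")
  chk(is.numeric(cfg$seed), "seed")
  chk(cfg$window %in% c("none", "hann"), "window")
  chk(cfg$pad_factor %in% c(1, 2, 4, 8), "pad_factor")
  chk(length(cfg$anchor_band_thz) == 2 &&
        cfg$anchor_band_thz[1] > 0 &&
        cfg$anchor_band_thz[2] > cfg$anchor_band_thz[1], "anchor_band_thz")
  chk(is.numeric(cfg$floor_db) && cfg$floor_db > 0, "floor_db must be positive")
  chk(cfg$min_prominence_frac > 0 && cfg$min_prominence_frac < 1,
      "min_prominence_frac must be in (0,1)")
  chk(cfg$baseline %in% c("none", "rolling_min"), "baseline")
  chk(is.numeric(cfg$baseline_window_thz) && cfg$baseline_window_thz > 0,
      "baseline_window_thz must be positive")
  chk(is.numeric(cfg$smooth_thz) && cfg$smooth_thz >= 0, "smooth_thz")
  chk(cfg$tolerance_one_to_one_thz > 0, "tolerance_one_to_one_thz must be positive")
  chk(cfg$tolerance_many_to_one_thz > 0, "tolerance_many_to_one_thz must be positive")
  chk(all(cfg$concentrations_g_ml >= 0 & cfg$concentrations_g_ml <= 1),
      "concentrations_g_ml must lie in [0, 1]")
  invisible(cfg)
}

#' Serialize / parse a pipeline configuration
#'
#' The round trip `parse_config(unparse_config(cfg))` is the identity on all
#' parameter values.
#'
#' @param cfg A [tds_config()].
#' @param text YAML text (or a file path for `read_config`).
#' @return YAML text (`unparse_config`) or a `tds_config` (`parse_config`,
#'   `read_config`).
#' @export
unparse_config <- function(cfg) {
  stopifnot(inherits(cfg, "tds_config"))
  yaml::as.yaml(unclass(cfg), precision = 17)
}

#' @rdname unparse_config
#' @export
parse_config <- function(text) {
  cfg <- yaml::yaml.load(text)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  class(cfg) <- c("tds_config", "list")
  cfg
}

#' @rdname unparse_config
#' @param path File path.
#' @export
read_config <- function(path) parse_config(paste(readLines(path), collapse = "\n"))

#' @rdname unparse_config
#' @export
write_config <- function(cfg, path) {
  writeLines(unparse_config(cfg), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates one end-to-end run: simulate the measurement for the
#' configured preset, extract optical constants, detect peaks, match them
#' against the corresponding published list, and (for solutions) run the
#' concentration series.  Every output file embeds the configuration
#' fingerprint; the run is deterministic given the configuration, including
#' its seed.
#'
#' @param config A [tds_config()].
#' @param mode `"solid"` or `"solution"`; must agree with the preset's
#'   geometry.
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param verbose Log stage timings to the console.
#' @return A list with `oc` (optical constants), `peaks`, `match`,
#'   `reference_list`, `series` (solutions only), `config_hash`, and
#'   `files` (paths written).
#' @examples
#' \donttest{
#' res <- run_pipeline(tds_config("erythritol_solid"), mode = "solid",
#'                     out_dir = tempfile())
#' res$peaks
#' }
#' @export
run_pipeline <- function(config, mode = c("solid", "solution"),
                         out_dir = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  validate_config(config)
  hash <- config_fingerprint(unparse_config(config))
  say <- function(fmt, ...) if (verbose)
    message(sprintf("[teraspec %s] ", hash), sprintf(fmt, ...))
  t_start <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      tds_stop("stage_failure", sprintf("stage '%s': %s", name,
                                        conditionMessage(e)))
    })
    say("%s done in %.2f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  opts <- config[c("window", "pad_factor", "anchor_band_thz", "floor_db")]
  meas <- stage("simulate", {
    if (mode == "solid")
      simulate_tablet(config$preset, snr = config$snr, seed = config$seed)
    else
      simulate_solution(config$preset,
                        concentration_g_ml = config$concentration_g_ml,
                        snr = config$snr, seed = config$seed)
  })
  oc <- stage("extract", extract_optical_constants(
    meas$sample, meas$reference, meas$d_mm, options = opts))
  say("validity band %.3g - %.3g THz", oc$band[1], oc$band[2])
  ps <- stage("peaks", detect_peaks(
    oc, min_prominence_frac = config$min_prominence_frac,
    baseline = config$baseline,
    baseline_window_thz = config$baseline_window_thz,
    smooth_thz = config$smooth_thz))
  ref_list_name <- switch(config$preset,
                          mannitol_solid = "mannitol_solid_experiment",
                          mannitol_solid_fig3 = "mannitol_solid_fig3",
                          erythritol_solid = "erythritol_solid_experiment",
                          mannitol_solution = "mannitol_solution",
                          erythritol_solution = "erythritol_solution",
                          NULL)
  ref_list <- if (!is.null(ref_list_name)) reference_peaks(ref_list_name)
  mr <- if (!is.null(ref_list))
    stage("match", match_peaks(ps, ref_list,
                               tolerance_thz = config$tolerance_one_to_one_thz,
                               mode = "one_to_one"))
  series <- if (mode == "solution")
    stage("series", simulate_series(config$preset,
                                    config$concentrations_g_ml,
                                    snr = config$snr, seed = config$seed))
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      config = file.path(out_dir, "config.yaml"),
      reference = file.path(out_dir, "reference.txt"),
      sample = file.path(out_dir, "sample.txt"),
      oc = file.path(out_dir, "optical_constants.csv"),
      peaks = file.path(out_dir, "peaks.json"),
      match = file.path(out_dir, "match.json"))
    writeLines(c(sprintf("# config_hash: %s", hash), unparse_config(config)),
               paths$config)
    meas$reference$label <- paste0(meas$reference$label,
                                   " | config ", hash)
    meas$sample$label <- paste0(meas$sample$label, " | config ", hash)
    write_trace(meas$reference, paths$reference)
    write_trace(meas$sample, paths$sample)
    write_optical_constants(oc, paths$oc)
    ps_out <- ps; ps_out$label <- paste0(ps$label, " | config ", hash)
    write_peak_set(ps_out, paths$peaks)
    if (!is.null(mr)) write_match(mr, paths$match)
    if (!is.null(series)) write_series(series, file.path(out_dir, "series"))
    files <- unlist(paths)
  }
  say("pipeline done in %.2f s",
      as.numeric(Sys.time() - t_start, units = "secs"))
  list(oc = oc, peaks = ps, match = mr, reference_list = ref_list,
       series = series, config_hash = hash, files = files)
}
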