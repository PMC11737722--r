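# End-to-end orchestration: simulate -> score -> model -> report from a
# single config, with structured logging and reproducible outputs.

#' Build a run configuration
#'
#' Every analysis choice that the underlying methods leave open (grid
#' resolution, change-normalisation mode, support rule, collinearity
#' handling, variance-test variant, multiplicity correction) surfaces
#' here, so sensitivity to each is scriptable.
#'
#' @param mode `"simulate"` (write synthetic inputs only), `"analyze"`
#'   (read an existing dose-response CSV) or `"full"` (simulate then
#'   analyse).
#' @param seed integer seed governing all randomness of the run.
#' @param dose_truth a [dose_truth()] (simulate/full modes), or `NULL`.
#' @param latency_truth optional [dose_truth()] for the latency
#'   outcome.
#' @param waveform_truth optional [waveform_truth()]; when present,
#'   simulate/full modes also emit synthetic sweeps and their scored
#'   features.
#' @param input dose-response CSV path (analyze mode).
#' @param grid a [grid_spec()].
#' @param alphas significance levels for threshold selection.
#' @param delta_mode `"difference"` or `"relative"`, see
#'   [normalize_change()].
#' @param support_min minimum combined supra-threshold count, see
#'   [select_thresholds()].
#' @param collinear_tol hinge collinearity cutoff, see
#'   [build_design()].
#' @param bonferroni correct p-values across the grid before
#'   selection.
#' @param variance_test `"ratio"` or `"brown-forsythe"`.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze"),
                       seed = 1L,
                       dose_truth = NULL, latency_truth = NULL,
                       waveform_truth = NULL,
                       input = NULL,
                       grid = grid_spec(),
                       alphas = c(0.05, 0.01, 0.001),
                       delta_mode = c("difference", "relative"),
                       support_min = 3,
                       collinear_tol = 0.99,
                       bonferroni = FALSE,
                       variance_test = c("ratio", "brown-forsythe")) {
  mode <- match.arg(mode)
  delta_mode <- match.arg(delta_mode)
  variance_test <- match.arg(variance_test)
  if (any(alphas <= 0 | alphas >= 1))
    stop("run_config: alphas must lie in (0, 1)")
  if (mode %in% c("simulate", "full") && is.null(dose_truth))
    stop("run_config: '", mode, "' mode needs a dose_truth")
  if (mode == "analyze" && is.null(input))
    stop("run_config: 'analyze' mode needs an input CSV path")
  structure(list(mode = mode, seed = as.integer(seed),
                 dose_truth = dose_truth, latency_truth = latency_truth,
                 waveform_truth = waveform_truth, input = input,
                 grid = grid, alphas = alphas, delta_mode = delta_mode,
                 support_min = support_min,
                 collinear_tol = collinear_tol,
                 bonferroni = bonferroni,
                 variance_test = variance_test),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised keys mirror the [run_config()] arguments; `dose_truth`,
#' `latency_truth` and `waveform_truth` are nested maps of the
#' corresponding constructor arguments, and `grid` a map of
#' [grid_spec()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  mk <- function(spec, ctor) if (is.null(spec)) NULL else do.call(ctor, spec)
  dt <- y$dose_truth
  lt <- y$latency_truth
  # design may be given inline as a list of {theta, phi} or defaults to
  # the pilot reconstruction
  fix_design <- function(spec) {
    if (is.null(spec)) return(NULL)
    if (!is.null(spec$design)) spec$design <- as.data.frame(spec$design)
    spec
  }
  args <- list(
    mode = y$mode %||% "full",
    seed = y$seed %||% 1L,
    dose_truth = mk(fix_design(dt), dose_truth),
    latency_truth = mk(fix_design(lt), dose_truth),
    waveform_truth = mk(y$waveform_truth, waveform_truth),
    input = y$input,
    grid = if (is.null(y$grid)) grid_spec() else do.call(grid_spec, y$grid),
    alphas = y$alphas %||% c(0.05, 0.01, 0.001),
    delta_mode = y$delta_mode %||% "difference",
    support_min = y$support_min %||% 3,
    collinear_tol = y$collinear_tol %||% 0.99,
    bonferroni = y$bonferroni %||% FALSE,
    variance_test = y$variance_test %||% "ratio")
  do.call(run_config, args)
}

#' Validate a dose-response table
#'
#' Flags rows with non-finite responses (both outcomes missing),
#' out-of-range doses, or duplicated subject/eye/timepoint keys.
#' Flagged rows are excluded from analysis but always listed with
#' their reasons, never silently dropped.
#'
#' @param records dose-response data frame.
#' @param theta_max,phi_max admissible dose ranges (defaults are the
#'   apparatus limits: 47 degrees, 3320 degrees/s).
#' @return List: `clean` (retained rows), `excluded` (rows + `reason`),
#'   `n_flags`.
#' @export
validate_inputs <- function(records, theta_max = 47, phi_max = 3320) {
  reasons <- rep(NA_character_, nrow(records))
  flag <- function(idx, why) {
    new <- idx & is.na(reasons)
    reasons[new] <<- why
  }
  no_dy <- !is.finite(records$dy_amplitude) &
    !is.finite(records$dy_latency %||% rep(NA_real_, nrow(records)))
  flag(no_dy, "no finite response")
  flag(!is.finite(records$theta_deg) | records$theta_deg < 0 |
         records$theta_deg > theta_max, "theta out of range")
  flag(!is.finite(records$phi_deg_s) | records$phi_deg_s < 0 |
         records$phi_deg_s > phi_max, "phi out of range")
  key <- paste(records$subject_id, records$eye, records$timepoint)
  flag(duplicated(key), "duplicate subject/eye/timepoint")
  excl <- !is.na(reasons)
  excluded <- records[excl, , drop = FALSE]
  if (nrow(excluded) > 0L) excluded$reason <- reasons[excl]
  else excluded$reason <- character(0)
  list(clean = records[!excl, , drop = FALSE],
       excluded = excluded, n_flags = sum(excl))
}

#' Run the pipeline end to end
#'
#' Simulates inputs if asked, validates them, scans the threshold grid
#' for each available outcome, selects thresholds per significance
#' level, compares sub- vs supra-threshold variance, and writes a
#' reproducible output directory: `dose_response.csv`,
#' `p_surface_<outcome>.csv`, `coefficients_<outcome>.csv`,
#' `contours_<outcome>.csv`, `contour_<outcome>.png`,
#' `selections.json`, `features.csv` (when waveforms were simulated),
#' `report.json` and `run.log`.  Identical config + seed yields an
#' identical report.
#'
#' @param config a [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @param out_dir output directory, created if needed.
#' @param seed optional override of `config$seed`.
#' @param quiet suppress log lines on the console.
#' @return The run report (also written to `report.json`), invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, quiet = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logline <- function(...) {
    msg <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", ...)
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  cfg_hash <- digest::digest(config[setdiff(names(config), "input")])
  logline("run start; mode=", config$mode, " seed=", config$seed,
          " config=", cfg_hash)

  # ---- inputs ----
  if (config$mode %in% c("simulate", "full")) {
    dt <- config$dose_truth
    dt$seed <- config$seed
    lt <- config$latency_truth
    if (!is.null(lt)) lt$seed <- config$seed + 1L
    records <- generate_dose_response(dt, lt)
    write_dose_csv(records, file.path(out_dir, "dose_response.csv"))
    logline("simulated ", nrow(records), " dose-response records")
    if (!is.null(config$waveform_truth)) {
      wt <- config$waveform_truth
      wt$seed <- config$seed
      sig <- generate_waveform(wt, "erg")
      ctl <- generate_control_sweeps(wt, "erg")
      w <- subtract_control(average_sweeps(sig), average_sweeps(ctl))
      feats <- score_erg(w)
      wt_v <- wt; wt_v$seed <- config$seed + 2L
      sigv <- generate_waveform(wt_v, "fvep")
      ctlv <- generate_control_sweeps(wt_v, "fvep")
      wv <- subtract_control(average_sweeps(sigv), average_sweeps(ctlv))
      fv <- measure_fvep(wv)
      rows <- rbind(features_to_rows(feats, "SIM", units = "uV"),
                    features_to_rows(fv, "SIM", units = "mV"))
      utils::write.csv(rows, file.path(out_dir, "features.csv"),
                       row.names = FALSE)
      write_sweeps_csv(sig, file.path(out_dir, "sweeps_erg.csv"), wt)
      logline("scored ", nrow(rows), " simulated waveform features")
    }
  } else {
    records <- read_dose_csv(config$input)
    logline("read ", nrow(records), " records from ", config$input)
  }
  if (config$mode == "simulate") {
    report <- list(mode = config$mode, seed = config$seed,
                   config_hash = cfg_hash,
                   n_records = nrow(records),
                   package_version = as.character(
                     utils::packageVersion("ergthresh")))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logline("run complete (simulate only)")
    return(invisible(report))
  }

  # ---- validation ----
  qc <- validate_inputs(records)
  if (qc$n_flags > 0L) {
    utils::write.csv(qc$excluded, file.path(out_dir, "excluded_rows.csv"),
                     row.names = FALSE)
    logline("excluded ", qc$n_flags, " rows (see excluded_rows.csv)")
  }
  records <- qc$clean
  if (nrow(records) == 0L) stop("run_pipeline: no valid records remain")

  # ---- grid scans ----
  outcomes <- c("amplitude",
                if (any(is.finite(records$dy_latency))) "latency")
  selections <- list()
  variance <- list()
  for (oc in outcomes) {
    scan <- grid_scan(records, config$grid, outcome = oc,
                      collinear_tol = config$collinear_tol)
    logline("scanned ", length(scan$p), " cells for ", oc,
            "; min p = ", signif(min(scan$p), 3))
    write_scan_csv(scan, out_dir, oc)
    sel <- select_thresholds(scan, config$alphas,
                             support_min = config$support_min,
                             bonferroni = config$bonferroni)
    selections[[oc]] <- sel
    ct <- contour_surface(scan, levels = config$alphas)
    utils::write.csv(ct, file.path(out_dir,
                                   paste0("contours_", oc, ".csv")),
                     row.names = FALSE)
    plot_contours(scan, config$alphas,
                  file.path(out_dir, paste0("contour_", oc, ".png")))
    # variance comparison at the alpha = 0.05 selection, if any
    s05 <- sel[["alpha_0.05"]]
    if (!is.null(s05)) {
      y <- outcome_vector(records, oc)
      supra_idx <- records$theta_deg >= s05$theta0 |
        records$phi_deg_s >= s05$phi0
      sub <- y[!supra_idx & is.finite(y)]
      supra <- y[supra_idx & is.finite(y)]
      variance[[oc]] <- if (length(sub) >= 2L && length(supra) >= 2L &&
                            stats::var(sub) > 0) {
        variance_change_test(sub, supra, method = config$variance_test)
      } else list(statistic = NA_real_, p_value = NA_real_,
                  method = config$variance_test,
                  note = "insufficient observations for variance test")
    }
  }
  jsonlite::write_json(selections, file.path(out_dir, "selections.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  report <- list(mode = config$mode, seed = config$seed,
                 config_hash = cfg_hash,
                 package_version = as.character(
                   utils::packageVersion("ergthresh")),
                 n_records = nrow(records), n_excluded = qc$n_flags,
                 delta_mode = config$delta_mode,
                 support_min = config$support_min,
                 bonferroni = config$bonferroni,
                 selections = selections,
                 variance = variance)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logline("run complete")
  invisible(report)
}

write_scan_csv <- function(scan, out_dir, outcome) {
  cells <- expand.grid(theta0 = scan$theta_grid, phi0 = scan$phi_grid,
                       KEEP.OUT.ATTRS = FALSE)
  cells$p_value <- as.vector(scan$p)
  utils::write.csv(cells, file.path(out_dir,
                                    paste0("p_surface_", outcome, ".csv")),
                   row.names = FALSE)
  cells$c1 <- as.vector(scan$c1)
  cells$c2 <- as.vector(scan$c2)
  cells$rss <- as.vector(scan$rss)
  cells$identifiable <- as.vector(scan$identifiable)
  utils::write.csv(cells[, c("theta0", "phi0", "c1", "c2", "rss",
                             "identifiable")],
                   file.path(out_dir,
                             paste0("coefficients_", outcome, ".csv")),
                   row.names = FALSE)
}

plot_contours <- function(scan, levels, path) {
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::filled.contour(
    scan$theta_grid, scan$phi_grid, log10(pmax(scan$p, 1e-16)),
    color.palette = grDevices::hcl.colors,
    xlab = "postulated amplitude threshold (degrees)",
    ylab = "postulated velocity threshold (degrees/s)",
    main = paste0("log10 p-value surface (", scan$outcome, ")"),
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      graphics::contour(scan$theta_grid, scan$phi_grid, scan$p,
                        levels = levels, add = TRUE, lwd = 1.5)
    })
}

#' Convert an S1-style wide table into dose-response records
#'
#' In the study's supplementary workbook each row is a variable and
#' each column an animal.  Given such a table (already read into a
#' data frame whose first column holds the variable names), this maps
#' the named variables onto the dose-response contract.
#'
#' @param df data frame: first column variable names, remaining columns
#'   one animal each.
#' @param map named list with entries `theta`, `phi`, `dy_amplitude`
#'   and optionally `dy_latency`, giving the variable name (first
#'   column value) holding each quantity.
#' @return Dose-response records data frame.
#' @export
s1_table_to_records <- function(df, map) {
  need <- c("theta", "phi", "dy_amplitude")
  if (!all(need %in% names(map)))
    stop("s1_table_to_records: map needs ", paste(need, collapse = ", "))
  vars <- as.character(df[[1]])
  grab <- function(name) {
    i <- match(name, vars)
    if (is.na(i)) stop("s1_table_to_records: variable '", name,
                       "' not found in the table")
    as.numeric(unlist(df[i, -1]))
  }
  theta <- grab(map$theta)
  phi <- grab(map$phi)
  dy_a <- grab(map$dy_amplitude)
  dy_l <- if (is.null(map$dy_latency)) rep(NA_real_, length(theta))
  else grab(map$dy_latency)
  data.frame(subject_id = colnames(df)[-1], eye = "OS", timepoint = "D7",
             theta_deg = theta, phi_deg_s = phi,
             dy_amplitude = dy_a, dy_latency = dy_l,
             stringsAsFactors = FALSE)
}

#' Read an S1-style XLSX workbook of dose-response data
#'
#' Requires the `readxl` package.  The workbook layout is not fully
#' standardised, so an explicit column map (see
#' [s1_table_to_records()]) is mandatory.
#'
#' @param path XLSX path.
#' @param map variable-name map, see [s1_table_to_records()].
#' @param sheet sheet name or index.
#' @return Dose-response records data frame.
#' @export
read_s1_workbook <- function(path, map, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("read_s1_workbook: the 'readxl' package is required")
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet,
                                         col_names = TRUE))
  s1_table_to_records(df, map)
}
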