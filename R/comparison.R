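#' Trigger-and-scan pipeline on a flushed field
#'
#' Monitors `M_w` at the lens start position from the moment injection
#' starts, triggers the pull-back at the first frame meeting the CIF
#' threshold, and runs the full scan.
#'
#' @param field A haematocrit field ([solve_flushing()] output or fixture).
#' @param config An [ivoct_config()].
#' @param monitor_from Time at which monitoring starts (s); defaults to the
#'   second cardiac cycle (injection start).
#' @param start_time Optional explicit scan start, bypassing the trigger.
#' @return A list with `scan` (the [run_scan()] tibble), `trigger_time`, and
#'   `monitor` (the monitored `time`/`m_w` series).
#' @export
trigger_and_scan <- function(field, config = ivoct_config(),
                             monitor_from = NULL, start_time = NULL) {
  proto <- config$scan
  geo <- config$geometry
  if (is.null(monitor_from)) monitor_from <- config$clock$cycle_period
  monitor <- NULL
  if (is.null(start_time)) {
    horizon <- field_horizon(field) %||% config$clock$total_time
    latest <- horizon - proto$scan_duration
    if (latest < monitor_from) {
      abort("truncation error: horizon too short to monitor and scan",
        class = "ivoct_domain_error")
    }
    times <- seq(monitor_from, latest, by = proto$frame_dt)
    m_w <- vapply(times, function(t) {
      frame_mw(field, proto$lens_start_z, geo, t)
    }, numeric(1))
    monitor <- tibble(time = times, m_w = m_w)
    start_time <- pullback_trigger(monitor, proto$cif_threshold)
  }
  scan <- run_scan(field, proto, geo, start_time)
  list(scan = scan, trigger_time = start_time, monitor = monitor)
}

#' Continuous vs. intermittent injection comparison
#'
#' Runs the full in silico experiment for both default injection schemes
#' (or any named schemes in the configuration): blood flushing, automatic
#' pull-back triggering at the CIF threshold, scan scoring, and dosage
#' accounting; then reports the per-scheme summaries and the relative
#' dosage and quality reductions of the second scheme versus the first.
#'
#' @param config An [ivoct_config()].
#' @param fidelity Solver fidelity (see [solve_flushing()]).
#' @param schemes Character vector of two scheme names found in
#'   `config$schemes`.
#' @param t_end Solver horizon (s); defaults to the clock total time.
#' @param verbose Progress output.
#' @return An `ivoct_comparison` list: `summaries` (tibble, one row per
#'   scheme), `dosage_reduction_pct`, `quality_reduction_pct`, `cil`, and
#'   the per-scheme scan tibbles.
#' @export
run_comparison <- function(config = ivoct_config(),
                           fidelity = config$solver$fidelity,
                           schemes = c("continuous", "intermittent"),
                           t_end = NULL, verbose = FALSE) {
  stopifnot(length(schemes) == 2)
  blood <- blood_inflow_waveform(constants = config$constants)
  results <- lapply(schemes, function(nm) {
    sch <- config$schemes[[nm]]
    if (is.null(sch)) {
      abort(sprintf("configuration error: scheme '%s' not found", nm),
        class = "ivoct_config_error")
    }
    wf <- scheme_waveform(sch, config$clock)
    flush <- solve_flushing(config, blood, wf, fidelity = fidelity,
      t_end = t_end, verbose = verbose)
    ts <- trigger_and_scan(flush, config)
    summ <- scan_summary(ts$scan, wf, horizon = config$clock$total_time,
      scheme = nm)
    list(flush = flush, scan = ts$scan, monitor = ts$monitor, summary = summ)
  })
  names(results) <- schemes
  summaries <- dplyr::bind_rows(lapply(results, `[[`, "summary"))
  v <- summaries$dosage_ml
  g <- summaries$gamma
  structure(
    list(
      summaries = summaries,
      dosage_reduction_pct = 100 * (v[1] - v[2]) / v[1],
      quality_reduction_pct = 100 * (g[1] - g[2]) / g[1],
      scans = lapply(results, `[[`, "scan"),
      monitors = lapply(results, `[[`, "monitor"),
      flushes = lapply(results, `[[`, "flush")
    ),
    class = "ivoct_comparison"
  )
}

#' @export
print.ivoct_comparison <- function(x, ...) {
  cat("<ivoct_comparison>\n")
  print(as.data.frame(x$summaries[, c("scheme", "gamma", "cil_mm", "dosage_ml")]),
    row.names = FALSE)
  cat(sprintf("dosage reduction: %.1f%%   quality reduction: %.1f%%\n",
    x$dosage_reduction_pct, x$quality_reduction_pct))
  invisible(x)
}

#' Write a comparison report to disk
#'
#' One JSON summary, one CSV of per-frame quality, and one longitudinal PNG
#' per scheme.
#'
#' @param comparison An [run_comparison()] result.
#' @param dir Output directory (created if missing).
#' @param config The configuration used (for the optics geometry).
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(comparison, dir, config = ivoct_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(
      summaries = comparison$summaries,
      dosage_reduction_pct = comparison$dosage_reduction_pct,
      quality_reduction_pct = comparison$quality_reduction_pct
    ),
    file.path(dir, "comparison.json"), auto_unbox = TRUE, digits = NA
  )
  frames <- dplyr::bind_rows(comparison$scans, .id = "scheme")
  write.csv(as.data.frame(frames), file.path(dir, "frames.csv"),
    row.names = FALSE)
  for (nm in names(comparison$scans)) {
    flush <- comparison$flushes[[nm]]
    scan <- comparison$scans[[nm]]
    alines <- lapply(seq_len(nrow(scan)), function(i) {
      col <- haematocrit_at(flush, scan$lens_z[i], scan$time[i])
      propagate(medium_profile(config$geometry, col))
    })
    img <- stack_longitudinal(alines, z = scan$lens_z)
    write_image(img, file.path(dir, sprintf("longitudinal_%s.png", nm)))
  }
  invisible(dir)
}
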