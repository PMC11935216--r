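#' Simulate a cohort and write it to disk
#'
#' Stage 1 of the pipeline: generate a seeded synthetic cohort and write the
#' spectra, manifest and a config echo under `out_dir`. The analysis drivers
#' under `analysis/` call the three pipeline stages in order.
#'
#' @param out_dir Output directory.
#' @param presets Named list of [intervention_preset()]s.
#' @param n_biological,n_technical Replicate counts.
#' @param sigma Relative noise scale.
#' @param seed Master seed.
#' @return The manifest path, invisibly.
#' @export
run_simulate <- function(out_dir, presets = intervention_presets(),
                         n_biological = 2, n_technical = 3, sigma = 0.01,
                         seed = 1L) {
  ds <- simulate_cohort(presets, n_biological = n_biological,
                        n_technical = n_technical,
                        noise = noise_model(sigma), seed = seed)
  manifest <- write_dataset(ds, out_dir)
  jsonlite::write_json(
    list(stage = "simulate", seed = as.integer(seed), noise_sigma = sigma,
         n_biological = n_biological, n_technical = n_technical,
         presets = names(presets),
         version = as.character(utils::packageVersion("barrierEIS"))),
    file.path(out_dir, "run_config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(manifest)
}

#' Fit every spectrum referenced by a manifest
#'
#' Stage 2: load the dataset, fit the equivalent circuit per (device,
#' timepoint) and write the tidy results table.
#'
#' @param manifest_path Path to `manifest.json`.
#' @param config A [fit_config()].
#' @param out_csv Optional path for the results CSV.
#' @return The results data.frame (see [fit_dataset()]).
#' @export
run_fit <- function(manifest_path, config = fit_config(), out_csv = NULL) {
  man <- read_manifest(manifest_path)
  tcs <- load_timecourses(man)
  res <- fit_dataset(tcs, config)
  if (!is.null(out_csv)) utils::write.csv(res, out_csv, row.names = FALSE)
  res
}

#' Metrics and group statistics from fitted results
#'
#' Stage 3: rebuild per-device `R_b` fold-changes from a results table,
#' compute the normalised cross-section series from the spectra, summarise
#' endpoint fold-changes versus the control arm, and run the between-group
#' inference (Levene gate, one-way ANOVA, Tukey HSD) on the endpoint. When
#' no control arm is present the statistics section is skipped with a
#' warning.
#'
#' @param results Results data.frame from [run_fit()] / [fit_dataset()].
#' @param manifest_path Path to the dataset `manifest.json`.
#' @param out_dir Optional directory for the metric CSVs and report files.
#' @param f0 Cross-section frequency in Hz.
#' @param t_end Endpoint time in hours for the group comparison.
#' @param control_label Control-arm label.
#' @return A list with `metrics` (tidy table), `endpoint` (per-device ratios
#'   and per-arm summaries), and `report` (a `comparison_report`, or `NULL`
#'   when skipped).
#' @export
run_report <- function(results, manifest_path, out_dir = NULL, f0 = 500,
                       t_end = 24, control_label = "control") {
  man <- read_manifest(manifest_path)
  tcs <- load_timecourses(man)

  # an empty flags field may round-trip through CSV as NA
  results$flags[is.na(results$flags)] <- ""
  rb <- results[results$converged & results$flags != "fit_failed",
                c("device_id", "intervention", "timepoint_h", "r_barrier")]
  rb <- data.frame(device_id = rb$device_id, intervention = rb$intervention,
                   timepoint_h = rb$timepoint_h, metric = "rb",
                   value = rb$r_barrier, flag = "",
                   stringsAsFactors = FALSE)
  # fold-changes need a fitted baseline; devices without one are reported in
  # the rb table but excluded (with a warning) from fold-change analytics
  has_base <- vapply(split(rb$timepoint_h, rb$device_id),
                     function(tp) 0 %in% tp, logical(1))
  if (any(!has_base)) {
    warning("device(s) without a fitted baseline excluded from ",
            "fold-changes: ",
            paste(names(has_base)[!has_base], collapse = ", "),
            call. = FALSE)
  }
  fc <- rb_foldchange(rb[rb$device_id %in% names(has_base)[has_base], ])
  cs <- do.call(rbind, lapply(tcs, normalized_crosssection_series, f0 = f0))
  cs$flag <- ""
  metrics <- rbind(cs, rb, fc)
  row.names(metrics) <- NULL

  endpoint <- NULL
  report <- NULL
  has_control <- control_label %in% fc$intervention
  if (!has_control) {
    warning("no '", control_label,
            "' arm in the dataset; group statistics skipped", call. = FALSE)
  } else if (length(unique(fc$intervention)) < 2) {
    warning("control arm only; group statistics not applicable",
            call. = FALSE)
  } else {
    at_end <- fc[fc$timepoint_h == t_end & !is.na(fc$value), ]
    endpoint <- foldchange_vs_control(fc, t = t_end,
                                      control_label = control_label)
    report <- comparison_report(group_table(at_end$value,
                                            at_end$intervention))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(endpoint)) {
      utils::write.csv(endpoint$summary,
                       file.path(out_dir, "endpoint_summary.csv"),
                       row.names = FALSE)
    }
    if (!is.null(report)) {
      report_to_json(report, file.path(out_dir, "comparison_report.json"))
      txt <- utils::capture.output(print(report))
      writeLines(txt, file.path(out_dir, "comparison_report.txt"))
    }
  }
  list(metrics = metrics, endpoint = endpoint, report = report)
}
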