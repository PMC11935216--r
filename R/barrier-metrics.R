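#' Normalised impedance cross-section time series
#'
#' The qualitative barrier-integrity readout: `|Z|` at `f0` (default 500 Hz,
#' a mid-frequency point dominated by the paracellular resistance) at each
#' timepoint, normalised to the same device's t = 0 pre-inoculation baseline,
#' `v(t) = |Z(f0, t)| / |Z(f0, 0)|`. `v(0) = 1` exactly by construction.
#'
#' @param tc A `time_course` containing a t = 0 baseline.
#' @param f0 Cross-section frequency in Hz.
#' @return A data.frame (`device_id`, `intervention`, `timepoint_h`,
#'   `metric = "norm_z500"`, `value`).
#' @export
normalized_crosssection_series <- function(tc, f0 = 500) {
  stopifnot(inherits(tc, "time_course"))
  if (!0 %in% tc$timepoints) {
    stop("time-course for device ", tc$device_id,
         " has no t = 0 baseline spectrum", call. = FALSE)
  }
  cs <- vapply(tc$spectra, crosssection, numeric(1), f0 = f0)
  base <- cs[which(tc$timepoints == 0)]
  data.frame(device_id = tc$device_id, intervention = tc$intervention,
             timepoint_h = tc$timepoints,
             metric = "norm_z500", value = as.numeric(cs / base),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Barrier-resistance time series
#'
#' Fits each timepoint's spectrum (unless fits are already cached on the
#' time-course) and returns the extracted `R_b(t)`. Timepoints whose fit
#' failed are reported as `NA` with a `fit_failed` flag rather than dropped.
#'
#' @param tc A `time_course`.
#' @param config A [fit_config()]; ignored when fits are cached.
#' @return A data.frame (`device_id`, `intervention`, `timepoint_h`,
#'   `metric = "rb"`, `value` in Ohm, `flag`).
#' @export
rb_series <- function(tc, config = fit_config()) {
  stopifnot(inherits(tc, "time_course"))
  if (is.null(tc$fits)) tc <- fit_timecourse(tc, config)
  vals <- vapply(tc$fits, function(f) {
    if (inherits(f, "fit_result")) f$params$r_barrier else NA_real_
  }, numeric(1))
  flags <- vapply(tc$fits, function(f) {
    if (inherits(f, "fit_result")) paste(f$flags, collapse = ";")
    else "fit_failed"
  }, character(1))
  data.frame(device_id = tc$device_id, intervention = tc$intervention,
             timepoint_h = tc$timepoints, metric = "rb",
             value = as.numeric(vals), flag = flags,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-device barrier-resistance fold-change
#'
#' `F(t) = R_b(t) / R_b(0)` per device; `F(0) = 1` exactly.
#'
#' @param series An `rb` series data.frame from [rb_series()] (may contain
#'   several devices).
#' @return A data.frame with `metric = "rb_foldchange"`.
#' @export
rb_foldchange <- function(series) {
  stopifnot(is.data.frame(series), all(series$metric == "rb"))
  out <- lapply(split(series, series$device_id), function(df) {
    base_row <- df[df$timepoint_h == 0, ]
    if (!nrow(base_row)) {
      stop("device ", df$device_id[1], " has no t = 0 R_b", call. = FALSE)
    }
    if (is.na(base_row$value) || nzchar(base_row$flag)) {
      stop("baseline R_b for device ", df$device_id[1],
           " is flagged (", base_row$flag, "); fold-change undefined",
           call. = FALSE)
    }
    df$metric <- "rb_foldchange"
    df$value <- df$value / base_row$value
    df
  })
  out <- do.call(rbind, out)
  row.names(out) <- NULL
  out
}

#' Endpoint fold-changes relative to the control arm
#'
#' Divides each intervention device's `R_b` fold-change at time `t` by the
#' control-arm mean fold-change at the matched timepoint, and summarises each
#' intervention as mean +/- SD - the endpoint the group statistics run on.
#' Devices with failed fits at `t` are excluded pairwise.
#'
#' @param foldchanges A `rb_foldchange` data.frame from [rb_foldchange()]
#'   covering intervention and control devices.
#' @param t Endpoint time in hours (default 24).
#' @param control_label Label of the control arm.
#' @return A list with `per_device` (device-level ratios) and `summary`
#'   (per-intervention `mean`, `sd`, `n`).
#' @export
foldchange_vs_control <- function(foldchanges, t = 24,
                                  control_label = "control") {
  stopifnot(is.data.frame(foldchanges),
            all(foldchanges$metric == "rb_foldchange"))
  at_t <- foldchanges[foldchanges$timepoint_h == t & !is.na(foldchanges$value), ]
  ctrl <- at_t[at_t$intervention == control_label, ]
  if (!nrow(ctrl)) stop("no control-arm devices with R_b at t = ", t,
                        call. = FALSE)
  if (!nrow(at_t[at_t$intervention != control_label, ])) {
    stop("no intervention devices with R_b at t = ", t, call. = FALSE)
  }
  ctrl_mean <- mean(ctrl$value)
  per_device <- at_t
  per_device$metric <- "rb_foldchange_vs_control"
  per_device$value <- per_device$value / ctrl_mean
  agg <- split(per_device$value, per_device$intervention)
  summary <- data.frame(intervention = names(agg),
                        mean = vapply(agg, mean, numeric(1)),
                        sd = vapply(agg, stats::sd, numeric(1)),
                        n = vapply(agg, length, integer(1)),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(per_device = per_device, summary = summary)
}

#' All time-course metrics for a cohort
#'
#' Convenience wrapper producing the tidy metric table (normalised `f0`
#' cross-section, `R_b`, and `R_b` fold-change) for every device.
#'
#' @param timecourses List of `time_course` objects.
#' @param config A [fit_config()].
#' @param f0 Cross-section frequency in Hz.
#' @return A tidy data.frame (`device_id`, `intervention`, `timepoint_h`,
#'   `metric`, `value`, `flag`).
#' @export
cohort_metrics <- function(timecourses, config = fit_config(), f0 = 500) {
  rows <- list()
  for (tc in timecourses) {
    tc <- if (is.null(tc$fits)) fit_timecourse(tc, config) else tc
    cs <- normalized_crosssection_series(tc, f0 = f0)
    cs$flag <- ""
    rb <- rb_series(tc)
    fc <- tryCatch(rb_foldchange(rb), error = function(e) NULL)
    rows[[length(rows) + 1L]] <- rbind(cs, rb, fc)
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
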