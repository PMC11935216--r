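#' Default measurement sweep
#'
#' The measurement protocol sweep: 100 kHz down to 100 mHz at 10 points per
#' decade (61 log-spaced grid points over 6 decades).
#'
#' @return A [frequency_sweep()].
#' @export
make_sweep <- function() frequency_sweep(f_min = 0.1, f_max = 1e5,
                                         points_per_decade = 10)

#' Measurement noise model
#'
#' Multiplicative complex Gaussian noise, independent per frequency:
#' `Z_noisy(f) = Z(f) * (1 + sigma * (eps_re + 1i * eps_im))` with standard
#' normal `eps`. A constant relative scale is the simplest model consistent
#' with a roughly constant relative error across the ~3 decades that `|Z|`
#' spans over the sweep. `sigma = 0` reproduces the forward model exactly.
#'
#' @param sigma Relative noise scale (>= 0; default 0.01).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.01) {
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, kind = "multiplicative-complex"),
            class = "noise_model")
}

# Central (pre-jitter) circuit values for a barrier-forming device. C_b
# balances two constraints: small enough that the barrier element shapes the
# mid-frequency band and |Z(500 Hz)| grows monotonically with R_b across the
# whole programmed fraction range (the testable form of the cross-section
# tracking the paracellular resistance; verified under device jitter), yet
# large enough that its residual real part at 100 kHz
# (~ 1/(omega^2 R_b C_b^2)) stays far below the series-resistance fixing
# rule's recovery tolerance. Q_CE reflects the large-area electrodes
# (electrode capacitances are maximised by design, keeping the abiotic tail
# below ~10 Hz): blank devices are then flat from mid to high frequency,
# with the counter-electrode capacitance dominating only the lowest decades.
default_circuit_values <- function() {
  c(r_ce = 2000, q_ce = 2e-3, alpha_ce = 0.9, r_electrolyte = 120,
    r_barrier = 900, c_barrier = 5e-7)
}

#' Timepoints of the intervention protocol
#'
#' Baseline (0 h, pre-inoculation) followed by measurements at 30 min, 2, 4,
#' 8, 12 and 24 h post-inoculation.
#' @return Numeric vector of hours.
#' @export
anchor_times <- function() c(0, 0.5, 2, 4, 8, 12, 24)

#' Intervention preset
#'
#' A programmed barrier-resistance trajectory for the synthetic generator:
#' per-anchor fractions of the baseline `R_b` (and optionally `C_b`) that a
#' device follows during a 24-hour intervention. The default preset tables
#' (see [intervention_presets()]) are configurable qualitative emulations of
#' the intervention dynamics seen in this class of experiment - a rapid early
#' drop with arm-specific rate and plateau, or partial recovery - and are not
#' measured ground truth; all checks in this package compare fitted values
#' against the programmed fractions.
#'
#' @param label Arm label.
#' @param rb_fractions Fraction of baseline `R_b` at each anchor time; must
#'   start at 1 and stay positive (blank devices carry `R_b = 0` via
#'   `tissue_state`, not via fractions).
#' @param cb_fractions Fraction of baseline `C_b` at each anchor (default all
#'   1).
#' @param times Anchor times in hours, strictly increasing, starting at 0.
#' @param device_jitter_cv Log-normal coefficient of variation of baseline
#'   parameters across devices (default 0.10).
#' @param tissue_state `"barrier"` or `"blank"` (host-tissue-free device).
#' @param caveat Optional free-text caveat carried in provenance (used for
#'   the non-default anaerobe preset whose co-culture conditions were not
#'   viable and which is excluded from default cohorts).
#' @return An object of class `intervention_preset`.
#' @export
intervention_preset <- function(label, rb_fractions,
                                cb_fractions = rep(1, length(rb_fractions)),
                                times = anchor_times(),
                                device_jitter_cv = 0.10,
                                tissue_state = c("barrier", "blank"),
                                caveat = NULL) {
  tissue_state <- match.arg(tissue_state)
  if (length(rb_fractions) != length(times) ||
      length(cb_fractions) != length(times)) {
    stop("fraction tables must match the anchor times in length", call. = FALSE)
  }
  if (any(diff(times) <= 0) || times[1] != 0) {
    stop("anchor times must be strictly increasing and start at 0", call. = FALSE)
  }
  if (tissue_state == "barrier") {
    if (rb_fractions[1] != 1 || cb_fractions[1] != 1) {
      stop("baseline (t = 0) fraction must equal 1", call. = FALSE)
    }
    if (any(rb_fractions <= 0) || any(cb_fractions <= 0)) {
      stop("fractions must be > 0 for non-blank presets", call. = FALSE)
    }
  }
  if (device_jitter_cv < 0) stop("device_jitter_cv must be >= 0", call. = FALSE)
  structure(list(label = label, times = times,
                 rb_fractions = rb_fractions, cb_fractions = cb_fractions,
                 device_jitter_cv = device_jitter_cv,
                 tissue_state = tissue_state, caveat = caveat),
            class = "intervention_preset")
}

#' Default intervention presets
#'
#' Programmed `R_b(t)/R_b(0)` tables at the protocol anchors
#' (0, 0.5, 2, 4, 8, 12, 24 h) for the study arms: an untreated control, two
#' inactivated (postbiotic) consortia with pro- and anti-inflammatory
#' character, the full simplified-microbiota (SIHUMI) postbiotic, two live
#' E. coli strains (a commensal lab strain showing recovery, and the
#' adherent-invasive strain LF82 showing progressive loss), a blank
#' host-tissue-free device, and - available by request only - the anaerobe
#' arm flagged with a viability caveat and excluded from default cohorts.
#'
#' @param labels Which presets to return.
#' @return Named list of [intervention_preset()] objects.
#' @export
intervention_presets <- function(labels = c("control", "pro_inflammatory",
                                            "anti_inflammatory", "sihumi",
                                            "ecoli_top10", "ecoli_lf82")) {
  all <- list(
    control = intervention_preset("control", rep(1, 7)),
    pro_inflammatory = intervention_preset(
      "pro_inflammatory", c(1, .70, .60, .52, .45, .42, .40)),
    anti_inflammatory = intervention_preset(
      "anti_inflammatory", c(1, .85, .75, .65, .55, .45, .40)),
    sihumi = intervention_preset(
      "sihumi", c(1, .90, .85, .82, .80, .79, .78)),
    ecoli_top10 = intervention_preset(
      "ecoli_top10", c(1, .95, .90, .85, .85, .88, .90)),
    ecoli_lf82 = intervention_preset(
      "ecoli_lf82", c(1, .90, .80, .70, .60, .52, .45)),
    blank = intervention_preset("blank", rep(1, 7), tissue_state = "blank"),
    f_prausnitzii = intervention_preset(
      "f_prausnitzii", c(1, .95, .90, .88, .92, 1.00, 1.10),
      caveat = paste("anaerobe co-culture conditions not viable (no",
                     "colonies recovered post-experiment); excluded from",
                     "barrier-resistance analysis by default"))
  )
  missing <- setdiff(labels, names(all))
  if (length(missing)) {
    stop("unknown preset label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  all[labels]
}

#' Draw baseline circuit parameters for a device
#'
#' Baseline parameters are the documented central values with multiplicative
#' log-normal jitter (mean 1, coefficient of variation `jitter_cv`) applied
#' per parameter, keeping every parameter positive. `alpha_ce` is jittered
#' the same way and then clamped into `[0.3, 1]` to respect the CPE exponent
#' bound. Blank and fibroblast-only (day-5) devices carry
#' `r_barrier = c_barrier = 0`: their spectra show the flat ohmic line of a
#' tissue-free scaffold at high-to-mid frequency with the low-frequency tail
#' dominated by the counter-electrode capacitance.
#'
#' @param tissue_state One of `"barrier"`, `"blank"`, `"fibroblast_day5"`.
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @param jitter_cv Coefficient of variation of the log-normal jitter
#'   (default 0.10).
#' @return A [circuit_params()].
#' @export
baseline_parameters <- function(tissue_state = c("barrier", "blank",
                                                 "fibroblast_day5"),
                                seed = NULL, jitter_cv = 0.10) {
  tissue_state <- match.arg(tissue_state)
  centre <- default_circuit_values()
  with_seed_or_stream(seed, {
    if (jitter_cv > 0) {
      sdlog <- sqrt(log1p(jitter_cv^2))
      mult <- stats::rlnorm(6, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      mult <- rep(1, 6)
    }
    vals <- centre * mult
    vals["alpha_ce"] <- min(1, max(0.3, vals["alpha_ce"]))
    if (tissue_state != "barrier") {
      vals["r_barrier"] <- 0
      vals["c_barrier"] <- 0
    }
    circuit_params(r_ce = vals[["r_ce"]], q_ce = vals[["q_ce"]],
                   alpha_ce = vals[["alpha_ce"]],
                   r_electrolyte = vals[["r_electrolyte"]],
                   r_barrier = vals[["r_barrier"]],
                   c_barrier = vals[["c_barrier"]])
  })
}

#' Simulate one noisy spectrum
#'
#' Evaluates the forward circuit on the sweep and applies the multiplicative
#' complex noise model. With `sigma = 0` the output is bitwise equal to
#' [circuit_impedance()].
#'
#' @param params A [circuit_params()].
#' @param sweep A [frequency_sweep()].
#' @param noise A [noise_model()].
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @param meta Metadata attached to the spectrum.
#' @return An [impedance_spectrum()].
#' @export
simulate_spectrum <- function(params, sweep = make_sweep(),
                              noise = noise_model(), seed = NULL,
                              meta = list()) {
  spec <- circuit_impedance(params, sweep, meta = meta)
  if (noise$sigma == 0) return(spec)
  n <- length(spec$frequencies)
  with_seed_or_stream(seed, {
    eps_re <- stats::rnorm(n)
    eps_im <- stats::rnorm(n)
    spec$z <- spec$z * (1 + noise$sigma * complex(real = eps_re,
                                                  imaginary = eps_im))
  })
  spec
}

#' Simulate a device time-course
#'
#' Draws one set of baseline parameters for the device, then at each protocol
#' timepoint scales `r_barrier` (and `c_barrier`) by piecewise-linear
#' interpolation of the preset's programmed fraction tables and simulates one
#' noisy spectrum. The t = 0 spectrum is the pre-inoculation baseline.
#'
#' @param preset An [intervention_preset()].
#' @param sweep A [frequency_sweep()].
#' @param noise A [noise_model()].
#' @param seed Integer seed for the device (drives both the baseline jitter
#'   and the per-timepoint noise).
#' @param device_id Device identifier (defaults to the preset label).
#' @param timepoints Measurement times in hours (default: the preset
#'   anchors).
#' @param biological,technical Replicate indices carried as metadata.
#' @return An object of class `time_course`: device metadata, ordered
#'   timepoints, one spectrum per timepoint, and the generating truth
#'   (baseline parameters and programmed fractions).
#' @export
simulate_timecourse <- function(preset, sweep = make_sweep(),
                                noise = noise_model(), seed = 1L,
                                device_id = preset$label,
                                timepoints = preset$times,
                                biological = 1L, technical = 1L) {
  stopifnot(inherits(preset, "intervention_preset"))
  if (!0 %in% timepoints) stop("timepoints must include the t = 0 baseline",
                               call. = FALSE)
  timepoints <- sort(unique(timepoints))
  seeds <- derive_seeds(seed, 1L + length(timepoints))
  tissue <- if (preset$tissue_state == "blank") "blank" else "barrier"
  base <- baseline_parameters(tissue, seed = seeds[1],
                              jitter_cv = preset$device_jitter_cv)
  rb_frac <- stats::approx(preset$times, preset$rb_fractions,
                           xout = timepoints, rule = 2)$y
  cb_frac <- stats::approx(preset$times, preset$cb_fractions,
                           xout = timepoints, rule = 2)$y
  spectra <- vector("list", length(timepoints))
  for (i in seq_along(timepoints)) {
    p_t <- base
    p_t$r_barrier <- base$r_barrier * rb_frac[i]
    p_t$c_barrier <- base$c_barrier * cb_frac[i]
    spectra[[i]] <- simulate_spectrum(
      p_t, sweep, noise, seed = seeds[1L + i],
      meta = list(device_id = device_id, timepoint_h = timepoints[i],
                  intervention = preset$label, tissue_state = tissue))
  }
  names(spectra) <- as.character(timepoints)
  structure(list(device_id = device_id, intervention = preset$label,
                 biological = biological, technical = technical,
                 timepoints = timepoints, spectra = spectra,
                 truth = list(baseline = base, rb_fractions = rb_frac,
                              cb_fractions = cb_frac),
                 seed = seed, fits = NULL),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time-course %s (%s): %d timepoints (%s h)%s\n",
              x$device_id, x$intervention, length(x$timepoints),
              paste(x$timepoints, collapse = ", "),
              if (is.null(x$fits)) "" else ", fitted"))
  invisible(x)
}

#' Simulate a replicated intervention cohort
#'
#' Generates `n_biological * n_technical` devices per preset, each with its
#' own deterministically derived seed, mirroring the replicate structure of
#' the study (N biological experiments, n technical devices each). A control
#' arm is required for downstream control-normalised metrics and is added
#' (with a message) if missing from `presets`.
#'
#' @param presets Named list of [intervention_preset()]s.
#' @param n_biological,n_technical Replicate counts (defaults 2 and 3).
#' @param noise A [noise_model()].
#' @param seed Master seed; the dataset is fully reproducible from
#'   `(presets, n_biological, n_technical, noise, seed)`.
#' @param sweep A [frequency_sweep()].
#' @return An object of class `synthetic_dataset`: a device table, the list
#'   of `time_course` objects, and provenance (sweep, noise, master seed).
#' @export
simulate_cohort <- function(presets = intervention_presets(),
                            n_biological = 2, n_technical = 3,
                            noise = noise_model(), seed = 1L,
                            sweep = make_sweep()) {
  stopifnot(n_biological >= 1, n_technical >= 1)
  labels <- vapply(presets, function(p) p$label, character(1))
  if (!"control" %in% labels) {
    message("adding a control arm (required for control-normalised metrics)")
    presets <- c(presets, intervention_presets("control"))
  }
  grid <- expand.grid(technical = seq_len(n_technical),
                      biological = seq_len(n_biological),
                      preset = seq_along(presets))
  n_dev <- nrow(grid)
  seeds <- derive_seeds(seed, n_dev)
  tcs <- vector("list", n_dev)
  rows <- vector("list", n_dev)
  for (i in seq_len(n_dev)) {
    p <- presets[[grid$preset[i]]]
    id <- sprintf("%s_b%d_t%d", p$label, grid$biological[i], grid$technical[i])
    tcs[[i]] <- simulate_timecourse(p, sweep = sweep, noise = noise,
                                    seed = seeds[i], device_id = id,
                                    biological = grid$biological[i],
                                    technical = grid$technical[i])
    rows[[i]] <- data.frame(device_id = id, intervention = p$label,
                            biological = grid$biological[i],
                            technical = grid$technical[i], seed = seeds[i],
                            stringsAsFactors = FALSE)
  }
  names(tcs) <- vapply(tcs, function(tc) tc$device_id, character(1))
  structure(list(devices = do.call(rbind, rows), timecourses = tcs,
                 sweep = sweep, noise = noise, seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d devices (%s), %d timepoints each, sigma = %g, seed = %d\n",
              nrow(x$devices),
              paste(unique(x$devices$intervention), collapse = ", "),
              length(x$timecourses[[1]]$timepoints), x$noise$sigma, x$seed))
  invisible(x)
}
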