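#' Equivalent-circuit parameters
#'
#' Parameter container for the two-electrode equivalent circuit used to model
#' barrier-tissue devices:
#' `(R_CE // Q_CE) - R_electrolyte - (R_barrier // C_barrier)`,
#' where `//` is a parallel combination and `-` a series connection. The
#' counter-electrode branch is a resistance in parallel with a constant phase
#' element (CPE) and implicitly lumps in the working-electrode/scaffold
#' impedance; the barrier branch models the paracellular (resistive) and
#' transcellular (capacitive) ionic pathways of the epithelial tissue.
#'
#' `r_barrier = 0` and `c_barrier = 0` together encode a blank
#' (host-tissue-free) device: the barrier element then contributes zero
#' impedance at every frequency.
#'
#' @param r_ce Counter-electrode resistance, Ohm (>= 0).
#' @param q_ce CPE magnitude, S.s^alpha (>= 0; 0 encodes an open CPE branch).
#' @param alpha_ce CPE exponent, dimensionless, in (0, 1].
#' @param r_electrolyte Series electrolyte (solution) resistance, Ohm (>= 0).
#' @param r_barrier Barrier resistance R_b, Ohm (>= 0).
#' @param c_barrier Barrier capacitance C_b, F (>= 0; 0 encodes an open
#'   capacitor branch).
#' @return An object of class `circuit_params`.
#' @examples
#' p <- circuit_params(r_ce = 2000, q_ce = 1e-4, alpha_ce = 0.9,
#'                     r_electrolyte = 120, r_barrier = 900,
#'                     c_barrier = 2e-6)
#' @export
circuit_params <- function(r_ce, q_ce, alpha_ce, r_electrolyte,
                           r_barrier, c_barrier) {
  vals <- c(r_ce = r_ce, q_ce = q_ce, alpha_ce = alpha_ce,
            r_electrolyte = r_electrolyte, r_barrier = r_barrier,
            c_barrier = c_barrier)
  if (any(!is.finite(vals))) {
    stop("all circuit parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals[c("r_ce", "q_ce", "r_electrolyte", "r_barrier",
                 "c_barrier")] < 0)) {
    stop("r_ce, q_ce, r_electrolyte, r_barrier and c_barrier must be >= 0",
         call. = FALSE)
  }
  if (alpha_ce <= 0 || alpha_ce > 1) {
    stop("alpha_ce must lie in (0, 1]", call. = FALSE)
  }
  structure(as.list(vals), class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Equivalent-circuit parameters (R_CE//Q_CE)-R_el-(R_b//C_b):\n")
  cat(sprintf("  R_CE  = %.6g Ohm   Q_CE = %.6g S.s^a   alpha = %.4f\n",
              x$r_ce, x$q_ce, x$alpha_ce))
  cat(sprintf("  R_el  = %.6g Ohm   R_b  = %.6g Ohm     C_b   = %.6g F\n",
              x$r_electrolyte, x$r_barrier, x$c_barrier))
  if (x$r_barrier == 0 && x$c_barrier == 0) cat("  (blank device: barrier element open/shorted out)\n")
  invisible(x)
}

#' Logarithmic frequency sweep
#'
#' Describes a log10-spaced frequency grid swept from `f_max` down to `f_min`
#' (the instrument sweep direction) with `points_per_decade` points per
#' decade, both endpoints included. The default measurement protocol sweeps
#' 100 kHz to 100 mHz at 10 points per decade, giving 61 grid points.
#'
#' @param f_min Lowest frequency, Hz (> 0).
#' @param f_max Highest frequency, Hz (> `f_min`).
#' @param points_per_decade Grid density (>= 1).
#' @return An object of class `frequency_sweep`.
#' @seealso [make_sweep()] for the default protocol sweep,
#'   [sweep_frequencies()] for the realised grid.
#' @export
frequency_sweep <- function(f_min = 0.1, f_max = 1e5, points_per_decade = 10) {
  if (!is.finite(f_min) || f_min <= 0) stop("f_min must be > 0", call. = FALSE)
  if (!is.finite(f_max) || f_max <= f_min) stop("f_max must exceed f_min", call. = FALSE)
  if (points_per_decade < 1) stop("points_per_decade must be >= 1", call. = FALSE)
  structure(list(f_min = f_min, f_max = f_max,
                 points_per_decade = points_per_decade),
            class = "frequency_sweep")
}

#' Realise the frequency grid of a sweep
#'
#' @param sweep A [frequency_sweep()].
#' @return Numeric vector of frequencies in Hz, descending from `f_max` to
#'   `f_min`, log10-spaced, endpoints included.
#' @export
sweep_frequencies <- function(sweep) {
  stopifnot(inherits(sweep, "frequency_sweep"))
  n_dec <- log10(sweep$f_max / sweep$f_min)
  n <- max(2L, round(sweep$points_per_decade * n_dec) + 1L)
  10^seq(log10(sweep$f_max), log10(sweep$f_min), length.out = n)
}

#' Impedance spectrum container
#'
#' A complex impedance spectrum sampled on a frequency grid, with device and
#' timepoint metadata. Frequencies are stored strictly descending (the sweep
#' direction, `f_max` to `f_min`); the imaginary part of `z` is stored signed,
#' negative for capacitive behaviour.
#'
#' @param frequencies Frequencies in Hz (> 0, no duplicates). Re-ordered to
#'   descending if supplied in another order.
#' @param z Complex impedances, Ohm; same length as `frequencies`.
#' @param meta Named list of metadata (e.g. `device_id`, `timepoint_h`,
#'   `intervention`, `tissue_state`).
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(frequencies, z, meta = list()) {
  if (length(frequencies) != length(z)) {
    stop("frequencies and z must have equal length", call. = FALSE)
  }
  if (length(frequencies) == 0) stop("spectrum must be non-empty", call. = FALSE)
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("all frequencies must be finite and > 0", call. = FALSE)
  }
  if (anyDuplicated(frequencies)) {
    stop("duplicate frequencies in spectrum", call. = FALSE)
  }
  ord <- order(frequencies, decreasing = TRUE)
  structure(list(frequencies = as.numeric(frequencies[ord]),
                 z = as.complex(z[ord]),
                 meta = meta),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: %d frequencies, %.3g-%.3g Hz\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Sentinel for an open (infinite-impedance) branch, used so a single
# parameter set can encode blank devices (C = 0, Q = 0) exactly.
open_impedance <- function(n = 1L) complex(real = rep(Inf, n),
                                           imaginary = rep(0, n))

is_open_impedance <- function(z) !is.finite(Re(z)) | !is.finite(Im(z))

#' Ideal capacitor impedance
#'
#' `Z_C = 1 / (j * omega * C)` with `omega = 2 * pi * f`: purely imaginary
#' with negative imaginary part (phase -90 degrees).
#'
#' @param c Capacitance in F (> 0).
#' @param f Frequency in Hz (> 0); vectorised.
#' @return Complex impedance in Ohm.
#' @export
capacitor_impedance <- function(c, f) {
  if (!is.numeric(c) || any(c <= 0)) stop("capacitance must be > 0", call. = FALSE)
  if (!is.numeric(f) || any(f <= 0)) stop("frequency must be > 0", call. = FALSE)
  1 / (2i * pi * f * c)
}

#' Constant phase element impedance
#'
#' `Z_Q = 1 / (Q * (j * omega)^alpha)` with `omega = 2 * pi * f`. The phase is
#' constant at `-alpha * 90` degrees across frequency; `alpha = 1` recovers an
#' ideal capacitor of capacitance `Q`.
#'
#' @param q CPE magnitude in S.s^alpha (> 0).
#' @param alpha CPE exponent in (0, 1].
#' @param f Frequency in Hz (> 0); vectorised.
#' @return Complex impedance in Ohm.
#' @export
cpe_impedance <- function(q, alpha, f) {
  if (!is.numeric(q) || any(q <= 0)) stop("CPE magnitude q must be > 0", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("CPE exponent alpha must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(f) || any(f <= 0)) stop("frequency must be > 0", call. = FALSE)
  1 / (q * (2i * pi * f)^alpha)
}

#' Parallel combination of two impedances
#'
#' Computed in admittance space, `Z = 1 / (1/z1 + 1/z2)`, so that an open
#' branch (infinite impedance, the encoding of `Q = 0` or `C = 0`) leaves the
#' other branch unchanged, and a shorted branch (`z = 0`) shorts the
#' combination. Two open branches return the open sentinel.
#'
#' @param z1,z2 Complex impedances (vectorised, recycled to common length).
#'   Use `open_impedance()` (infinite real part) for an open branch.
#' @return Complex impedance of the parallel combination.
#' @export
parallel_impedance <- function(z1, z2) {
  z1 <- as.complex(z1)
  z2 <- as.complex(z2)
  n <- max(length(z1), length(z2))
  z1 <- rep_len(z1, n)
  z2 <- rep_len(z2, n)
  out <- complex(n)
  o1 <- is_open_impedance(z1)
  o2 <- is_open_impedance(z2)
  out[o1 & o2] <- open_impedance(sum(o1 & o2))
  out[o1 & !o2] <- z2[o1 & !o2]
  out[o2 & !o1] <- z1[o2 & !o1]
  reg <- !o1 & !o2
  shorted <- reg & (z1 == 0 | z2 == 0)
  out[shorted] <- 0 + 0i
  reg <- reg & !shorted
  out[reg] <- 1 / (1 / z1[reg] + 1 / z2[reg])
  out
}

# Vectorised forward model at arbitrary frequencies (internal workhorse for
# both simulation and fitting).
circuit_z <- function(params, f) {
  n <- length(f)
  ce_cpe <- if (params$q_ce == 0) open_impedance(n) else {
    cpe_impedance(params$q_ce, params$alpha_ce, f)
  }
  ce <- parallel_impedance(complex(real = params$r_ce), ce_cpe)
  bar_cap <- if (params$c_barrier == 0) open_impedance(n) else {
    capacitor_impedance(params$c_barrier, f)
  }
  bar <- parallel_impedance(complex(real = params$r_barrier), bar_cap)
  ce + params$r_electrolyte + bar
}

#' Forward evaluation of the equivalent circuit over a sweep
#'
#' Evaluates `Z(f) = (R_CE // Z_Q) + R_electrolyte + (R_b // Z_C)` on the
#' sweep grid. For every valid parameter set the model is passive:
#' `Im(Z) <= 0` and `Re(Z) > 0` (for positive `r_electrolyte`), and `Re(Z)`
#' is monotone non-increasing in frequency. Blank devices
#' (`r_barrier = c_barrier = 0`) contribute a zero barrier term.
#'
#' @param params A [circuit_params()].
#' @param sweep A [frequency_sweep()].
#' @param meta Metadata list attached to the returned spectrum.
#' @return An [impedance_spectrum()].
#' @export
circuit_impedance <- function(params, sweep, meta = list()) {
  stopifnot(inherits(params, "circuit_params"))
  f <- sweep_frequencies(sweep)
  impedance_spectrum(f, circuit_z(params, f), meta = meta)
}

#' Bode quantities of a spectrum
#'
#' @param spectrum An [impedance_spectrum()].
#' @return A data.frame with columns `frequency_hz`, `magnitude_ohm`
#'   (`|Z|`) and `phase_deg` (`atan2(Im, Re)` in degrees).
#' @export
bode <- function(spectrum) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  data.frame(frequency_hz = spectrum$frequencies,
             magnitude_ohm = Mod(spectrum$z),
             phase_deg = atan2(Im(spectrum$z), Re(spectrum$z)) * 180 / pi)
}

#' Impedance-magnitude cross-section at a single frequency
#'
#' Reads `|Z|` at `f0` (default 500 Hz, the mid-frequency point dominated by
#' the paracellular barrier resistance). `f0` rarely sits exactly on the
#' measurement grid (the default grid brackets 500 Hz with 398.1 and
#' 501.2 Hz), so the value is obtained by linear interpolation of
#' `log10|Z|` versus `log10 f`; an exact grid hit returns the stored value.
#'
#' @param spectrum An [impedance_spectrum()].
#' @param f0 Cross-section frequency in Hz; must lie within the measured
#'   range.
#' @return `|Z(f0)|` in Ohm.
#' @export
crosssection <- function(spectrum, f0 = 500) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequencies
  if (f0 < min(f) || f0 > max(f)) {
    stop(sprintf("f0 = %g Hz outside the measured range [%g, %g] Hz",
                 f0, min(f), max(f)), call. = FALSE)
  }
  m <- Mod(spectrum$z)
  hit <- which(f == f0)
  if (length(hit)) return(m[hit[1]])
  ord <- order(f)
  10^stats::approx(log10(f[ord]), log10(m[ord]), xout = log10(f0))$y
}
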