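#' Fitting configuration
#'
#' Controls the multistart complex non-linear least-squares (CNLS) fit.
#' Bounds are in natural units; internally the magnitude parameters
#' (resistances, CPE magnitude, capacitance) are optimised in log10 space -
#' which both enforces positivity and conditions the search across the many
#' decades the bounds span - while `alpha_ce` stays in natural space.
#'
#' @param n_starts Number of multistart initial points (>= 1, default 32).
#' @param bounds Named list of `c(low, high)` bounds per parameter; see
#'   [default_fit_bounds()].
#' @param weighting `"modulus"` (residuals scaled by `1/|Z_obs|`; default,
#'   since `|Z|` spans ~3 decades over the sweep) or `"unit"`.
#' @param seed Integer seed for the start-point stream; fits are reproducible
#'   given (spectrum, config). Start sets are nested: the first `k` starts
#'   are identical for any two configs sharing a seed, so the best cost is
#'   non-increasing in `n_starts`.
#' @param ftol Relative cost-change convergence tolerance of the local
#'   optimiser (default 1e-12).
#' @param fix_r_electrolyte If `TRUE` (default), fix the series resistance to
#'   the real part of the highest-frequency impedance measurement
#'   ([fix_series_resistance()]) instead of co-fitting it.
#' @param model `"full"` (both branches) or `"barrier_free"` (no barrier
#'   element; for blank, host-tissue-free devices).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_starts = 32, bounds = default_fit_bounds(),
                       weighting = c("modulus", "unit"), seed = 1L,
                       ftol = 1e-12, fix_r_electrolyte = TRUE,
                       model = c("full", "barrier_free")) {
  weighting <- match.arg(weighting)
  model <- match.arg(model)
  stopifnot(n_starts >= 1)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || any(b <= 0) || b[1] >= b[2]) {
      stop("bounds for ", nm, " must be positive with low < high",
           call. = FALSE)
    }
  }
  structure(list(n_starts = as.integer(n_starts), bounds = bounds,
                 weighting = weighting, seed = as.integer(seed),
                 ftol = ftol, fix_r_electrolyte = fix_r_electrolyte,
                 model = model),
            class = "fit_config")
}

#' Default parameter bounds
#'
#' Resistances span `[1e-2, 1e9]` Ohm, the CPE magnitude `[1e-12, 1e-1]`,
#' the CPE exponent `[0.3, 1]`. The barrier capacitance is bounded at
#' `1e-4` F: epithelial monolayers over tens of mm^2 sit near `1` uF/cm^2,
#' orders of magnitude below the electrode-interface capacitance, and
#' capping `c_barrier` well under typical `q_ce` removes the branch
#' role-swap degeneracy in which the barrier element impersonates the
#' counter-electrode interface.
#'
#' @return Named list of `c(low, high)` bounds per parameter.
#' @export
default_fit_bounds <- function() {
  list(r_ce = c(1e-2, 1e9), q_ce = c(1e-12, 1e-1), alpha_ce = c(0.3, 1.0),
       r_electrolyte = c(1e-2, 1e9), r_barrier = c(1e-2, 1e9),
       c_barrier = c(1e-12, 1e-4))
}

#' Series-resistance fixing rule
#'
#' Returns the real part of the impedance at the highest measured frequency,
#' where both parallel branches have negligible real contribution; during
#' fitting the series electrolyte resistance is fixed to this measured value
#' (noise included) rather than co-fitted.
#'
#' @param spectrum An [impedance_spectrum()].
#' @return Resistance in Ohm.
#' @export
fix_series_resistance <- function(spectrum) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  if (!length(spectrum$frequencies)) stop("empty spectrum", call. = FALSE)
  Re(spectrum$z[which.max(spectrum$frequencies)])
}

#' CNLS residual vector
#'
#' Stacked weighted residuals over the spectrum's frequencies:
#' `[w_i (Re Z_model,i - Re Z_obs,i), w_i (Im Z_model,i - Im Z_obs,i)]`
#' with modulus weighting `w_i = 1/|Z_obs,i|` or unit weighting `w_i = 1`.
#' The fit cost is the sum of squares of this vector.
#'
#' @param params A [circuit_params()].
#' @param spectrum An [impedance_spectrum()].
#' @param weighting `"modulus"` or `"unit"`.
#' @return Numeric vector of length `2 * length(frequencies)`.
#' @export
cnls_residuals <- function(params, spectrum,
                           weighting = c("modulus", "unit")) {
  weighting <- match.arg(weighting)
  z_obs <- spectrum$z
  w <- if (weighting == "modulus") {
    m <- Mod(z_obs)
    if (any(m == 0)) {
      stop("zero |Z_obs| is incompatible with modulus weighting",
           call. = FALSE)
    }
    1 / m
  } else {
    rep(1, length(z_obs))
  }
  z_mod <- circuit_z(params, spectrum$frequencies)
  c(w * (Re(z_mod) - Re(z_obs)), w * (Im(z_mod) - Im(z_obs)))
}

# Free-parameter bookkeeping: which parameters are optimised for a given
# model/fixing configuration, and the log10 transform for magnitudes.
free_param_names <- function(config) {
  nm <- c("r_ce", "q_ce", "alpha_ce")
  if (!config$fix_r_electrolyte) nm <- c(nm, "r_electrolyte")
  if (config$model == "full") nm <- c(nm, "r_barrier", "c_barrier")
  nm
}

to_internal <- function(values, names) {
  ifelse(names == "alpha_ce", values, log10(values))
}

from_internal <- function(par, names) {
  ifelse(names == "alpha_ce", par, 10^par)
}

assemble_params <- function(par, names, config, r_el_fixed) {
  vals <- stats::setNames(from_internal(par, names), names)
  circuit_params(
    r_ce = vals[["r_ce"]], q_ce = vals[["q_ce"]],
    alpha_ce = vals[["alpha_ce"]],
    r_electrolyte = if (config$fix_r_electrolyte) r_el_fixed
                    else vals[["r_electrolyte"]],
    r_barrier = if (config$model == "full") vals[["r_barrier"]] else 0,
    c_barrier = if (config$model == "full") vals[["c_barrier"]] else 0)
}

# Analytic Jacobian of the weighted residual vector with respect to the
# internal (log10-transformed) free parameters. Within the fit bounds every
# parameter is strictly positive, so no open-branch special cases arise.
# With Z_CE = 1/(1/r_ce + q s^a) and Z_b = 1/(1/r_b + s c), s = j omega:
#   dZ/dlog10(r_ce) = ln10 * Z_CE^2 / r_ce      dZ/dlog10(q) = -ln10 * Z_CE^2 q s^a
#   dZ/dalpha       = -Z_CE^2 q s^a ln(s)       dZ/dlog10(r_el) = ln10 * r_el
#   dZ/dlog10(r_b)  = ln10 * Z_b^2 / r_b        dZ/dlog10(c) = -ln10 * Z_b^2 s c
cnls_jacobian <- function(par, names, config, r_el_fixed, spectrum, w) {
  vals <- stats::setNames(from_internal(par, names), names)
  f <- spectrum$frequencies
  s <- 2i * pi * f
  ln10 <- log(10)
  q_sa <- vals[["q_ce"]] * s^vals[["alpha_ce"]]
  z_ce <- 1 / (1 / vals[["r_ce"]] + q_sa)
  dz <- vector("list", length(names))
  names(dz) <- names
  dz[["r_ce"]] <- ln10 * z_ce^2 / vals[["r_ce"]]
  dz[["q_ce"]] <- -ln10 * z_ce^2 * q_sa
  dz[["alpha_ce"]] <- -z_ce^2 * q_sa * (log(2 * pi * f) + 1i * pi / 2)
  if ("r_electrolyte" %in% names) {
    dz[["r_electrolyte"]] <- rep(ln10 * vals[["r_electrolyte"]] + 0i,
                                 length(f))
  }
  if (config$model == "full") {
    z_b <- 1 / (1 / vals[["r_barrier"]] + s * vals[["c_barrier"]])
    dz[["r_barrier"]] <- ln10 * z_b^2 / vals[["r_barrier"]]
    dz[["c_barrier"]] <- -ln10 * z_b^2 * s * vals[["c_barrier"]]
  }
  jac <- matrix(0, nrow = 2 * length(f), ncol = length(names))
  for (j in seq_along(names)) {
    jac[, j] <- c(w * Re(dz[[j]]), w * Im(dz[[j]]))
  }
  jac
}

# Draw the multistart initial points one start at a time so that the first k
# rows are identical for every n_starts sharing a seed (nested start sets).
draw_starts <- function(config, names) {
  lo <- vapply(config$bounds[names], `[`, numeric(1), 1)
  hi <- vapply(config$bounds[names], `[`, numeric(1), 2)
  lo_i <- to_internal(lo, names)
  hi_i <- to_internal(hi, names)
  withr::with_seed(config$seed, {
    t(vapply(seq_len(config$n_starts), function(i) {
      stats::runif(length(names), lo_i, hi_i)
    }, numeric(length(names))))
  })
}

#' Fit the equivalent circuit to a spectrum
#'
#' Complex non-linear least squares with multistart global optimisation:
#' `n_starts` initial points are drawn log-uniformly within the bounds
#' (`alpha_ce` uniformly), each is refined by bounded Levenberg-Marquardt
#' least squares ([minpack.lm::nls.lm()]) on the weighted residual vector,
#' and the lowest final cost wins (ties broken by lowest start index). When
#' `fix_r_electrolyte` is on, the series resistance is held bit-exactly at
#' [fix_series_resistance()] of the spectrum.
#'
#' @param spectrum An [impedance_spectrum()] with at least 12 frequencies.
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: `params` (best-fit
#'   [circuit_params()]), `cost` (weighted sum of squared residuals),
#'   `per_start` diagnostics (initial point, final cost, convergence flag per
#'   start), `n_function_evals`, `r_electrolyte_fixed` (the fixed value, or
#'   `NA` when co-fitted), and `flags` (`"no_barrier"` when the fitted
#'   barrier element is degenerate: `r_barrier` pinned near its lower bound,
#'   a sub-2% sliver of the DC resistance, or a shunt whose corner frequency
#'   lies below the measured band - the expected outcomes on blank devices).
#' @export
fit_spectrum <- function(spectrum, config = fit_config()) {
  stopifnot(inherits(spectrum, "impedance_spectrum"),
            inherits(config, "fit_config"))
  if (length(spectrum$frequencies) < 12) {
    stop("spectrum has fewer than 12 frequencies; too little information ",
         "for a 6-parameter circuit", call. = FALSE)
  }
  names <- free_param_names(config)
  r_el_fixed <- if (config$fix_r_electrolyte) {
    fix_series_resistance(spectrum)
  } else NA_real_
  if (config$fix_r_electrolyte && r_el_fixed < 0) {
    # a noisy high-frequency point can dip below zero; the circuit requires
    # a non-negative series resistance
    r_el_fixed <- 0
  }
  lo <- to_internal(vapply(config$bounds[names], `[`, numeric(1), 1), names)
  hi <- to_internal(vapply(config$bounds[names], `[`, numeric(1), 2), names)
  starts <- draw_starts(config, names)
  # hot path: precompute everything that does not change across evaluations
  # and evaluate the model without container construction (cnls_residuals is
  # the reference implementation; equality is covered by the test suite)
  f_hz <- spectrum$frequencies
  s <- 2i * pi * f_hz
  z_re <- Re(spectrum$z)
  z_im <- Im(spectrum$z)
  if (config$weighting == "modulus" && any(Mod(spectrum$z) == 0)) {
    stop("zero |Z_obs| is incompatible with modulus weighting", call. = FALSE)
  }
  w <- if (config$weighting == "modulus") 1 / Mod(spectrum$z)
       else rep(1, length(spectrum$z))
  is_log <- names != "alpha_ce"
  i_rce <- match("r_ce", names)
  i_q <- match("q_ce", names)
  i_a <- match("alpha_ce", names)
  i_rel <- match("r_electrolyte", names)
  i_rb <- match("r_barrier", names)
  i_cb <- match("c_barrier", names)
  full <- config$model == "full"
  resid_fn <- function(par) {
    v <- par
    v[is_log] <- 10^par[is_log]
    z <- 1 / (1 / v[i_rce] + v[i_q] * s^v[i_a]) +
      (if (config$fix_r_electrolyte) r_el_fixed else v[i_rel])
    if (full) z <- z + 1 / (1 / v[i_rb] + s * v[i_cb])
    c(w * (Re(z) - z_re), w * (Im(z) - z_im))
  }
  jac_fn <- function(par) {
    cnls_jacobian(par, names, config, r_el_fixed, spectrum, w)
  }
  # two-phase multistart: a short exploration pass from every start, then a
  # full-tolerance polish of the most promising basins
  ctrl_explore <- minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-10,
                                             gtol = 0, maxiter = 50,
                                             maxfev = 20000)
  ctrl_polish <- minpack.lm::nls.lm.control(ftol = config$ftol, ptol = 1e-14,
                                            gtol = 0, maxiter = 400,
                                            maxfev = 20000)
  n_polish <- min(4L, config$n_starts)
  per_start <- vector("list", config$n_starts)
  n_evals <- 0L
  for (i in seq_len(config$n_starts)) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = starts[i, ], lower = lo, upper = hi,
                           fn = resid_fn, jac = jac_fn,
                           control = ctrl_explore)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      per_start[[i]] <- list(start = starts[i, ], cost = Inf, par = NULL,
                             converged = FALSE,
                             message = conditionMessage(fit))
      next
    }
    n_evals <- n_evals + fit$niter
    per_start[[i]] <- list(start = starts[i, ], cost = fit$deviance,
                           par = fit$par, converged = TRUE,
                           message = fit$message)
  }
  explore_costs <- vapply(per_start, `[[`, numeric(1), "cost")
  polish_idx <- order(explore_costs)[seq_len(n_polish)]
  for (i in polish_idx) {
    if (!is.finite(per_start[[i]]$cost)) next
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = per_start[[i]]$par, lower = lo, upper = hi,
                           fn = resid_fn, jac = jac_fn,
                           control = ctrl_polish)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      per_start[[i]]$converged <- FALSE
      per_start[[i]]$message <- conditionMessage(fit)
      next
    }
    n_evals <- n_evals + fit$niter
    per_start[[i]]$cost <- fit$deviance
    per_start[[i]]$par <- fit$par
    per_start[[i]]$converged <- fit$info %in% 1:4
    per_start[[i]]$message <- fit$message
  }
  # every start that finished (converged or iteration-capped) is a
  # candidate; only hard optimiser errors are excluded
  finals <- vapply(per_start, function(s) {
    if (!is.null(s$par)) s$cost else Inf
  }, numeric(1))
  best_i <- which.min(finals)  # ties: lowest start index
  best_cost <- finals[best_i]
  best_par <- if (is.finite(best_cost)) per_start[[best_i]]$par else NULL
  if (is.null(best_par)) {
    err <- structure(class = c("fit_failure", "error", "condition"),
                     list(message = "all multistart fits failed",
                          call = sys.call(), per_start = per_start))
    stop(err)
  }
  params <- assemble_params(best_par, names, config, r_el_fixed)
  flags <- character(0)
  # no-barrier detection. On blank devices the barrier element is
  # unidentifiable and the fit parks it in one of three degenerate shapes:
  # r_barrier pinned at (within 2x of) its lower bound; a sub-2% sliver of
  # the DC resistance absorbing the series-resistance fixing offset; or a
  # large-C shunt whose corner frequency 1/(2 pi R_b C_b) falls below the
  # measured band, so the element never expresses a resistive plateau.
  # Genuine barriers sit at tens of percent of the DC resistance with their
  # corner well inside the sweep.
  if (config$model == "full") {
    corner_hz <- 1 / (2 * pi * params$r_barrier * params$c_barrier)
    if (params$r_barrier <= 2 * config$bounds$r_barrier[1] ||
        params$r_barrier < 0.02 * (params$r_ce + params$r_electrolyte +
                                     params$r_barrier) ||
        corner_hz < min(spectrum$frequencies)) {
      flags <- c(flags, "no_barrier")
    }
  }
  structure(list(params = params, cost = best_cost, per_start = per_start,
                 n_function_evals = n_evals,
                 r_electrolyte_fixed = r_el_fixed,
                 config = config, flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  n_conv <- sum(vapply(x$per_start, `[[`, logical(1), "converged"))
  cat(sprintf("CNLS fit: cost = %.3e (%d/%d starts converged)%s\n",
              x$cost, n_conv, length(x$per_start),
              if (length(x$flags)) paste0(" [", paste(x$flags,
                                                      collapse = ", "), "]")
              else ""))
  print(x$params)
  invisible(x)
}

#' Extract the barrier resistance from a fit
#'
#' `R_b` - the resistance of the paracellular pathway - is the figure of
#' merit for barrier integrity. When the fitted barrier element is
#' degenerate (see [fit_spectrum()]) the value carries the `"no_barrier"`
#' flag, the expected outcome for blank devices where the barrier element is
#' unidentifiable.
#'
#' @param result A `fit_result` from [fit_spectrum()].
#' @return `r_barrier` in Ohm, with the fit's flags (if any) attached as the
#'   `"flags"` attribute.
#' @export
extract_rb <- function(result) {
  stopifnot(inherits(result, "fit_result"))
  rb <- result$params$r_barrier
  if (length(result$flags)) attr(rb, "flags") <- result$flags
  rb
}

#' Fit every timepoint of a time-course
#'
#' @param tc A `time_course`.
#' @param config A [fit_config()].
#' @return The time-course with a `fits` list (one `fit_result` per
#'   timepoint, or a `fit_failure` condition where a spectrum could not be
#'   fitted) cached on it.
#' @export
fit_timecourse <- function(tc, config = fit_config()) {
  stopifnot(inherits(tc, "time_course"))
  tc$fits <- lapply(tc$spectra, function(sp) {
    tryCatch(fit_spectrum(sp, config), fit_failure = function(e) e)
  })
  names(tc$fits) <- names(tc$spectra)
  tc
}

#' Fit a whole dataset into a results table
#'
#' Fits every (device, timepoint) spectrum and returns one tidy row per fit.
#' Per-spectrum failures are recorded (`converged = FALSE`, `NA` parameters)
#' and the run continues.
#'
#' @param timecourses A list of `time_course` objects (e.g. from
#'   [simulate_cohort()]'s `$timecourses` or [load_timecourses()]).
#' @param config A [fit_config()].
#' @return A data.frame with columns `device_id`, `intervention`,
#'   `timepoint_h`, the six circuit parameters, `cost`, `converged`, and
#'   `flags`.
#' @export
fit_dataset <- function(timecourses, config = fit_config()) {
  rows <- list()
  for (tc in timecourses) {
    tc <- fit_timecourse(tc, config)
    for (j in seq_along(tc$timepoints)) {
      fit <- tc$fits[[j]]
      ok <- inherits(fit, "fit_result")
      p <- if (ok) fit$params else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        device_id = tc$device_id, intervention = tc$intervention,
        timepoint_h = tc$timepoints[j],
        r_ce = if (ok) p$r_ce else NA_real_,
        q_ce = if (ok) p$q_ce else NA_real_,
        alpha_ce = if (ok) p$alpha_ce else NA_real_,
        r_electrolyte = if (ok) p$r_electrolyte else NA_real_,
        r_barrier = if (ok) p$r_barrier else NA_real_,
        c_barrier = if (ok) p$c_barrier else NA_real_,
        cost = if (ok) fit$cost else NA_real_,
        converged = ok,
        flags = if (ok) paste(fit$flags, collapse = ";") else "fit_failed",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
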