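#' Write a spectrum to CSV
#'
#' Canonical dialect: columns `frequency_hz, z_real_ohm, z_imag_ohm`, one row
#' per frequency in sweep (descending) order, preceded by `#`-comment header
#' lines carrying the spectrum metadata. Numbers are written with 17
#' significant digits so a write/read round-trip reproduces the in-memory
#' doubles exactly.
#'
#' @param spectrum An [impedance_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  header <- character(0)
  if (length(spectrum$meta)) {
    header <- sprintf("# %s: %s", names(spectrum$meta),
                      vapply(spectrum$meta, function(v) format(v, digits = 17),
                             character(1)))
  }
  lines <- c(header,
             "frequency_hz,z_real_ohm,z_imag_ohm",
             sprintf("%.17g,%.17g,%.17g", spectrum$frequencies,
                     Re(spectrum$z), Im(spectrum$z)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spectrum from CSV
#'
#' Supports the canonical rectangular dialect
#' (`frequency_hz, z_real_ohm, z_imag_ohm`) and the polar dialect
#' (`frequency_hz, z_mod_ohm, z_phase_deg`, converted via
#' `Z = |Z| (cos phi + j sin phi)`). `#`-comment lines of the form
#' `# key: value` are parsed into spectrum metadata. Rows are re-sorted to
#' descending frequency; malformed rows are reported by data-row number.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (detect from the header), `"canonical"` or
#'   `"polar"`.
#' @return An [impedance_spectrum()].
#' @export
read_spectrum <- function(path, dialect = c("auto", "canonical", "polar")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  meta <- parse_meta_comments(lines[is_comment])
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) < 2) stop("no data rows in ", path, call. = FALSE)
  df <- utils::read.csv(text = body, colClasses = "character",
                        check.names = FALSE)
  canonical_cols <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
  polar_cols <- c("frequency_hz", "z_mod_ohm", "z_phase_deg")
  if (dialect == "auto") {
    dialect <- if (all(canonical_cols %in% names(df))) "canonical"
    else if (all(polar_cols %in% names(df))) "polar"
    else stop("unrecognised spectrum columns in ", path, ": ",
              paste(names(df), collapse = ", "), call. = FALSE)
  }
  cols <- if (dialect == "canonical") canonical_cols else polar_cols
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- lapply(df[cols], function(x) suppressWarnings(as.numeric(x)))
  for (cl in cols) {
    bad <- which(is.na(num[[cl]]) & !(trimws(df[[cl]]) %in% c("NA", "")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column %s, data row %d of %s",
                   df[[cl]][bad[1]], cl, bad[1], path), call. = FALSE)
    }
    bad <- which(is.na(num[[cl]]))
    if (length(bad)) {
      stop(sprintf("missing value in column %s, data row %d of %s",
                   cl, bad[1], path), call. = FALSE)
    }
  }
  f <- num$frequency_hz
  nonpos <- which(f <= 0)
  if (length(nonpos)) {
    stop(sprintf("non-positive frequency at data row %d of %s",
                 nonpos[1], path), call. = FALSE)
  }
  dup <- which(duplicated(f))
  if (length(dup)) {
    stop(sprintf("duplicate frequency %g at data row %d of %s",
                 f[dup[1]], dup[1], path), call. = FALSE)
  }
  z <- if (dialect == "canonical") {
    complex(real = num$z_real_ohm, imaginary = num$z_imag_ohm)
  } else {
    phi <- num$z_phase_deg * pi / 180
    complex(modulus = num$z_mod_ohm, argument = phi)
  }
  impedance_spectrum(f, z, meta = meta)
}

parse_meta_comments <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2])
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

spectrum_filename <- function(device_id, timepoint) {
  sprintf("%s_t%s.csv", device_id, gsub("[.]", "p", as.character(timepoint)))
}

#' Write a synthetic dataset to disk
#'
#' Writes one canonical CSV per (device, timepoint) plus a JSON manifest
#' (`manifest.json`) recording device records, relative file paths, the
#' sweep, the noise level and the master seed. Re-running the generator with
#' the same configuration and seed reproduces the files byte-identically.
#'
#' @param dataset A `synthetic_dataset` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  devices <- vector("list", length(dataset$timecourses))
  for (i in seq_along(dataset$timecourses)) {
    tc <- dataset$timecourses[[i]]
    files <- character(length(tc$timepoints))
    for (j in seq_along(tc$timepoints)) {
      files[j] <- spectrum_filename(tc$device_id, tc$timepoints[j])
      write_spectrum(tc$spectra[[j]], file.path(dir, files[j]))
    }
    devices[[i]] <- list(device_id = tc$device_id,
                         intervention = tc$intervention,
                         biological = tc$biological,
                         technical = tc$technical,
                         seed = tc$seed,
                         timepoints_h = tc$timepoints,
                         files = files)
  }
  manifest <- list(
    generator = "barrierEIS",
    version = as.character(utils::packageVersion("barrierEIS")),
    master_seed = dataset$seed,
    noise_sigma = dataset$noise$sigma,
    sweep = list(f_min = dataset$sweep$f_min, f_max = dataset$sweep$f_max,
                 points_per_decade = dataset$sweep$points_per_decade),
    devices = devices)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate a dataset manifest
#'
#' Parses `manifest.json` and validates its invariants: every referenced
#' spectrum file exists, (device, timepoint) pairs are unique, and every
#' device has exactly one t = 0 baseline entry. Violations are reported with
#' the offending path or device.
#'
#' @param path Path to a manifest JSON file.
#' @return An object of class `dataset_manifest` (the parsed manifest with a
#'   `dir` field pointing at the dataset directory).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  man$dir <- dirname(path)
  if (is.null(man$devices) || !length(man$devices)) {
    stop("manifest lists no devices: ", path, call. = FALSE)
  }
  seen <- character(0)
  for (dev in man$devices) {
    tp <- as.numeric(dev$timepoints_h)
    files <- as.character(dev$files)
    if (length(tp) != length(files)) {
      stop("manifest timepoints/files length mismatch for device ",
           dev$device_id, call. = FALSE)
    }
    keys <- paste(dev$device_id, tp)
    dup <- keys[keys %in% seen]
    if (length(dup)) {
      stop("duplicate (device, timepoint) in manifest: ", dup[1],
           call. = FALSE)
    }
    seen <- c(seen, keys)
    if (!0 %in% tp) {
      stop("device ", dev$device_id, " has no t = 0 baseline entry",
           call. = FALSE)
    }
    missing <- files[!file.exists(file.path(man$dir, files))]
    if (length(missing)) {
      stop("manifest references missing file: ",
           file.path(man$dir, missing[1]), call. = FALSE)
    }
  }
  structure(man, class = "dataset_manifest")
}

#' Load the time-courses referenced by a manifest
#'
#' @param manifest A `dataset_manifest` from [read_manifest()].
#' @return Named list of `time_course` objects (without generating truth -
#'   the manifest records measurement provenance only).
#' @export
load_timecourses <- function(manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  out <- vector("list", length(manifest$devices))
  for (i in seq_along(manifest$devices)) {
    dev <- manifest$devices[[i]]
    tp <- as.numeric(dev$timepoints_h)
    ord <- order(tp)
    spectra <- lapply(as.character(dev$files)[ord], function(fn) {
      read_spectrum(file.path(manifest$dir, fn))
    })
    names(spectra) <- as.character(tp[ord])
    out[[i]] <- structure(list(device_id = dev$device_id,
                               intervention = dev$intervention,
                               biological = dev$biological,
                               technical = dev$technical,
                               timepoints = tp[ord], spectra = spectra,
                               truth = NULL, seed = dev$seed, fits = NULL),
                          class = "time_course")
  }
  names(out) <- vapply(manifest$devices, function(d) d$device_id,
                       character(1))
  out
}
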