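#' Group table for between-arm comparisons
#'
#' @param values Numeric vector of endpoint values (e.g. 24 h `R_b`
#'   fold-change per device), or a named list of numeric vectors (one per
#'   group, `groups` then ignored).
#' @param groups Group labels matching `values`.
#' @return A named list of numeric vectors, classed `group_table`.
#' @export
group_table <- function(values, groups = NULL) {
  tab <- if (is.list(values)) {
    lapply(values, as.numeric)
  } else {
    if (is.null(groups) || length(groups) != length(values)) {
      stop("groups must match values in length", call. = FALSE)
    }
    split(as.numeric(values), groups)
  }
  if (length(tab) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(tab, function(v) any(!is.finite(v)), logical(1)))) {
    stop("non-finite values in group table", call. = FALSE)
  }
  structure(tab, class = "group_table")
}

as_long_df <- function(table) {
  data.frame(value = unlist(table, use.names = FALSE),
             group = factor(rep(names(table), lengths(table)),
                            levels = names(table)))
}

check_group_sizes <- function(table) {
  small <- names(table)[lengths(table) < 2]
  if (length(small)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
}

#' Levene's homogeneity-of-variance test
#'
#' Classic (mean-centred) Levene test: a one-way ANOVA on the absolute
#' deviations of each observation from its group centre. The protocol
#' applies it as a gate at p > 0.01 before the between-group ANOVA; the gate
#' outcome is reported, not acted on automatically. `center = "median"`
#' gives the Brown-Forsythe variant.
#'
#' @param table A [group_table()].
#' @param center `"mean"` (default) or `"median"`.
#' @return List with `statistic`, `df`, `p`, and a `flag`
#'   (`"not_applicable"` when all within-group deviations are zero).
#' @export
levene_test <- function(table, center = c("mean", "median")) {
  stopifnot(inherits(table, "group_table"))
  center <- match.arg(center)
  check_group_sizes(table)
  df <- as_long_df(table)
  centre_fn <- if (center == "mean") mean else stats::median
  dev <- abs(df$value - stats::ave(df$value, df$group, FUN = centre_fn))
  if (all(dev == 0)) {
    return(list(statistic = NA_real_, df = c(length(table) - 1L,
                                             nrow(df) - length(table)),
                p = NA_real_, center = center, flag = "not_applicable"))
  }
  lt <- car::leveneTest(df$value, df$group, center = centre_fn)
  list(statistic = lt[1, "F value"], df = c(lt[1, "Df"], lt[2, "Df"]),
       p = lt[1, "Pr(>F)"], center = center, flag = "")
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition via [stats::aov()].
#'
#' @param table A [group_table()].
#' @return List with `f`, `df_between` (k - 1), `df_within` (N - k), `p`,
#'   and a `flag` (`"zero_within_variance"` when SSW = 0).
#' @export
oneway_anova <- function(table) {
  stopifnot(inherits(table, "group_table"))
  check_group_sizes(table)
  df <- as_long_df(table)
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  ssw <- tab["Residuals", "Sum Sq"]
  ssb <- tab["group", "Sum Sq"]
  flag <- if (ssw <= .Machine$double.eps * max(ssb, 1)) {
    "zero_within_variance"
  } else ""
  list(f = tab["group", "F value"],
       df_between = as.integer(tab["group", "Df"]),
       df_within = as.integer(tab["Residuals", "Df"]),
       p = tab["group", "Pr(>F)"],
       flag = flag, aov = fit)
}

#' Significance stars at the reporting thresholds
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes (`""` when not significant).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise mean differences with studentized-range adjusted p-values
#' via [stats::TukeyHSD()] (Tukey-Kramer denominator for unbalanced groups),
#' coded with significance stars at the four reporting thresholds.
#'
#' @param table A [group_table()].
#' @param alpha Family-wise significance level used for the `significant`
#'   column (default 0.05).
#' @return A data.frame with one row per pair: `pair`, `diff` (difference of
#'   means), `p_adj`, `significant`, `stars`.
#' @export
tukey_hsd <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "group_table"))
  aovres <- oneway_anova(table)
  tk <- stats::TukeyHSD(aovres$aov, conf.level = 1 - alpha)$group
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    p_adj = tk[, "p adj"],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (aovres$flag == "zero_within_variance") out$p_adj <- NaN
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$stars <- significance_stars(out$p_adj)
  out
}

#' Full between-group comparison report
#'
#' The inference chain applied to an endpoint metric (typically the 24 h
#' `R_b` fold-change per device): Levene's homogeneity check (gate at
#' p > 0.01, reported), one-way ANOVA, and Tukey HSD post-hoc comparisons.
#'
#' @param table A [group_table()].
#' @param alpha Significance level for the Tukey `significant` flag.
#' @param levene_gate_p Gate threshold reported for the Levene check.
#' @return An object of class `comparison_report`.
#' @export
comparison_report <- function(table, alpha = 0.05, levene_gate_p = 0.01) {
  stopifnot(inherits(table, "group_table"))
  lev <- levene_test(table)
  aovres <- oneway_anova(table)
  tk <- tukey_hsd(table, alpha = alpha)
  structure(list(
    groups = data.frame(group = names(table), n = lengths(table),
                        mean = vapply(table, mean, numeric(1)),
                        sd = vapply(table, stats::sd, numeric(1)),
                        stringsAsFactors = FALSE, row.names = NULL),
    levene = lev,
    levene_gate = list(threshold = levene_gate_p,
                       passed = !is.na(lev$p) && lev$p > levene_gate_p),
    anova = aovres[c("f", "df_between", "df_within", "p", "flag")],
    tukey = tk, alpha = alpha), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Between-group comparison\n")
  cat("========================\n")
  print(x$groups, digits = 4)
  if (identical(x$levene$flag, "not_applicable")) {
    cat("\nLevene: not applicable (zero within-group deviations)\n")
  } else {
    cat(sprintf("\nLevene (center = %s): F(%d, %d) = %.4g, p = %.4g (gate p > %g: %s)\n",
                x$levene$center, x$levene$df[1], x$levene$df[2],
                x$levene$statistic, x$levene$p, x$levene_gate$threshold,
                if (x$levene_gate$passed) "passed" else "failed"))
  }
  cat(sprintf("ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$anova$df_between, x$anova$df_within, x$anova$f, x$anova$p,
              if (nzchar(x$anova$flag)) paste0(" [", x$anova$flag, "]")
              else ""))
  cat(sprintf("\nTukey HSD (alpha = %g):\n", x$alpha))
  print(x$tukey, digits = 4)
  invisible(x)
}

#' Serialise a comparison report to JSON
#'
#' @param report A `comparison_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  obj <- unclass(report)
  if (!is.null(path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(path))
  }
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   na = "null")
}
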