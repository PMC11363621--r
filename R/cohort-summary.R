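#' Summarize a cohort of bilateral length measurements
#'
#' Applies the full cohort analysis to per-patient, per-observer signed
#' right-minus-left differences: observer adjudication (> 1 mm rule),
#' sample means and SDs (n-1 denominator) of the signed, absolute and
#' relative differences, min/max absolute difference, per-factor subgroup
#' t-tests (age group 18-49 vs 50+, sex, malunion side; absolute and
#' relative), a Kolmogorov-Smirnov normality check of the absolute
#' differences, and the two-observer ICC(2,1).
#'
#' @param records A cohort tibble with columns `obs1_mm`, `obs2_mm`
#'   (signed mm), optionally `obs3_mm` (adjudicated), `age` or
#'   `age_group`, `sex`, `malunion_side`, `length_mm` (longer ulna, mm;
#'   needed for relative differences). [simulate_cohort()] and
#'   [read_cohort_csv()] both produce this shape.
#' @param adjudication_threshold Observer-discrepancy threshold (mm),
#'   default 1.
#' @param var_equal Use Student's pooled t-test instead of Welch,
#'   default FALSE.
#' @param lilliefors Lilliefors-corrected normality test, default TRUE.
#' @param subgroup_tests,icc,normality Toggles for the corresponding
#'   analysis blocks (all TRUE by default); switching them off is useful
#'   in large simulation loops.
#' @param flagged_value Passed to [adjudicate()].
#' @return A `cohort_summary` object; see [tidy.cohort_summary()] /
#'   [glance.cohort_summary()] and the print method, which renders the
#'   per-factor table (variables x mean (SD) x p-value).
#' @export
summarize_cohort <- function(records, adjudication_threshold = 1,
                             var_equal = FALSE, lilliefors = TRUE,
                             subgroup_tests = TRUE, icc = TRUE,
                             normality = TRUE,
                             flagged_value = c("adjudicated", "mean")) {
  records <- tibble::as_tibble(records)
  if (nrow(records) < 2) {
    stop("insufficient data: cohort summary needs n >= 2", call. = FALSE)
  }
  need <- c("obs1_mm", "obs2_mm")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"age_group" %in% names(records) && "age" %in% names(records)) {
    records$age_group <- ifelse(records$age < 50, "18-49", "50+")
  }

  records <- adjudicate(records, threshold = adjudication_threshold,
                        flagged_value = flagged_value)
  signed <- records$final_mm
  abs_d <- abs(signed)
  records$abs_diff_mm <- abs_d
  rel <- if ("length_mm" %in% names(records) &&
             all(is.finite(records$length_mm))) {
    100 * abs_d / records$length_mm
  } else {
    rep(NA_real_, nrow(records))
  }
  records$relative_diff_pct <- rel

  subgroups <- NULL
  if (subgroup_tests) {
    factors <- intersect(c("age_group", "sex", "malunion_side"),
                         names(records))
    measures <- list(absolute = abs_d)
    if (all(is.finite(rel))) measures$relative <- rel
    rows <- list()
    for (fac in factors) {
      g <- records[[fac]]
      if (length(unique(g)) != 2 || min(table(g)) < 2) next
      for (mn in names(measures)) {
        tt <- subgroup_t_test(measures[[mn]], g, var_equal = var_equal)
        rows[[length(rows) + 1]] <-
          dplyr::bind_cols(tibble::tibble(factor = fac, measure = mn), tt)
      }
    }
    subgroups <- if (length(rows)) dplyr::bind_rows(rows) else NULL
  }

  ks <- if (normality) ks_normality(abs_d, lilliefors = lilliefors) else NULL
  icc_res <- if (icc) icc_two_observers(cbind(records$obs1_mm,
                                              records$obs2_mm)) else NULL

  structure(list(
    n = nrow(records),
    mean_abs = mean(abs_d), sd_abs = stats::sd(abs_d),
    mean_signed = mean(signed), sd_signed = stats::sd(signed),
    mean_rel = if (all(is.finite(rel))) mean(rel) else NA_real_,
    sd_rel = if (all(is.finite(rel))) stats::sd(rel) else NA_real_,
    min_abs = min(abs_d), max_abs = max(abs_d),
    n_adjudicated = sum(records$flagged),
    icc = icc_res, ks = ks, subgroups = subgroups,
    records = records
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 2, ...) {
  cat(format_cohort_table(x, digits = digits), sep = "\n")
  invisible(x)
}

#' Render a cohort summary as a per-factor text table
#'
#' Produces the classic cohort table: one block per factor (overall N,
#' age group, sex, malunion side) with group sizes, mean (SD) absolute
#' and relative differences, and the subgroup p-values.
#'
#' @param x A `cohort_summary`.
#' @param digits Digits for means/SDs, default 2.
#' @return Character vector of table lines.
#' @export
format_cohort_table <- function(x, digits = 2) {
  fm <- function(m, s) {
    if (!is.finite(m)) return("-")
    sprintf("%.*f (%.*f)", digits, m, digits, s)
  }
  fp <- function(p) if (is.null(p) || !is.finite(p)) "-" else
    sprintf("%.2f", p)
  pval <- function(fac, meas) {
    if (is.null(x$subgroups)) return(NA_real_)
    r <- x$subgroups[x$subgroups$factor == fac & x$subgroups$measure == meas, ]
    if (nrow(r) == 0) NA_real_ else r$p[1]
  }
  lines <- c(
    sprintf("%-28s %-10s %-18s %-8s %-18s %-8s", "Variable", "N (%)",
            "Absolute diff (mm)", "p", "Relative diff (%)", "p"),
    strrep("-", 94),
    sprintf("%-28s %-10s %-18s %-8s %-18s %-8s", "N",
            sprintf("%d (100%%)", x$n), fm(x$mean_abs, x$sd_abs), "",
            fm(x$mean_rel, x$sd_rel), "")
  )
  rec <- x$records
  for (fac in c("age_group", "sex", "malunion_side")) {
    if (is.null(x$subgroups) || !fac %in% x$subgroups$factor) next
    title <- c(age_group = "Age", sex = "Sex",
               malunion_side = "Malunion side")[[fac]]
    lines <- c(lines, sprintf("%-28s %-10s %-18s %-8s %-18s %-8s", title, "",
                              "", fp(pval(fac, "absolute")), "",
                              fp(pval(fac, "relative"))))
    for (lev in sort(unique(rec[[fac]]))) {
      i <- rec[[fac]] == lev
      lines <- c(lines, sprintf(
        "%-28s %-10s %-18s %-8s %-18s %-8s", paste0("  ", lev),
        sprintf("%d (%.0f%%)", sum(i), 100 * mean(i)),
        fm(mean(rec$abs_diff_mm[i]), stats::sd(rec$abs_diff_mm[i])), "",
        fm(mean(rec$relative_diff_pct[i]),
           stats::sd(rec$relative_diff_pct[i])), ""))
    }
  }
  extra <- c(
    sprintf("Signed (right-left): %.2f (%.2f) mm; min |d| %.2f, max |d| %.2f",
            x$mean_signed, x$sd_signed, x$min_abs, x$max_abs),
    sprintf("Adjudicated cases (> threshold): %d", x$n_adjudicated))
  if (!is.null(x$icc)) {
    extra <- c(extra, sprintf("ICC(2,1): %.3f (95%% CI %.3f-%.3f)",
                              x$icc$icc, x$icc$ci_low, x$icc$ci_high))
  }
  if (!is.null(x$ks)) {
    extra <- c(extra, sprintf("Normality (%s): D = %.3f, p = %.3f",
                              x$ks$method, x$ks$statistic, x$ks$p))
  }
  c(lines, strrep("-", 94), extra)
}

#' Tidy and glance methods for cohort summaries
#'
#' `tidy()` returns the per-factor subgroup test table; `glance()` a
#' one-row tibble of the whole-cohort quantities.
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cohort_summary <- function(x, ...) {
  if (is.null(x$subgroups)) return(tibble::tibble())
  x$subgroups
}

#' @rdname tidy.cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    mean_abs = x$mean_abs, sd_abs = x$sd_abs,
    mean_signed = x$mean_signed, sd_signed = x$sd_signed,
    mean_rel = x$mean_rel, sd_rel = x$sd_rel,
    min_abs = x$min_abs, max_abs = x$max_abs,
    n_adjudicated = x$n_adjudicated,
    icc = if (!is.null(x$icc)) x$icc$icc else NA_real_,
    icc_ci_low = if (!is.null(x$icc)) x$icc$ci_low else NA_real_,
    icc_ci_high = if (!is.null(x$icc)) x$icc$ci_high else NA_real_,
    ks_statistic = if (!is.null(x$ks)) x$ks$statistic else NA_real_,
    ks_p = if (!is.null(x$ks)) x$ks$p else NA_real_
  )
}

#' Violin plot of absolute bilateral differences
#'
#' The cohort's absolute length differences as a violin with per-patient
#' points and the cohort mean, mirroring the standard presentation of this
#' measurement.
#'
#' @param object A `cohort_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  df <- tibble::tibble(abs_diff = object$records$abs_diff_mm, x = "cohort")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$abs_diff)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.06, alpha = 0.6, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3,
                          colour = "red") +
    ggplot2::labs(x = NULL, y = "absolute ulnar length difference (mm)",
                  title = sprintf("n = %d, mean %.2f mm (SD %.2f)",
                                  object$n, object$mean_abs, object$sd_abs)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
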