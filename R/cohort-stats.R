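#' Mean and standard deviation of a group of values
#'
#' @param values Numeric vector, length at least 2.
#' @param label Group label recorded in the summary.
#' @return One-row tibble with `label`, `n`, `mean`, `sd` (sample sd,
#'   n - 1 denominator).
#' @export
summarize_group <- function(values, label = "group") {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop_input("need at least two non-missing values to summarize a group")
  }
  tibble(label = as.character(label), n = length(values),
         mean = mean(values), sd = sd(values))
}

new_sig_ttest <- function(ht, test_kind) {
  structure(
    list(
      statistic = unname(ht$statistic),
      degrees_of_freedom = unname(ht$parameter),
      p_value = unname(ht$p.value),
      test_kind = test_kind,
      significant_at_0_01 = unname(ht$p.value) < 0.01,
      htest = ht
    ),
    class = "sig_ttest"
  )
}

#' @export
print.sig_ttest <- function(x, ...) {
  cat(sprintf(
    "<sig_ttest> %s: t = %.4f, df = %.2f, p = %.4g (%ssignificant at the 0.01 level)\n",
    x$test_kind, x$statistic, x$degrees_of_freedom, x$p_value,
    if (x$significant_at_0_01) "" else "not "
  ))
  invisible(x)
}

#' @rdname paired_t
#' @param x A `sig_ttest` object.
#' @param ... Unused.
#' @export
tidy.sig_ttest <- function(x, ...) {
  tibble(
    test_kind = x$test_kind,
    statistic = x$statistic,
    degrees_of_freedom = x$degrees_of_freedom,
    p_value = x$p_value,
    significant_at_0_01 = x$significant_at_0_01
  )
}

#' Paired t test: tumor vs contralateral decisive SIGs
#'
#' Within-subject comparison of the decisive SIG on the tumor side with
#' the matched value from the subject's own contralateral hemisphere.
#' Classical paired t on the differences, df = n - 1, two-sided p-value.
#' Significance is reported at the 0.01 level (99% confidence).
#'
#' @param tumor_values,contralateral_values Equal-length numeric vectors
#'   (one entry per subject), n >= 2.
#' @return A `sig_ttest` object; see [tidy.sig_ttest()].
#' @export
paired_t <- function(tumor_values, contralateral_values) {
  x <- as.numeric(tumor_values)
  y <- as.numeric(contralateral_values)
  if (length(x) != length(y)) stop_input("paired vectors must have equal length")
  if (length(x) < 2L || anyNA(x) || anyNA(y)) {
    stop_input("need at least two complete pairs")
  }
  d <- x - y
  if (sd(d) < .Machine$double.eps^0.5 * max(1, mean(abs(d)))) {
    stop_degenerate("differences have zero variance; the paired t statistic is undefined")
  }
  new_sig_ttest(stats::t.test(x, y, paired = TRUE), "paired")
}

#' Two-sample t test between subject groups
#'
#' Between-group comparison (e.g. RSIG in glioma vs meningioma subjects).
#' The default is Welch's unequal-variance t with Welch-Satterthwaite
#' degrees of freedom, appropriate for groups of different size and
#' spread; set `var_equal = TRUE` for the pooled-variance Student
#' variant. Two-sided p-value, significance reported at the 0.01 level.
#'
#' @param group_a,group_b Numeric vectors, each n >= 2.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return A `sig_ttest` object; see [tidy.sig_ttest()].
#' @export
two_sample_t <- function(group_a, group_b, var_equal = FALSE) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L || anyNA(a) || anyNA(b)) {
    stop_input("each group needs at least two non-missing values")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    stop_degenerate("both groups have zero variance; the t statistic is undefined")
  }
  new_sig_ttest(
    stats::t.test(a, b, var.equal = var_equal),
    if (var_equal) "two_sample_pooled" else "two_sample_welch"
  )
}

#' Cohort summary table
#'
#' Per-group mean +/- sd of the decisive SIG on each side and of RSIG —
#' the shape of a cohort results table.
#'
#' @param cohort Data frame with one row per subject: columns `subject_id`,
#'   `group`, `decisive_sig_tumor`, `decisive_sig_contralateral`, `rsig`.
#' @return A tibble with one row per group.
#' @export
cohort_table <- function(cohort) {
  cohort <- validate_cohort(cohort)
  dplyr::summarise(
    dplyr::group_by(cohort, .data$group),
    n = dplyr::n(),
    decisive_sig_tumor_mean = mean(.data$decisive_sig_tumor),
    decisive_sig_tumor_sd = sd(.data$decisive_sig_tumor),
    decisive_sig_contralateral_mean = mean(.data$decisive_sig_contralateral),
    decisive_sig_contralateral_sd = sd(.data$decisive_sig_contralateral),
    rsig_mean = mean(.data$rsig),
    rsig_sd = sd(.data$rsig),
    .groups = "drop"
  )
}

validate_cohort <- function(cohort) {
  needed <- c("subject_id", "group", "decisive_sig_tumor",
              "decisive_sig_contralateral", "rsig")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0L) {
    stop_input("cohort is missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (nrow(cohort) == 0L) stop_input("cohort has no rows")
  as_tibble(cohort)
}

#' Full cohort statistical report
#'
#' Assembles the group summary table, a within-group paired t test of
#' tumor vs contralateral decisive SIG for every group with at least two
#' subjects, and — when exactly two groups are present — the between-group
#' comparison of RSIG (Welch by default, with the pooled-variance Student
#' variant reported alongside).
#'
#' @inheritParams cohort_table
#' @return An object of class `cohort_report` with fields `table`
#'   (tibble), `paired` (named list of `sig_ttest`), `between`
#'   (`sig_ttest` or `NULL`), `between_pooled` (`sig_ttest` or `NULL`).
#' @export
cohort_report <- function(cohort) {
  cohort <- validate_cohort(cohort)
  groups <- split(cohort, cohort$group)
  paired <- purrr::map(groups, function(g) {
    if (nrow(g) < 2L) return(NULL)
    paired_t(g$decisive_sig_tumor, g$decisive_sig_contralateral)
  })
  paired <- paired[!vapply(paired, is.null, logical(1))]
  between <- between_pooled <- NULL
  if (length(groups) == 2L && all(vapply(groups, nrow, integer(1)) >= 2L)) {
    between <- two_sample_t(groups[[1]]$rsig, groups[[2]]$rsig)
    between_pooled <- two_sample_t(groups[[1]]$rsig, groups[[2]]$rsig,
                                   var_equal = TRUE)
  } else if (length(groups) != 2L) {
    warn(sprintf("between-group test needs exactly 2 groups; cohort has %d",
                 length(groups)))
  }
  structure(
    list(table = cohort_table(cohort), paired = paired,
         between = between, between_pooled = between_pooled,
         group_names = names(groups)),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort summary (mean +/- sd)\n")
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf(
      "  %-16s n=%2d  decisive SIG tumor %7.2f +/- %6.2f  contralateral %6.2f +/- %5.2f  RSIG %6.2f +/- %5.2f\n",
      r$group, r$n, r$decisive_sig_tumor_mean, r$decisive_sig_tumor_sd,
      r$decisive_sig_contralateral_mean, r$decisive_sig_contralateral_sd,
      r$rsig_mean, r$rsig_sd
    ))
  }
  if (length(x$paired) > 0L) {
    cat("Within-subject: tumor vs contralateral decisive SIG (paired t)\n")
    for (g in names(x$paired)) {
      p <- x$paired[[g]]
      cat(sprintf("  %-16s t = %.3f, df = %g, p = %.3g\n",
                  g, p$statistic, p$degrees_of_freedom, p$p_value))
    }
  }
  if (!is.null(x$between)) {
    cat(sprintf("Between groups (%s vs %s), RSIG:\n",
                x$group_names[1], x$group_names[2]))
    cat(sprintf("  Welch:  t = %.3f, df = %.2f, p = %.3g (%ssignificant at 0.01)\n",
                x$between$statistic, x$between$degrees_of_freedom,
                x$between$p_value,
                if (x$between$significant_at_0_01) "" else "not "))
    cat(sprintf("  Pooled: t = %.3f, df = %g, p = %.3g\n",
                x$between_pooled$statistic, x$between_pooled$degrees_of_freedom,
                x$between_pooled$p_value))
  }
  invisible(x)
}

#' @rdname cohort_report
#' @param x A `cohort_report` object.
#' @param ... Unused.
#' @export
tidy.cohort_report <- function(x, ...) x$table

#' @rdname cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  tibble(
    n_groups = nrow(x$table),
    n_subjects = sum(x$table$n),
    between_t = if (is.null(x$between)) NA_real_ else x$between$statistic,
    between_df = if (is.null(x$between)) NA_real_ else x$between$degrees_of_freedom,
    between_p = if (is.null(x$between)) NA_real_ else x$between$p_value,
    significant_at_0_01 = if (is.null(x$between)) NA else x$between$significant_at_0_01
  )
}
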