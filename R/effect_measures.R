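#' A 2x2 success/failure table
#'
#' The substrate of all effect measures: success and failure counts for
#' two groups. Tables with an empty arm are constructed but flagged
#' degenerate; estimation functions refuse them.
#'
#' @param success_a,failure_a,success_b,failure_b Non-negative counts.
#' @param label_a,label_b Group labels.
#' @return An object of class `two_by_two`.
#' @examples
#' two_by_two(673, 14, 46, 50, "EBPA", "controls")
#' @export
two_by_two <- function(success_a, failure_a, success_b, failure_b,
                       label_a = "A", label_b = "B") {
  counts <- c(success_a, failure_a, success_b, failure_b)
  if (any(is.na(counts) | counts < 0 | counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(
    success_a = success_a, failure_a = failure_a,
    success_b = success_b, failure_b = failure_b,
    n_a = success_a + failure_a, n_b = success_b + failure_b,
    label_a = label_a, label_b = label_b,
    degenerate = (success_a + failure_a == 0) || (success_b + failure_b == 0)
  ), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$success_a, x$failure_a, x$success_b, x$failure_b),
              nrow = 2, byrow = TRUE,
              dimnames = list(c(x$label_a, x$label_b),
                              c("success", "failure")))
  print(m)
  if (x$degenerate) cat("(degenerate: empty arm)\n")
  invisible(x)
}

#' Reconstruct a 2x2 table from printed proportions
#'
#' Published arm summaries report success proportions and sizes; counts
#' are recovered as the nearest integer to `p * n` (half away from zero).
#' The rounding residuals are attached as the `"residual"` attribute,
#' since printed proportions are themselves rounded.
#'
#' @param p_a,p_b Success proportions in `[0, 1]`.
#' @param n_a,n_b Arm sizes.
#' @param label_a,label_b Group labels.
#' @return A [two_by_two()] table.
#' @examples
#' table_from_proportions(0.98, 687, 0.48, 96)
#' @export
table_from_proportions <- function(p_a, n_a, p_b, n_b,
                                   label_a = "A", label_b = "B") {
  stopifnot(p_a >= 0, p_a <= 1, p_b >= 0, p_b <= 1, n_a >= 0, n_b >= 0)
  sa <- floor(p_a * n_a + 0.5)
  sb <- floor(p_b * n_b + 0.5)
  tab <- two_by_two(sa, n_a - sa, sb, n_b - sb, label_a, label_b)
  attr(tab, "residual") <- c(a = p_a * n_a - sa, b = p_b * n_b - sb)
  tab
}

apply_haldane <- function(tab) {
  structure(list(
    success_a = tab$success_a + 0.5, failure_a = tab$failure_a + 0.5,
    success_b = tab$success_b + 0.5, failure_b = tab$failure_b + 0.5,
    n_a = tab$n_a + 1, n_b = tab$n_b + 1,
    label_a = tab$label_a, label_b = tab$label_b,
    degenerate = tab$degenerate
  ), class = "two_by_two")
}

#' Relative risk of success with a Katz log-method confidence interval
#'
#' Point estimate `(success_a / n_a) / (success_b / n_b)`; the interval is
#' computed on the log scale,
#' `exp(log(rr) +/- z * sqrt(failure_a / (n_a * success_a) +
#' failure_b / (n_b * success_b)))`.
#'
#' @param tab A [two_by_two()] table.
#' @param alpha Two-sided significance level (default 0.05 for a 95% CI).
#' @param correction Add 0.5 to every cell (Haldane–Anscombe) before
#'   estimating; required when a success cell is zero.
#' @return List with `rr`, `lo`, `hi`.
#' @examples
#' relative_risk(table_from_proportions(0.98, 687, 0.48, 96))
#' @export
relative_risk <- function(tab, alpha = 0.05, correction = FALSE) {
  stopifnot(inherits(tab, "two_by_two"))
  if (tab$degenerate) stop("degenerate table: empty arm", call. = FALSE)
  if (correction) tab <- apply_haldane(tab)
  if (tab$success_b == 0) {
    stop("no successes in the reference arm; relative risk undefined ",
         "(consider correction = TRUE)", call. = FALSE)
  }
  rr <- (tab$success_a / tab$n_a) / (tab$success_b / tab$n_b)
  if (tab$success_a == 0) {
    return(list(rr = rr, lo = NA_real_, hi = NA_real_))
  }
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(tab$failure_a / (tab$n_a * tab$success_a) +
               tab$failure_b / (tab$n_b * tab$success_b))
  list(rr = rr, lo = exp(log(rr) - z * se), hi = exp(log(rr) + z * se))
}

#' Number needed to treat with a Wald-interval CI
#'
#' `nnt = 1 / arr` where `arr = p_a - p_b` is the absolute risk
#' difference. The confidence bounds invert the Wald interval for `arr`
#' and are reported in ascending order; when the `arr` interval spans
#' zero the upper bound is unbounded (`Inf`). A zero risk difference
#' yields `nnt = Inf` (flagged, not an error).
#'
#' @inheritParams relative_risk
#' @return List with `nnt`, `lo`, `hi`, `arr`, `arr_lo`, `arr_hi`.
#' @examples
#' number_needed_to_treat(table_from_proportions(0.98, 687, 0.48, 96))
#' @export
number_needed_to_treat <- function(tab, alpha = 0.05) {
  stopifnot(inherits(tab, "two_by_two"))
  if (tab$degenerate) stop("degenerate table: empty arm", call. = FALSE)
  p_a <- tab$success_a / tab$n_a
  p_b <- tab$success_b / tab$n_b
  arr <- p_a - p_b
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(p_a * (1 - p_a) / tab$n_a + p_b * (1 - p_b) / tab$n_b)
  arr_lo <- arr - z * se
  arr_hi <- arr + z * se
  if (arr == 0) {
    return(list(nnt = Inf, lo = NA_real_, hi = NA_real_,
                arr = arr, arr_lo = arr_lo, arr_hi = arr_hi))
  }
  # same-sign interval inverts cleanly; an interval spanning zero makes
  # the far bound unbounded
  bounds <- if (arr_lo > 0 || arr_hi < 0) {
    sort(c(1 / arr_lo, 1 / arr_hi))
  } else if (arr > 0) {
    c(1 / arr_hi, Inf)
  } else {
    c(-Inf, 1 / arr_lo)
  }
  list(nnt = 1 / arr, lo = bounds[1], hi = bounds[2],
       arr = arr, arr_lo = arr_lo, arr_hi = arr_hi)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Computed from observed and expected counts with one degree of freedom;
#' Yates continuity correction only on request.
#'
#' @inheritParams relative_risk
#' @param correction Apply the Yates continuity correction.
#' @return List with `chi2`, `df`, `p`.
#' @examples
#' chi_square(two_by_two(8, 2, 4, 6))
#' @export
chi_square <- function(tab, correction = FALSE) {
  stopifnot(inherits(tab, "two_by_two"))
  o <- matrix(c(tab$success_a, tab$failure_a, tab$success_b, tab$failure_b),
              nrow = 2, byrow = TRUE)
  n <- sum(o)
  e <- outer(rowSums(o), colSums(o)) / n
  if (any(e == 0) || n == 0) {
    stop("expected count of zero: chi-square undefined", call. = FALSE)
  }
  dev <- abs(o - e)
  if (correction) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / e)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' Student's t-test computed from means, standard deviations and sizes
#' alone (no raw data), pooling the two variances;
#' `df = n_a + n_b - 2`, two-sided p-value.
#'
#' @param mean_a,mean_b Group means.
#' @param sd_a,sd_b Group standard deviations (>= 0).
#' @param n_a,n_b Group sizes (> 1).
#' @return List with `t`, `df`, `p`.
#' @examples
#' t_test_from_summaries(157.3, 9.1, 687, 153.6, 10.6, 96)
#' @export
t_test_from_summaries <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a > 1, n_b > 1, sd_a >= 0, sd_b >= 0)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 == 0) {
    if (mean_a == mean_b) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means: t is unbounded")
    return(list(t = sign(mean_a - mean_b) * Inf, df = df, p = 0))
  }
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

effect_row <- function(tab, analysis, alpha = 0.05) {
  rr_est <- relative_risk(tab, alpha)
  nnt_est <- number_needed_to_treat(tab, alpha)
  ch <- chi_square(tab)
  tibble(
    analysis = analysis, group_a = tab$label_a, group_b = tab$label_b,
    n_a = tab$n_a, p_success_a = tab$success_a / tab$n_a,
    n_b = tab$n_b, p_success_b = tab$success_b / tab$n_b,
    rr = rr_est$rr, rr_lo = rr_est$lo, rr_hi = rr_est$hi,
    arr = nnt_est$arr, nnt = nnt_est$nnt,
    nnt_lo = nnt_est$lo, nnt_hi = nnt_est$hi,
    chi2 = ch$chi2, p = ch$p
  )
}

#' Effect measures from two arms' published proportions
#'
#' Composes [table_from_proportions()], [relative_risk()],
#' [number_needed_to_treat()] and [chi_square()] into one result row.
#'
#' @inheritParams table_from_proportions
#' @param analysis Label for the analysis column (e.g. `"efficacy"`).
#' @param alpha Two-sided significance level.
#' @return One-row tibble of effect measures.
#' @export
effect_from_proportions <- function(p_a, n_a, p_b, n_b,
                                    label_a = "A", label_b = "B",
                                    analysis = "efficacy", alpha = 0.05) {
  effect_row(table_from_proportions(p_a, n_a, p_b, n_b, label_a, label_b),
             analysis, alpha)
}

#' Benchmark a cohort subgroup against a published RCT arm
#'
#' Selects the records eligible for the benchmark (its inclusion
#' criteria), computes their success proportion under the benchmark's
#' outcome definition, and compares it to the published arm. Patients
#' still in treatment are excluded from both analyses. The efficacy
#' analysis uses completed patients only; the worst-case intent-to-treat
#' analysis additionally counts every dropout as a failure.
#'
#' @param cohort A validated (typically filtered) cohort tibble.
#' @param spec A benchmark specification from [benchmark_specs()].
#' @param arm `"control"` or `"treated"`: which published arm to compare
#'   against.
#' @param analysis `"efficacy"` or `"itt"`.
#' @param missing_policy Passed to [benchmark_eligibility()].
#' @param alpha Two-sided significance level.
#' @return One-row tibble of effect measures (see [effect_from_proportions()]).
#' @export
build_comparison <- function(cohort, spec, arm = c("control", "treated"),
                             analysis = c("efficacy", "itt"),
                             missing_policy = c("pass", "strict"),
                             alpha = 0.05) {
  arm <- match.arg(arm)
  analysis <- match.arg(analysis)
  cohort <- validate_cohort(cohort)
  arm_summary <- spec$arms[[arm]]
  if (is.null(arm_summary) || is.null(arm_summary$success_prop)) {
    stop("benchmark '", spec$name, "' has no published success proportion ",
         "for the ", arm, " arm", call. = FALSE)
  }
  eligible <- cohort[benchmark_eligibility(cohort, spec, missing_policy) &
                       cohort$status != "in_treatment", , drop = FALSE]
  if (nrow(eligible) == 0) {
    stop("no eligible records for benchmark '", spec$name, "'",
         call. = FALSE)
  }
  completed <- eligible[eligible$status == "completed", , drop = FALSE]
  if (analysis == "efficacy" && nrow(completed) == 0) {
    stop("no completed records for benchmark '", spec$name, "'",
         call. = FALSE)
  }
  succ <- if (nrow(completed) > 0) sum(benchmark_success(completed, spec))
          else 0L
  if (analysis == "efficacy") {
    n_ebpa <- nrow(completed)
  } else {
    n_ebpa <- nrow(eligible)  # dropouts enter the denominator as failures
  }
  succ_arm <- floor(arm_summary$success_prop * arm_summary$n + 0.5)
  tab <- two_by_two(succ, n_ebpa - succ,
                    succ_arm, arm_summary$n - succ_arm,
                    label_a = paste0("EBPA_", spec$name),
                    label_b = paste0(arm, "_", spec$name))
  effect_row(tab, analysis, alpha)
}

#' Full effect-measure table for a cohort against all benchmarks
#'
#' One row per benchmark x published arm x analysis, for every benchmark
#' whose arms carry success proportions. Mirrors the layout of a
#' benchmarking results table: RR with CI, chi-square, NNT with CI.
#'
#' @inheritParams build_comparison
#' @param benchmarks Named list from [benchmark_specs()].
#' @param analyses Character vector of analyses to run.
#' @return Tibble with a `benchmark` column and the columns of
#'   [effect_from_proportions()].
#' @export
benchmark_table <- function(cohort, benchmarks = benchmark_specs(),
                            analyses = c("efficacy", "itt"),
                            missing_policy = c("pass", "strict"),
                            alpha = 0.05) {
  rows <- list()
  for (nm in names(benchmarks)) {
    spec <- benchmarks[[nm]]
    for (arm in c("control", "treated")) {
      if (is.null(spec$arms[[arm]]$success_prop)) next
      for (an in analyses) {
        row <- build_comparison(cohort, spec, arm, an, missing_policy,
                                alpha)
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble(benchmark = spec$name), row)
      }
    }
  }
  dplyr::bind_rows(rows)
}
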