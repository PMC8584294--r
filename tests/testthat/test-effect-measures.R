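test_that("counts are reconstructed from printed proportions", {
  tab <- table_from_proportions(0.98, 687, 0.48, 96)
  expect_equal(c(tab$success_a, tab$failure_a, tab$success_b, tab$failure_b),
               c(673, 14, 46, 50))
  tab2 <- table_from_proportions(1.0, 10, 0.0, 10)
  expect_equal(c(tab2$success_a, tab2$failure_b), c(10, 10))
  expect_true(table_from_proportions(0.5, 0, 0.5, 10)$degenerate)
  expect_lt(max(abs(attr(tab, "residual"))), 0.5)
})

test_that("relative risk reproduces the published benchmark values", {
  tab <- table_from_proportions(0.98, 687, 0.48, 96)
  rr <- relative_risk(tab)
  expect_equal(round_to_printed(rr$rr), 2.0)
  expect_equal(round_to_printed(rr$lo), 1.7)
  expect_equal(round_to_printed(rr$hi), 2.5)

  rr2 <- relative_risk(table_from_proportions(0.98, 687, 0.72, 146))
  expect_equal(round_to_printed(rr2$rr), 1.4)

  same <- two_by_two(30, 20, 30, 20)
  expect_equal(relative_risk(same)$rr, 1.0)
})

test_that("relative risk flags degenerate and zero-cell tables", {
  expect_error(relative_risk(two_by_two(0, 0, 5, 5)), "degenerate")
  expect_error(relative_risk(two_by_two(5, 5, 0, 10)), "undefined")
  rr <- relative_risk(two_by_two(5, 5, 0, 10), correction = TRUE)
  expect_gt(rr$rr, 1)
  expect_true(is.finite(rr$hi))
})

test_that("relative risk point estimates are symmetric under group swap", {
  set.seed(4)
  for (i in 1:25) {
    a <- sample(1:40, 2); b <- sample(1:40, 2)
    t1 <- two_by_two(a[1], a[2], b[1], b[2])
    t2 <- two_by_two(b[1], b[2], a[1], a[2])
    expect_equal(relative_risk(t1)$rr, 1 / relative_risk(t2)$rr)
  }
})

test_that("scaling both arms leaves RR and ARR fixed and narrows the CIs", {
  tab <- two_by_two(40, 10, 25, 25)
  big <- two_by_two(400, 100, 250, 250)
  r1 <- relative_risk(tab); r2 <- relative_risk(big)
  expect_equal(r1$rr, r2$rr)
  expect_lt(r2$hi - r2$lo, r1$hi - r1$lo)
  n1 <- number_needed_to_treat(tab); n2 <- number_needed_to_treat(big)
  expect_equal(n1$arr, n2$arr)
  expect_lt(n2$arr_hi - n2$arr_lo, n1$arr_hi - n1$arr_lo)
})

test_that("number needed to treat reproduces the published values", {
  nnt <- number_needed_to_treat(table_from_proportions(0.98, 687, 0.48, 96))
  expect_equal(round_to_printed(nnt$nnt), 2.0)
  expect_equal(round_to_printed(nnt$lo), 1.7)
  expect_equal(round_to_printed(nnt$hi), 2.5)
  nnt2 <- number_needed_to_treat(table_from_proportions(0.98, 687,
                                                        0.72, 146))
  expect_equal(round_to_printed(nnt2$nnt), 3.8)
})

test_that("degenerate risk differences are signalled, not thrown", {
  same <- two_by_two(30, 20, 30, 20)
  expect_equal(number_needed_to_treat(same)$nnt, Inf)
  # a difference whose Wald interval spans zero leaves the NNT unbounded
  near <- two_by_two(11, 9, 10, 10)
  res <- number_needed_to_treat(near)
  expect_true(res$arr_lo < 0 && res$arr_hi > 0)
  expect_equal(res$hi, Inf)
  expect_true(res$lo > 0)
})

test_that("chi-square matches hand-computed closed-form values", {
  expect_equal(round(chi_square(two_by_two(8, 2, 4, 6))$chi2, 3), 3.333)
  expect_equal(chi_square(two_by_two(10, 0, 0, 10))$chi2, 20)
  expect_equal(chi_square(two_by_two(5, 5, 5, 5))$chi2, 0)
  expect_error(chi_square(two_by_two(5, 0, 5, 0)), "expected count")
})

test_that("chi-square agrees with stats::chisq.test with and without Yates", {
  set.seed(7)
  for (i in 1:30) {
    cnt <- sample(1:30, 4, replace = TRUE)
    tab <- two_by_two(cnt[1], cnt[2], cnt[3], cnt[4])
    m <- matrix(cnt, nrow = 2, byrow = TRUE)
    plain <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    yates <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    expect_equal(chi_square(tab)$chi2, unname(plain$statistic))
    expect_equal(chi_square(tab)$p, plain$p.value)
    expect_equal(chi_square(tab, correction = TRUE)$chi2,
                 unname(yates$statistic))
  }
})

test_that("summary t-test matches t.test on raw data with equal variances", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(25, 10, 2); y <- rnorm(40, 11, 3)
    ours <- t_test_from_summaries(mean(x), sd(x), length(x),
                                  mean(y), sd(y), length(y))
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value)
  }
})

test_that("summary t-test reproduces the published baseline comparisons", {
  height <- t_test_from_summaries(157.3, 9.1, 687, 153.6, 10.6, 96)
  expect_lt(height$p, 5e-4)       # printed as 0.0002
  cobb <- t_test_from_summaries(28.4, 5.8, 687, 30.3, 6.5, 96)
  expect_lt(abs(cobb$p - 0.003), 1e-3)
  same <- t_test_from_summaries(10, 2, 30, 10, 2, 30)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("cohort benchmarking composes selection, success and the 2x2", {
  coh <- generate_cohort(synthetic_params(n_patients = 3000, seed = 31))
  coh <- apply_study_filters(coh)
  specs <- benchmark_specs()
  res <- build_comparison(coh, specs$braist, "control", "efficacy")
  # recompute by hand from the same subgroup
  elig <- coh[benchmark_eligibility(coh, specs$braist) &
                coh$status == "completed", ]
  p_hat <- mean(benchmark_success(elig, specs$braist))
  expect_equal(res$p_success_a, p_hat)
  expect_equal(res$n_b, 96)
  expect_equal(res$rr, p_hat / (46 / 96))

  full <- benchmark_table(coh, specs)
  expect_true(all(c("efficacy", "itt") %in% full$analysis))
  expect_false("PSSE" %in% full$benchmark)  # no published proportions
})

test_that("worst-case intent to treat can only lower the cohort arm", {
  coh <- generate_cohort(synthetic_params(n_patients = 4000, seed = 17,
                                          dropout_prob = 0.10))
  coh <- apply_study_filters(coh)
  specs <- benchmark_specs()
  eff <- build_comparison(coh, specs$braist, "control", "efficacy")
  itt <- build_comparison(coh, specs$braist, "control", "itt")
  expect_lte(itt$p_success_a, eff$p_success_a)
  expect_lte(itt$rr, eff$rr)
})

test_that("an all-dropout cohort has zero ITT successes", {
  coh <- dplyr::bind_rows(lapply(1:8, function(i) {
    patient_row(paste0("D", i), status = "dropout",
                risser_end = NA_integer_, cobb_start = 25, cobb_end = 28,
                age_start = 12, risser_start = 1L)
  }))
  specs <- benchmark_specs()
  itt <- build_comparison(coh, specs$braist, "control", "itt")
  expect_equal(itt$p_success_a, 0)
  expect_error(build_comparison(coh, specs$braist, "control", "efficacy"),
               "no completed")
})
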