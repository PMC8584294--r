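test_that("change classification uses strict 5-degree inequalities", {
  expect_equal(as.character(classify_change(28, 18)), "improved")
  expect_equal(as.character(classify_change(20, 25)), "stable")  # 5 not > 5
  expect_equal(as.character(classify_change(22.0, 27.5)), "progressed")
  expect_equal(as.character(classify_change(30, 24.9)), "improved")
  expect_error(classify_change(28, NA), "not completed")
})

test_that("guideline aims follow the severity bands", {
  expect_equal(classify_aims(15, 18),
               tibble::tibble(primary_aim_met = TRUE,
                              minimal_aim_met = TRUE))
  expect_equal(classify_aims(43, 47),
               tibble::tibble(primary_aim_met = FALSE,
                              minimal_aim_met = TRUE))
  # boundary: 30 is not < 30
  expect_false(classify_aims(25, 30)$primary_aim_met)
  expect_error(classify_aims(46, 30), "\\[11, 45\\]")
})

test_that("over-treatment needs improvement beyond the band-specific margin", {
  expect_true(classify_over_treatment(15, 8))    # 7 > 5 in the low band
  expect_true(classify_over_treatment(28, 18))   # 10 > 9 and end < 30
  expect_false(classify_over_treatment(28, 20))  # 8 <= 9
  expect_false(classify_over_treatment(43, 20))  # severe band: never over
  # margin formula at the band edge: start 40 needs improvement > 15
  expect_true(classify_over_treatment(40, 24.9))
  expect_false(classify_over_treatment(40, 25))
})

test_that("under-treatment follows the 30/60-degree thresholds", {
  expect_true(classify_under_treatment(25, 35, 3))   # crossed 30
  expect_false(classify_under_treatment(35, 42, 6))  # maximal intensity exempt
  expect_true(classify_under_treatment(35, 42, 4))   # 7 > 5 at intensity < 6
  expect_false(classify_under_treatment(35, 39, 4))  # 4 <= 5
  expect_true(classify_under_treatment(43, 61, 6))   # severe: crossed 60
  expect_false(classify_under_treatment(43, 59, 0))
})

test_that("the strict any-progression reading drops the intensity exemption", {
  expect_true(classify_under_treatment(35, 36, 6, any_progression = TRUE))
  expect_false(classify_under_treatment(35, 35, 6, any_progression = TRUE))
  expect_false(classify_under_treatment(35, 36, 4))  # default: 1 <= 5
})

test_that("every start angle maps to exactly one band", {
  s <- seq(11, 45, by = 0.5)
  bands <- cobb_band(s)
  expect_false(any(is.na(bands)))
  expect_equal(as.character(cobb_band(c(20, 20.5, 30, 30.5, 40, 40.5))),
               c("11-20", "21-30", "21-30", "31-40", "31-40", "41-45"))
  expect_error(cobb_band(10.5), "\\[11, 45\\]")
})

test_that("over- and under-treatment are monotone in effect size", {
  for (s in c(22, 28, 35, 40)) {
    ends <- seq(0, 70, by = 0.5)
    over <- classify_over_treatment(rep(s, length(ends)), ends)
    # improvement grows as the end angle falls: over-treatment is an
    # indicator of ends below one cutoff
    expect_false(is.unsorted(rev(over)))
    under <- classify_under_treatment(rep(s, length(ends)), ends,
                                      rep(3, length(ends)))
    expect_false(is.unsorted(under))  # monotone non-decreasing in end
  }
})

test_that("benchmark eligibility matches the trials' inclusion criteria", {
  specs <- benchmark_specs()
  rec <- patient_row(age_start = 12.5, risser_start = 1L, cobb_start = 25,
                     apex_level = "T9", menarche_status = "premenarchal",
                     prior_treatment = FALSE)
  expect_true(benchmark_eligibility(rec, specs$braist))
  expect_true(benchmark_eligibility(rec, specs$spinecor))
  expect_true(benchmark_eligibility(rec, specs$psse))

  expect_false(benchmark_eligibility(patient_row(cobb_start = 19),
                                     specs$braist))  # below 20-40
  expect_false(benchmark_eligibility(patient_row(risser_start = 2L),
                                     specs$psse))    # needs 0-1
  expect_false(benchmark_eligibility(
    patient_row(apex_level = "T5"), specs$braist))   # cranial to T7
  expect_false(benchmark_eligibility(
    patient_row(menarche_status = "postmenarchal_gt_1y"), specs$braist))
  expect_false(benchmark_eligibility(
    patient_row(prior_treatment = TRUE), specs$braist))
})

test_that("missing optional fields pass or fail eligibility per policy", {
  specs <- benchmark_specs()
  rec <- patient_row(apex_level = NA_character_,
                     menarche_status = NA_character_)
  expect_true(benchmark_eligibility(rec, specs$braist, "pass"))
  expect_false(benchmark_eligibility(rec, specs$braist, "strict"))
  # males are not excluded by the menarche rule
  male <- patient_row(sex = "male", menarche_status = "unknown")
  expect_true(benchmark_eligibility(male, specs$braist, "strict"))
})

test_that("benchmark success definitions use the trials' failure thresholds", {
  expect_true(benchmark_success(patient_row(cobb_start = 30,
                                            cobb_end = 49.5),
                                "end_below_50"))
  expect_false(benchmark_success(patient_row(cobb_end = 50), "end_below_50"))
  expect_true(benchmark_success(patient_row(cobb_start = 20, cobb_end = 25),
                                "progression_le_5"))  # 5 <= 5
  expect_false(benchmark_success(patient_row(cobb_start = 20, cobb_end = 24),
                                 "progression_le_3")) # 4 > 3
  expect_true(benchmark_success(patient_row(cobb_end = 44.9),
                                "end_below_45"))
})

test_that("the adherence matrix tabulates intensities per clinical cell", {
  coh <- dplyr::bind_rows(lapply(1:10, function(i) {
    patient_row(paste0("P", i), cobb_start = 15, risser_start = 0L,
                treatment_intensity = 1L)
  }))
  am <- adherence_matrix(coh)
  cell <- am[am$band == "11-20" & am$risser == 0, ]
  expect_equal(cell$pct_1, 100)
  expect_equal(cell$n, 10)
  expect_equal(cell$frac_outside_expected, 0)
  expect_true(all(is.na(am$pct_0[am$n == 0])))

  empty <- adherence_matrix(coh[0, ])
  expect_equal(nrow(empty), 12)
  expect_true(all(empty$n == 0))
  expect_true(all(is.na(empty$pct_3)))
})

test_that("adherence percentages sum to 100 and flag off-range choices", {
  coh <- generate_cohort(synthetic_params(n_patients = 3000, seed = 13))
  am <- adherence_matrix(coh)
  sums <- rowSums(as.matrix(am[paste0("pct_", 0:6)]))
  expect_equal(sums[am$n > 0], rep(100, sum(am$n > 0)),
               ignore_attr = TRUE)
  expect_true(all(am$frac_outside_expected[am$n > 0] >= 0 &
                    am$frac_outside_expected[am$n > 0] <= 1))
})

test_that("cohort classification labels only records with an end angle", {
  coh <- generate_cohort(synthetic_params(n_patients = 400, seed = 9,
                                          in_treatment_prob = 0.2))
  labs <- classify_cohort(coh, benchmark_specs())
  intr <- coh$status == "in_treatment"
  expect_true(all(is.na(labs$change[intr])))
  expect_true(all(!is.na(labs$change[!intr])))
  expect_true(all(c("eligible_braist", "success_braist",
                    "eligible_psse") %in% names(labs)))
  # improvement and progression never co-occur
  both <- labs$improvement & labs$progression
  expect_false(any(both[!is.na(both)]))
})

test_that("the intensity scale is strictly ordered with unique labels", {
  sc <- intensity_scale()
  expect_equal(sc$level, 0:6)
  expect_equal(anyDuplicated(sc$label), 0)
})
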