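#' Ordinal treatment-intensity scale
#'
#' The seven conservative treatment classes ordered from the least to the
#' most demanding (and effective): observation, scoliosis-specific
#' exercises, elastic bracing, rigid plastic bracing part- and full-time,
#' very rigid bracing part- and full-time.
#'
#' @return A tibble with `level` (0–6) and `label`.
#' @export
intensity_scale <- function() {
  tibble(
    level = 0:6,
    label = c(
      "Observation",
      "Physiotherapeutic scoliosis-specific exercises",
      "Elastic brace (SpineCor)",
      "Rigid plastic brace, 21 h/day or less",
      "Rigid plastic brace, 22-24 h/day",
      "Very rigid plastic brace, 18-21 h/day",
      "Very rigid plastic brace, 22-24 h/day"
    )
  )
}

check_angles <- function(cobb_start, cobb_end) {
  if (any(is.na(cobb_end))) {
    stop("cobb_end missing: record has not completed observation",
         call. = FALSE)
  }
  if (any(is.na(cobb_start) | cobb_start < 0 | cobb_end < 0)) {
    stop("Cobb angles must be present and non-negative", call. = FALSE)
  }
}

#' Classify the Cobb-angle change over observation
#'
#' Improvement and progression are changes strictly larger than the
#' radiographic measurement error `delta` (default 5 degrees); anything
#' within `delta` of the start is stable.
#'
#' @param cobb_start,cobb_end Cobb angles (degrees) at start and end of
#'   observation; both required.
#' @param delta Change threshold in degrees (strict inequality).
#' @return Factor vector with levels `improved`, `stable`, `progressed`.
#' @examples
#' classify_change(c(28, 20, 22), c(18, 25, 27.5))
#' @export
classify_change <- function(cobb_start, cobb_end, delta = 5) {
  check_angles(cobb_start, cobb_end)
  out <- rep("stable", length(cobb_start))
  out[cobb_start - cobb_end > delta] <- "improved"
  out[cobb_end - cobb_start > delta] <- "progressed"
  factor(out, levels = c("improved", "stable", "progressed"))
}

#' Guideline aims of treatment by clinical situation
#'
#' Evaluates the primary (optimal) and minimal (fallback) end-of-growth
#' aims for each starting band: below 20 degrees for low curves (11–20),
#' below 30 for moderate-to-high curves (21–40), below 45 for severe
#' curves (41–45); the minimal aim is below 45 everywhere except the
#' severe band, where it is below 60 (the threshold beyond which surgery
#' is considered unavoidable).
#'
#' @inheritParams classify_change
#' @return A tibble with logical columns `primary_aim_met` and
#'   `minimal_aim_met`.
#' @export
classify_aims <- function(cobb_start, cobb_end) {
  check_angles(cobb_start, cobb_end)
  band <- cobb_band(cobb_start)
  primary_below <- c("11-20" = 20, "21-30" = 30, "31-40" = 30,
                     "41-45" = 45)[as.character(band)]
  minimal_below <- c("11-20" = 45, "21-30" = 45, "31-40" = 45,
                     "41-45" = 60)[as.character(band)]
  tibble(primary_aim_met = unname(cobb_end < primary_below),
         minimal_aim_met = unname(cobb_end < minimal_below))
}

#' Over-treatment: unnecessary improvement
#'
#' An improvement is unnecessary when it exceeds what reaching adulthood
#' below the 30-degree threshold required. For low starts (at most 20
#' degrees) any improvement beyond the 5-degree measurement error
#' qualifies. For starts above 20 (up to 40), the required margin grows
#' with the starting angle — improvement must exceed
#' `5 + (cobb_start - 20) / 2` — and the end angle must be below 30
#' degrees. Severe starts (above 40) are never over-treated: no
#' improvement is unnecessary there.
#'
#' @inheritParams classify_change
#' @return Logical vector.
#' @examples
#' classify_over_treatment(c(15, 28, 28), c(8, 18, 20))
#' @export
classify_over_treatment <- function(cobb_start, cobb_end) {
  check_angles(cobb_start, cobb_end)
  if (any(cobb_start < 11 | cobb_start > 45)) {
    stop("cobb_start outside the study range [11, 45]", call. = FALSE)
  }
  improvement <- cobb_start - cobb_end
  ifelse(cobb_start <= 20,
         improvement > 5,
         ifelse(cobb_start <= 40,
                improvement > 5 + (cobb_start - 20) / 2 & cobb_end < 30,
                FALSE))
}

#' Under-treatment: progression despite treatment
#'
#' Judged against the 30-degree adulthood threshold. Patients starting
#' below 30 degrees are under-treated when they end above it. Patients
#' starting at 30–40 degrees are under-treated when they progress by more
#' than `progression_delta` degrees — unless they already received the
#' maximal intensity (level 6), which exempts them: nothing stronger could
#' have been offered. Severe starts (above 40) are under-treated only when
#' they cross the 60-degree surgical threshold.
#'
#' `any_progression = TRUE` switches the 30–40 band to the stricter
#' reading under which any progression at all marks under-treatment.
#'
#' @inheritParams classify_change
#' @param intensity Treatment intensity 0–6 actually applied.
#' @param progression_delta Progression threshold (degrees) for the 30–40
#'   band.
#' @param any_progression Use the strict "progressed at all" rule for the
#'   30–40 band (no intensity exemption).
#' @return Logical vector.
#' @examples
#' classify_under_treatment(c(25, 35, 35), c(35, 42, 42), c(3, 6, 4))
#' @export
classify_under_treatment <- function(cobb_start, cobb_end, intensity,
                                     progression_delta = 5,
                                     any_progression = FALSE) {
  check_angles(cobb_start, cobb_end)
  if (any(!intensity %in% 0:6)) {
    stop("intensity must be in 0..6", call. = FALSE)
  }
  mid <- if (any_progression) {
    cobb_end > cobb_start
  } else {
    cobb_end - cobb_start > progression_delta & intensity < 6
  }
  ifelse(cobb_start < 30,
         cobb_end > 30,
         ifelse(cobb_start <= 40, mid, cobb_end > 60))
}

#' Per-patient classification of a cohort
#'
#' Applies every per-patient rule to the records with an end-of-observation
#' Cobb angle (completed patients and dropouts at their last observed
#' value): change category, 30/50-degree outcomes, guideline aims, over-
#' and under-treatment, and — when benchmark specifications are supplied —
#' eligibility and success per benchmark. Patients still in treatment get
#' `NA` outcome labels.
#'
#' @param cohort A validated cohort tibble.
#' @param benchmarks Optional named list of benchmark specifications (see
#'   [benchmark_specs()]).
#' @param delta Change threshold in degrees for improvement/progression.
#' @param any_progression Passed to [classify_under_treatment()].
#' @param missing_policy Passed to [benchmark_eligibility()].
#' @return A tibble with one row per patient: `patient_id`, `cobb_band`,
#'   `change`, `improvement`, `progression`, `end_below_30`,
#'   `end_below_50`, `primary_aim_met`, `minimal_aim_met`, `over_treated`,
#'   `under_treated`, and per benchmark `eligible_<name>` /
#'   `success_<name>`.
#' @export
classify_cohort <- function(cohort, benchmarks = NULL, delta = 5,
                            any_progression = FALSE,
                            missing_policy = c("pass", "strict")) {
  cohort <- validate_cohort(cohort)
  missing_policy <- match.arg(missing_policy)
  has_end <- !is.na(cohort$cobb_end)
  res <- tibble(
    patient_id = cohort$patient_id,
    cobb_band = cobb_band(cohort$cobb_start),
    change = factor(NA, levels = c("improved", "stable", "progressed")),
    improvement = NA, progression = NA,
    end_below_30 = NA, end_below_50 = NA,
    primary_aim_met = NA, minimal_aim_met = NA,
    over_treated = NA, under_treated = NA
  )
  if (any(has_end)) {
    s <- cohort$cobb_start[has_end]
    e <- cohort$cobb_end[has_end]
    ch <- classify_change(s, e, delta)
    aims <- classify_aims(s, e)
    res$change[has_end] <- ch
    res$improvement[has_end] <- ch == "improved"
    res$progression[has_end] <- ch == "progressed"
    res$end_below_30[has_end] <- e < 30
    res$end_below_50[has_end] <- e < 50
    res$primary_aim_met[has_end] <- aims$primary_aim_met
    res$minimal_aim_met[has_end] <- aims$minimal_aim_met
    res$over_treated[has_end] <- classify_over_treatment(s, e)
    res$under_treated[has_end] <- classify_under_treatment(
      s, e, cohort$treatment_intensity[has_end],
      progression_delta = delta, any_progression = any_progression)
  }
  for (nm in names(benchmarks)) {
    spec <- benchmarks[[nm]]
    res[[paste0("eligible_", nm)]] <-
      benchmark_eligibility(cohort, spec, missing_policy)
    succ <- rep(NA, nrow(cohort))
    succ[has_end] <- benchmark_success(cohort[has_end, , drop = FALSE], spec)
    res[[paste0("success_", nm)]] <- succ
  }
  res
}

#' Eligibility of cohort records for a benchmark trial
#'
#' Applies an RCT's inclusion criteria to every record: age, Risser stage
#' and Cobb angle ranges, plus — where the trial specifies them — a
#' menarche rule (premenarchal or at most one year post), an apex rule
#' (major-curve apex at or caudal to a vertebral level), and a
#' no-prior-treatment rule. Records missing an optional field covered by a
#' predicate pass by default (`missing_policy = "pass"`) or are excluded
#' under `"strict"`; the ranges on required fields always apply.
#'
#' @param cohort A validated cohort tibble (or any data frame with the
#'   schema columns).
#' @param spec A single benchmark specification from [benchmark_specs()].
#' @param missing_policy `"pass"` or `"strict"` for missing menarche/apex.
#' @return Logical vector, one element per record.
#' @export
benchmark_eligibility <- function(cohort, spec,
                                  missing_policy = c("pass", "strict")) {
  missing_policy <- match.arg(missing_policy)
  ok <- cohort$age_start >= spec$age_range[1] &
    cohort$age_start <= spec$age_range[2] &
    cohort$risser_start >= spec$risser_range[1] &
    cohort$risser_start <= spec$risser_range[2] &
    cohort$cobb_start >= spec$cobb_range[1] &
    cohort$cobb_start <= spec$cobb_range[2]
  missing_pass <- missing_policy == "pass"
  if (isTRUE(spec$menarche_rule)) {
    men <- cohort$menarche_status
    known <- !is.na(men) & men != "unknown"
    men_ok <- ifelse(cohort$sex == "male", TRUE,
                     ifelse(known,
                            men %in% c("premenarchal",
                                       "postmenarchal_le_1y"),
                            missing_pass))
    ok <- ok & men_ok
  }
  if (!is.null(spec$apex_at_or_below)) {
    cutoff <- apex_rank(spec$apex_at_or_below)
    rk <- apex_rank(cohort$apex_level)
    ok <- ok & ifelse(is.na(rk), missing_pass, rk >= cutoff)
  }
  if (isTRUE(spec$no_prior_treatment)) {
    ok <- ok & !cohort$prior_treatment
  }
  ok
}

#' Success of cohort records under a benchmark's outcome definition
#'
#' The paired trials define failure, and success is its complement:
#' remaining below 50 degrees (plastic bracing), remaining below 45
#' degrees (elastic bracing, as used for the published risk ratios),
#' progression of at most 5 degrees (elastic bracing, protocol reading),
#' or progression of at most 3 degrees (exercises).
#'
#' @param cohort Records with `cobb_start` and `cobb_end` present.
#' @param spec A benchmark specification, or a character scalar naming the
#'   success definition directly (`"end_below_50"`, `"end_below_45"`,
#'   `"progression_le_5"`, `"progression_le_3"`).
#' @return Logical vector.
#' @export
benchmark_success <- function(cohort, spec) {
  def <- if (is.character(spec)) spec else spec$success_definition
  def <- match.arg(def, c("end_below_50", "end_below_45",
                          "progression_le_5", "progression_le_3"))
  check_angles(cohort$cobb_start, cohort$cobb_end)
  switch(def,
    end_below_50 = cohort$cobb_end < 50,
    end_below_45 = cohort$cobb_end < 45,
    progression_le_5 = cohort$cobb_end - cohort$cobb_start <= 5,
    progression_le_3 = cohort$cobb_end - cohort$cobb_start <= 3
  )
}

#' Adherence matrix: treatment intensity by clinical situation
#'
#' Cross-tabulates treatment intensity (0–6) against the clinical
#' situation grid (Cobb band x Risser 0–2) as percentages within each
#' cell, and flags the fraction of each cell outside the expected
#' intensity range for that situation.
#'
#' @param cohort A validated, filtered cohort (Risser 0–2).
#' @param expected Named list mapping band label to the integer vector of
#'   expected intensities; default [expected_intensity_ranges()].
#' @return A tibble with one row per (band, Risser) cell: `band`,
#'   `risser`, `n`, `pct_0` ... `pct_6` (percentages summing to 100;
#'   `NA` for empty cells), and `frac_outside_expected`.
#' @export
adherence_matrix <- function(cohort, expected = expected_intensity_ranges()) {
  cohort <- validate_cohort(cohort)
  grid <- tidyr::expand_grid(band = factor(band_levels, levels = band_levels,
                                           ordered = TRUE),
                             risser = 0:2)
  if (nrow(cohort) == 0) {
    counts <- matrix(0L, nrow(grid), 7)
  } else {
    band <- cobb_band(cohort$cobb_start)
    counts <- t(vapply(seq_len(nrow(grid)), function(i) {
      sel <- band == grid$band[i] & cohort$risser_start == grid$risser[i]
      tabulate(cohort$treatment_intensity[sel] + 1L, nbins = 7)
    }, integer(7)))
  }
  n_cell <- rowSums(counts)
  pct <- counts / ifelse(n_cell == 0, NA_real_, n_cell) * 100
  colnames(pct) <- paste0("pct_", 0:6)
  out <- dplyr::bind_cols(grid, n = n_cell, as_tibble(pct))
  out$frac_outside_expected <- vapply(seq_len(nrow(out)), function(i) {
    exp_lv <- expected[[as.character(out$band[i])]]
    if (n_cell[i] == 0) return(NA_real_)
    sum(counts[i, setdiff(0:6, exp_lv) + 1L]) / n_cell[i]
  }, numeric(1))
  out
}
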