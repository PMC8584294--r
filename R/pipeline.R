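#' Round half away from zero to the precision a table prints
#'
#' Published effect measures are printed to one decimal; comparisons with
#' them use commercial rounding (half away from zero), not banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded vector.
#' @examples
#' round_to_printed(c(2.044, 1.659, 2.519))
#' @export
round_to_printed <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Treatment-intensity shift of a subgroup against its trial protocol
#'
#' Each benchmark trial applied a single treatment intensity to everyone;
#' a personalised approach spreads its subgroup across the scale. This
#' reports the proportions of eligible patients treated above, at, and
#' below the trial's protocol intensity.
#'
#' @param cohort A validated cohort tibble.
#' @param spec A benchmark specification from [benchmark_specs()].
#' @param rct_intensity The trial's protocol intensity level (defaults to
#'   the one recorded in `spec`).
#' @param missing_policy Passed to [benchmark_eligibility()].
#' @return Named numeric vector `c(above, at, below)` summing to 1.
#' @export
intensity_shift <- function(cohort, spec, rct_intensity = spec$rct_intensity,
                            missing_policy = c("pass", "strict")) {
  stopifnot(rct_intensity %in% 0:6)
  cohort <- validate_cohort(cohort)
  sub <- cohort[benchmark_eligibility(cohort, spec, missing_policy), ,
                drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no eligible records for benchmark '", spec$name, "'",
         call. = FALSE)
  }
  c(above = mean(sub$treatment_intensity > rct_intensity),
    at = mean(sub$treatment_intensity == rct_intensity),
    below = mean(sub$treatment_intensity < rct_intensity))
}

#' Intensity shift from a printed intensity distribution
#'
#' Same summary as [intensity_shift()], computed directly from a published
#' percentage distribution over intensities 0–6 (e.g. a subgroup column of
#' a baseline table). Sums are reported in the input's own units (percent)
#' without renormalising, exactly as a reader of the printed column would
#' add them.
#'
#' @param pct Numeric vector of length 7 (names `"0"`–`"6"` optional, in
#'   that order otherwise) of percentages.
#' @param rct_intensity Protocol intensity level 0–6.
#' @return Named numeric vector `c(above, at, below)` in percent.
#' @examples
#' intensity_shift_from_percentages(
#'   c("0" = 1, "1" = 14, "2" = 9, "3" = 29, "4" = 11, "5" = 9, "6" = 28), 3)
#' @export
intensity_shift_from_percentages <- function(pct, rct_intensity) {
  stopifnot(length(pct) == 7, rct_intensity %in% 0:6)
  if (!is.null(names(pct))) {
    stopifnot(setequal(names(pct), as.character(0:6)))
    pct <- pct[as.character(0:6)]
  }
  lv <- 0:6
  c(above = sum(pct[lv > rct_intensity]),
    at = sum(pct[lv == rct_intensity]),
    below = sum(pct[lv < rct_intensity]))
}

#' Recompute the published benchmark comparisons from printed inputs
#'
#' Rebuilds the efficacy effect-measure table (relative risk of success,
#' confidence intervals, chi-square, number needed to treat) purely from
#' the packaged published summaries — subgroup and trial-arm sizes and
#' success proportions — with no patient-level data, plus the
#' intensity-shift summaries from the packaged subgroup intensity
#' distributions. This is the reproducibility check for the published
#' numbers.
#'
#' Only efficacy rows are recomputed: the published intent-to-treat rows
#' rest on subgroup-specific dropout denominators that were not reported.
#'
#' @param benchmarks Named list from [benchmark_specs()].
#' @param alpha Two-sided significance level.
#' @return List with `effects` (tibble of effect-measure rows) and
#'   `intensity_shift` (tibble with percent above/at/below per benchmark).
#' @examples
#' chk <- published_benchmark_table()
#' chk$effects[, c("benchmark", "group_b", "rr", "rr_lo", "rr_hi", "nnt")]
#' @export
published_benchmark_table <- function(benchmarks = benchmark_specs(),
                                      alpha = 0.05) {
  eff <- list()
  shift <- list()
  for (nm in names(benchmarks)) {
    spec <- benchmarks[[nm]]
    ebpa <- spec$arms$ebpa
    for (arm in c("control", "treated")) {
      a <- spec$arms[[arm]]
      if (is.null(a$success_prop) || is.null(ebpa$success_prop)) next
      row <- effect_from_proportions(
        ebpa$success_prop, ebpa$n, a$success_prop, a$n,
        label_a = paste0("EBPA_", spec$name),
        label_b = paste0(arm, "_", spec$name),
        analysis = "efficacy", alpha = alpha)
      eff[[length(eff) + 1L]] <- dplyr::bind_cols(
        tibble(benchmark = spec$name), row)
    }
    if (!is.null(ebpa$intensity_pct)) {
      sh <- intensity_shift_from_percentages(ebpa$intensity_pct,
                                             spec$rct_intensity)
      shift[[length(shift) + 1L]] <- tibble(
        benchmark = spec$name, rct_intensity = spec$rct_intensity,
        pct_above = sh[["above"]], pct_at = sh[["at"]],
        pct_below = sh[["below"]])
    }
  }
  list(effects = dplyr::bind_rows(eff),
       intensity_shift = dplyr::bind_rows(shift))
}

#' Configuration of a full study run
#'
#' Exactly one of `input` (path to a cohort CSV) or `params`
#' ([synthetic_params()]) must be given.
#'
#' @param input Optional path to a cohort CSV.
#' @param params Optional synthetic-cohort parameters.
#' @param benchmarks_path,expected_path,aims_path Optional YAML overrides
#'   for the packaged configs.
#' @param analyses Analyses to run: subset of `c("efficacy", "itt")`.
#' @param missing_policy Eligibility policy for missing optional fields.
#' @param min_visits In-charge threshold for the study filters.
#' @param out Optional output directory for TSV/JSON report files.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = NULL, params = NULL,
                       benchmarks_path = NULL, expected_path = NULL,
                       aims_path = NULL,
                       analyses = c("efficacy", "itt"),
                       missing_policy = c("pass", "strict"),
                       min_visits = 3, out = NULL) {
  if (is.null(input) == is.null(params)) {
    stop("exactly one of 'input' and 'params' must be supplied",
         call. = FALSE)
  }
  if (!is.null(params) && !inherits(params, "synthetic_params")) {
    stop("params must come from synthetic_params()", call. = FALSE)
  }
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(
    input = input, params = params,
    benchmarks_path = benchmarks_path, expected_path = expected_path,
    aims_path = aims_path, analyses = analyses,
    missing_policy = match.arg(missing_policy),
    min_visits = min_visits, out = out
  ), class = "run_config")
}

#' Run the full benchmarking study
#'
#' End-to-end pipeline: load or generate the cohort, apply the study
#' filters, classify every patient, and produce the study report —
#' attrition ledger, cohort outcome summary, adherence matrix, baseline
#' comparability against every benchmark arm (pooled t-tests from
#' summaries), the effect-measure table, and the intensity-shift summary.
#' Deterministic given the configuration (and the seed inside any
#' synthetic parameters). With `out` set, every section is written as TSV
#' plus one machine-readable JSON.
#'
#' @param config A [run_config()].
#' @return A `study_report` list with elements `attrition`,
#'   `outcome_summary`, `adherence`, `baseline_comparability`,
#'   `effect_table`, `intensity_shift`, and `meta`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  benchmarks <- benchmark_specs(config$benchmarks_path)
  expected <- expected_intensity_ranges(config$expected_path)
  aims <- aims_rules(config$aims_path)

  cohort <- if (!is.null(config$input)) read_cohort(config$input)
            else generate_cohort(config$params)
  filtered <- apply_study_filters(cohort, min_visits = config$min_visits)
  ledger <- attrition(filtered)

  analysed <- filtered[filtered$status != "in_treatment", , drop = FALSE]
  ledger <- dplyr::bind_rows(ledger, tibble(
    criterion = "still_in_treatment",
    excluded = nrow(filtered) - nrow(analysed),
    remaining = nrow(analysed)))

  labels <- classify_cohort(filtered, benchmarks,
                            delta = aims$change_delta,
                            any_progression =
                              aims$under_treatment_any_progression,
                            missing_policy = config$missing_policy)
  completed_lab <- labels[labels$patient_id %in%
                            filtered$patient_id[filtered$status ==
                                                  "completed"], ,
                          drop = FALSE]
  outcome_summary <- tibble(
    n_filtered = nrow(filtered),
    n_analysed = nrow(analysed),
    n_completed = nrow(completed_lab),
    prop_baseline_below_30 = mean(filtered$cobb_start < 30),
    prop_end_below_30 = mean(completed_lab$end_below_30),
    prop_end_below_50 = mean(completed_lab$end_below_50),
    prop_improved = mean(completed_lab$improvement),
    prop_progressed = mean(completed_lab$progression),
    prop_primary_aim = mean(completed_lab$primary_aim_met),
    prop_minimal_aim = mean(completed_lab$minimal_aim_met),
    prop_under_treated = mean(completed_lab$under_treated),
    prop_over_treated = mean(completed_lab$over_treated),
    prop_dropout = mean(filtered$status == "dropout")
  )

  adherence <- adherence_matrix(filtered, expected)

  base_rows <- list()
  for (nm in names(benchmarks)) {
    spec <- benchmarks[[nm]]
    elig <- filtered[benchmark_eligibility(filtered, spec,
                                           config$missing_policy), ,
                     drop = FALSE]
    vars <- list(age = elig$age_start, height = elig$height_start,
                 cobb = elig$cobb_start)
    for (arm in c("control", "treated")) {
      arm_sum <- spec$arms[[arm]]$baselines
      for (v in names(vars)) {
        if (is.null(arm_sum[[v]])) next
        x <- vars[[v]][!is.na(vars[[v]])]
        if (length(x) < 2) next
        tt <- t_test_from_summaries(mean(x), stats::sd(x), length(x),
                                    arm_sum[[v]]$mean, arm_sum[[v]]$sd,
                                    spec$arms[[arm]]$n)
        base_rows[[length(base_rows) + 1L]] <- tibble(
          benchmark = spec$name, arm = arm, variable = v,
          subgroup_mean = mean(x), subgroup_sd = stats::sd(x),
          subgroup_n = length(x),
          arm_mean = arm_sum[[v]]$mean, arm_sd = arm_sum[[v]]$sd,
          arm_n = spec$arms[[arm]]$n,
          t = tt$t, df = tt$df, p = tt$p)
      }
    }
  }
  baseline_comparability <- dplyr::bind_rows(base_rows)

  effect_table <- benchmark_table(filtered, benchmarks,
                                  analyses = config$analyses,
                                  missing_policy = config$missing_policy)

  shift_rows <- list()
  for (nm in names(benchmarks)) {
    spec <- benchmarks[[nm]]
    sh <- tryCatch(intensity_shift(filtered, spec,
                                   missing_policy = config$missing_policy),
                   error = function(e) NULL)
    if (is.null(sh)) next
    shift_rows[[length(shift_rows) + 1L]] <- tibble(
      benchmark = spec$name, rct_intensity = spec$rct_intensity,
      prop_above = sh[["above"]], prop_at = sh[["at"]],
      prop_below = sh[["below"]])
  }

  report <- structure(list(
    attrition = ledger,
    outcome_summary = outcome_summary,
    adherence = adherence,
    baseline_comparability = baseline_comparability,
    effect_table = effect_table,
    intensity_shift = dplyr::bind_rows(shift_rows),
    meta = list(
      n_input = nrow(cohort), n_filtered = nrow(filtered),
      analyses = config$analyses, missing_policy = config$missing_policy,
      min_visits = config$min_visits,
      change_delta = aims$change_delta,
      under_treatment_any_progression =
        aims$under_treatment_any_progression,
      seed = if (!is.null(config$params)) config$params$seed else NA
    )
  ), class = "study_report")

  if (!is.null(config$out)) write_study_report(report, config$out)
  report
}

#' Write a study report to disk
#'
#' One TSV per report section plus a single `study.json` holding
#' everything.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sections <- c("attrition", "outcome_summary", "adherence",
                "baseline_comparability", "effect_table",
                "intensity_shift")
  for (s in sections) {
    readr::write_tsv(report[[s]], file.path(dir, paste0(s, ".tsv")),
                     progress = FALSE)
  }
  jsonlite::write_json(unclass(report), file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}
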