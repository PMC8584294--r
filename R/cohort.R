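#' @importFrom dplyr %>% mutate filter select arrange group_by summarise
#'   ungroup across all_of bind_rows left_join n
#' @importFrom tibble tibble as_tibble
NULL

# Canonical wide (one row per patient) schema. Column order is fixed so that
# write_cohort() output is byte-stable and diffable.
cohort_columns <- c(
  "patient_id", "sex", "age_start", "height_start", "menarche_status",
  "cobb_start", "cobb_end", "risser_start", "risser_end", "apex_level",
  "prior_treatment", "braced_at_first_visit", "n_visits",
  "treatment_intensity", "treatment_years", "status", "xray_window_ok"
)

cohort_col_types <- readr::cols(
  patient_id            = readr::col_character(),
  sex                   = readr::col_character(),
  age_start             = readr::col_double(),
  height_start          = readr::col_double(),
  menarche_status       = readr::col_character(),
  cobb_start            = readr::col_double(),
  cobb_end              = readr::col_double(),
  risser_start          = readr::col_integer(),
  risser_end            = readr::col_integer(),
  apex_level            = readr::col_character(),
  prior_treatment       = readr::col_logical(),
  braced_at_first_visit = readr::col_logical(),
  n_visits              = readr::col_integer(),
  treatment_intensity   = readr::col_integer(),
  treatment_years       = readr::col_double(),
  status                = readr::col_character(),
  xray_window_ok        = readr::col_logical()
)

sex_levels      <- c("female", "male")
status_levels   <- c("completed", "dropout", "in_treatment")
menarche_levels <- c("premenarchal", "postmenarchal_le_1y",
                     "postmenarchal_gt_1y", "unknown")
apex_levels     <- c(paste0("T", 1:12), paste0("L", 1:5))

#' Rank of a vertebral apex level
#'
#' Maps apex labels to an ordinal rank with T1 < T2 < ... < T12 < L1 < ... <
#' L5, so that criteria such as "apex at or caudal to T7" become numeric
#' comparisons. Unknown labels and `NA` map to `NA`.
#'
#' @param level Character vector of vertebral levels (`"T1"`–`"T12"`,
#'   `"L1"`–`"L5"`).
#' @return Integer vector of ranks (T1 = 1, ..., L5 = 17).
#' @examples
#' apex_rank(c("T7", "L1", NA))
#' @export
apex_rank <- function(level) {
  match(toupper(as.character(level)), apex_levels)
}

#' Validate a scoliosis cohort table
#'
#' Checks a wide one-row-per-patient table against the cohort schema:
#' required columns, enumerations (`sex`, `status`, `menarche_status`,
#' `apex_level`), ranges (Cobb angles non-negative, Risser stages 0–4,
#' treatment intensity 0–6), uniqueness of `patient_id`, and the rule that
#' completed patients carry an end-of-observation Cobb angle. All problems
#' are collected and reported together with row numbers.
#'
#' @param cohort A data frame using the cohort schema (see
#'   [read_cohort()] for the column list).
#' @return The validated cohort as a tibble in canonical column order,
#'   invisibly usable downstream. Errors (with row-level diagnostics) if any
#'   check fails.
#' @export
validate_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cohort <- cohort[cohort_columns]

  problems <- character(0)
  flag <- function(bad, msg) {
    idx <- which(bad)
    if (length(idx) > 0) {
      shown <- utils::head(idx, 5)
      problems <<- c(problems, sprintf(
        "%s (row%s %s%s)", msg, if (length(idx) > 1) "s" else "",
        paste(shown, collapse = ", "),
        if (length(idx) > length(shown)) ", ..." else ""))
    }
  }

  dup <- duplicated(cohort$patient_id) | is.na(cohort$patient_id)
  if (any(dup)) {
    ids <- unique(cohort$patient_id[duplicated(cohort$patient_id)])
    flag(dup, paste0("duplicate or missing patient_id: ",
                     paste(utils::head(ids, 5), collapse = ", ")))
  }
  flag(!cohort$sex %in% sex_levels, "sex not in {female, male}")
  flag(!cohort$status %in% status_levels,
       "status not in {completed, dropout, in_treatment}")
  flag(!is.na(cohort$menarche_status) &
         !cohort$menarche_status %in% menarche_levels,
       "unrecognised menarche_status")
  flag(!is.na(cohort$apex_level) & is.na(apex_rank(cohort$apex_level)),
       "apex_level does not parse as T1..T12 or L1..L5")
  flag(is.na(cohort$cobb_start) | cohort$cobb_start < 0,
       "cobb_start missing or negative")
  flag(!is.na(cohort$cobb_end) & cohort$cobb_end < 0, "cobb_end negative")
  flag(!cohort$risser_start %in% 0:4, "risser_start not in 0..4")
  flag(!is.na(cohort$risser_end) & !cohort$risser_end %in% 0:4,
       "risser_end not in 0..4")
  flag(!cohort$treatment_intensity %in% 0:6,
       "treatment_intensity not in 0..6")
  flag(is.na(cohort$n_visits) | cohort$n_visits < 0, "n_visits invalid")
  flag(is.na(cohort$prior_treatment) | is.na(cohort$braced_at_first_visit) |
         is.na(cohort$xray_window_ok), "logical flags must be TRUE/FALSE")
  flag(cohort$status == "completed" & is.na(cohort$cobb_end),
       "completed patient without cobb_end")
  flag(cohort$status == "in_treatment" & !is.na(cohort$cobb_end),
       "in_treatment patient with cobb_end")

  if (length(problems) > 0) {
    stop("invalid cohort:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  cohort
}

#' Read a cohort from a wide CSV file
#'
#' Reads a one-row-per-patient CSV in the canonical cohort schema and
#' validates it. Empty fields in optional columns (`height_start`,
#' `cobb_end`, `risser_end`, `apex_level`, `menarche_status`,
#' `treatment_years`) become `NA`, never zero.
#'
#' @param path Path to a CSV file with header
#'   `patient_id,sex,age_start,height_start,menarche_status,cobb_start,
#'   cobb_end,risser_start,risser_end,apex_level,prior_treatment,
#'   braced_at_first_visit,n_visits,treatment_intensity,treatment_years,
#'   status,xray_window_ok` (UTF-8, comma-separated, "." decimal mark).
#' @return A validated cohort tibble.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = cohort_col_types,
                         na = c("", "NA"), progress = FALSE)
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE, show_col_types = FALSE))
  if (!setequal(hdr, cohort_columns)) {
    stop("cohort CSV header does not match the documented schema; ",
         "unexpected: ", paste(setdiff(hdr, cohort_columns), collapse = ", "),
         "; missing: ", paste(setdiff(cohort_columns, hdr), collapse = ", "),
         call. = FALSE)
  }
  validate_cohort(raw)
}

#' Write a cohort to CSV
#'
#' Writes the canonical column order; re-reading with [read_cohort()]
#' reproduces the cohort field for field (numbers at full precision).
#'
#' @param cohort A validated cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  readr::write_csv(cohort, path, na = "", progress = FALSE)
  invisible(path)
}

#' Apply the study inclusion and exclusion filters
#'
#' Restricts a cohort to the study population: largest-curve Cobb angle in
#' 11–45 degrees (inclusive), Risser stage 0–2 at the start, in charge
#' (at least `min_visits` consultations), not wearing a brace at the first
#' consultation, and radiographs within three months of the start and end
#' of observation. Filters are applied in that fixed order and an attrition
#' ledger (one exclusion count per criterion) is attached as the
#' `"attrition"` attribute, retrievable with [attrition()].
#'
#' @param cohort A validated cohort tibble.
#' @param min_visits Minimum number of consultations to count as in charge
#'   (default 3).
#' @return The filtered cohort, with an attrition ledger attribute.
#' @examples
#' coh <- generate_cohort(synthetic_params(n_patients = 100, seed = 1))
#' filtered <- apply_study_filters(coh)
#' attrition(filtered)
#' @export
apply_study_filters <- function(cohort, min_visits = 3) {
  cohort <- validate_cohort(cohort)
  steps <- list(
    cobb_range   = function(d) d$cobb_start >= 11 & d$cobb_start <= 45,
    risser_0_2   = function(d) d$risser_start <= 2,
    in_charge    = function(d) d$n_visits >= min_visits,
    not_braced_at_first = function(d) !d$braced_at_first_visit,
    xray_window  = function(d) d$xray_window_ok
  )
  ledger <- tibble(criterion = names(steps),
                   excluded = NA_integer_, remaining = NA_integer_)
  out <- cohort
  for (i in seq_along(steps)) {
    keep <- steps[[i]](out)
    ledger$excluded[i] <- sum(!keep)
    out <- out[keep, , drop = FALSE]
    ledger$remaining[i] <- nrow(out)
  }
  attr(ledger, "n_input") <- nrow(cohort)
  attr(out, "attrition") <- ledger
  out
}

#' Attrition ledger of a filtered cohort
#'
#' @param cohort A cohort returned by [apply_study_filters()].
#' @return A tibble with one row per filter criterion (in application
#'   order), the number excluded at that step and the number remaining.
#' @export
attrition <- function(cohort) {
  ledger <- attr(cohort, "attrition")
  if (is.null(ledger)) stop("cohort carries no attrition ledger; ",
                            "apply apply_study_filters() first", call. = FALSE)
  ledger
}
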