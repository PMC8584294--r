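#' Cobb-angle band of the clinical situation at the start
#'
#' Bands follow the guideline severity grid used throughout the rule
#' engine: 11–20 (low), 21–30 (moderate, pooling the 21–25 and 26–30
#' rows that share one treatment-aims rule), 31–40, and 41–45 (severe).
#' Decimal angles fall in the band whose printed integer range brackets
#' them (e.g. 20.5 is moderate).
#'
#' @param cobb_start Numeric vector of starting Cobb angles in `[11, 45]`.
#' @return Factor with levels `"11-20" < "21-30" < "31-40" < "41-45"`.
#' @export
cobb_band <- function(cobb_start) {
  if (any(is.na(cobb_start) | cobb_start < 11 | cobb_start > 45)) {
    stop("cobb_start outside the study range [11, 45]", call. = FALSE)
  }
  cut(cobb_start, breaks = c(11, 20, 30, 40, 45),
      labels = c("11-20", "21-30", "31-40", "41-45"),
      include.lowest = TRUE, right = TRUE, ordered_result = TRUE)
}

band_levels <- c("11-20", "21-30", "31-40", "41-45")

#' Default treatment-intensity assignment policy
#'
#' Probability of each treatment intensity 0–6 conditional on the clinical
#' situation (Cobb band x Risser stage), mirroring the adherence pattern of
#' the full study population: almost all low curves get exercises, moderate
#' curves mostly rigid part-time bracing, high curves predominantly very
#' rigid full-time bracing. Each cell's printed percentages are normalised
#' to sum exactly to one.
#'
#' @return A tibble with columns `band`, `risser`, and `p0`–`p6` (rows sum
#'   to 1).
#' @export
default_intensity_policy <- function() {
  raw <- rbind(
    # band, risser, intensities 0..6 (percent)
    c(10, 78,  5,  5,  1,  1,  0),  # 11-20, Risser 0
    c( 6, 80,  4, 10,  0,  1,  0),  # 11-20, Risser 1
    c( 6, 82,  1, 10,  0,  2,  0),  # 11-20, Risser 2
    c( 1, 16, 14, 39, 13,  8,  9),  # 21-30, Risser 0
    c( 1, 18,  9, 45,  7, 11,  8),  # 21-30, Risser 1
    c( 1, 24,  6, 47,  6, 10,  7),  # 21-30, Risser 2
    c( 0,  1,  0,  9, 16,  4, 70),  # 31-40, Risser 0
    c( 0,  0,  1,  7, 15, 17, 59),  # 31-40, Risser 1
    c( 0,  1,  1,  4,  9, 18, 67),  # 31-40, Risser 2
    c( 0,  0,  0,  0,  2,  0, 98),  # 41-45, Risser 0
    c( 0,  0,  0,  0,  0,  0, 100), # 41-45, Risser 1
    c( 0,  0,  0,  0,  0,  7, 93)   # 41-45, Risser 2
  )
  probs <- raw / rowSums(raw)
  colnames(probs) <- paste0("p", 0:6)
  dplyr::bind_cols(
    tibble(band = rep(band_levels, each = 3), risser = rep(0:2, times = 4)),
    as_tibble(probs)
  )
}

#' Parameters for the synthetic cohort generator
#'
#' Bundles and validates everything [generate_cohort()] needs. Defaults
#' emulate a high-risk adolescent idiopathic scoliosis cohort at first
#' consultation: ~83% female, age 12.7 +/- 1.3 y, baseline Cobb a normal
#' truncated to the 11–45 degree inclusion range, Risser 0/1/2 in
#' proportions 56/22/22, intensity assigned from
#' [default_intensity_policy()], and an 11% dropout rate.
#'
#' `effect_by_intensity` (mean end-minus-start Cobb change per intensity,
#' negative = improvement) and `outcome_sd` are calibration knobs of the
#' generator, not estimates from any clinical dataset; tests must not read
#' them as ground truth about scoliosis.
#'
#' @param n_patients Number of patients (>= 0).
#' @param seed Integer random seed; the generator is fully deterministic
#'   given the seed.
#' @param female_fraction Probability of female sex.
#' @param age_mean,age_sd Age at first consultation (years).
#' @param cobb_start_mean,cobb_start_sd Baseline Cobb (degrees) before
#'   truncation to `[11, 45]`.
#' @param risser_probs Probabilities of Risser 0, 1, 2 at the start.
#' @param intensity_policy Tibble as from [default_intensity_policy()]:
#'   `band`, `risser`, `p0`–`p6`, rows summing to 1.
#' @param effect_by_intensity Named numeric vector (`"0"`–`"6"`): mean Cobb
#'   change (degrees) at end of growth for each intensity.
#' @param outcome_sd Biological plus measurement spread (degrees) around
#'   the mean change.
#' @param measurement_error_sd Pure radiographic error (degrees) added
#'   independently to the recorded start and end angles; 0 disables. The
#'   conventional 5-degree Cobb reading error corresponds to sd ~ 2.5.
#' @param dropout_prob,in_treatment_prob Probabilities of the `dropout`
#'   and `in_treatment` statuses (remainder completes).
#' @return A validated `synthetic_params` list.
#' @export
synthetic_params <- function(n_patients,
                             seed,
                             female_fraction = 0.83,
                             age_mean = 12.7, age_sd = 1.3,
                             cobb_start_mean = 24, cobb_start_sd = 8,
                             risser_probs = c(0.56, 0.22, 0.22),
                             intensity_policy = default_intensity_policy(),
                             effect_by_intensity = c("0" = 6, "1" = 3,
                                                     "2" = 1, "3" = -2,
                                                     "4" = -3, "5" = -4,
                                                     "6" = -6),
                             outcome_sd = 6,
                             measurement_error_sd = 0,
                             dropout_prob = 0.11,
                             in_treatment_prob = 0) {
  stopifnot(length(n_patients) == 1, n_patients >= 0,
            n_patients == round(n_patients),
            length(seed) == 1, is.finite(seed))
  probs_ok <- function(p) all(p >= 0) && abs(sum(p) - 1) < 1e-9
  if (!probs_ok(risser_probs) || length(risser_probs) != 3) {
    stop("risser_probs must be 3 non-negative values summing to 1",
         call. = FALSE)
  }
  for (p in c(female_fraction, dropout_prob, in_treatment_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]",
                             call. = FALSE)
  }
  if (dropout_prob + in_treatment_prob > 1) {
    stop("dropout_prob + in_treatment_prob must not exceed 1", call. = FALSE)
  }
  if (any(c(age_sd, cobb_start_sd, outcome_sd, measurement_error_sd) < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  pol <- as_tibble(intensity_policy)
  pcols <- paste0("p", 0:6)
  stopifnot(all(c("band", "risser", pcols) %in% names(pol)))
  pm <- as.matrix(pol[pcols])
  if (any(pm < 0) || any(abs(rowSums(pm) - 1) > 1e-9)) {
    stop("each intensity_policy row must be a probability vector",
         call. = FALSE)
  }
  if (!setequal(paste(pol$band, pol$risser),
                paste(rep(band_levels, each = 3), rep(0:2, 4)))) {
    stop("intensity_policy must cover all 12 (band, risser) cells",
         call. = FALSE)
  }
  if (!identical(sort(names(effect_by_intensity)), as.character(0:6))) {
    stop("effect_by_intensity must be named '0'..'6'", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    female_fraction = female_fraction,
    age_mean = age_mean, age_sd = age_sd,
    cobb_start_mean = cobb_start_mean, cobb_start_sd = cobb_start_sd,
    risser_probs = risser_probs, intensity_policy = pol,
    effect_by_intensity = effect_by_intensity[as.character(0:6)],
    outcome_sd = outcome_sd, measurement_error_sd = measurement_error_sd,
    dropout_prob = dropout_prob, in_treatment_prob = in_treatment_prob
  ), class = "synthetic_params")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic scoliosis cohort
#'
#' Draws one wide cohort table from the generative model described in
#' [synthetic_params()]: baseline characteristics, a treatment intensity
#' sampled from the (Cobb band x Risser) policy, an end-of-growth Cobb
#' angle equal to the start plus the intensity's mean effect plus
#' `Normal(0, outcome_sd)` noise (floored at 0), optional independent
#' radiographic reading error on both angles, and a status draw.
#' Dropouts keep their last observed Cobb angle but no end Risser stage;
#' patients still in treatment have no end measurements. All generated
#' patients are in charge (`n_visits >= 3`), unbraced at first visit and
#' have valid radiograph windows, so [apply_study_filters()] retains them.
#'
#' @param params A [synthetic_params()] object.
#' @return A validated cohort tibble; byte-identical across calls with
#'   equal `params`.
#' @examples
#' coh <- generate_cohort(synthetic_params(n_patients = 50, seed = 7))
#' table(coh$treatment_intensity)
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "synthetic_params")) {
    stop("params must come from synthetic_params()", call. = FALSE)
  }
  n <- params$n_patients
  empty <- tibble(
    patient_id = character(0), sex = character(0), age_start = numeric(0),
    height_start = numeric(0), menarche_status = character(0),
    cobb_start = numeric(0), cobb_end = numeric(0),
    risser_start = integer(0), risser_end = integer(0),
    apex_level = character(0), prior_treatment = logical(0),
    braced_at_first_visit = logical(0), n_visits = integer(0),
    treatment_intensity = integer(0), treatment_years = numeric(0),
    status = character(0), xray_window_ok = logical(0)
  )
  if (n == 0) return(validate_cohort(empty))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  sex <- ifelse(stats::runif(n) < params$female_fraction, "female", "male")
  age <- stats::rnorm(n, params$age_mean, params$age_sd)
  height <- stats::rnorm(n, 157, 9.2)
  cobb_true <- round(rtruncnorm(n, params$cobb_start_mean,
                                params$cobb_start_sd, 11, 45), 1)
  risser <- sample(0:2, n, replace = TRUE, prob = params$risser_probs)
  band <- cobb_band(cobb_true)

  # intensity: one multinomial draw per (band, risser) policy cell
  pol <- params$intensity_policy
  cell_key <- paste(band, risser)
  pol_key <- paste(pol$band, pol$risser)
  pm <- as.matrix(pol[paste0("p", 0:6)])
  cum <- t(apply(pm, 1, cumsum))
  u <- stats::runif(n)
  row_idx <- match(cell_key, pol_key)
  intensity <- rowSums(u > cum[row_idx, , drop = FALSE])  # 0..6

  effect <- params$effect_by_intensity[as.character(intensity)]
  cobb_end_true <- pmax(0, cobb_true + effect +
                          stats::rnorm(n, 0, params$outcome_sd))

  me <- params$measurement_error_sd
  cobb_start_obs <- cobb_true
  cobb_end_obs <- round(cobb_end_true, 1)
  if (me > 0) {
    cobb_start_obs <- round(pmin(45, pmax(11, cobb_true +
                                            stats::rnorm(n, 0, me))), 1)
    cobb_end_obs <- round(pmax(0, cobb_end_true + stats::rnorm(n, 0, me)), 1)
  }

  status <- sample(c("dropout", "in_treatment", "completed"), n,
                   replace = TRUE,
                   prob = c(params$dropout_prob, params$in_treatment_prob,
                            1 - params$dropout_prob -
                              params$in_treatment_prob))

  menarche <- rep("unknown", n)
  fem <- sex == "female"
  menarche[fem] <- sample(menarche_levels[1:3], sum(fem), replace = TRUE,
                          prob = c(0.55, 0.25, 0.20))
  apex <- sample(c(paste0("T", 5:12), paste0("L", 1:2)), n, replace = TRUE,
                 prob = c(2, 4, 7, 12, 14, 12, 8, 6, 5, 3))
  years <- pmax(0.5, stats::rnorm(n, 3.7, 2.1))
  years[status == "dropout"] <- pmax(0.25,
                                     stats::rnorm(sum(status == "dropout"),
                                                  1.8, 0.8))
  visits <- 3L + stats::rpois(n, 2 * years)

  coh <- tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    sex = sex,
    age_start = round(age, 2),
    height_start = round(height, 1),
    menarche_status = menarche,
    cobb_start = cobb_start_obs,
    cobb_end = ifelse(status == "in_treatment", NA_real_, cobb_end_obs),
    risser_start = as.integer(risser),
    risser_end = ifelse(status == "completed", 4L, NA_integer_),
    apex_level = apex,
    prior_treatment = stats::runif(n) < 0.05,
    braced_at_first_visit = FALSE,
    n_visits = as.integer(visits),
    treatment_intensity = as.integer(intensity),
    treatment_years = round(years, 2),
    status = status,
    xray_window_ok = TRUE
  )
  validate_cohort(coh)
}

#' Simulate success counts for two arms
#'
#' Binomial fixture generator for effect-measure recovery experiments: one
#' draw of successes per arm at the stated success probabilities.
#'
#' @param p_success_a,p_success_b Success probabilities in `[0, 1]`.
#' @param n_a,n_b Arm sizes (>= 0).
#' @param seed Integer seed; deterministic given the seed.
#' @return A [two_by_two()] table (degenerate and flagged if an arm is
#'   empty).
#' @export
generate_two_arm_counts <- function(p_success_a, n_a, p_success_b, n_b,
                                    seed) {
  stopifnot(p_success_a >= 0, p_success_a <= 1,
            p_success_b >= 0, p_success_b <= 1, n_a >= 0, n_b >= 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  sa <- stats::rbinom(1, n_a, p_success_a)
  sb <- stats::rbinom(1, n_b, p_success_b)
  two_by_two(sa, n_a - sa, sb, n_b - sb,
             label_a = "arm_a", label_b = "arm_b")
}
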