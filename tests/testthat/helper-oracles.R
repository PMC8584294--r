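# Independent scalar transcription of the printed aims / over- /
# under-treatment rules, one band row at a time. Deliberately written as
# plain if/else so it shares no code path with the vectorised classifiers
# it checks.
oracle_rules <- function(s, e, intensity) {
  if (s >= 11 && s <= 20) {
    primary <- e < 20
    minimal <- e < 45
    over <- (s - e) > 5
    under <- e > 30
  } else if (s > 20 && s <= 25) {
    primary <- e < 30
    minimal <- e < 45
    over <- (s - e) > 5 + (s - 20) / 2 && e < 30
    under <- e > 30
  } else if (s > 25 && s <= 30) {
    primary <- e < 30
    minimal <- e < 45
    over <- (s - e) > 5 + (s - 20) / 2 && e < 30
    under <- if (s < 30) e > 30 else (e - s > 5 && intensity < 6)
  } else if (s > 30 && s <= 40) {
    primary <- e < 30
    minimal <- e < 45
    over <- (s - e) > 5 + (s - 20) / 2 && e < 30
    under <- e - s > 5 && intensity < 6
  } else if (s > 40 && s <= 45) {
    primary <- e < 45
    minimal <- e < 60
    over <- FALSE
    under <- e > 60
  } else {
    stop("start angle outside the study range")
  }
  list(primary = primary, minimal = minimal, over = over, under = under)
}

# Closed form of the 2x2 Pearson statistic.
chi2_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# A valid single patient row with overridable fields.
patient_row <- function(patient_id = "P1", sex = "female",
                        age_start = 12.5, height_start = 155,
                        menarche_status = "premenarchal",
                        cobb_start = 25, cobb_end = 27,
                        risser_start = 1L, risser_end = 4L,
                        apex_level = "T9", prior_treatment = FALSE,
                        braced_at_first_visit = FALSE, n_visits = 5L,
                        treatment_intensity = 3L, treatment_years = 3,
                        status = "completed", xray_window_ok = TRUE) {
  tibble::tibble(
    patient_id = patient_id, sex = sex, age_start = age_start,
    height_start = height_start, menarche_status = menarche_status,
    cobb_start = cobb_start, cobb_end = cobb_end,
    risser_start = as.integer(risser_start),
    risser_end = as.integer(risser_end), apex_level = apex_level,
    prior_treatment = prior_treatment,
    braced_at_first_visit = braced_at_first_visit,
    n_visits = as.integer(n_visits),
    treatment_intensity = as.integer(treatment_intensity),
    treatment_years = treatment_years, status = status,
    xray_window_ok = xray_window_ok
  )
}
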