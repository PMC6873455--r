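# Shared fixtures: tiny hand-traceable tables and a small-but-complete
# simulation config. Everything is built in code at test time.

# a quiet config for clean statistical checks: one procedure, no planted
# exclusions, no lookback/post-acute noise unless asked for
quiet_config <- function(n_hrrs = 10, episodes_per_hrr = 20, seed = 1,
                         tau_true = 0.04, outcome_cv = 0.5, ...) {
  sim_config(n_hrrs = n_hrrs, episodes_per_hrr = episodes_per_hrr,
             procedures = "PHR", tau_true = tau_true,
             outcome_cv = outcome_cv,
             exclusion_rates = c(dual_coverage = 0), seed = seed, ...)
}

# model frame taken straight from ground truth (bypasses episode building)
truth_frame <- function(sim) {
  tr <- sim$truth$episodes
  b <- sim$beneficiaries
  tibble::tibble(
    hrr_id = tr$hrr_id,
    total = tr$total_std,
    index_hospitalization = tr$index_std,
    readmissions = tr$readmission_std,
    post_acute = tr$post_acute_std,
    professional_fees = tr$professional_std,
    age = b$age, sex = b$sex,
    race = ifelse(is.na(b$race), b$sponsor_race, b$race),
    junior_enlisted = b$sponsor_rank_category == "junior_enlisted",
    charlson = b$charlson,
    prior_6mo_payments = tr$prior_std
  )
}

recovery_covariates <- c("age", "sex", "race", "junior_enlisted", "charlson",
                         "prior")

# one hand-written claims fixture used across episode/payment tests:
# beneficiary B1 has a PHR index claim with a full spread of window claims
hand_claims <- function() {
  tibble::tibble(
    claim_id = sprintf("C%02d", 1:10),
    beneficiary_id = c("B1", "B1", "B1", "B1", "B1", "B1", "B1", "B1",
                       "B2", "B2"),
    claim_class = c("inpatient_facility", "professional", "inpatient_facility",
                    "snf", "professional", "outpatient_facility",
                    "outpatient_facility", "outpatient_facility",
                    "inpatient_facility", "professional"),
    admission_date = c(100L, NA, 135L, NA, NA, NA, NA, NA, 300L, NA),
    discharge_date = c(105L, NA, 137L, NA, NA, NA, NA, NA, 304L, NA),
    service_date = c(100L, 102L, 135L, 120L, 140L, 195L, 196L, 50L, 300L, 310L),
    provider_zip = "Z1",
    paid_amount = c(10000, 800, 5000, 1000, 300, 200, 150, 100, 9000, 500),
    procedure_codes = c("P8151", "", "P9999", "", "", "", "", "", "P8151",
                        "P8151"),
    diagnosis_codes = "",
    drg_weight = NA_real_,
    admission_source = c("home", NA, "home", NA, NA, NA, NA, NA, "home", NA),
    discharge_status = c("home", NA, "home", NA, NA, NA, NA, NA, "home", NA),
    emergent = c(FALSE, NA, FALSE, NA, NA, NA, NA, NA, FALSE, NA)
  )
}

hand_beneficiaries <- function() {
  tibble::tibble(
    beneficiary_id = c("B1", "B2"),
    age = c(55, 48),
    sex = c("F", "M"),
    race = c("white", NA),
    sponsor_race = c("white", "black"),
    sponsor_rank_category = c("senior_enlisted", "junior_enlisted"),
    charlson = c(0L, 1L),
    dual_coverage = c(FALSE, FALSE)
  )
}

hand_crosswalk <- function() {
  tibble::tibble(zip = "Z1", hrr_id = "HRR001", wage_index = 1.0)
}
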