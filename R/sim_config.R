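#' Simulation configuration for the synthetic claims generator
#'
#' Bundles every knob of the generative model: the number of hospital
#' referral regions (HRRs), episode volume, true case-mix coefficients on
#' the log scale, the between-HRR variance of the multiplicative regional
#' effect, episode-level cost noise, regional wage-index price inflation,
#' the expected split of episode cost over the four payment components,
#' readmission and post-acute utilisation rates, and the rates at which
#' records carrying each exclusion trigger are planted.
#'
#' Defaults describe a universally insured working-age (18-65) surgical
#' population: five index procedures with readmission probabilities of
#' 6% (hip replacement, PHR), 6% (knee replacement, PKR), 13% (coronary
#' bypass, CABG), 7% (lumbar spinal fusion, LSF) and 20% (colectomy); a
#' 20% dual-coverage rate; and rare (<1%) facility-source admissions and
#' in-hospital deaths.
#'
#' @param n_hrrs number of HRRs.
#' @param episodes_per_hrr episodes per HRR: a single count or a
#'   length-2 inclusive range sampled uniformly.
#' @param procedures character vector of procedure names; must match
#'   names in `procedure_intercepts`, `procedure_mix` and
#'   `readmission_prob`.
#' @param beta_true named numeric, true log-scale case-mix coefficients
#'   over the generator's covariate dictionary (`age_c`, `age_c2`,
#'   `male`, `junior_enlisted`, `charlson`, `log1p_prior`, `drg_weight`,
#'   `emergent`, `cancer`). Unnamed covariates default to zero effect.
#' @param procedure_intercepts named numeric, per-procedure intercept on
#'   the log-cost scale.
#' @param procedure_mix named numeric, multinomial procedure shares
#'   (normalised internally).
#' @param tau_true between-HRR variance of the multiplicative regional
#'   effect (gamma with mean 1, variance `tau_true`).
#' @param outcome_cv coefficient of variation of episode-level cost noise
#'   (gamma distributed; 0 means noise free).
#' @param wage_index_range length-2 positive interval around 1 from which
#'   each locality's wage index is drawn uniformly.
#' @param labor_share labor-related fraction of payments subject to the
#'   wage index, in \[0, 1\].
#' @param component_mix named non-negative numeric: expected fractions of
#'   episode cost for `index_hospitalization`, `readmissions`,
#'   `post_acute`, `professional_fees` (normalised internally).
#' @param readmission_prob named numeric, per-procedure probability of an
#'   inpatient readmission within the 90-day window.
#' @param postacute_claim_rate Poisson mean number of post-acute claims
#'   per episode.
#' @param lookback_claim_rate Poisson mean number of claims per episode
#'   in the 183-day pre-admission lookback.
#' @param exclusion_rates named numeric probabilities for planted
#'   exclusion triggers: `dual_coverage`, `trauma` (PHR/PKR only),
#'   `multilevel_fusion` (LSF only), `non_elective` (an emergent index
#'   admission for an elective-only procedure), `admitted_from_facility`,
#'   `died_before_discharge`, `day91_claim` (an out-of-window claim at
#'   day 91, a window-boundary probe rather than an exclusion).
#' @param confound_strength standard deviation of an HRR-level shift in
#'   mean Charlson burden (case-mix confounding between regions); 0
#'   disables confounding.
#' @param seed integer seed; all randomness flows from it.
#' @return a validated `bv_sim_config` list.
#' @export
sim_config <- function(n_hrrs = 40,
                       episodes_per_hrr = c(80, 120),
                       procedures = c("PHR", "PKR", "CABG", "LSF", "colectomy"),
                       beta_true = c(age_c = 0.04, age_c2 = 0.01, male = 0.02,
                                     junior_enlisted = -0.06, charlson = 0.12,
                                     log1p_prior = 0.02, drg_weight = 0.35,
                                     emergent = 0.20, cancer = 0.25),
                       procedure_intercepts = c(PHR = log(15000), PKR = log(16000),
                                                CABG = log(33000), LSF = log(27000),
                                                colectomy = log(22000)),
                       procedure_mix = c(PHR = 0.15, PKR = 0.28, CABG = 0.07,
                                         LSF = 0.44, colectomy = 0.06),
                       tau_true = 0.04,
                       outcome_cv = 0.9,
                       wage_index_range = c(0.85, 1.25),
                       labor_share = 0.62,
                       component_mix = c(index_hospitalization = 0.68,
                                         readmissions = 0.08,
                                         post_acute = 0.04,
                                         professional_fees = 0.20),
                       readmission_prob = c(PHR = 0.06, PKR = 0.06, CABG = 0.13,
                                            LSF = 0.07, colectomy = 0.20),
                       postacute_claim_rate = 0.8,
                       lookback_claim_rate = 2,
                       exclusion_rates = c(dual_coverage = 0.20,
                                           trauma = 0.02,
                                           multilevel_fusion = 0.02,
                                           non_elective = 0.02,
                                           admitted_from_facility = 0.005,
                                           died_before_discharge = 0.005,
                                           day91_claim = 0.05),
                       confound_strength = 0,
                       seed = 1L) {
  cfg <- list(
    n_hrrs = n_hrrs, episodes_per_hrr = episodes_per_hrr,
    procedures = procedures, beta_true = beta_true,
    procedure_intercepts = procedure_intercepts,
    procedure_mix = procedure_mix, tau_true = tau_true,
    outcome_cv = outcome_cv, wage_index_range = wage_index_range,
    labor_share = labor_share, component_mix = component_mix,
    readmission_prob = readmission_prob,
    postacute_claim_rate = postacute_claim_rate,
    lookback_claim_rate = lookback_claim_rate,
    exclusion_rates = exclusion_rates,
    confound_strength = confound_strength,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "bv_sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    bv_abort(sprintf("invalid simulation config field '%s': %s", field, why),
             "bundlevar_config_error")
  }
  if (!is.numeric(cfg$n_hrrs) || length(cfg$n_hrrs) != 1 || cfg$n_hrrs < 1)
    fail("n_hrrs", "must be a positive count")
  if (!is.numeric(cfg$episodes_per_hrr) ||
      !length(cfg$episodes_per_hrr) %in% c(1, 2) ||
      any(cfg$episodes_per_hrr < 1))
    fail("episodes_per_hrr", "must be a positive count or length-2 range")
  if (length(cfg$procedures) < 1)
    fail("procedures", "must name at least one procedure")
  for (fld in c("procedure_intercepts", "procedure_mix", "readmission_prob")) {
    miss <- setdiff(cfg$procedures, names(cfg[[fld]]))
    if (length(miss) > 0)
      fail(fld, paste("missing entries for", paste(miss, collapse = ", ")))
  }
  if (!is.numeric(cfg$tau_true) || cfg$tau_true < 0)
    fail("tau_true", "must be >= 0")
  if (!is.numeric(cfg$outcome_cv) || cfg$outcome_cv < 0)
    fail("outcome_cv", "must be >= 0")
  if (length(cfg$wage_index_range) != 2 || any(cfg$wage_index_range <= 0) ||
      diff(cfg$wage_index_range) < 0)
    fail("wage_index_range", "must be a positive non-decreasing interval")
  if (cfg$labor_share < 0 || cfg$labor_share > 1)
    fail("labor_share", "must lie in [0, 1]")
  comp <- c("index_hospitalization", "readmissions", "post_acute",
            "professional_fees")
  if (!all(comp %in% names(cfg$component_mix)) || any(cfg$component_mix < 0) ||
      sum(cfg$component_mix) <= 0)
    fail("component_mix", "needs non-negative entries for all four components")
  probs <- c(cfg$readmission_prob[cfg$procedures], cfg$exclusion_rates)
  if (any(probs < 0 | probs > 1))
    fail(if (any(cfg$readmission_prob[cfg$procedures] < 0 |
                 cfg$readmission_prob[cfg$procedures] > 1))
           "readmission_prob" else "exclusion_rates",
         "probabilities must lie in [0, 1]")
  if (cfg$postacute_claim_rate < 0)
    fail("postacute_claim_rate", "must be >= 0")
  if (cfg$confound_strength < 0)
    fail("confound_strength", "must be >= 0")
  invisible(cfg)
}
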