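# Synthetic claims generator.
#
# Cost model: standardized episode total ~ Gamma with mean
#   mu_ij = exp(x_ij' beta) * u_j,   u_j ~ Gamma(shape 1/tau, rate 1/tau)
# (mean-1 multiplicative HRR effect, variance tau), episode noise with the
# configured CV. Paid amounts on claims are the standardized amounts
# inflated by labor_share * wage_index + (1 - labor_share) — the exact
# inverse of standardize_payment().

exclusion_rate <- function(cfg, reason) {
  x <- cfg$exclusion_rates[reason]
  if (length(x) == 0 || is.na(x)) 0 else unname(x)
}

#' Generate the synthetic beneficiary population and geography
#'
#' Draws one provider zip per HRR with a uniform wage index, a mean-1
#' gamma-distributed multiplicative cost effect per HRR with variance
#' `tau_true`, and a beneficiary per planned episode carrying age (18-65),
#' sex, race (with occasional missingness backed by a sponsor race),
#' sponsor-rank category, Charlson index and a dual-coverage flag.
#'
#' @param config a [sim_config()] object.
#' @return list with `beneficiaries`, `crosswalk` (zip, hrr_id,
#'   wage_index) and `truth` (a `bv_ground_truth` holding `u_by_hrr`,
#'   `beta_true`, `tau_true` and the per-episode plan).
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  hrr_id <- sprintf("HRR%03d", seq_len(cfg$n_hrrs))
  crosswalk <- tibble::tibble(
    zip = sprintf("Z%05d", seq_len(cfg$n_hrrs)),
    hrr_id = hrr_id,
    wage_index = stats::runif(cfg$n_hrrs, cfg$wage_index_range[1],
                              cfg$wage_index_range[2])
  )

  u <- if (cfg$tau_true == 0) rep(1, cfg$n_hrrs) else
    stats::rgamma(cfg$n_hrrs, shape = 1 / cfg$tau_true, rate = 1 / cfg$tau_true)
  names(u) <- hrr_id

  n_ep <- if (length(cfg$episodes_per_hrr) == 1)
    rep(cfg$episodes_per_hrr, cfg$n_hrrs)
  else
    sample(cfg$episodes_per_hrr[1]:cfg$episodes_per_hrr[2], cfg$n_hrrs,
           replace = TRUE)
  n_total <- sum(n_ep)
  ep_hrr <- rep(hrr_id, n_ep)

  # region-level shift in comorbidity burden (case-mix confounding)
  charlson_shift <- stats::rnorm(cfg$n_hrrs, 0, cfg$confound_strength)
  names(charlson_shift) <- hrr_id
  charlson_mean <- pmax(0.05, 0.4 + charlson_shift[ep_hrr])

  mix <- cfg$procedure_mix[cfg$procedures] / sum(cfg$procedure_mix[cfg$procedures])
  procedure <- if (length(cfg$procedures) == 1)
    rep(cfg$procedures, n_total)
  else
    sample(cfg$procedures, n_total, replace = TRUE, prob = mix)

  race_pool <- c("white", "black", "other")
  true_race <- sample(race_pool, n_total, replace = TRUE, prob = c(0.6, 0.2, 0.2))
  race_missing <- stats::runif(n_total) < 0.05

  beneficiaries <- tibble::tibble(
    beneficiary_id = sprintf("B%06d", seq_len(n_total)),
    age = sample(18:65, n_total, replace = TRUE),
    sex = sample(c("F", "M"), n_total, replace = TRUE),
    race = ifelse(race_missing, NA_character_, true_race),
    sponsor_race = true_race,
    sponsor_rank_category = sample(
      c("junior_enlisted", "senior_enlisted", "officer"), n_total,
      replace = TRUE, prob = c(0.35, 0.45, 0.20)),
    charlson = stats::rpois(n_total, charlson_mean),
    dual_coverage = stats::runif(n_total) < exclusion_rate(cfg, "dual_coverage")
  )

  elective_only <- c(PHR = TRUE, PKR = TRUE, CABG = FALSE, LSF = TRUE,
                     colectomy = FALSE)[procedure]
  elective_only[is.na(elective_only)] <- TRUE

  plan <- tibble::tibble(
    episode_id = sprintf("E%06d", seq_len(n_total)),
    beneficiary_id = beneficiaries$beneficiary_id,
    hrr_id = ep_hrr,
    zip = crosswalk$zip[match(ep_hrr, crosswalk$hrr_id)],
    procedure = procedure,
    admission_date = sample(250:1100, n_total, replace = TRUE),
    los = sample(2:6, n_total, replace = TRUE),
    # planted exclusion and window triggers
    trig_trauma = procedure %in% c("PHR", "PKR") &
      stats::runif(n_total) < exclusion_rate(cfg, "trauma"),
    trig_fusion = procedure == "LSF" &
      stats::runif(n_total) < exclusion_rate(cfg, "multilevel_fusion"),
    trig_non_elective = elective_only &
      stats::runif(n_total) < exclusion_rate(cfg, "non_elective"),
    trig_facility = stats::runif(n_total) <
      exclusion_rate(cfg, "admitted_from_facility"),
    trig_died = stats::runif(n_total) <
      exclusion_rate(cfg, "died_before_discharge"),
    trig_day91 = stats::runif(n_total) < exclusion_rate(cfg, "day91_claim"),
    emergent = (!elective_only & stats::runif(n_total) < 0.3),
    cancer = procedure == "colectomy" & stats::runif(n_total) < 0.5,
    drg_weight = ifelse(procedure %in% c("CABG", "LSF", "colectomy"),
                        stats::rlnorm(n_total, 0, 0.25), NA_real_)
  )
  plan$emergent <- plan$emergent | plan$trig_non_elective
  plan$discharge_date <- plan$admission_date + plan$los
  plan$trig_dual <- beneficiaries$dual_coverage

  truth <- structure(list(
    u_by_hrr = u,
    tau_true = cfg$tau_true,
    beta_true = cfg$beta_true,
    procedure_intercepts = cfg$procedure_intercepts,
    charlson_shift = charlson_shift,
    episodes = plan
  ), class = "bv_ground_truth")

  list(beneficiaries = beneficiaries, crosswalk = crosswalk, truth = truth)
}

# split a cents-rounded total across k parts, remainder to the first part
split_cents <- function(total, weights) {
  parts <- round(total * weights / sum(weights), 2)
  parts[1] <- parts[1] + round(total - sum(parts), 2)
  parts
}

#' Generate the synthetic claims table
#'
#' Realizes each planned episode into claims: the index inpatient facility
#' claim, an optional inpatient readmission (admitted uniformly in days
#' 1-90 after discharge), Poisson-many post-acute claims across the
#' post-acute claim classes, professional claims, lookback claims in the
#' 183 days before admission, and — where planted — an out-of-window
#' claim at day 91. Episode totals follow the log-linear cost model with
#' the HRR's multiplicative effect; component amounts are exact cents
#' summing to the episode total; paid amounts are wage-index inflated.
#'
#' @param config a [sim_config()] object.
#' @param population output of [generate_population()].
#' @return list with `claims` (tibble) and an updated `truth` whose
#'   episode table gains true expected cost (`mu_true`), realized
#'   standardized totals, component amounts and claim ids.
#' @export
generate_claims <- function(config, population) {
  validate_sim_config(config)
  cfg <- config
  ben <- population$beneficiaries
  xw <- population$crosswalk
  plan <- population$truth$episodes
  if (!all(plan$beneficiary_id %in% ben$beneficiary_id) ||
      !all(plan$zip %in% xw$zip))
    bv_abort("population tables are inconsistent (beneficiary or zip not found)",
             "bundlevar_integrity_error")
  set.seed(cfg$seed + 1L)

  n <- nrow(plan)
  b <- ben[match(plan$beneficiary_id, ben$beneficiary_id), ]
  wage_index <- xw$wage_index[match(plan$zip, xw$zip)]
  inflate <- cfg$labor_share * wage_index + (1 - cfg$labor_share)

  # ---- lookback claims (contribute the prior-spending covariate) ----
  n_lb <- stats::rpois(n, cfg$lookback_claim_rate)
  lb_ep <- rep(seq_len(n), n_lb)
  lb_std <- round(stats::rlnorm(sum(n_lb), log(400), 0.8), 2)
  lb_day <- plan$admission_date[lb_ep] - sample(183, sum(n_lb), replace = TRUE)
  lb_class <- sample(c("outpatient_facility", "professional"), sum(n_lb),
                     replace = TRUE, prob = c(0.6, 0.4))
  prior_std <- rep(0, n)
  if (length(lb_ep) > 0) {
    agg <- tapply(lb_std, lb_ep, sum)
    prior_std[as.integer(names(agg))] <- as.numeric(agg)
  }

  # ---- linear predictor over the covariate dictionary ----
  beta <- cfg$beta_true
  bget <- function(nm) unname(if (nm %in% names(beta)) beta[nm] else 0)
  age_c <- (b$age - 40) / 10
  x <- cbind(
    age_c = age_c, age_c2 = age_c^2, male = as.numeric(b$sex == "M"),
    junior_enlisted = as.numeric(b$sponsor_rank_category == "junior_enlisted"),
    charlson = b$charlson, log1p_prior = log1p(prior_std),
    drg_weight = ifelse(is.na(plan$drg_weight), 0, plan$drg_weight),
    emergent = as.numeric(plan$emergent), cancer = as.numeric(plan$cancer)
  )
  eta <- cfg$procedure_intercepts[plan$procedure] +
    as.numeric(x %*% vapply(colnames(x), bget, 0))
  u_ep <- population$truth$u_by_hrr[plan$hrr_id]
  mu_true <- exp(eta) * u_ep

  total_std <- if (cfg$outcome_cv == 0) mu_true else
    stats::rgamma(n, shape = 1 / cfg$outcome_cv^2,
                  rate = 1 / (cfg$outcome_cv^2 * mu_true))
  total_std <- round(pmax(total_std, 50), 2)

  # ---- component split (zeroed components redistribute to the rest) ----
  readmit <- stats::runif(n) < cfg$readmission_prob[plan$procedure]
  n_post <- stats::rpois(n, cfg$postacute_claim_rate)
  comp_names <- c("index_hospitalization", "readmissions", "post_acute",
                  "professional_fees")
  w <- matrix(rep(cfg$component_mix[comp_names], each = n), nrow = n,
              dimnames = list(NULL, comp_names))
  w[!readmit, "readmissions"] <- 0
  w[n_post == 0, "post_acute"] <- 0
  comp <- t(vapply(seq_len(n),
                   function(i) split_cents(total_std[i], w[i, ]),
                   numeric(4)))
  colnames(comp) <- comp_names

  # ---- claim rows ----
  claim_row <- function(ep, claim_class, admission_date, discharge_date,
                        service_date, paid_std, procedure_codes = "",
                        diagnosis_codes = "", drg_weight = NA_real_,
                        admission_source = NA_character_,
                        discharge_status = NA_character_, emergent = NA) {
    tibble::tibble(
      ep = ep, beneficiary_id = plan$beneficiary_id[ep],
      claim_class = claim_class, admission_date = admission_date,
      discharge_date = discharge_date, service_date = service_date,
      provider_zip = plan$zip[ep],
      paid_amount = unname(paid_std * inflate[ep]),
      procedure_codes = procedure_codes, diagnosis_codes = diagnosis_codes,
      drg_weight = drg_weight, admission_source = admission_source,
      discharge_status = discharge_status, emergent = emergent
    )
  }

  index_codes <- c(PHR = "P8151", PKR = "P8154", CABG = "P3610",
                   LSF = "P8106", colectomy = "P1735")
  proc_codes <- index_codes[plan$procedure]
  proc_codes[plan$trig_fusion] <- paste(proc_codes[plan$trig_fusion], "P8107",
                                        sep = ";")
  dx <- ifelse(plan$trig_trauma, "D8080", "")
  dx <- ifelse(plan$cancer, paste0(dx, ifelse(dx == "", "", ";"), "D1530"), dx)

  idx <- claim_row(
    seq_len(n), "inpatient_facility", plan$admission_date,
    plan$discharge_date, plan$admission_date, comp[, "index_hospitalization"],
    procedure_codes = proc_codes, diagnosis_codes = dx,
    drg_weight = plan$drg_weight,
    admission_source = ifelse(plan$trig_facility,
                              sample(c("snf", "ltc", "hospice"), n, TRUE),
                              "home"),
    discharge_status = ifelse(plan$trig_died, "died", "home"),
    emergent = plan$emergent
  )

  re_ep <- which(readmit)
  re_adm <- plan$discharge_date[re_ep] + sample(90, length(re_ep), replace = TRUE)
  readm <- claim_row(re_ep, "inpatient_facility", re_adm, re_adm + 2, re_adm,
                     comp[re_ep, "readmissions"], procedure_codes = "P9999",
                     admission_source = "home", discharge_status = "home",
                     emergent = FALSE)

  pa_ep <- rep(seq_len(n), n_post)
  pa_classes <- c("snf", "rehab", "home_health", "hospice", "dme",
                  "outpatient_facility")
  pa_amt <- unlist(lapply(which(n_post > 0), function(i)
    split_cents(comp[i, "post_acute"], rep(1, n_post[i]))), use.names = FALSE)
  postacute <- claim_row(
    pa_ep, sample(pa_classes, length(pa_ep), replace = TRUE),
    NA_integer_, NA_integer_,
    plan$discharge_date[pa_ep] + sample(90, length(pa_ep), replace = TRUE),
    if (length(pa_ep) > 0) pa_amt else numeric(0)
  )

  prof_split <- t(vapply(seq_len(n), function(i)
    split_cents(comp[i, "professional_fees"], c(0.6, 0.4)), numeric(2)))
  prof1 <- claim_row(seq_len(n), "professional", NA_integer_, NA_integer_,
                     plan$admission_date + 1, prof_split[, 1])
  prof2 <- claim_row(seq_len(n), "professional", NA_integer_, NA_integer_,
                     plan$discharge_date + sample(5:60, n, replace = TRUE),
                     prof_split[, 2])

  lookback <- claim_row(lb_ep, lb_class, NA_integer_, NA_integer_, lb_day,
                        lb_std)

  d91_ep <- which(plan$trig_day91)
  day91 <- claim_row(d91_ep, "outpatient_facility", NA_integer_, NA_integer_,
                     plan$discharge_date[d91_ep] + 91L, rep(500, length(d91_ep)))

  claims <- dplyr::bind_rows(idx, readm, postacute, prof1, prof2, lookback,
                             day91)
  claims$claim_id <- sprintf("C%07d", seq_len(nrow(claims)))
  # tag roles so tests can find planted records; downstream code ignores this
  claims$sim_role <- rep(
    c("index", "readmission", "post_acute", "professional", "professional",
      "lookback", "day91"),
    c(nrow(idx), nrow(readm), nrow(postacute), nrow(prof1), nrow(prof2),
      nrow(lookback), nrow(day91)))

  truth <- population$truth
  truth$episodes <- dplyr::mutate(
    plan,
    mu_true = mu_true, eta_true = eta, u_true = unname(u_ep),
    total_std = total_std,
    index_std = comp[, "index_hospitalization"],
    readmission_std = comp[, "readmissions"],
    post_acute_std = comp[, "post_acute"],
    professional_std = comp[, "professional_fees"],
    prior_std = prior_std,
    index_claim_id = claims$claim_id[match(seq_len(n), claims$ep)]
  )
  truth$episodes$day91_claim_id <- claims$claim_id[
    match(seq_len(n), ifelse(claims$sim_role == "day91", claims$ep, NA))]

  claims <- dplyr::select(
    claims, "claim_id", "beneficiary_id", "claim_class", "admission_date",
    "discharge_date", "service_date", "provider_zip", "paid_amount",
    "procedure_codes", "diagnosis_codes", "drg_weight", "admission_source",
    "discharge_status", "emergent", "sim_role")

  list(claims = claims, truth = truth)
}

#' Run the full synthetic data generator
#'
#' Convenience wrapper around [generate_population()] and
#' [generate_claims()].
#'
#' @param config a [sim_config()] object.
#' @return list with `beneficiaries`, `claims`, `crosswalk`, `truth`.
#' @export
simulate_claims <- function(config) {
  pop <- generate_population(config)
  gen <- generate_claims(config, pop)
  list(beneficiaries = pop$beneficiaries, claims = gen$claims,
       crosswalk = pop$crosswalk, truth = gen$truth)
}

#' Write a simulation to delimited files plus a ground-truth sidecar
#'
#' Writes `beneficiaries.csv`, `claims.csv`, `crosswalk.csv` (UTF-8,
#' header row, integer day offsets) and `ground_truth.json` (the HRR
#' effects, true coefficients, variance and per-episode truth table).
#'
#' @param sim output of [simulate_claims()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$beneficiaries, file.path(dir, "beneficiaries.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(sim$claims, file.path(dir, "claims.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(sim$crosswalk, file.path(dir, "crosswalk.csv"),
                   row.names = FALSE, na = "")
  truth <- sim$truth
  jsonlite::write_json(
    list(u_by_hrr = as.list(truth$u_by_hrr), tau_true = truth$tau_true,
         beta_true = as.list(truth$beta_true),
         procedure_intercepts = as.list(truth$procedure_intercepts),
         episodes = truth$episodes),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
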