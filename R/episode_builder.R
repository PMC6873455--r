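# Episode construction: index-admission identification, eligibility and
# exclusion rules, the 183-day lookback covariate, and the minimum-HRR-
# count rule. Exclusion reasons are assigned first-match in a fixed order
# so every candidate carries exactly one labeled outcome.

EXCLUSION_ORDER <- c("dual_coverage", "trauma", "multilevel_fusion",
                     "non_elective", "admitted_from_facility",
                     "died_before_discharge", "overlapping_episode")

split_codes <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

#' Identify candidate index admissions
#'
#' Scans inpatient facility claims for procedure codes in each procedure
#' definition's index code set, restricted to beneficiaries aged 18-65 at
#' admission. A claim matching several procedure definitions yields one
#' candidate per matched definition, flagged `multi_procedure` for
#' review. Claims whose provider zip is absent from the crosswalk are
#' kept and flagged `zip_resolved = FALSE`, never silently dropped.
#' Missing race is imputed from the sponsor's race when available, else
#' coded "unknown".
#'
#' @param claims claims tibble (standardized or raw).
#' @param beneficiaries beneficiary tibble.
#' @param procedure_defs named list of [procedure_definition()] objects.
#' @param crosswalk tibble with `zip`, `hrr_id`, `wage_index`.
#' @return candidate episode tibble with `status = "candidate"`.
#' @export
identify_index_admissions <- function(claims, beneficiaries, procedure_defs,
                                      crosswalk) {
  check_columns(claims, c("claim_id", "beneficiary_id", "claim_class",
                          "admission_date", "discharge_date", "provider_zip",
                          "paid_amount", "procedure_codes", "diagnosis_codes"),
                "claims table")
  check_columns(beneficiaries, c("beneficiary_id", "age", "sex", "race",
                                 "sponsor_rank_category", "charlson",
                                 "dual_coverage"), "beneficiary table")
  inpt <- claims[claims$claim_class == "inpatient_facility", ]
  codes <- split_codes(inpt$procedure_codes)

  cand <- list()
  for (def in procedure_defs) {
    hit <- vapply(codes, function(cc) any(cc %in% def$index_code_set), TRUE)
    if (!any(hit)) next
    sub <- inpt[hit, ]
    cand[[def$name]] <- tibble::tibble(
      procedure = def$name,
      index_claim_id = sub$claim_id,
      beneficiary_id = sub$beneficiary_id,
      admission_date = sub$admission_date,
      discharge_date = sub$discharge_date,
      provider_zip = sub$provider_zip,
      procedure_codes = sub$procedure_codes,
      diagnosis_codes = sub$diagnosis_codes,
      drg_weight = sub$drg_weight,
      admission_source = sub$admission_source,
      discharge_status = sub$discharge_status,
      emergent = isTRUE_vec(sub$emergent)
    )
  }
  out <- dplyr::bind_rows(cand)
  if (nrow(out) == 0) return(empty_candidates())

  out$multi_procedure <- out$index_claim_id %in%
    out$index_claim_id[duplicated(out$index_claim_id)]

  b <- beneficiaries[match(out$beneficiary_id, beneficiaries$beneficiary_id), ]
  race <- as.character(b$race)
  miss <- is.na(race) | race == ""
  if (!is.null(b$sponsor_race)) race[miss] <- as.character(b$sponsor_race)[miss]
  miss <- is.na(race) | race == ""
  race[miss] <- "unknown"
  out$age <- b$age
  out$sex <- b$sex
  out$race <- race
  out$junior_enlisted <- b$sponsor_rank_category == "junior_enlisted"
  out$charlson <- b$charlson
  out$dual_coverage <- isTRUE_vec(b$dual_coverage)

  m <- match(out$provider_zip, crosswalk$zip)
  out$hrr_id <- crosswalk$hrr_id[m]
  out$wage_index <- crosswalk$wage_index[m]
  out$zip_resolved <- !is.na(m)

  # cancer-management flag where the procedure definition declares codes
  out$cancer_management <- FALSE
  dxs <- split_codes(out$diagnosis_codes)
  for (def in procedure_defs) {
    if (length(def$cancer_flag_codes) == 0) next
    sel <- out$procedure == def$name
    out$cancer_management[sel] <- vapply(
      dxs[sel], function(dd) any(dd %in% def$cancer_flag_codes), TRUE)
  }

  out <- out[out$age >= 18 & out$age <= 65, ]
  out <- out[order(out$beneficiary_id, out$admission_date, out$index_claim_id), ]
  out$episode_id <- sprintf("EP%06d", seq_len(nrow(out)))
  out$status <- "candidate"
  out$exclusion_reason <- NA_character_
  out$prior_6mo_payments <- NA_real_
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

empty_candidates <- function() {
  tibble::tibble(
    procedure = character(), index_claim_id = character(),
    beneficiary_id = character(), admission_date = integer(),
    discharge_date = integer(), provider_zip = character(),
    procedure_codes = character(), diagnosis_codes = character(),
    drg_weight = numeric(), admission_source = character(),
    discharge_status = character(), emergent = logical(),
    multi_procedure = logical(), age = numeric(), sex = character(),
    race = character(), junior_enlisted = logical(), charlson = numeric(),
    dual_coverage = logical(), hrr_id = character(), wage_index = numeric(),
    zip_resolved = logical(), cancer_management = logical(),
    episode_id = character(), status = character(),
    exclusion_reason = character(), prior_6mo_payments = numeric()
  )
}

#' Apply eligibility and exclusion rules to candidate episodes
#'
#' Marks each candidate included or excluded with exactly one reason,
#' testing rules in a fixed order: dual coverage; trauma (procedures
#' with a trauma code set, i.e. hip/knee replacement); multi-level
#' fusion (spinal fusion with fusion codes at two or more distinct
#' levels on the index claim); non-elective admission for elective-only
#' procedures; admission from a skilled nursing facility, long-term care
#' facility or hospice; death before discharge; and overlap with an
#' earlier included episode of the same beneficiary (a qualifying
#' admission inside an earlier episode's 90-day window is treated as a
#' readmission, not a new episode; first by admission date wins, ties
#' broken by claim id).
#'
#' @param candidates output of [identify_index_admissions()].
#' @param procedure_defs named list of [procedure_definition()] objects.
#' @param window_days post-discharge window length (days), default 90.
#' @return list with `episodes` (status and reason set) and `tally`
#'   (exclusion counts and percentages by procedure and reason, with
#'   both episode and beneficiary denominators).
#' @export
apply_exclusions <- function(candidates, procedure_defs, window_days = 90) {
  ep <- candidates
  n <- nrow(ep)
  reason <- rep(NA_character_, n)

  defs <- procedure_defs[match(ep$procedure, vapply(procedure_defs, `[[`, "",
                                                    "name"))]
  pcodes <- split_codes(ep$procedure_codes)
  dcodes <- split_codes(ep$diagnosis_codes)

  for (i in seq_len(n)) {
    def <- defs[[i]]
    r <- if (isTRUE_vec(ep$dual_coverage[i])) "dual_coverage"
    else if (length(def$trauma_exclusion_codes) > 0 &&
             any(dcodes[[i]] %in% def$trauma_exclusion_codes)) "trauma"
    else if (def$multilevel_fusion_rule &&
             length(unique(intersect(pcodes[[i]],
                                     def$fusion_level_codes))) >= 2)
      "multilevel_fusion"
    else if (def$elective_only && isTRUE_vec(ep$emergent[i])) "non_elective"
    else if (!is.na(ep$admission_source[i]) &&
             ep$admission_source[i] %in% c("snf", "ltc", "hospice"))
      "admitted_from_facility"
    else if (!is.na(ep$discharge_status[i]) && ep$discharge_status[i] == "died")
      "died_before_discharge"
    else NA_character_
    reason[i] <- r
  }

  # overlapping-episode pass over survivors, in admission-date order
  ord <- order(ep$beneficiary_id, ep$admission_date, ep$index_claim_id)
  window_end <- stats::setNames(numeric(0), character(0))
  last_claim <- stats::setNames(character(0), character(0))
  for (i in ord) {
    if (!is.na(reason[i])) next
    b <- ep$beneficiary_id[i]
    we <- window_end[b]
    if (!is.na(we) && length(we) == 1 && !is.null(we) &&
        ep$admission_date[i] <= we &&
        !identical(last_claim[[b]], ep$index_claim_id[i])) {
      reason[i] <- "overlapping_episode"
    } else {
      window_end[b] <- ep$discharge_date[i] + window_days
      last_claim[b] <- ep$index_claim_id[i]
    }
  }

  ep$exclusion_reason <- reason
  ep$status <- ifelse(is.na(reason), "included", "excluded")
  list(episodes = ep, tally = exclusion_tally(ep))
}

exclusion_tally <- function(ep) {
  dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(procedure = ep$procedure,
                     reason = ifelse(is.na(ep$exclusion_reason), "included",
                                     ep$exclusion_reason),
                     beneficiary_id = ep$beneficiary_id),
      .data$procedure, .data$reason),
    n_episodes = dplyr::n(),
    n_beneficiaries = dplyr::n_distinct(.data$beneficiary_id),
    .groups = "drop") |>
    dplyr::group_by(.data$procedure) |>
    dplyr::mutate(
      pct_episodes = 100 * .data$n_episodes / sum(.data$n_episodes),
      pct_beneficiaries = 100 * .data$n_beneficiaries /
        sum(.data$n_beneficiaries)) |>
    dplyr::ungroup()
}

#' Attach the six-month lookback spending covariate
#'
#' Sums each beneficiary's paid amounts over the 183 days before the
#' index admission (service dates in `[admission - 183, admission - 1]`;
#' facility claims dated by admission date). Run on price-standardized
#' claims so the covariate carries no regional price signal.
#'
#' @param episodes episode tibble.
#' @param claims claims tibble (standardized).
#' @param lookback_days lookback length in days, default 183.
#' @return episodes with `prior_6mo_payments` filled.
#' @export
attach_lookback <- function(episodes, claims, lookback_days = 183) {
  ev <- claim_event_date(claims)
  out <- episodes
  out$prior_6mo_payments <- vapply(seq_len(nrow(out)), function(i) {
    sel <- claims$beneficiary_id == out$beneficiary_id[i] &
      !is.na(ev) &
      ev >= out$admission_date[i] - lookback_days &
      ev <= out$admission_date[i] - 1
    sum(claims$paid_amount[sel])
  }, 0)
  out
}

claim_event_date <- function(claims) {
  ifelse(claims$claim_class == "inpatient_facility" &
           !is.na(claims$admission_date),
         claims$admission_date, claims$service_date)
}

#' Exclude episodes in low-volume HRRs
#'
#' Per procedure, marks included episodes whose HRR has fewer than
#' `min_count` included episodes of that procedure as excluded with
#' reason `small_hrr`.
#'
#' @param episodes episode tibble with status set.
#' @param min_count minimum included episodes per HRR per procedure,
#'   default 5.
#' @return list with `episodes` and `tally` (count and fraction excluded
#'   per procedure).
#' @export
filter_small_hrrs <- function(episodes, min_count = 5) {
  ep <- episodes
  inc <- ep$status == "included"
  key <- paste(ep$procedure, ep$hrr_id, sep = "\r")
  counts <- table(key[inc])
  small <- inc & counts[key] < min_count
  small[is.na(small)] <- FALSE
  ep$status[small] <- "excluded"
  ep$exclusion_reason[small] <- "small_hrr"
  tally <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(procedure = episodes$procedure[inc],
                                   small = small[inc]),
                    .data$procedure),
    n_excluded = sum(.data$small),
    fraction_excluded = mean(.data$small),
    .groups = "drop")
  list(episodes = ep, tally = tally)
}

#' Build episodes end to end
#'
#' Standardizes claims, identifies candidates, applies the exclusion
#' rules, attaches the lookback covariate and enforces the minimum HRR
#' count.
#'
#' @param claims raw claims tibble.
#' @param beneficiaries beneficiary tibble.
#' @param crosswalk zip/HRR/wage-index crosswalk.
#' @param procedure_defs named list of procedure definitions; default
#'   [default_procedures()].
#' @param labor_share wage-index labor share, default 0.62.
#' @param min_hrr_count minimum included episodes per HRR per procedure.
#' @param permissive pass unmatched zips through standardization.
#' @return list with `episodes`, `exclusion_tally`, `small_hrr_tally`
#'   and the standardized `claims`.
#' @export
build_episodes <- function(claims, beneficiaries, crosswalk,
                           procedure_defs = default_procedures(),
                           labor_share = 0.62, min_hrr_count = 5,
                           permissive = FALSE) {
  std <- standardize_claims(claims, crosswalk, labor_share, permissive)
  cand <- identify_index_admissions(std, beneficiaries, procedure_defs,
                                    crosswalk)
  exc <- apply_exclusions(cand, procedure_defs)
  ep <- attach_lookback(exc$episodes, std)
  flt <- filter_small_hrrs(ep, min_hrr_count)
  list(episodes = flt$episodes, exclusion_tally = exc$tally,
       small_hrr_tally = flt$tally, claims = std)
}
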