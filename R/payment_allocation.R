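# Payment allocation: every in-window claim lands in exactly one of four
# components — index hospitalization, readmissions, post-acute care,
# professional fees. Professional claims are one undivided category
# regardless of setting; readmissions are attributed by admission date
# (a stay admitted on or before day 90 counts in full).

POST_ACUTE_CLASSES <- c("rehab", "snf", "outpatient_facility", "home_health",
                        "hospice", "dme")
KNOWN_CLASSES <- c("inpatient_facility", "professional", POST_ACUTE_CLASSES)

#' Collect the claims belonging to one episode's payment window
#'
#' Returns the index claim, claims dated during the index stay, and the
#' beneficiary's claims with event date in days 1-90 after discharge
#' (facility claims dated by admission date, others by service date). A
#' claim at day 90 is in; day 91 is out.
#'
#' @param episode one-row episode tibble.
#' @param claims claims tibble.
#' @param window_days post-discharge window length, default 90.
#' @return claims tibble subset.
#' @export
collect_window_claims <- function(episode, claims, window_days = 90) {
  stopifnot(nrow(episode) == 1)
  ev <- claim_event_date(claims)
  sel <- claims$claim_id == episode$index_claim_id |
    (claims$beneficiary_id == episode$beneficiary_id & !is.na(ev) &
       ((ev >= episode$admission_date & ev <= episode$discharge_date) |
          (ev >= episode$discharge_date + 1 &
             ev <= episode$discharge_date + window_days)))
  claims[sel, ]
}

#' Bucket an episode's window claims into the four payment components
#'
#' Assignment rules, each claim to exactly one bucket: professional
#' claims always go to professional fees; the index claim and other
#' facility claims dated during the index stay go to index
#' hospitalization; inpatient facility claims admitted after discharge
#' go to readmissions; post-acute claim classes (rehab, SNF, outpatient
#' facility, home health, hospice, DME) go to post-acute care. A claim
#' of unknown class is a hard error listing the claim ids.
#'
#' @param window_claims output of [collect_window_claims()].
#' @param episode the one-row episode the claims belong to.
#' @return a one-row tibble of the four components and their total.
#' @export
bucket_payments <- function(window_claims, episode) {
  cl <- window_claims
  unknown <- !cl$claim_class %in% KNOWN_CLASSES
  if (any(unknown))
    bv_abort(sprintf("claim(s) with unknown class: %s",
                     paste(cl$claim_id[unknown], collapse = ", ")),
             "bundlevar_class_error")
  bucket <- bucket_of(cl, episode)
  amt <- function(bk) sum(cl$paid_amount[bucket == bk])
  tibble::tibble(
    episode_id = episode$episode_id,
    index_hospitalization = amt("index_hospitalization"),
    readmissions = amt("readmissions"),
    post_acute = amt("post_acute"),
    professional_fees = amt("professional_fees")
  ) |>
    dplyr::mutate(total = .data$index_hospitalization + .data$readmissions +
                    .data$post_acute + .data$professional_fees)
}

bucket_of <- function(cl, episode) {
  ev <- claim_event_date(cl)
  in_stay <- !is.na(ev) & ev >= episode$admission_date &
    ev <= episode$discharge_date
  dplyr::case_when(
    cl$claim_class == "professional" ~ "professional_fees",
    cl$claim_id == episode$index_claim_id ~ "index_hospitalization",
    in_stay ~ "index_hospitalization",
    cl$claim_class == "inpatient_facility" ~ "readmissions",
    cl$claim_class %in% POST_ACUTE_CLASSES ~ "post_acute",
    TRUE ~ NA_character_
  )
}

#' Allocate payments for every included episode
#'
#' Runs window collection and bucketing across all included episodes and
#' returns per-episode component payments plus a per-claim assignment
#' ledger (each claim id appears in at most one bucket of one episode).
#'
#' @param episodes episode tibble with status set.
#' @param claims claims tibble (standardized).
#' @param window_days post-discharge window length, default 90.
#' @return list with `payments` (episode id, HRR, procedure, four
#'   components, total) and `assignment` (claim_id, episode_id, bucket).
#' @export
allocate_payments <- function(episodes, claims, window_days = 90) {
  inc <- episodes[episodes$status == "included", ]
  pay <- vector("list", nrow(inc))
  asg <- vector("list", nrow(inc))
  for (i in seq_len(nrow(inc))) {
    epi <- inc[i, ]
    wc <- collect_window_claims(epi, claims, window_days)
    pay[[i]] <- bucket_payments(wc, epi)
    asg[[i]] <- tibble::tibble(claim_id = wc$claim_id,
                               episode_id = epi$episode_id,
                               bucket = bucket_of(wc, epi))
  }
  payments <- dplyr::bind_rows(pay)
  if (nrow(payments) > 0) {
    payments <- dplyr::left_join(
      payments,
      dplyr::select(inc, "episode_id", "hrr_id", "procedure"),
      by = "episode_id")
  }
  assignment <- dplyr::bind_rows(asg)
  if (nrow(assignment) > 0 && anyDuplicated(assignment$claim_id) > 0)
    bv_abort("claim assigned to more than one episode bucket",
             "bundlevar_integrity_error")
  list(payments = payments, assignment = assignment)
}

#' Readmission rate per procedure
#'
#' Fraction of included episodes with any readmission payment.
#'
#' @param payments payments tibble from [allocate_payments()].
#' @return tibble of procedure and readmission rate.
#' @export
readmission_rate <- function(payments) {
  dplyr::summarise(dplyr::group_by(payments, .data$procedure),
                   rate = mean(.data$readmissions > 0), .groups = "drop")
}
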