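procs <- default_procedures()

test_that("index admissions are found on inpatient facility claims only", {
  cand <- identify_index_admissions(hand_claims(), hand_beneficiaries(),
                                    procs, hand_crosswalk())
  # two inpatient claims carry the PHR code; the professional claim with the
  # same code is ignored
  expect_equal(nrow(cand), 2)
  expect_setequal(cand$index_claim_id, c("C01", "C09"))
  expect_true(all(cand$procedure == "PHR"))
  # missing race imputed from the sponsor
  expect_equal(cand$race[cand$beneficiary_id == "B2"], "black")
})

test_that("empty claims yield an empty candidate list", {
  cand <- identify_index_admissions(hand_claims()[0, ], hand_beneficiaries(),
                                    procs, hand_crosswalk())
  expect_equal(nrow(cand), 0)
})

test_that("a claim matching two procedure definitions yields two flagged candidates", {
  cl <- hand_claims()[1, ]
  cl$procedure_codes <- "P8151;P8154"
  cand <- identify_index_admissions(cl, hand_beneficiaries(), procs,
                                    hand_crosswalk())
  expect_equal(nrow(cand), 2)
  expect_setequal(cand$procedure, c("PHR", "PKR"))
  expect_true(all(cand$multi_procedure))
})

test_that("age outside 18-65 is not a candidate", {
  ben <- hand_beneficiaries()
  ben$age[1] <- 70
  cand <- identify_index_admissions(hand_claims(), ben, procs,
                                    hand_crosswalk())
  expect_false("B1" %in% cand$beneficiary_id)
})

test_that("unresolvable zips are flagged, not dropped", {
  cl <- hand_claims()
  cl$provider_zip[9] <- "Z9"
  cand <- identify_index_admissions(cl, hand_beneficiaries(), procs,
                                    hand_crosswalk())
  expect_equal(nrow(cand), 2)
  expect_false(cand$zip_resolved[cand$index_claim_id == "C09"])
})

make_candidate <- function(procedure = "PHR", dual = FALSE, dx = "",
                           pcodes = "P8151", emergent = FALSE,
                           source = "home", status = "home") {
  cl <- hand_claims()[1, ]
  cl$procedure_codes <- pcodes
  cl$diagnosis_codes <- dx
  cl$emergent <- emergent
  cl$admission_source <- source
  cl$discharge_status <- status
  ben <- hand_beneficiaries()
  ben$dual_coverage[1] <- dual
  cand <- identify_index_admissions(cl, ben, procs, hand_crosswalk())
  cand[cand$procedure == procedure, ]
}

test_that("each exclusion rule fires with its own reason", {
  r <- function(cand) apply_exclusions(cand, procs)$episodes$exclusion_reason
  expect_equal(r(make_candidate(dual = TRUE)), "dual_coverage")
  expect_equal(r(make_candidate(dx = "D8080")), "trauma")
  expect_equal(r(make_candidate("LSF", pcodes = "P8106;P8107")),
               "multilevel_fusion")
  expect_equal(r(make_candidate(emergent = TRUE)), "non_elective")
  expect_equal(r(make_candidate(source = "snf")), "admitted_from_facility")
  expect_equal(r(make_candidate(status = "died")), "died_before_discharge")
  expect_equal(r(make_candidate()), NA_character_)
})

test_that("trauma exclusion is scoped to procedures with trauma codes", {
  # the same trauma diagnosis on a CABG index claim does not exclude
  cabg <- make_candidate("CABG", pcodes = "P3610", dx = "D8080")
  out <- apply_exclusions(cabg, procs)$episodes
  expect_equal(out$status, "included")
  # single-level fusion is kept
  lsf <- make_candidate("LSF", pcodes = "P8106")
  expect_equal(apply_exclusions(lsf, procs)$episodes$status, "included")
})

test_that("emergent CABG and colectomy enter case mix rather than being excluded", {
  cabg <- make_candidate("CABG", pcodes = "P3610", emergent = TRUE)
  out <- apply_exclusions(cabg, procs)$episodes
  expect_equal(out$status, "included")
  expect_true(out$emergent)
})

test_that("exclusion order is fixed and every candidate gets exactly one label", {
  # dual coverage wins over trauma when both apply
  both <- make_candidate(dual = TRUE, dx = "D8080")
  expect_equal(apply_exclusions(both, procs)$episodes$exclusion_reason,
               "dual_coverage")
})

test_that("a qualifying admission inside an earlier window is an overlap, not a new episode", {
  cl <- hand_claims()[c(1, 1), ]
  cl$claim_id <- c("C01", "C20")
  cl$admission_date <- c(100L, 150L)   # 150 is inside 100..(105+90)
  cl$discharge_date <- c(105L, 153L)
  cl$service_date <- cl$admission_date
  cand <- identify_index_admissions(cl, hand_beneficiaries(), procs,
                                    hand_crosswalk())
  out <- apply_exclusions(cand, procs)$episodes
  expect_equal(out$exclusion_reason[out$index_claim_id == "C20"],
               "overlapping_episode")
  expect_equal(out$status[out$index_claim_id == "C01"], "included")
  # an admission after the window opens a fresh episode
  cl$admission_date[2] <- 300L
  cl$discharge_date[2] <- 303L
  cl$service_date <- cl$admission_date
  cand2 <- identify_index_admissions(cl, hand_beneficiaries(), procs,
                                     hand_crosswalk())
  expect_true(all(apply_exclusions(cand2, procs)$episodes$status ==
                    "included"))
})

test_that("candidates partition into included plus one reason each", {
  sim <- simulate_claims(sim_config(n_hrrs = 10, episodes_per_hrr = 15,
                                    seed = 21))
  std <- standardize_claims(sim$claims, sim$crosswalk)
  cand <- identify_index_admissions(std, sim$beneficiaries, procs,
                                    sim$crosswalk)
  out <- apply_exclusions(cand, procs)
  ep <- out$episodes
  expect_equal(sum(ep$status == "included") +
                 sum(!is.na(ep$exclusion_reason)), nrow(cand))
  expect_true(all(is.na(ep$exclusion_reason[ep$status == "included"])))
  expect_true(all(!is.na(ep$exclusion_reason[ep$status == "excluded"])))
  # tally reconciles with the episode table
  tly <- out$tally
  expect_equal(sum(tly$n_episodes), nrow(cand))
})

test_that("lookback window is [admission - 183, admission - 1]", {
  ep <- tibble::tibble(episode_id = "EP1", beneficiary_id = "B1",
                       admission_date = 200L)
  mk <- function(days, amts) tibble::tibble(
    claim_id = paste0("L", seq_along(days)), beneficiary_id = "B1",
    claim_class = "outpatient_facility", admission_date = NA_integer_,
    discharge_date = NA_integer_, service_date = days, paid_amount = amts)
  # boundary: -183 in, -184 out
  out <- attach_lookback(ep, mk(c(200L - 183L, 200L - 184L), c(100, 100)))
  expect_equal(out$prior_6mo_payments, 100)
  out2 <- attach_lookback(ep, mk(c(30L, 100L, 150L), c(10, 20, 30)))
  expect_equal(out2$prior_6mo_payments, 60)
  out3 <- attach_lookback(ep, mk(integer(0), numeric(0)))
  expect_equal(out3$prior_6mo_payments, 0)
})

test_that("the minimum-count rule applies per procedure within an HRR", {
  ep <- tibble::tibble(
    episode_id = sprintf("EP%02d", 1:9),
    beneficiary_id = sprintf("B%02d", 1:9),
    procedure = c(rep("PHR", 4), rep("PKR", 5)),
    hrr_id = "HRR001",
    status = "included",
    exclusion_reason = NA_character_
  )
  out <- filter_small_hrrs(ep, min_count = 5)
  expect_true(all(out$episodes$status[out$episodes$procedure == "PHR"] ==
                    "excluded"))
  expect_true(all(out$episodes$exclusion_reason[
    out$episodes$procedure == "PHR"] == "small_hrr"))
  expect_true(all(out$episodes$status[out$episodes$procedure == "PKR"] ==
                    "included"))
  tly <- out$tally
  expect_equal(tly$n_excluded[tly$procedure == "PHR"], 4L)
  expect_equal(tly$n_excluded[tly$procedure == "PKR"], 0L)
  # exactly at the threshold is retained
  ep5 <- ep[ep$procedure == "PKR", ]
  out5 <- filter_small_hrrs(ep5, min_count = 5)
  expect_true(all(out5$episodes$status == "included"))
})

test_that("planted exclusion triggers are recalled exactly", {
  cfg <- sim_config(n_hrrs = 15, episodes_per_hrr = 40, seed = 31,
                    exclusion_rates = c(dual_coverage = 0.1, trauma = 0.1,
                                        multilevel_fusion = 0.1,
                                        non_elective = 0.1,
                                        admitted_from_facility = 0.05,
                                        died_before_discharge = 0.05))
  sim <- simulate_claims(cfg)
  std <- standardize_claims(sim$claims, sim$crosswalk)
  cand <- identify_index_admissions(std, sim$beneficiaries, procs,
                                    sim$crosswalk)
  ep <- apply_exclusions(cand, procs)$episodes
  tr <- sim$truth$episodes
  m <- match(ep$index_claim_id, tr$index_claim_id)
  planted <- tibble::tibble(
    dual_coverage = tr$trig_dual[m],
    trauma = !tr$trig_dual[m] & tr$trig_trauma[m],
    multilevel_fusion = !tr$trig_dual[m] & tr$trig_fusion[m],
    admitted_from_facility = tr$trig_facility[m],
    died_before_discharge = tr$trig_died[m]
  )
  expect_gt(sum(planted$dual_coverage), 0)
  expect_gt(sum(planted$trauma), 0)
  expect_gt(sum(planted$multilevel_fusion), 0)
  expect_gt(sum(planted$admitted_from_facility), 0)
  expect_gt(sum(planted$died_before_discharge), 0)
  # recall is 100%: every planted dual/trauma/fusion trigger is labeled
  expect_true(all(ep$exclusion_reason[planted$dual_coverage] ==
                    "dual_coverage"))
  expect_true(all(ep$exclusion_reason[planted$trauma] == "trauma"))
  expect_true(all(ep$exclusion_reason[planted$multilevel_fusion] ==
                    "multilevel_fusion"))
  # facility/death triggers are labeled with their reason unless an
  # earlier-ordered rule also applied
  early <- c("dual_coverage", "trauma", "multilevel_fusion", "non_elective")
  sel <- planted$admitted_from_facility & !ep$exclusion_reason %in% early
  expect_true(all(ep$exclusion_reason[sel] == "admitted_from_facility"))
  sel <- planted$died_before_discharge &
    !ep$exclusion_reason %in% c(early, "admitted_from_facility")
  expect_true(all(ep$exclusion_reason[sel] == "died_before_discharge"))
})
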