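# Schema-validated table IO and end-to-end pipeline orchestration.
# Delimited UTF-8 tables with documented headers are the interchange
# format; dates are integer day offsets from a fixed epoch.

TABLE_SCHEMAS <- list(
  claims = list(
    required = c("claim_id", "beneficiary_id", "claim_class",
                 "admission_date", "discharge_date", "service_date",
                 "provider_zip", "paid_amount", "procedure_codes",
                 "diagnosis_codes", "drg_weight", "admission_source",
                 "discharge_status", "emergent"),
    numeric = c("admission_date", "discharge_date", "service_date",
                "paid_amount", "drg_weight")
  ),
  beneficiaries = list(
    required = c("beneficiary_id", "age", "sex", "race",
                 "sponsor_rank_category", "charlson", "dual_coverage"),
    numeric = c("age", "charlson")
  ),
  crosswalk = list(
    required = c("zip", "hrr_id", "wage_index"),
    numeric = c("wage_index")
  )
)

#' Read and validate a pipeline table
#'
#' Reads a delimited UTF-8 table, checks the header against the named
#' schema (`"claims"`, `"beneficiaries"` or `"crosswalk"`), coerces
#' typed columns, and collects row-level violations (unparseable
#' numbers, negative paid amounts, non-positive wage indices) with line
#' numbers. Violations abort the run unless `permissive = TRUE`, in
#' which case offending rows are dropped with a warning.
#'
#' @param path file path.
#' @param schema_name one of `names(TABLE_SCHEMAS)`.
#' @param permissive drop bad rows instead of aborting.
#' @return validated tibble.
#' @export
read_table <- function(path, schema_name, permissive = FALSE) {
  if (!file.exists(path))
    bv_abort(sprintf("file not found: %s", path), "bundlevar_io_error")
  schema <- TABLE_SCHEMAS[[schema_name]]
  if (is.null(schema))
    bv_abort(sprintf("unknown schema '%s'", schema_name),
             "bundlevar_config_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  check_columns(df, schema$required, sprintf("%s file '%s'", schema_name, path))

  bad <- integer(0)
  for (col in schema$numeric) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- union(bad, which(!is.na(df[[col]]) & is.na(v)))
    df[[col]] <- v
  }
  if ("paid_amount" %in% names(df))
    bad <- union(bad, which(!is.na(df$paid_amount) & df$paid_amount < 0))
  if ("wage_index" %in% names(df))
    bad <- union(bad, which(!is.na(df$wage_index) & df$wage_index <= 0))
  if ("emergent" %in% names(df))
    df$emergent <- toupper(df$emergent) %in% c("TRUE", "T", "1")
  if ("dual_coverage" %in% names(df))
    df$dual_coverage <- toupper(df$dual_coverage) %in% c("TRUE", "T", "1")

  if (length(bad) > 0) {
    msg <- sprintf("%s rows failing validation at line(s): %s",
                   schema_name,
                   paste(utils::head(sort(bad) + 1L, 20), collapse = ", "))
    if (!permissive) bv_abort(msg, "bundlevar_validation_error")
    warning(msg, call. = FALSE)
    df <- df[-bad, ]
  }
  tibble::as_tibble(df)
}

#' Pipeline configuration
#'
#' Assembles everything [run_pipeline()] needs. Defaults follow the
#' study design: a 90-day post-discharge window, a 183-day (six-month)
#' lookback, and a minimum of 5 cases per HRR per procedure.
#'
#' @param sim optional [sim_config()]; if given, inputs are simulated.
#' @param claims,beneficiaries,crosswalk file paths, used when `sim` is
#'   `NULL`.
#' @param procedures named list of procedure definitions.
#' @param labor_share wage-index labor share.
#' @param min_hrr_count minimum cases per HRR per procedure.
#' @param window_days post-discharge window length.
#' @param lookback_days lookback length.
#' @param n_boot bootstrap replicates for quintile CIs.
#' @param seed seed for all pipeline randomness (bootstrap; simulation
#'   uses the seed in `sim`).
#' @param out_dir optional output directory for report tables and the
#'   manifest.
#' @param permissive pass-through/row-drop behaviour for IO and
#'   standardization.
#' @return a `bv_pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, claims = NULL, beneficiaries = NULL,
                            crosswalk = NULL,
                            procedures = default_procedures(),
                            labor_share = 0.62, min_hrr_count = 5,
                            window_days = 90, lookback_days = 183,
                            n_boot = 1000, seed = 1L, out_dir = NULL,
                            permissive = FALSE) {
  if (is.null(sim) &&
      (is.null(claims) || is.null(beneficiaries) || is.null(crosswalk)))
    bv_abort("either a simulation config or all three input paths are required",
             "bundlevar_config_error")
  structure(list(sim = sim, claims = claims, beneficiaries = beneficiaries,
                 crosswalk = crosswalk, procedures = procedures,
                 labor_share = labor_share, min_hrr_count = min_hrr_count,
                 window_days = window_days, lookback_days = lookback_days,
                 n_boot = n_boot, seed = as.integer(seed), out_dir = out_dir,
                 permissive = permissive),
            class = "bv_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) -> price-standardize -> build episodes -> allocate
#' payments -> fit case-mix shrinkage models per procedure (total
#' payments with and without case-mix covariates, plus each payment
#' component) -> quintile variation report. A manifest records the
#' seed, stage row counts and a claim ledger that reconciles every input
#' claim to exactly one disposition (bucketed, lookback, excluded
#' episode, out of window, or unmatched).
#'
#' @param config a [pipeline_config()].
#' @return list with `episodes`, `payments`, `assignment`, `fits`,
#'   `estimates`, `report`, `readmission_rates`, `exclusion_tally`,
#'   `small_hrr_tally`, `manifest`, and `truth` when simulated.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bv_pipeline_config"))
  stage <- "input"
  res <- tryCatch({
    truth <- NULL
    if (!is.null(config$sim)) {
      sim <- simulate_claims(config$sim)
      claims <- sim$claims
      beneficiaries <- sim$beneficiaries
      crosswalk <- sim$crosswalk
      truth <- sim$truth
    } else {
      claims <- read_table(config$claims, "claims", config$permissive)
      beneficiaries <- read_table(config$beneficiaries, "beneficiaries",
                                  config$permissive)
      crosswalk <- read_table(config$crosswalk, "crosswalk", config$permissive)
    }

    stage <- "standardize"
    std <- standardize_claims(claims, crosswalk, config$labor_share,
                              config$permissive)

    stage <- "build-episodes"
    cand <- identify_index_admissions(std, beneficiaries, config$procedures,
                                      crosswalk)
    exc <- apply_exclusions(cand, config$procedures, config$window_days)
    ep <- attach_lookback(exc$episodes, std, config$lookback_days)
    flt <- filter_small_hrrs(ep, config$min_hrr_count)
    episodes <- flt$episodes

    stage <- "allocate"
    alloc <- allocate_payments(episodes, std, config$window_days)
    payments <- alloc$payments

    stage <- "fit"
    inc <- episodes[episodes$status == "included", ]
    frame <- dplyr::inner_join(
      inc, dplyr::select(payments, -"hrr_id", -"procedure"),
      by = "episode_id")
    fits <- list()
    estimates <- list()
    for (def in config$procedures) {
      pf <- frame[frame$procedure == def$name, ]
      if (nrow(pf) == 0 || length(unique(pf$hrr_id)) < 5) next
      covs <- casemix_covariates(def)
      lab_fits <- list()
      lab_fits$total_price_std <- fit_casemix_model(pf, "total", character(0))
      lab_fits$total_casemix <- fit_casemix_model(pf, "total", covs)
      for (comp in c("index_hospitalization", "readmissions", "post_acute",
                     "professional_fees")) {
        if (all(pf[[comp]] == 0)) {
          warning(sprintf("%s: component '%s' all zero; model skipped",
                          def$name, comp), call. = FALSE)
          next
        }
        lab_fits[[comp]] <- fit_casemix_model(pf, comp, covs)
      }
      fits[[def$name]] <- lab_fits
      estimates[[def$name]] <- lapply(lab_fits, compute_hrr_estimates)
    }

    stage <- "report"
    report <- build_report(estimates, n_boot = config$n_boot,
                           seed = config$seed)
    readm <- readmission_rate(payments)

    manifest <- build_manifest(config, claims, episodes, alloc, fits)

    out <- list(episodes = episodes, payments = payments,
                assignment = alloc$assignment, fits = fits,
                estimates = estimates, report = report,
                readmission_rates = readm,
                exclusion_tally = exc$tally,
                small_hrr_tally = flt$tally,
                manifest = manifest, truth = truth,
                claims = std, beneficiaries = beneficiaries,
                crosswalk = crosswalk)
    if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
    out
  }, bundlevar_error = function(e) {
    bv_abort(sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)), "bundlevar_pipeline_error")
  })
  res
}

build_manifest <- function(config, claims, episodes, alloc, fits) {
  inc <- episodes[episodes$status == "included", ]
  bucketed <- claims$claim_id %in% alloc$assignment$claim_id
  lb <- rep(FALSE, nrow(claims))
  ev <- claim_event_date(claims)
  for (i in seq_len(nrow(inc))) {
    lb <- lb | (claims$beneficiary_id == inc$beneficiary_id[i] & !is.na(ev) &
                  ev >= inc$admission_date[i] - config$lookback_days &
                  ev <= inc$admission_date[i] - 1)
  }
  excl_ben <- unique(episodes$beneficiary_id[episodes$status == "excluded"])
  disposition <- ifelse(bucketed, "bucketed",
                        ifelse(lb, "lookback",
                               ifelse(claims$beneficiary_id %in% excl_ben,
                                      "excluded_episode", "out_of_window")))
  ledger <- as.list(table(disposition))
  ledger$total <- nrow(claims)
  list(
    package_version = as.character(utils::packageVersion("bundlevar")),
    seed = config$seed,
    labor_share = config$labor_share,
    min_hrr_count = config$min_hrr_count,
    window_days = config$window_days,
    lookback_days = config$lookback_days,
    n_claims = nrow(claims),
    n_candidates = nrow(episodes),
    n_included = nrow(inc),
    n_excluded = sum(episodes$status == "excluded"),
    models_fit = sum(lengths(fits)),
    claim_ledger = ledger
  )
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, na = "")
  wr(out$episodes, "episodes.csv")
  wr(out$payments, "payments.csv")
  wr(out$report, "report.csv")
  wr(out$readmission_rates, "readmission_rates.csv")
  wr(out$exclusion_tally, "exclusion_tally.csv")
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
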