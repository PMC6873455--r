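# Quintile ranking of HRR adjusted mean costs and inter-quintile
# variation statistics. HRRs are ranked ascending; rank k goes to the
# smallest quintile q with k <= ceiling(q * J / 5); ties break by HRR id
# so runs are reproducible.

#' Rank HRRs and assign quintiles
#'
#' @param estimates tibble from [compute_hrr_estimates()] (or any table
#'   with `hrr_id` and the ranking column).
#' @param ranking_quantity column to rank on, default `"adjusted_mean"`.
#' @return `estimates` sorted ascending with `rank` and `quintile`
#'   columns.
#' @export
rank_and_quintile <- function(estimates, ranking_quantity = "adjusted_mean") {
  check_columns(estimates, c("hrr_id", ranking_quantity), "estimates")
  J <- nrow(estimates)
  if (J < 5)
    bv_abort("quintiles are undefined for fewer than 5 HRRs",
             "bundlevar_domain_error")
  ord <- order(estimates[[ranking_quantity]], estimates$hrr_id)
  out <- estimates[ord, ]
  out$rank <- seq_len(J)
  cut <- ceiling((1:5) * J / 5)
  out$quintile <- vapply(out$rank, function(k) which(k <= cut)[1], 0L)
  out
}

#' Quintile mean payments with bootstrap confidence intervals
#'
#' Unweighted mean of member-HRR adjusted means per quintile, with a
#' seeded percentile bootstrap (resampling member HRRs with replacement)
#' for the 95% interval. A quintile with a single HRR gets a degenerate
#' interval and is flagged.
#'
#' @param assignment output of [rank_and_quintile()].
#' @param value column to summarize, default the ranking quantity
#'   `"adjusted_mean"`.
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level, default 0.95.
#' @return tibble with `quintile`, `hrr_count`, `mean_payment`,
#'   `ci_low`, `ci_high`, `degenerate_ci`, `member_hrrs`.
#' @export
quintile_means <- function(assignment, value = "adjusted_mean",
                           n_boot = 1000, seed = 7L, conf = 0.95) {
  check_columns(assignment, c("quintile", "hrr_id", value), "assignment")
  set.seed(seed)
  a <- (1 - conf) / 2
  res <- lapply(1:5, function(q) {
    v <- assignment[[value]][assignment$quintile == q]
    ids <- assignment$hrr_id[assignment$quintile == q]
    if (length(v) == 0)
      return(tibble::tibble(quintile = q, hrr_count = 0L,
                            mean_payment = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, degenerate_ci = TRUE,
                            member_hrrs = list(character(0))))
    boots <- vapply(seq_len(n_boot), function(b)
      mean(v[sample.int(length(v), replace = TRUE)]), 0)
    qs <- stats::quantile(boots, c(a, 1 - a), names = FALSE)
    tibble::tibble(quintile = q, hrr_count = length(v),
                   mean_payment = mean(v), ci_low = qs[1], ci_high = qs[2],
                   degenerate_ci = length(v) == 1,
                   member_hrrs = list(ids))
  })
  dplyr::bind_rows(res)
}

#' Inter-quintile variation statistics
#'
#' Absolute difference between the highest and lowest quintile means in
#' whole dollars, and the difference as a percentage of the lowest
#' quintile mean, rounded half away from zero to whole percent. If the
#' lowest quintile mean is not positive the percentage is undefined
#' (`NA`, flagged); the absolute difference is still returned.
#'
#' @param q1_mean lowest-quintile mean payment (USD).
#' @param q5_mean highest-quintile mean payment (USD).
#' @return tibble with `abs_difference`, `pct_difference`,
#'   `pct_undefined`.
#' @export
interquintile_stats <- function(q1_mean, q5_mean) {
  abs_diff <- round_half_away(q5_mean - q1_mean)
  undef <- q1_mean <= 0
  pct <- ifelse(undef, NA_real_,
                round_half_away(100 * (q5_mean - q1_mean) / q1_mean))
  tibble::tibble(abs_difference = abs_diff, pct_difference = pct,
                 pct_undefined = undef)
}

#' Build the full variation report
#'
#' For each procedure: total-payment quintile rows for the
#' price-standardized-only and case-mix-adjusted estimates, and
#' per-component quintile rows with each component independently
#' re-ranked into its own quintiles, each row carrying the quintile
#' means, bootstrap confidence intervals and the inter-quintile
#' difference in dollars and percent.
#'
#' @param estimates_by named list: `estimates_by[[procedure]][[label]]`
#'   is an HRR-estimates tibble, labels like `"total_price_std"`,
#'   `"total_casemix"`, `"index_hospitalization"`, `"readmissions"`,
#'   `"post_acute"`, `"professional_fees"`. Missing labels are skipped
#'   with a warning.
#' @param n_boot bootstrap replicates for quintile CIs.
#' @param seed bootstrap seed.
#' @return tibble in long form: procedure, payment label, quintile
#'   columns `q1`..`q5` (means), CI columns, and the difference columns.
#' @export
build_report <- function(estimates_by, n_boot = 1000, seed = 7L) {
  rows <- list()
  for (proc in names(estimates_by)) {
    for (label in names(estimates_by[[proc]])) {
      est <- estimates_by[[proc]][[label]]
      if (is.null(est) || nrow(est) == 0) {
        warning(sprintf("no estimates for %s / %s; row omitted", proc, label),
                call. = FALSE)
        next
      }
      asg <- rank_and_quintile(est)
      qm <- quintile_means(asg, n_boot = n_boot, seed = seed)
      iq <- interquintile_stats(qm$mean_payment[1], qm$mean_payment[5])
      row <- tibble::tibble(procedure = proc, payment = label)
      for (q in 1:5) {
        row[[paste0("q", q)]] <- round_half_away(qm$mean_payment[q])
        row[[paste0("q", q, "_lo")]] <- round_half_away(qm$ci_low[q])
        row[[paste0("q", q, "_hi")]] <- round_half_away(qm$ci_high[q])
      }
      row$abs_difference <- iq$abs_difference
      row$pct_difference <- iq$pct_difference
      rows[[paste(proc, label)]] <- row
    }
  }
  dplyr::bind_rows(rows)
}
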