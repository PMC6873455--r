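#' Price-standardize a paid amount
#'
#' Removes geographic payment variation attributable to the wage index by
#' deflating the labor-related share of the payment:
#' `paid / (labor_share * wage_index + (1 - labor_share))`. At a wage
#' index of 1 (national average) the payment is unchanged.
#'
#' @param paid non-negative payment in USD.
#' @param wage_index positive wage index ratio (1 = national average).
#' @param labor_share labor-related fraction of payments in \[0, 1\];
#'   default 0.62.
#' @return standardized payment in USD.
#' @export
standardize_payment <- function(paid, wage_index, labor_share = 0.62) {
  if (any(wage_index <= 0, na.rm = TRUE) || anyNA(wage_index))
    bv_abort("wage_index must be positive", "bundlevar_domain_error")
  if (labor_share < 0 || labor_share > 1)
    bv_abort("labor_share must lie in [0, 1]", "bundlevar_domain_error")
  paid / (labor_share * wage_index + (1 - labor_share))
}

#' Price-standardize every claim in a claims table
#'
#' Joins each claim's provider zip to the crosswalk and replaces
#' `paid_amount` with its standardized value, retaining the original in
#' `paid_amount_raw`. Claims whose zip is absent from the crosswalk abort
#' with an error naming the zips unless `permissive = TRUE`, in which
#' case they pass through unstandardized and are reported via a warning.
#'
#' @param claims claims tibble with `provider_zip` and `paid_amount`.
#' @param crosswalk tibble with `zip`, `hrr_id`, `wage_index`.
#' @param labor_share labor-related fraction in \[0, 1\].
#' @param permissive pass unmatched zips through instead of erroring.
#' @return claims tibble with standardized `paid_amount`,
#'   `paid_amount_raw`, and joined `hrr_id`, `wage_index`.
#' @export
standardize_claims <- function(claims, crosswalk, labor_share = 0.62,
                               permissive = FALSE) {
  check_columns(claims, c("provider_zip", "paid_amount"), "claims table")
  check_columns(crosswalk, c("zip", "hrr_id", "wage_index"), "crosswalk")
  if (anyDuplicated(crosswalk$zip))
    bv_abort("crosswalk zips must be unique", "bundlevar_schema_error")
  if (any(crosswalk$wage_index <= 0))
    bv_abort("crosswalk wage_index must be positive", "bundlevar_domain_error")

  m <- match(claims$provider_zip, crosswalk$zip)
  unmatched <- unique(claims$provider_zip[is.na(m)])
  if (length(unmatched) > 0) {
    msg <- sprintf("zip(s) missing from crosswalk: %s",
                   paste(unmatched, collapse = ", "))
    if (!permissive) bv_abort(msg, "bundlevar_crosswalk_error")
    warning(msg, call. = FALSE)
  }
  wi <- crosswalk$wage_index[m]
  out <- claims
  out$paid_amount_raw <- claims$paid_amount
  out$wage_index <- wi
  out$hrr_id <- crosswalk$hrr_id[m]
  std <- ifelse(is.na(wi), claims$paid_amount,
                claims$paid_amount / (labor_share * wi + (1 - labor_share)))
  out$paid_amount <- std
  out
}
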