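# Case-mix model with multiplicative HRR effect, fit by an iterative
# moment / quasi-likelihood scheme:
#   (1) log-link GLM of episode cost on covariates with offset log(u_j)
#   (2) mu_ij = exp(x_ij' beta); E_j = sum_i mu_ij; O_j = sum_i y_ij
#   (3) phi = Pearson dispersion on the squared-CV scale
#   (4) tau = max(floor, mean_j[(r_j - 1)^2 - phi * sum_i mu_ij^2 / E_j^2])
#   (5) u_j = (alpha + O_j/phi) / (alpha + E_j/phi),  alpha = 1/tau
# iterated to convergence in beta. Step (5) is conjugate gamma-frailty
# shrinkage of the observed/expected ratio toward 1 with reliability
# weight w_j = (E_j/phi) / (E_j/phi + alpha).

#' Default case-mix covariate set for a procedure
#'
#' Age (linear and quadratic), sex, race, junior-enlisted sponsor rank
#' (socioeconomic proxy), Charlson index and log1p prior-six-month
#' payments for every procedure; DRG weight (resource-use intensity)
#' where the definition requests it; admission acuity (emergent) for
#' procedures not restricted to elective admissions; cancer-management
#' for procedures with cancer flag codes.
#'
#' @param procedure_def a [procedure_definition()].
#' @return character vector of covariate names understood by
#'   [fit_casemix_model()].
#' @export
casemix_covariates <- function(procedure_def) {
  cov <- c("age", "sex", "race", "junior_enlisted", "charlson", "prior")
  if (procedure_def$use_drg_weight) cov <- c(cov, "drg_weight")
  if (!procedure_def$elective_only) cov <- c(cov, "emergent")
  if (length(procedure_def$cancer_flag_codes) > 0) cov <- c(cov, "cancer")
  cov
}

# build the design matrix with fixed encodings; drops constant columns
build_design <- function(data, covariates) {
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  for (cv in covariates) {
    switch(cv,
      age = {
        age_c <- (data$age - 40) / 10
        cols$age_c <- age_c
        cols$age_c2 <- age_c^2
      },
      sex = cols$male <- as.numeric(data$sex == "M"),
      race = {
        for (lev in setdiff(sort(unique(data$race)), "white"))
          cols[[paste0("race_", lev)]] <- as.numeric(data$race == lev)
      },
      junior_enlisted = cols$junior_enlisted <-
        as.numeric(data$junior_enlisted),
      charlson = cols$charlson <- as.numeric(data$charlson),
      prior = cols$log1p_prior <- log1p(data$prior_6mo_payments),
      drg_weight = cols$drg_weight <- as.numeric(data$drg_weight),
      emergent = cols$emergent <- as.numeric(data$emergent),
      cancer = cols$cancer <- as.numeric(data$cancer_management),
      bv_abort(sprintf("unknown covariate '%s'", cv), "bundlevar_config_error")
    )
  }
  X <- do.call(cbind, cols)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, stats::sd) > 0)
  X <- X[, keep, drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    bv_abort(sprintf("singular design: collinear covariate column(s): %s",
                     paste(bad, collapse = ", ")),
             "bundlevar_singular_error")
  }
  X
}

#' Fit the case-mix model with a multiplicative gamma HRR effect
#'
#' Fits a log-link generalized linear model of episode cost on case-mix
#' covariates with a mean-1 multiplicative effect per hospital referral
#' region, by iterating a GLM step (gamma family for strictly positive
#' outcomes; a log-link quasi-Poisson estimating equation when the
#' outcome contains zeros, as payment components routinely do) with
#' moment updates of the dispersion, the between-HRR variance and the
#' empirical-Bayes shrunken HRR ratios.
#'
#' @param data episode-level tibble: one procedure, with `hrr_id`, the
#'   outcome column, and the case-mix columns (`age`, `sex`, `race`,
#'   `junior_enlisted`, `charlson`, `prior_6mo_payments`, and where used
#'   `drg_weight`, `emergent`, `cancer_management`).
#' @param outcome name of the outcome column (e.g. `"total"`,
#'   `"readmissions"`).
#' @param covariates character vector of covariate names (see
#'   [casemix_covariates()]); `character(0)` fits an intercept-only
#'   model (price-standardized-only estimates).
#' @param max_iter maximum iterations, default 50.
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change, default 1e-6.
#' @param tau_floor lower bound for the between-HRR variance estimate;
#'   an estimate at the floor means no detectable HRR variation.
#' @return a `bv_shrinkage_fit` list: `beta`, `phi`, `tau_hat`,
#'   `alpha_hat`, `u_hat`, `O`, `E`, `mu`, `n_iter`, `converged`,
#'   `outcome_label`, `hrr_id` (per episode), `n_episodes`.
#' @export
fit_casemix_model <- function(data, outcome = "total",
                              covariates = character(0),
                              max_iter = 50, tol = 1e-6, tau_floor = 1e-8) {
  check_columns(data, c("hrr_id", outcome), "episode data")
  y <- data[[outcome]]
  if (anyNA(y) || any(y < 0))
    bv_abort("outcome must be non-negative and complete",
             "bundlevar_domain_error")
  if (all(y == 0))
    bv_abort(sprintf("outcome '%s' is zero for every episode", outcome),
             "bundlevar_domain_error")
  hrr <- as.character(data$hrr_id)
  hrrs <- sort(unique(hrr))
  if (length(hrrs) < 2)
    bv_abort("at least 2 HRRs are required", "bundlevar_domain_error")
  hi <- match(hrr, hrrs)

  X <- build_design(data, covariates)
  p <- ncol(X)
  n <- nrow(X)
  fam <- if (all(y > 0)) stats::Gamma(link = "log")
         else stats::quasipoisson(link = "log")

  u <- rep(1, length(hrrs))
  beta_prev <- NULL
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    off <- log(u)[hi]
    glmfit <- suppressWarnings(
      stats::glm.fit(X, y, family = fam, offset = off,
                     control = stats::glm.control(maxit = 100)))
    beta <- glmfit$coefficients
    mu <- as.numeric(exp(X %*% beta))
    m_full <- mu * u[hi]
    phi <- max(sum((y - m_full)^2 / m_full^2) / max(n - p, 1), 1e-12)
    O <- as.numeric(tapply(y, hi, sum))
    E <- as.numeric(tapply(mu, hi, sum))
    r <- O / E
    s2 <- as.numeric(tapply(mu^2, hi, sum)) / E^2
    tau <- max(tau_floor, mean((r - 1)^2 - phi * s2))
    alpha <- 1 / tau
    u_raw <- (alpha + O / phi) / (alpha + E / phi)
    # mean-1 convention: normalize the offsets so the overall level stays
    # in the intercept rather than drifting into the random effect
    u <- u_raw / mean(u_raw)
    if (!is.null(beta_prev) && max(abs(beta - beta_prev)) < tol) {
      converged <- TRUE
      break
    }
    beta_prev <- beta
  }
  if (!converged)
    warning(sprintf("case-mix model for '%s' did not converge in %d iterations",
                    outcome, max_iter), call. = FALSE)

  structure(list(
    beta = stats::setNames(as.numeric(beta), colnames(X)),
    phi = phi, tau_hat = tau, alpha_hat = alpha,
    tau_at_floor = tau <= tau_floor,
    u_hat = stats::setNames(u_raw, hrrs),
    O = stats::setNames(O, hrrs), E = stats::setNames(E, hrrs),
    mu = mu, hrr_id = hrr, n_iter = n_iter, converged = converged,
    outcome_label = outcome, n_episodes = n,
    family = fam$family
  ), class = "bv_shrinkage_fit")
}

#' @export
print.bv_shrinkage_fit <- function(x, ...) {
  cat(sprintf(
    "Case-mix shrinkage fit: outcome '%s', %d episodes, %d HRRs\n",
    x$outcome_label, x$n_episodes, length(x$u_hat)))
  cat(sprintf("  phi = %.4f, tau_hat = %.5f%s, %d iteration(s), %s\n",
              x$phi, x$tau_hat,
              if (x$tau_at_floor) " (at floor: no detectable HRR variation)"
              else "",
              x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$beta, 4))
  invisible(x)
}

#' Empirical-Bayes shrinkage of an observed/expected cost ratio
#'
#' Conjugate gamma-frailty shrinkage of `O/E` toward 1:
#' `(alpha + O/phi) / (alpha + E/phi)`, equivalently
#' `w * (O/E) + (1 - w)` with reliability weight
#' `w = (E/phi) / (E/phi + alpha)`. Equals 1 exactly when `O = E`, and
#' approaches 1 (full shrinkage) as `alpha` grows.
#'
#' @param O observed total cost (USD), non-negative.
#' @param E expected (case-mix-predicted) total cost (USD), positive.
#' @param phi dispersion, positive.
#' @param alpha gamma shape (1 / between-HRR variance), positive.
#' @return the shrunken ratio.
#' @export
eb_shrink <- function(O, E, phi, alpha) {
  if (any(E <= 0) || any(phi <= 0) || any(alpha <= 0) || any(O < 0))
    bv_abort("eb_shrink requires O >= 0, E > 0, phi > 0, alpha > 0",
             "bundlevar_domain_error")
  (alpha + O / phi) / (alpha + E / phi)
}

#' Reliability-adjusted mean cost per HRR
#'
#' Scales each HRR's empirical-Bayes ratio by the national average
#' case-mix-predicted cost (indirect standardization): the adjusted mean
#' for HRR j is `u_hat_j * mean(mu)` over all modeled episodes.
#'
#' @param fit a `bv_shrinkage_fit` from [fit_casemix_model()].
#' @return tibble with one row per HRR: `hrr_id`, `n_episodes`,
#'   `observed`, `expected`, `ratio`, `reliability`, `eb_ratio`,
#'   `adjusted_mean`.
#' @export
compute_hrr_estimates <- function(fit) {
  stopifnot(inherits(fit, "bv_shrinkage_fit"))
  hrrs <- names(fit$u_hat)
  national_mean <- mean(fit$mu)
  tibble::tibble(
    hrr_id = hrrs,
    n_episodes = as.integer(table(factor(fit$hrr_id, levels = hrrs))),
    observed = unname(fit$O),
    expected = unname(fit$E),
    ratio = unname(fit$O / fit$E),
    reliability = unname((fit$E / fit$phi) / (fit$E / fit$phi + fit$alpha_hat)),
    eb_ratio = unname(fit$u_hat),
    adjusted_mean = unname(fit$u_hat) * national_mean
  )
}
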