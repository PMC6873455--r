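test_that("eb_shrink matches its closed form and limits", {
  expect_equal(eb_shrink(100, 100, phi = 2.3, alpha = 7), 1)
  expect_equal(eb_shrink(150, 100, phi = 1, alpha = 10), 160 / 110)
  # enormous alpha means full shrinkage to 1
  expect_equal(eb_shrink(200, 100, phi = 1, alpha = 1e12), 1,
               tolerance = 1e-9)
  # zero observed stays strictly positive
  expect_gt(eb_shrink(0, 100, phi = 1, alpha = 5), 0)
  expect_error(eb_shrink(100, 0, phi = 1, alpha = 1), "E > 0")
  expect_error(eb_shrink(100, 100, phi = -1, alpha = 1), "phi")
})

test_that("noise-free constant-cost data recover beta0 exactly and tau at floor", {
  cfg <- sim_config(n_hrrs = 5, episodes_per_hrr = 10, procedures = "PHR",
                    beta_true = c(age_c = 0), tau_true = 0, outcome_cv = 0,
                    procedure_intercepts = c(PHR = log(20000)),
                    lookback_claim_rate = 0,
                    exclusion_rates = c(dual_coverage = 0), seed = 2)
  sim <- simulate_claims(cfg)
  f <- fit_casemix_model(truth_frame(sim), "total", character(0))
  expect_lt(abs(f$beta[["(Intercept)"]] - log(20000)), 1e-6)
  expect_true(f$tau_at_floor)
  expect_equal(unname(f$u_hat), rep(1, 5), tolerance = 1e-8)
})

test_that("collinear covariates raise a singular-design error", {
  sim <- simulate_claims(quiet_config(n_hrrs = 4, episodes_per_hrr = 10))
  pf <- truth_frame(sim)
  pf$junior_enlisted <- pf$sex == "M"   # duplicates the sex column
  expect_error(fit_casemix_model(pf, "total", c("sex", "junior_enlisted")),
               "collinear")
})

test_that("the fit matches a brute-force evaluation on a tiny fixture", {
  # 3 HRRs x 2 episodes, intercept-only: every step of the moment scheme
  # has a closed form (Gamma score gives exp(b0) = mean(y/u))
  y <- c(100, 140, 90, 110, 200, 260)
  hrr <- c("A", "A", "B", "B", "C", "C")
  pf <- tibble::tibble(hrr_id = hrr, total = y)
  f <- fit_casemix_model(pf, "total", character(0), max_iter = 200,
                         tol = 1e-12)

  hi <- match(hrr, c("A", "B", "C"))
  u <- rep(1, 3)
  for (it in 1:100) {
    b0 <- log(mean(y / u[hi]))
    mu <- rep(exp(b0), 6)
    mfull <- mu * u[hi]
    phi <- max(sum((y - mfull)^2 / mfull^2) / (6 - 1), 1e-12)
    O <- tapply(y, hi, sum); E <- tapply(mu, hi, sum)
    r <- O / E
    s2 <- tapply(mu^2, hi, sum) / E^2
    tau <- max(1e-8, mean((r - 1)^2 - phi * s2))
    alpha <- 1 / tau
    u_raw <- as.numeric((alpha + O / phi) / (alpha + E / phi))
    u <- u_raw / mean(u_raw)
  }
  expect_equal(f$beta[["(Intercept)"]], b0, tolerance = 1e-8)
  expect_equal(unname(f$E), unname(as.numeric(E)), tolerance = 1e-6)
  expect_equal(unname(f$O / f$E), unname(as.numeric(r)), tolerance = 1e-8)
  expect_equal(unname(f$u_hat), u_raw, tolerance = 1e-6)
  expect_equal(f$phi, phi, tolerance = 1e-6)
  expect_equal(f$tau_hat, tau, tolerance = 1e-6)
})

test_that("shrinkage keeps every u_hat between 1 and its raw ratio", {
  for (s in 1:5) {
    sim <- simulate_claims(quiet_config(seed = 40 + s))
    f <- fit_casemix_model(truth_frame(sim), "total", recovery_covariates)
    r <- f$O / f$E
    expect_true(all(abs(f$u_hat - 1) <= abs(r - 1) + 1e-12))
    expect_true(all((f$u_hat - 1) * (r - 1) >= -1e-12))
    # reliability grows with expected volume
    est <- compute_hrr_estimates(f)
    expect_true(all(diff(est$reliability[order(est$expected)]) >= -1e-12))
  }
})

test_that("an inflated HRR is detected but shrunk toward 1", {
  cfg <- quiet_config(n_hrrs = 8, episodes_per_hrr = 30, tau_true = 0,
                      outcome_cv = 0.5, seed = 77)
  pop <- generate_population(cfg)
  pop$truth$u_by_hrr["HRR003"] <- 1.5
  gen <- generate_claims(cfg, pop)
  sim <- list(truth = gen$truth, beneficiaries = pop$beneficiaries)
  f <- fit_casemix_model(truth_frame(sim), "total", recovery_covariates)
  u <- f$u_hat
  r <- f$O / f$E
  expect_equal(names(which.max(u)), "HRR003")
  expect_gt(u[["HRR003"]], max(u[names(u) != "HRR003"]))
  # shrunk from its raw ratio toward 1, but clearly elevated
  expect_lt(u[["HRR003"]], r[["HRR003"]])
  expect_gt(u[["HRR003"]], 1.05)
})

test_that("zero-cost outcomes in an HRR are handled by the component model", {
  sim <- simulate_claims(quiet_config(n_hrrs = 6, episodes_per_hrr = 40,
                                      seed = 55))
  pf <- truth_frame(sim)
  # wipe readmissions in one HRR entirely
  pf$readmissions[pf$hrr_id == "HRR002"] <- 0
  f <- fit_casemix_model(pf, "readmissions", character(0))
  expect_equal(f$family, "quasipoisson")
  expect_gt(f$u_hat[["HRR002"]], 0)
  expect_lt(f$u_hat[["HRR002"]], 1)
  est <- compute_hrr_estimates(f)
  expect_true(all(est$adjusted_mean > 0))
})

test_that("adjusted means equal the national predicted mean when all ratios are 1", {
  sim <- simulate_claims(quiet_config(n_hrrs = 5, episodes_per_hrr = 10,
                                      tau_true = 0, outcome_cv = 0, seed = 3))
  f <- fit_casemix_model(truth_frame(sim), "total", recovery_covariates)
  est <- compute_hrr_estimates(f)
  expect_equal(unname(f$u_hat), rep(1, 5), tolerance = 1e-6)
  expect_equal(est$adjusted_mean, rep(mean(f$mu), 5), tolerance = 1e-6)
})

test_that("estimated regional effects track the truth in rank", {
  # moderate volume: ranks should be nearly right even with noise
  rhos <- vapply(1:5, function(s) {
    cfg <- sim_config(n_hrrs = 25, episodes_per_hrr = 200, procedures = "PHR",
                      beta_true = c(age_c = 0), tau_true = 0.04,
                      outcome_cv = 0.9, lookback_claim_rate = 0,
                      exclusion_rates = c(dual_coverage = 0), seed = 60 + s)
    sim <- simulate_claims(cfg)
    f <- fit_casemix_model(truth_frame(sim), "total", character(0))
    stats::cor(f$u_hat[names(sim$truth$u_by_hrr)], sim$truth$u_by_hrr,
               method = "spearman")
  }, 0)
  expect_gt(stats::median(rhos), 0.8)
})

test_that("adjusted means are unconfounded by regional case mix under the null", {
  # strong regional differences in Charlson burden, no true HRR effect:
  # case-mix adjustment should leave no association between adjusted means
  # and the regional covariate mix
  cfg <- sim_config(n_hrrs = 20, episodes_per_hrr = 100, procedures = "PHR",
                    tau_true = 0, outcome_cv = 0.5, confound_strength = 0.5,
                    exclusion_rates = c(dual_coverage = 0), seed = 91)
  sim <- simulate_claims(cfg)
  pf <- truth_frame(sim)
  f <- fit_casemix_model(pf, "total", recovery_covariates)
  est <- compute_hrr_estimates(f)
  mix <- tapply(pf$charlson, pf$hrr_id, mean)[est$hrr_id]
  ct <- stats::cor.test(est$adjusted_mean, mix)
  expect_gt(ct$p.value, 0.05)
  # without adjustment the same data show a real association
  f0 <- fit_casemix_model(pf, "total", character(0))
  est0 <- compute_hrr_estimates(f0)
  ct0 <- stats::cor.test(est0$adjusted_mean, mix)
  expect_lt(ct0$p.value, 0.05)
})
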