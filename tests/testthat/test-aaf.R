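## true-parameter fit with a single binary factor, constant hazard, theta 0
toy_fit <- function(hr = 2, lam0 = 2e-4, theta = 0) {
  frailty_fit_from_parameters(
    log_hr = list(birth_weight_group = c(lt2500 = log(hr))),
    theta = theta, baseline_breaks = 0, baseline_rates = lam0,
    max_time = 730
  )
}

toy_records <- function(N = 1000, p = 0.4) {
  make_records(N, birth_weight_group = rep(c("lt2500", "ge2500"),
                                           c(round(p * N), N - round(p * N))))
}

test_that("expected deaths follow directly from predicted survival", {
  ## zero hazard -> zero expected deaths
  fit0 <- frailty_fit_from_parameters(
    log_hr = list(birth_weight_group = c(lt2500 = 0)), theta = 0,
    baseline_breaks = 0, baseline_rates = 0, max_time = 730
  )
  d0 <- expected_deaths(fit0, toy_records(50), 730)
  expect_equal(d0$expected_deaths, 0)
  ## N identical children with S(t) = 0.9 -> D = 0.1 N
  lam <- -log(0.9) / 730
  fit9 <- frailty_fit_from_parameters(
    log_hr = list(birth_weight_group = c(lt2500 = 0)), theta = 0,
    baseline_breaks = 0, baseline_rates = lam, max_time = 730
  )
  d9 <- expected_deaths(fit9, make_records(200), 730)
  expect_equal(d9$expected_deaths, 0.1 * 200, tolerance = 1e-9)
})

test_that("model-expected mortality matches the generator's true death probability", {
  cfg <- binary_factor_config(p_exposed = 0.4, hr = 2.5, theta = 0,
                              lambda0 = 3e-4, n_studies = 4,
                              children_per_study = 2000)
  rec <- generate_cohort(cfg, seed = 81)
  fit <- frailty_fit_from_parameters(
    cfg$true_log_hr, theta = 0, baseline_breaks = cfg$baseline_breaks,
    baseline_rates = cfg$baseline_rates, max_time = 730
  )
  d <- expected_deaths(fit, rec, 730)
  p_true <- 0.6 * (1 - exp(-3e-4 * 730)) + 0.4 * (1 - exp(-2.5 * 3e-4 * 730))
  se <- sqrt(p_true * (1 - p_true) / nrow(rec))
  expect_lt(abs(d$expected_deaths / d$n - p_true), 3 * se)
})

test_that("attributable fraction matches the closed form at true parameters", {
  p <- 0.4
  lam0 <- 2e-4
  hr <- 2
  res <- compute_aaf(toy_fit(hr, lam0), toy_records(1000, p),
                     factors = list(lbw = "birth_weight_group"),
                     horizons = c(183, 365, 730))
  for (i in seq_len(nrow(res))) {
    t <- res$horizon_days[i]
    expect_lt(abs(res$aaf[i] - closed_form_af(p, lam0, hr * lam0, t)), 1e-8)
  }
})

test_that("attributable fraction is zero under zero prevalence, null level or null effect", {
  ## nobody exposed
  res0 <- compute_aaf(toy_fit(), toy_records(100, p = 0),
                      factors = list(lbw = "birth_weight_group"),
                      horizons = 730)
  expect_equal(res0$aaf, 0)
  ## counterfactual equal to factual for everyone (all already ge2500)
  expect_equal(res0$attributable_deaths, 0)
  ## exposed but with a null coefficient
  res_null <- compute_aaf(toy_fit(hr = 1), toy_records(100, p = 0.5),
                          factors = list(lbw = "birth_weight_group"),
                          horizons = 730)
  expect_lt(abs(res_null$aaf), 1e-12)
})

test_that("attributable plus non-attributable deaths decompose exactly and scale-invariantly", {
  rec <- toy_records(400, 0.3)
  res <- compute_aaf(toy_fit(3), rec,
                     factors = list(lbw = "birth_weight_group"),
                     horizons = c(365, 730))
  expect_equal(res$attributable_deaths + res$expected_deaths_cf,
               res$expected_deaths, tolerance = 1e-12)
  ## duplicating every record leaves the fraction unchanged
  dup <- dplyr::bind_rows(rec, dplyr::mutate(rec, child_id = paste0(child_id, "_d")))
  res2 <- compute_aaf(toy_fit(3), dup,
                      factors = list(lbw = "birth_weight_group"),
                      horizons = c(365, 730))
  expect_equal(res2$aaf, res$aaf, tolerance = 1e-12)
  expect_equal(res2$attributable_deaths, 2 * res$attributable_deaths,
               tolerance = 1e-9)
})

test_that("the combined attributable fraction dominates each single factor", {
  ## two harmful multiplicative factors on a toy population
  fit <- frailty_fit_from_parameters(
    log_hr = list(birth_weight_group = c(lt2500 = log(2.5)),
                  ever_breastfed = c("FALSE" = log(2))),
    theta = 0, baseline_breaks = 0, baseline_rates = 3e-4, max_time = 730
  )
  rec <- make_records(400,
    birth_weight_group = rep(c("lt2500", "ge2500"), each = 200),
    ever_breastfed = rep(c(TRUE, FALSE), 200),
    weaning_age_days = rep(c(183, NA), 200)
  )
  res <- compute_aaf(
    fit, rec,
    factors = list(lbw = "birth_weight_group", bf = "ever_breastfed",
                   both = c("birth_weight_group", "ever_breastfed")),
    horizons = 730
  )
  both <- res$aaf[res$factor == "both"]
  expect_gte(both, res$aaf[res$factor == "lbw"])
  expect_gte(both, res$aaf[res$factor == "bf"])
})

test_that("estimated aAF approaches the generator truth as the cohort grows", {
  cfg_of_n <- function(n) {
    binary_factor_config(p_exposed = 0.35, hr = 2.9, theta = 0.2,
                         lambda0 = 4e-4, n_studies = 8,
                         children_per_study = n / 8)
  }
  truth <- true_attributable_fraction(cfg_of_n(2000), "birth_weight_group",
                                      horizon_days = 730, n_mc = 2e5)
  err <- vapply(c(2000, 8000), function(n) {
    cfg <- cfg_of_n(n)
    devs <- vapply(1:6, function(i) {
      rec <- generate_cohort(cfg, seed = 8200 + n + i)
      ep <- split_episodes(rec, "maternal_vital_only")
      fit <- fit_frailty_cox(ep, "birth_weight_group",
                             control = frailty_control(eps = 1e-5,
                                                       compute_se = FALSE))
      res <- compute_aaf(fit, rec,
                         factors = list(lbw = "birth_weight_group"),
                         horizons = 730)
      res$aaf - as.numeric(truth)
    }, numeric(1))
    abs(mean(devs))
  }, numeric(1))
  ## the floor covers Monte-Carlo noise of the replicate mean
  expect_lt(err[2], max(err[1], 0.03))
})

test_that("bootstrap intervals are reproducible and honest about nulls", {
  cfg <- binary_factor_config(p_exposed = 0.4, hr = 1, theta = 0.1,
                              lambda0 = 6e-4, n_studies = 5,
                              children_per_study = 200)
  rec <- generate_cohort(cfg, seed = 83)
  b1 <- bootstrap_aaf(rec, "birth_weight_group",
                      factors = list(lbw = "birth_weight_group"),
                      horizons = 730, B = 12, seed = 84)
  b2 <- bootstrap_aaf(rec, "birth_weight_group",
                      factors = list(lbw = "birth_weight_group"),
                      horizons = 730, B = 12, seed = 84)
  expect_equal(b1$ci_lower, b2$ci_lower)
  expect_equal(b1$ci_upper, b2$ci_upper)
  ## a factor with no effect: the interval straddles zero
  expect_lte(b1$ci_lower, 0.05)
  expect_gte(b1$ci_upper, -0.05)
  expect_error(bootstrap_aaf(rec, "birth_weight_group", B = 12),
               "seed")
})
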