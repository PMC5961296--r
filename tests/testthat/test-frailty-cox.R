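library(survival)

## shared fixture: one event-rich multi-study cohort with enough maternal
## deaths that every model level carries events
frailty_fixture <- local({
  rec <- quiet_categorize(
    generate_cohort(fast_config(n_studies = 8, children_per_study = 400,
                                theta = 0.4, maternal_death_rate = 2e-4),
                    seed = 61)
  )
  split_episodes(rec, "maternal_vital_only")
})

## dense single-study fixture for exact reduction to plain Cox
reduction_fixture <- reduction_fixture_acceptance(seed = 60)

relevel_for_coxph <- function(ep) {
  dplyr::mutate(ep,
    birth_weight_group = relevel(factor(birth_weight_group), "ge2500"),
    ever_breastfed = factor(ever_breastfed, c("TRUE", "FALSE")),
    cd4_group = relevel(factor(cd4_group), "ge350"),
    mother_dead = factor(mother_dead)
  )
}

test_that("with theta fixed at zero the fit reduces to an ordinary Cox model", {
  ep <- reduction_fixture
  fit <- fit_frailty_cox(ep, c("birth_weight_group", "ever_breastfed",
                               "mother_dead", "cd4_group"), theta = 0)
  cx <- coxph(
    Surv(start, stop, event) ~ birth_weight_group + ever_breastfed +
      mother_dead + cd4_group,
    data = relevel_for_coxph(ep), ties = "breslow",
    control = coxph.control(eps = 1e-11, iter.max = 50,
                            toler.chol = 1e-13)
  )
  b <- coef(cx)
  expect_lt(max(abs(fit$beta - b[names(fit$beta)])), 1e-6)
  expect_lt(max(abs(fit$se_beta - sqrt(diag(vcov(cx)))[names(fit$beta)])),
            1e-6)
  ## Breslow baseline agrees too
  bh <- basehaz(cx, centered = FALSE)
  expect_lt(max(abs(fit$baseline$cumhaz -
                      bh$hazard[match(fit$baseline$time, bh$time)])), 1e-8)
})

test_that("estimates agree with the established gamma-frailty implementation", {
  fit <- suppressWarnings(
    fit_frailty_cox(frailty_fixture,
                    c("birth_weight_group", "ever_breastfed", "mother_dead"))
  )
  cf <- coxph(
    Surv(start, stop, event) ~ birth_weight_group + ever_breastfed +
      mother_dead + frailty(study_id, distribution = "gamma", eps = 1e-10),
    data = relevel_for_coxph(frailty_fixture), ties = "breslow",
    outer.max = 50
  )
  b <- coef(cf)
  expect_lt(max(abs(fit$beta - b[names(fit$beta)])), 1e-3)
  expect_lt(abs(fit$theta - cf$history[[1]]$theta), 1e-2)
  ## frailty normalization: posterior means average near 1
  expect_lt(abs(mean(fit$frailties) - 1), 0.1)
  expect_gte(min(fit$frailties), 0)
})

test_that("a contrast-free covariate is excluded with a warning and the fit proceeds", {
  ep <- dplyr::mutate(frailty_fixture, constant_cov = "same")
  expect_warning(
    fit <- fit_frailty_cox(ep, c("birth_weight_group", "constant_cov"),
                           theta = 0),
    "single level"
  )
  expect_false(any(grepl("constant_cov", names(fit$beta))))
  expect_true("constant_cov" %in% fit$dropped)
})

test_that("rescaling all episode times leaves the hazard ratios unchanged", {
  fit1 <- fit_frailty_cox(frailty_fixture, "birth_weight_group", theta = 0.2)
  scaled <- dplyr::mutate(frailty_fixture, start = start * 7, stop = stop * 7)
  fit2 <- fit_frailty_cox(scaled, "birth_weight_group", theta = 0.2)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-8)
})

test_that("frailty variance estimates collapse when studies are homogeneous", {
  cfg <- binary_factor_config(p_exposed = 0.3, hr = 1.5, theta = 0,
                              lambda0 = 4e-4, n_studies = 6,
                              children_per_study = 150)
  thetas <- vapply(1:30, function(i) {
    rec <- generate_cohort(cfg, seed = 6100 + i)
    ep <- split_episodes(rec, "maternal_vital_only")
    fit <- fit_frailty_cox(ep, "birth_weight_group",
                           control = frailty_control(eps = 1e-5,
                                                     compute_se = FALSE))
    fit$theta
  }, numeric(1))
  expect_lt(median(thetas), 0.02)
})

test_that("coefficient bias shrinks as the cohort grows", {
  true_b <- log(2.9)
  bias <- vapply(c(400, 1600, 6400), function(n) {
    cfg <- binary_factor_config(p_exposed = 0.3, hr = 2.9, theta = 0.2,
                                lambda0 = 4e-4, n_studies = 8,
                                children_per_study = n / 8)
    est <- vapply(1:6, function(i) {
      rec <- generate_cohort(cfg, seed = 6200 + 17 * n + i)
      ep <- split_episodes(rec, "maternal_vital_only")
      fit_frailty_cox(ep, "birth_weight_group",
                      control = frailty_control(eps = 1e-5,
                                                compute_se = FALSE))$beta[[1]]
    }, numeric(1))
    abs(mean(est) - true_b)
  }, numeric(1))
  expect_lt(bias[3], bias[1])
})

test_that("marginal survival prediction matches its analytic forms", {
  fit <- frailty_fit_from_parameters(
    log_hr = list(birth_weight_group = c(lt2500 = log(2))),
    theta = 0.5, baseline_breaks = c(0, 100, 300),
    baseline_rates = c(5e-4, 3e-4, 1e-4), max_time = 730
  )
  paths <- tibble::tibble(
    child_id = c("a", "b"), start = 0, stop = 730,
    birth_weight_group = c("lt2500", "ge2500")
  )
  ## t = 0 gives survival 1
  s0 <- predict_marginal_survival(fit, paths, 0)
  expect_equal(s0$survival, c(1, 1))
  ## quadrature oracle: integrate exp(-u H) over the gamma(1/theta, 1/theta)
  t <- 500
  H <- c(2, 1) * (100 * 5e-4 + 200 * 3e-4 + (t - 300) * 1e-4)
  s <- predict_marginal_survival(fit, paths, t)
  for (i in 1:2) {
    quad <- stats::integrate(function(u) {
      exp(-u * H[i]) * stats::dgamma(u, shape = 2, rate = 2)
    }, 0, Inf, rel.tol = 1e-12)$value
    expect_lt(abs(s$survival[i] - quad), 1e-8)
  }
  ## theta -> 0 limit equals exp(-H)
  fit0 <- frailty_fit_from_parameters(
    log_hr = list(birth_weight_group = c(lt2500 = log(2))),
    theta = 1e-12, baseline_breaks = c(0, 100, 300),
    baseline_rates = c(5e-4, 3e-4, 1e-4), max_time = 730
  )
  s_lim <- predict_marginal_survival(fit0, paths, t)
  expect_lt(max(abs(s_lim$survival - exp(-H))), 1e-10)
})

test_that("conditional prediction uses the study's own frailty", {
  fit <- suppressWarnings(
    fit_frailty_cox(frailty_fixture, "birth_weight_group")
  )
  rec <- make_records(1, study_id = "S01")
  paths <- build_prediction_paths(rec, 730)
  s_m <- predict_marginal_survival(fit, paths, 400)
  s_c <- predict_marginal_survival(fit, paths, 400, type = "conditional")
  H <- -log(s_c$survival) / fit$frailties[["S01"]]
  expect_equal(s_m$survival, (1 + fit$theta * H)^(-1 / fit$theta),
               tolerance = 1e-8)
})
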