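## fixture with a real effect, a null covariate and maternal ARV exposure
selection_fixture <- local({
  cfg <- fast_config(
    n_studies = 8, children_per_study = 300, theta = 0.2,
    true_log_hr = list(
      birth_weight_group = c(lt2500 = log(2.9)),
      mother_dead = c("1" = log(8))
    )
  )
  rec <- quiet_categorize(generate_cohort(cfg, seed = 71))
  ## pure-noise covariate, independent of everything
  set.seed(72)
  rec$noise_cov <- sample(c("x", "y"), nrow(rec), replace = TRUE)
  split_episodes(rec, "maternal_vital_only") %>%
    dplyr::left_join(dplyr::distinct(rec, child_id, noise_cov),
                     by = "child_id")
})

test_that("univariate screen reports one frailty model per covariate", {
  sc <- univariate_screen(selection_fixture,
                          c("birth_weight_group", "mother_dead", "noise_cov"))
  expect_setequal(unique(sc$covariate),
                  c("birth_weight_group", "mother_dead", "noise_cov"))
  ## strong effects detected, noise not
  expect_lt(sc$block_p[sc$covariate == "birth_weight_group"][1], 1e-4)
  expect_lt(sc$block_p[sc$covariate == "mother_dead"][1], 1e-4)
  expect_gt(sc$block_p[sc$covariate == "noise_cov"][1], 0.01)
  ## a duplicated covariate gives the identical hazard ratio
  dup <- dplyr::mutate(selection_fixture, bw_copy = birth_weight_group)
  sc2 <- univariate_screen(dup, c("birth_weight_group", "bw_copy"),
                           reference = list(bw_copy = "ge2500"))
  expect_equal(sc2$hr[sc2$covariate == "birth_weight_group"],
               sc2$hr[sc2$covariate == "bw_copy"], tolerance = 1e-8)
})

test_that("univariate Wald p-values hold their type-I error on null covariates", {
  cfg <- binary_factor_config(p_exposed = 0.5, hr = 1, theta = 0,
                              lambda0 = 6e-4, n_studies = 4,
                              children_per_study = 100)
  set.seed(73)
  pvals <- vapply(1:120, function(i) {
    rec <- generate_cohort(cfg, seed = 7300 + i)
    ep <- split_episodes(rec, "maternal_vital_only")
    sc <- univariate_screen(ep, "birth_weight_group", theta = 0,
                            control = frailty_control(compute_se = TRUE))
    sc$block_p[1]
  }, numeric(1))
  ## ~10% of null covariates pass the 0.1 screen (binomial 3-sigma band)
  expect_lt(abs(mean(pvals < 0.1) - 0.1), 3 * sqrt(0.1 * 0.9 / 120))
})

test_that("a strong effect at large n is overwhelmingly significant", {
  cfg <- binary_factor_config(p_exposed = 0.3, hr = 3, theta = 0,
                              lambda0 = 4e-4, n_studies = 5,
                              children_per_study = 1000)
  rec <- generate_cohort(cfg, seed = 74)
  ep <- split_episodes(rec, "maternal_vital_only")
  sc <- univariate_screen(ep, "birth_weight_group")
  expect_lt(sc$p.value[1], 1e-4)
})

test_that("stepwise descent drops noise, keeps real effects and protected covariates", {
  spec <- model_spec(
    c("birth_weight_group", "mother_dead", "noise_cov", "arv_category"),
    always_keep = "arv_category", forced = character(0)
  )
  sel <- stepwise_descending_select(selection_fixture, spec)
  expect_false("noise_cov" %in% sel$spec$covariates)
  expect_true(all(c("birth_weight_group", "mother_dead") %in%
                    sel$spec$covariates))
  ## arv_category was simulated null here yet must remain
  expect_true("arv_category" %in% sel$spec$covariates)
  expect_s3_class(sel$fit, "frailty_cox_fit")
})

test_that("noise covariates are dropped in the vast majority of replicates", {
  kept <- vapply(1:25, function(i) {
    cfg <- binary_factor_config(p_exposed = 0.3, hr = 2.5, theta = 0,
                                lambda0 = 6e-4, n_studies = 4,
                                children_per_study = 150)
    rec <- generate_cohort(cfg, seed = 7500 + i)
    set.seed(7600 + i)
    rec$noise_cov <- sample(c("x", "y"), nrow(rec), replace = TRUE)
    ep <- split_episodes(rec, "maternal_vital_only")
    ep$noise_cov <- rec$noise_cov[match(ep$child_id, rec$child_id)]
    spec <- model_spec(c("birth_weight_group", "noise_cov"),
                       always_keep = character(0), forced = character(0))
    sel <- stepwise_descending_select(ep, spec, theta = 0,
                                      control = frailty_control(eps = 1e-5))
    "noise_cov" %in% sel$spec$covariates
  }, logical(1))
  ## nominal retention rate is stay_p = 0.05; allow a 3-sigma binomial band
  expect_lte(sum(kept), ceiling(25 * 0.05 + 3 * sqrt(25 * 0.05 * 0.95)))
})

test_that("the joint breastfeeding-by-ART model recovers the four-category gradient", {
  cfg <- fast_config(
    n_studies = 10, children_per_study = 500, theta = 0.2,
    baseline_rates = c(1.6e-3, 1e-3, 6e-4, 4e-4),
    true_log_hr = list(
      bf_art_category = c(B = log(0.63), C = log(0.08), D = log(0.04))
    ),
    prevalences = list(
      region = c(Africa = 1), sex = c(male = 1),
      birth_weight_group = c(ge2500 = 0.88, lt2500 = 0.12),
      ever_breastfed = c("TRUE" = 0.7, "FALSE" = 0.3),
      arv_category = c(none = 0.4, mono_dual_pmtct = 0.2, art_pmtct = 0.25,
                       art_life = 0.15),
      cd4_group = c(ge350 = 0.6, lt350 = 0.4)
    )
  )
  rec <- quiet_categorize(generate_cohort(cfg, seed = 76))
  ep <- split_episodes(rec, "bf_by_art_joint")
  expect_setequal(unique(ep$bf_art_category), c("A", "B", "C", "D"))
  fit <- fit_joint_bf_art(ep, adjusters = c("cd4_group",
                                            "birth_weight_group"))
  td <- tidy(fit, exponentiate = TRUE)
  truth <- c(bf_art_categoryB = 0.63, bf_art_categoryC = 0.08,
             bf_art_categoryD = 0.04)
  for (nm in names(truth)) {
    row <- td[td$term == nm, ]
    expect_lt(row$conf.low, truth[[nm]])
    expect_gt(row$conf.high, truth[[nm]])
  }
  ## all-A degenerate data flag the missing levels
  rec_a <- make_records(50, ever_breastfed = FALSE,
                        weaning_age_days = NA_real_,
                        child_death_age_days = c(rep(300, 5), rep(NA, 45)),
                        censor_age_days = c(rep(300, 5), rep(NA, 45)))
  rec_a$censor_age_days[is.na(rec_a$censor_age_days)] <- 730
  ep_a <- split_episodes(quiet_categorize(rec_a), "bf_by_art_joint")
  expect_warning(try(fit_joint_bf_art(ep_a, adjusters = NULL), silent = TRUE),
                 "one breastfeeding/ART category")
  expect_error(suppressWarnings(fit_joint_bf_art(ep_a, adjusters = NULL)),
               "No estimable")
})

test_that("relabeling the exposure categories permutes the hazard ratios consistently", {
  rec <- quiet_categorize(generate_cohort(fast_config(n_studies = 4,
                                                      children_per_study = 400),
                                          seed = 77))
  ep <- split_episodes(rec, "bf_by_art_joint")
  fit1 <- fit_frailty_cox(ep, "bf_art_category", theta = 0.1)
  ## swap labels B and C; fit with the same reference A
  ep2 <- dplyr::mutate(ep, bf_art_category = dplyr::recode(bf_art_category,
                                                           B = "C", C = "B"))
  fit2 <- fit_frailty_cox(ep2, "bf_art_category", theta = 0.1)
  expect_equal(fit1$beta[["bf_art_categoryB"]],
               fit2$beta[["bf_art_categoryC"]], tolerance = 1e-8)
  expect_equal(fit1$beta[["bf_art_categoryC"]],
               fit2$beta[["bf_art_categoryB"]], tolerance = 1e-8)
})
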