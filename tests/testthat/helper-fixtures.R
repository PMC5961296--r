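## Minimal valid child record(s); override any column by name.
make_records <- function(n = 1, ...) {
  rec <- tibble::tibble(
    child_id = sprintf("c%03d", seq_len(n)),
    study_id = "S01",
    region = "Africa",
    sex = "male",
    birth_weight_group = "ge2500",
    ever_breastfed = TRUE,
    weaning_age_days = 183,
    arv_category = "none",
    art_start_age_days = NA_real_,
    art_end_age_days = NA_real_,
    cd4_group = "ge350",
    maternal_death_age_days = NA_real_,
    child_death_age_days = NA_real_,
    censor_age_days = 730
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

## Small, event-rich generator config for fast model tests.
fast_config <- function(n_studies = 6, children_per_study = 150,
                        theta = 0.25,
                        baseline_rates = c(8e-4, 5e-4, 3e-4, 2e-4), ...) {
  cohort_config(
    n_studies = n_studies, children_per_study = children_per_study,
    theta = theta, baseline_rates = baseline_rates,
    ...
  )
}

## One-factor config with analytically convenient structure.
binary_factor_config <- function(p_exposed = 0.4, hr = 2.9, theta = 0,
                                 lambda0 = 2e-4, n_studies = 1,
                                 children_per_study = 500, ...) {
  cohort_config(
    n_studies = n_studies, children_per_study = children_per_study,
    theta = theta,
    baseline_breaks = 0, baseline_rates = lambda0,
    true_log_hr = list(birth_weight_group = c(lt2500 = log(hr))),
    prevalences = list(
      region = c(Africa = 1), sex = c(male = 1),
      birth_weight_group = c(ge2500 = 1 - p_exposed, lt2500 = p_exposed),
      ever_breastfed = c("TRUE" = 1), arv_category = c(none = 1),
      cd4_group = c(ge350 = 1)
    ),
    maternal_death_rate = 0,
    ...
  )
}

## Dense single-study cohort where every model level carries events:
## the fixture for exact reduction-to-Cox comparisons.
reduction_fixture_acceptance <- function(seed = 60) {
  cfg <- fast_config(
    n_studies = 1, children_per_study = 500, theta = 0,
    baseline_rates = c(1.6e-3, 1e-3, 6e-4, 4e-4),
    maternal_death_rate = 3e-4,
    prevalences = list(
      region = c(Africa = 1), sex = c(male = 0.5, female = 0.5),
      birth_weight_group = c(ge2500 = 0.7, lt2500 = 0.3),
      ever_breastfed = c("TRUE" = 0.65, "FALSE" = 0.35),
      arv_category = c(none = 1), cd4_group = c(ge350 = 0.6, lt350 = 0.4)
    )
  )
  split_episodes(quiet_categorize(generate_cohort(cfg, seed = seed)),
                 "maternal_vital_only")
}

quiet_categorize <- function(rec, ...) {
  apply_categorization(rec, quiet = TRUE, ...)
}

## Closed-form AF for one binary factor, constant hazards, no frailty.
closed_form_af <- function(p, lam0, lam1, t) {
  (p * (exp(-lam0 * t) - exp(-lam1 * t))) /
    (1 - p * exp(-lam1 * t) - (1 - p) * exp(-lam0 * t))
}
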