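#' Default counterfactual ("nonexposed") assignments
#'
#' The four risk factors whose population-level contribution the analysis
#' quantifies, with the counterfactual level each child is assigned when
#' computing the attributable fraction:
#'
#' * `birth_weight_group` — everyone to `"ge2500"` (no low birth weight);
#' * `ever_breastfed` — everyone breastfed, never-breastfed children given
#'   the default breastfeeding path (birth to `impute_bf_days`, or the
#'   mother's death if earlier);
#' * `arv_category` — every mother on 3-drug ART for life (the protective
#'   extreme, not the model's reference level of no ARVs);
#' * `mother_dead` — every mother alive throughout follow-up.
#'
#' @return Named list mapping factor set name to the character vector of
#'   factors it reassigns (`"combined"` applies all four at once).
#' @export
aaf_factors <- function() {
  list(
    mother_not_on_art_life = "arv_category",
    low_birth_weight = "birth_weight_group",
    never_breastfed = "ever_breastfed",
    maternal_death = "mother_dead",
    combined = c("arv_category", "birth_weight_group", "ever_breastfed",
                 "mother_dead")
  )
}

## Apply the counterfactual reassignments to child records.
counterfactual_records <- function(records, factors, impute_bf_days = 183) {
  r <- records
  known <- c("birth_weight_group", "ever_breastfed", "arv_category",
             "mother_dead")
  bad <- setdiff(factors, known)
  if (length(bad)) {
    abort(paste0("Unknown counterfactual factor(s): ",
                 paste(bad, collapse = ", ")))
  }
  if ("birth_weight_group" %in% factors) {
    r$birth_weight_group <- "ge2500"
  }
  if ("ever_breastfed" %in% factors) {
    md <- ifelse(is.na(r$maternal_death_age_days), Inf,
                 r$maternal_death_age_days)
    imputed <- pmin(impute_bf_days, md)
    r$weaning_age_days <- ifelse(isTRUE_vec(r$ever_breastfed),
                                 r$weaning_age_days, imputed)
    r$ever_breastfed <- TRUE
  }
  if ("arv_category" %in% factors) {
    r$arv_category <- "art_life"
    r$art_start_age_days <- 0
    r$art_end_age_days <- Inf
  }
  if ("mother_dead" %in% factors) {
    r$maternal_death_age_days <- NA_real_
  }
  r
}

infer_scheme <- function(fit) {
  covs <- fit$terms$covariate
  if ("bf_art_category" %in% covs || "mother_on_art3" %in% covs) {
    "bf_by_art_joint"
  } else if ("currently_breastfed" %in% covs) {
    "plus_bf_cessation"
  } else {
    "maternal_vital_only"
  }
}

#' Model-expected number of deaths by a horizon
#'
#' `D(t) = N - sum_i S_i(t)`: the total population minus the sum of each
#' child's predicted marginal survival probability, with every covariate
#' path extended to the horizon (prediction is a full-population
#' expectation, not restricted to observed follow-up).
#'
#' @param fit a `frailty_cox_fit`.
#' @param records categorized child records.
#' @param t horizon(s) in days.
#' @param scheme path-expansion scheme; default inferred from the fit's
#'   covariates.
#' @return A tibble with `horizon_days`, `n`, `expected_deaths`.
#' @export
expected_deaths <- function(fit, records, t = 730, scheme = NULL) {
  scheme <- scheme %||% infer_scheme(fit)
  paths <- build_prediction_paths(records, horizon = max(t), scheme = scheme)
  missing_path <- setdiff(records$child_id, paths$child_id)
  if (length(missing_path)) {
    abort(paste0("No covariate path for child(ren): ",
                 paste(utils::head(missing_path, 5), collapse = ", ")))
  }
  pred <- predict_marginal_survival(fit, paths, t)
  pred %>%
    group_by(horizon_days = .data$horizon_days) %>%
    summarise(n = n(), expected_deaths = n() - sum(.data$survival),
              .groups = "drop")
}

#' Counterfactual adjusted attributable fractions
#'
#' For each factor set and horizon `t`, computes the expected deaths `D(t)`
#' under the factual covariate paths, the expected deaths `D_cf(t)` after
#' reassigning every child the nonexposed level of the factor(s) (other
#' covariates unchanged), and the adjusted attributable fraction
#' `aAF = (D - D_cf) / D`, the share of expected deaths that would be
#' averted under the counterfactual. Combined factor sets apply all
#' reassignments simultaneously.
#'
#' @param fit a `frailty_cox_fit` (estimated, or constructed from known
#'   parameters via [frailty_fit_from_parameters()]).
#' @param records categorized child records.
#' @param factors named list of factor sets, as [aaf_factors()].
#' @param horizons evaluation ages in days (default 6, 12, 24 months).
#' @param impute_bf_days breastfeeding path assigned to never-breastfed
#'   children under the breastfeeding counterfactual.
#' @param scheme path-expansion scheme; default inferred from the fit.
#' @return A tibble of class `aaf_result` with `factor`, `horizon_days`,
#'   `n`, `expected_deaths`, `expected_deaths_cf`, `attributable_deaths`,
#'   `aaf`.
#' @export
#' @examples
#' fit <- frailty_fit_from_parameters(
#'   log_hr = list(birth_weight_group = c(lt2500 = log(2))),
#'   theta = 0, baseline_breaks = 0, baseline_rates = 1e-4
#' )
#' rec <- tibble::tibble(
#'   child_id = c("a", "b"), study_id = "s", region = "Africa",
#'   sex = "male", birth_weight_group = c("lt2500", "ge2500"),
#'   ever_breastfed = TRUE, weaning_age_days = 183, arv_category = "none",
#'   art_start_age_days = NA_real_, art_end_age_days = NA_real_,
#'   cd4_group = "ge350", maternal_death_age_days = NA_real_,
#'   child_death_age_days = NA_real_, censor_age_days = 730
#' )
#' compute_aaf(fit, rec, factors = list(lbw = "birth_weight_group"),
#'             horizons = 730)
compute_aaf <- function(fit, records, factors = aaf_factors(),
                        horizons = c(183, 365, 730), impute_bf_days = 183,
                        scheme = NULL) {
  stopifnot(inherits(fit, "frailty_cox_fit"))
  scheme <- scheme %||% infer_scheme(fit)
  d_fact <- expected_deaths(fit, records, horizons, scheme = scheme)
  if (any(d_fact$expected_deaths <= 0)) {
    warn("Expected deaths are zero at some horizon; aAF undefined (NA).")
  }
  out <- purrr::imap_dfr(factors, function(fs, nm) {
    rec_cf <- counterfactual_records(records, fs,
                                     impute_bf_days = impute_bf_days)
    d_cf <- expected_deaths(fit, rec_cf, horizons, scheme = scheme)
    tibble(
      factor = nm,
      horizon_days = d_fact$horizon_days,
      n = d_fact$n,
      expected_deaths = d_fact$expected_deaths,
      expected_deaths_cf = d_cf$expected_deaths,
      attributable_deaths = d_fact$expected_deaths - d_cf$expected_deaths,
      aaf = ifelse(d_fact$expected_deaths > 0,
                   (d_fact$expected_deaths - d_cf$expected_deaths) /
                     d_fact$expected_deaths,
                   NA_real_)
    )
  })
  class(out) <- c("aaf_result", class(out))
  out
}

#' Bootstrap confidence intervals for attributable fractions
#'
#' Resamples children with replacement within each study stratum (study
#' sizes preserved), re-runs the full pipeline — episode splitting, frailty
#' Cox fit, attributable fractions — on every resample, and reports
#' percentile 95% intervals around the full-data estimates. Resamples with
#' no events are skipped and counted; more than 20% skips is an error.
#'
#' @param records categorized child records.
#' @param covariates model covariates (character vector or [model_spec()])
#'   refitted on each resample.
#' @param factors named list of factor sets, as [aaf_factors()].
#' @param horizons evaluation ages in days.
#' @param B number of bootstrap resamples (default 500).
#' @param seed RNG seed (required for reproducibility).
#' @param cluster cluster column.
#' @param theta `NULL` to re-estimate the frailty variance per resample.
#' @param scheme episode scheme for fitting; default inferred from the
#'   covariates.
#' @param impute_bf_days breastfeeding path for the never-breastfed
#'   counterfactual.
#' @param conf_level interval level (default 0.95).
#' @param control fitting control for the resample fits; defaults to a
#'   fast configuration without standard errors.
#' @return An `aaf_result` tibble with `ci_lower`, `ci_upper`,
#'   `n_bootstrap` (usable resamples) and `n_skipped` columns, and the
#'   bootstrap draws in attribute `"boot_aaf"`.
#' @export
bootstrap_aaf <- function(records, covariates, factors = aaf_factors(),
                          horizons = c(183, 365, 730), B = 500L, seed,
                          cluster = "study_id", theta = NULL, scheme = NULL,
                          impute_bf_days = 183, conf_level = 0.95,
                          control = frailty_control(eps = 1e-4,
                                                    nr_max_iter = 2L,
                                                    compute_se = FALSE)) {
  if (missing(seed)) abort("`seed` is required for a reproducible bootstrap.")
  stopifnot(B >= 2)
  if (inherits(covariates, "heu_model_spec")) {
    cluster <- covariates$cluster
    covariates <- covariates$covariates
  }
  covs_for_scheme <- covariates
  scheme <- scheme %||% {
    if ("bf_art_category" %in% covs_for_scheme) "bf_by_art_joint"
    else if ("currently_breastfed" %in% covs_for_scheme) "plus_bf_cessation"
    else "maternal_vital_only"
  }
  local_seed(seed)

  run_once <- function(rec, init = NULL, init_theta = 0.1,
                       ctrl = control) {
    ep <- split_episodes(rec, scheme)
    if (sum(ep$event) == 0L) return(NULL)
    fit <- fit_frailty_cox(ep, covariates, cluster = cluster, theta = theta,
                           init = init, init_theta = init_theta,
                           control = ctrl)
    list(fit = fit,
         aaf = compute_aaf(fit, rec, factors = factors, horizons = horizons,
                           impute_bf_days = impute_bf_days, scheme = scheme))
  }

  main <- run_once(records,
                   ctrl = frailty_control(compute_se = FALSE))
  if (is.null(main)) abort("No events in `records`.")
  est <- main$aaf

  idx_by_study <- split(seq_len(nrow(records)), records$study_id)
  draws <- vector("list", B)
  skipped <- 0L
  for (b in seq_len(B)) {
    take <- unlist(lapply(idx_by_study, function(ii) {
      sample(ii, length(ii), replace = TRUE)
    }), use.names = FALSE)
    rec_b <- records[take, , drop = FALSE]
    rec_b$child_id <- sprintf("bb%07d", seq_along(take))
    res <- tryCatch(
      suppressWarnings(run_once(rec_b, init = main$fit$beta,
                                init_theta = max(main$fit$theta, 1e-3))),
      error = function(e) NULL
    )
    if (is.null(res)) {
      skipped <- skipped + 1L
      next
    }
    draws[[b]] <- res$aaf %>% mutate(replicate = b)
  }
  if (skipped > 0.2 * B) {
    abort(paste0("Bootstrap failed: ", skipped, " of ", B,
                 " resamples unusable (> 20%)."))
  }
  boot <- bind_rows(draws)
  alpha <- (1 - conf_level) / 2
  cis <- boot %>%
    group_by(factor = .data$factor, horizon_days = .data$horizon_days) %>%
    summarise(
      ci_lower = quantile(.data$aaf, alpha, na.rm = TRUE, names = FALSE),
      ci_upper = quantile(.data$aaf, 1 - alpha, na.rm = TRUE, names = FALSE),
      boot_se = sd(.data$aaf, na.rm = TRUE),
      .groups = "drop"
    )
  out <- est %>%
    left_join(cis, by = c("factor", "horizon_days")) %>%
    mutate(n_bootstrap = B - skipped, n_skipped = skipped)
  class(out) <- c("aaf_result", class(out))
  attr(out, "boot_aaf") <- boot
  out
}

#' @export
autoplot.aaf_result <- function(object, ...) {
  df <- dplyr::mutate(object,
                      horizon = paste0(.data$horizon_days, " d"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = 100 * .data$aaf,
                                        fill = .data$horizon)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Adjusted attributable fraction (%)",
                  fill = NULL) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
  if ("ci_lower" %in% names(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * .data$ci_lower, ymax = 100 * .data$ci_upper),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25
    )
  }
  p
}
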