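heu_default_covariates <- c("region", "sex", "birth_weight_group",
                            "ever_breastfed", "cd4_group", "arv_category",
                            "mother_dead")

#' Run the full pooled-analysis pipeline
#'
#' End-to-end orchestration on a conforming cohort: validation,
#' categorization/imputation, descriptive tables (per-study death counts,
#' covariate prevalences, Kaplan-Meier by region with log-rank test,
#' cumulative incidence, mortality rates per 100 child-years), univariate
#' screening, stepwise-descending selection, the final multivariable
#' frailty-Cox model, the weaning (time-dependent breastfeeding-cessation)
#' model among ever-breastfed children, the joint breastfeeding-by-ART
#' model, adjusted attributable fractions (with bootstrap CIs when
#' `aaf$B > 0`), and configurable sensitivity re-fits. Results are returned
#' as a list and, when `out_dir` is set, written as CSV/JSON files together
#' with a machine-readable manifest (package version, seed, config hash,
#' exclusion and imputation counts).
#'
#' @param config a named list (or path to a YAML/JSON file holding one)
#'   with elements:
#'   * `input` — path to a cohort CSV, or a data frame; exactly one of
#'     `input`/`simulate` must be present.
#'   * `simulate` — a [cohort_config()] (or list of its arguments).
#'   * `seed` — RNG seed; mandatory when simulating or bootstrapping.
#'   * `rules` — a [categorization_rules()] (optional).
#'   * `model` — list: `candidates` (covariates entering screening),
#'     `always_keep`, `forced`, `theta` (optional).
#'   * `aaf` — list: `horizons`, `B` (0 = no bootstrap), `impute_bf_days`.
#'   * `sensitivity` — character vector among `"exclude_reassigned_arv"`,
#'     `"exclude_imputed_weaning"`: record-exclusion re-fits.
#' @param out_dir optional output directory.
#' @param quiet suppress progress messages.
#' @return A list of class `heu_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    abort("Config must contain exactly one of `input` and `simulate`.")
  }
  aaf_cfg <- config$aaf %||% list()
  B <- aaf_cfg$B %||% 0L
  if ((has_sim || B > 0) && is.null(config$seed)) {
    abort("`seed` is mandatory when simulating or bootstrapping.")
  }
  say <- function(...) if (!quiet) inform(paste0(...))

  ## ---- input ----
  raw <- if (has_input) {
    if (is.data.frame(config$input)) as_tibble(config$input)
    else read_cohort(config$input)
  } else {
    sim <- as_cohort_config(config$simulate)
    say("Simulating cohort (seed ", config$seed, ")")
    generate_cohort(sim, seed = config$seed)
  }
  diagnostics <- validate_input(raw)
  if (nrow(diagnostics$violations) > 0) {
    abort(paste0("Input violates the cohort schema (",
                 nrow(diagnostics$violations), " rows); see validate_input()."))
  }

  rules <- config$rules %||% categorization_rules()
  records <- apply_categorization(raw, rules, quiet = quiet)
  log <- attr(records, "heu_log")
  say("Categorized ", nrow(records), " children")

  ## ---- descriptives ----
  summary_tabs <- summarize_cohort(records)
  km_region <- kaplan_meier(records, group_by = "region")
  lr_region <- if (length(unique(records$region)) > 1L) {
    log_rank_test(records, "region")
  } else {
    tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  }
  cuminc <- cumulative_incidence(records)
  episodes <- split_episodes(records, "maternal_vital_only")
  rates <- bind_rows(
    mortality_rate_per_100cy(episodes) %>% mutate(covariate = "overall"),
    mortality_rate_per_100cy(episodes, "arv_category") %>%
      mutate(covariate = "arv_category"),
    mortality_rate_per_100cy(episodes, "mother_dead") %>%
      mutate(covariate = "mother_dead")
  )

  ## ---- models ----
  model_cfg <- config$model %||% list()
  candidates <- model_cfg$candidates %||%
    intersect(heu_default_covariates,
              c(names(records), "mother_dead"))
  spec <- model_spec(
    candidates,
    cluster = "study_id",
    always_keep = model_cfg$always_keep %||% "arv_category",
    forced = model_cfg$forced %||% c("region", "cd4_group"),
    selection = "stepwise_descending"
  )
  say("Stepwise selection over: ", paste(candidates, collapse = ", "))
  sel <- stepwise_descending_select(episodes, spec,
                                    theta = model_cfg$theta %||% NULL)
  final_fit <- sel$fit
  final_table <- tidy(final_fit, exponentiate = TRUE)

  ## weaning model: breastfeeding cessation time-dependent, breastfed only
  bf_records <- records[isTRUE_vec(records$ever_breastfed), , drop = FALSE]
  weaning_fit <- NULL
  if (nrow(bf_records) > 0) {
    ep_bf <- split_episodes(bf_records, "plus_bf_cessation")
    if (sum(ep_bf$event) > 0) {
      weaning_fit <- fit_frailty_cox(
        ep_bf,
        c("currently_breastfed", "region", "birth_weight_group",
          "cd4_group", "arv_category"),
        reference = list(currently_breastfed = "1"),
        theta = model_cfg$theta %||% NULL
      )
    }
  }

  ## joint breastfeeding x 3-drug ART model
  ep_joint <- split_episodes(records, "bf_by_art_joint")
  joint_fit <- fit_joint_bf_art(ep_joint, theta = model_cfg$theta %||% NULL)
  joint_rates <- mortality_rate_per_100cy(ep_joint, "bf_art_category")

  ## ---- attributable fractions ----
  horizons <- aaf_cfg$horizons %||% c(183, 365, 730)
  impute_bf <- aaf_cfg$impute_bf_days %||% 183
  aaf <- if (B > 0) {
    say("Bootstrapping aAF (B = ", B, ")")
    bootstrap_aaf(records, sel$spec$covariates, horizons = horizons, B = B,
                  seed = config$seed + 1L, impute_bf_days = impute_bf)
  } else {
    compute_aaf(final_fit, records, horizons = horizons,
                impute_bf_days = impute_bf)
  }

  ## ---- sensitivity re-fits ----
  sens <- list()
  for (s in (config$sensitivity %||% character(0))) {
    keep <- switch(
      s,
      exclude_reassigned_arv = !(is.na(raw$arv_category[
        match(records$child_id, raw$child_id)]) |
          raw$arv_category[match(records$child_id, raw$child_id)] == "missing"),
      exclude_imputed_weaning = !records$imputed_weaning,
      abort(paste0("Unknown sensitivity filter: ", s))
    )
    say("Sensitivity '", s, "': excluding ", sum(!keep), " children")
    rec_s <- records[keep, , drop = FALSE]
    ep_s <- split_episodes(rec_s, "maternal_vital_only")
    fit_s <- fit_frailty_cox(ep_s, sel$spec$covariates,
                             theta = model_cfg$theta %||% NULL)
    sens[[s]] <- list(n_excluded = sum(!keep),
                      table = tidy(fit_s, exponentiate = TRUE))
  }

  manifest <- list(
    package = "heusurv",
    version = as.character(utils::packageVersion("heusurv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_children = nrow(records),
    n_events = sum(!is.na(records$child_death_age_days)),
    counts = log,
    stages = c("validate", "categorize", "describe", "screen", "select",
               "fit_final", "fit_weaning", "fit_joint", "aaf",
               names(sens))
  )

  report <- structure(
    list(
      records = records, diagnostics = diagnostics, summary = summary_tabs,
      km_region = km_region, logrank_region = lr_region,
      cumulative_incidence = cuminc, mortality_rates = rates,
      screen = sel$screen, selection_trace = sel$trace,
      final_fit = final_fit, final_table = final_table,
      weaning_fit = weaning_fit, joint_fit = joint_fit,
      joint_rates = joint_rates, aaf = aaf, sensitivity = sens,
      manifest = manifest
    ),
    class = "heu_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

## Coerce a plain list (e.g. parsed from YAML/JSON, where named vectors
## arrive as nested lists) into a cohort_config.
as_cohort_config <- function(x) {
  if (inherits(x, "cohort_config")) return(x)
  for (nm in c("true_log_hr", "prevalences")) {
    if (!is.null(x[[nm]])) x[[nm]] <- lapply(x[[nm]], unlist)
  }
  do.call(cohort_config, x)
}

read_run_config <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML configs needs the yaml package.")
    }
    yaml::read_yaml(path)
  }
}

#' Write a pipeline report bundle to disk
#'
#' @param report a `heu_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")))
  }
  w(report$summary$studies, "table1_study_deaths")
  w(report$summary$covariates, "table2_covariates")
  w(as_tibble(report$km_region), "fig2_km_by_region")
  w(report$cumulative_incidence, "cumulative_incidence")
  w(report$mortality_rates, "mortality_rates")
  w(report$screen, "table3_univariate")
  w(report$final_table, "table3_multivariable")
  if (!is.null(report$weaning_fit)) {
    w(tidy(report$weaning_fit, exponentiate = TRUE), "weaning_model")
  }
  w(tidy(report$joint_fit, exponentiate = TRUE), "table4_joint_bf_art")
  w(report$joint_rates, "table4_rates")
  w(as_tibble(report$aaf), "table5_aaf")
  for (nm in names(report$sensitivity)) {
    w(report$sensitivity[[nm]]$table, paste0("sensitivity_", nm))
  }
  jsonlite::write_json(report$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' @export
print.heu_report <- function(x, ...) {
  cat("Pooled HEU survival analysis report\n")
  cat("  children:", x$manifest$n_children,
      " deaths:", x$manifest$n_events, "\n")
  cat("  final model:", paste(x$final_fit$covariates, collapse = ", "), "\n")
  cat("  frailty variance:", signif(x$final_fit$theta, 3), "\n\n")
  print(x$aaf)
  invisible(x)
}
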