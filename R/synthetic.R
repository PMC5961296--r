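#' Configuration for the multi-study synthetic cohort generator
#'
#' Defines the generating model of a pooled multi-study HEU cohort: per-study
#' gamma frailties, a piecewise-constant baseline hazard of death by age,
#' multiplicative covariate effects (fixed and time-dependent), covariate
#' prevalences, independent maternal-death / weaning / ART-window processes,
#' and study-level administrative censoring plus random loss to follow-up.
#'
#' Defaults emulate the pooled population the package targets: ~19000
#' children in 20 studies; low birth weight 12.1%, never breastfed 30.2%,
#' maternal ARV mix 22.8/61.4/11.7/4.0% (none / single-dual PMTCT / 3-drug
#' ART for PMTCT / ART for life), antenatal CD4 >350 57.9%; between-study
#' frailty variance 0.25; baseline hazard declining with age so that
#' cumulative mortality reaches roughly 2% by 3 months and 5-6% by 24 months
#' in the reference stratum; maternal mortality ~1.6% by 24 months; weaning
#' ages log-normal with median 181 days; follow-up capped at 730 days.
#'
#' @param n_studies number of study clusters.
#' @param children_per_study integer (recycled) or length-`n_studies` vector.
#' @param theta variance of the mean-1 gamma study frailty (0 = homogeneous).
#' @param baseline_breaks,baseline_rates piecewise-constant baseline hazard:
#'   `baseline_rates[k]` (per day) applies on
#'   `[baseline_breaks[k], baseline_breaks[k+1])`; `baseline_breaks[1]` must
#'   be 0.
#' @param true_log_hr named list mapping covariate name to a named numeric
#'   vector of log hazard ratios per non-reference level. Time-dependent
#'   covariates `mother_dead`, `currently_breastfed`, `mother_on_art3` use
#'   levels `"1"`; `bf_art_category` uses `"B"`, `"C"`, `"D"`.
#' @param prevalences named list of category probability vectors for the
#'   fixed covariates (`region` is drawn per study, the rest per child).
#' @param maternal_death_rate per-day exponential rate of maternal death.
#' @param weaning_meanlog,weaning_sdlog log-normal weaning-age distribution
#'   (days) for breastfed children; weaning is advanced to the mother's death
#'   when she dies while breastfeeding.
#' @param admin_caps,admin_cap_probs study-level administrative follow-up
#'   caps (days) and their sampling probabilities.
#' @param dropout_rate per-day exponential rate of loss to follow-up.
#' @param followup_cap_days hard cap on follow-up (days).
#' @param missing_weaning_prob fraction of breastfed children whose weaning
#'   age is masked (`NA`), emulating unknown weaning dates.
#' @param unknown_bf_prob fraction of children whose breastfeeding status is
#'   masked (`NA`), emulating unknown feeding status.
#' @param missing_arv_prob fraction of mothers with ARV category masked to
#'   `"missing"`.
#' @param seed default RNG seed used by [generate_cohort()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    n_studies = 20L,
    children_per_study = 960L,
    theta = 0.25,
    baseline_breaks = c(0, 91, 183, 365),
    baseline_rates = c(2.4e-4, 1.1e-4, 8e-5, 3e-5),
    true_log_hr = list(
      region = c(Asia = log(0.05)),
      birth_weight_group = c(lt2500 = log(2.9), unknown = log(2.4)),
      ever_breastfed = c("FALSE" = log(2.5)),
      cd4_group = c(lt350 = log(1.43), unknown = log(1.49)),
      arv_category = c(mono_dual_pmtct = log(0.78), art_pmtct = log(0.66),
                       art_life = log(0.5)),
      mother_dead = c("1" = log(11.1))
    ),
    prevalences = list(
      region = c(Africa = 0.77, Asia = 0.23),
      sex = c(male = 0.512, female = 0.488),
      birth_weight_group = c(ge2500 = 0.866, lt2500 = 0.121, unknown = 0.013),
      ever_breastfed = c("TRUE" = 0.698, "FALSE" = 0.302),
      arv_category = c(none = 0.228, mono_dual_pmtct = 0.614,
                       art_pmtct = 0.117, art_life = 0.041),
      cd4_group = c(ge350 = 0.579, lt350 = 0.365, unknown = 0.056)
    ),
    maternal_death_rate = 2.2e-5,
    weaning_meanlog = log(181),
    weaning_sdlog = 0.8,
    admin_caps = c(365, 550, 730),
    admin_cap_probs = c(0.3, 0.3, 0.4),
    dropout_rate = 2e-4,
    followup_cap_days = 730L,
    missing_weaning_prob = 0,
    unknown_bf_prob = 0,
    missing_arv_prob = 0,
    seed = 20170101L) {
  stopifnot(
    n_studies >= 1, all(children_per_study >= 1), theta >= 0,
    baseline_breaks[1] == 0, !is.unsorted(baseline_breaks, strictly = TRUE),
    length(baseline_rates) == length(baseline_breaks),
    all(baseline_rates >= 0), maternal_death_rate >= 0, dropout_rate >= 0,
    weaning_sdlog > 0, followup_cap_days > 0,
    length(admin_caps) == length(admin_cap_probs),
    missing_weaning_prob >= 0, missing_weaning_prob < 1,
    unknown_bf_prob >= 0, unknown_bf_prob < 1,
    missing_arv_prob >= 0, missing_arv_prob < 1
  )
  for (p in prevalences) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      abort("Each prevalence vector must be nonnegative and sum to 1.")
    }
  }
  if (abs(sum(admin_cap_probs) - 1) > 1e-8) {
    abort("`admin_cap_probs` must sum to 1.")
  }
  if (!all(vapply(true_log_hr, function(b) is.numeric(b) && !is.null(names(b)),
                  logical(1)))) {
    abort("`true_log_hr` must be a list of named numeric vectors.")
  }
  cps <- rep_len(as.integer(children_per_study), n_studies)
  structure(
    list(
      n_studies = as.integer(n_studies), children_per_study = cps,
      theta = theta, baseline_breaks = baseline_breaks,
      baseline_rates = baseline_rates, true_log_hr = true_log_hr,
      prevalences = prevalences, maternal_death_rate = maternal_death_rate,
      weaning_meanlog = weaning_meanlog, weaning_sdlog = weaning_sdlog,
      admin_caps = admin_caps, admin_cap_probs = admin_cap_probs,
      dropout_rate = dropout_rate,
      followup_cap_days = as.integer(followup_cap_days),
      missing_weaning_prob = missing_weaning_prob,
      unknown_bf_prob = unknown_bf_prob, missing_arv_prob = missing_arv_prob,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

## Restore the caller's RNG state after seeded simulation
local_seed <- function(seed, env = parent.frame()) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  expr <- if (has_old) {
    bquote(assign(".Random.seed", .(get(".Random.seed", globalenv())),
                  globalenv()))
  } else {
    quote(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = env)
  set.seed(seed)
}

row_min <- function(m, cap) {
  b <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) b <- pmin(b, m[, j])
  pmin(b, cap)
}

## Linear predictor just after age `t` for each child, given the latent
## per-child state table. Covariates not named in `beta` contribute 0.
eta_after <- function(state, t, beta) {
  eta <- numeric(nrow(state))
  lookup <- function(b, lev) {
    v <- b[lev]
    v[is.na(v)] <- 0
    unname(v)
  }
  bf_now <- NULL
  art_now <- NULL
  for (nm in names(beta)) {
    b <- beta[[nm]]
    lev <- switch(nm,
      mother_dead = as.character(as.integer(!is.na(state$T_m) & state$T_m <= t)),
      currently_breastfed = {
        bf_now <- !is.na(state$W) & state$W > t
        as.character(as.integer(bf_now))
      },
      mother_on_art3 = {
        art_now <- !is.na(state$art_s) & state$art_s <= t &
          !is.na(state$art_e) & state$art_e > t
        as.character(as.integer(art_now))
      },
      bf_art_category = {
        bf_now <- !is.na(state$W) & state$W > t
        art_now <- !is.na(state$art_s) & state$art_s <= t &
          !is.na(state$art_e) & state$art_e > t
        c("A", "B", "C", "D")[1L + as.integer(art_now) + 2L * as.integer(bf_now)]
      },
      as.character(state[[nm]])
    )
    eta <- eta + lookup(b, lev)
  }
  eta
}

## Candidate change-point matrix (columns) for the hazard walker
change_matrix <- function(state, config) {
  cbind(
    matrix(config$baseline_breaks, nrow(state), length(config$baseline_breaks),
           byrow = TRUE),
    state$T_m, state$W, state$art_s, state$art_e
  )
}

## Piecewise-exponential sampling of death ages given frailty and covariate
## paths: walk the refinement of baseline breaks and per-child change-points,
## spending an Exp(1) budget against the cumulative hazard.
sample_death_ages <- function(state, u, config, cap) {
  n <- nrow(state)
  cand <- change_matrix(state, config)
  E <- rexp(n)
  t <- numeric(n)
  death <- rep(Inf, n)
  active <- rep(TRUE, n)
  beta <- config$true_log_hr
  for (step in seq_len(ncol(cand) + 2L)) {
    if (!any(active)) break
    ta <- t[active]
    ca <- cand[active, , drop = FALSE]
    ca[!(ca > ta) | is.na(ca)] <- Inf
    b <- row_min(ca, cap)
    rate <- u[active] *
      config$baseline_rates[findInterval(ta, config$baseline_breaks)] *
      exp(eta_after(state[active, , drop = FALSE], ta, beta))
    dH <- rate * (b - ta)
    dies <- E[active] <= dH & rate > 0
    idx <- which(active)
    death[idx[dies]] <- ta[dies] + E[idx[dies]] / rate[dies]
    E[idx[!dies]] <- E[idx[!dies]] - dH[!dies]
    t[idx] <- b
    active[idx] <- !dies & b < cap
  }
  death
}

## Conditional cumulative hazard integral(h0(s) exp(eta(s)) ds) on (0, t]
## for each child (frailty excluded).
cum_hazard_paths <- function(state, config, horizon) {
  n <- nrow(state)
  cand <- change_matrix(state, config)
  t <- numeric(n)
  H <- numeric(n)
  active <- rep(TRUE, n)
  beta <- config$true_log_hr
  for (step in seq_len(ncol(cand) + 2L)) {
    if (!any(active)) break
    ta <- t[active]
    ca <- cand[active, , drop = FALSE]
    ca[!(ca > ta) | is.na(ca)] <- Inf
    b <- row_min(ca, horizon)
    rate <- config$baseline_rates[findInterval(ta, config$baseline_breaks)] *
      exp(eta_after(state[active, , drop = FALSE], ta, beta))
    idx <- which(active)
    H[idx] <- H[idx] + rate * (b - ta)
    t[idx] <- b
    active[idx] <- b < horizon
  }
  H
}

## Latent per-child state (covariates + change-point ages), before censoring
draw_state <- function(config, n_per_study) {
  n <- sum(n_per_study)
  study <- rep(seq_along(n_per_study), n_per_study)
  draw_cat <- function(p, m) {
    names(p)[sample.int(length(p), m, replace = TRUE, prob = p)]
  }
  region_study <- draw_cat(config$prevalences$region, length(n_per_study))
  state <- tibble(
    study = study,
    region = region_study[study],
    sex = draw_cat(config$prevalences$sex, n),
    birth_weight_group = draw_cat(config$prevalences$birth_weight_group, n),
    ever_breastfed = draw_cat(config$prevalences$ever_breastfed, n) == "TRUE",
    arv_category = draw_cat(config$prevalences$arv_category, n),
    cd4_group = draw_cat(config$prevalences$cd4_group, n)
  )
  state$T_m <- if (config$maternal_death_rate > 0) {
    rexp(n, config$maternal_death_rate)
  } else {
    rep(Inf, n)
  }
  W <- rlnorm(n, config$weaning_meanlog, config$weaning_sdlog)
  W <- pmin(W, state$T_m)  # maternal death ends breastfeeding
  state$W <- ifelse(state$ever_breastfed, W, NA_real_)
  cap183 <- 183
  state$art_s <- ifelse(state$arv_category %in% c("art_pmtct", "art_life"),
                        0, NA_real_)
  state$art_e <- dplyr::case_when(
    state$arv_category == "art_life" ~ Inf,
    state$arv_category == "art_pmtct" & state$ever_breastfed ~
      pmin(state$W, cap183),
    state$arv_category == "art_pmtct" ~ 0,
    TRUE ~ NA_real_
  )
  state
}

#' Generate a synthetic multi-study cohort
#'
#' Draws a cohort from the generating model of a [cohort_config()]: per-study
#' gamma(mean 1, variance `theta`) frailties; per-child covariates from the
#' configured prevalences; maternal death, weaning and maternal ART windows
#' as independent processes; death ages by piecewise-exponential inversion of
#' the hazard `u_s * h0(t) * exp(x_i(t)' beta)`; censoring from study
#' administrative caps and exponential dropout. Identical config and seed
#' give identical output.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A child-level tibble in the cohort schema (see
#'   `?"cohort-schema"`), with attribute `"true_frailties"` (per-study
#'   frailty draws).
#' @export
#' @examples
#' cfg <- cohort_config(n_studies = 2, children_per_study = 50)
#' cohort <- generate_cohort(cfg, seed = 1)
#' dplyr::count(cohort, study_id)
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  local_seed(seed)
  cap <- config$followup_cap_days
  n_per_study <- config$children_per_study
  u_study <- if (config$theta > 0) {
    rgamma(config$n_studies, shape = 1 / config$theta, rate = 1 / config$theta)
  } else {
    rep(1, config$n_studies)
  }
  state <- draw_state(config, n_per_study)
  n <- nrow(state)

  death <- sample_death_ages(state, u_study[state$study], config, cap)

  admin <- config$admin_caps[
    sample.int(length(config$admin_caps), config$n_studies, replace = TRUE,
               prob = config$admin_cap_probs)
  ]
  cens <- pmin(admin[state$study],
               if (config$dropout_rate > 0) rexp(n, config$dropout_rate)
               else Inf,
               cap)
  cens <- pmax(ceiling(cens), 1)
  died <- death <= cens
  death_age <- ifelse(died, pmax(ceiling(death), 1), NA_real_)
  censor_age <- ifelse(died, death_age, cens)

  rec <- tibble(
    child_id = sprintf("c%06d", seq_len(n)),
    study_id = sprintf("S%02d", state$study),
    region = state$region,
    sex = state$sex,
    birth_weight_group = state$birth_weight_group,
    ever_breastfed = state$ever_breastfed,
    weaning_age_days = ifelse(is.na(state$W), NA_real_, ceiling(state$W)),
    arv_category = state$arv_category,
    art_start_age_days = state$art_s,
    art_end_age_days = ifelse(is.finite(state$art_e), ceiling(state$art_e),
                              ifelse(is.na(state$art_e), NA_real_, cap)),
    cd4_group = state$cd4_group,
    maternal_death_age_days = ifelse(is.finite(state$T_m),
                                     ceiling(state$T_m), NA_real_),
    child_death_age_days = death_age,
    censor_age_days = censor_age
  )

  ## optional missingness masks emulating incomplete source data
  if (config$missing_weaning_prob > 0) {
    mask <- rec$ever_breastfed & !is.na(rec$weaning_age_days) &
      runif(n) < config$missing_weaning_prob
    rec$weaning_age_days[mask] <- NA_real_
  }
  if (config$unknown_bf_prob > 0) {
    mask <- runif(n) < config$unknown_bf_prob
    rec$ever_breastfed[mask] <- NA
    rec$weaning_age_days[mask] <- NA_real_
  }
  if (config$missing_arv_prob > 0) {
    mask <- runif(n) < config$missing_arv_prob
    rec$arv_category[mask] <- "missing"
    rec$art_start_age_days[mask] <- NA_real_
    rec$art_end_age_days[mask] <- NA_real_
  }
  attr(rec, "true_frailties") <- setNames(u_study,
                                          sprintf("S%02d", seq_len(config$n_studies)))
  rec
}

#' Ground-truth attributable fraction of the generating model
#'
#' Computes, from a [cohort_config()] rather than from data, the fraction of
#' expected deaths by `horizon_days` that the configured factor(s) account
#' for: `AF(t) = (D(t) - D_cf(t)) / D(t)`, where `D(t)` sums `1 - S_i(t)`
#' over a large quasi-population of covariate paths drawn from the config,
#' `S_i(t)` is the exact conditional survival under the piecewise-constant
#' generating hazard marginalized over the gamma frailty
#' (`S = (1 + theta * H)^(-1/theta)`), and `D_cf` repeats the computation
#' after assigning every child the nonexposed level of each factor (other
#' covariates unchanged, common random numbers).
#'
#' Supported factors and their nonexposed assignments:
#' `"birth_weight_group"` (to `ge2500`), `"ever_breastfed"` (to breastfed,
#' with weaning at the earlier of 183 days and the mother's death),
#' `"arv_category"` (to ART for life), `"mother_dead"` (mother alive
#' throughout). `"combined"` applies all four at once.
#'
#' @param config a [cohort_config()].
#' @param factor character vector of factor names (or `"combined"`).
#' @param horizon_days evaluation age in days.
#' @param n_mc number of covariate paths drawn (Monte Carlo over the
#'   covariate distribution only; survival given the path is exact).
#' @param seed RNG seed for the path draw.
#' @return The attributable fraction (scalar in `[0, 1]` for harmful
#'   factors), with attribute `"mc_se"` (Monte-Carlo standard error).
#' @export
true_attributable_fraction <- function(config, factor, horizon_days = 730,
                                       n_mc = 2e5, seed = config$seed + 1L) {
  stopifnot(inherits(config, "cohort_config"), horizon_days > 0)
  factors <- if (identical(factor, "combined")) {
    c("birth_weight_group", "ever_breastfed", "arv_category", "mother_dead")
  } else {
    factor
  }
  known <- c("birth_weight_group", "ever_breastfed", "arv_category",
             "mother_dead")
  if (!all(factors %in% known)) {
    abort(paste0("Unknown factor(s): ",
                 paste(setdiff(factors, known), collapse = ", ")))
  }
  local_seed(seed)
  per_study <- ceiling(n_mc / config$n_studies)
  state <- draw_state(config, rep(per_study, config$n_studies))

  surv <- function(st) {
    H <- cum_hazard_paths(st, config, horizon_days)
    if (config$theta > 0) (1 + config$theta * H)^(-1 / config$theta)
    else exp(-H)
  }
  s_fact <- surv(state)
  state_cf <- counterfactual_state(state, factors, config)
  s_cf <- surv(state_cf)

  d <- (1 - s_fact)
  d_cf <- (1 - s_cf)
  af <- (sum(d) - sum(d_cf)) / sum(d)
  diff <- d - d_cf
  ## delta-method MC standard error of a ratio of means
  m_d <- mean(d); m_diff <- mean(diff); nn <- length(d)
  v <- stats::var(diff) / m_d^2 + m_diff^2 * stats::var(d) / m_d^4 -
    2 * m_diff * stats::cov(diff, d) / m_d^3
  attr(af, "mc_se") <- sqrt(max(v, 0) / nn)
  af
}

counterfactual_state <- function(state, factors, config) {
  if ("birth_weight_group" %in% factors) {
    state$birth_weight_group <- "ge2500"
  }
  if ("ever_breastfed" %in% factors) {
    default_w <- pmin(183, ifelse(is.na(state$T_m), Inf, state$T_m))
    state$W <- ifelse(state$ever_breastfed, state$W, default_w)
    state$ever_breastfed <- TRUE
  }
  if ("arv_category" %in% factors) {
    state$arv_category <- "art_life"
    state$art_s <- 0
    state$art_e <- Inf
  }
  if ("mother_dead" %in% factors) {
    state$T_m <- Inf
  }
  state
}
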