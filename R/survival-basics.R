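## Accept either child records or counting-process episodes and return a
## standardized (start, stop, event, group) tibble.
as_surv_input <- function(data, group_by = NULL) {
  data <- as_tibble(data)
  if (all(c("start", "stop", "event") %in% names(data))) {
    out <- tibble(start = data$start, stop = data$stop,
                  event = as.logical(data$event))
  } else if (all(c("child_death_age_days", "censor_age_days") %in% names(data))) {
    fu <- heu_fu_end(data)
    out <- tibble(
      start = 0,
      stop = fu,
      event = !is.na(data$child_death_age_days) &
        data$child_death_age_days <= data$censor_age_days
    )
  } else {
    abort("`data` must be child records or counting-process episodes.")
  }
  out$group <- if (is.null(group_by)) "all" else as.character(data[[group_by]])
  out
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimator of survival from birth, overall or by group, with
#' Greenwood standard errors and log-log 95% confidence intervals. Accepts
#' child records (one row per child) or counting-process episodes.
#'
#' @param data child records or episode table.
#' @param group_by optional column name to stratify by.
#' @param conf_level confidence level for the pointwise intervals.
#' @return A tibble of class `heu_km` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, `std_err`, `conf_low`,
#'   `conf_high`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_studies = 2,
#'                                         children_per_study = 100), seed = 1)
#' km <- kaplan_meier(cohort, group_by = "region")
#' head(km)
kaplan_meier <- function(data, group_by = NULL, conf_level = 0.95) {
  inp <- as_surv_input(data, group_by)
  groups <- unique(inp$group)
  out <- purrr::map_dfr(groups, function(g) {
    d <- inp[inp$group == g, ]
    if (nrow(d) == 0L || all(d$stop <= 0)) {
      warn(paste0("No usable subjects in group '", g, "'; empty curve."))
      return(tibble(group = character(), time = numeric(),
                    n_risk = numeric(), n_event = numeric(),
                    n_censor = numeric(), survival = numeric(),
                    std_err = numeric(), conf_low = numeric(),
                    conf_high = numeric()))
    }
    fit <- survival::survfit(
      survival::Surv(d$start, d$stop, d$event) ~ 1,
      conf.type = "log-log", conf.int = conf_level
    )
    tibble(
      group = g, time = fit$time, n_risk = fit$n.risk,
      n_event = fit$n.event, n_censor = fit$n.censor,
      survival = fit$surv, std_err = fit$std.err,
      conf_low = fit$lower, conf_high = fit$upper
    )
  })
  class(out) <- c("heu_km", class(out))
  out
}

#' @export
autoplot.heu_km <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(group = unique(object$group), time = 0, survival = 1),
    object[c("group", "time", "survival")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Age (days)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Log-rank test for survival differences between groups
#'
#' @param data child records or episode table.
#' @param group_by grouping column name (>= 2 groups required).
#' @return A tibble with `statistic` (chi-square), `df` and `p_value`.
#' @export
log_rank_test <- function(data, group_by) {
  inp <- as_surv_input(data, group_by)
  if (length(unique(inp$group)) < 2L) {
    abort("Log-rank test needs at least two groups.")
  }
  if (sum(inp$event) < 1L) abort("Log-rank test needs at least one event.")
  if (any(inp$start != 0)) {
    abort("Log-rank test requires child-level data (one interval from birth).")
  }
  fit <- survival::survdiff(survival::Surv(inp$stop, inp$event) ~ inp$group)
  df <- length(fit$n) - 1L
  tibble(
    statistic = fit$chisq,
    df = df,
    p_value = pchisq(fit$chisq, df, lower.tail = FALSE)
  )
}

#' Mortality rates per 100 child-years
#'
#' `100 * deaths / (person-days / 365.25)` within each group; person-time is
#' attributed to the group of the current (possibly time-dependent) covariate
#' value, so rates computed on episode data follow covariate changes.
#'
#' @param data child records or episode table.
#' @param group_by optional grouping column.
#' @return A tibble with `group`, `n_deaths`, `child_years`,
#'   `rate_per_100cy` (rounded to 1 decimal in `rate_display`). Groups with
#'   zero person-time carry `NA` rates.
#' @export
mortality_rate_per_100cy <- function(data, group_by = NULL) {
  inp <- as_surv_input(data, group_by)
  out <- inp %>%
    group_by(group = .data$group) %>%
    summarise(
      n_deaths = sum(.data$event),
      child_years = sum(.data$stop - .data$start) / 365.25,
      .groups = "drop"
    ) %>%
    mutate(
      rate_per_100cy = ifelse(.data$child_years > 0,
                              100 * .data$n_deaths / .data$child_years,
                              NA_real_),
      rate_display = round(.data$rate_per_100cy, 1)
    )
  if (any(is.na(out$rate_per_100cy))) {
    warn("Some groups have zero person-time; rate undefined (NA).")
  }
  out
}

#' Cumulative incidence of death at fixed horizons
#'
#' `1 - S(t)` from the Kaplan-Meier estimator at each horizon, with
#' Greenwood/log-log 95% confidence bounds.
#'
#' @param data child records or episode table.
#' @param horizons ages (days) at which to evaluate; defaults to 3, 6, 12
#'   and 24 months.
#' @param group_by optional grouping column.
#' @return A tibble with `group`, `horizon_days`, `cum_incidence`,
#'   `conf_low`, `conf_high`.
#' @export
cumulative_incidence <- function(data, horizons = c(91, 183, 365, 730),
                                 group_by = NULL) {
  km <- kaplan_meier(data, group_by = group_by)
  purrr::map_dfr(unique(km$group), function(g) {
    cg <- km[km$group == g, ]
    last_t <- max(cg$time)
    purrr::map_dfr(horizons, function(h) {
      if (h > last_t) {
        warn(paste0("Horizon ", h, " d beyond last observed time (", last_t,
                    " d); carrying last value."))
      }
      at <- cg[cg$time <= h, ]
      if (nrow(at) == 0L) {
        return(tibble(group = g, horizon_days = h, cum_incidence = 0,
                      conf_low = 0, conf_high = 0))
      }
      i <- which.max(at$time)
      tibble(
        group = g, horizon_days = h,
        cum_incidence = 1 - at$survival[i],
        conf_low = 1 - ifelse(is.na(at$conf_high[i]), at$survival[i],
                              at$conf_high[i]),
        conf_high = 1 - ifelse(is.na(at$conf_low[i]), at$survival[i],
                               at$conf_low[i])
      )
    })
  })
}
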