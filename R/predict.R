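## Baseline cumulative hazard of a fit at arbitrary times. Breslow fits use
## a right-continuous step function; parameter-constructed fits use exact
## piecewise-linear interpolation. Beyond the supported range the hazard is
## extended flat.
baseline_cumhaz_at <- function(fit, t) {
  bl <- fit$baseline
  if (any(t > (fit$max_time %||% max(bl$time)))) {
    warn("Prediction time beyond the baseline-hazard support; extending flat.")
  }
  if (identical(fit$baseline_type, "linear")) {
    approx(bl$time, bl$cumhaz, pmax(pmin(t, max(bl$time)), 0),
           rule = 2)$y
  } else {
    idx <- findInterval(t, bl$time)
    c(0, bl$cumhaz)[idx + 1L]
  }
}

## Linear predictor of a fit evaluated on episode-style rows
eta_from_fit <- function(fit, data) {
  eta <- numeric(nrow(data))
  for (i in seq_len(nrow(fit$terms))) {
    cov <- fit$terms$covariate[i]
    if (!cov %in% names(data)) {
      abort(paste0("Prediction data lack covariate `", cov, "`."))
    }
    eta <- eta + fit$beta[[fit$terms$term[i]]] *
      (as.character(data[[cov]]) == fit$terms$level[i])
  }
  eta
}

## Per-child cumulative hazard integral exp(x(s)'beta) dH0(s) on (0, t]
## from a covariate-path episode table. Returns a named vector.
child_cum_hazard <- function(fit, paths, t) {
  keep <- paths$start < t
  pp <- paths[keep, , drop = FALSE]
  inc <- exp(eta_from_fit(fit, pp)) *
    (baseline_cumhaz_at(fit, pmin(pp$stop, t)) -
       baseline_cumhaz_at(fit, pmin(pp$start, t)))
  H <- rowsum(inc, pp$child_id)
  all_ids <- unique(paths$child_id)
  out <- setNames(numeric(length(all_ids)), all_ids)
  out[rownames(H)] <- H[, 1]
  out
}

#' Predict marginal survival from a frailty-Cox fit
#'
#' For each child's covariate path, accumulates the cumulative hazard
#' `H_i(t) = integral of exp(x_i(s)' beta) dH0(s)` over the path's episodes
#' and returns survival marginalized over the gamma frailty,
#' `S_i(t) = (1 + theta * H_i(t))^(-1/theta)` (the Laplace transform of the
#' gamma distribution), falling back to `exp(-H_i(t))` as `theta`
#' approaches 0. With `type = "conditional"` the child's own study frailty
#' estimate is used instead: `S_i(t) = exp(-u_s * H_i(t))`.
#'
#' @param fit a `frailty_cox_fit`.
#' @param paths episode-style tibble of covariate paths: `child_id`,
#'   `start`, `stop` and every model covariate (plus `study_id` for
#'   conditional prediction). Paths must cover `[0, t]`; build them with
#'   [build_prediction_paths()] to extend past censoring.
#' @param t horizon(s) in days.
#' @param type `"marginal"` (default) or `"conditional"`.
#' @return A tibble with `child_id`, `horizon_days`, `survival`.
#' @export
predict_marginal_survival <- function(fit, paths, t,
                                      type = c("marginal", "conditional")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "frailty_cox_fit"), all(t >= 0))
  purrr::map_dfr(t, function(tt) {
    if (tt == 0) {
      ids <- unique(paths$child_id)
      return(tibble(child_id = ids, horizon_days = 0,
                    survival = rep(1, length(ids))))
    }
    H <- child_cum_hazard(fit, paths, tt)
    s <- if (type == "conditional") {
      if (is.null(fit$frailties)) {
        abort("Conditional prediction needs estimated frailties.")
      }
      study_of <- paths$study_id[match(names(H), paths$child_id)]
      exp(-unname(fit$frailties[study_of]) * H)
    } else if (fit$theta < 1e-8) {
      exp(-H)
    } else {
      (1 + fit$theta * H)^(-1 / fit$theta)
    }
    tibble(child_id = names(H), horizon_days = tt, survival = unname(s))
  })
}

#' Build full-follow-up covariate paths for prediction
#'
#' Prediction for attributable fractions is a full-population expectation:
#' every child's covariate path is extended to the horizon even past the
#' child's actual censoring or death, holding the last observed category
#' (change-points recorded after the child's exit are not applied).
#'
#' @param records categorized child records.
#' @param horizon path end in days.
#' @param scheme episode-splitting scheme (see [split_episodes()]).
#' @return An episode-style tibble covering `(0, horizon]` for every child.
#' @export
build_prediction_paths <- function(records, horizon = 730,
                                   scheme = "maternal_vital_only") {
  fu <- heu_fu_end(records)
  r <- records
  drop_after_exit <- function(x) ifelse(!is.na(x) & x <= fu, x, NA_real_)
  r$maternal_death_age_days <- drop_after_exit(r$maternal_death_age_days)
  ## weaning after exit: still breastfed at exit, hold (NA = breastfed
  ## throughout the extended path)
  r$weaning_age_days <- drop_after_exit(r$weaning_age_days)
  ## ART continuing at exit is held to the horizon
  r$art_end_age_days <- ifelse(
    !is.na(r$art_start_age_days) &
      (is.na(r$art_end_age_days) | r$art_end_age_days > fu),
    horizon, r$art_end_age_days
  )
  r$child_death_age_days <- NA_real_
  r$censor_age_days <- horizon
  split_episodes(r, scheme)
}
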