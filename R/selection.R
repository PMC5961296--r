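#' Univariate frailty-Cox screen
#'
#' Fits one single-covariate shared-frailty Cox model per candidate
#' covariate and reports per-term hazard ratios with Wald tests plus a
#' joint (block) Wald p-value per covariate, the screening quantity used by
#' [stepwise_descending_select()].
#'
#' @param episodes counting-process episode table.
#' @param covariates candidate covariate names.
#' @param cluster cluster column.
#' @param theta `NULL` to estimate the frailty variance per model, or fixed.
#' @param reference named list of reference levels.
#' @param control a [frailty_control()].
#' @return A tibble with one row per non-reference level: `covariate`,
#'   `level`, `term`, `estimate` (log HR), `std.error`, `hr`, `conf.low`,
#'   `conf.high` (HR scale), `p.value` (per term) and `block_p` (joint per
#'   covariate).
#' @export
univariate_screen <- function(episodes, covariates, cluster = "study_id",
                              theta = NULL, reference = list(),
                              control = frailty_control()) {
  purrr::map_dfr(covariates, function(cov) {
    fit <- fit_frailty_cox(episodes, cov, cluster = cluster,
                           reference = reference, theta = theta,
                           control = control)
    td <- tidy(fit)
    tibble(
      covariate = cov, level = td$level, term = td$term,
      estimate = td$estimate, std.error = td$std.error,
      hr = exp(td$estimate), conf.low = exp(td$conf.low),
      conf.high = exp(td$conf.high), p.value = td$p.value,
      block_p = block_wald_p(fit, cov)
    )
  })
}

#' Stepwise-descending covariate selection
#'
#' Starts from the covariates univariately associated with mortality at
#' `entry_p` (default 0.1) plus the always-kept covariates (maternal ARV
#' exposure is retained regardless of significance), together with the
#' forced adjusters (region and maternal CD4 group). Iteratively refits the
#' multivariable frailty-Cox model and drops the eligible covariate with the
#' largest joint Wald p-value at or above `stay_p` (default 0.05), stopping
#' when every remaining eligible covariate is significant. Covariates are
#' kept or dropped as blocks: an `"unknown"` level never leaves the model
#' on its own.
#'
#' @param episodes counting-process episode table.
#' @param spec a [model_spec()] whose `covariates` are the candidates.
#' @param theta `NULL` to estimate the frailty variance, or fixed.
#' @param control a [frailty_control()].
#' @return A list of class `heu_stepwise` with `spec` (final
#'   [model_spec()]), `fit` (final `frailty_cox_fit`), `screen` (the
#'   univariate screen) and `trace` (tibble of drop decisions).
#' @export
stepwise_descending_select <- function(episodes, spec, theta = NULL,
                                       control = frailty_control()) {
  stopifnot(inherits(spec, "heu_model_spec"))
  screen <- univariate_screen(episodes, spec$covariates,
                              cluster = spec$cluster,
                              reference = spec$reference, theta = theta,
                              control = control)
  passed <- unique(screen$covariate[screen$block_p < spec$entry_p])
  keep_always <- union(spec$always_keep, spec$forced)
  current <- union(union(passed, keep_always), character(0))
  if (length(current) == 0L) current <- keep_always
  current <- intersect(spec$covariates, union(current, keep_always))
  if (length(current) == 0L) {
    abort("No candidate covariates enter the multivariable model.")
  }

  trace <- list()
  repeat {
    fit <- fit_frailty_cox(episodes, current, cluster = spec$cluster,
                           reference = spec$reference, theta = theta,
                           control = control)
    droppable <- setdiff(intersect(current, fit$terms$covariate), keep_always)
    if (length(droppable) == 0L) break
    pvals <- vapply(droppable, function(cov) block_wald_p(fit, cov),
                    numeric(1))
    worst <- which.max(pvals)
    if (is.na(pvals[worst]) || pvals[worst] < spec$stay_p) break
    trace[[length(trace) + 1L]] <- tibble(
      dropped = droppable[worst], block_p = pvals[worst],
      n_remaining = length(current) - 1L
    )
    current <- setdiff(current, droppable[worst])
  }
  structure(
    list(
      spec = model_spec(current, cluster = spec$cluster,
                        reference = spec$reference,
                        always_keep = spec$always_keep, forced = spec$forced,
                        selection = "stepwise_descending",
                        entry_p = spec$entry_p, stay_p = spec$stay_p),
      fit = fit,
      screen = screen,
      trace = if (length(trace)) bind_rows(trace) else
        tibble(dropped = character(), block_p = numeric(),
               n_remaining = integer())
    ),
    class = "heu_stepwise"
  )
}

#' @export
print.heu_stepwise <- function(x, ...) {
  cat("Stepwise-descending selection\n")
  cat("  final covariates:", paste(x$spec$covariates, collapse = ", "), "\n")
  if (nrow(x$trace)) {
    cat("  dropped:", paste(x$trace$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Joint breastfeeding-by-maternal-ART exposure model
#'
#' Fits the four-level time-dependent exposure classifying observation time
#' by current breastfeeding (yes/no) and mother currently on 3-drug ART
#' (yes/no) — categories A (neither, reference), B (ART only), C
#' (breastfeeding only), D (both) — with the configured adjusters, on
#' episodes expanded under the `"bf_by_art_joint"` scheme.
#'
#' @param episodes episode table from
#'   `split_episodes(records, "bf_by_art_joint")`.
#' @param adjusters adjustment covariates (default region, maternal CD4
#'   group and birth weight).
#' @param cluster cluster column.
#' @param theta `NULL` to estimate the frailty variance, or fixed.
#' @param reference named list of reference levels.
#' @param control a [frailty_control()].
#' @return A `frailty_cox_fit` whose `bf_art_category` terms are the
#'   adjusted hazard ratios for B, C and D versus A.
#' @export
fit_joint_bf_art <- function(episodes,
                             adjusters = c("region", "cd4_group",
                                           "birth_weight_group"),
                             cluster = "study_id", theta = NULL,
                             reference = list(),
                             control = frailty_control()) {
  if (!"bf_art_category" %in% names(episodes)) {
    abort(paste0("`episodes` lacks `bf_art_category`; expand records with ",
                 'split_episodes(records, "bf_by_art_joint").'))
  }
  present <- vapply(episodes[c("bf_art_category", adjusters)],
                    function(x) length(unique(x)) > 1L, logical(1))
  if (!present[["bf_art_category"]]) {
    warn("All person-time falls in one breastfeeding/ART category; the other levels cannot be estimated.")
  }
  fit_frailty_cox(episodes, c("bf_art_category", adjusters),
                  cluster = cluster, reference = reference, theta = theta,
                  control = control)
}
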