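#' Child-level cohort schema
#'
#' The analysis consumes one row per child, with calendar dates already
#' converted to integer ages in days. Columns:
#'
#' * `child_id` — unique identifier (character or integer).
#' * `study_id` — trial/cohort label; the clustering unit of the frailty model.
#'   Multi-site trials whose sites were analysed separately should carry one
#'   `study_id` per site.
#' * `region` — `"Africa"` or `"Asia"`.
#' * `subregion` — optional finer region label.
#' * `sex` — `"male"`, `"female"` or `"unknown"`/`NA`.
#' * `birth_weight_group` — `"ge2500"`, `"lt2500"` or `"unknown"`/`NA`.
#' * `ever_breastfed` — logical; `NA` means unknown feeding status (such
#'   children are excluded during categorization).
#' * `weaning_age_days` — age at breastfeeding cessation; `NA` if unknown or
#'   never breastfed.
#' * `arv_category` — maternal antiretroviral exposure: `"none"`,
#'   `"mono_dual_pmtct"` (single/double peripartum ARVs), `"art_pmtct"`
#'   (3-drug ART for PMTCT), `"art_life"` (3-drug ART for life) or
#'   `"missing"`.
#' * `art_start_age_days`, `art_end_age_days` — maternal 3-drug ART window
#'   relative to child's birth; `NA` when unknown (imputed) or not applicable.
#' * `cd4_group` — antenatal maternal CD4: `"ge350"`, `"lt350"`,
#'   `"unknown"`/`NA`.
#' * `maternal_death_age_days` — child age when the mother died; `NA` if she
#'   survived follow-up. May exceed `censor_age_days` (ignored post exit).
#' * `child_death_age_days` — age at death; `NA` if alive at last contact.
#' * `censor_age_days` — age at end of follow-up (death, study end or loss to
#'   follow-up).
#'
#' @name cohort-schema
#' @keywords internal
NULL

heu_required_cols <- c(
  "child_id", "study_id", "region", "sex", "birth_weight_group",
  "ever_breastfed", "weaning_age_days", "arv_category",
  "art_start_age_days", "art_end_age_days", "cd4_group",
  "maternal_death_age_days", "child_death_age_days", "censor_age_days"
)

heu_age_cols <- c(
  "weaning_age_days", "art_start_age_days", "art_end_age_days",
  "maternal_death_age_days", "child_death_age_days", "censor_age_days"
)

#' Categorization and imputation rules
#'
#' Conventions applied to raw child records before episode splitting:
#' follow-up is capped at 24 months; breastfed children with unknown weaning
#' date are assumed breastfed until 6 months of age, study exit, or the
#' mother's death, whichever comes first; mothers on 3-drug ART with unknown
#' stop date are assumed to have continued until weaning or 6 months
#' post-partum, whichever came first; mothers with missing antiretroviral
#' information are assumed to have followed study protocol and reassigned to
#' the single/double-ARV PMTCT category.
#'
#' @param followup_cap_days administrative cap on follow-up ("24 months");
#'   default 730 days.
#' @param unknown_weaning_impute_days imputed weaning age ("6 months") when a
#'   breastfed child's weaning date is unknown; default 183 days.
#' @param art_end_impute_days cap used when a 3-drug-ART-for-PMTCT stop date
#'   is unknown (continued until `min(weaning, art_end_impute_days)`);
#'   default 183 days.
#' @param missing_arv_to category to which `arv_category = "missing"` is
#'   reassigned; default `"mono_dual_pmtct"`.
#' @return A `heu_rules` list.
#' @export
#' @examples
#' categorization_rules()
categorization_rules <- function(followup_cap_days = 730L,
                                 unknown_weaning_impute_days = 183L,
                                 art_end_impute_days = 183L,
                                 missing_arv_to = "mono_dual_pmtct") {
  stopifnot(
    followup_cap_days > 0, unknown_weaning_impute_days > 0,
    art_end_impute_days > 0,
    followup_cap_days >= unknown_weaning_impute_days,
    followup_cap_days >= art_end_impute_days
  )
  missing_arv_to <- match.arg(missing_arv_to,
                              c("mono_dual_pmtct", "none", "art_pmtct", "art_life"))
  structure(
    list(
      followup_cap_days = as.integer(followup_cap_days),
      unknown_weaning_impute_days = as.integer(unknown_weaning_impute_days),
      art_end_impute_days = as.integer(art_end_impute_days),
      missing_arv_to = missing_arv_to
    ),
    class = "heu_rules"
  )
}

#' @export
print.heu_rules <- function(x, ...) {
  cat("Categorization rules:\n")
  cat("  follow-up cap:            ", x$followup_cap_days, "days\n")
  cat("  unknown weaning imputed:  ", x$unknown_weaning_impute_days, "days\n")
  cat("  unknown ART end imputed:  min(weaning,", x$art_end_impute_days, "days)\n")
  cat("  missing ARV reassigned to:", x$missing_arv_to, "\n")
  invisible(x)
}

#' Validate a child-level cohort table
#'
#' Schema and invariant checks. Always returns a diagnostics object; never
#' errors on bad data rows (use the diagnostics to filter or fix).
#'
#' @param records a data frame following the child-level schema
#'   (see `?"cohort-schema"`), or a path to a CSV file holding one.
#' @return A list of class `heu_diagnostics` with elements `n_rows`,
#'   `missing_columns`, `missingness` (per-column NA counts) and `violations`
#'   (tibble of row-level invariant violations with `child_id`).
#' @export
validate_input <- function(records) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_cohort(records)
  }
  records <- as_tibble(records)
  missing_cols <- setdiff(heu_required_cols, names(records))
  present <- intersect(heu_required_cols, names(records))
  missingness <- tibble(
    column = present,
    n_missing = vapply(records[present], function(x) sum(is.na(x)), integer(1))
  )

  viol <- list()
  flag <- function(cond, rule) {
    cond[is.na(cond)] <- FALSE
    if (any(cond)) {
      viol[[length(viol) + 1L]] <<- tibble(
        child_id = as.character(records$child_id[cond]), rule = rule
      )
    }
  }
  if (length(missing_cols) == 0L) {
    for (col in heu_age_cols) {
      flag(records[[col]] < 0, paste0("negative ", col))
    }
    flag(is.na(records$censor_age_days), "censor_age_days missing")
    flag(records$child_death_age_days > records$censor_age_days,
         "death after censoring date")
    flag(!is.na(records$weaning_age_days) & !isTRUE_vec(records$ever_breastfed),
         "weaning date on never/unknown-breastfed child")
    flag(duplicated(records$child_id), "duplicate child_id")
  }
  structure(
    list(
      n_rows = nrow(records),
      missing_columns = missing_cols,
      missingness = missingness,
      violations = if (length(viol)) bind_rows(viol) else
        tibble(child_id = character(), rule = character())
    ),
    class = "heu_diagnostics"
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.heu_diagnostics <- function(x, ...) {
  cat("Cohort diagnostics:", x$n_rows, "rows\n")
  if (length(x$missing_columns)) {
    cat("  missing columns:", paste(x$missing_columns, collapse = ", "), "\n")
  }
  cat("  invariant violations:", nrow(x$violations), "\n")
  if (nrow(x$violations)) print(x$violations, n = 10)
  invisible(x)
}

#' Read / write a cohort CSV
#'
#' Thin wrappers around [readr::read_csv()] / [readr::write_csv()] fixing the
#' column types of the child-level schema.
#'
#' @param path file path.
#' @param records cohort table.
#' @return `read_cohort()` returns a tibble; `write_cohort()` its input,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      child_id = readr::col_character(),
      study_id = readr::col_character(),
      ever_breastfed = readr::col_logical(),
      weaning_age_days = readr::col_double(),
      art_start_age_days = readr::col_double(),
      art_end_age_days = readr::col_double(),
      maternal_death_age_days = readr::col_double(),
      child_death_age_days = readr::col_double(),
      censor_age_days = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
}

#' @rdname read_cohort
#' @export
write_cohort <- function(records, path) {
  readr::write_csv(records, path)
  invisible(records)
}

#' Apply categorization and imputation rules to raw child records
#'
#' Applies, in order: rejection of records with negative ages; exclusion of
#' children with unknown breastfeeding status; reassignment of missing
#' maternal ARV information to the protocol category; recoding of missing
#' categorical covariates to an explicit `"unknown"` level; imputation of
#' unknown weaning ages for breastfed children (6 months, study exit or
#' maternal death, whichever first); imputation of unknown 3-drug ART windows;
#' and truncation of follow-up at the 24-month cap (deaths beyond the cap
#' become censorings).
#'
#' The operation is idempotent: applying it to its own output changes nothing.
#' Exclusion and imputation counts are recorded in the `"heu_log"` attribute
#' and reported via [inform()].
#'
#' @param records child-level cohort table (see `?"cohort-schema"`).
#' @param rules a [categorization_rules()] object.
#' @param quiet suppress count messages.
#' @return The categorized tibble, with attribute `"heu_log"` (named list of
#'   counts) and logical column `imputed_weaning`.
#' @export
apply_categorization <- function(records, rules = categorization_rules(),
                                 quiet = FALSE) {
  stopifnot(inherits(rules, "heu_rules"))
  records <- as_tibble(records)
  if (nrow(records) == 0L) abort("`records` is empty.")
  missing_cols <- setdiff(heu_required_cols, names(records))
  if (length(missing_cols)) {
    abort(paste0("`records` lacks required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }

  for (col in heu_age_cols) {
    bad <- !is.na(records[[col]]) & records[[col]] < 0
    if (any(bad)) {
      abort(paste0(
        "Negative ", col, " for child(ren): ",
        paste(utils::head(records$child_id[bad], 5), collapse = ", ")
      ))
    }
  }
  bad <- !is.na(records$child_death_age_days) &
    records$child_death_age_days > records$censor_age_days
  if (any(bad)) {
    abort(paste0(
      "child_death_age_days exceeds censor_age_days for child(ren): ",
      paste(utils::head(records$child_id[bad], 5), collapse = ", ")
    ))
  }

  log <- list()

  ## unknown feeding status: excluded (counts logged)
  excl <- is.na(records$ever_breastfed)
  log$excluded_unknown_breastfeeding <- sum(excl)
  records <- records[!excl, , drop = FALSE]
  if (nrow(records) == 0L) abort("All records excluded (unknown breastfeeding status).")

  ## missing ARV information -> protocol category
  miss_arv <- is.na(records$arv_category) | records$arv_category == "missing"
  log$reassigned_missing_arv <- sum(miss_arv)
  records$arv_category[miss_arv] <- rules$missing_arv_to

  ## explicit "unknown" categorical levels
  for (col in c("sex", "birth_weight_group", "cd4_group", "region")) {
    records[[col]][is.na(records[[col]])] <- "unknown"
  }

  ## follow-up cap: deaths after the cap become censorings at the cap
  cap <- rules$followup_cap_days
  late_death <- !is.na(records$child_death_age_days) &
    records$child_death_age_days > cap
  log$deaths_censored_at_cap <- sum(late_death)
  records$child_death_age_days[late_death] <- NA_real_
  records$censor_age_days <- pmin(records$censor_age_days, cap)

  fu_end <- pmin(
    ifelse(is.na(records$child_death_age_days), Inf, records$child_death_age_days),
    records$censor_age_days
  )

  ## unknown weaning for breastfed children: 6 mo / exit / maternal death
  if (!"imputed_weaning" %in% names(records)) {
    records$imputed_weaning <- FALSE
  }
  need_wean <- records$ever_breastfed & is.na(records$weaning_age_days)
  log$imputed_weaning <- sum(need_wean)
  imput <- pmin(
    rules$unknown_weaning_impute_days,
    fu_end,
    ifelse(is.na(records$maternal_death_age_days), Inf,
           records$maternal_death_age_days)
  )
  records$weaning_age_days[need_wean] <- imput[need_wean]
  records$imputed_weaning <- records$imputed_weaning | need_wean

  ## 3-drug ART windows: antenatal start -> birth; unknown end ->
  ## min(weaning, 183 d) for PMTCT-ART, end of follow-up for ART-for-life
  on_art3 <- records$arv_category %in% c("art_pmtct", "art_life")
  records$art_start_age_days[on_art3 & is.na(records$art_start_age_days)] <- 0
  need_end <- on_art3 & is.na(records$art_end_age_days)
  log$imputed_art_end <- sum(need_end & records$arv_category == "art_pmtct")
  ## PMTCT-ART runs to min(weaning, 183 d) when breastfeeding and ends at
  ## delivery when exclusively formula-fed
  pmtct_end <- ifelse(
    isTRUE_vec(records$ever_breastfed),
    pmin(ifelse(is.na(records$weaning_age_days), rules$art_end_impute_days,
                records$weaning_age_days),
         rules$art_end_impute_days),
    0
  )
  records$art_end_age_days[need_end] <- ifelse(
    records$arv_category[need_end] == "art_life", cap, pmtct_end[need_end]
  )
  records$art_start_age_days[!on_art3] <- NA_real_
  records$art_end_age_days[!on_art3] <- NA_real_

  if (!quiet) {
    for (nm in names(log)) {
      if (log[[nm]] > 0) inform(paste0(nm, ": n = ", log[[nm]]))
    }
  }
  attr(records, "heu_log") <- log
  records
}
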