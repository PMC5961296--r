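heu_fu_end <- function(records) {
  pmin(
    ifelse(is.na(records$child_death_age_days), Inf, records$child_death_age_days),
    records$censor_age_days
  )
}

#' Expand child records into counting-process episodes
#'
#' Converts one-row-per-child records into `(start, stop]` episodes within
#' which every covariate is constant, cutting at the change-points of the
#' time-dependent covariates of the requested scheme:
#'
#' * `"maternal_vital_only"` — cut at maternal death; carries the indicator
#'   `mother_dead`.
#' * `"plus_bf_cessation"` — additionally cut at weaning; carries
#'   `mother_dead` and `currently_breastfed`.
#' * `"bf_by_art_joint"` — cut at weaning and at the maternal 3-drug ART
#'   start/stop; carries `currently_breastfed`, `mother_on_art3` and the
#'   four-level `bf_art_category` (A = not breastfed/no ART3, B = not
#'   breastfed/ART3, C = breastfed/no ART3, D = breastfed/ART3).
#'
#' Episodes are half-open `(start, stop]` with the event placed at `stop` of
#' the last episode. A change-point coinciding with the event or censoring
#' time produces no cut (the death falls in the episode with the pre-change
#' covariate value); a change-point at age 0 means the first episode already
#' carries the post-change value.
#'
#' @param records categorized child records (see [apply_categorization()]).
#' @param scheme which time-dependent covariates to expand.
#' @return A tibble with columns `child_id`, `study_id`, `start`, `stop`,
#'   `event`, the fixed covariates, and the scheme's time-dependent columns
#'   (integer 0/1 indicators). Attribute `"scheme"` records the scheme.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   child_id = "c1", study_id = "s1", region = "Africa", sex = "male",
#'   birth_weight_group = "ge2500", ever_breastfed = TRUE,
#'   weaning_age_days = 150, arv_category = "none",
#'   art_start_age_days = NA_real_, art_end_age_days = NA_real_,
#'   cd4_group = "ge350", maternal_death_age_days = 100,
#'   child_death_age_days = NA_real_, censor_age_days = 300
#' )
#' split_episodes(rec, "maternal_vital_only")
split_episodes <- function(records,
                           scheme = c("maternal_vital_only",
                                      "plus_bf_cessation",
                                      "bf_by_art_joint")) {
  scheme <- match.arg(scheme)
  records <- as_tibble(records)
  if (nrow(records) == 0L) abort("`records` is empty.")
  n <- nrow(records)
  fu_end <- heu_fu_end(records)
  if (any(!is.finite(fu_end) | fu_end <= 0)) {
    abort("Every child needs a positive, finite follow-up end (death/censor age).")
  }
  died <- !is.na(records$child_death_age_days) &
    records$child_death_age_days <= records$censor_age_days

  md <- records$maternal_death_age_days
  wean <- ifelse(isTRUE_vec(records$ever_breastfed),
                 ifelse(is.na(records$weaning_age_days), fu_end,
                        records$weaning_age_days),
                 NA_real_)
  art_start <- records$art_start_age_days
  art_end <- records$art_end_age_days

  cut_sources <- switch(scheme,
    maternal_vital_only = list(md),
    plus_bf_cessation = list(md, wean),
    bf_by_art_joint = list(wean, art_start, art_end)
  )

  idx <- seq_len(n)
  cut_i <- integer(0)
  cut_t <- numeric(0)
  for (v in cut_sources) {
    keep <- !is.na(v) & v > 0 & v < fu_end
    cut_i <- c(cut_i, idx[keep])
    cut_t <- c(cut_t, v[keep])
  }
  bi <- c(idx, cut_i)
  bt <- c(fu_end, cut_t)
  ord <- order(bi, bt)
  bi <- bi[ord]; bt <- bt[ord]
  dup <- c(FALSE, bi[-1] == bi[-length(bi)] & bt[-1] == bt[-length(bt)])
  bi <- bi[!dup]; bt <- bt[!dup]

  first <- !duplicated(bi)
  last <- !duplicated(bi, fromLast = TRUE)
  start <- c(0, bt[-length(bt)])
  start[first] <- 0

  ep <- tibble(
    child_id = records$child_id[bi],
    study_id = records$study_id[bi],
    start = start,
    stop = bt,
    event = last & died[bi],
    region = records$region[bi],
    sex = records$sex[bi],
    birth_weight_group = records$birth_weight_group[bi],
    ever_breastfed = records$ever_breastfed[bi],
    arv_category = records$arv_category[bi],
    cd4_group = records$cd4_group[bi]
  )

  ## covariate value on (start, stop] is the value just after `start`
  if (scheme %in% c("maternal_vital_only", "plus_bf_cessation")) {
    ep$mother_dead <- as.integer(!is.na(md[bi]) & md[bi] <= start)
  }
  if (scheme %in% c("plus_bf_cessation", "bf_by_art_joint")) {
    ep$currently_breastfed <- as.integer(!is.na(wean[bi]) & wean[bi] > start)
  }
  if (scheme == "bf_by_art_joint") {
    ep$mother_on_art3 <- as.integer(
      !is.na(art_start[bi]) & art_start[bi] <= start &
        !is.na(art_end[bi]) & art_end[bi] > start
    )
    ep$bf_art_category <- c("A", "B", "C", "D")[
      1L + ep$mother_on_art3 + 2L * ep$currently_breastfed
    ]
  }
  attr(ep, "scheme") <- scheme
  ep
}

#' Merge adjacent episodes with identical covariates
#'
#' Inverse of an over-fine split: re-merges contiguous episodes of one child
#' whose covariate values coincide, yielding the minimal counting-process
#' representation. Used mainly to check that episode covariates are
#' right-continuous step functions of age.
#'
#' @param episodes an episode table from [split_episodes()].
#' @return The merged episode tibble.
#' @export
merge_episodes <- function(episodes) {
  covs <- setdiff(names(episodes), c("child_id", "start", "stop", "event"))
  key <- do.call(paste, c(episodes[c("child_id", covs)], sep = "\r"))
  episodes <- episodes[order(episodes$child_id, episodes$start), ]
  key <- key[order(episodes$child_id, episodes$start)]
  new_block <- c(TRUE, key[-1] != key[-length(key)] |
                   episodes$start[-1] != episodes$stop[-nrow(episodes)])
  last_idx <- which(c(new_block[-1], TRUE))
  out <- episodes[new_block, , drop = FALSE]
  out$stop <- episodes$stop[last_idx]
  out$event <- episodes$event[last_idx]
  as_tibble(out)
}

#' Descriptive cohort summaries
#'
#' Per-study and overall counts, crude death proportions and covariate
#' prevalences, with percentages rounded to one decimal.
#'
#' @param records categorized child records.
#' @return A list of class `heu_cohort_summary` with tibbles `studies`
#'   (`study_id`, `n_children`, `n_deaths`, `death_pct`), `overall` (one
#'   row), and `covariates` (`covariate`, `level`, `n`, `pct`).
#' @export
summarize_cohort <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) abort("`records` is empty.")
  died <- !is.na(records$child_death_age_days) &
    records$child_death_age_days <= records$censor_age_days

  studies <- records %>%
    mutate(died = died) %>%
    group_by(.data$study_id) %>%
    summarise(
      n_children = n(),
      n_deaths = sum(.data$died),
      death_pct = round(100 * .data$n_deaths / .data$n_children, 1),
      .groups = "drop"
    )
  overall <- tibble(
    n_children = nrow(records),
    n_deaths = sum(died),
    death_pct = round(100 * sum(died) / nrow(records), 1)
  )
  cov_cols <- intersect(
    c("region", "subregion", "sex", "birth_weight_group", "ever_breastfed",
      "arv_category", "cd4_group"),
    names(records)
  )
  covariates <- purrr::map_dfr(cov_cols, function(col) {
    records %>%
      count(level = as.character(.data[[col]])) %>%
      mutate(covariate = col, pct = round(100 * n / nrow(records), 1)) %>%
      select("covariate", "level", "n", "pct")
  })
  structure(
    list(studies = studies, overall = overall, covariates = covariates),
    class = "heu_cohort_summary"
  )
}

#' @export
print.heu_cohort_summary <- function(x, ...) {
  cat("Cohort:", x$overall$n_children, "children,",
      x$overall$n_deaths, "deaths (", x$overall$death_pct, "%) across",
      nrow(x$studies), "studies\n\n")
  print(x$covariates, n = 30)
  invisible(x)
}
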