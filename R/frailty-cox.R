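heu_default_refs <- c(
  region = "Africa", subregion = "Southern Africa", sex = "male",
  birth_weight_group = "ge2500", ever_breastfed = "TRUE",
  arv_category = "none", cd4_group = "ge350", mother_dead = "0",
  currently_breastfed = "0", mother_on_art3 = "0", bf_art_category = "A"
)

#' Model specification for the frailty Cox fit
#'
#' @param covariates character vector of covariate column names, fitted as
#'   categorical terms (each non-reference level gets a log hazard ratio).
#' @param cluster clustering column carrying the shared frailty
#'   (default `"study_id"`).
#' @param reference named list/vector of reference levels; sensible defaults
#'   exist for all standard cohort covariates.
#' @param always_keep covariates retained through stepwise selection
#'   regardless of significance (default maternal ARV category).
#' @param forced covariates forced into every multivariable model and never
#'   eligible for dropping (default region and maternal CD4 group).
#' @param selection `"none"` or `"stepwise_descending"`.
#' @param entry_p univariate screening threshold (default 0.1).
#' @param stay_p retention threshold in the final model (default 0.05).
#' @return A `heu_model_spec` list.
#' @export
model_spec <- function(covariates,
                       cluster = "study_id",
                       reference = list(),
                       always_keep = "arv_category",
                       forced = c("region", "cd4_group"),
                       selection = c("none", "stepwise_descending"),
                       entry_p = 0.1, stay_p = 0.05) {
  selection <- match.arg(selection)
  stopifnot(is.character(covariates), length(covariates) >= 1,
            entry_p > 0, entry_p < 1, stay_p > 0, stay_p < 1)
  structure(
    list(covariates = covariates, cluster = cluster,
         reference = as.list(reference),
         always_keep = intersect(always_keep, covariates),
         forced = intersect(forced, covariates),
         selection = selection, entry_p = entry_p, stay_p = stay_p),
    class = "heu_model_spec"
  )
}

#' Numerical control for the frailty Cox fitter
#'
#' @param eps outer convergence tolerance on `max(|d beta|, |d theta|)`.
#' @param max_iter maximum EM iterations.
#' @param nr_eps,nr_max_iter inner Newton-Raphson tolerance/iterations for
#'   the partial-likelihood maximization.
#' @param theta_max upper bound of the frailty-variance search.
#' @param compute_se compute standard errors from the penalized observed
#'   information (skip for speed inside bootstrap loops).
#' @export
frailty_control <- function(eps = 1e-6, max_iter = 200L, nr_eps = 1e-10,
                            nr_max_iter = 30L, theta_max = 20,
                            compute_se = TRUE) {
  list(eps = eps, max_iter = as.integer(max_iter), nr_eps = nr_eps,
       nr_max_iter = as.integer(nr_max_iter), theta_max = theta_max,
       compute_se = compute_se)
}

## ---- design matrix ---------------------------------------------------------

## Indicator design for categorical covariates with declared references.
## Returns X (n x p), a terms tibble (term, covariate, level) and the list
## of covariates dropped for lack of contrast.
build_design <- function(data, covariates, reference = list()) {
  cols <- list()
  terms <- list()
  dropped <- character(0)
  for (cov in covariates) {
    if (!cov %in% names(data)) {
      abort(paste0("Covariate `", cov, "` not found in the episode table."))
    }
    x <- as.character(data[[cov]])
    levs <- sort(unique(x))
    ref <- as.character(reference[[cov]] %||% NA)
    if (is.na(ref)) {
      ref <- unname(heu_default_refs[match(cov, names(heu_default_refs))])
    }
    if (is.na(ref) || !ref %in% levs) ref <- levs[1]
    non_ref <- setdiff(levs, ref)
    if (length(non_ref) == 0L) {
      warn(paste0("Covariate `", cov, "` has a single level; no contrast, ",
                  "excluded from the model."))
      dropped <- c(dropped, cov)
      next
    }
    for (lev in non_ref) {
      cols[[paste0(cov, lev)]] <- as.numeric(x == lev)
      terms[[length(terms) + 1L]] <- tibble(
        term = paste0(cov, lev), covariate = cov, level = lev, reference = ref
      )
    }
  }
  if (length(cols) == 0L) abort("No estimable covariate contrasts.")
  list(
    X = do.call(cbind, cols),
    terms = bind_rows(terms),
    dropped = dropped
  )
}

## ---- partial-likelihood machinery -----------------------------------------

## Risk-set suffix-sum machinery for counting-process data: precomputes the
## orderings and per-event-time indices so that risk sums over
## {j : start_j < t_k <= stop_j} reduce to differences of cumulative sums.
pl_engine <- function(start, stop, event) {
  if (any(start >= stop)) abort("Episodes need start < stop.")
  et <- sort(unique(stop[event]))
  if (length(et) == 0L) abort("No events in the data.")
  list(
    et = et,
    d = as.numeric(tapply(rep(1, sum(event)), factor(stop[event], levels = et),
                          sum)),
    ord_start = order(start),
    ord_stop = order(stop),
    k_start = findInterval(et, sort(start), left.open = TRUE),
    k_stop = findInterval(et, sort(stop), left.open = TRUE),
    event = event
  )
}

## column-wise cumulative sums in one pass: cumsum the whole matrix and
## subtract each column's inherited offset
col_cumsum <- function(M) {
  d <- dim(M)
  CS <- matrix(cumsum(M), d[1L], d[2L])
  if (d[2L] > 1L) CS <- CS - rep(c(0, CS[d[1L], -d[2L]]), each = d[1L])
  CS
}

## Column-wise risk sums at the event times: V is n x m.
risk_sums <- function(eng, V) {
  css <- function(ord, k) {
    C <- col_cumsum(V[ord, , drop = FALSE])
    out <- C[pmax(k, 1L), , drop = FALSE]
    out[k == 0L, ] <- 0
    out
  }
  css(eng$ord_start, eng$k_start) - css(eng$ord_stop, eng$k_stop)
}

## Loop-invariant quantities of the Newton-Raphson partial-likelihood
## maximization: design, pairwise products for the information matrix and
## the event covariate totals.
nr_context <- function(X, eng) {
  p <- ncol(X)
  pp_idx <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  list(
    X = X, p = p,
    XX = X[, pp_idx[, 1], drop = FALSE] * X[, pp_idx[, 2], drop = FALSE],
    x_events = colSums(X[eng$event, , drop = FALSE])
  )
}

## Newton-Raphson maximization of the Breslow partial likelihood with a
## fixed offset. Returns beta, the Breslow baseline increments, the
## converged weights and the partial log-likelihood.
cox_nr <- function(ctx, eng, offset, init = NULL, nr_eps = 1e-10,
                   nr_max_iter = 30L) {
  X <- ctx$X
  XX <- ctx$XX
  x_events <- ctx$x_events
  p <- ctx$p
  beta <- if (is.null(init)) numeric(p) else init

  unpack <- function(v) {
    M <- matrix(0, p, p)
    M[upper.tri(M, diag = TRUE)] <- v
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  }
  eval_pl <- function(beta) {
    eta <- drop(X %*% beta) + offset
    w <- exp(pmin(eta, 500))
    S0 <- drop(risk_sums(eng, cbind(w)))
    list(eta = eta, w = w, S0 = S0,
         ll = sum(eta[eng$event]) - sum(eng$d * log(S0)))
  }

  st <- eval_pl(beta)
  converged <- FALSE
  it <- 0L
  repeat {
    ## score and information at the current beta (also the exit values)
    S12 <- risk_sums(eng, st$w * cbind(X, XX))
    S1 <- S12[, seq_len(p), drop = FALSE]
    S2 <- S12[, p + seq_len(ncol(XX)), drop = FALSE]
    mu <- S1 / st$S0
    U <- x_events - colSums(eng$d * mu)
    Ifull <- unpack(colSums(eng$d * (S2 / st$S0))) -
      crossprod(sqrt(eng$d) * mu)
    if (converged || it >= nr_max_iter) break
    it <- it + 1L
    step <- tryCatch(solve(Ifull, U), error = function(e) {
      solve(Ifull + diag(1e-8 * (1 + abs(diag(Ifull))), p), U)
    })
    ## step-halving to guarantee ascent; cap |beta| against separation
    for (h in 0:20) {
      cand <- pmin(pmax(beta + step / 2^h, -15), 15)
      st_new <- eval_pl(cand)
      if (st_new$ll >= st$ll - 1e-12) break
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    st <- st_new
    if (delta < nr_eps) converged <- TRUE
  }
  list(beta = beta, w = st$w, S0 = st$S0, ll = st$ll, eta = st$eta,
       info = Ifull, dH0 = eng$d / st$S0, nr_converged = converged)
}

## Gamma-frailty piece of the marginal log-likelihood given per-cluster
## event counts D and cumulative-hazard loads L.
gamma_marginal_piece <- function(theta, D, L) {
  if (theta <= 0) return(sum(-L))
  inv <- 1 / theta
  sum(D * log(theta) + lgamma(inv + D) - lgamma(inv) -
        (inv + D) * log1p(theta * L))
}

## ---- the fitter ------------------------------------------------------------

#' Fit a shared gamma-frailty Cox model on counting-process episodes
#'
#' Estimates log hazard ratios for categorical covariates, a per-cluster
#' gamma frailty (mean 1, variance `theta`) and the Breslow baseline
#' cumulative hazard, by expectation-maximization: the E-step replaces each
#' cluster's frailty by its posterior mean
#' `(1/theta + events_s) / (1/theta + hazard load_s)`; the M-step maximizes
#' the Breslow partial likelihood with log-frailties as offsets
#' (Newton-Raphson); `theta` is updated each cycle by maximizing the
#' profile marginal likelihood. Standard errors come from the observed
#' information of the penalized likelihood jointly in the regression
#' coefficients and the log-frailties, so between-study uncertainty
#' propagates into study-level covariates.
#'
#' @param episodes counting-process episode table from [split_episodes()]
#'   (columns `start`, `stop`, `event`, the covariates, and the cluster).
#' @param covariates character vector of covariate names, or a
#'   [model_spec()].
#' @param cluster cluster column name (ignored when `covariates` is a spec).
#' @param reference named list of reference levels (ignored for a spec).
#' @param theta `NULL` to estimate the frailty variance, or a fixed
#'   nonnegative value (0 = no frailty, plain Cox).
#' @param init optional named vector of starting log hazard ratios.
#' @param init_theta starting value for the frailty variance.
#' @param control a [frailty_control()] list.
#' @return An object of class `frailty_cox_fit`; see [tidy.frailty_cox_fit()]
#'   and [glance.frailty_cox_fit()] for tabular views.
#' @export
#' @examples
#' cfg <- cohort_config(n_studies = 4, children_per_study = 300, theta = 0.2)
#' rec <- apply_categorization(generate_cohort(cfg, seed = 2), quiet = TRUE)
#' ep <- split_episodes(rec, "maternal_vital_only")
#' fit <- fit_frailty_cox(ep, c("birth_weight_group", "mother_dead"))
#' tidy(fit)
fit_frailty_cox <- function(episodes, covariates, cluster = "study_id",
                            reference = list(), theta = NULL,
                            init = NULL, init_theta = 0.1,
                            control = frailty_control()) {
  if (inherits(covariates, "heu_model_spec")) {
    spec <- covariates
    covariates <- spec$covariates
    cluster <- spec$cluster
    reference <- spec$reference
  }
  episodes <- as_tibble(episodes)
  stopifnot(all(c("start", "stop", "event", cluster) %in% names(episodes)))
  des <- build_design(episodes, covariates, reference)
  X <- des$X
  p <- ncol(X)
  eng <- pl_engine(episodes$start, episodes$stop, episodes$event)
  cl <- factor(episodes[[cluster]])
  K <- nlevels(cl)
  cli <- as.integer(cl)
  D_s <- drop(rowsum(as.numeric(episodes$event), cli,
                     reorder = TRUE))
  ctx <- nr_context(X, eng)

  fixed_theta <- !is.null(theta)
  if (fixed_theta) stopifnot(theta >= 0)
  th <- if (fixed_theta) theta else init_theta
  u <- rep(1, K)
  beta <- if (is.null(init)) NULL else unname(init[des$terms$term])
  if (!is.null(beta) && anyNA(beta)) beta <- NULL

  H0_at <- function(cumH, t) {
    idx <- findInterval(t, eng$et)
    c(0, cumH)[idx + 1L]
  }

  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    off <- log(u)[cli]
    nr <- cox_nr(ctx, eng, off, init = beta, nr_eps = control$nr_eps,
                 nr_max_iter = control$nr_max_iter)
    new_beta <- nr$beta
    cumH <- cumsum(nr$dH0)
    ## per-cluster hazard load (frailty excluded)
    risk <- exp(drop(X %*% new_beta)) *
      (H0_at(cumH, episodes$stop) - H0_at(cumH, episodes$start))
    L_s <- drop(rowsum(risk, cli, reorder = TRUE))

    new_th <- th
    if (!fixed_theta) {
      opt <- optimize(gamma_marginal_piece, c(1e-8, control$theta_max),
                      D = D_s, L = L_s, maximum = TRUE, tol = 1e-8)
      new_th <- if (gamma_marginal_piece(0, D_s, L_s) >= opt$objective) 0
                else opt$maximum
    }
    u <- if (new_th > 0) (1 / new_th + D_s) / (1 / new_th + L_s) else rep(1, K)

    delta <- max(abs(new_beta - (beta %||% rep(0, p))), abs(new_th - th))
    beta <- new_beta
    th <- new_th
    if ((fixed_theta && th == 0 && nr$nr_converged) || delta < control$eps) {
      converged <- TRUE
      break
    }
    if (iterations >= control$max_iter) break
  }

  if (!converged) {
    warn(paste0("Frailty Cox EM did not converge in ", iterations,
                " iterations (last max change ",
                signif(delta, 3), ")."))
  }
  separated <- abs(beta) >= 15
  if (any(separated)) {
    warn(paste0("Possible separation (no events in a level?): ",
                paste(des$terms$term[separated], collapse = ", "),
                "; coefficients capped, standard errors unreliable."))
  }

  ## standard errors: penalized observed information in (beta, log u)
  se <- rep(NA_real_, p)
  var_beta <- NULL
  if (control$compute_se) {
    if (th > 0) {
      Z <- matrix(0, nrow(X), K)
      Z[cbind(seq_len(nrow(X)), cli)] <- 1
      Xa <- cbind(X, Z)
      nra <- cox_nr(nr_context(Xa, eng), eng, offset = rep(0, nrow(X)),
                    init = c(beta, log(u)), nr_max_iter = 0L)
      Ia <- nra$info
      diag(Ia)[(p + 1):(p + K)] <- diag(Ia)[(p + 1):(p + K)] + u / th
      V <- tryCatch(solve(Ia), error = function(e) {
        solve(Ia + diag(1e-8, ncol(Ia)))
      })
      var_beta <- V[seq_len(p), seq_len(p), drop = FALSE]
    } else {
      var_beta <- tryCatch(solve(nr$info), error = function(e) {
        solve(nr$info + diag(1e-8, p))
      })
    }
    se <- sqrt(pmax(diag(var_beta), 0))
  }

  ll <- sum(drop(X %*% beta)[eng$event]) + sum(eng$d * log(nr$dH0)) +
    gamma_marginal_piece(th, D_s, L_s)

  structure(
    list(
      beta = setNames(beta, des$terms$term),
      se_beta = setNames(se, des$terms$term),
      var_beta = var_beta,
      theta = th,
      theta_fixed = fixed_theta,
      frailties = setNames(u, levels(cl)),
      baseline = tibble(time = eng$et, hazard = nr$dH0,
                        cumhaz = cumsum(nr$dH0)),
      baseline_type = "step",
      max_time = max(episodes$stop),
      loglik = ll,
      n_episodes = nrow(episodes),
      n_subjects = if ("child_id" %in% names(episodes))
        dplyr::n_distinct(episodes$child_id) else NA_integer_,
      n_events = sum(eng$d),
      n_clusters = K,
      iterations = iterations,
      converged = converged,
      terms = des$terms,
      dropped = des$dropped,
      covariates = setdiff(covariates, des$dropped),
      cluster = cluster
    ),
    class = "frailty_cox_fit"
  )
}

#' Build a frailty-Cox fit object from known parameters
#'
#' Constructs a `frailty_cox_fit` directly from specified log hazard ratios,
#' frailty variance and a piecewise-constant baseline hazard, without
#' estimation. Useful for evaluating predictions and attributable fractions
#' at the true parameters of a generating model.
#'
#' @param log_hr named list: covariate -> named vector of log hazard ratios
#'   per non-reference level (as in [cohort_config()]'s `true_log_hr`).
#' @param theta frailty variance.
#' @param baseline_breaks,baseline_rates piecewise-constant baseline hazard
#'   (per day); `baseline_breaks[1]` must be 0.
#' @param max_time support of the baseline (days).
#' @param reference named list of reference levels.
#' @return A `frailty_cox_fit` with an exact (piecewise-linear) baseline
#'   cumulative hazard.
#' @export
frailty_fit_from_parameters <- function(log_hr, theta, baseline_breaks,
                                        baseline_rates, max_time = 730,
                                        reference = list()) {
  stopifnot(baseline_breaks[1] == 0,
            length(baseline_rates) == length(baseline_breaks))
  knots <- c(baseline_breaks, max_time)
  cumhaz <- c(0, cumsum(baseline_rates * diff(knots)))
  terms <- purrr::map_dfr(names(log_hr), function(cov) {
    tibble(term = paste0(cov, names(log_hr[[cov]])), covariate = cov,
           level = names(log_hr[[cov]]),
           reference = as.character(reference[[cov]] %||%
                                      heu_default_refs[[cov]] %||% ""))
  })
  beta <- unlist(lapply(names(log_hr), function(cov) {
    setNames(log_hr[[cov]], paste0(cov, names(log_hr[[cov]])))
  }))
  structure(
    list(
      beta = beta, se_beta = setNames(rep(NA_real_, length(beta)),
                                      names(beta)),
      var_beta = NULL, theta = theta, theta_fixed = TRUE,
      frailties = NULL,
      baseline = tibble(time = knots, cumhaz = cumhaz),
      baseline_type = "linear",
      max_time = max_time,
      loglik = NA_real_, n_episodes = NA_integer_, n_subjects = NA_integer_,
      n_events = NA_integer_, n_clusters = NA_integer_,
      iterations = 0L, converged = TRUE,
      terms = terms, dropped = character(0),
      covariates = names(log_hr), cluster = "study_id"
    ),
    class = "frailty_cox_fit"
  )
}

#' @export
print.frailty_cox_fit <- function(x, ...) {
  cat("Shared gamma-frailty Cox model\n")
  cat("  episodes:", x$n_episodes, " events:", x$n_events,
      " clusters:", x$n_clusters, "\n")
  cat("  frailty variance theta =", signif(x$theta, 4),
      if (x$theta_fixed) "(fixed)" else "", "\n")
  cat("  marginal log-likelihood = ", signif(x$loglik, 6),
      " (", x$iterations, " EM iterations",
      if (!x$converged) ", NOT converged" else "", ")\n", sep = "")
  print(tidy(x, exponentiate = TRUE), n = 30)
  invisible(x)
}

#' Tidy a frailty-Cox fit
#'
#' @param x a `frailty_cox_fit`.
#' @param exponentiate report hazard ratios instead of log hazard ratios.
#' @param conf_level Wald confidence level.
#' @param ... unused.
#' @return A tibble with `covariate`, `level`, `reference`, `term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.frailty_cox_fit <- function(x, exponentiate = FALSE, conf_level = 0.95,
                                 ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- x$terms %>%
    mutate(
      estimate = unname(x$beta[.data$term]),
      std.error = unname(x$se_beta[.data$term]),
      statistic = .data$estimate / .data$std.error,
      p.value = 2 * pnorm(-abs(.data$statistic)),
      conf.low = .data$estimate - z * .data$std.error,
      conf.high = .data$estimate + z * .data$std.error
    )
  if (exponentiate) {
    out <- out %>% mutate(
      estimate = exp(.data$estimate),
      conf.low = exp(.data$conf.low),
      conf.high = exp(.data$conf.high)
    )
  }
  out
}

#' Model-level summary of a frailty-Cox fit
#'
#' @param x a `frailty_cox_fit`.
#' @param ... unused.
#' @return A one-row tibble with `n_episodes`, `n_subjects`, `n_events`,
#'   `n_clusters`, `theta`, `loglik`, `iterations`, `converged`.
#' @export
glance.frailty_cox_fit <- function(x, ...) {
  tibble(
    n_episodes = x$n_episodes, n_subjects = x$n_subjects,
    n_events = x$n_events, n_clusters = x$n_clusters,
    theta = x$theta, loglik = x$loglik,
    iterations = x$iterations, converged = x$converged
  )
}

## Wald chi-square test of all terms of one covariate jointly
block_wald_p <- function(fit, covariate) {
  idx <- which(fit$terms$covariate == covariate)
  if (length(idx) == 0L || is.null(fit$var_beta)) return(NA_real_)
  b <- fit$beta[idx]
  V <- fit$var_beta[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  if (is.na(stat)) return(NA_real_)
  pchisq(stat, df = length(idx), lower.tail = FALSE)
}
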