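# Subtype mixture fitting: hierarchical splitting + EM over (responsibilities,
# mixture fractions, per-subtype sequences), and BIC model selection.

new_sustain_model <- function(orderings, f, events, sigma, z_max, logLik,
                              em_trace = numeric(0), degenerate = FALSE) {
  structure(list(
    n_subtypes = length(orderings),
    orderings  = orderings,
    sequences  = lapply(orderings, as_event_sequence, events = events),
    f          = f / sum(f),
    sigma      = rep_len(sigma, events$n_biomarkers),
    z_max      = rep_len(z_max, events$n_biomarkers),
    events     = events,
    biomarkers = events$labels,
    n_events   = events$n_events,
    logLik     = logLik,
    em_trace   = em_trace,
    degenerate = degenerate
  ), class = "sustain_model")
}

# Total mixture log-likelihood and responsibilities for fixed parameters.
mixture_estep <- function(Z, orderings, f, events, sigma, z_max) {
  LLc <- vapply(orderings, function(o) marginal_loglik(Z, o, events, sigma, z_max),
                numeric(nrow(Z)))
  LLc <- matrix(LLc, nrow = nrow(Z))
  lw <- sweep(LLc, 2, log(f), "+")
  lse <- row_logsumexp(lw)
  list(total = sum(lse), r = exp(lw - lse), LLc = LLc)
}

# Alternating maximisation: E-step responsibilities, M-step fraction update
# and per-subtype sequence re-optimisation (warm-started hill climb).
em_subtypes <- function(Z, orderings, f, events, sigma, z_max,
                        em_iters = 100, tol = 1e-6) {
  trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max(1L, em_iters))) {
    es <- mixture_estep(Z, orderings, f, events, sigma, z_max)
    trace <- c(trace, es$total)
    if (es$total - prev < tol && it > 1L) break
    prev <- es$total
    f <- pmax(colSums(es$r), 1e-12)
    f <- f / sum(f)
    for (c in seq_along(orderings)) {
      wc <- es$r[, c]
      if (sum(wc) < 1e-10) next  # vanished component: keep its sequence
      orderings[[c]] <- climb_sequence(orderings[[c]], Z, wc, events, sigma, z_max)$ord
    }
  }
  es <- mixture_estep(Z, orderings, f, events, sigma, z_max)
  trace <- c(trace, es$total)
  list(orderings = orderings, f = f, logLik = es$total, r = es$r, trace = trace)
}

#' Fit z-score subtype-and-stage models for 1..max_subtypes subtypes
#'
#' Fits the one-subtype model by greedy sequence optimisation, then grows
#' the number of subtypes hierarchically: the subtype with the largest
#' membership is split by random bipartition (best of several seeded
#' splits), and all parameters are refined by expectation-maximisation
#' until the total log-likelihood improves by less than `tol`.
#'
#' @param Z patients x biomarkers z-score matrix (column names required;
#'   patients only — controls define the z reference, not the model).
#' @param max_subtypes largest number of subtypes to fit.
#' @param z_thresholds z event thresholds (default `c(1, 2, 3)`).
#' @param sigma,z_max per-biomarker likelihood SD and asymptotic z.
#' @param n_restarts random restarts for sequence search (default 25).
#' @param em_iters maximum EM iterations per candidate model.
#' @param seed integer seed; the whole fit is deterministic given it.
#' @param tol EM convergence tolerance on the total log-likelihood.
#' @return list of `sustain_model` objects, one per number of subtypes.
#' @export
fit_subtypes <- function(Z, max_subtypes = 2, z_thresholds = c(1, 2, 3),
                         sigma = 1, z_max = 5, n_restarts = 25,
                         em_iters = 100, seed = 1, tol = 1e-6) {
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) stop_arg("Z must have biomarker column names")
  if (max_subtypes < 1) stop_arg("max_subtypes must be >= 1")
  if (nrow(Z) < 2 * max_subtypes)
    stop_arg("need at least 2 patients per candidate subtype")
  events <- make_events(colnames(Z), z_thresholds)
  set.seed(substream(seed, 0L))
  one <- optimize_sequence_core(Z, rep(1, nrow(Z)), events, sigma, z_max, n_restarts)
  models <- list(new_sustain_model(list(one$ord), 1, events, sigma, z_max,
                                   sum(marginal_loglik(Z, one$ord, events, sigma, z_max)),
                                   degenerate = one$degenerate))
  if (max_subtypes == 1) return(models)
  n_split_starts <- max(1L, ceiling(n_restarts / 5))
  split_restarts <- max(1L, ceiling(n_restarts / 5))
  for (C in 2:max_subtypes) {
    prev <- models[[C - 1L]]
    es <- mixture_estep(Z, prev$orderings, prev$f, events, sigma, z_max)
    hard <- max.col(es$r, ties.method = "first")
    target <- which.max(tabulate(hard, nbins = C - 1L))
    members <- which(hard == target)
    best <- NULL
    for (s in seq_len(n_split_starts + 1L)) {
      set.seed(substream(seed, C * 1000L + s))
      if (s == 1L && length(members) >= 6L) {
        # primary split: 2-means on row-normalised z profiles, separating
        # atrophy *shape* (which regions lead) from severity (stage)
        Pm <- Z[members, , drop = FALSE]
        Pm <- Pm / pmax(sqrt(rowSums(Pm^2)), 1e-8)
        grp <- stats::kmeans(Pm, 2, nstart = 5)$cluster - 1L
      } else {
        grp <- stats::rbinom(length(members), 1, 0.5)
      }
      while (length(unique(grp)) < 2L) grp <- stats::rbinom(length(members), 1, 0.5)
      halves <- lapply(0:1, function(g) {
        w <- numeric(nrow(Z))
        w[members[grp == g]] <- 1
        optimize_sequence_core(Z, w, events, sigma, z_max, split_restarts,
                               init = prev$orderings[[target]])$ord
      })
      orderings <- c(prev$orderings[-target], halves)
      f0 <- c(prev$f[-target], prev$f[target] * c(mean(grp == 0), mean(grp == 1)))
      fit <- em_subtypes(Z, orderings, f0, events, sigma, z_max, em_iters, tol)
      if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
    models[[C]] <- new_sustain_model(best$orderings, best$f, events, sigma,
                                     z_max, best$logLik, em_trace = best$trace)
  }
  models
}

#' Select the number of subtypes by BIC
#'
#' `BIC_C = -2 logL_C + P_C log(n)` with the positional parameter-count
#' convention `P_C = C * N_events + (C - 1)`: one positional degree of
#' freedom per event per subtype plus the free mixture fractions. Ties go
#' to the smaller number of subtypes.
#'
#' @param models list of `sustain_model` objects for C = 1, 2, ...
#' @param n_patients number of patients the models were fitted on.
#' @param n_params optional function `(C, n_events) -> P_C` overriding the
#'   parameter-count convention.
#' @return integer: the selected number of subtypes. The full BIC table is
#'   attached as attribute `"bic"`.
#' @export
select_model <- function(models, n_patients, n_params = NULL) {
  if (length(models) == 0) stop_arg("empty model list")
  n_params <- n_params %||% function(C, n_events) C * n_events + (C - 1)
  tab <- data.frame(
    n_subtypes = vapply(models, `[[`, numeric(1), "n_subtypes"),
    logLik     = vapply(models, `[[`, numeric(1), "logLik")
  )
  tab$n_params <- vapply(seq_len(nrow(tab)), function(i)
    n_params(tab$n_subtypes[i], models[[i]]$n_events), numeric(1))
  tab$BIC <- -2 * tab$logLik + tab$n_params * log(n_patients)
  tab <- tab[order(tab$n_subtypes), ]
  sel <- tab$n_subtypes[which.min(tab$BIC)]  # which.min takes the smaller C on ties
  structure(as.integer(sel), bic = tab)
}

#' Maximum-likelihood subtype and stage assignment
#'
#' Assigns each patient to the subtype maximising `f_c P(z | S_c)` and to
#' the maximum a-posteriori stage of that subtype's stage posterior. Ties
#' are broken deterministically toward the lower subtype index and lower
#' stage, and flagged.
#'
#' @param Z patients x biomarkers z-score matrix (column names must match
#'   the model's biomarker panel).
#' @param model a `sustain_model`.
#' @param keep_posterior keep the full per-patient stage posterior as
#'   attribute `"stage_posterior"` (default TRUE).
#' @return data frame with columns `subject`, `subtype`, `stage`,
#'   `subtype_posterior`, `subtype_tied`, `stage_tied`.
#' @export
assign_subjects <- function(Z, model, keep_posterior = TRUE) {
  Z <- as.matrix(Z)
  if (!identical(colnames(Z), model$biomarkers))
    stop_arg("biomarker columns of Z do not match the fitted model")
  n <- nrow(Z)
  C <- model$n_subtypes
  K1 <- model$n_events + 1L
  stage_ll <- lapply(model$orderings, function(o)
    stage_loglik(Z, expected_z_matrix(o, model$events, model$z_max), model$sigma))
  marg <- vapply(stage_ll, function(M) row_logsumexp(M) - log(K1), numeric(n))
  marg <- matrix(marg, nrow = n)
  score <- sweep(marg, 2, log(model$f), "+")
  lse <- row_logsumexp(score)
  post <- exp(score - lse)
  subtype <- max.col(score, ties.method = "first")
  subtype_tied <- rowSums(abs(score - score[cbind(seq_len(n), subtype)]) < 1e-9) > 1L
  stage <- integer(n)
  stage_tied <- logical(n)
  stage_post <- if (keep_posterior) matrix(NA_real_, n, K1) else NULL
  for (i in seq_len(n)) {
    ll <- stage_ll[[subtype[i]]][i, ]
    sp <- exp(ll - logsumexp(ll))
    sp <- sp / sum(sp)
    k <- which.max(sp)
    stage[i] <- k - 1L
    stage_tied[i] <- sum(sp >= sp[k] - 1e-12) > 1L
    if (keep_posterior) stage_post[i, ] <- sp
  }
  out <- data.frame(
    subject = rownames(Z) %||% as.character(seq_len(n)),
    subtype = subtype,
    stage = stage,
    subtype_posterior = post[cbind(seq_len(n), subtype)],
    subtype_tied = subtype_tied,
    stage_tied = stage_tied,
    stringsAsFactors = FALSE
  )
  if (keep_posterior) {
    colnames(stage_post) <- as.character(0:(K1 - 1L))
    attr(out, "stage_posterior") <- stage_post
  }
  class(out) <- c("sustain_assignment", "data.frame")
  out
}

#' Fit a subtype-and-stage progression model to atrophy z-scores
#'
#' The main fitting interface. Fits z-score event-based mixture models with
#' 1..`max_subtypes` subtypes ([fit_subtypes()]), selects the number of
#' subtypes by BIC ([select_model()]), and assigns every patient a
#' maximum-likelihood subtype and stage ([assign_subjects()]).
#'
#' @inheritParams fit_subtypes
#' @param n_params optional BIC parameter-count convention, see
#'   [select_model()].
#' @return an object of class `"sustain"` with components `models` (all
#'   candidate fits), `bic` (model-selection table), `n_subtypes`
#'   (selected), `model` (the selected `sustain_model`), and `assignments`.
#'   Methods: `print`, `summary`, `coef`, `logLik`, `predict`, `plot`,
#'   `simulate`, `residuals`.
#' @examples
#' coh <- simulate_cohort(n_controls = 40, n_patients = 30, n_subtypes = 1,
#'                        z_thresholds = c(1, 2), seed = 7)
#' fit <- sustain(coh$zscores_patients, max_subtypes = 1,
#'                z_thresholds = c(1, 2), n_restarts = 3, seed = 7)
#' fit
#' @export
sustain <- function(Z, max_subtypes = 2, z_thresholds = c(1, 2, 3), sigma = 1,
                    z_max = 5, n_restarts = 25, em_iters = 100, seed = 1,
                    tol = 1e-6, n_params = NULL) {
  cl <- match.call()
  models <- fit_subtypes(Z, max_subtypes, z_thresholds, sigma, z_max,
                         n_restarts, em_iters, seed, tol)
  sel <- select_model(models, nrow(Z), n_params)
  model <- models[[as.integer(sel)]]
  out <- list(
    models = models,
    bic = attr(sel, "bic"),
    n_subtypes = as.integer(sel),
    model = model,
    assignments = assign_subjects(as.matrix(Z), model),
    Z = as.matrix(Z),
    n_patients = nrow(Z),
    seed = seed,
    call = cl
  )
  class(out) <- "sustain"
  out
}
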