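# Greedy sequence search: hill climbing over single-event relocation moves
# from random valid restarts, maximising the weighted stage-marginalised
# log-likelihood. Deterministic given the RNG state.

# Evaluate a candidate ordering: weighted total marginal log-likelihood.
weighted_seq_loglik <- function(ord, Z, w, events, sigma, z_max) {
  sum(w * marginal_loglik(Z, ord, events, sigma, z_max))
}

# One hill climb from a starting ordering. Each pass visits every event in
# random order and relocates it to its best valid position; stops when a
# full pass makes no improving move.
climb_sequence <- function(ord, Z, w, events, sigma, z_max, tol = 1e-9) {
  K <- length(ord)
  cur <- weighted_seq_loglik(ord, Z, w, events, sigma, z_max)
  repeat {
    improved <- FALSE
    for (e in sample.int(K)) {
      p <- which(ord == e)
      base <- ord[-p]
      b <- events$biomarker[e]
      best_ll <- cur
      best_ord <- NULL
      for (q in seq_len(K)) {
        if (q == p) next
        cand <- append(base, e, after = q - 1L)
        if (!valid_for_biomarker(cand, events, b)) next
        ll <- weighted_seq_loglik(cand, Z, w, events, sigma, z_max)
        if (ll > best_ll + tol) {
          best_ll <- ll
          best_ord <- cand
        }
      }
      if (!is.null(best_ord)) {
        ord <- best_ord
        cur <- best_ll
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(ord = ord, loglik = cur)
}

#' Optimise a single event sequence by greedy hill climbing
#'
#' Maximises the (optionally weighted) stage-marginalised log-likelihood of
#' a z-score matrix over valid event orderings, using single-event
#' relocation moves from `n_restarts` random valid starting sequences.
#'
#' @param Z numeric matrix of atrophy z-scores (subjects x biomarkers, with
#'   column names).
#' @param weights per-subject non-negative weights (default all 1).
#' @param z_thresholds strictly increasing z event thresholds.
#' @param sigma,z_max per-biomarker likelihood SD and asymptotic z.
#' @param n_restarts number of random restarts (default 25).
#' @param seed integer seed making the search deterministic.
#' @param init optional starting ordering (integer event ids or an
#'   `event_sequence`); used as one additional restart.
#' @return list with `sequence` (an `event_sequence`), `ordering` (integer
#'   event ids), `loglik`, and a logical `degenerate` flag set when two or
#'   more distinct restart optima tie to within `1e-9`.
#' @export
optimize_sequence <- function(Z, weights = NULL, z_thresholds = c(1, 2, 3),
                              sigma = 1, z_max = 5, n_restarts = 25,
                              seed = 1, init = NULL) {
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("bm", seq_len(ncol(Z)))
  events <- make_events(colnames(Z), z_thresholds)
  w <- weights %||% rep(1, nrow(Z))
  if (length(w) != nrow(Z) || any(w < 0)) stop_arg("weights must be non-negative, one per subject")
  if (sum(w) <= 0) stop_arg("all weights are zero")
  set.seed(seed)
  res <- optimize_sequence_core(Z, w, events, sigma, z_max, n_restarts, init)
  res$sequence <- as_event_sequence(res$ord, events)
  res[c("sequence", "ordering", "loglik", "degenerate")]
}

# Core search (no seeding; relies on the caller's RNG state).
optimize_sequence_core <- function(Z, w, events, sigma, z_max, n_restarts,
                                   init = NULL) {
  best <- NULL
  optima <- list()
  starts <- if (is.null(init)) list() else
    list(if (is.numeric(init) && is.null(dim(init))) as.integer(init)
         else sequence_ordering(init, events))
  for (r in seq_len(max(1L, n_restarts))) {
    starts[[length(starts) + 1L]] <- random_valid_sequence(events)
  }
  for (s in starts) {
    if (!is_valid_sequence(s, events)) stop_arg("invalid starting sequence")
    fit <- climb_sequence(s, Z, w, events, sigma, z_max)
    optima[[length(optima) + 1L]] <- fit
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  lls <- vapply(optima, `[[`, numeric(1), "loglik")
  tied <- which(lls >= best$loglik - 1e-9)
  distinct <- unique(lapply(optima[tied], `[[`, "ord"))
  list(ord = best$ord, ordering = best$ord, loglik = best$loglik,
       degenerate = length(distinct) > 1L)
}
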