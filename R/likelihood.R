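# Stage-marginalised Gaussian likelihood of the z-score event model.
#
# Conditional on a sequence and an integer stage k, each biomarker's z is
# Normal(expected_z_at_stage(k), sigma_i). The subject-level likelihood
# marginalises the stage over a uniform prior on 0..N_events. Everything is
# computed in log space so that extreme z-scores do not underflow.

# Per-stage log-likelihood matrix for all subjects: n x (N_events + 1).
# Z: n x B z-score matrix; E: B x (N_events + 1) expected-z matrix.
stage_loglik <- function(Z, E, sigma) {
  n <- nrow(Z)
  B <- ncol(Z)
  sigma <- rep_len(sigma, B)
  if (any(sigma <= 0)) stop_arg("sigma must be positive")
  inv2 <- 1 / sigma^2
  const <- -0.5 * B * log(2 * pi) - sum(log(sigma))
  zz <- drop((Z^2) %*% inv2)                 # n
  cross <- (Z * rep(inv2, each = n)) %*% E   # n x K1
  ee <- colSums(E^2 * inv2)                  # K1
  const - 0.5 * (matrix(zz, n, ncol(E)) - 2 * cross +
                   matrix(ee, n, ncol(E), byrow = TRUE))
}

# Stage-marginalised log-likelihood per subject under one sequence.
marginal_loglik <- function(Z, ord, events, sigma, z_max) {
  E <- expected_z_matrix(ord, events, z_max)
  LL <- stage_loglik(Z, E, sigma)
  row_logsumexp(LL) - log(ncol(LL))
}

#' Stage-marginalised log-likelihood of one subject
#'
#' Computes the z-score event model likelihood of a single subject's
#' biomarker z-vector under a given event sequence, marginalising the
#' latent stage over a uniform prior on `0..N_events`, together with the
#' posterior distribution over stages.
#'
#' @param z_row numeric vector of atrophy z-scores, one per biomarker, in
#'   the order of the sequence's biomarker panel.
#' @param sequence an `event_sequence` data frame.
#' @param sigma per-biomarker likelihood SD in z units (recycled; default 1).
#' @param z_max per-biomarker asymptotic z (recycled; default 5).
#' @return list with `loglik` (scalar) and `stage_posterior` (numeric vector
#'   over stages 0..N_events summing to 1).
#' @export
subject_log_likelihood <- function(z_row, sequence, sigma = 1, z_max = 5) {
  events <- attr(sequence, "events")
  if (is.null(events)) events <- make_events(unique(sequence$biomarker), sort(unique(sequence$z)))
  ord <- sequence_ordering(sequence, events)
  if (length(z_row) != events$n_biomarkers)
    stop_arg("z_row must have one value per biomarker (", events$n_biomarkers, ")")
  if (!all(is.finite(z_row))) stop_arg("z_row must be finite")
  E <- expected_z_matrix(ord, events, z_max)
  LL <- stage_loglik(matrix(z_row, 1), E, sigma)[1, ]
  lse <- logsumexp(LL)
  post <- exp(LL - lse)
  names(post) <- colnames(E)
  list(loglik = lse - log(length(LL)), stage_posterior = post / sum(post))
}
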