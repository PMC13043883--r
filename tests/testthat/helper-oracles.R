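# Independent oracles and small fixture builders used across test files.

# Piecewise-linear expected z computed directly from an event table,
# independent of the package's internal trajectory code.
oracle_expected_z <- function(ord, biomarker_of, z_of, b, stage, z_max = 5) {
  K <- length(ord)
  ids <- which(biomarker_of == b)
  pos <- match(ids, ord)
  o <- order(pos)
  x <- c(0, pos[o])
  y <- c(0, z_of[ids][o])
  if (max(x) < K) {
    x <- c(x, K)
    y <- c(y, z_max)
  }
  approx(x, y, xout = stage)$y
}

# Brute-force stage-marginalised likelihood in linear space.
oracle_marginal_loglik <- function(z, ord, biomarker_of, z_of, sigma = 1, z_max = 5) {
  K <- length(ord)
  B <- length(z)
  tot <- 0
  for (k in 0:K) {
    ez <- vapply(seq_len(B), function(b)
      oracle_expected_z(ord, biomarker_of, z_of, b, k, z_max), numeric(1))
    tot <- tot + prod(dnorm(z, ez, rep_len(sigma, B)))
  }
  log(tot / (K + 1))
}

# All valid sequences (within-biomarker threshold order respected) of a
# small event set, by filtering full enumeration.
oracle_valid_sequences <- function(biomarker_of, z_of) {
  E <- length(biomarker_of)
  perms <- sustainz:::all_permutations(E)
  keep <- vapply(perms, function(p) {
    for (b in unique(biomarker_of)) {
      if (is.unsorted(match(which(biomarker_of == b), p), strictly = TRUE)) return(FALSE)
    }
    TRUE
  }, logical(1))
  perms[keep]
}

# Small shared 2-subtype cohort reused by several tests (built once).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      reg <- default_registry()
      reg <- reg[reg$biomarker %in% unique(reg$biomarker)[1:5], ]
      cache <<- simulate_cohort(n_controls = 60, n_patients = 120,
                                n_subtypes = 2, registry = reg,
                                z_thresholds = c(1, 2), noise_sd = 0.2,
                                seed = 42)
    }
    cache
  }
})

# Best subtype-label pairing accuracy against ground truth (2 subtypes).
pairing_accuracy <- function(assigned, truth) {
  tab <- table(factor(assigned, levels = 1:2), factor(truth, levels = 1:2))
  max(sum(diag(tab)), tab[1, 2] + tab[2, 1]) / sum(tab)
}
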