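# Internal numerical and plumbing helpers.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp of a matrix, vectorised via max.col
row_logsumexp <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  mx + log(rowSums(exp(M - mx)))
}

# Deterministic sub-stream seeds derived from a root seed; kept < 2^31 - 1.
substream <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + offset * 1299721) %% 2147483629)
}

stop_arg <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of a serialised R object (used for config hashes in output headers)
object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

# all permutations of 1..n as a list (exhaustive permutation mode; n <= 8)
all_permutations <- function(n) {
  if (n > 8L) stop_arg("exhaustive permutation enumeration limited to n <= 8")
  rec <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  rec(seq_len(n))
}
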