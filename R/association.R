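# Permutation-based partial Spearman association of inferred disease stage
# with regional volumes and connectome edges, with BH-FDR across the scan
# family and max-statistic FWER control under dependence.

#' OLS residuals of a vector against a covariate design
#'
#' @param y numeric response vector.
#' @param covariates data frame or matrix of covariates (an intercept is
#'   added automatically); `NULL` means intercept only, i.e. centring.
#' @return residual vector, orthogonal to the design columns.
#' @export
residualize <- function(y, covariates = NULL) {
  X <- build_design(covariates, length(y))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop_arg("rank-deficient covariate design")
  drop(qr.resid(qx, as.numeric(y)))
}

build_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  if (is.matrix(covariates)) {
    X <- cbind(`(Intercept)` = 1, covariates)
  } else {
    covariates <- as.data.frame(covariates)
    # constant columns carry no information beyond the intercept (e.g. a
    # single-scanner subtype); drop them rather than fail on contrasts
    keep <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) > 1, logical(1))
    covariates <- covariates[, keep, drop = FALSE]
    X <- if (ncol(covariates) == 0) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
         else stats::model.matrix(~ ., data = covariates)
  }
  if (nrow(X) != n) stop_arg("covariates are not row-aligned with the data")
  X
}

#' Partial Spearman rank correlation
#'
#' Rank correlation, with average ranks for ties, between the OLS residuals
#' of `x` and `y` on the covariate design.
#'
#' @param x,y aligned numeric vectors (`n >= 4`).
#' @param covariates covariate data frame/matrix or `NULL`.
#' @return the partial Spearman rho; `NA` (with a warning) when either
#'   residual vector is constant so the correlation is undefined.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (length(x) != length(y)) stop_arg("x and y must be aligned")
  if (length(x) < 4) stop_arg("need at least 4 observations")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  eps <- function(v, r) stats::sd(r) <= 1e-10 * max(1, max(abs(v)))
  if (eps(x, rx) || eps(y, ry)) {
    warning("constant residual vector: partial Spearman correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(rank(rx), rank(ry))
}

#' Enumerate unique region pairs (connectome edges)
#'
#' All unordered pairs `i < j` in row-major order; 96 regions yield 4560
#' unique connections.
#'
#' @param n_regions number of regions (>= 2).
#' @return data frame with integer columns `i`, `j`.
#' @export
edge_enumeration <- function(n_regions) {
  if (n_regions < 2) stop_arg("need at least 2 regions")
  p <- utils::combn(as.integer(n_regions), 2L)
  data.frame(i = p[1, ], j = p[2, ])
}

#' Flatten a connectivity stack to a subjects x edges matrix
#'
#' @param stack `R x R x n` connectivity array with region dimnames.
#' @return matrix `n x R(R-1)/2`; edge columns named `"regionA--regionB"`.
#' @export
edge_matrix <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3 || d[1] != d[2]) stop_arg("stack must be R x R x subjects")
  pairs <- edge_enumeration(d[1])
  regions <- dimnames(stack)[[1]] %||% as.character(seq_len(d[1]))
  flat <- matrix(unclass(stack), d[1] * d[2], d[3])
  out <- t(flat[(pairs$j - 1L) * d[1] + pairs$i, , drop = FALSE])
  colnames(out) <- paste(regions[pairs$i], regions[pairs$j], sep = "--")
  rownames(out) <- dimnames(stack)[[3]]
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values over the full scan family (wraps
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values in (0, 1].
#' @export
bh_fdr <- function(p) {
  if (!length(p)) stop_arg("empty p-value vector")
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop_arg("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Permutation scan of stage against many test units
#'
#' For each unit (region volume or connectome edge), computes the partial
#' Spearman correlation between inferred stage and the unit after
#' residualising both on the covariates, then assesses significance by
#' permuting the stage residual vector. One shared permutation stream is
#' used across all units, which is what allows the max-statistic method to
#' control the family-wise error rate under the units' dependence: each
#' observed |rho| is also compared against the permutation distribution of
#' the maximum |rho| across the whole family.
#'
#' @param stage per-patient stage values (within one subtype).
#' @param targets matrix (patients x units) of test units, or a vector for
#'   a single unit.
#' @param covariates covariate data frame/matrix or `NULL`.
#' @param B number of random permutations (>= 100; default 20000).
#' @param seed integer seed; the scan is deterministic given it.
#' @param exhaustive enumerate all `n!` permutations instead of sampling
#'   (requires `n <= 8`); p-values are then exact proportions over the full
#'   permutation group.
#' @param p_mode `"add_one"` (default) computes `p = (1 + #exceed) / (B+1)`
#'   so p-values are valid and never exactly zero; `"proportion"` uses the
#'   raw proportion `#exceed / B`.
#' @return data frame of class `assoc_scan` with columns `unit`, `rho`,
#'   `p_perm` (two-sided on |rho|), `q_fdr` (BH over all units), `p_fwer`
#'   (max-statistic), plus attributes `B`, `n`, `covariates`, `seed`.
#' @export
permutation_scan <- function(stage, targets, covariates = NULL, B = 20000,
                             seed = 1, exhaustive = FALSE,
                             p_mode = c("add_one", "proportion")) {
  p_mode <- match.arg(p_mode)
  targets <- as.matrix(targets)
  n <- length(stage)
  if (nrow(targets) != n) stop_arg("stage and targets are not row-aligned")
  X <- build_design(covariates, n)
  if (n < ncol(X) + 2) stop_arg("fewer patients than covariate columns + 2")
  if (!exhaustive && B < 100) stop_arg("B must be >= 100")
  units <- colnames(targets) %||% paste0("unit", seq_len(ncol(targets)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop_arg("rank-deficient covariate design")
  rs <- drop(qr.resid(qx, as.numeric(stage)))
  rt <- qr.resid(qx, targets)
  if (stats::sd(rs) <= 1e-10 * max(1, max(abs(stage))))
    stop_arg("stage residuals are constant; correlation undefined")
  std_rank <- function(v, scale_ref) {
    if (stats::sd(v) <= 1e-10 * max(1, scale_ref)) return(rep(NA_real_, length(v)))
    r <- rank(v, ties.method = "average")
    r <- r - mean(r)
    r / sqrt(sum(r^2))
  }
  s <- std_rank(rs, max(abs(stage)))
  Tm <- vapply(seq_len(ncol(rt)), function(j)
    std_rank(rt[, j], max(abs(targets[, j]))), numeric(n))
  Tm <- matrix(Tm, nrow = n)
  const_unit <- colSums(is.na(Tm)) > 0
  if (any(const_unit)) {
    warning("constant residuals in unit(s): ",
            paste(units[const_unit], collapse = ", "), call. = FALSE)
    Tm[, const_unit] <- 0
  }
  rho <- drop(crossprod(s, Tm))
  # permutations of the stage residual vector, shared across all units
  if (exhaustive) {
    perms <- all_permutations(n)
    Bp <- length(perms)
    P <- vapply(perms, function(p) s[p], numeric(n))
  } else {
    set.seed(seed)
    Bp <- as.integer(B)
    P <- vapply(seq_len(Bp), function(b) s[sample.int(n)], numeric(n))
  }
  exceed <- integer(length(rho))
  exceed_max <- integer(length(rho))
  athr <- abs(rho)
  chunk <- 1000L
  for (b0 in seq(1L, Bp, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1L, Bp)
    R <- abs(crossprod(P[, bi, drop = FALSE], Tm))   # |rho| for chunk x units
    mx <- apply(R, 1, max)
    exceed <- exceed + colSums(R >= rep(athr, each = length(bi)) - 1e-12)
    exceed_max <- exceed_max + vapply(athr, function(a) sum(mx >= a - 1e-12), numeric(1))
  }
  if (exhaustive || p_mode == "proportion") {
    p <- exceed / Bp
    p_fwer <- exceed_max / Bp
    p <- pmax(p, 1 / Bp)          # identity permutation guarantees >= 1/B
    p_fwer <- pmax(p_fwer, 1 / Bp)
  } else {
    p <- (1 + exceed) / (Bp + 1)
    p_fwer <- (1 + exceed_max) / (Bp + 1)
  }
  rho[const_unit] <- NA_real_
  p[const_unit] <- NA_real_
  p_fwer[const_unit] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_fdr(p[!is.na(p)])
  out <- data.frame(unit = units, rho = rho, p_perm = p, q_fdr = q,
                    p_fwer = p_fwer, stringsAsFactors = FALSE)
  attr(out, "B") <- Bp
  attr(out, "n") <- n
  attr(out, "covariates") <- setdiff(colnames(X), "(Intercept)")
  attr(out, "seed") <- if (exhaustive) NA_integer_ else as.integer(seed)
  attr(out, "exhaustive") <- exhaustive
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' @export
print.assoc_scan <- function(x, n_top = 10, ...) {
  cat("Permutation association scan:", nrow(x), "units,",
      attr(x, "B"), "permutations, n =", attr(x, "n"), "\n")
  cv <- attr(x, "covariates")
  if (length(cv)) cat("covariates:", paste(cv, collapse = ", "), "\n")
  ord <- order(-abs(x$rho), na.last = TRUE)
  print.data.frame(utils::head(as.data.frame(x)[ord, ], n_top),
                   row.names = FALSE, digits = 4)
  invisible(x)
}
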