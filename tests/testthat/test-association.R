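test_that("residualization matches closed-form least squares", {
  y <- c(2, 4, 5, 4, 7)
  expect_equal(residualize(y, NULL), y - mean(y))
  x <- c(1, 2, 3, 4, 5)
  cov <- data.frame(x = x)
  # normal-equation oracle computed by hand
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(residualize(y, cov), drop(y - X %*% beta), tolerance = 1e-12)
  expect_lt(max(abs(crossprod(X, residualize(y, cov)))), 1e-8)
  # exact linear dependence leaves nothing
  expect_equal(residualize(3 + 2 * x, cov), rep(0, 5), tolerance = 1e-10)
  expect_error(residualize(y, data.frame(a = x, b = 2 * x)), "rank")
})

test_that("partial Spearman reproduces rank-based oracles", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(partial_spearman(x, x), 1)
  expect_equal(partial_spearman(x, -x), -1)
  # 8-point example with a tie, against a hand-rolled rank formula
  y <- c(2.5, 1.0, 4.0, 4.0, 3.0, 7.0, 6.0, 9.0)
  rk <- function(v) rank(v, ties.method = "average")
  oracle <- cov(rk(x - mean(x)), rk(y - mean(y))) /
    (sd(rk(x - mean(x))) * sd(rk(y - mean(y))))
  expect_equal(partial_spearman(x, y), oracle, tolerance = 1e-12)
  expect_warning(r <- partial_spearman(x, rep(1, 8)), "constant")
  expect_true(is.na(r))
  expect_error(partial_spearman(1:3, 1:3), "at least 4")
})

test_that("noise covariates barely perturb the partial correlation", {
  set.seed(60)
  deltas <- replicate(20, {
    x <- rnorm(100)
    y <- 0.5 * x + rnorm(100)
    r0 <- partial_spearman(x, y)
    r1 <- partial_spearman(x, y, data.frame(junk = rnorm(100)))
    abs(r1 - r0)
  })
  expect_lt(mean(deltas), 0.05)
})

test_that("BH adjustment follows the step-up closed form", {
  expect_equal(bh_fdr(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p - 1e-15) && all(q <= 1))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("edge enumeration counts unordered pairs", {
  expect_equal(nrow(edge_enumeration(2)), 1)
  expect_equal(nrow(edge_enumeration(10)), 45)
  e <- edge_enumeration(5)
  expect_true(all(e$i < e$j))
  expect_equal(e$i[1:4], rep(1L, 4))  # row-major order
  expect_error(edge_enumeration(1), "at least 2")
})

test_that("edge matrix flattening picks the upper triangle consistently", {
  subjects <- generate_demographics(3, 3, seed = 5)
  tr <- generate_truth(3, 1, paste0("r", 1:4), c(1, 2), fractions = 1, seed = 5)
  stack <- generate_connectivity(subjects, tr, n_regions = 5, seed = 5)
  em <- edge_matrix(stack)
  expect_equal(dim(em), c(6, 10))
  expect_equal(unname(em[2, "roi_01--roi_03"]), stack[1, 3, 2])
  expect_equal(unname(em[4, "roi_02--roi_05"]), stack[5, 2, 4])
})

test_that("a single-unit scan has FWER p equal to its per-unit p", {
  set.seed(14)
  stage <- sample(0:20, 30, replace = TRUE)
  y <- rnorm(30)
  scan <- permutation_scan(stage, y, B = 500, seed = 3)
  expect_equal(scan$p_fwer, scan$p_perm)
})

test_that("shared permutations make the scan consistent with single-unit runs", {
  set.seed(15)
  stage <- sample(0:20, 25, replace = TRUE)
  targets <- matrix(rnorm(25 * 5), 25, 5,
                    dimnames = list(NULL, paste0("u", 1:5)))
  cov <- data.frame(age = rnorm(25))
  scan <- permutation_scan(stage, targets, cov, B = 400, seed = 9)
  for (u in 1:5) {
    single <- permutation_scan(stage, targets[, u, drop = FALSE], cov,
                               B = 400, seed = 9)
    expect_equal(single$p_perm, scan$p_perm[u])
    expect_equal(single$rho, scan$rho[u])
  }
  expect_true(all(scan$p_fwer >= scan$p_perm - 1e-12))
})

test_that("exhaustive mode reproduces full permutation enumeration", {
  set.seed(16)
  stage <- c(3, 8, 1, 12, 6, 10)
  targets <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  scan <- permutation_scan(stage, targets, exhaustive = TRUE)
  expect_equal(attr(scan, "B"), 720)
  # direct enumeration oracle
  rs <- stage - mean(stage)
  perms <- sustainz:::all_permutations(6)
  for (u in 1:2) {
    rt <- targets[, u] - mean(targets[, u])
    obs <- abs(cor(rank(rs), rank(rt)))
    null <- vapply(perms, function(p) abs(cor(rank(rs[p]), rank(rt))), numeric(1))
    expect_equal(scan$p_perm[u], mean(null >= obs - 1e-12), tolerance = 1e-12)
  }
})

test_that("scan rejects ill-posed inputs", {
  stage <- sample(0:10, 12, replace = TRUE)
  y <- matrix(rnorm(24), 12, 2)
  expect_error(permutation_scan(stage, y, B = 50, seed = 1), "B must be")
  big_cov <- as.data.frame(matrix(rnorm(12 * 10), 12))
  expect_error(permutation_scan(stage, y, big_cov, B = 200), "covariate columns")
  expect_error(permutation_scan(rep(1, 12), y, B = 200), "constant")
})
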