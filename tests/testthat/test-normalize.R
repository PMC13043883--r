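test_that("TIV is the sum of tissue compartments", {
  expect_equal(compute_tiv(600000, 500000, 300000), 1400000)
  expect_equal(compute_tiv(0, 0, 0), 0)
  expect_equal(compute_tiv(300000, 500000, 600000), compute_tiv(600000, 500000, 300000))
  expect_error(compute_tiv(-1, 0, 0), "non-negative")
})

test_that("bilateral averaging replaces pairs by their mean", {
  v <- cbind(a_L = c(10, 20), a_R = c(14, 22), ctx = c(5, 6))
  pairing <- data.frame(left = "a_L", right = "a_R", name = "a")
  out <- average_bilateral(v, pairing)
  expect_equal(colnames(out), c("a", "ctx"))
  expect_equal(out[, "a"], c(12, 21))
  expect_equal(out[, "ctx"], v[, "ctx"])
  expect_equal(ncol(out), ncol(v) - nrow(pairing))
  # identical hemispheres pass through unchanged
  v2 <- cbind(a_L = c(3, 4), a_R = c(3, 4))
  expect_equal(unname(average_bilateral(v2, pairing)[, 1]), c(3, 4))
  expect_error(average_bilateral(v[, -1], pairing), "missing")
})

test_that("control model recovers known coefficients", {
  set.seed(12)
  subjects <- generate_demographics(60, 10, seed = 12)
  X <- sustainz:::control_design(subjects)
  betas <- rbind(r1 = c(5e4, -100, -500, 0.05), r2 = c(2e4, -30, -200, 0.02))
  Y <- X %*% t(betas)
  # zero-noise volumes: coefficients recovered to numerical precision
  expect_warning(cm <- fit_control_model(Y, subjects), "zero control residual SD")
  expect_equal(unname(cm$coefficients), unname(betas), tolerance = 1e-8)
  expect_error(compute_zscores(Y, subjects, cm), "zero residual SD")
  # with noise: close but not exact, and residual SD uses n - 4
  noise <- matrix(rnorm(nrow(Y) * 2, 0, c(100, 50)[col(Y)]), ncol = 2)
  cm2 <- fit_control_model(Y + noise, subjects)
  expect_equal(unname(cm2$coefficients[, 1]), unname(betas[, 1]),
               tolerance = 0.5)
  nctrl <- sum(subjects$group == "control")
  res <- (Y + noise)[subjects$group == "control", ] -
    X[subjects$group == "control", ] %*% t(cm2$coefficients)
  expect_equal(unname(cm2$resid_sd), sqrt(colSums(res^2) / (nctrl - 4)),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("z-scores are atrophy-positive and control-calibrated", {
  coh <- simulate_cohort(n_controls = 224, n_patients = 20, n_subtypes = 1,
                         seed = 77)
  z <- coh$zscores
  ctrl <- coh$subjects$group == "control"
  expect_true(all(abs(colMeans(z[ctrl, ])) < 0.05))
  expect_true(all(apply(z[ctrl, ], 2, sd) > 0.95 & apply(z[ctrl, ], 2, sd) < 1.05))
  # sign convention: observed two residual SDs below prediction scores +2
  cm <- coh$control_model
  one <- coh$volumes_bilateral[1, , drop = FALSE]
  subj <- coh$subjects[1, , drop = FALSE]
  pred <- sustainz:::control_design(subj) %*% t(cm$coefficients)
  shifted <- pred - 2 * rep(cm$resid_sd, each = 1)
  colnames(shifted) <- colnames(one)
  expect_equal(unname(compute_zscores(shifted, subj, cm)[1, ]),
               rep(2, ncol(one)), tolerance = 1e-10)
  expect_equal(unname(compute_zscores(pred, subj, cm))[1, ],
               rep(0, ncol(one)), ignore_attr = TRUE)
})

test_that("z-scores are invariant to positive rescaling of a region", {
  coh <- simulate_cohort(n_controls = 80, n_patients = 30, n_subtypes = 1,
                         seed = 5)
  v <- coh$volumes_bilateral
  v2 <- v
  v2[, 3] <- v2[, 3] * 3.7
  z1 <- compute_zscores(v, coh$subjects, fit_control_model(v, coh$subjects))
  z2 <- compute_zscores(v2, coh$subjects, fit_control_model(v2, coh$subjects))
  expect_equal(z1, z2, tolerance = 1e-8)
})

test_that("coefficients are invariant to duplicating the whole control pool", {
  coh <- simulate_cohort(n_controls = 50, n_patients = 12, n_subtypes = 1, seed = 8)
  v <- coh$volumes_bilateral
  s <- coh$subjects
  dup <- c(which(s$group == "control"), seq_len(nrow(s)))
  s2 <- s[dup, ]
  s2$subject_id <- paste0(s2$subject_id, "_", seq_along(dup))
  cm1 <- fit_control_model(v, s)
  cm2 <- fit_control_model(v[dup, ], s2)
  expect_equal(cm1$coefficients, cm2$coefficients, tolerance = 1e-9)
})

test_that("rank-deficient designs fail with the offending column named", {
  subjects <- generate_demographics(30, 5, seed = 3)
  subjects$tiv <- 1400000  # constant TIV cannot be separated from intercept
  v <- matrix(rnorm(35 * 2, 5e4, 100), 35, 2, dimnames = list(NULL, c("r1", "r2")))
  expect_error(fit_control_model(v, subjects), "tiv")
  # unseen region at scoring time
  coh <- simulate_cohort(40, 10, 1, seed = 2)
  v2 <- coh$volumes_bilateral
  colnames(v2)[1] <- "mystery_region"
  expect_error(compute_zscores(v2, coh$subjects, coh$control_model), "mystery_region")
})

test_that("round trip recovers planted patient z within the displacement noise", {
  coh <- simulate_cohort(n_controls = 200, n_patients = 150, n_subtypes = 2,
                         noise_sd = 0.25, seed = 31)
  tr <- coh$truth
  Ez <- lapply(tr$orderings, sustainz:::expected_z_matrix, events = tr$events,
               z_max = tr$z_max)
  want <- t(vapply(seq_along(tr$subtype), function(i)
    Ez[[tr$subtype[i]]][, tr$stage[i] + 1], numeric(13)))
  got <- coh$zscores_patients
  rmse <- sqrt(mean((got - want)^2))
  # error budget: displacement noise (0.25) plus control-reference
  # estimation error — the residual SD estimate has relative error
  # ~ 1/sqrt(2 n_ctrl), which multiplies the trajectory z (RMS approx 2.4
  # over uniform stages), plus the prediction error of the fitted betas
  budget <- sqrt(0.25^2 + (2.4 / sqrt(2 * 200))^2) * 1.15
  expect_lt(rmse, budget)
  expect_gt(rmse, 0.25 * 0.8)
})
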