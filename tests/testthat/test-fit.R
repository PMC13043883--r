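test_that("EM log-likelihood trace is monotone non-decreasing", {
  coh <- small_cohort()
  fit <- sustain(coh$zscores_patients, max_subtypes = 2, z_thresholds = c(1, 2),
                 n_restarts = 3, em_iters = 12, seed = 4)
  tr <- fit$models[[2]]$em_trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) >= -1e-9))
})

test_that("two well-separated planted subtypes are recovered", {
  coh <- small_cohort()
  fit <- sustain(coh$zscores_patients, max_subtypes = 2, z_thresholds = c(1, 2),
                 n_restarts = 3, em_iters = 12, seed = 4)
  expect_equal(fit$n_subtypes, 2L)
  acc <- pairing_accuracy(fit$assignments$subtype, coh$truth$subtype)
  expect_gte(acc, 0.9)
})

test_that("BIC model selection prefers one subtype on null cohorts", {
  reg <- default_registry()
  reg <- reg[reg$biomarker %in% unique(reg$biomarker)[1:5], ]
  hits <- 0
  for (sd in 1:5) {
    coh <- simulate_cohort(n_controls = 50, n_patients = 100, n_subtypes = 1,
                           registry = reg, z_thresholds = c(1, 2), seed = sd)
    fit <- sustain(coh$zscores_patients, max_subtypes = 2,
                   z_thresholds = c(1, 2), n_restarts = 3, em_iters = 10,
                   seed = sd)
    hits <- hits + (fit$n_subtypes == 1L)
  }
  expect_gte(hits, 4)
})

test_that("BIC ties resolve to the smaller number of subtypes", {
  mk <- function(C, logLik) structure(
    list(n_subtypes = C, logLik = logLik, n_events = 10), class = "sustain_model")
  n <- 100
  # logLik of the larger model exactly offsets its extra BIC penalty
  l1 <- -500
  l2 <- l1 + ((2 * 10 + 1) - (1 * 10 + 0)) * log(n) / 2
  sel <- select_model(list(mk(1, l1), mk(2, l2)), n)
  expect_equal(as.integer(sel), 1L)
  expect_equal(as.integer(select_model(list(mk(1, l1)), n)), 1L)
  expect_error(select_model(list(), n), "empty")
})

test_that("assignment is exact for noiseless patients and symmetric in labels", {
  ev <- make_events(paste0("r", 1:4), c(1, 2))
  ord1 <- sustainz:::staggered_sequence(ev, 1:4)
  ord2 <- sustainz:::staggered_sequence(ev, 4:1)
  m <- sustainz:::new_sustain_model(list(ord1, ord2), c(0.5, 0.5), ev, 0.3, 5, NA_real_)
  E1 <- sustainz:::expected_z_matrix(ord1, ev, 5)
  E2 <- sustainz:::expected_z_matrix(ord2, ev, 5)
  Z <- rbind(E1[, 8], E2[, 5], rep(0, 4))
  colnames(Z) <- ev$labels
  a <- assign_subjects(Z, m)
  expect_equal(a$subtype[1:2], c(1L, 2L))
  expect_equal(a$stage[1:2], c(7L, 4L))
  expect_equal(a$stage[3], 0L)
  expect_true(a$subtype_tied[3])  # all-zero row fits both subtypes equally
  expect_true(all(abs(rowSums(attr(a, "stage_posterior")) - 1) < 1e-9))
  # permuting subtype order permutes labels but not stages
  m_rev <- sustainz:::new_sustain_model(list(ord2, ord1), c(0.5, 0.5), ev, 0.3, 5, NA_real_)
  a_rev <- assign_subjects(Z, m_rev)
  expect_equal(a_rev$stage, a$stage)
  expect_equal(a_rev$subtype[1:2], c(2L, 1L))
})

test_that("fitting interface validates its inputs", {
  Z <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_subtypes(Z, max_subtypes = 6, z_thresholds = c(1, 2)),
               "2 patients per")
  expect_error(fit_subtypes(unname(Z), 1, c(1, 2)), "column names")
  ev <- make_events(c("a", "b"), c(1, 2))
  m <- sustainz:::new_sustain_model(list(1:4), 1, ev, 1, 5, NA_real_)
  bad <- Z
  colnames(bad) <- c("x", "y")
  expect_error(assign_subjects(bad, m), "biomarker")
})

test_that("sustain methods expose the fitted model coherently", {
  coh <- small_cohort()
  fit <- sustain(coh$zscores_patients, max_subtypes = 1, z_thresholds = c(1, 2),
                 n_restarts = 3, seed = 9)
  expect_s3_class(fit, "sustain")
  expect_output(print(fit), "selected subtypes")
  expect_output(print(summary(fit)), "Earliest events")
  expect_length(coef(fit), 1)
  expect_s3_class(coef(fit)[[1]], "event_sequence")
  expect_equal(as.numeric(logLik(fit)), fit$model$logLik)
  # predict on training data reproduces stored assignments
  pr <- predict(fit, coh$zscores_patients)
  expect_equal(pr$stage, fit$assignments$stage)
  # simulate round-trip: simulated patients carry subtype/stage attributes
  sim <- simulate(fit, nsim = 25, seed = 1)
  expect_equal(dim(sim), c(25, ncol(coh$zscores_patients)))
  expect_true(all(attr(sim, "stage") >= 0 & attr(sim, "stage") <= fit$model$n_events))
  r <- residuals(fit)
  expect_equal(dim(r), dim(coh$zscores_patients))
  pdf(NULL)  # plot method draws without error
  expect_silent(plot(fit))
  dev.off()
})
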