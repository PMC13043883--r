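test_that("generators are bitwise deterministic given the seed", {
  a <- simulate_cohort(30, 20, 2, z_thresholds = c(1, 2), n_regions = 8,
                       clinical_slopes = list(s1 = c(1, -1)), seed = 6)
  b <- simulate_cohort(30, 20, 2, z_thresholds = c(1, 2), n_regions = 8,
                       clinical_slopes = list(s1 = c(1, -1)), seed = 6)
  expect_identical(a, b)
  c <- generate_demographics(25, 10, seed = 99)
  d <- generate_demographics(25, 10, seed = 99)
  expect_identical(c, d)
})

test_that("demographics honour group sizes and degenerate variances", {
  tab <- generate_demographics(224, 85, seed = 1)
  expect_equal(nrow(tab), 309)
  expect_equal(sum(tab$group == "control"), 224)
  expect_equal(sum(tab$group == "patient"), 85)
  expect_true(!anyDuplicated(tab$subject_id))
  expect_true(all(tab$age > 0) && all(tab$tiv > 0))
  p0 <- demographic_params()
  p0$age$control["sd"] <- 0
  p0$age$patient["sd"] <- 0
  p0$tiv$male["sd"] <- 0
  p0$tiv$female["sd"] <- 0
  t0 <- generate_demographics(1, 1, params = p0, seed = 0)
  expect_equal(t0$age, c(34.5, 39.8))
  expect_true(all(t0$tiv %in% c(1500000, 1350000)))
  expect_error(generate_demographics(0, 5), ">= 1")
})

test_that("ground truth spans the full event grid", {
  tr <- generate_truth(50, 2, paste0("r", 1:13), c(1, 2, 3), seed = 3)
  expect_equal(tr$events$n_events, 39)
  expect_true(all(tr$stage >= 0 & tr$stage <= 39))
  expect_true(all(tr$subtype %in% 1:2))
  expect_equal(sum(tr$fractions), 1)
  tr1 <- generate_truth(20, 1, paste0("r", 1:4), c(1, 2), fractions = 1, seed = 1)
  expect_true(all(tr1$subtype == 1L))
  expect_error(generate_truth(10, 2, paste0("r", 1:4), c(2, 1)), "increasing")
  expect_error(generate_truth(10, 2, paste0("r", 1:4), c(1, 2), fractions = c(1)),
               "one entry per subtype")
})

test_that("contrasting subtype sequences reverse the biomarker onset order", {
  tr <- generate_truth(10, 2, paste0("r", 1:6), c(1), seed = 2)
  expect_equal(sequence_kendall(tr$orderings[[1]], tr$orderings[[2]]), -1)
})

test_that("patient volumes follow the planted trajectory displacement", {
  reg <- default_registry()
  cb <- default_control_betas(reg)
  subjects <- generate_demographics(20, 3, seed = 4)
  tr <- generate_truth(3, 1, sustainz:::registry_biomarkers(reg), c(1, 2, 3),
                       fractions = 1, seed = 4)
  tr$stage <- c(0L, 10L, 25L)
  v <- generate_volumes(subjects, tr, cb, reg, noise_sd = 0, seed = 4)
  pred <- sustainz:::control_design(subjects) %*% t(cb$betas[colnames(v), ])
  # stage 0: no events, volume equals the control-model prediction exactly
  p1 <- which(subjects$group == "patient")[1]
  expect_equal(unname(v[p1, ]), unname(pred[p1, ]))
  # later stages: displaced by expected z times the residual SD
  E <- sustainz:::expected_z_matrix(tr$orderings[[1]], tr$events, tr$z_max)
  bm <- match(reg$biomarker, sustainz:::registry_biomarkers(reg))
  for (j in 2:3) {
    pj <- which(subjects$group == "patient")[j]
    want <- pred[pj, ] - E[bm, tr$stage[j] + 1] * cb$resid_sd[colnames(v)]
    expect_equal(unname(v[pj, ]), unname(want), tolerance = 1e-10)
  }
  # a biomarker past its z=2 event sits exactly 2 residual SDs below prediction
  lead <- which(E[, 11] == 2)[1]
  cols <- which(bm == lead)
  expect_equal(unname(v[which(subjects$group == "patient")[2], cols]),
               unname(pred[which(subjects$group == "patient")[2], cols] -
                        2 * cb$resid_sd[colnames(v)[cols]]), tolerance = 1e-10)
})

test_that("null patients are statistically indistinguishable from controls", {
  coh0 <- simulate_cohort(n_controls = 120, n_patients = 100, n_subtypes = 1,
                          seed = 13)
  tr <- coh0$truth
  tr$stage[] <- 0L
  # at stage 0 a patient's z is pure N(0, noise_sd) noise; with noise at the
  # control scale the two groups' z distributions coincide
  v <- generate_volumes(coh0$subjects, tr, noise_sd = 1, seed = 14)
  vb <- average_bilateral(v, sustainz:::bilateral_pairs())
  cm <- fit_control_model(vb, coh0$subjects)
  z <- compute_zscores(vb, coh0$subjects, cm)
  ks <- ks.test(as.vector(z[coh0$subjects$group == "control", ]),
                as.vector(z[coh0$subjects$group == "patient", ]))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted edge effects realise the requested Spearman magnitude", {
  planted <- data.frame(region_i = 1, region_j = 5, rho = 0.7)
  rhos <- vapply(1:20, function(sd) {
    subjects <- generate_demographics(10, 60, seed = sd)
    tr <- generate_truth(60, 1, paste0("r", 1:4), c(1, 2), fractions = 1,
                         planted_edges = planted, seed = sd)
    stack <- generate_connectivity(subjects, tr, n_regions = 8, seed = sd)
    em <- edge_matrix(stack)
    pat <- subjects$group == "patient"
    cor(em[pat, "roi_01--roi_05"], tr$stage, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.7), 0.15)
  expect_true(all(abs(rhos - 0.7) < 0.3))
})

test_that("connectivity stacks are symmetric with zero diagonal", {
  subjects <- generate_demographics(5, 5, seed = 1)
  tr <- generate_truth(5, 1, paste0("r", 1:4), c(1, 2), fractions = 1, seed = 1)
  stack <- generate_connectivity(subjects, tr, n_regions = 6, seed = 1)
  for (s in 1:10) {
    m <- stack[, , s]
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
  }
  bad <- data.frame(region_i = 2, region_j = 2, rho = 0.5)
  expect_error(generate_connectivity(subjects, tr, 6, planted = bad), "self-edge")
  bad2 <- data.frame(region_i = 1, region_j = 99, rho = 0.5)
  expect_error(generate_connectivity(subjects, tr, 6, planted = bad2), "outside")
})

test_that("clinical scores follow per-subtype stage slopes", {
  subjects <- generate_demographics(10, 40, seed = 21)
  tr <- generate_truth(40, 2, paste0("r", 1:4), c(1, 2), seed = 21)
  # zero slope, zero noise: constant at baseline
  flat <- generate_clinical(subjects, tr, slopes = list(s = c(0, 0)),
                            baselines = c(s = 7), score_noise_sd = 0,
                            missing_rate = 0, seed = 1)
  expect_true(all(flat$s[flat$group == "patient"] == 7))
  expect_true(all(is.na(flat$s[flat$group == "control"])))
  # positive slope, zero noise: strictly increasing in stage within subtype
  up <- generate_clinical(subjects, tr, slopes = list(s = c(0.5, 2)),
                          score_noise_sd = 0, missing_rate = 0, seed = 1)
  pat <- which(subjects$group == "patient")
  for (c in 1:2) {
    sel <- pat[tr$subtype == c]
    o <- order(tr$stage[tr$subtype == c])
    expect_true(all(diff(up$s[sel][o]) >= 0))
  }
  expect_error(generate_clinical(subjects, tr, slopes = list(s = 1)),
               "every subtype")
})

test_that("planted clinical slope is recovered within its confidence interval", {
  subjects <- generate_demographics(10, 44, seed = 8)
  tr <- generate_truth(44, 1, paste0("r", 1:5), c(1, 2, 3), fractions = 1, seed = 8)
  d <- generate_clinical(subjects, tr, slopes = list(hostility = 0.735),
                         baselines = c(hostility = 2), score_noise_sd = 4,
                         missing_rate = 0, seed = 8)
  pat <- d$group == "patient"
  reg <- stage_clinical_regression(d$hostility[pat], tr$stage,
                                   d$age[pat], d$sex[pat])
  expect_lt(abs(reg$beta_stage - 0.735), 2 * reg$se)
})
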