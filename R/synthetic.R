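# Seeded synthetic cohort generator. Emulates the statistical structure the
# downstream pipeline assumes: control volumes linear in age/sex/TIV with
# Gaussian residuals, patient volumes displaced along subtype-specific
# z-score event sequences, connectivity edges with planted monotone stage
# associations, and clinical scores with per-subtype stage slopes.

#' Default biomarker registry
#'
#' Thirteen biomarkers over eighteen volume columns: four cortical lobes
#' analysed per hemisphere (8 biomarkers) and five subcortical structures
#' whose left/right volumes are averaged into bilateral biomarkers.
#'
#' @return data frame with columns `column`, `biomarker`, `hemisphere`,
#'   `mean_volume` (typical per-hemisphere volume in mm^3).
#' @export
default_registry <- function() {
  lobes <- c(frontal = 160000, temporal = 110000, parietal = 95000, occipital = 70000)
  sub <- c(limbic = 16000, insula = 13000, amygdala = 1700,
           basal_ganglia = 16000, thalamus = 7500)
  cort <- do.call(rbind, lapply(names(lobes), function(l)
    data.frame(column = paste0(l, "_", c("L", "R")),
               biomarker = paste0(l, "_", c("L", "R")),
               hemisphere = c("L", "R"), mean_volume = lobes[[l]])))
  subc <- do.call(rbind, lapply(names(sub), function(s)
    data.frame(column = paste0(s, "_", c("L", "R")),
               biomarker = s, hemisphere = c("L", "R"), mean_volume = sub[[s]])))
  rbind(cort, subc)
}

# Left/right pairing for biomarkers spanning two columns.
bilateral_pairs <- function(registry = default_registry()) {
  bi <- registry[ave(seq_len(nrow(registry)), registry$biomarker, FUN = length) == 2, ]
  data.frame(
    left  = bi$column[bi$hemisphere == "L"],
    right = bi$column[bi$hemisphere == "R"],
    name  = bi$biomarker[bi$hemisphere == "L"],
    stringsAsFactors = FALSE
  )
}

registry_biomarkers <- function(registry = default_registry()) unique(registry$biomarker)

#' Default demographic distribution parameters
#'
#' Control and patient moments mirror a mid-adulthood psychiatric imaging
#' cohort: control age 34.5 +/- 12.8 y, patient age 39.8 +/- 10.4 y, about
#' 61%/52% male, ~95% right-handed, two scanners, TIV around 1.40--1.55 l
#' for males and 1.30--1.40 l for females.
#'
#' @return nested list of distribution parameters consumed by
#'   [generate_demographics()].
#' @export
demographic_params <- function() {
  list(
    age = list(control = c(mean = 34.5, sd = 12.8),
               patient = c(mean = 39.8, sd = 10.4), min = 18),
    prob_male = c(control = 0.607, patient = 0.518),
    prob_right = c(control = 0.960, patient = 0.929),
    prob_scanner_A = c(control = 0.290, patient = 0.541),
    tiv = list(male = c(mean = 1500000, sd = 110000),
               female = c(mean = 1350000, sd = 110000))
  )
}

#' Generate a synthetic subject table
#'
#' @param n_controls,n_patients group sizes (both >= 1).
#' @param params distribution parameters, see [demographic_params()].
#' @param seed integer seed; output is byte-identical given the same seed.
#' @return data frame with columns `subject_id`, `group`, `age`, `sex`,
#'   `handedness`, `scanner`, `tiv`.
#' @export
generate_demographics <- function(n_controls, n_patients,
                                  params = demographic_params(), seed = 1) {
  if (n_controls < 1 || n_patients < 1) stop_arg("group sizes must be >= 1")
  set.seed(seed)
  n <- n_controls + n_patients
  group <- rep(c("control", "patient"), c(n_controls, n_patients))
  draw_age <- function(g, k) {
    p <- params$age[[g]]
    a <- stats::rnorm(k, p["mean"], p["sd"])
    while (any(a < params$age$min)) {
      i <- a < params$age$min
      a[i] <- stats::rnorm(sum(i), p["mean"], p["sd"])
    }
    a
  }
  age <- c(draw_age("control", n_controls), draw_age("patient", n_patients))
  pm <- params$prob_male[group]
  sex <- ifelse(stats::runif(n) < pm, "male", "female")
  hand <- ifelse(stats::runif(n) < params$prob_right[group], "right", "left")
  scanner <- ifelse(stats::runif(n) < params$prob_scanner_A[group], "A", "B")
  tivm <- vapply(sex, function(s) params$tiv[[s]]["mean"], numeric(1))
  tivs <- vapply(sex, function(s) params$tiv[[s]]["sd"], numeric(1))
  tiv <- stats::rnorm(n, tivm, tivs)
  tiv <- pmax(tiv, 900000)
  data.frame(
    subject_id = c(sprintf("C%04d", seq_len(n_controls)),
                   sprintf("P%04d", seq_len(n_patients))),
    group = group, age = age, sex = sex, handedness = hand,
    scanner = scanner, tiv = unname(tiv),
    stringsAsFactors = FALSE
  )
}

#' Generate ground-truth progression structure for synthetic patients
#'
#' Draws (or accepts) one valid event sequence per subtype, assigns each
#' patient a subtype from the mixture fractions and a stage uniformly over
#' `0..N_events` (matching the model's uniform stage prior).
#'
#' @param n_patients number of patients.
#' @param n_subtypes number of subtypes.
#' @param biomarkers character vector of biomarker names.
#' @param z_thresholds strictly increasing z thresholds (default `c(1,2,3)`).
#' @param fractions subtype mixture fractions (simplex; default uniform).
#' @param sequences `"contrasting"` (default: wave-like sequences whose
#'   biomarker onset orders are reversed between the first two subtypes,
#'   emulating anterior-first versus posterior-first progression),
#'   `"random"`, or a list of orderings/`event_sequence`s, one per subtype.
#' @param z_max asymptotic z (default 5).
#' @param planted_edges optional data frame (`region_i`, `region_j`, `rho`,
#'   optional `subtype`) recorded for [generate_connectivity()].
#' @param clinical_slopes optional named list recorded for
#'   [generate_clinical()].
#' @param seed integer seed.
#' @return object of class `cohort_truth`.
#' @export
generate_truth <- function(n_patients, n_subtypes, biomarkers,
                           z_thresholds = c(1, 2, 3),
                           fractions = rep(1 / n_subtypes, n_subtypes),
                           sequences = "contrasting", z_max = 5,
                           planted_edges = NULL, clinical_slopes = NULL,
                           seed = 1) {
  if (any(diff(z_thresholds) <= 0)) stop_arg("z_thresholds must be strictly increasing")
  if (length(fractions) != n_subtypes) stop_arg("fractions must have one entry per subtype")
  if (abs(sum(fractions) - 1) > 1e-9) stop_arg("fractions must sum to 1")
  events <- make_events(biomarkers, z_thresholds)
  set.seed(seed)
  B <- events$n_biomarkers
  if (is.character(sequences) && length(sequences) == 1L) {
    sequences <- switch(sequences,
      contrasting = {
        orders <- list(seq_len(B), rev(seq_len(B)))
        lapply(seq_len(n_subtypes), function(c)
          if (c <= 2) staggered_sequence(events, orders[[c]])
          else random_valid_sequence(events))
      },
      random = lapply(seq_len(n_subtypes), function(c) random_valid_sequence(events)),
      stop_arg("sequences must be 'contrasting', 'random', or a list"))
  } else {
    if (length(sequences) != n_subtypes) stop_arg("need one sequence per subtype")
    sequences <- lapply(sequences, sequence_ordering, events = events)
    ok <- vapply(sequences, is_valid_sequence, logical(1), events = events)
    if (!all(ok)) stop_arg("supplied sequence violates event ordering constraints")
  }
  subtype <- sample.int(n_subtypes, n_patients, replace = TRUE, prob = fractions)
  stage <- sample.int(events$n_events + 1L, n_patients, replace = TRUE) - 1L
  structure(list(
    events = events,
    biomarkers = events$labels,
    z_thresholds = as.numeric(z_thresholds),
    orderings = sequences,
    sequences = lapply(sequences, as_event_sequence, events = events),
    fractions = fractions,
    subtype = subtype,
    stage = stage,
    z_max = z_max,
    planted_edges = planted_edges,
    clinical_slopes = clinical_slopes
  ), class = "cohort_truth")
}

#' Default control-model coefficients for the synthetic generator
#'
#' Per volume column: intercept, age slope (mild age-related decline), a
#' small sex offset beyond TIV, and a TIV slope scaling volumes with head
#' size. Residual SD defaults to 4% of the structure's typical volume.
#'
#' @param registry biomarker registry, see [default_registry()].
#' @return list with `betas` (columns x 4 matrix) and `resid_sd`.
#' @export
default_control_betas <- function(registry = default_registry()) {
  mv <- registry$mean_volume
  b_age <- -0.0015 * mv
  b_sex <- -0.01 * mv      # female offset beyond TIV
  b_tiv <- 0.7 * mv / 1400000
  b0 <- mv - b_age * 35 - b_tiv * 1400000
  betas <- cbind(`(Intercept)` = b0, age = b_age, sexfemale = b_sex, tiv = b_tiv)
  rownames(betas) <- registry$column
  list(betas = betas, resid_sd = stats::setNames(0.04 * mv, registry$column))
}

#' Generate a synthetic volume matrix
#'
#' Control volumes are the linear covariate predictor plus Gaussian
#' residuals; their scatter defines the z-score unit. Patient volumes are
#' the predictor displaced downwards by `(expected z at true stage +
#' noise) * residual SD`, so more atrophy means smaller volume and a
#' patient's atrophy z-score is the trajectory value plus `noise_sd`-scale
#' noise. Control residual variation of left/right columns of a bilateral
#' biomarker shares a common component (hemispheric symmetry) plus an
#' antisymmetric part that cancels in the bilateral average.
#'
#' @param subjects subject table from [generate_demographics()].
#' @param truth `cohort_truth` for the patient rows (in order).
#' @param control_betas list with `betas` and `resid_sd`, see
#'   [default_control_betas()]; must cover every registry column.
#' @param registry biomarker registry.
#' @param noise_sd SD (z units) of patient-level displacement noise around
#'   the trajectory (default 0.25).
#' @param asym_frac SD of the left/right antisymmetric control residual
#'   component, as a fraction of the residual SD (default 0.3).
#' @param seed integer seed.
#' @return subjects x columns volume matrix (mm^3), strictly positive, with
#'   a `"hemisphere"` attribute.
#' @export
generate_volumes <- function(subjects, truth,
                             control_betas = default_control_betas(registry),
                             registry = default_registry(),
                             noise_sd = 0.25, asym_frac = 0.3, seed = 1) {
  if (!setequal(rownames(control_betas$betas), registry$column))
    stop_arg("control_betas do not cover the registry's volume columns")
  if (!identical(registry_biomarkers(registry), truth$biomarkers))
    stop_arg("registry biomarkers do not match the ground truth's biomarker list")
  set.seed(seed)
  n <- nrow(subjects)
  cols <- registry$column
  betas <- control_betas$betas[cols, , drop = FALSE]
  sds <- control_betas$resid_sd[cols]
  X <- control_design(subjects)
  pred <- X %*% t(betas)
  bm_of_col <- match(registry$biomarker, registry_biomarkers(registry))
  B <- length(truth$biomarkers)
  # shared residual per (subject, biomarker), antisymmetric part per column
  base_bm <- matrix(stats::rnorm(n * B), n, B)
  asym <- matrix(stats::rnorm(n * length(cols), 0, asym_frac), n, length(cols))
  sign_asym <- ifelse(registry$hemisphere == "L", 1, -1)
  # cortical biomarkers map to a single column: no antisymmetric part there
  single <- registry$biomarker %in% registry$biomarker[ave(seq_len(nrow(registry)),
              registry$biomarker, FUN = length) == 1]
  asym[, single] <- 0
  resid <- sweep(base_bm[, bm_of_col, drop = FALSE] +
                   sweep(asym, 2, sign_asym, "*"), 2, sds, "*")
  vol <- pred + resid
  # patients: pure trajectory displacement about the predictor (their
  # z-score noise is noise_sd, the scale the event model sees)
  pat <- which(subjects$group == "patient")
  if (length(pat) != length(truth$subtype))
    stop_arg("truth does not cover the subject table's patient rows")
  if (length(pat)) {
    vol[pat, ] <- pred[pat, ]
    Es <- lapply(truth$orderings, expected_z_matrix, events = truth$events,
                 z_max = truth$z_max)
    zb <- t(vapply(seq_along(pat), function(i)
      Es[[truth$subtype[i]]][, truth$stage[i] + 1L], numeric(B)))
    zb <- zb + matrix(stats::rnorm(length(pat) * B, 0, noise_sd), length(pat), B)
    vol[pat, ] <- vol[pat, ] - sweep(zb[, bm_of_col, drop = FALSE], 2, sds, "*")
  }
  colnames(vol) <- cols
  rownames(vol) <- subjects$subject_id
  attr(vol, "hemisphere") <- registry$hemisphere
  vol
}

#' Generate a synthetic connectivity stack
#'
#' Per-subject symmetric region x region matrices of Fisher-transformed
#' correlations. Every edge has a fixed population mean; unplanted edges
#' vary around it independently of stage. Planted edges add, for patients
#' (optionally of one subtype), a mean shift linear in the normal scores of
#' the true stage rank, scaled via the bivariate-normal rank-correlation
#' identity `r = 2 sin(pi * rho_s / 6)` so the sample Spearman correlation
#' with stage approximates the requested `rho` at the given noise.
#'
#' @param subjects subject table.
#' @param truth `cohort_truth` for the patient rows.
#' @param n_regions number of regions R (edges = R(R-1)/2).
#' @param planted data frame with columns `region_i`, `region_j`, `rho` and
#'   optional `subtype` (NA or absent = effect across all patients);
#'   defaults to `truth$planted_edges`.
#' @param edge_noise_sd subject-level edge noise SD in Fisher-z units.
#' @param baseline_mean,baseline_sd distribution of per-edge population
#'   means.
#' @param seed integer seed.
#' @return array `R x R x n_subjects` with region dimnames, symmetric with
#'   zero diagonal; class `connectivity_stack`.
#' @export
generate_connectivity <- function(subjects, truth, n_regions = 96,
                                  planted = truth$planted_edges,
                                  edge_noise_sd = 0.2, baseline_mean = 0.25,
                                  baseline_sd = 0.15, seed = 1) {
  if (n_regions < 2) stop_arg("need at least 2 regions")
  set.seed(seed)
  n <- nrow(subjects)
  regions <- sprintf("roi_%02d", seq_len(n_regions))
  pairs <- edge_enumeration(n_regions)
  U <- nrow(pairs)
  mu <- stats::rnorm(U, baseline_mean, baseline_sd)
  E <- matrix(stats::rnorm(n * U, 0, edge_noise_sd), n, U)
  E <- sweep(E, 2, mu, "+")
  pat <- which(subjects$group == "patient")
  if (!is.null(planted) && nrow(planted) > 0) {
    if (any(planted$region_i == planted$region_j)) stop_arg("planted self-edge")
    if (any(planted$region_i < 1 | planted$region_j < 1 |
            planted$region_i > n_regions | planted$region_j > n_regions))
      stop_arg("planted edge references a region outside 1..n_regions")
    key <- paste(pmin(planted$region_i, planted$region_j),
                 pmax(planted$region_i, planted$region_j))
    idx <- match(key, paste(pairs$i, pairs$j))
    for (k in seq_len(nrow(planted))) {
      st <- if ("subtype" %in% names(planted) && !is.na(planted$subtype[k]))
        planted$subtype[k] else NA
      sel <- if (is.na(st)) seq_along(pat) else which(truth$subtype == st)
      if (length(sel) < 3) next
      stg <- truth$stage[sel]
      u <- stats::qnorm((rank(stg, ties.method = "average") - 0.5) / length(stg))
      u <- u / stats::sd(u)
      r <- 2 * sin(pi * planted$rho[k] / 6)
      beta <- edge_noise_sd * r / sqrt(1 - r^2)
      E[pat[sel], idx[k]] <- E[pat[sel], idx[k]] + beta * u
    }
  }
  stack <- array(0, dim = c(n_regions, n_regions, n),
                 dimnames = list(regions, regions, subjects$subject_id))
  ii <- cbind(pairs$i, pairs$j)
  for (s in seq_len(n)) {
    m <- matrix(0, n_regions, n_regions)
    m[ii] <- E[s, ]
    m <- m + t(m)
    stack[, , s] <- m
  }
  class(stack) <- "connectivity_stack"
  stack
}

#' Generate synthetic clinical scores
#'
#' Patient scores follow `baseline + slope[subtype] * stage + noise`;
#' controls receive norm-referenced scores where a control baseline is
#' given, otherwise `NA` (symptom scales are undefined for controls).
#' Missingness is simulated by per-score Bernoulli masks on patients,
#' mimicking incomplete clinical assessment.
#'
#' @param subjects subject table.
#' @param truth `cohort_truth` for the patient rows.
#' @param slopes named list: score name -> numeric vector of per-subtype
#'   stage slopes (score units per stage); defaults to
#'   `truth$clinical_slopes`.
#' @param baselines named numeric: score value at stage 0.
#' @param control_baselines named numeric of control means; scores absent
#'   from it are `NA` for controls.
#' @param score_noise_sd residual SD in score units (recycled per score).
#' @param missing_rate Bernoulli missingness probability for patient scores.
#' @param seed integer seed.
#' @return the subject table with one appended column per score.
#' @export
generate_clinical <- function(subjects, truth, slopes = truth$clinical_slopes,
                              baselines = NULL, control_baselines = NULL,
                              score_noise_sd = 1, missing_rate = 0.05, seed = 1) {
  if (is.null(slopes) || !length(slopes)) stop_arg("no clinical slopes supplied")
  set.seed(seed)
  n_subtypes <- length(truth$fractions)
  pat <- which(subjects$group == "patient")
  ctrl <- which(subjects$group == "control")
  sdv <- rep_len(score_noise_sd, length(slopes))
  out <- subjects
  for (k in seq_along(slopes)) {
    nm <- names(slopes)[k]
    sl <- slopes[[k]]
    if (length(sl) != n_subtypes)
      stop_arg("slopes for '", nm, "' must name every subtype (need ",
               n_subtypes, " values)")
    b0 <- if (!is.null(baselines) && nm %in% names(baselines)) baselines[[nm]] else 0
    v <- rep(NA_real_, nrow(subjects))
    v[pat] <- b0 + sl[truth$subtype] * truth$stage +
      stats::rnorm(length(pat), 0, sdv[k])
    if (!is.null(control_baselines) && nm %in% names(control_baselines)) {
      v[ctrl] <- control_baselines[[nm]] + stats::rnorm(length(ctrl), 0, sdv[k])
    }
    if (missing_rate > 0) {
      drop <- pat[stats::runif(length(pat)) < missing_rate]
      v[drop] <- NA_real_
    }
    out[[nm]] <- v
  }
  out
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining demographics, ground truth, volumes,
#' optional connectivity and clinical scores, plus the control-referenced
#' z-score normalization, with named sub-streams of one root seed.
#'
#' @param n_controls,n_patients group sizes.
#' @param n_subtypes number of planted subtypes.
#' @param registry biomarker registry (default [default_registry()]).
#' @param z_thresholds z event thresholds.
#' @param sequences passed to [generate_truth()].
#' @param fractions subtype fractions.
#' @param noise_sd volume displacement noise in z units.
#' @param n_regions connectivity regions (0 skips connectivity).
#' @param planted_edges,clinical_slopes,baselines planted effects.
#' @param edge_noise_sd connectivity noise SD (Fisher-z units).
#' @param score_noise_sd,missing_rate clinical noise and missingness.
#' @param seed root seed.
#' @return list with `subjects`, `truth`, `volumes`, `volumes_bilateral`,
#'   `control_model`, `zscores`, `zscores_patients`, and (when generated)
#'   `connectivity` and clinical columns merged into `subjects`.
#' @export
simulate_cohort <- function(n_controls, n_patients, n_subtypes = 2,
                            registry = default_registry(),
                            z_thresholds = c(1, 2, 3),
                            sequences = "contrasting",
                            fractions = rep(1 / n_subtypes, n_subtypes),
                            noise_sd = 0.25, n_regions = 0,
                            planted_edges = NULL, clinical_slopes = NULL,
                            baselines = NULL, edge_noise_sd = 0.2,
                            score_noise_sd = 1, missing_rate = 0.05, seed = 1) {
  subjects <- generate_demographics(n_controls, n_patients, seed = substream(seed, 1L))
  truth <- generate_truth(n_patients, n_subtypes, registry_biomarkers(registry),
                          z_thresholds, fractions, sequences,
                          planted_edges = planted_edges,
                          clinical_slopes = clinical_slopes,
                          seed = substream(seed, 2L))
  volumes <- generate_volumes(subjects, truth, registry = registry,
                              noise_sd = noise_sd, seed = substream(seed, 3L))
  vb <- average_bilateral(volumes, bilateral_pairs(registry))
  cm <- fit_control_model(vb, subjects)
  z <- compute_zscores(vb, subjects, cm)
  out <- list(subjects = subjects, truth = truth, volumes = volumes,
              volumes_bilateral = vb, control_model = cm, zscores = z,
              zscores_patients = z[subjects$group == "patient", , drop = FALSE])
  if (n_regions >= 2) {
    out$connectivity <- generate_connectivity(subjects, truth, n_regions,
                                              planted = planted_edges,
                                              edge_noise_sd = edge_noise_sd,
                                              seed = substream(seed, 4L))
  }
  if (!is.null(clinical_slopes)) {
    out$subjects <- generate_clinical(subjects, truth, clinical_slopes,
                                      baselines = baselines,
                                      score_noise_sd = score_noise_sd,
                                      missing_rate = missing_rate,
                                      seed = substream(seed, 5L))
  }
  out
}
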