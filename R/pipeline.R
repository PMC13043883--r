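# Orchestration and I/O: one call runs simulate -> normalize -> fit ->
# assign -> associate -> clinical, writing an auditable results directory.
# All CSV outputs carry a header comment with package version and config
# hash; readers skip comment lines.

#' Default pipeline configuration
#'
#' A fully serialisable run configuration at demonstration scale. Every
#' downstream stage reads only from it; unknown keys are rejected by
#' [run_pipeline()].
#'
#' @param seed root seed; all stochastic stages draw named sub-streams of it.
#' @return nested list of class `sustainz_config`.
#' @export
default_config <- function(seed = 1) {
  cfg <- list(
    seed = seed,
    cohort = list(
      n_controls = 60, n_patients = 48, n_subtypes = 2,
      fractions = c(0.5, 0.5), sequences = "contrasting",
      noise_sd = 0.25, n_regions = 12, edge_noise_sd = 0.2,
      planted_edges = list(
        list(region_i = 1, region_j = 5, rho = -0.56, subtype = 1),
        list(region_i = 2, region_j = 7, rho = 0.70, subtype = 2)),
      clinical_slopes = list(hostility = c(0.735, 0),
                             social_withdrawal = c(0, -1.052)),
      baselines = c(hostility = 2, social_withdrawal = 3),
      score_noise_sd = 4, missing_rate = 0.04
    ),
    z_thresholds = c(1, 2),
    sustain = list(max_subtypes = 2, n_restarts = 3, em_iters = 10,
                   sigma = 1, z_max = 5),
    association = list(B = 500, alpha = 0.05, q_threshold = 0.05,
                       covariates_volumes = c("age", "sex", "handedness", "tiv"),
                       covariates_connectivity = c("age", "sex", "handedness", "scanner"))
  )
  class(cfg) <- c("sustainz_config", "list")
  cfg
}

validate_config <- function(config) {
  template <- unclass(default_config())
  check <- function(cfg, tpl, path = "") {
    extra <- setdiff(names(cfg), names(tpl))
    if (length(extra))
      stop_arg("unknown config key(s): ", paste0(path, extra, collapse = ", "))
    miss <- setdiff(names(tpl), names(cfg))
    if (length(miss))
      stop_arg("missing config key(s): ", paste0(path, miss, collapse = ", "))
    for (k in names(tpl)) {
      if (is.list(tpl[[k]]) && !is.null(names(tpl[[k]])) &&
          !k %in% c("planted_edges", "clinical_slopes")) {
        check(cfg[[k]], tpl[[k]], paste0(path, k, "$"))
      }
    }
  }
  check(unclass(config), template)
  invisible(config)
}

pkg_version <- function() as.character(utils::packageVersion("sustainz"))

write_csv_stamped <- function(x, path, hash, row_label = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sustainz %s config_hash=%s", pkg_version(), hash), con)
  if (!is.null(row_label) && is.matrix(x)) {
    x <- data.frame(id = rownames(x), x, check.names = FALSE)
    names(x)[1] <- row_label
  }
  utils::write.csv(x, con, row.names = FALSE)
}

read_csv_stamped <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' Write a connectivity stack as a long-format CSV
#'
#' One row per (subject, edge) with `i < j`; round-trips losslessly through
#' [read_inputs()].
#' @param stack connectivity array.
#' @param path output CSV path.
#' @param hash config hash for the header comment (default "none").
#' @export
write_connectivity_csv <- function(stack, path, hash = "none") {
  em <- edge_matrix(stack)
  pairs <- edge_enumeration(dim(stack)[1])
  regions <- dimnames(stack)[[1]]
  long <- data.frame(
    subject_id = rep(rownames(em), times = ncol(em)),
    region_i = rep(regions[pairs$i], each = nrow(em)),
    region_j = rep(regions[pairs$j], each = nrow(em)),
    value = as.vector(em), stringsAsFactors = FALSE)
  write_csv_stamped(long, path, hash)
}

read_connectivity_csv <- function(path, tol = 1e-8) {
  long <- read_csv_stamped(path)
  regions <- sort(unique(c(long$region_i, long$region_j)))
  subjects <- unique(long$subject_id)
  R <- length(regions)
  stack <- array(0, dim = c(R, R, length(subjects)),
                 dimnames = list(regions, regions, subjects))
  si <- match(long$subject_id, subjects)
  ri <- match(long$region_i, regions)
  rj <- match(long$region_j, regions)
  if (any(!is.finite(long$value))) stop_arg("non-numeric connectivity value in ", path)
  provided <- array(FALSE, dim = dim(stack))
  stack[cbind(ri, rj, si)] <- long$value
  provided[cbind(ri, rj, si)] <- TRUE
  # mirror only directions the file did not state, so genuine asymmetries
  # between stated (i, j) and (j, i) records survive for validation
  mirror <- provided & !aperm(provided, c(2, 1, 3))
  tstack <- aperm(stack, c(2, 1, 3))
  idx <- which(aperm(mirror, c(2, 1, 3)))
  stack[idx] <- tstack[idx]
  class(stack) <- "connectivity_stack"
  stack
}

#' Read and validate pipeline input files
#'
#' @param paths named list with entries `subjects`, `volumes`, and
#'   optionally `connectivity` (long-format CSV).
#' @param tol symmetry tolerance for connectivity matrices.
#' @return list with validated, row-aligned `subjects`, `volumes`, and
#'   `connectivity` (when supplied).
#' @export
read_inputs <- function(paths, tol = 1e-8) {
  subjects <- read_csv_stamped(paths$subjects)
  if (anyDuplicated(subjects$subject_id))
    stop_arg("duplicate subject_id: ",
             subjects$subject_id[duplicated(subjects$subject_id)][1])
  vraw <- read_csv_stamped(paths$volumes)
  if (!"subject_id" %in% names(vraw)) stop_arg("volumes CSV needs a subject_id column")
  vm <- as.matrix(vraw[setdiff(names(vraw), "subject_id")])
  if (!is.numeric(vm)) {
    bad <- names(which(!vapply(vraw[setdiff(names(vraw), "subject_id")],
                               is.numeric, logical(1))))[1]
    stop_arg("non-numeric cell(s) in volume column '", bad, "'")
  }
  rownames(vm) <- vraw$subject_id
  if (!identical(rownames(vm), subjects$subject_id))
    vm <- vm[match(subjects$subject_id, rownames(vm)), , drop = FALSE]
  if (anyNA(rownames(vm))) stop_arg("volume rows do not cover all subjects")
  out <- list(subjects = subjects, volumes = vm)
  if (!is.null(paths$connectivity)) {
    stack <- read_connectivity_csv(paths$connectivity, tol)
    for (s in seq_len(dim(stack)[3])) {
      m <- stack[, , s]
      asym <- abs(m - t(m))
      if (max(asym) > tol) {
        w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
        stop_arg("asymmetric connectivity for subject ",
                 dimnames(stack)[[3]][s], " at pair (",
                 dimnames(stack)[[1]][w[1]], ", ",
                 dimnames(stack)[[2]][w[2]], "): |a - t(a)| = ",
                 format(max(asym)))
      }
      if (any(diag(m) != 0)) stop_arg("nonzero diagonal for subject ",
                                      dimnames(stack)[[3]][s])
    }
    out$connectivity <- stack
  }
  out
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort from the configuration, normalizes volumes to
#' control-referenced z-scores, fits the subtype-and-stage model, assigns
#' patients, runs the per-subtype stage-association scans on volumes and
#' connectivity edges, computes the clinical comparisons, and writes every
#' artefact (plus a timing/seed log) to `out_dir`. Re-running with the same
#' configuration reproduces all numeric outputs.
#'
#' @param config configuration list, see [default_config()].
#' @param out_dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return (invisibly) a list with the in-memory results and the output
#'   paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir, overwrite = FALSE) {
  validate_config(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop_arg("output directory is not empty (a partial prior run?); ",
             "use overwrite = TRUE to replace it")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- object_hash(unclass(config))
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    log_lines <<- c(log_lines, msg)
  }
  timed <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    say(label, " done in ", sprintf("%.2f s", proc.time()[["elapsed"]] - t0))
    v
  }
  seed <- config$seed
  say("run seed = ", seed, ", config hash = ", hash)
  co <- config$cohort
  planted <- if (length(co$planted_edges))
    do.call(rbind, lapply(co$planted_edges, as.data.frame)) else NULL
  slopes <- lapply(co$clinical_slopes, as.numeric)
  sim <- timed("simulate", simulate_cohort(
    n_controls = co$n_controls, n_patients = co$n_patients,
    n_subtypes = co$n_subtypes, z_thresholds = config$z_thresholds,
    sequences = co$sequences, fractions = co$fractions,
    noise_sd = co$noise_sd, n_regions = co$n_regions,
    planted_edges = planted, clinical_slopes = slopes,
    baselines = unlist(co$baselines), edge_noise_sd = co$edge_noise_sd,
    score_noise_sd = co$score_noise_sd, missing_rate = co$missing_rate,
    seed = seed))
  su <- config$sustain
  fit <- timed("fit", sustain(sim$zscores_patients,
    max_subtypes = su$max_subtypes, z_thresholds = config$z_thresholds,
    sigma = su$sigma, z_max = su$z_max, n_restarts = su$n_restarts,
    em_iters = su$em_iters, seed = substream(seed, 10L)))
  say("selected ", fit$n_subtypes, " subtype(s) by BIC")
  assignments <- fit$assignments
  patients <- sim$subjects[sim$subjects$group == "patient", , drop = FALSE]
  asc <- config$association
  assoc <- list()
  for (c in sort(unique(assignments$subtype))) {
    rows <- which(assignments$subtype == c)
    covv <- patients[rows, asc$covariates_volumes, drop = FALSE]
    if (length(rows) >= ncol(covv) + 4) {
      assoc[[paste0("volumes_subtype", c)]] <- timed(
        paste0("assoc volumes subtype ", c),
        permutation_scan(assignments$stage[rows],
                         sim$volumes_bilateral[patients$subject_id[rows], , drop = FALSE],
                         covv, B = asc$B, seed = substream(seed, 20L + c)))
      if (!is.null(sim$connectivity)) {
        em <- edge_matrix(sim$connectivity)[patients$subject_id[rows], , drop = FALSE]
        covc <- patients[rows, asc$covariates_connectivity, drop = FALSE]
        assoc[[paste0("edges_subtype", c)]] <- timed(
          paste0("assoc edges subtype ", c),
          permutation_scan(assignments$stage[rows], em, covc,
                           B = asc$B, seed = substream(seed, 30L + c)))
      }
    } else say("subtype ", c, ": too few patients for association scan, skipped")
  }
  # clinical: subtype comparisons, stage-adjusted ANCOVA, stage regressions
  clinical <- NULL
  score_names <- names(slopes)
  if (length(score_names) && fit$n_subtypes >= 2) {
    clin_rows <- list()
    for (sc in score_names) {
      y <- patients[[sc]]
      cg <- tryCatch(compare_groups(y, factor(assignments$subtype), variable = sc),
                     error = function(e) NULL)
      av <- tryCatch(ancova_stage_adjusted(y, factor(assignments$subtype),
                                           assignments$stage),
                     error = function(e) NULL)
      for (c in sort(unique(assignments$subtype))) {
        rows <- which(assignments$subtype == c)
        sr <- tryCatch(stage_clinical_regression(y[rows], assignments$stage[rows],
                                                 patients$age[rows], patients$sex[rows]),
                       error = function(e) NULL)
        clin_rows[[length(clin_rows) + 1L]] <- data.frame(
          score = sc, subtype = c,
          beta_stage = if (is.null(sr)) NA_real_ else sr$beta_stage,
          p_stage = if (is.null(sr)) NA_real_ else sr$p,
          n_stage = if (is.null(sr)) NA_integer_ else sr$n,
          mw_p = if (is.null(cg)) NA_real_ else cg$p,
          ancova_stage_F = if (is.null(av)) NA_real_ else unname(av$stage["F"]),
          ancova_stage_p = if (is.null(av)) NA_real_ else unname(av$stage["p"]),
          ancova_interaction_F = if (is.null(av)) NA_real_ else unname(av$interaction["F"]),
          ancova_interaction_p = if (is.null(av)) NA_real_ else unname(av$interaction["p"]))
      }
    }
    clinical <- do.call(rbind, clin_rows)
  }
  # ---- write artefacts ----
  jw <- function(x, f) jsonlite::write_json(x, file.path(out_dir, f),
                                            auto_unbox = TRUE, digits = NA,
                                            pretty = TRUE, force = TRUE)
  jw(unclass(config), "config.json")
  jw(list(
    fractions = sim$truth$fractions,
    subtype = sim$truth$subtype,
    stage = sim$truth$stage,
    z_max = sim$truth$z_max,
    sequences = lapply(sim$truth$sequences, function(s)
      lapply(seq_len(nrow(s)), function(i) list(biomarker = s$biomarker[i], z = s$z[i])))
  ), "truth.json")
  jw(list(coefficients = as.data.frame(sim$control_model$coefficients),
          regions = rownames(sim$control_model$coefficients),
          resid_sd = sim$control_model$resid_sd,
          n_controls = sim$control_model$n_controls), "control_model.json")
  jw(list(
    n_subtypes = fit$n_subtypes,
    bic = fit$bic,
    fractions = fit$model$f,
    sigma = fit$model$sigma, z_max = fit$model$z_max,
    logLik = fit$model$logLik,
    sequences = lapply(fit$model$sequences, function(s)
      lapply(seq_len(nrow(s)), function(i) list(biomarker = s$biomarker[i], z = s$z[i])))
  ), "model.json")
  write_csv_stamped(sim$subjects, file.path(out_dir, "subjects.csv"), hash)
  write_csv_stamped(sim$volumes, file.path(out_dir, "volumes.csv"), hash, "subject_id")
  write_csv_stamped(round(sim$zscores, 10), file.path(out_dir, "zscores.csv"),
                    hash, "subject_id")
  write_csv_stamped(as.data.frame(assignments), file.path(out_dir, "assignments.csv"), hash)
  if (!is.null(sim$connectivity))
    write_connectivity_csv(sim$connectivity, file.path(out_dir, "connectivity.csv"), hash)
  # expected z per (subtype, biomarker, stage): heat-map data
  heat <- do.call(rbind, lapply(seq_len(fit$n_subtypes), function(c) {
    E <- expected_z_matrix(fit$model$orderings[[c]], fit$model$events, fit$model$z_max)
    data.frame(subtype = c, biomarker = rep(rownames(E), ncol(E)),
               stage = rep(as.integer(colnames(E)), each = nrow(E)),
               expected_z = as.vector(E))
  }))
  write_csv_stamped(heat, file.path(out_dir, "expected_z.csv"), hash)
  for (nm in names(assoc)) {
    a <- assoc[[nm]]
    a <- a[order(-abs(a$rho), a$unit), ]
    write_csv_stamped(as.data.frame(a), file.path(out_dir, paste0("assoc_", nm, ".csv")), hash)
  }
  if (!is.null(clinical))
    write_csv_stamped(clinical, file.path(out_dir, "clinical.csv"), hash)
  writeLines(log_lines, log_path)
  invisible(list(config = config, simulation = sim, fit = fit,
                 assignments = assignments, associations = assoc,
                 clinical = clinical, out_dir = out_dir, hash = hash))
}
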