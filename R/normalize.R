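# Control-referenced volume normalization: covariate adjustment in the
# control group and conversion to atrophy-positive z-scores.

#' Total intracranial volume
#'
#' TIV is the sum of grey matter, white matter and cerebrospinal fluid
#' volumes, all in cubic millimetres.
#'
#' @param gm,wm,csf tissue volumes in mm^3 (vectorised, all non-negative).
#' @return numeric vector of TIV in mm^3.
#' @export
compute_tiv <- function(gm, wm, csf) {
  if (any(c(gm, wm, csf) < 0)) stop_arg("tissue volumes must be non-negative")
  gm + wm + csf
}

#' Average left/right volume columns into bilateral biomarkers
#'
#' Paired hemispheric columns are replaced (at the left member's position)
#' by their arithmetic mean under the bilateral name; unmapped columns are
#' untouched. Used to reduce subcortical dimensionality while cortical
#' lobes stay hemisphere-specific.
#'
#' @param volumes subjects x regions volume matrix with column names.
#' @param pairing data frame with columns `left`, `right`, `name`.
#' @return volume matrix with paired columns collapsed; the `"hemisphere"`
#'   attribute (if present) is updated, collapsed columns flagged
#'   `"bilateral"`.
#' @export
average_bilateral <- function(volumes, pairing) {
  volumes <- as.matrix(volumes)
  if (is.null(pairing) || nrow(pairing) == 0) return(volumes)
  miss <- setdiff(c(pairing$left, pairing$right), colnames(volumes))
  if (length(miss))
    stop_arg("pair member(s) missing from volume matrix: ", paste(miss, collapse = ", "))
  hemi <- attr(volumes, "hemisphere")
  out <- volumes
  for (i in seq_len(nrow(pairing))) {
    li <- match(pairing$left[i], colnames(out))
    out[, li] <- (out[, li] + volumes[, pairing$right[i]]) / 2
    colnames(out)[li] <- pairing$name[i]
    if (!is.null(hemi)) hemi[li] <- "bilateral"
  }
  drop_idx <- match(pairing$right, colnames(volumes))
  out <- out[, -drop_idx, drop = FALSE]
  if (!is.null(hemi)) attr(out, "hemisphere") <- hemi[-drop_idx]
  out
}

#' Fit the per-region control covariate model
#'
#' Ordinary least squares of each region's volume on age, sex and TIV in
#' the control rows only. The residual SD uses the unbiased `n - p`
#' denominator (p = 4 coefficients). Patients are later scored against this
#' control-anchored reference.
#'
#' @param volumes subjects x regions volume matrix (rows aligned with
#'   `subjects`).
#' @param subjects subject table with columns `group` ("control"/"patient"),
#'   `age`, `sex` ("male"/"female"), `tiv`.
#' @return object of class `control_model`: coefficient matrix
#'   (regions x 4), per-region residual SD, control sample size.
#' @export
fit_control_model <- function(volumes, subjects) {
  volumes <- as.matrix(volumes)
  if (nrow(volumes) != nrow(subjects)) stop_arg("volumes and subjects are not row-aligned")
  ctrl <- subjects$group == "control"
  n <- sum(ctrl)
  if (n < 10) stop_arg("need at least 10 controls to fit the reference model")
  X <- control_design(subjects[ctrl, , drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    # name the offending column for the diagnostic
    bad <- colnames(X)[-1][vapply(colnames(X)[-1], function(cn)
      stats::var(X[, cn]) < .Machine$double.eps, logical(1))]
    if (!length(bad)) bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_arg("rank-deficient control design; offending column(s): ",
             paste(bad, collapse = ", "))
  }
  Y <- volumes[ctrl, , drop = FALSE]
  coefs <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  sd <- sqrt(colSums(res^2) / (n - ncol(X)))
  degen <- sd <= 1e-10 * pmax(1, colMeans(abs(Y)))
  if (any(degen)) {
    warning("zero control residual SD in region(s): ",
            paste(colnames(volumes)[degen], collapse = ", "),
            "; z-scores for these regions are undefined", call. = FALSE)
    sd[degen] <- NA_real_
  }
  structure(list(
    coefficients = t(coefs),           # regions x 4
    resid_sd = stats::setNames(sd, colnames(volumes)),
    n_controls = n,
    covariates = colnames(X)
  ), class = "control_model")
}

control_design <- function(subjects) {
  cbind("(Intercept)" = 1,
        age = as.numeric(subjects$age),
        sexfemale = as.numeric(subjects$sex == "female"),
        tiv = as.numeric(subjects$tiv))
}

#' @export
print.control_model <- function(x, ...) {
  cat("Control covariate model:", nrow(x$coefficients), "regions,",
      x$n_controls, "controls; covariates:",
      paste(x$covariates[-1], collapse = ", "), "\n")
  invisible(x)
}

#' Convert volumes to atrophy-positive z-scores
#'
#' For every subject (controls and patients alike) each region's z-score is
#' `(predicted - observed) / residual SD` under the control-fitted model,
#' so volume deficit relative to the control expectation is positive — the
#' orientation the monotone-increase event model requires.
#'
#' @param volumes subjects x regions volume matrix.
#' @param subjects subject table aligned with `volumes` rows.
#' @param model a `control_model` covering every volume column.
#' @param cap optional symmetric cap on |z| (default `Inf`, no capping).
#' @return subjects x regions z-score matrix.
#' @export
compute_zscores <- function(volumes, subjects, model, cap = Inf) {
  volumes <- as.matrix(volumes)
  unseen <- setdiff(colnames(volumes), rownames(model$coefficients))
  if (length(unseen))
    stop_arg("region column(s) not covered by the control model: ",
             paste(unseen, collapse = ", "))
  if (nrow(volumes) != nrow(subjects)) stop_arg("volumes and subjects are not row-aligned")
  if (anyNA(model$resid_sd[colnames(volumes)]) ||
      any(model$resid_sd[colnames(volumes)] <= 0))
    stop_arg("control model has zero residual SD for a requested region")
  X <- control_design(subjects)
  co <- model$coefficients[colnames(volumes), , drop = FALSE]
  pred <- X %*% t(co)
  z <- sweep(pred - volumes, 2, model$resid_sd[colnames(volumes)], "/")
  if (is.finite(cap)) z <- pmin(pmax(z, -cap), cap)
  rownames(z) <- rownames(volumes)
  z
}
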