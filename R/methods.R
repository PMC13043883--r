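# S3 methods for fitted sustain objects.

#' @export
print.sustain_model <- function(x, ...) {
  cat("z-score event model:", x$n_subtypes, "subtype(s),",
      x$n_events, "events over", length(x$biomarkers), "biomarkers\n")
  cat("mixture fractions:", paste(sprintf("%.3f", x$f), collapse = ", "), "\n")
  cat("log-likelihood:", format(x$logLik, digits = 8), "\n")
  invisible(x)
}

#' @export
print.sustain <- function(x, ...) {
  cat("Subtype-and-stage inference fit\n")
  cat("  patients:", x$n_patients, "  biomarkers:",
      length(x$model$biomarkers), "  events:", x$model$n_events, "\n")
  cat("  selected subtypes (BIC):", x$n_subtypes, "\n")
  tab <- x$bic
  tab$BIC <- round(tab$BIC, 2)
  tab$logLik <- round(tab$logLik, 2)
  print(tab, row.names = FALSE)
  cat("  stage range of assignments:",
      paste(range(x$assignments$stage), collapse = "-"), "\n")
  invisible(x)
}

#' @export
summary.sustain <- function(object, ...) {
  a <- object$assignments
  per <- split(a$stage, a$subtype)
  out <- list(
    n_subtypes = object$n_subtypes,
    bic = object$bic,
    fractions = object$model$f,
    stage_summary = t(vapply(per, function(s)
      c(n = length(s), mean = mean(s), median = stats::median(s),
        min = min(s), max = max(s)), numeric(5))),
    first_events = lapply(object$model$sequences, utils::head, 5)
  )
  class(out) <- "summary.sustain"
  out
}

#' @export
print.summary.sustain <- function(x, ...) {
  cat("Selected", x$n_subtypes, "subtype(s); mixture fractions:",
      paste(sprintf("%.3f", x$fractions), collapse = ", "), "\n\n")
  cat("Per-subtype assigned stages:\n")
  print(round(x$stage_summary, 2))
  cat("\nEarliest events per subtype:\n")
  for (c in seq_along(x$first_events)) {
    s <- x$first_events[[c]]
    cat("  subtype ", c, ": ",
        paste(sprintf("%s(z=%g)", s$biomarker, s$z), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.sustain <- function(object, ...) object$model$sequences

#' @export
logLik.sustain <- function(object, ...) {
  structure(object$model$logLik,
            df = object$n_subtypes * object$model$n_events + object$n_subtypes - 1,
            nobs = object$n_patients, class = "logLik")
}

#' Assign new patients to subtypes and stages
#'
#' @param object a fitted `"sustain"` object.
#' @param newdata patients x biomarkers z-score matrix; defaults to the
#'   training assignments when omitted.
#' @param ... passed to [assign_subjects()].
#' @export
predict.sustain <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$assignments)
  assign_subjects(as.matrix(newdata), object$model, ...)
}

#' Expected-z progression heat maps of a fitted model
#'
#' One panel per subtype: biomarkers (rows) by stage (columns), colour
#' encoding the model's expected atrophy z-score. Reproduces the data
#' behind stage-progression heat maps.
#'
#' @param x a `"sustain"` object.
#' @param ... ignored.
#' @export
plot.sustain <- function(x, ...) {
  m <- x$model
  C <- m$n_subtypes
  op <- graphics::par(mfrow = c(1, C), mar = c(4, 7, 2, 1))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  for (c in seq_len(C)) {
    E <- expected_z_matrix(m$orderings[[c]], m$events, m$z_max)
    graphics::image(x = 0:m$n_events, y = seq_along(m$biomarkers),
                    z = t(E)[, rev(seq_len(nrow(E))), drop = FALSE],
                    col = cols, xlab = "stage", ylab = "", yaxt = "n",
                    main = paste0("subtype ", c, " (f=", sprintf("%.2f", m$f[c]), ")"))
    graphics::axis(2, at = seq_along(m$biomarkers), labels = rev(rownames(E)),
                   las = 2, cex.axis = 0.7)
  }
  invisible(x)
}

#' Simulate patient z-scores from a fitted model
#'
#' Draws subtype from the fitted mixture fractions, stage uniformly over
#' `0..N_events`, and biomarker z-scores from the model's Gaussian
#' observation model around the expected trajectory.
#'
#' @param object a `"sustain"` object.
#' @param nsim number of patients to simulate.
#' @param seed integer seed.
#' @param ... ignored.
#' @return z-score matrix with attributes `"subtype"` and `"stage"`.
#' @export
simulate.sustain <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- object$model
  B <- length(m$biomarkers)
  subtype <- sample.int(m$n_subtypes, nsim, replace = TRUE, prob = m$f)
  stage <- sample.int(m$n_events + 1L, nsim, replace = TRUE) - 1L
  Z <- matrix(NA_real_, nsim, B, dimnames = list(NULL, m$biomarkers))
  Es <- lapply(m$orderings, expected_z_matrix, events = m$events, z_max = m$z_max)
  for (i in seq_len(nsim)) {
    Z[i, ] <- Es[[subtype[i]]][, stage[i] + 1L] + stats::rnorm(B, 0, m$sigma)
  }
  attr(Z, "subtype") <- subtype
  attr(Z, "stage") <- stage
  Z
}

#' Residual z-scores about the assigned trajectory point
#'
#' Observed z minus the model's expected z at each patient's assigned
#' (subtype, stage).
#'
#' @param object a `"sustain"` object.
#' @param newdata optional new z-score matrix; defaults to the training data.
#' @param ... ignored.
#' @export
residuals.sustain <- function(object, newdata = NULL, ...) {
  m <- object$model
  Z <- if (is.null(newdata)) object$Z else as.matrix(newdata)
  a <- if (is.null(newdata)) object$assignments else assign_subjects(Z, m)
  Es <- lapply(m$orderings, expected_z_matrix, events = m$events, z_max = m$z_max)
  fitted <- t(vapply(seq_len(nrow(Z)), function(i)
    Es[[a$subtype[i]]][, a$stage[i] + 1L], numeric(length(m$biomarkers))))
  colnames(fitted) <- m$biomarkers
  Z - fitted
}
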