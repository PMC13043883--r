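# Subtype-wise clinical comparisons and stage-adjusted models.

#' Two-group comparison of a clinical or demographic variable
#'
#' Mann-Whitney U (two-sided, normal approximation with continuity and tie
#' correction; exact for small groups) for continuous variables, Pearson
#' chi-square (no Yates correction by default) for categorical ones.
#' Missing rows are dropped per variable and the analysed n is reported.
#'
#' @param values numeric (continuous) or factor/character (categorical).
#' @param labels two-level group factor aligned with `values`.
#' @param variable name used in the result (default from the call).
#' @param exact_max use the exact Mann-Whitney distribution when both
#'   groups have at most this many observations (default 12).
#' @param correct_chisq apply Yates continuity correction (default FALSE).
#' @return object of class `group_comparison`: variable, test, per-group
#'   summaries, statistic, p, n.
#' @export
compare_groups <- function(values, labels, variable = deparse(substitute(values)),
                           exact_max = 12, correct_chisq = FALSE) {
  lev <- levels(droplevels(factor(labels)))
  if (length(lev) != 2) stop_arg("labels must have exactly two groups")
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- factor(labels[keep], levels = lev)
  n_by <- table(labels)
  if (any(n_by == 0)) stop_arg("group '", lev[n_by == 0][1], "' is empty after removing missing rows")
  if (is.numeric(values)) {
    g1 <- values[labels == lev[1]]
    g2 <- values[labels == lev[2]]
    exact <- max(length(g1), length(g2)) <= exact_max && !anyDuplicated(values)
    ht <- stats::wilcox.test(g1, g2, exact = exact, correct = TRUE)
    summaries <- rbind(
      c(n = length(g1), mean = mean(g1), sd = stats::sd(g1)),
      c(n = length(g2), mean = mean(g2), sd = stats::sd(g2)))
    rownames(summaries) <- lev
    test <- "Mann-Whitney U"
  } else {
    tab <- table(factor(values), labels)
    ht <- stats::chisq.test(tab, correct = correct_chisq)
    summaries <- tab
    test <- "Pearson chi-square"
  }
  structure(list(variable = variable, test = test, summaries = summaries,
                 statistic = unname(ht$statistic), p = ht$p.value,
                 n = sum(n_by)), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$variable, " (", x$test, "): statistic = ",
      format(x$statistic, digits = 5), ", p = ", format(x$p, digits = 4),
      ", n = ", x$n, "\n", sep = "")
  print(x$summaries)
  invisible(x)
}

#' Stage-adjusted ANCOVA of a clinical outcome across subtypes
#'
#' Linear model `outcome ~ subtype + stage + subtype:stage` with type-II
#' sums of squares, reporting the subtype main effect, the stage covariate
#' effect and the stage-by-subtype interaction. Confirms whether a subtype
#' difference survives adjustment for disease progression stage.
#'
#' @param outcome numeric outcome.
#' @param subtype factor of subtype labels (>= 2 levels present).
#' @param stage numeric (or integer) inferred stage.
#' @return object of class `ancova_result` with per-term F and p, and n.
#' @export
ancova_stage_adjusted <- function(outcome, subtype, stage) {
  keep <- stats::complete.cases(outcome, subtype, stage)
  outcome <- outcome[keep]
  subtype <- droplevels(factor(subtype[keep]))
  stage <- as.numeric(stage[keep])
  if (nlevels(subtype) < 2) stop_arg("need at least two subtypes")
  n <- length(outcome)
  if (n <= 5 + 2 * nlevels(subtype)) stop_arg("too few observations for the ANCOVA")
  fit <- stats::lm(outcome ~ subtype * stage)
  aa <- car::Anova(fit, type = 2)
  pick <- function(term) c(F = aa[term, "F value"], p = aa[term, "Pr(>F)"])
  structure(list(
    subtype = pick("subtype"),
    stage = pick("stage"),
    interaction = pick("subtype:stage"),
    n = n, model = fit
  ), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat("Stage-adjusted ANCOVA (type-II SS), n =", x$n, "\n")
  tab <- rbind(subtype = x$subtype, stage = x$stage, interaction = x$interaction)
  print(round(tab, 4))
  invisible(x)
}

#' Stage-clinical multiple regression with age and sex covariates
#'
#' OLS of `outcome ~ stage + age + sex`, returning the stage coefficient
#' (outcome units per stage) and its two-sided p-value. Used within each
#' subtype to identify stage-related clinical correlates.
#'
#' @param outcome numeric outcome.
#' @param stage numeric inferred stage.
#' @param age numeric age in years.
#' @param sex factor/character sex.
#' @return list with `beta_stage`, `se`, `p`, `n`, and the coefficient
#'   table.
#' @export
stage_clinical_regression <- function(outcome, stage, age, sex) {
  keep <- stats::complete.cases(outcome, stage, age, sex)
  d <- data.frame(outcome = outcome, stage = as.numeric(stage),
                  age = as.numeric(age), sex = factor(sex))[keep, ]
  if (nrow(d) < 10) stop_arg("need at least 10 complete observations")
  if (stats::var(d$stage) == 0) stop_arg("stage is constant; slope undefined")
  fit <- stats::lm(outcome ~ stage + age + sex, data = d)
  co <- summary(fit)$coefficients
  list(beta_stage = unname(co["stage", "Estimate"]),
       se = unname(co["stage", "Std. Error"]),
       p = unname(co["stage", "Pr(>|t|)"]),
       n = nrow(d), coefficients = co)
}
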