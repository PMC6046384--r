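# Cohort-level statistics: heart-rate adjustment, two-group comparisons
# with Cohen's d under Bonferroni-grouped alpha levels, and two-step
# hierarchical (moderated) regressions of symptom scores.

#' Heart-rate adjustment of cardiac measures
#'
#' Several HRV and complexity measures carry a mathematical dependence on
#' the mean heart rate itself. To control this bias, each measure is
#' adjusted by the subject's mean HR according to the sign of its
#' cross-subject correlation with HR: negatively correlated measures are
#' divided by HR, positively correlated measures are multiplied by it. A
#' measure with zero (or undefined) correlation is left unadjusted with a
#' warning. Adjusted values are added as `<measure>_adj` columns; raw
#' columns are retained.
#'
#' @param cohort data frame, one row per subject.
#' @param measures character vector of measure column names to adjust.
#' @param hr_col name of the mean-HR column (default `"hr"`).
#' @return list with `cohort` (the input plus `_adj` columns) and
#'   `report` (data frame: `measure`, `correlation`, `operation`).
#' @export
hr_adjust <- function(cohort, measures, hr_col = "hr") {
  if (!hr_col %in% names(cohort)) stop("missing HR column '", hr_col, "'")
  if (nrow(cohort) < 3) stop("need >= 3 subjects for the correlation sign")
  hr <- cohort[[hr_col]]
  if (any(is.na(hr))) stop("HR must be present for all subjects")
  rep_rows <- lapply(measures, function(mname) {
    x <- cohort[[mname]]
    if (is.null(x)) stop("missing measure column '", mname, "'")
    ok <- !is.na(x)
    rho <- if (sd(x[ok]) == 0 || sd(hr[ok]) == 0) NA_real_
           else cor(x[ok], hr[ok])
    if (is.na(rho) || rho == 0) {
      warning("measure '", mname,
              "' has zero or undefined correlation with HR; left unadjusted")
      op <- "unadjusted"
      adj <- x
    } else if (rho > 0) {
      op <- "multiplied_by_hr"
      adj <- x * hr
    } else {
      op <- "divided_by_hr"
      adj <- x / hr
    }
    cohort[[paste0(mname, "_adj")]] <<- adj
    data.frame(measure = mname, correlation = rho, operation = op,
               stringsAsFactors = FALSE)
  })
  list(cohort = cohort, report = do.call(rbind, rep_rows))
}

#' Cohen's d from summary statistics
#'
#' Standardized mean difference using the pooled standard deviation,
#' reported as a magnitude (absolute value):
#' d = |m1 - m2| / sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)).
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return Cohen's d (>= 0).
#' @examples
#' cohens_d(38.16, 13.89, 80, 33.24, 12.31, 86) # ~0.38
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(sd1, sd2) < 0)) stop("standard deviations must be >= 0")
  if (any(c(n1, n2) < 2)) stop("group sizes must be >= 2")
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (pooled == 0) stop("pooled SD is zero: d undefined")
  abs(mean1 - mean2) / pooled
}

#' Bonferroni-corrected alpha level
#'
#' @param base_alpha family-wise alpha (e.g. 0.05).
#' @param family_size number of tests in the family.
#' @return per-test alpha `base_alpha / family_size`.
#' @export
bonferroni_alpha <- function(base_alpha, family_size) {
  if (family_size < 1) stop("family_size must be >= 1")
  base_alpha / family_size
}

#' Two-group comparison of cardiac measures
#'
#' Per-measure one-way ANOVA (two groups, so F on 1 and N-2 degrees of
#' freedom, equal to the squared pooled-variance t) with Cohen's d and a
#' significance flag at the supplied family-wise Bonferroni alpha.
#'
#' @param cohort data frame, one row per subject.
#' @param measures character vector of measure column names.
#' @param family_alpha per-test alpha after Bonferroni grouping
#'   (default 0.05).
#' @param group_col grouping column with exactly two levels (default
#'   `"sex_code"`, coded 1 = boys, 2 = girls).
#' @return data frame, one row per measure: group means/SDs/ns, `f`,
#'   `df1`, `df2`, `p`, `cohens_d`, `family_alpha`, `significant`.
#' @export
compare_groups <- function(cohort, measures, family_alpha = 0.05,
                           group_col = "sex_code") {
  g <- factor(cohort[[group_col]])
  if (nlevels(g) != 2) stop("grouping column must have exactly two levels")
  rows <- lapply(measures, function(mname) {
    x <- cohort[[mname]]
    if (is.null(x)) stop("missing measure column '", mname, "'")
    ok <- !is.na(x) & !is.na(g)
    x <- x[ok]; gg <- droplevels(g[ok])
    if (any(table(gg) < 2)) stop("each group needs n >= 2")
    x1 <- x[gg == levels(gg)[1]]
    x2 <- x[gg == levels(gg)[2]]
    a <- anova(lm(x ~ gg))
    data.frame(measure = mname,
               mean1 = mean(x1), sd1 = sd(x1), n1 = length(x1),
               mean2 = mean(x2), sd2 = sd(x2), n2 = length(x2),
               f = a[["F value"]][1], df1 = a[["Df"]][1],
               df2 = a[["Df"]][2], p = a[["Pr(>F)"]][1],
               cohens_d = cohens_d(mean(x1), sd(x1), length(x1),
                                   mean(x2), sd(x2), length(x2)),
               family_alpha = family_alpha,
               significant = a[["Pr(>F)"]][1] < family_alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-step hierarchical regression of a symptom score
#'
#' Step 1 fits `outcome ~ sex + z(measure)` by ordinary least squares;
#' step 2 adds the `sex x z(measure)` interaction. The cardiac measure is
#' standardized across the cohort (all complete-case rows of this
#' regression) to prevent multicollinearity with its interaction; sex
#' enters as the raw 1/2 code, uncentred. Coefficients are reported as
#' standardized betas (b * sd(x) / sd(y)) alongside their p-values; each
#' step reports R-squared and the increment over the previous step.
#' Rows missing the outcome or the measure are dropped listwise.
#'
#' @param cohort data frame, one row per subject.
#' @param outcome name of the symptom (dependent) column.
#' @param measure name of the cardiac-measure column.
#' @param sex_col name of the sex-code column (1 = boys, 2 = girls).
#' @return object of class `hier_reg`: list with `outcome`, `measure`,
#'   `n`, and per step `r2`, `delta_r2`, and a `coef` data frame
#'   (`term`, `beta`, `p`).
#' @export
hierarchical_regression <- function(cohort, outcome, measure,
                                    sex_col = "sex_code") {
  need <- c(outcome, measure, sex_col)
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) stop("missing column(s): ",
                             paste(miss, collapse = ", "))
  d <- cohort[, need]
  names(d) <- c("y", "x", "sex")
  d <- d[complete.cases(d), ]
  if (nrow(d) < 10) stop("fewer than 10 complete cases")
  if (sd(d$x) == 0) stop("measure '", measure, "' has zero variance")
  d$z <- (d$x - mean(d$x)) / sd(d$x)
  d$zint <- d$sex * d$z
  fit1 <- lm(y ~ sex + z, data = d)
  fit2 <- lm(y ~ sex + z + zint, data = d)
  qr2 <- qr(cbind(1, d$sex, d$z, d$zint))
  if (qr2$rank < 4) stop("rank-deficient design: sex, z(", measure,
                         ") and their interaction are collinear")
  std_beta <- function(fit, terms, cols) {
    b <- coef(fit)[terms]
    pv <- summary(fit)$coefficients[terms, 4]
    sds <- vapply(cols, function(cc) sd(d[[cc]]), numeric(1))
    data.frame(term = terms, beta = unname(b * sds / sd(d$y)),
               p = unname(pv), stringsAsFactors = FALSE)
  }
  r2_1 <- summary(fit1)$r.squared
  r2_2 <- summary(fit2)$r.squared
  structure(list(
    outcome = outcome, measure = measure, n = nrow(d),
    step1 = list(r2 = r2_1, delta_r2 = r2_1,
                 coef = std_beta(fit1, c("sex", "z"), c("sex", "z"))),
    step2 = list(r2 = r2_2, delta_r2 = r2_2 - r2_1,
                 coef = std_beta(fit2, c("sex", "z", "zint"),
                                 c("sex", "z", "zint")))),
    class = "hier_reg")
}

#' @export
print.hier_reg <- function(x, ...) {
  cat(sprintf("<hier_reg> %s ~ sex + z(%s)  (n = %d)\n",
              x$outcome, x$measure, x$n))
  cat(sprintf("  step 1: R2 = %.3f\n", x$step1$r2))
  print(x$step1$coef, row.names = FALSE)
  cat(sprintf("  step 2: dR2 = %.3f\n", x$step2$delta_r2))
  print(x$step2$coef, row.names = FALSE)
  invisible(x)
}

#' Flatten a hierarchical regression to tidy rows
#'
#' @param x a `hier_reg` object.
#' @return data frame, one row per step x term, with `outcome`,
#'   `measure`, `step`, `delta_r2`, `term`, `beta`, `p`, `n`.
#' @export
tidy_hier_reg <- function(x) {
  stopifnot(inherits(x, "hier_reg"))
  do.call(rbind, lapply(1:2, function(s) {
    st <- x[[paste0("step", s)]]
    data.frame(outcome = x$outcome, measure = x$measure, step = s,
               delta_r2 = st$delta_r2, term = st$coef$term,
               beta = st$coef$beta, p = st$coef$p, n = x$n,
               stringsAsFactors = FALSE)
  }))
}
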