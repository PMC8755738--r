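#' Two-way ANOVA with Tukey HSD post-test on a regional metric
#'
#' Fits `value ~ age_group * region` on one metric of a tidy metrics table and
#' tests the main and interaction effects (Type II sums of squares by default,
#' appropriate for the unbalanced cohort; Type I reproduces the classical
#' sequential decomposition on balanced designs). Tukey-adjusted pairwise
#' age-group contrasts within each region are returned as the post-test.
#'
#' @param table data.frame with columns `subject, age_group, region,
#'   metric_name, value` (one row per subject x region x metric). An optional
#'   logical `qc_pass` column marks subjects excluded by quality control
#'   (e.g. an acquisition aborted prematurely); rows with `qc_pass == FALSE`
#'   are dropped before testing.
#' @param metric_name which metric to test.
#' @param ss_type `"II"` (default) or `"I"` sums of squares.
#' @param tukey compute the Tukey HSD post-test (skippable for speed in
#'   calibration loops).
#' @return list `anova` (data.frame effect, df, sum_sq, statistic, p_value),
#'   `tukey` (data.frame region, contrast, estimate, p_adj or `NULL`),
#'   `model` (the `lm` fit).
#' @export
two_way_anova_tukey <- function(table, metric_name, ss_type = c("II", "I"),
                                tukey = TRUE) {
  ss_type <- match.arg(ss_type)
  d <- table[table$metric_name == metric_name, , drop = FALSE]
  if (!nrow(d)) stop("metric '", metric_name, "' not present in the table")
  d <- apply_qc(d)
  d <- d[is.finite(d$value), , drop = FALSE]
  d$age_group <- factor(d$age_group)
  d$region <- factor(d$region)
  if (nlevels(d$age_group) < 2 || nlevels(d$region) < 2) {
    stop("need at least 2 levels per factor (age_group, region)")
  }
  cells <- table(d$age_group, d$region)
  if (any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)
    stop("cells with fewer than 2 observations: ",
         paste(sprintf("%s:%s", rownames(cells)[bad[, 1]],
                       colnames(cells)[bad[, 2]]), collapse = ", "))
  }
  fit <- stats::lm(value ~ age_group * region, data = d)
  if (stats::sigma(fit) < 1e-12) {
    # degenerate (zero residual variance): report F = 0 / p = 1 when the
    # effect sums of squares are zero too (identical values in all cells)
    eff <- c("age_group", "region", "age_group:region")
    an <- data.frame(effect = eff, df = NA_real_, sum_sq = 0,
                     statistic = 0, p_value = 1)
    return(list(anova = an, tukey = NULL, model = fit))
  }
  an_raw <- if (ss_type == "II") {
    a <- car::Anova(fit, type = 2)
    data.frame(effect = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
               statistic = a$`F value`, p_value = a$`Pr(>F)`)
  } else {
    a <- stats::anova(fit)
    data.frame(effect = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
               statistic = a$`F value`, p_value = a$`Pr(>F)`)
  }
  an <- an_raw[an_raw$effect != "Residuals", , drop = FALSE]
  attr(an, "residual") <- an_raw[an_raw$effect == "Residuals", , drop = FALSE]
  tk <- NULL
  if (tukey) {
    emm <- emmeans::emmeans(fit, ~ age_group | region)
    prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
    tk <- data.frame(region = prs$region, contrast = prs$contrast,
                     estimate = prs$estimate, se = prs$SE,
                     p_adj = prs$p.value)
  }
  list(anova = an, tukey = tk, model = fit)
}

#' Multivariate linear regression of a regional metric on age and sex
#'
#' Ordinary least squares of `value ~ age_weeks + sex` within one region,
#' returning the coefficient table (estimate, standard error, t, p).
#'
#' @param table data.frame with columns `subject, age_weeks, sex, region,
#'   metric_name, value`.
#' @param metric_name which metric to fit.
#' @param region which region to fit.
#' @return data.frame `term, estimate, se, statistic, p_value`.
#' @export
multivariate_regression <- function(table, metric_name, region) {
  d <- table[table$metric_name == metric_name & table$region == region, ,
             drop = FALSE]
  d <- apply_qc(d)
  d <- d[is.finite(d$value), , drop = FALSE]
  if (nrow(d) < 4) stop("need at least 4 subjects")
  if (length(unique(d$sex)) < 2) {
    stop("collinear design: both sexes must be present")
  }
  d$sex <- factor(d$sex)
  fit <- stats::lm(value ~ age_weeks + sex, data = d)
  cf <- summary(fit)$coefficients
  data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
             statistic = cf[, 3], p_value = cf[, 4], row.names = NULL)
}

# Honor an optional per-subject quality-control flag: rows with
# qc_pass == FALSE are excluded from aggregation.
apply_qc <- function(d) {
  if ("qc_pass" %in% names(d)) d <- d[d$qc_pass %in% c(TRUE, NA), , drop = FALSE]
  d
}

#' Compare velocity-distribution skewness between cohorts
#'
#' Welch two-sample t-test on per-subject skewness values (the test choice is
#' a recorded design decision; returned in the result).
#'
#' @param young,aged numeric vectors of per-subject skewness (>= 2 each).
#' @return list `statistic` (t), `df` (Welch-Satterthwaite), `p_value`,
#'   `means` (group means), `test` = "welch_t".
#' @export
compare_skewness <- function(young, aged) {
  stopifnot(length(young) >= 2, length(aged) >= 2)
  if ((stats::var(young) == 0 && length(young) == 2) ||
      (stats::var(aged) == 0 && length(aged) == 2)) {
    warning("a group has zero variance with n = 2; test is degenerate")
  }
  tt <- stats::t.test(aged, young)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       means = c(young = mean(young), aged = mean(aged)),
       test = "welch_t")
}
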