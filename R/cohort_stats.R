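#' Initiating-event prevalence by group
#'
#' Fraction of cases in each group carrying at least one event among a
#' gene set (default the initiating drivers KRAS, BRAF, CDKN2A). The
#' percentage is reported to one decimal.
#'
#' @param event_matrix gene x case 0/1 matrix ([build_event_matrix()]).
#' @param groups character vector: group label per case (column).
#' @param genes gene set defining an "initiating event".
#' @return data.frame with one row per group: `group`, `n_event`, `n`,
#'   `fraction`, `percent` (one decimal).
#' @examples
#' # 83 of 87 grade-1 cases with an event -> 95.4%
#' @export
prevalence_by_grade <- function(event_matrix, groups,
                                genes = c("KRAS", "BRAF", "CDKN2A")) {
  stopifnot(ncol(event_matrix) == length(groups))
  genes <- intersect(genes, rownames(event_matrix))
  if (!length(genes)) stop("none of the requested genes are in the matrix")
  has_event <- colSums(event_matrix[genes, , drop = FALSE]) > 0
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    idx <- groups == g
    if (!any(idx)) stop("empty group: ", g)
    k <- sum(has_event[idx]); n <- sum(idx)
    data.frame(group = g, n_event = k, n = n, fraction = k / n,
               percent = round(100 * k / n, 1), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact test on a 2x2 co-occurrence table
#'
#' Exact p-value (sum of hypergeometric probabilities no larger than the
#' observed table's), conditional maximum-likelihood odds ratio and
#' exact confidence interval. Zero cells are handled by the exact
#' method: one CI bound can be 0 or infinite, and no continuity
#' correction is applied to the p-value. The odds ratio refers to the
#' table as given (rows = first factor, columns = second factor), so the
#' orientation is part of the result.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param conf_level confidence level for the CI (default 0.95).
#' @return List with `p_value`, `odds_ratio`, `conf_int` and
#'   `orientation` (a reminder string).
#' @export
fisher_cooccurrence <- function(table, conf_level = 0.95) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (sum(table) == 0) stop("all-zero table")
  ft <- stats::fisher.test(table, conf.level = conf_level)
  list(p_value = ft$p.value,
       odds_ratio = unname(ft$estimate),
       conf_int = as.numeric(ft$conf.int),
       orientation = "odds ratio of row1 given column1 vs column2, as tabled")
}

#' Two-factor ANOVA with Tukey post-tests
#'
#' Linear-model ANOVA of a per-case statistic (FGA, mutation burden) on
#' a group factor (grade or classification) with sequencing platform as
#' a covariate factor, followed by Tukey honest significant differences
#' on the group factor (studentized-range p-values).
#'
#' @param values numeric per-case statistic.
#' @param groups group factor (>= 2 levels, >= 2 values each).
#' @param covariate optional second factor (e.g. platform mode).
#' @return List with `F`, `df` (group numerator df), `p_value`, the
#'   `anova` table and `tukey` (pairwise comparisons for the group
#'   factor).
#' @export
anova_tukey <- function(values, groups, covariate = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 values")
  dat <- data.frame(y = values, g = groups)
  if (!is.null(covariate) && length(unique(covariate)) > 1) {
    dat$cov <- factor(covariate)
    fit <- stats::aov(y ~ g + cov, data = dat)
  } else {
    fit <- stats::aov(y ~ g, data = dat)
  }
  tab <- summary(fit)[[1]]
  i <- which(trimws(rownames(tab)) == "g")
  tk <- stats::TukeyHSD(fit, which = "g")
  list(F = tab[i, "F value"], df = tab[i, "Df"],
       p_value = tab[i, "Pr(>F)"], anova = tab, tukey = tk$g)
}

#' Kaplan-Meier curves and logrank test
#'
#' Product-limit survival estimates per group and the logrank
#' (score) chi-square on k - 1 degrees of freedom. Disease-specific
#' survival: deaths of disease are events, everything else is censored.
#'
#' @param time survival time in months (>= 0).
#' @param event logical or 0/1 event indicator (death of disease).
#' @param groups group label per record (e.g. FGA-high / FGA-low).
#' @return List with `fit` (a [survival::survfit] object), `chisq`,
#'   `df` and `p_value`.
#' @export
km_logrank <- function(time, event, groups) {
  if (!is.factor(groups)) groups <- factor(groups)
  if (any(table(groups) == 0)) stop("a group has zero records")
  if (any(time < 0, na.rm = TRUE)) stop("negative survival time")
  event <- as.integer(event)
  dat <- data.frame(time = time, event = event, g = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = dat)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
  df <- length(sd$n) - 1
  list(fit = fit, chisq = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Median split of a per-case statistic
#'
#' Default dichotomization of FGA for survival comparison: values above
#' the median are "high", the rest "low". The cut point is returned so
#' it can be logged alongside results.
#'
#' @param values numeric vector.
#' @return List with `group` (factor high/low) and `cut` (the median).
#' @export
median_split <- function(values) {
  cut <- stats::median(values, na.rm = TRUE)
  list(group = factor(ifelse(values > cut, "high", "low"),
                      levels = c("low", "high")),
       cut = cut)
}

#' Pearson chi-square test of profile type by grade
#'
#' Without continuity correction; expected counts are reported and a
#' warning is raised when any expected count falls below 5.
#'
#' @param table contingency matrix (profile types x grades).
#' @return List with `chisq`, `df`, `p_value` and `expected`.
#' @export
profile_chisq <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero-margin row or column")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(ct$expected < 5))
    warning("expected count below 5; chi-square approximation is weak")
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}
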