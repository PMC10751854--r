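# Cohort statistics: descriptive summaries with a normality gate, omnibus
# three-group tests, Bonferroni post-hoc pairwise tests, and covariate-
# adjusted ANCOVA.

#' Describe a metric per group
#'
#' Normality is decided per group by Shapiro-Wilk at `alpha` (overridable via
#' `force`): normally distributed metrics are summarised as mean +/- SD,
#' otherwise as median (IQR, 25th-75th percentiles).
#'
#' @param values numeric vector.
#' @param groups factor of the same length.
#' @param alpha Shapiro-Wilk significance level for the normality gate.
#' @param force `NA` (gate decides), `TRUE` (treat as normal) or `FALSE`.
#' @return list with `normal` (logical), per-group data.frame `stats`
#'   (n, mean, sd, median, q1, q3, shapiro_p) and `formatted` strings.
#' @export
describe_metric <- function(values, groups, alpha = 0.05, force = NA) {
  groups <- droplevels(as.factor(groups))
  if (any(tapply(values, groups, length) < 2))
    stop("each group needs at least 2 observations")
  st <- do.call(rbind, lapply(split(values, groups), function(x) {
    sw <- if (length(unique(x)) > 1 && length(x) >= 3 && length(x) <= 5000)
      shapiro.test(x)$p.value else NA_real_
    data.frame(n = length(x), mean = mean(x), sd = sd(x),
               median = median(x),
               q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)),
               shapiro_p = sw)
  }))
  st$group <- rownames(st)
  normal <- if (!is.na(force)) force else
    all(is.na(st$shapiro_p) | st$shapiro_p >= alpha)
  fmt <- if (normal)
    sprintf("%.3g ± %.3g", st$mean, st$sd)
  else
    sprintf("%.3g (%.3g, %.3g)", st$median, st$q1, st$q3)
  list(normal = normal, stats = st, formatted = setNames(fmt, st$group))
}

#' Omnibus group comparison
#'
#' One-way ANOVA or Kruskal-Wallis (tie-corrected) for continuous metrics,
#' chi-squared for categorical ones. `family = "auto"` uses the Shapiro-Wilk
#' normality gate to choose between ANOVA and Kruskal-Wallis.
#'
#' @param values numeric vector (or factor for chi-squared).
#' @param groups factor.
#' @param family `"auto"`, `"anova"`, `"kruskal_wallis"` or `"chi_squared"`.
#' @return list with `statistic`, `p.value`, `family`, `method`.
#' @export
omnibus_test <- function(values, groups,
                         family = c("auto", "anova", "kruskal_wallis",
                                    "chi_squared")) {
  family <- match.arg(family)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  categorical <- is.factor(values) || is.character(values) || is.logical(values)
  if (family == "chi_squared" && !categorical)
    stop("chi-squared requires a categorical variable")
  if (family == "auto")
    family <- if (categorical) "chi_squared"
              else if (describe_metric(values, groups)$normal) "anova"
              else "kruskal_wallis"
  res <- switch(family,
    anova = {
      fit <- summary(aov(values ~ groups))[[1]]
      list(statistic = fit[["F value"]][1], p.value = fit[["Pr(>F)"]][1])
    },
    kruskal_wallis = {
      k <- kruskal.test(values, groups)
      list(statistic = unname(k$statistic), p.value = k$p.value)
    },
    chi_squared = {
      k <- suppressWarnings(chisq.test(table(groups, values)))
      list(statistic = unname(k$statistic), p.value = k$p.value)
    })
  c(res, list(family = family,
              method = c(anova = "one-way ANOVA",
                         kruskal_wallis = "Kruskal-Wallis",
                         chi_squared = "chi-squared")[[family]]))
}

#' Bonferroni-adjusted pairwise post-hoc tests
#'
#' All pairwise tests of the same family as the omnibus test: two-sample
#' t-tests after ANOVA, two-group Kruskal-Wallis tests after Kruskal-Wallis.
#' Adjusted p = min(1, raw p x number of pairs).
#'
#' @param values numeric vector.
#' @param groups factor (>= 2 levels).
#' @param family `"anova"` (t-tests) or `"kruskal_wallis"`.
#' @return data.frame: group1, group2, p_raw, p_adj.
#' @export
posthoc_pairwise <- function(values, groups,
                             family = c("anova", "kruskal_wallis")) {
  family <- match.arg(family)
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  res <- apply(pairs, 2, function(pr) {
    sel <- groups %in% pr
    x <- values[sel]
    g <- droplevels(groups[sel])
    if (family == "anova") t.test(x ~ g)$p.value
    else kruskal.test(x, g)$p.value
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             p_raw = res, p_adj = pmin(1, res * m))
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Linear model `metric ~ group + covariates` with a type-II F-test on the
#' group factor. Zero-variance covariates are dropped (the model then reduces
#' exactly to one-way ANOVA); covariates collinear with the group factor or
#' each other raise an error.
#'
#' @param data data.frame.
#' @param metric metric column name.
#' @param group group column name (factor).
#' @param covariates character vector of numeric covariate columns.
#' @return list with `p.value`, `F`, `covariates` used, and the fitted `lm`.
#' @export
ancova_group_test <- function(data, metric, group = "group",
                              covariates = "bmi") {
  for (cv in covariates) {
    if (!is.numeric(data[[cv]])) stop("covariate ", cv, " must be numeric")
    if (anyNA(data[[cv]])) stop("covariate ", cv, " has missing values")
  }
  keep <- covariates[vapply(covariates, function(cv)
    sd(data[[cv]]) > 0, logical(1))]
  fml <- stats::reformulate(c(group, keep), response = metric)
  fit <- lm(fml, data = data)
  if (anyNA(coef(fit)))
    stop("collinear covariate in ANCOVA model")
  tab <- car::Anova(fit, type = 2)
  i <- match(group, rownames(tab))
  list(p.value = tab[i, "Pr(>F)"], F = tab[i, "F value"],
       covariates = keep, fit = fit)
}

#' Run the full group-comparison battery over a cohort table
#'
#' For each metric: per-group descriptive summary (normality-gated), omnibus
#' test (ANOVA / Kruskal-Wallis / chi-squared), Bonferroni post-hoc pairwise
#' tests, and (for continuous metrics) BMI-adjusted ANCOVA.
#'
#' @param cohort a `cohort_table` (or data.frame with a `group` factor).
#' @param metrics metric column names; default all numeric metric columns.
#' @param covariates ANCOVA covariates (default `"bmi"`); set `NULL` to skip.
#' @return list of class `group_comparison`: `summary` (one row per metric:
#'   per-group formatted summaries, test family, statistic, p),
#'   `pairwise` (long table of adjusted pairwise p-values), `ancova`.
#' @export
compare_groups <- function(cohort, metrics = NULL, covariates = "bmi") {
  stopifnot("group" %in% names(cohort))
  if (is.null(metrics)) {
    skip <- c("patient_id", "group")
    metrics <- setdiff(names(cohort), skip)
  }
  grp <- droplevels(as.factor(cohort$group))
  summ <- list(); pw <- list(); anc <- list()
  for (m in metrics) {
    v <- cohort[[m]]
    if (is.numeric(v)) {
      d <- describe_metric(v, grp)
      fam <- if (d$normal) "anova" else "kruskal_wallis"
      om <- omnibus_test(v, grp, fam)
      row <- data.frame(metric = m, family = om$family,
                        statistic = om$statistic, p = om$p.value)
      for (g in levels(grp)) row[[g]] <- unname(d$formatted[g])
      summ[[m]] <- row
      p <- posthoc_pairwise(v, grp, fam)
      p$metric <- m
      pw[[m]] <- p
      if (!is.null(covariates) && !(m %in% covariates)) {
        a <- ancova_group_test(cbind(cohort, .metric = v), ".metric",
                               "group", covariates)
        anc[[m]] <- data.frame(metric = m, F = a$F, p_adjusted = a$p.value,
                               covariates = paste(a$covariates, collapse = "+"))
      }
    } else {
      om <- omnibus_test(as.factor(v), grp, "chi_squared")
      row <- data.frame(metric = m, family = om$family,
                        statistic = om$statistic, p = om$p.value)
      for (g in levels(grp)) {
        tb <- table(v[grp == g])
        row[[g]] <- paste(sprintf("%s:%d", names(tb), tb), collapse = " ")
      }
      summ[[m]] <- row
    }
  }
  structure(list(summary = do.call(rbind, summ),
                 pairwise = do.call(rbind, pw),
                 ancova = do.call(rbind, anc)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
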