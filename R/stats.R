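#' Collapse per-NMJ values into one larval datapoint
#'
#' The unit of statistical replication is the larva: per-NMJ measurements
#' within one larva are averaged, and downstream `n` counts larvae.
#'
#' @param values numeric per-NMJ values.
#' @param larvae larva identifiers, same length (omit to average one
#'   larva's values).
#' @return named numeric vector, one mean per larva.
#' @export
larvalDatapoint <- function(values, larvae = NULL) {
  if (is.null(larvae)) return(mean(values))
  vapply(split(values, larvae), mean, numeric(1))
}

#' Per-group summaries (n, mean, SEM, median, IQR)
#'
#' @param values numeric datapoints (one per larva).
#' @param groups group labels.
#' @return data.frame, one row per group.
#' @export
groupSummary <- function(values, groups) {
  do.call(rbind, lapply(split(values, groups), function(v)
    data.frame(n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)),
               median = stats::median(v), iqr = stats::IQR(v))))
}

#' Normality gate: choose the parametric or nonparametric route
#'
#' Shapiro-Wilk tests each group's distribution; the parametric route is
#' taken iff every group passes at `alpha`. Levene's test for equality of
#' group variances is run and reported alongside, but routing follows
#' normality. Downstream: two groups go to Student's t vs Mann-Whitney U;
#' more than two to ANOVA vs Kruskal-Wallis.
#'
#' @param values numeric datapoints.
#' @param groups group labels; every group needs n >= 3 and non-zero
#'   variance.
#' @param alpha Shapiro-Wilk level; default 0.05.
#' @return list with `route` (`"parametric"` or `"nonparametric"`),
#'   `shapiro_p` (per group), `levene_p`.
#' @export
normalityGate <- function(values, groups, alpha = 0.05) {
  gs <- split(values, groups)
  if (any(vapply(gs, length, 1L) < 3L))
    stop("every group needs at least 3 datapoints for the normality gate")
  if (any(vapply(gs, stats::sd, 1) == 0))
    stop("degenerate group with zero variance; normality test undefined")
  sw <- vapply(gs, function(v) stats::shapiro.test(v)$p.value, 1)
  lev <- car::leveneTest(values ~ factor(groups))[1, "Pr(>F)"]
  list(route = if (all(sw >= alpha)) "parametric" else "nonparametric",
       shapiro_p = sw, levene_p = lev)
}

#' Two-group comparison (Student's t or Mann-Whitney U)
#'
#' Parametric route: unpaired two-tailed Student's t test with pooled
#' variance (`welch = TRUE` switches to the Welch form). Nonparametric
#' route: Mann-Whitney U, exact when the smaller group has <= 8
#' observations and there are no ties, otherwise the normal approximation
#' with tie correction.
#'
#' @param g1,g2 numeric samples.
#' @param route `"parametric"`, `"nonparametric"`, or `"auto"` to apply
#'   the normality gate.
#' @param welch use the Welch (unpooled) t form.
#' @return list with `test`, `statistic`, `df`, `p_value`, `groups`
#'   (summaries), `route`.
#' @export
twoGroupTest <- function(g1, g2, route = c("auto", "parametric",
                                           "nonparametric"),
                         welch = FALSE) {
  route <- match.arg(route)
  if (route == "auto")
    route <- normalityGate(c(g1, g2),
                           rep(c("g1", "g2"), c(length(g1), length(g2))))$route
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs at least 2 observations")
  if (route == "parametric") {
    if (stats::sd(g1) == 0 && stats::sd(g2) == 0)
      stop("degenerate variance: both groups are constant")
    tt <- stats::t.test(g1, g2, var.equal = !welch)
    res <- list(test = if (welch) "Welch t" else "Student t",
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value)
  } else {
    exact <- min(length(g1), length(g2)) <= 8 &&
      !any(duplicated(c(g1, g2)))
    wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = exact,
                                              correct = !exact))
    res <- list(test = "Mann-Whitney U", statistic = unname(wt$statistic),
                df = NA_real_, p_value = wt$p.value)
  }
  res$route <- route
  res$groups <- groupSummary(c(g1, g2),
                             rep(c("g1", "g2"), c(length(g1), length(g2))))
  res
}

#' Student's t test from summary statistics
#'
#' Pooled-variance unpaired two-tailed t test computed from group means,
#' SEMs and sizes, for checking published summary tables.
#'
#' @param mean1,sem1,n1,mean2,sem2,n2 group summaries.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
tTestFromSummary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  v1 <- (sem1 * sqrt(n1))^2
  v2 <- (sem2 * sqrt(n2))^2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (mean1 - mean2) / se
  df <- n1 + n2 - 2
  list(statistic = tval, df = df,
       p_value = 2 * stats::pt(-abs(tval), df))
}

#' Multi-group / repeated-measures comparison
#'
#' For the study's genotype x stimulation-frequency design: a
#' mixed-effects repeated-measures analysis with genotype as the
#' between-subject factor, frequency as the within-subject factor and a
#' per-larva random intercept, fitted by REML (lmerTest) with
#' Satterthwaite degrees of freedom. This tolerates missing cells and
#' unbalanced larva counts; a larva present at a single frequency is
#' retained (with a warning). With a single frequency level the design
#' collapses to a one-way between-subject comparison (for two genotypes,
#' F equals t squared). A plain one-way route (`values`/`groups` without
#' frequency) runs ANOVA or Kruskal-Wallis per the route argument.
#'
#' @param data data.frame with columns `value`, `genotype`, `frequency`,
#'   `larva_id` (repeated-measures form); or `NULL` when `values` and
#'   `groups` are given.
#' @param values,groups one-way form.
#' @param route `"parametric"` or `"nonparametric"` for the one-way form.
#' @return list with `test`, `effects` (data.frame of term, F/statistic,
#'   df, p_value) and the fitted `model` where applicable.
#' @export
multiGroupTest <- function(data = NULL, values = NULL, groups = NULL,
                           route = "parametric") {
  if (is.null(data)) {
    if (route == "parametric") {
      fit <- stats::aov(values ~ factor(groups))
      s <- summary(fit)[[1]]
      eff <- data.frame(term = "group", statistic = s[1, "F value"],
                        df1 = s[1, "Df"], df2 = s[2, "Df"],
                        p_value = s[1, "Pr(>F)"])
      return(list(test = "one-way ANOVA", effects = eff, model = fit))
    }
    kt <- stats::kruskal.test(values, factor(groups))
    return(list(test = "Kruskal-Wallis",
                effects = data.frame(term = "group",
                                     statistic = unname(kt$statistic),
                                     df1 = unname(kt$parameter),
                                     df2 = NA, p_value = kt$p.value),
                model = NULL))
  }
  stopifnot(all(c("value", "genotype", "frequency", "larva_id") %in%
                names(data)))
  data$genotype <- factor(data$genotype)
  data$frequency <- factor(data$frequency)
  perLarva <- tapply(data$frequency, data$larva_id,
                     function(f) length(unique(f)))
  if (any(perLarva == 1L) && nlevels(data$frequency) > 1L)
    warning("some larvae appear at a single frequency level; ",
            "retained via the mixed model")
  if (nlevels(data$frequency) == 1L) {
    fit <- stats::lm(value ~ genotype, data = data)
    a <- stats::anova(fit)
    eff <- data.frame(term = "genotype", statistic = a[1, "F value"],
                      df1 = a[1, "Df"], df2 = a[2, "Df"],
                      p_value = a[1, "Pr(>F)"])
    return(list(test = "one-way (single frequency)", effects = eff,
                model = fit))
  }
  fit <- lmerTest::lmer(value ~ genotype * frequency + (1 | larva_id),
                        data = data)
  a <- stats::anova(fit)  # Satterthwaite, type III
  eff <- data.frame(term = rownames(a), statistic = a[, "F value"],
                    df1 = a[, "NumDF"], df2 = a[, "DenDF"],
                    p_value = a[, "Pr(>F)"], row.names = NULL)
  list(test = "mixed-effects repeated-measures ANOVA", effects = eff,
       model = fit)
}

#' Post-hoc multiple comparisons (Tukey HSD or Dunnett)
#'
#' Tukey compares each group with every other group; Dunnett performs the
#' planned comparisons of every group against a single control.
#' Implemented on estimated marginal means (emmeans) of a one-way fit (or
#' a supplied mixed model).
#'
#' @param values,groups one-way data (ignored when `model` is given).
#' @param method `"tukey"` or `"dunnett"`.
#' @param controlLabel control group label (required for Dunnett).
#' @param model optional fitted model with a `groups`-like factor named
#'   `genotype`.
#' @return data.frame with `comparison`, `estimate`, `p_adj`.
#' @export
postHoc <- function(values = NULL, groups = NULL,
                    method = c("tukey", "dunnett"), controlLabel = NULL,
                    model = NULL) {
  method <- match.arg(method)
  if (is.null(model)) {
    df <- data.frame(value = values, group = factor(groups))
    model <- stats::lm(value ~ group, data = df)
    spec <- "group"
  } else spec <- "genotype"
  em <- emmeans::emmeans(model, spec)
  if (method == "tukey") {
    ct <- summary(emmeans::contrast(em, method = "pairwise",
                                    adjust = "tukey"))
  } else {
    if (is.null(controlLabel))
      stop("Dunnett comparisons require a control group label")
    lev <- levels(factor(if (is.null(values)) em@grid[[spec]]
                         else groups))
    ref <- match(controlLabel, lev)
    if (is.na(ref)) stop("control label '", controlLabel, "' not found")
    ct <- summary(emmeans::contrast(em, method = "trt.vs.ctrl",
                                    ref = ref, adjust = "dunnett"))
  }
  data.frame(comparison = as.character(ct$contrast),
             estimate = ct$estimate, p_adj = ct$p.value)
}
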