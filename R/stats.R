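# Hypothesis tests and correlation used for plate-reader datasets.

#' Pearson correlation between copy number and expression
#'
#' Correlates replicate-level `(copy number, FL/OD)` points — not condition
#' means — so a design with 5 copy levels and 4 biological replicates gives
#' `df = N - 2 = 18`. The two-sided p-value is t-based.
#'
#' @param copies copy number of each replicate point.
#' @param flod matching FL/OD values.
#' @return A list with `r`, `p`, `df` and `n`.
#' @examples
#' copy_correlation(rep(c(1, 2, 4, 6, 8), each = 4),
#'                  rep(c(1, 2, 4, 6, 8), each = 4) * 100)
#' @export
copy_correlation <- function(copies, flod) {
  if (length(copies) != length(flod)) stop("copies and flod differ in length")
  keep <- is.finite(copies) & is.finite(flod)
  copies <- copies[keep]; flod <- flod[keep]
  if (length(unique(copies)) < 3)
    stop("copy correlation needs >= 3 distinct copy levels")
  if (stats::var(copies) == 0 || stats::var(flod) == 0)
    stop("correlation undefined: zero variance in copies or FL/OD")
  ht <- stats::cor.test(copies, flod, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), p = ht$p.value, df = unname(ht$parameter),
       n = length(copies))
}

#' Welch's two-sample t-test
#'
#' Two-tailed t-test assuming unequal variances. Returns the exact
#' (fractional) Welch-Satterthwaite degrees of freedom alongside the pooled
#' convention `n1 + n2 - 2` that reporting often quotes for balanced n = 4
#' designs (df = 6); the p-value always uses the Welch df.
#'
#' @param a,b numeric replicate vectors, each of length >= 2.
#' @return A list with `t`, `df` (Welch), `df_pooled`, and two-tailed `p`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs >= 2 replicates")
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       df_pooled = length(a) + length(b) - 2L, p = ht$p.value)
}

# Significance stars at the conventional thresholds.
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = TRUE)
}

#' ANOVA with post-hoc Tukey HSD
#'
#' One- or two-way fixed-effects ANOVA over labelled replicate groups (with
#' interaction when two factors are given), followed by Tukey's honest
#' significant difference test on all pairwise cell comparisons. Pairwise
#' adjusted p-values are annotated at the .05 / .01 / .001 thresholds.
#'
#' @param values numeric replicate measurements.
#' @param f1 first categorical factor (coerced to factor).
#' @param f2 optional second categorical factor.
#' @return A list with `anova` (data frame: term, df, F, p) and `tukey`
#'   (data frame: term, comparison, diff, p_adj, signif).
#' @export
anova_tukey <- function(values, f1, f2 = NULL) {
  f1 <- factor(f1)
  dat <- data.frame(y = values, f1 = f1)
  if (!is.null(f2)) dat$f2 <- factor(f2)
  cell <- if (is.null(f2)) dat$f1 else interaction(dat$f1, dat$f2, drop = TRUE)
  if (any(table(cell) < 2))
    stop("every factor cell needs >= 2 replicates")
  fml <- if (is.null(f2)) y ~ f1 else y ~ f1 * f2
  fit <- stats::aov(fml, data = dat)
  an <- stats::anova(fit)
  keep <- rownames(an) != "Residuals"
  an_tab <- data.frame(term = rownames(an)[keep], df = an$Df[keep],
                       F = an$`F value`[keep], p = an$`Pr(>F)`[keep])
  # a design with zero between-group signal can produce F = 0/0; report p = 1
  an_tab$p[!is.finite(an_tab$F)] <- 1
  an_tab$F[!is.finite(an_tab$F)] <- 0
  tk <- stats::TukeyHSD(fit)
  tuk <- do.call(rbind, lapply(names(tk), function(term) {
    m <- tk[[term]]
    data.frame(term = term, comparison = rownames(m),
               diff = m[, "diff"], p_adj = m[, "p adj"], row.names = NULL)
  }))
  tuk$p_adj[is.nan(tuk$p_adj)] <- 1
  tuk$signif <- as.character(p_stars(tuk$p_adj))
  list(anova = an_tab, tukey = tuk)
}
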