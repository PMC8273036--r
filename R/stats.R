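#' Significance stars at the 0.05 / 0.01 / 0.001 thresholds
#' @param p p-value.
#' @return `"***"`, `"**"`, `"*"` or `"ns"` (strict `<` at each threshold).
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Shapiro-Wilk normality decision
#'
#' Used by [compare_two()] and [compare_many()] to choose between
#' parametric and nonparametric tests. Degenerate samples (near-zero
#' variance) are reported non-normal with a warning rather than erroring.
#'
#' @param x numeric vector, `n >= 3`.
#' @param alpha significance level (default 0.05).
#' @return A list with `normal` (logical), `p_value`, `method`.
#' @export
normality_check <- function(x, alpha = 0.05) {
  if (length(x) < 3L) stopf("normality_check needs n >= 3")
  if (sd(x) < .Machine$double.eps^0.5 * max(1, abs(mean(x)))) {
    warnf("normality_check: sample is (near-)constant; reported non-normal")
    return(list(normal = FALSE, p_value = NA_real_,
                method = "shapiro-wilk (degenerate sample)"))
  }
  sw <- shapiro.test(x)
  list(normal = sw$p.value >= alpha, p_value = unname(sw$p.value),
       method = "shapiro-wilk")
}

new_group_comparison <- function(groups, test_used, statistic, p_value,
                                 posthoc = NULL, normality = NULL) {
  structure(list(groups = groups, test_used = test_used,
                 statistic = unname(statistic), p_value = unname(p_value),
                 posthoc = posthoc, normality = normality,
                 significance_stars = significance_stars(p_value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g %s\n",
              x$test_used, x$statistic, x$p_value, x$significance_stars))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc:\n")
    for (i in seq_len(nrow(x$posthoc)))
      cat(sprintf("    %s vs %s: p.adj = %.4g %s\n",
                  x$posthoc$group1[i], x$posthoc$group2[i],
                  x$posthoc$p_adjusted[i],
                  significance_stars(x$posthoc$p_adjusted[i])))
  }
  invisible(x)
}

#' Compare two conditions (t-test or Mann-Whitney, chosen by normality)
#'
#' If both groups pass a Shapiro-Wilk normality check a two-sided
#' unpaired Welch t-test is used; otherwise a two-sided Mann-Whitney U
#' test (exact for small tie-free samples, normal approximation with
#' continuity and tie correction otherwise).
#'
#' @param a,b numeric vectors, each `n >= 3`.
#' @param names names of the two groups.
#' @param test `"auto"` (normality-based choice, the default), or force
#'   `"t"` / `"mann-whitney"`.
#' @return A `"group_comparison"` object; `test_used` records the choice.
#' @export
compare_two <- function(a, b, names = c("a", "b"),
                        test = c("auto", "t", "mann-whitney")) {
  test <- match.arg(test)
  if (length(a) < 3L || length(b) < 3L)
    stopf("insufficient-n: compare_two needs n >= 3 per group")
  na <- suppressWarnings(normality_check(a))
  nb <- suppressWarnings(normality_check(b))
  normality <- list(na, nb); base::names(normality) <- names
  parametric <- switch(test, auto = isTRUE(na$normal) && isTRUE(nb$normal),
                       t = TRUE, `mann-whitney` = FALSE)
  if (parametric) {
    tt <- t.test(a, b, var.equal = FALSE)
    return(new_group_comparison(stats::setNames(list(a, b), names),
                                "welch-t", tt$statistic, tt$p.value,
                                normality = normality))
  }
  exact <- max(length(a), length(b)) <= 8 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  new_group_comparison(stats::setNames(list(a, b), names),
                       if (exact) "mann-whitney-exact"
                       else "mann-whitney-approx",
                       wt$statistic, wt$p.value, normality = normality)
}

# Dunn's post test after Kruskal-Wallis: pairwise z statistics on mean
# ranks with tie correction, Bonferroni family adjustment.
dunn_test <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  rk <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- vapply(split(rk, g), mean, numeric(1))
  n <- lengths(groups)
  pairs <- utils::combn(seq_along(groups), 2)
  k <- ncol(pairs)
  out <- data.frame(group1 = character(k), group2 = character(k),
                    statistic = numeric(k), p_unadjusted = numeric(k),
                    p_adjusted = numeric(k))
  for (j in seq_len(k)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i1] + 1 / n[i2]))
    z <- (mean_rank[i1] - mean_rank[i2]) / se
    p <- 2 * pnorm(-abs(z))
    out$group1[j] <- names(groups)[i1]
    out$group2[j] <- names(groups)[i2]
    out$statistic[j] <- z
    out$p_unadjusted[j] <- p
    out$p_adjusted[j] <- min(1, p * k)
  }
  out
}

#' Compare three or more conditions
#'
#' If every group passes Shapiro-Wilk normality and Bartlett's test does
#' not reject equal variances, a one-way ANOVA with Tukey HSD post test is
#' used; otherwise Kruskal-Wallis with Dunn's post test
#' (Bonferroni-adjusted over all pairs).
#'
#' @param groups named list (length >= 3) of numeric vectors, each
#'   `n >= 3`.
#' @param test `"auto"` (normality + Bartlett-based choice, the default),
#'   or force `"anova"` / `"kruskal"`.
#' @return A `"group_comparison"` with a populated `posthoc` table
#'   (`group1`, `group2`, `statistic`, `p_unadjusted`, `p_adjusted`).
#' @export
compare_many <- function(groups, test = c("auto", "anova", "kruskal")) {
  test <- match.arg(test)
  if (!is.list(groups) || length(groups) < 3L)
    stopf("compare_many needs >= 3 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 3L))
    stopf("insufficient-n: compare_many needs n >= 3 per group")
  normality <- lapply(groups, function(g) suppressWarnings(normality_check(g)))
  all_normal <- all(vapply(normality, `[[`, logical(1), "normal"))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (test == "anova" || (test == "auto" && all_normal)) {
    bt <- bartlett.test(x, g)
    if (test == "anova" || bt$p.value >= 0.05) {
      fit <- aov(x ~ g)
      an <- summary(fit)[[1]]
      tuk <- TukeyHSD(fit)$g
      ph <- data.frame(
        group1 = sub("-.*", "", rownames(tuk)),
        group2 = sub(".*-", "", rownames(tuk)),
        statistic = unname(tuk[, "diff"]),
        p_unadjusted = unname(tuk[, "p adj"]),
        p_adjusted = unname(tuk[, "p adj"]))
      cmp <- new_group_comparison(groups, "anova-tukey",
                                  an$`F value`[1], an$`Pr(>F)`[1],
                                  posthoc = ph, normality = normality)
      cmp$bartlett_p <- unname(bt$p.value)
      return(cmp)
    }
  }
  kw <- kruskal.test(x, g)
  cmp <- new_group_comparison(groups, "kruskal-dunn", kw$statistic,
                              kw$p.value, posthoc = dunn_test(groups),
                              normality = normality)
  cmp
}

#' Partial-inhibition flag
#'
#' An inhibitor produces a *partial* inhibition when the inhibited
#' condition differs significantly from both the stimulated condition and
#' the corresponding control (strict `p < 0.05` on each comparison).
#'
#' @param vs_stimulated a `"group_comparison"` of inhibited vs stimulated.
#' @param vs_control a `"group_comparison"` of inhibited vs control.
#' @param alpha significance level (default 0.05, strict).
#' @return `TRUE` iff both comparisons are significant.
#' @export
partial_inhibition_flag <- function(vs_stimulated, vs_control,
                                    alpha = 0.05) {
  if (missing(vs_stimulated) || missing(vs_control) ||
      !inherits(vs_stimulated, "group_comparison") ||
      !inherits(vs_control, "group_comparison"))
    stopf("partial_inhibition_flag needs both group comparisons")
  vs_stimulated$p_value < alpha && vs_control$p_value < alpha
}
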