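#' Group comparison with effect size
#'
#' Independent or paired t-tests (two-sided), one-sided Mann-Whitney U
#' tests for small samples, or chi-square tests for categorical counts.
#' Cohen's D uses the pooled sd for independent designs and the sd of the
#' differences for paired ones.
#'
#' @param a,b Numeric vectors (counts/factors for `chi_square`).
#' @param method One of `"independent_t"`, `"paired_t"`,
#'   `"mannwhitney_one_sided"`, `"chi_square"`.
#' @param alternative Direction for the one-sided Mann-Whitney test
#'   (`"greater"` means a tends larger than b); must be supplied explicitly
#'   for that method.
#' @param paired Paired flag for the Mann-Whitney method (signed-rank).
#' @return A list of class `stat_result`: `statistic`, `p`, `ci_low`,
#'   `ci_high`, `df`, `effect_size`, `method`.
#' @export
compare_groups <- function(a, b,
                           method = c("independent_t", "paired_t",
                                      "mannwhitney_one_sided", "chi_square"),
                           alternative = NULL, paired = FALSE) {
  method <- match.arg(method)
  as_result <- function(statistic, p, ci = c(NA, NA), df = NA,
                        effect_size = NA) {
    structure(list(statistic = unname(statistic), p = unname(p),
                   ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                   df = unname(df), effect_size = unname(effect_size),
                   method = method),
              class = "stat_result")
  }
  if (method == "chi_square") {
    tab <- if (is.matrix(a)) a else table(a, b)
    ht <- stats::chisq.test(tab, correct = FALSE)
    return(as_result(ht$statistic, ht$p.value, df = ht$parameter))
  }
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (method == "paired_t") {
    if (length(a) != length(b)) stop("paired design needs equal lengths")
    d <- a - b
    if (stats::sd(d) == 0) {
      stop("zero variance of paired differences; t-test degenerate",
           call. = FALSE)
    }
    ht <- stats::t.test(a, b, paired = TRUE)
    return(as_result(ht$statistic, ht$p.value, ht$conf.int, ht$parameter,
                     effect_size = mean(d) / stats::sd(d)))
  }
  if (method == "independent_t") {
    na <- length(a); nb <- length(b)
    pooled <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
                     (na + nb - 2))
    if (pooled == 0) stop("zero pooled variance; t-test degenerate")
    ht <- stats::t.test(a, b, var.equal = TRUE)
    return(as_result(ht$statistic, ht$p.value, ht$conf.int, ht$parameter,
                     effect_size = (mean(a) - mean(b)) / pooled))
  }
  # one-sided Mann-Whitney U (or signed-rank when paired)
  if (is.null(alternative)) {
    stop("the one-sided Mann-Whitney direction must be supplied explicitly")
  }
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, paired = paired,
                       conf.int = TRUE))
  as_result(ht$statistic, ht$p.value, ht$conf.int)
}

#' Cohen's f-squared from a correlation
#'
#' `f^2 = r^2 / (1 - r^2)`, the effect size used for correlations and
#' regression fits.
#'
#' @param r Correlation with `|r| < 1`.
#' @return Scalar f-squared.
#' @export
effect_size_f2 <- function(r) {
  if (abs(r) >= 1) stop("|r| must be below 1")
  r^2 / (1 - r^2)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up BH procedure; q-values are monotone nondecreasing in sorted
#' p-value order and rejection means q <= alpha.
#'
#' @param pvals P-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `qvals` and logical `reject`.
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  list(qvals = q, reject = q <= alpha)
}

#' ANCOVA for a group effect on brain-age gaps
#'
#' Linear model of the gap on group plus covariates (age, sex, education),
#' reporting the group coefficient, its p-value, and the partial f-squared
#' (`t^2 / df_residual`).
#'
#' @param outcome Numeric gap vector.
#' @param group Two-level factor or 0/1 vector.
#' @param covariates Data frame of covariates (e.g. age, sex, education);
#'   factors are indicator-coded by the model matrix.
#' @return A `stat_result` list with `method = "ancova"` plus
#'   `group_coefficient`.
#' @export
ancova_group_effect <- function(outcome, group, covariates) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("group must have two levels")
  dat <- data.frame(outcome = outcome, group = group, covariates)
  if (nrow(dat) <= ncol(stats::model.matrix(~ ., dat[-1])) + 1) {
    stop("too few observations for the design")
  }
  fit <- stats::lm(outcome ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design: group confounded with a covariate")
  }
  sm <- summary(fit)
  coefs <- sm$coefficients
  grow <- grep("^group", rownames(coefs))[1]
  tval <- coefs[grow, "t value"]
  df_res <- fit$df.residual
  ci <- stats::confint(fit)[grow, ]
  structure(
    list(statistic = tval, p = coefs[grow, "Pr(>|t|)"],
         ci_low = unname(ci[1]), ci_high = unname(ci[2]), df = df_res,
         effect_size = tval^2 / df_res, method = "ancova",
         group_coefficient = unname(coefs[grow, "Estimate"])),
    class = "stat_result"
  )
}

#' Percentile split of brain-age gaps
#'
#' Labels values strictly below the `lo`th percentile "younger", strictly
#' above the `hi`th percentile "older", and everything else "excluded".
#' Percentiles use linear interpolation.
#'
#' @param bags Numeric vector with at least 3 distinct values.
#' @param lo,hi Percentiles (defaults 35 and 65), `lo < hi`.
#' @return Factor with levels `younger`, `older`, `excluded`.
#' @export
percentile_split <- function(bags, lo = 35, hi = 65) {
  stopifnot(lo < hi)
  if (length(unique(bags)) < 3) stop("need at least 3 distinct values")
  qs <- stats::quantile(bags, c(lo, hi) / 100, type = 7, names = FALSE)
  out <- rep("excluded", length(bags))
  out[bags < qs[1]] <- "younger"
  out[bags > qs[2]] <- "older"
  factor(out, levels = c("younger", "older", "excluded"))
}

#' Pooled expertise-gap association across domains
#'
#' Z-scores gaps and expertise scores within each domain, pools them on the
#' common scale, and reports the Pearson correlation with its two-sided p
#' and Cohen's f-squared. Domains with constant scores carry no information
#' and are dropped with a warning.
#'
#' @param bags Named list of numeric gap vectors, one per domain.
#' @param scores Named list of matching expertise-score vectors.
#' @return List with `r`, `p`, `f2`, `n`.
#' @export
expertise_bag_association <- function(bags, scores) {
  stopifnot(length(bags) == length(scores))
  zb <- c(); zs <- c()
  for (d in seq_along(bags)) {
    stopifnot(length(bags[[d]]) == length(scores[[d]]))
    if (stats::sd(scores[[d]]) == 0 || stats::sd(bags[[d]]) == 0) {
      warning(sprintf("domain %s has constant scores or gaps; dropped",
                      names(bags)[d] %||% d))
      next
    }
    zb <- c(zb, zscore(bags[[d]]))
    zs <- c(zs, zscore(scores[[d]]))
  }
  if (length(zb) < 3) stop("no usable domains for the pooled association")
  ht <- stats::cor.test(zb, zs)
  r <- unname(ht$estimate)
  list(r = r, p = ht$p.value,
       f2 = if (abs(r) < 1) effect_size_f2(r) else Inf, n = length(zb))
}
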