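# Compositional statistics layer: CLR transform, PCA, two-way permutation
# PERMANOVA, two-way ANOVA, Welch t-tests, BH correction, and the
# normality/homoscedasticity gate that chooses between them.

#' Centered log-ratio transform of an abundance matrix
#'
#' Per sample (row): \eqn{x \mapsto \log(x + pc) - \overline{\log(x + pc)}}.
#' Rows of the result sum to zero, making compositional abundances amenable
#' to Euclidean statistics. Applied to absolute abundances, a pseudocount of
#' one gene copy is a negligible perturbation.
#'
#' @param x samples-by-taxa numeric matrix (or data frame) of non-negative
#'   abundances.
#' @param pseudocount positive value added before the log.
#' @return Matrix of the same shape; rows sum to 0.
#' @examples
#' clr_transform(matrix(c(1, 1, 1, 10, 20, 70), 2, byrow = TRUE))
#' @export
clr_transform <- function(x, pseudocount = 1) {
  x <- as.matrix(x)
  if (any(x < 0)) abort("abundances must be non-negative")
  if (pseudocount <= 0) abort("`pseudocount` must be > 0")
  if (any(rowSums(x) == 0)) {
    abort("degenerate sample(s): all-zero abundance row(s)")
  }
  lx <- log(x + pseudocount)
  lx - rowMeans(lx)
}

#' Principal component analysis of a samples-by-variables matrix
#'
#' Centered (unscaled) PCA via singular value decomposition. Euclidean
#' distances between rows of the full score matrix reproduce the distances
#' between the centered data rows.
#'
#' @param x samples-by-variables numeric matrix; rownames become sample ids.
#' @return Object of class `qsip_pca`: list with `scores` (samples x PCs),
#'   `loadings`, `variance_explained` (sums to 1), `sdev`. [tidy()] returns
#'   scores as a tibble, [glance()] the variance profile, [autoplot()] a
#'   score plot.
#' @examples
#' m <- matrix(rnorm(40), 8)
#' pca_ordination(m)$variance_explained
#' @export
pca_ordination <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("PCA needs at least two samples")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2
  ve <- if (sum(ve) > 0) ve / sum(ve) else ve
  structure(
    list(scores = p$x, loadings = p$rotation, variance_explained = ve,
         sdev = p$sdev),
    class = "qsip_pca"
  )
}

#' @export
print.qsip_pca <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$variance_explained[1],
              100 * (x$variance_explained[2] %||% NA)))
  invisible(x)
}

#' @rdname pca_ordination
#' @param x,object a `qsip_pca` object.
#' @param ... unused.
#' @method tidy qsip_pca
#' @export
tidy.qsip_pca <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "sample_id")
}

#' @rdname pca_ordination
#' @method glance qsip_pca
#' @export
glance.qsip_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$variance_explained),
                 variance_explained = x$variance_explained)
}

#' @rdname pca_ordination
#' @param colour optional vector (length = samples) mapped to point colour.
#' @method autoplot qsip_pca
#' @export
autoplot.qsip_pca <- function(object, colour = NULL, ...) {
  df <- tidy(object)
  if (!is.null(colour)) df$group <- colour
  ve <- object$variance_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::labs(colour = NULL)
  }
}

#' Two-way permutation PERMANOVA on a distance matrix
#'
#' Partitions distance-based sums of squares sequentially (factor A, then B,
#' then their interaction), with pseudo-F statistics and p-values from
#' seeded label permutations: \eqn{p = (1 + \#\{F^{perm} \ge F\}) / (1 +
#' n_{perm})}. Per-term \eqn{R^2} values and the residual sum to 1. Built on
#' \code{vegan::adonis2} with sequential (type-I) sums of squares; factor
#' order therefore matters and is the argument order.
#'
#' @param d a `dist` object or square distance matrix.
#' @param factor_a,factor_b factors (or coercible) aligned with the rows of
#'   `d`; `factor_b = NULL` runs a one-way analysis.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream (mandatory, for
#'   reproducibility).
#' @return Tibble `term`, `df`, `sum_sq`, `r_squared`, `statistic`,
#'   `p_value` (terms, Residual, Total).
#' @examples
#' m <- matrix(rnorm(32), 16)
#' a <- rep(c("x", "y"), each = 8)
#' b <- rep(c("u", "v"), 8)
#' permanova_two_way(dist(m), a, b, n_perm = 199, seed = 1)
#' @export
permanova_two_way <- function(d, factor_a, factor_b = NULL, n_perm = 9999,
                              seed) {
  if (missing(seed)) abort("`seed` is required for reproducible permutations")
  if (n_perm < 99) abort("`n_perm` must be >= 99")
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  a <- factor(factor_a)
  if (length(a) != n) abort("`factor_a` length must match the distance matrix")
  if (nlevels(a) < 2) abort("collinear design: `factor_a` has a single level")
  meta <- data.frame(A = a)
  fml <- d ~ A
  if (!is.null(factor_b)) {
    b <- factor(factor_b)
    if (length(b) != n) abort("`factor_b` length must match the distance matrix")
    if (nlevels(b) < 2) abort("collinear design: `factor_b` has a single level")
    meta$B <- b
    fml <- d ~ A * B
  }
  # degenerate case: all points identical, nothing to partition
  if (sum(d^2) < 1e-12) {
    terms <- c("A", if (!is.null(factor_b)) c("B", "A:B"), "Residual", "Total")
    k <- length(terms) - 2L
    return(tibble::tibble(
      term = terms,
      df = c(rep(1L, k), n - 1L - k, n - 1L),
      sum_sq = 0, r_squared = NA_real_,
      statistic = c(rep(0, k), NA, NA),
      p_value = c(rep(1, k), NA, NA)
    ))
  }
  set.seed(seed)
  res <- vegan::adonis2(fml, data = meta, permutations = n_perm, by = "terms")
  terms <- rownames(res)
  name_a <- deparse(substitute(factor_a))
  name_b <- if (is.null(factor_b)) NULL else deparse(substitute(factor_b))
  relabel <- c(A = name_a, B = name_b,
               `A:B` = if (!is.null(name_b)) paste0(name_a, ":", name_b))
  terms <- ifelse(terms %in% names(relabel), relabel[terms], terms)
  tibble::tibble(
    term = terms,
    df = res$Df,
    sum_sq = res$SumOfSqs,
    r_squared = res$R2,
    statistic = res$F,
    p_value = res$`Pr(>F)`
  )
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Full-factorial ANOVA (sequential sums of squares; on a balanced design
#' identical to any standard formulation), reporting F, degrees of freedom
#' and p per term.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (or coercible) of equal length.
#' @return Tibble `term`, `df`, `sum_sq`, `mean_sq`, `statistic`, `p_value`.
#' @examples
#' a <- rep(c("no", "yes"), each = 8)
#' b <- rep(rep(c("amb", "fut"), each = 4), 2)
#' anova_two_way(rnorm(16), a, b)
#' @export
anova_two_way <- function(values, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (length(values) != length(a) || length(values) != length(b)) {
    abort("`values`, `factor_a`, `factor_b` must have equal length")
  }
  if (any(table(a, b) == 0)) {
    abort("design error: empty cell in the two-way layout")
  }
  name_a <- deparse(substitute(factor_a))
  name_b <- deparse(substitute(factor_b))
  fit <- aov(values ~ a * b)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  relabel <- c(a = name_a, b = name_b, `a:b` = paste0(name_a, ":", name_b))
  terms <- ifelse(terms %in% names(relabel), relabel[terms], terms)
  out <- tibble::tibble(
    term = terms,
    df = tab$Df,
    sum_sq = tab$`Sum Sq`,
    mean_sq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p_value = tab$`Pr(>F)`
  )
  # constant response: every SS is 0 and F is 0/0; report no effect
  zero <- is.nan(out$statistic) & out$sum_sq < .Machine$double.eps
  out$statistic[zero] <- 0
  out$p_value[zero] <- 1
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite (possibly
#' fractional) degrees of freedom, two-sided. When both groups have zero
#' variance and equal means, p = 1 by convention.
#'
#' @param x,y numeric vectors (each >= 2 values).
#' @return One-row tibble `term`, `estimate` (mean(x) - mean(y)),
#'   `statistic`, `df`, `p_value`.
#' @examples
#' welch_t_test(rnorm(4), rnorm(4, 1))
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("each group needs >= 2 values")
  if (var(x) == 0 && var(y) == 0) {
    # conventions for noiseless groups: equal means are indistinguishable
    # (p = 1); any constant offset is infinitely significant (p = 0)
    same <- mean(x) == mean(y)
    return(tibble::tibble(
      term = "x vs y", estimate = mean(x) - mean(y),
      statistic = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
      df = length(x) + length(y) - 2,
      p_value = if (same) 1 else 0
    ))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    term = "x vs y",
    estimate = unname(tt$estimate[1] - tt$estimate[2]),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR correction: sorted p-values are multiplied by m/rank,
#' monotonicity is enforced from the largest down, results capped at 1 and
#' returned in the original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.04))
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Gate between parametric ANOVA and rank-based pairwise tests
#'
#' Runs Shapiro-Wilk on the residuals of a one-way fit across the groups and
#' a median-centered Levene test of variance homogeneity. If both pass at
#' `alpha`, downstream analysis may use ANOVA; otherwise (or when the gate
#' cannot be assessed: groups smaller than 3, or constant data) it routes to
#' pairwise rank tests.
#'
#' @param values numeric response.
#' @param groups group labels of equal length.
#' @param alpha significance level of the gate tests.
#' @return List with `decision` (`"anova"` or `"pairwise-rank"`),
#'   `shapiro_p`, `levene_p`, `abstained`.
#' @examples
#' normality_homoscedasticity_gate(rnorm(16), rep(letters[1:4], each = 4))
#' @export
normality_homoscedasticity_gate <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (length(values) != length(g)) abort("`values` and `groups` lengths differ")
  if (any(table(g) < 3)) {
    return(list(decision = "pairwise-rank", shapiro_p = NA_real_,
                levene_p = NA_real_, abstained = TRUE))
  }
  res <- resid(aov(values ~ g))
  gate <- tryCatch({
    sw <- shapiro.test(res)$p.value
    lv <- car::leveneTest(values ~ g, center = median)[1, "Pr(>F)"]
    list(decision = if (sw >= alpha && lv >= alpha) "anova" else "pairwise-rank",
         shapiro_p = sw, levene_p = lv, abstained = FALSE)
  }, error = function(e) {
    list(decision = "pairwise-rank", shapiro_p = NA_real_,
         levene_p = NA_real_, abstained = TRUE)
  })
  gate
}

#' Pairwise Wilcoxon rank-sum tests between groups
#'
#' Fallback when the [normality_homoscedasticity_gate()] rejects ANOVA:
#' standard rank-sum tests for every pair of groups, exact for group sizes
#' up to 8 (without ties), normal approximation otherwise.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param p_adjust adjust the p-values with [bh_adjust()].
#' @return Tibble `group1`, `group2`, `statistic`, `p_value` (and `p_adj`).
#' @export
pairwise_rank_tests <- function(values, groups, p_adjust = TRUE) {
  g <- factor(groups)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    x <- values[g == pairs[1, i]]
    y <- values[g == pairs[2, i]]
    exact <- length(x) <= 8 && length(y) <= 8
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
    tibble::tibble(group1 = pairs[1, i], group2 = pairs[2, i],
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  if (p_adjust) out$p_adj <- bh_adjust(out$p_value)
  out
}
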