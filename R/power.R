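#' Standardised mean difference (Cohen's d) between two groups
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 values.
#' @return `(mean_a - mean_b) / pooled_sd`; the sign is preserved.
#' @export
effect_size <- function(values_a, values_b) {
  na <- length(values_a)
  nb <- length(values_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  (mean(values_a) - mean(values_b)) / sqrt(sp2)
}

t_test_power <- function(d, n, alpha = 0.05, two_sided = TRUE) {
  stats::power.t.test(n = n, delta = abs(d), sd = 1, sig.level = alpha,
                      type = "two.sample",
                      alternative = if (two_sided) "two.sided"
                                    else "one.sided")$power
}

#' Smallest per-group sample size reaching a target power
#'
#' Uses the noncentral-t power of a two-sample t test (noncentrality
#' \eqn{d\sqrt{n/2}}) and returns the smallest integer n per group whose
#' achieved power meets the target; minimality is verified by stepping.
#'
#' @param d Standardised effect size, non-zero.
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @param two_sided Two-sided test (default `TRUE`).
#' @return List with `n` (per group) and `achieved_power`.
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.8,
                                 two_sided = TRUE) {
  if (abs(d) <= 0) stop("d = 0: the target power is unachievable")
  alt <- if (two_sided) "two.sided" else "one.sided"
  n0 <- tryCatch(
    ceiling(stats::power.t.test(delta = abs(d), sd = 1, sig.level = alpha,
                                power = power, type = "two.sample",
                                alternative = alt)$n),
    error = function(e) 2)
  n <- max(2L, as.integer(n0))
  while (n > 2L && t_test_power(d, n - 1L, alpha, two_sided) >= power)
    n <- n - 1L
  while (t_test_power(d, n, alpha, two_sided) < power)
    n <- n + 1L
  list(n = n, achieved_power = t_test_power(d, n, alpha, two_sided))
}

#' Achieved power across a grid of per-group sample sizes
#'
#' @param d Standardised effect size.
#' @param n_grid Integer vector of per-group sample sizes (each >= 2).
#' @param alpha Significance level.
#' @param two_sided Two-sided test (default `TRUE`).
#' @return Numeric vector of achieved powers, non-decreasing in n.
#' @export
power_curve <- function(d, n_grid, alpha = 0.05, two_sided = TRUE) {
  if (any(n_grid < 2)) stop("all sample sizes must be >= 2")
  vapply(n_grid, function(n) t_test_power(d, n, alpha, two_sided), 0)
}

#' Effect sizes and required sample sizes for a set of genes
#'
#' For each gene, the expression values are split by the two sample groups,
#' Cohen's d is computed and the per-group sample size needed to reach the
#' target power under a two-sample t test is estimated.
#'
#' @param expr Expression matrix carrying a two-level `groups` attribute,
#'   or pass `groups` explicitly.
#' @param genes Genes to assess (default: all).
#' @param groups Per-sample group labels (two levels).
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @return Data frame with columns `gene`, `d`, `n_required`,
#'   `achieved_power`.
#' @export
power_analysis <- function(expr, genes = NULL, groups = attr(expr, "groups"),
                           alpha = 0.05, power = 0.8) {
  expr <- validate_expression(expr)
  if (is.null(groups)) stop("sample group labels are required")
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups are required")
  genes <- genes %||% rownames(expr)
  if (!all(genes %in% rownames(expr)))
    stop("unknown gene(s): ",
         paste(setdiff(genes, rownames(expr)), collapse = ", "))
  rows <- lapply(genes, function(g) {
    d <- effect_size(expr[g, groups == lv[1L]], expr[g, groups == lv[2L]])
    ss <- required_sample_size(d, alpha = alpha, power = power)
    data.frame(gene = g, d = d, n_required = ss$n,
               achieved_power = ss$achieved_power, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
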