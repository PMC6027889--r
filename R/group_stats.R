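#' Two-sided Fisher's exact test for a 2 x 2 contingency table
#'
#' Compares co-localization counts `k_a` of `n_a` versus `k_b` of `n_b`.
#' The two-sided p-value follows the standard convention: with the margins
#' fixed, sum the hypergeometric probabilities of every admissible table
#' whose probability does not exceed that of the observed table (a relative
#' tolerance of 1e-7 guards the comparison against floating-point ties,
#' matching the convention of [stats::fisher.test()]). Implemented directly
#' on [stats::dhyper()] so that large batches of tables vectorize cheaply.
#'
#' @param k_a,n_a successes and size of group A (0 <= k_a <= n_a).
#' @param k_b,n_b successes and size of group B.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(9, 10, 1, 10)
#' stats::fisher.test(matrix(c(9, 1, 1, 9), 2))$p.value
fisher_exact_2x2 <- function(k_a, n_a, k_b, n_b) {
  counts <- c(k_a = k_a, n_a = n_a, k_b = k_b, n_b = n_b)
  if (any(counts != round(counts)) || any(counts < 0) ||
      n_a < 1 || n_b < 1 || k_a > n_a || k_b > n_b)
    stop("fisher_exact_2x2: need 0 <= k <= n and n >= 1 for both groups",
         call. = FALSE)
  K <- k_a + k_b
  support <- max(0, K - n_b):min(K, n_a)
  probs <- stats::dhyper(support, n_a, n_b, K)
  p_obs <- stats::dhyper(k_a, n_a, n_b, K)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Two-sample Student's t-test on per-nucleus PCC values
#'
#' Classic equal-variance (pooled) two-sample t-test with
#' `df = n_a + n_b - 2`, two-sided. The equal-variance form (rather than
#' Welch's) is the one conventionally reported for mean-PCC comparisons in
#' this assay.
#'
#' @param pcc_a,pcc_b numeric vectors of defined PCC values (length >= 2
#'   each, nonzero pooled variance).
#' @return A list with `t_stat`, `p`, `df`. Swapping the groups negates
#'   `t_stat` and leaves `p` unchanged.
#' @export
#' @examples
#' students_t_two_sample(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
students_t_two_sample <- function(pcc_a, pcc_b) {
  pcc_a <- pcc_a[!is.na(pcc_a)]
  pcc_b <- pcc_b[!is.na(pcc_b)]
  if (length(pcc_a) < 2L || length(pcc_b) < 2L)
    stop("students_t_two_sample: need >= 2 defined values per group",
         call. = FALSE)
  if (stats::var(pcc_a) == 0 && stats::var(pcc_b) == 0)
    stop("students_t_two_sample: zero pooled variance", call. = FALSE)
  ht <- stats::t.test(pcc_a, pcc_b, var.equal = TRUE)
  list(t_stat = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Compare two cohorts on co-localization frequency and mean PCC
#'
#' The two cohort-level readouts of the assay: the frequency of nuclei
#' called co-localized, compared by [fisher_exact_2x2()], and the mean
#' in-mask PCC, compared by [students_t_two_sample()]. All nuclei —
#' including segmentation failures (call `FALSE`) and undefined-PCC nuclei —
#' count in the frequency denominator; only defined PCC values enter the
#' mean-PCC comparison. Significance flags are set at `alpha` (default
#' 0.01, the conventional level for this assay).
#'
#' @param records list of `coloc_record` objects (typically from
#'   [analyze_cohort()]).
#' @param group_a,group_b the two group labels to compare.
#' @param alpha significance level in (0, 1).
#' @return An object of class `group_comparison` with fields `group_a`,
#'   `group_b`, `n_a`, `n_b`, `k_a`, `k_b`, `freq_a`, `freq_b`,
#'   `mean_pcc_a`, `mean_pcc_b`, `sd_pcc_a`, `sd_pcc_b`, `n_pcc_a`,
#'   `n_pcc_b`, `fisher_p`, `significant_freq`, `pcc_test_available`,
#'   `t_stat`, `t_p`, `significant_pcc`, `alpha`.
#' @export
#' @examples
#' pairs <- simulate_cohort(list(
#'   cohort_group("her1", preset_params("her1"), 8),
#'   cohort_group("laco_only", preset_params("laco_only"), 8)), seed = 1)
#' compare_groups(analyze_cohort(pairs), "her1", "laco_only")
compare_groups <- function(records, group_a, group_b, alpha = 0.01) {
  stopifnot(all(vapply(records, inherits, TRUE, "coloc_record")))
  if (alpha <= 0 || alpha >= 1)
    stop("compare_groups: alpha must be in (0, 1)", call. = FALSE)
  groups <- vapply(records, function(r) as.character(r$group), "")
  for (g in c(group_a, group_b)) {
    if (!any(groups == g))
      stop(sprintf("compare_groups: unknown group label '%s'", g),
           call. = FALSE)
  }
  pick <- function(g) records[groups == g]
  ra <- pick(group_a); rb <- pick(group_b)
  calls <- function(rs) vapply(rs, function(r) isTRUE(r$coloc_call), TRUE)
  pccs <- function(rs) {
    v <- vapply(rs, function(r) r$pcc, 0)
    v[!is.na(v)]
  }
  n_a <- length(ra); n_b <- length(rb)
  k_a <- sum(calls(ra)); k_b <- sum(calls(rb))
  pcc_a <- pccs(ra); pcc_b <- pccs(rb)
  fisher_p <- fisher_exact_2x2(k_a, n_a, k_b, n_b)
  pcc_ok <- length(pcc_a) >= 2L && length(pcc_b) >= 2L &&
    !(stats::var(pcc_a) == 0 && stats::var(pcc_b) == 0)
  tt <- if (pcc_ok) students_t_two_sample(pcc_a, pcc_b) else
    list(t_stat = NA_real_, p = NA_real_, df = NA_real_)
  structure(list(
    group_a = group_a, group_b = group_b,
    n_a = n_a, n_b = n_b, k_a = k_a, k_b = k_b,
    freq_a = k_a / n_a, freq_b = k_b / n_b,
    mean_pcc_a = if (length(pcc_a)) mean(pcc_a) else NA_real_,
    mean_pcc_b = if (length(pcc_b)) mean(pcc_b) else NA_real_,
    sd_pcc_a = if (length(pcc_a) > 1) stats::sd(pcc_a) else NA_real_,
    sd_pcc_b = if (length(pcc_b) > 1) stats::sd(pcc_b) else NA_real_,
    n_pcc_a = length(pcc_a), n_pcc_b = length(pcc_b),
    fisher_p = fisher_p,
    significant_freq = fisher_p < alpha,
    pcc_test_available = pcc_ok,
    t_stat = tt$t_stat, t_p = tt$p, t_df = tt$df,
    significant_pcc = if (pcc_ok) tt$p < alpha else NA,
    alpha = alpha
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  star <- function(flag) if (isTRUE(flag)) " *" else ""
  cat(sprintf("<group_comparison> %s vs %s (alpha = %g)\n",
              x$group_a, x$group_b, x$alpha))
  cat(sprintf("  coloc frequency: %d/%d (%.0f%%) vs %d/%d (%.0f%%), Fisher p = %.3g%s\n",
              x$k_a, x$n_a, 100 * x$freq_a, x$k_b, x$n_b, 100 * x$freq_b,
              x$fisher_p, star(x$significant_freq)))
  if (isTRUE(x$pcc_test_available)) {
    cat(sprintf("  mean PCC: %.3f (sd %.3f, n %d) vs %.3f (sd %.3f, n %d), t = %.2f, p = %.3g%s\n",
                x$mean_pcc_a, x$sd_pcc_a, x$n_pcc_a,
                x$mean_pcc_b, x$sd_pcc_b, x$n_pcc_b,
                x$t_stat, x$t_p, star(x$significant_pcc)))
  } else {
    cat("  mean PCC comparison unavailable (too few defined PCC values)\n")
  }
  invisible(x)
}
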