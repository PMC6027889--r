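# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain-arithmetic evaluation of the defining formulas.

# Pearson r by direct evaluation of the sum formula
oracle_pcc <- function(y, c_) {
  ybar <- sum(y) / length(y)
  cbar <- sum(c_) / length(c_)
  num <- sum((y - ybar) * (c_ - cbar))
  num / sqrt(sum((y - ybar)^2) * sum((c_ - cbar)^2))
}

# Otsu threshold by exhaustive search over every candidate bin edge of a
# 256-bin histogram: maximize between-class variance, lowest edge on ties
oracle_otsu <- function(x, n_bins = 256L) {
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  bin <- findInterval(x, breaks, all.inside = TRUE)
  best_k <- NA_integer_
  best_v <- -Inf
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  for (k in seq_len(n_bins - 1L)) {
    lo <- bin <= k
    n0 <- sum(lo); n1 <- length(x) - n0
    if (n0 == 0L || n1 == 0L) next
    m0 <- sum(mids[bin[lo]]) / n0
    m1 <- sum(mids[bin[!lo]]) / n1
    v <- (n0 / length(x)) * (n1 / length(x)) * (m0 - m1)^2
    if (v > best_v + 1e-15) {
      best_v <- v
      best_k <- k
    }
  }
  breaks[best_k + 1L]
}

# two-sided Fisher p by exhaustive enumeration of all admissible tables,
# hypergeometric probabilities from binomial coefficients directly
oracle_fisher <- function(k_a, n_a, k_b, n_b) {
  K <- k_a + k_b
  N <- n_a + n_b
  ks <- max(0, K - n_b):min(K, n_a)
  logp <- lchoose(n_a, ks) + lchoose(n_b, K - ks) - lchoose(N, K)
  probs <- exp(logp)
  p_obs <- probs[ks == k_a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# pooled-variance two-sample t statistic and p, textbook closed form
oracle_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t_stat = t, p = 2 * pt(-abs(t), na + nb - 2))
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# a noise-free parameter set (analytic expectation images)
noise_free <- function(...) {
  sim_params(poisson_gain = Inf, read_sigma = 0, expression_scale_sd = 0,
             ...)
}

# minimal hand-built record satisfying the coloc_record contract
make_record <- function(id, group, pcc = NA_real_, call = FALSE,
                        status = "ok") {
  structure(list(nucleus_id = id, group = group, frame = 0L, time_min = 0,
                 status = status, threshold_used = 50, n_mask_px = 100L,
                 pcc = pcc, yfp_spots = NULL, cfp_spots = NULL,
                 coloc_call = call,
                 matched_pairs = if (call)
                   data.frame(cfp_index = 1L, yfp_index = 1L,
                              distance_px = 0) else NULL,
                 config = NULL),
            class = "coloc_record")
}
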