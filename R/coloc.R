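#' Pearson correlation between two channels inside the nucleus mask
#'
#' The per-nucleus co-localization statistic: the Pearson correlation
#' coefficient (PCC) of the two channels' intensities over the pixels of
#' the nucleus mask,
#' \deqn{r = \frac{\sum_i (Y_i - \bar Y)(C_i - \bar C)}
#'   {\sqrt{\sum_i (Y_i - \bar Y)^2 \sum_i (C_i - \bar C)^2}},}
#' with \eqn{i} ranging over mask pixels only. Positive values indicate
#' co-localization; values near zero indicate no association. Restricting
#' the sum to the nucleus is essential: including extranuclear background
#' pixels correlates the two channels through the shared nucleus geometry
#' and inflates r.
#'
#' @param yfp,cfp numeric intensity matrices of identical shape.
#' @param mask a `nucleus_mask` from [segment_nucleus()], or a logical
#'   matrix of the same shape with at least 3 `TRUE` pixels.
#' @return r in \[-1, 1\]. Symmetric in its channel arguments and invariant
#'   under per-channel positive affine intensity transforms.
#'   Zero variance of either channel within the mask raises a condition of
#'   class `nucoloc_undefined_pcc`.
#' @export
#' @examples
#' sim <- simulate_nucleus(preset_params("her1", seed = 1))
#' m <- segment_nucleus(sim$pair$yfp)
#' pearson_cc(sim$pair$yfp, sim$pair$cfp, m)
pearson_cc <- function(yfp, cfp, mask) {
  if (inherits(mask, "nucleus_mask")) mask <- mask$mask
  if (!identical(dim(yfp), dim(cfp)) || !identical(dim(yfp), dim(mask)))
    stop("pearson_cc: yfp, cfp and mask shapes must match", call. = FALSE)
  y <- yfp[mask]; c_ <- cfp[mask]
  if (length(y) < 3L)
    stop("pearson_cc: mask must contain at least 3 pixels", call. = FALSE)
  if (stats::var(y) == 0 || stats::var(c_) == 0) {
    stop(structure(class = c("nucoloc_undefined_pcc", "error", "condition"),
                   list(message = paste("pearson_cc: undefined (zero",
                                        "variance within mask)"),
                        call = NULL)))
  }
  stats::cor(y, c_)
}

# --- multi-scale Laplacian-of-Gaussian spot detection ------------------------

# cache of kernel FFTs keyed by image size and sigma
.log_cache <- new.env(parent = emptyenv())

# FFT of the scale-normalized negated LoG kernel, wrapped so the kernel
# centre sits at [1, 1] (circular convolution). The kernel is even in both
# axes, so its FFT is real; only the real part is stored, which halves the
# cost of the frequency-domain multiply.
.log_kernel_fft <- function(nr, nc, sigma) {
  key <- sprintf("%d_%d_%.6g", nr, nc, sigma)
  got <- .log_cache[[key]]
  if (!is.null(got)) return(got)
  wrap <- function(n) {
    d <- seq_len(n) - 1L
    ifelse(d > n / 2, d - n, d)
  }
  r2 <- outer(wrap(nr)^2, wrap(nc)^2, `+`)
  g <- exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  # scale-normalized, negated so bright blobs give positive peaks:
  # -sigma^2 * LoG = -(r^2 - 2 sigma^2) / sigma^2 * G
  k <- -(r2 - 2 * sigma^2) / sigma^2 * g
  k <- k - mean(k)   # exact zero DC: constant images give zero response
  kf <- Re(stats::fft(k))
  .log_cache[[key]] <- kf
  kf
}

# list of per-scale complex inverse transforms for one (already
# transformed) image; for a real input image the response is the real part
.log_responses_cplx <- function(img_fft, nr, nc, sigmas) {
  lapply(sigmas, function(s) {
    stats::fft(img_fft * .log_kernel_fft(nr, nc, s), inverse = TRUE) /
      (nr * nc)
  })
}

.log_responses <- function(img_fft, nr, nc, sigmas) {
  lapply(.log_responses_cplx(img_fft, nr, nc, sigmas), Re)
}

# 3 x 3 spatial neighbourhood max (including centre), -Inf beyond borders;
# separable two-pass max filter
.neigh_max3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  inf_row <- rep.int(-Inf, nc)
  up <- rbind(inf_row, m[-nr, , drop = FALSE], deparse.level = 0)
  dn <- rbind(m[-1L, , drop = FALSE], inf_row, deparse.level = 0)
  v <- pmax.int(pmax.int(up, dn), m)      # pmax.int drops dim
  dim(v) <- c(nr, nc)
  inf_col <- rep.int(-Inf, nr)
  lf <- cbind(inf_col, v[, -nc, drop = FALSE], deparse.level = 0)
  rt <- cbind(v[, -1L, drop = FALSE], inf_col, deparse.level = 0)
  out <- pmax.int(pmax.int(lf, rt), v)
  dim(out) <- c(nr, nc)
  out
}

# 1D sub-pixel offset of a parabola through (f_minus, f0, f_plus); clamped
.parabolic_offset <- function(fm, f0, fp) {
  den <- fm + fp - 2 * f0
  if (!is.finite(den) || den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (fm - fp) / den))
}

#' Detect spots inside the nucleus mask
#'
#' Multi-scale Laplacian-of-Gaussian (LoG) blob detection restricted to the
#' nucleus mask. The image is convolved with scale-normalized negated LoG
#' kernels over a geometric grid of scales; candidate spots are local
#' maxima of the response in the joint (row, col, scale) neighbourhood that
#' reach at least `peak_rel_threshold` times the maximum in-mask response
#' and at least `min_snr` times the robust (MAD) noise level of the in-mask
#' response at their scale — without the noise floor any image, including
#' one with no real spot at all, would yield detections at noise maxima.
#' Centroids are refined to sub-pixel precision by a quadratic fit around
#' the peak, and weaker detections closer than one scale-sigma to a
#' stronger one are suppressed.
#'
#' @param image numeric intensity matrix (one channel).
#' @param mask a `nucleus_mask` or logical matrix restricting the search.
#' @param sigma_range length-2 numeric, the smallest and largest blob scale
#'   (Gaussian sigma, pixels) to search; default `c(1, 4)`.
#' @param n_scales number of geometrically spaced scales (default 3, the
#'   classic octave spacing 1, 2, 4 over the default range).
#' @param peak_rel_threshold keep peaks whose response is at least this
#'   fraction of the maximum in-mask response (default 0.3).
#' @param min_snr keep peaks whose response is at least this multiple of
#'   the median-absolute-deviation noise level of the in-mask response at
#'   their scale (default 5); `0` disables the floor.
#' @return A data frame of class `spot_table`, one row per spot, sorted by
#'   descending response: `row`, `col` (0-based sub-pixel centroid),
#'   `scale_sigma`, `response`, `peak_intensity`. Zero rows when the
#'   in-mask image is flat or no response is positive.
#' @export
#' @examples
#' sim <- simulate_nucleus(preset_params("her1", seed = 1,
#'                                       poisson_gain = Inf, read_sigma = 0))
#' m <- segment_nucleus(sim$pair$yfp)
#' detect_spots(sim$pair$cfp, m)
detect_spots <- function(image, mask, sigma_range = c(1, 4), n_scales = 3L,
                         peak_rel_threshold = 0.3, min_snr = 5) {
  if (inherits(mask, "nucleus_mask")) mask <- mask$mask
  stopifnot(identical(dim(image), dim(mask)))
  sigmas <- .scale_grid(sigma_range, n_scales)
  resp <- .log_responses(stats::fft(image), nrow(image), ncol(image), sigmas)
  .detect_spots_core(image, mask, resp, sigmas, peak_rel_threshold, min_snr)
}

.scale_grid <- function(sigma_range, n_scales) {
  if (length(sigma_range) != 2L || any(sigma_range <= 0) ||
      sigma_range[1] > sigma_range[2])
    stop("detect_spots: sigma_range must be positive and increasing",
         call. = FALSE)
  if (sigma_range[1] == sigma_range[2]) return(sigma_range[1])
  exp(seq(log(sigma_range[1]), log(sigma_range[2]), length.out = n_scales))
}

.empty_spots <- function() {
  out <- data.frame(row = numeric(0), col = numeric(0),
                    scale_sigma = numeric(0), response = numeric(0),
                    peak_intensity = numeric(0))
  class(out) <- c("spot_table", "data.frame")
  out
}

.detect_spots_core <- function(image, mask, resp, sigmas,
                               peak_rel_threshold, min_snr = 5) {
  n_scales <- length(sigmas)
  nr <- nrow(image); nc <- ncol(image)
  top <- max(vapply(resp, function(r) max(r[mask], -Inf), 0))
  # a flat image leaves only FFT round-off in the response; treat any
  # maximum at round-off scale as "no blob anywhere"
  if (!is.finite(top) || top <= 1e-9 * max(1, max(abs(image[mask]))))
    return(.empty_spots())
  smax <- lapply(resp, .neigh_max3)
  cand <- list()
  for (s in seq_len(n_scales)) {
    nm <- smax[[s]]
    if (s > 1L) nm <- pmax.int(nm, smax[[s - 1L]])
    if (s < n_scales) nm <- pmax.int(nm, smax[[s + 1L]])
    floor_s <- if (min_snr > 0) min_snr * stats::mad(resp[[s]][mask]) else 0
    hit <- mask & resp[[s]] >= nm & resp[[s]] >= peak_rel_threshold * top &
      resp[[s]] >= floor_s
    if (any(hit)) {
      ij <- which(hit, arr.ind = TRUE)
      cand[[length(cand) + 1L]] <- cbind(ij, s = s, r = resp[[s]][hit])
    }
  }
  if (!length(cand)) return(.empty_spots())
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, "r"]), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  rows <- cand[, "row"]; cols <- cand[, "col"]
  for (i in seq_len(nrow(cand))) {       # greedy radius suppression
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1L):nrow(cand)
      d2 <- (rows[later] - rows[i])^2 + (cols[later] - cols[i])^2
      keep[later][d2 <= sigmas[cand[i, "s"]]^2] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(row = numeric(nrow(cand)), col = numeric(nrow(cand)),
                    scale_sigma = sigmas[cand[, "s"]],
                    response = cand[, "r"],
                    peak_intensity = NA_real_)
  for (i in seq_len(nrow(cand))) {
    ri <- cand[i, "row"]; ci <- cand[i, "col"]; si <- cand[i, "s"]
    sl <- resp[[si]]
    dr <- dc <- 0
    if (ri > 1L && ri < nr)
      dr <- .parabolic_offset(sl[ri - 1L, ci], sl[ri, ci], sl[ri + 1L, ci])
    if (ci > 1L && ci < nc)
      dc <- .parabolic_offset(sl[ri, ci - 1L], sl[ri, ci], sl[ri, ci + 1L])
    out$row[i] <- (ri - 1L) + dr        # 0-based sub-pixel coordinates
    out$col[i] <- (ci - 1L) + dc
    out$peak_intensity[i] <- image[ri, ci]
  }
  class(out) <- c("spot_table", "data.frame")
  out
}

# detect spots in both channels with one forward FFT: the LoG kernel FFT is
# real, so convolving yfp + 1i * cfp carries the YFP response in the real
# part and the CFP response in the imaginary part
.detect_spots_pair <- function(yfp, cfp, mask, sigma_range, n_scales,
                               peak_rel_threshold, min_snr = 5) {
  sigmas <- .scale_grid(sigma_range, n_scales)
  cplx <- .log_responses_cplx(stats::fft(yfp + (0 + 1i) * cfp),
                              nrow(yfp), ncol(yfp), sigmas)
  list(
    yfp = .detect_spots_core(yfp, mask, lapply(cplx, Re), sigmas,
                             peak_rel_threshold, min_snr),
    cfp = .detect_spots_core(cfp, mask, lapply(cplx, Im), sigmas,
                             peak_rel_threshold, min_snr)
  )
}

#' Binary co-localization call from two spot lists
#'
#' Operationalizes the visual "same location" criterion: a CFP (locus
#' marker) spot is considered co-localized when a YFP (reporter) spot lies
#' within `d_max_px` of its centroid. Matching is greedy nearest-neighbour
#' in order of decreasing CFP spot response; each YFP spot is used at most
#' once, and a distance of exactly `d_max_px` counts as matched (closed
#' boundary). The call is `TRUE` iff at least one CFP spot is matched, so
#' enlarging `d_max_px` can only turn calls from `FALSE` to `TRUE`.
#'
#' @param yfp_spots,cfp_spots spot tables from [detect_spots()] for the two
#'   channels of one nucleus.
#' @param d_max_px maximum centroid distance in pixels (default 2).
#' @return A list with `call` (logical) and `pairs` (data frame:
#'   `cfp_index`, `yfp_index`, `distance_px`), empty when nothing matches.
#' @export
call_colocalization <- function(yfp_spots, cfp_spots, d_max_px = 2) {
  if (!is.numeric(d_max_px) || d_max_px <= 0)
    stop("call_colocalization: d_max_px must be positive", call. = FALSE)
  pairs <- data.frame(cfp_index = integer(0), yfp_index = integer(0),
                      distance_px = numeric(0))
  if (!nrow(cfp_spots) || !nrow(yfp_spots))
    return(list(call = FALSE, pairs = pairs))
  used <- rep(FALSE, nrow(yfp_spots))
  for (i in seq_len(nrow(cfp_spots))) {
    d <- sqrt((yfp_spots$row - cfp_spots$row[i])^2 +
                (yfp_spots$col - cfp_spots$col[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= d_max_px) {
      used[j] <- TRUE
      pairs <- rbind(pairs, data.frame(cfp_index = i, yfp_index = j,
                                       distance_px = d[j]))
    }
  }
  list(call = nrow(pairs) > 0, pairs = pairs)
}

#' Analysis configuration
#'
#' Collects the tunable settings of the per-nucleus analysis. Defaults were
#' chosen on simulated presets and are recorded in every result.
#'
#' @param min_area_px minimum nucleus area accepted by [segment_nucleus()].
#' @param min_separation class-separation requirement of [segment_nucleus()].
#' @param sigma_range,n_scales,peak_rel_threshold,min_snr spot-detection
#'   settings, see [detect_spots()].
#' @param d_max_px spot-matching distance, see [call_colocalization()].
#' @param alpha significance level used by [compare_groups()].
#' @return A named list of class `coloc_config`.
#' @export
coloc_config <- function(min_area_px = 50L, min_separation = 3,
                         sigma_range = c(1, 4),
                         n_scales = 3L, peak_rel_threshold = 0.3,
                         min_snr = 5, d_max_px = 2, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1)
    stop("coloc_config: alpha must be in (0, 1)", call. = FALSE)
  structure(list(min_area_px = as.integer(min_area_px),
                 min_separation = as.numeric(min_separation),
                 sigma_range = as.numeric(sigma_range),
                 n_scales = as.integer(n_scales),
                 peak_rel_threshold = as.numeric(peak_rel_threshold),
                 min_snr = as.numeric(min_snr),
                 d_max_px = as.numeric(d_max_px),
                 alpha = as.numeric(alpha)),
            class = "coloc_config")
}

#' Analyze one nucleus image pair
#'
#' Runs the full per-nucleus pipeline: nucleus segmentation from the YFP
#' channel, in-mask PCC, spot detection in both channels, and the binary
#' co-localization call. Failures are recorded as explicit statuses, never
#' dropped: `"segmentation_failure"` when no nucleus is found (PCC and call
#' unavailable, call counted as `FALSE`), `"undefined_pcc"` when a channel
#' has zero variance inside the mask (nucleus still contributes spots and a
#' call, and counts in frequency statistics).
#'
#' @param pair a `nucleus_pair` (from the simulator or [read_cohort()]).
#' @param config a [coloc_config()].
#' @return An object of class `coloc_record`: `nucleus_id`, `group`,
#'   `frame`, `time_min`, `status`, `threshold_used`, `n_mask_px`, `pcc`,
#'   `yfp_spots`, `cfp_spots`, `coloc_call`, `matched_pairs`, `config`.
#' @export
#' @examples
#' sim <- simulate_nucleus(preset_params("her1", seed = 1))
#' rec <- analyze_nucleus(sim$pair)
#' c(rec$status, round(rec$pcc, 3), rec$coloc_call)
analyze_nucleus <- function(pair, config = coloc_config()) {
  stopifnot(inherits(pair, "nucleus_pair"), inherits(config, "coloc_config"))
  rec <- list(nucleus_id = pair$nucleus_id, group = pair$group,
              frame = pair$frame, time_min = pair$time_min,
              status = "ok", threshold_used = NA_real_,
              n_mask_px = NA_integer_, pcc = NA_real_,
              yfp_spots = NULL, cfp_spots = NULL,
              coloc_call = FALSE, matched_pairs = NULL, config = config)
  class(rec) <- "coloc_record"
  mask <- tryCatch(segment_nucleus(pair$yfp, config$min_area_px,
                                   config$min_separation),
                   error = function(e) e)
  if (inherits(mask, "error")) {
    rec$status <- "segmentation_failure"
    return(rec)
  }
  rec$threshold_used <- mask$threshold_used
  rec$n_mask_px <- mask$area_px
  pcc <- tryCatch(pearson_cc(pair$yfp, pair$cfp, mask),
                  error = function(e) e)
  if (inherits(pcc, "nucoloc_undefined_pcc")) {
    rec$status <- "undefined_pcc"
  } else if (inherits(pcc, "error")) {
    stop(pcc)
  } else {
    rec$pcc <- pcc
  }
  spots <- .detect_spots_pair(pair$yfp, pair$cfp, mask$mask,
                              config$sigma_range, config$n_scales,
                              config$peak_rel_threshold, config$min_snr)
  rec$yfp_spots <- spots$yfp
  rec$cfp_spots <- spots$cfp
  cl <- call_colocalization(rec$yfp_spots, rec$cfp_spots, config$d_max_px)
  rec$coloc_call <- cl$call
  rec$matched_pairs <- cl$pairs
  rec
}

#' Analyze every nucleus of a cohort
#'
#' @param pairs list of `nucleus_pair` objects.
#' @param config a [coloc_config()].
#' @return A list of `coloc_record` objects, one per input nucleus.
#' @export
analyze_cohort <- function(pairs, config = coloc_config()) {
  lapply(pairs, analyze_nucleus, config = config)
}

#' Tabulate per-nucleus results
#'
#' @param records list of `coloc_record` objects.
#' @return A data frame with one row per nucleus: `nucleus_id`, `group`,
#'   `frame`, `time_min`, `status`, `threshold_used`, `area_px`, `pcc`,
#'   `n_cfp_spots`, `n_yfp_spots`, `coloc_call`, `min_pair_distance_px`.
#' @export
coloc_results <- function(records) {
  stopifnot(all(vapply(records, inherits, TRUE, "coloc_record")))
  one <- function(r) {
    data.frame(
      nucleus_id = r$nucleus_id, group = r$group, frame = r$frame,
      time_min = r$time_min, status = r$status,
      threshold_used = r$threshold_used,
      area_px = ifelse(is.na(r$n_mask_px), NA_integer_, r$n_mask_px),
      pcc = r$pcc,
      n_cfp_spots = if (is.null(r$cfp_spots)) 0L else nrow(r$cfp_spots),
      n_yfp_spots = if (is.null(r$yfp_spots)) 0L else nrow(r$yfp_spots),
      coloc_call = r$coloc_call,
      min_pair_distance_px = if (!is.null(r$matched_pairs) &&
                                 nrow(r$matched_pairs))
        min(r$matched_pairs$distance_px) else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(records, one))
}

#' @export
print.coloc_record <- function(x, ...) {
  cat(sprintf("<coloc_record> %s [%s] status=%s pcc=%s call=%s\n",
              x$nucleus_id, x$group, x$status,
              ifelse(is.na(x$pcc), "NA", sprintf("%.3f", x$pcc)),
              x$coloc_call))
  invisible(x)
}
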