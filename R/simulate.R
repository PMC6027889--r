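#' @title Synthetic two-channel nucleus images with ground truth
#' @name simulate
#' @description
#' The generator draws, in a fixed order so that a seed fully determines the
#' output: the per-nucleus expression factor, the territory centres, the
#' spot position (when `"random"`), and finally the pixel noise. The
#' noise-free expectation is
#' \itemize{
#'   \item YFP: `bg_out` outside the nucleus; inside,
#'     `expression_factor * (yfp_nuc + sum of territory Gaussians +
#'     enrichment * yfp_nuc * G_spot)` where `G_spot` is a unit-peak
#'     Gaussian of width `spot_sigma_cfp` at the spot position;
#'   \item CFP: `bg_out` everywhere plus `cfp_amplitude * G_spot`.
#' }
#' Noise is Poisson shot noise on the photon-scaled expectation plus
#' additive zero-mean Gaussian read noise, clipped at zero. When any noise
#' stage is active the result is quantized to integer detector units
#' (0..65535), which is what a camera reports and what makes 16-bit TIFF
#' round trips exact; noise-free images are returned unquantized so they
#' equal the analytic expectation.
NULL

# squared distance (pixel centres, 0-based) from every pixel to a point
.dist2_grid <- function(image_size, point) {
  dr <- (seq_len(image_size[1]) - 1) - point[1]
  dc <- (seq_len(image_size[2]) - 1) - point[2]
  outer(dr^2, dc^2, `+`)
}

.gauss2d <- function(image_size, center, sigma) {
  exp(-.dist2_grid(image_size, center) / (2 * sigma^2))
}

# uniform point in a disk of radius R about `center` (consumes 2 uniforms)
.runif_disk <- function(center, R) {
  r <- R * sqrt(stats::runif(1))
  th <- 2 * pi * stats::runif(1)
  center + r * c(cos(th), sin(th))
}

.true_mask <- function(p) {
  .dist2_grid(p$image_size, p$nucleus_center) <= p$nucleus_radius^2
}

# noise-free expectation rasters given the realized latent variables
.expectation_rasters <- function(p, expression_factor, territory_centers,
                                 spot_pos) {
  inside <- .true_mask(p)
  spot_g <- .gauss2d(p$image_size, spot_pos, p$spot_sigma_cfp)
  yfp_in <- p$yfp_nuc + p$enrichment * p$yfp_nuc * spot_g
  if (length(territory_centers)) {
    for (tc in territory_centers) {
      yfp_in <- yfp_in +
        p$territory_amplitude * .gauss2d(p$image_size, tc, p$territory_sigma)
    }
  }
  yfp <- matrix(p$bg_out, p$image_size[1], p$image_size[2])
  yfp[inside] <- (expression_factor * yfp_in)[inside]
  cfp <- p$bg_out + p$cfp_amplitude * spot_g
  list(yfp = yfp, cfp = cfp, true_mask = inside)
}

.noise_active <- function(p) is.finite(p$poisson_gain) || p$read_sigma > 0

.apply_noise <- function(mu, p) {
  img <- mu
  if (is.finite(p$poisson_gain)) {
    img[] <- stats::rpois(length(mu), p$poisson_gain * mu) / p$poisson_gain
  }
  if (p$read_sigma > 0) {
    img <- img + stats::rnorm(length(mu), 0, p$read_sigma)
  }
  if (.noise_active(p)) {
    img[] <- pmin(pmax(round(img), 0), 65535)
  }
  img
}

# latent variables drawn in fixed order (expression, territories, spot)
.draw_latents <- function(p) {
  ef <- if (p$expression_scale_sd > 0) {
    stats::rlnorm(1, meanlog = -p$expression_scale_sd^2 / 2,
                  sdlog = p$expression_scale_sd)
  } else 1
  tc <- list()
  if (p$territory_count > 0L) {
    for (i in seq_len(p$territory_count)) {
      tc[[i]] <- .runif_disk(p$nucleus_center, 0.6 * p$nucleus_radius)
    }
  }
  # uniform over the whole disk: the locus position must be spatially
  # unbiased within the nucleus, otherwise shared central tendency with the
  # territory signal induces spurious positive PCC in unenriched nuclei
  sp <- if (identical(p$spot_position, "random")) {
    .runif_disk(p$nucleus_center, p$nucleus_radius)
  } else as.numeric(p$spot_position)
  list(expression_factor = ef, territory_centers = tc, spot_position = sp)
}

.new_pair <- function(yfp, cfp, nucleus_id, group, frame, time_min, params,
                      truth) {
  structure(list(yfp = yfp, cfp = cfp, nucleus_id = nucleus_id,
                 group = group, frame = frame, time_min = time_min,
                 params = params, truth = truth),
            class = "nucleus_pair")
}

#' Simulate one synthetic two-channel nucleus image
#'
#' @param params a [sim_params()] object.
#' @return A list with elements `pair` (class `nucleus_pair`: `yfp` and
#'   `cfp` intensity matrices plus metadata) and `truth` (class
#'   `ground_truth`: the true nucleus mask, realized spot position,
#'   enrichment and expression factor). `pair$truth` carries the same
#'   ground truth for convenience.
#' @export
#' @examples
#' sim <- simulate_nucleus(preset_params("her1", seed = 1))
#' sum(sim$truth$true_mask)
simulate_nucleus <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  set.seed(params$seed)
  lat <- .draw_latents(params)
  ex <- .expectation_rasters(params, lat$expression_factor,
                             lat$territory_centers, lat$spot_position)
  yfp <- .apply_noise(ex$yfp, params)
  cfp <- .apply_noise(ex$cfp, params)
  truth <- structure(list(true_mask = ex$true_mask,
                          spot_position = lat$spot_position,
                          enrichment_used = params$enrichment,
                          expression_factor = lat$expression_factor,
                          territory_centers = lat$territory_centers,
                          spot_track = NULL),
                     class = "ground_truth")
  pair <- .new_pair(yfp, cfp, nucleus_id = "nucleus_1", group = NA_character_,
                    frame = 0L, time_min = 0, params = params, truth = truth)
  list(pair = pair, truth = truth)
}

#' Define one cohort group for the simulator
#'
#' @param label group label (e.g. a genotype or condition name).
#' @param params a [sim_params()] object shared by the group.
#' @param n number of nuclei (>= 1).
#' @return A `cohort_group` list.
#' @export
cohort_group <- function(label, params, n) {
  stopifnot(is.character(label), length(label) == 1L,
            inherits(params, "sim_params"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("cohort_group: n must be >= 1", call. = FALSE)
  structure(list(label = label, params = params, n = n),
            class = "cohort_group")
}

# per-nucleus seed derived from the master seed by a fixed affine counter
# scheme; kept below 2^31 - 1 so it is a valid R integer seed
.derive_seed <- function(master, group_index, nucleus_index) {
  as.integer((abs(as.double(master)) + 1000003 * group_index +
                9176 * nucleus_index) %% 2147483629)
}

#' Simulate a cohort of nuclei across one or more groups
#'
#' Each nucleus gets its own seed derived deterministically from the master
#' seed, group index and nucleus index, so expression factors, territory
#' layouts and spot positions are i.i.d. across nuclei while the whole
#' cohort is exactly reproducible.
#'
#' @param groups a list of [cohort_group()] objects (a single group may be
#'   passed bare).
#' @param seed master integer seed.
#' @return A list of `nucleus_pair` objects, each carrying its group label,
#'   a unique `nucleus_id`, and its ground truth.
#' @export
#' @examples
#' groups <- list(
#'   cohort_group("her1", preset_params("her1"), 5),
#'   cohort_group("laco_only", preset_params("laco_only"), 5)
#' )
#' pairs <- simulate_cohort(groups, seed = 42)
#' table(vapply(pairs, function(p) p$group, ""))
simulate_cohort <- function(groups, seed) {
  if (inherits(groups, "cohort_group")) groups <- list(groups)
  if (!length(groups)) stop("simulate_cohort: empty group list", call. = FALSE)
  stopifnot(all(vapply(groups, inherits, TRUE, "cohort_group")))
  out <- list()
  for (g in seq_along(groups)) {
    grp <- groups[[g]]
    for (i in seq_len(grp$n)) {
      p_i <- grp$params
      p_i$seed <- .derive_seed(seed, g, i)
      sim <- simulate_nucleus(p_i)
      pair <- sim$pair
      pair$group <- grp$label
      pair$nucleus_id <- sprintf("%s_%03d", grp$label, i)
      out[[length(out) + 1L]] <- pair
    }
  }
  out
}

# radial reflection keeping the spot inside a disk of radius `bound`
.reflect_into_disk <- function(pos, center, bound) {
  v <- pos - center
  repeat {
    r <- sqrt(sum(v^2))
    if (r <= bound || r == 0) break
    v <- v * (2 * bound / r - 1)
  }
  center + v
}

#' Simulate a time-lapse series of one nucleus
#'
#' The spot performs a bounded random walk inside the nucleus (Gaussian
#' steps of standard deviation `walk_sd` per frame, reflected radially at a
#' boundary `2 * spot_sigma_cfp` inside the nucleus edge so the blob stays
#' within the nucleus). Expression factor and territory layout are drawn
#' once (same cell throughout); pixel noise is independent per frame.
#' Frame timestamps are `frame_interval_min * (0:(n_frames - 1))` minutes.
#'
#' @param params a [sim_params()] object with `n_frames >= 2`.
#' @return A list with `frames` (list of `nucleus_pair`, one per frame, each
#'   with `frame` index and `time_min` timestamp) and `truth` (class
#'   `ground_truth`, with `spot_track` an `n_frames` x 2 matrix of per-frame
#'   spot positions).
#' @export
#' @examples
#' tl <- simulate_timelapse(preset_params("rex1", n_frames = 11, seed = 3))
#' vapply(tl$frames, function(f) f$time_min, 0)
simulate_timelapse <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  if (params$n_frames < 2L)
    stop("simulate_timelapse: n_frames must be >= 2", call. = FALSE)
  set.seed(params$seed)
  lat <- .draw_latents(params)
  bound <- max(params$nucleus_radius - 2 * params$spot_sigma_cfp,
               params$spot_sigma_cfp)
  track <- matrix(NA_real_, params$n_frames, 2L,
                  dimnames = list(NULL, c("row", "col")))
  pos <- .reflect_into_disk(lat$spot_position, params$nucleus_center, bound)
  frames <- vector("list", params$n_frames)
  for (t in seq_len(params$n_frames)) {
    if (t > 1L && params$walk_sd > 0) {
      pos <- .reflect_into_disk(pos + stats::rnorm(2, 0, params$walk_sd),
                                params$nucleus_center, bound)
    }
    track[t, ] <- pos
    ex <- .expectation_rasters(params, lat$expression_factor,
                               lat$territory_centers, pos)
    yfp <- .apply_noise(ex$yfp, params)
    cfp <- .apply_noise(ex$cfp, params)
    frames[[t]] <- .new_pair(
      yfp, cfp, nucleus_id = "nucleus_1", group = NA_character_,
      frame = t - 1L, time_min = params$frame_interval_min * (t - 1),
      params = params,
      truth = NULL
    )
  }
  truth <- structure(list(true_mask = .true_mask(params),
                          spot_position = track[1L, ],
                          enrichment_used = params$enrichment,
                          expression_factor = lat$expression_factor,
                          territory_centers = lat$territory_centers,
                          spot_track = track),
                     class = "ground_truth")
  for (t in seq_along(frames)) {
    tr <- truth
    tr$spot_position <- track[t, ]
    frames[[t]]$truth <- tr
  }
  list(frames = frames, truth = truth)
}

#' @export
print.nucleus_pair <- function(x, ...) {
  cat(sprintf("<nucleus_pair> %s (group %s, frame %d, t = %g min), %d x %d px\n",
              x$nucleus_id, x$group, x$frame, x$time_min,
              nrow(x$yfp), ncol(x$yfp)))
  invisible(x)
}
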