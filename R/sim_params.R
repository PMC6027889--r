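#' Simulation parameters for a synthetic two-channel nucleus image
#'
#' Bundles every knob of the synthetic image generator into a validated
#' parameter object. The generator emulates single-nucleus two-channel
#' confocal acquisition: a roughly circular nucleus filled with a diffuse
#' YFP reporter signal, a small number of broad chromosome-territory
#' enrichments, and a single punctate CFP locus marker whose position may
#' also carry a tunable YFP co-enrichment.
#'
#' All coordinates are 0-based `(row, col)` pixel positions; intensities are
#' arbitrary units (a.u.). Distances between a pixel and the nucleus centre
#' are measured from pixel centres, and a pixel is "inside" the nucleus when
#' that distance is at most `nucleus_radius`.
#'
#' @param image_size integer `(rows, cols)`; default 128 x 128. Per-nucleus
#'   crops are analyzed, so the raster only needs to contain one nucleus;
#'   larger acquisition geometries (e.g. 640 x 640 fields, 512 x 256
#'   time-lapse frames) are available by passing the size explicitly.
#' @param nucleus_center `(row, col)` of the nucleus centre in pixels.
#' @param nucleus_radius nucleus disk radius in pixels.
#' @param bg_out extranuclear background intensity (a.u.).
#' @param yfp_nuc diffuse nuclear YFP level before expression scaling (a.u.).
#' @param expression_scale_sd log-scale standard deviation of the per-nucleus
#'   multiplicative expression factor, drawn lognormal with mean 1
#'   (`meanlog = -sd^2/2`). Models cell-to-cell and animal-to-animal
#'   variation in reporter expression; `0` fixes the factor at exactly 1.
#' @param territory_count number of broad chromosome-territory blobs (>= 0).
#' @param territory_amplitude peak amplitude of each territory Gaussian (a.u.,
#'   before expression scaling).
#' @param territory_sigma territory Gaussian width in pixels (default
#'   `nucleus_radius / 3`).
#' @param spot_position `(row, col)` of the CFP locus spot, or `"random"` to
#'   draw it uniformly inside the central part of the nucleus per nucleus.
#'   A fixed position must lie inside the nucleus disk.
#' @param spot_sigma_cfp Gaussian width of the CFP spot in pixels.
#' @param cfp_amplitude peak amplitude of the CFP spot (a.u.).
#' @param enrichment dimensionless >= 0: YFP amplitude at the spot position
#'   as a multiple of `yfp_nuc`. `0` gives a spot with no YFP co-enrichment
#'   (the LacO-only / male-like condition); large values give strong
#'   co-enrichment (the her-1-like condition). Expressed relative to the
#'   diffuse level so that the per-nucleus expression factor cancels from
#'   the noise-free correlation structure.
#' @param poisson_gain photons per a.u. for the Poisson (shot-noise) stage;
#'   `Inf` disables shot noise.
#' @param read_sigma standard deviation of additive Gaussian read noise
#'   (a.u.); `0` disables it.
#' @param n_frames number of time-lapse frames (>= 1; 1 = single snapshot).
#' @param frame_interval_min minutes between frames (default 30).
#' @param walk_sd per-frame step standard deviation (pixels) of the spot's
#'   bounded random walk in time-lapse mode; `0` freezes the spot.
#' @param seed integer seed; identical parameters plus seed give
#'   bit-identical images.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [preset_params()] for named cohort presets,
#'   [simulate_nucleus()], [simulate_cohort()], [simulate_timelapse()].
#' @export
#' @examples
#' p <- sim_params(enrichment = 4, seed = 1)
#' sim <- simulate_nucleus(p)
#' range(sim$pair$yfp)
sim_params <- function(image_size = c(128L, 128L),
                       nucleus_center = c(64, 64),
                       nucleus_radius = 40,
                       bg_out = 10,
                       yfp_nuc = 100,
                       expression_scale_sd = 0.3,
                       territory_count = 2L,
                       territory_amplitude = 60,
                       territory_sigma = nucleus_radius / 3,
                       spot_position = "random",
                       spot_sigma_cfp = 2,
                       cfp_amplitude = 300,
                       enrichment = 0,
                       poisson_gain = 1,
                       read_sigma = 2,
                       n_frames = 1L,
                       frame_interval_min = 30,
                       walk_sd = 1,
                       seed = 1L) {
  p <- list(
    image_size = as.integer(image_size),
    nucleus_center = as.numeric(nucleus_center),
    nucleus_radius = as.numeric(nucleus_radius),
    bg_out = as.numeric(bg_out),
    yfp_nuc = as.numeric(yfp_nuc),
    expression_scale_sd = as.numeric(expression_scale_sd),
    territory_count = as.integer(territory_count),
    territory_amplitude = as.numeric(territory_amplitude),
    territory_sigma = as.numeric(territory_sigma),
    spot_position = spot_position,
    spot_sigma_cfp = as.numeric(spot_sigma_cfp),
    cfp_amplitude = as.numeric(cfp_amplitude),
    enrichment = as.numeric(enrichment),
    poisson_gain = as.numeric(poisson_gain),
    read_sigma = as.numeric(read_sigma),
    n_frames = as.integer(n_frames),
    frame_interval_min = as.numeric(frame_interval_min),
    walk_sd = as.numeric(walk_sd),
    seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  fail <- function(field, msg) {
    stop(sprintf("invalid sim_params: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (length(p$image_size) != 2L || any(p$image_size < 2L))
    fail("image_size", "must be two integers >= 2")
  if (length(p$nucleus_center) != 2L || any(!is.finite(p$nucleus_center)))
    fail("nucleus_center", "must be two finite numbers")
  if (!is.finite(p$nucleus_radius) || p$nucleus_radius <= 0)
    fail("nucleus_radius", "must be positive")
  # nucleus must fit fully inside the image (0-based pixel coordinates)
  lo <- p$nucleus_center - p$nucleus_radius
  hi <- p$nucleus_center + p$nucleus_radius
  if (any(lo < 0) || any(hi > p$image_size - 1L))
    fail("nucleus_radius", "nucleus disk does not fit inside the image")
  for (f in c("bg_out", "yfp_nuc", "territory_amplitude", "territory_sigma",
              "spot_sigma_cfp", "cfp_amplitude", "enrichment",
              "expression_scale_sd", "read_sigma", "walk_sd")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]) ||
        p[[f]] < 0)
      fail(f, "must be a single non-negative number")
  }
  if (p$spot_sigma_cfp <= 0) fail("spot_sigma_cfp", "must be positive")
  if (!(is.infinite(p$poisson_gain) || p$poisson_gain > 0))
    fail("poisson_gain", "must be positive or Inf")
  if (p$territory_count < 0L) fail("territory_count", "must be >= 0")
  if (!identical(p$spot_position, "random")) {
    sp <- as.numeric(p$spot_position)
    if (length(sp) != 2L || any(!is.finite(sp)))
      fail("spot_position", "must be (row, col) or \"random\"")
    d <- sqrt(sum((sp - p$nucleus_center)^2))
    if (d > p$nucleus_radius)
      fail("spot_position", "must lie inside the nucleus disk")
  }
  if (p$n_frames < 1L) fail("n_frames", "must be >= 1")
  if (p$frame_interval_min < 0) fail("frame_interval_min", "must be >= 0")
  if (is.na(p$seed)) fail("seed", "must be an integer")
  invisible(p)
}

#' Named cohort presets for the simulator
#'
#' Maps experiment-style condition names to enrichment levels of the
#' synthetic generator. The presets emulate the qualitative contrast
#' structure of a mintbody/LacO-LacI co-localization experiment: a strongly
#' methylation-marked array (`"her1"`), an unmarked array (`"laco_only"`), a
#' weakly marked array (`"abts1b"`), an array rescued by a single
#' recruitment element (`"rex1"`), and a male-like condition with neither
#' array enrichment nor X-territory enrichment (`"male"`). Enrichment
#' levels are generator settings chosen to reproduce ordering and sign, not
#' calibrated absolute values.
#'
#' @param preset one of `"her1"`, `"laco_only"`, `"abts1b"`, `"rex1"`,
#'   `"male"`.
#' @param ... overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
#' @examples
#' preset_params("her1", seed = 7)$enrichment
preset_params <- function(preset = c("her1", "laco_only", "abts1b", "rex1",
                                     "male"),
                          ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    her1      = list(enrichment = 4),
    laco_only = list(enrichment = 0),
    abts1b    = list(enrichment = 0.5),
    rex1      = list(enrichment = 3),
    male      = list(enrichment = 0, territory_count = 0L)
  )
  args <- utils::modifyList(base, list(...))
  do.call(sim_params, args)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  image %d x %d px, nucleus r = %g px at (%g, %g)\n",
              x$image_size[1], x$image_size[2], x$nucleus_radius,
              x$nucleus_center[1], x$nucleus_center[2]))
  cat(sprintf("  YFP: bg %g, nuclear %g (expr sd %g), %d territories\n",
              x$bg_out, x$yfp_nuc, x$expression_scale_sd, x$territory_count))
  cat(sprintf("  CFP spot: amp %g, sigma %g px; YFP enrichment x%g\n",
              x$cfp_amplitude, x$spot_sigma_cfp, x$enrichment))
  cat(sprintf("  noise: gain %g, read sd %g; frames %d @ %g min; seed %d\n",
              x$poisson_gain, x$read_sigma, x$n_frames,
              x$frame_interval_min, x$seed))
  invisible(x)
}
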