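test_that("parameter invariants are enforced with the offending field named", {
  expect_error(sim_params(nucleus_radius = 80), "nucleus_radius")
  expect_error(sim_params(spot_position = c(0, 0)), "spot_position")
  expect_error(sim_params(enrichment = -1), "enrichment")
  expect_error(sim_params(cfp_amplitude = -5), "cfp_amplitude")
  expect_error(sim_params(n_frames = 0), "n_frames")
  expect_silent(validate_sim_params <- sim_params())
})

test_that("identical parameters and seed give bit-identical images", {
  p <- preset_params("her1", seed = 123)
  a <- simulate_nucleus(p)
  b <- simulate_nucleus(p)
  expect_identical(a$pair$yfp, b$pair$yfp)
  expect_identical(a$pair$cfp, b$pair$cfp)
  expect_identical(a$truth$spot_position, b$truth$spot_position)
})

test_that("without enrichment the noise-free YFP is flat inside the nucleus", {
  p <- noise_free(enrichment = 0, territory_count = 0L,
                  spot_position = c(64, 64), seed = 1)
  sim <- simulate_nucleus(p)
  inside <- sim$truth$true_mask
  expect_equal(length(unique(sim$pair$yfp[inside])), 1L)
  # with enrichment the spot pixel exceeds same-radius points
  p2 <- noise_free(enrichment = 2, territory_count = 0L,
                   spot_position = c(64, 64), seed = 1)
  sim2 <- simulate_nucleus(p2)
  expect_gt(sim2$pair$yfp[65, 65], sim2$pair$yfp[65 + 20, 65])
})

test_that("noise-free expectation rasters reproduce the direct-formula PCC", {
  p <- noise_free(enrichment = 2, territory_count = 0L,
                  spot_position = c(60, 70), seed = 5)
  sim <- simulate_nucleus(p)
  m <- sim$truth$true_mask
  expect_equal(pearson_cc(sim$pair$yfp, sim$pair$cfp, m),
               oracle_pcc(sim$pair$yfp[m], sim$pair$cfp[m]),
               tolerance = 1e-12)
})

test_that("expression factor scales the in-nucleus YFP expectation affinely", {
  # territory_count = 0 and a fixed spot make the expression factor the
  # only random draw, so the sd = 0 run shares the same layout
  base <- noise_free(territory_count = 0L, spot_position = c(60, 70),
                     enrichment = 1, seed = 9)
  varied <- sim_params(poisson_gain = Inf, read_sigma = 0,
                       expression_scale_sd = 0.5, territory_count = 0L,
                       spot_position = c(60, 70), enrichment = 1, seed = 9)
  a <- simulate_nucleus(base)
  b <- simulate_nucleus(varied)
  f <- b$truth$expression_factor
  inside <- a$truth$true_mask
  expect_false(isTRUE(all.equal(f, 1)))
  expect_equal(b$pair$yfp[inside], f * a$pair$yfp[inside], tolerance = 1e-12)
  # CFP carries no expression scaling
  expect_equal(b$pair$cfp, a$pair$cfp, tolerance = 1e-12)
})

test_that("ground truth is a filled disk containing the spot", {
  for (seed in 1:10) {
    sim <- simulate_nucleus(preset_params("her1", seed = seed))
    p <- sim$pair$params
    d2 <- outer(((seq_len(p$image_size[1]) - 1) - p$nucleus_center[1])^2,
                ((seq_len(p$image_size[2]) - 1) - p$nucleus_center[2])^2,
                `+`)
    expect_identical(sim$truth$true_mask, d2 <= p$nucleus_radius^2)
    sp <- sim$truth$spot_position
    expect_lte(sqrt(sum((sp - p$nucleus_center)^2)), p$nucleus_radius)
  }
})

test_that("cohorts are reproducible, labelled, and sized as requested", {
  groups <- list(cohort_group("a", preset_params("her1"), 4),
                 cohort_group("b", preset_params("laco_only"), 3))
  x <- simulate_cohort(groups, seed = 77)
  y <- simulate_cohort(groups, seed = 77)
  expect_length(x, 7L)
  expect_identical(lapply(x, `[[`, "yfp"), lapply(y, `[[`, "yfp"))
  expect_identical(vapply(x, `[[`, "", "group"),
                   c(rep("a", 4), rep("b", 3)))
  expect_identical(anyDuplicated(vapply(x, `[[`, "", "nucleus_id")), 0L)
  # nuclei differ from one another (independent latent draws)
  expect_false(identical(x[[1]]$yfp, x[[2]]$yfp))
  expect_error(simulate_cohort(list(), seed = 1), "empty")
})

test_that("zero expression spread gives expression factor exactly 1", {
  g <- cohort_group("g", sim_params(expression_scale_sd = 0), 5)
  pairs <- simulate_cohort(list(g), seed = 3)
  ef <- vapply(pairs, function(p) p$truth$expression_factor, 0)
  expect_identical(ef, rep(1, 5))
})

test_that("time-lapse timestamps span 0..300 min at the default cadence", {
  tl <- simulate_timelapse(preset_params("rex1", n_frames = 11, seed = 4))
  expect_identical(vapply(tl$frames, `[[`, 0, "time_min"), seq(0, 300, 30))
  expect_identical(nrow(tl$truth$spot_track), 11L)
})

test_that("a frozen walk keeps the spot position identical in all frames", {
  tl <- simulate_timelapse(preset_params("rex1", n_frames = 5, walk_sd = 0,
                                         seed = 8))
  expect_identical(apply(tl$truth$spot_track, 2, function(x)
    length(unique(x))), c(row = 1L, col = 1L))
})

test_that("the random walk is reflected so the spot never leaves the nucleus", {
  p <- preset_params("rex1", n_frames = 40, walk_sd = 25, seed = 13)
  tl <- simulate_timelapse(p)
  d <- sqrt(rowSums((tl$truth$spot_track -
                       matrix(p$nucleus_center, 40, 2, byrow = TRUE))^2))
  expect_true(all(d <= p$nucleus_radius))
})

test_that("a frozen noise-free series has constant per-frame PCC", {
  p <- sim_params(poisson_gain = Inf, read_sigma = 0, walk_sd = 0,
                  enrichment = 2, n_frames = 4, spot_position = c(60, 60),
                  seed = 2)
  tl <- simulate_timelapse(p)
  pccs <- vapply(tl$frames, function(f)
    pearson_cc(f$yfp, f$cfp, tl$truth$true_mask), 0)
  expect_equal(max(pccs) - min(pccs), 0, tolerance = 1e-12)
})
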