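mask5 <- function() {
  m <- matrix(FALSE, 3, 5)
  m[2, ] <- TRUE
  m
}
as_img <- function(v) {
  m <- matrix(0, 3, 5)
  m[2, ] <- v
  m
}

test_that("pearson_cc reproduces hand-computed values and limits", {
  m <- mask5()
  expect_equal(pearson_cc(as_img(1:5), as_img(1:5), m), 1.0)
  expect_equal(pearson_cc(as_img(1:5), as_img(-(1:5) + 100), m), -1.0)
  expect_equal(pearson_cc(as_img(1:5), as_img(c(1, 3, 2, 5, 4)), m),
               oracle_pcc(1:5, c(1, 3, 2, 5, 4)), tolerance = 1e-15)
})

test_that("pearson_cc is symmetric, affine-invariant and bounded", {
  set.seed(42)
  for (i in 1:20) {
    n <- 100L
    m <- matrix(FALSE, 20, 20)
    m[sample(400, n)] <- TRUE
    y <- matrix(rgamma(400, 2, 0.1), 20, 20)
    c_ <- matrix(rgamma(400, 2, 0.1), 20, 20)
    r <- pearson_cc(y, c_, m)
    expect_gte(r, -1); expect_lte(r, 1)
    expect_equal(r, pearson_cc(c_, y, m), tolerance = 1e-12)
    expect_equal(r, pearson_cc(3.7 * y + 11, 0.2 * c_ + 5, m),
                 tolerance = 1e-9)
    expect_equal(r, oracle_pcc(y[m], c_[m]), tolerance = 1e-12)
  }
})

test_that("degenerate PCC inputs raise typed errors", {
  m <- mask5()
  expect_error(pearson_cc(as_img(1:5), matrix(1, 2, 2), m), "shapes")
  expect_error(pearson_cc(as_img(rep(2, 5)), as_img(1:5), m),
               class = "nucoloc_undefined_pcc")
  m2 <- matrix(FALSE, 3, 5); m2[2, 1:2] <- TRUE
  expect_error(pearson_cc(as_img(1:5), as_img(1:5), m2), "3 pixels")
})

test_that("in-mask PCC differs from whole-frame PCC when background exists", {
  sim <- simulate_nucleus(preset_params("laco_only", seed = 6))
  m <- segment_nucleus(sim$pair$yfp)
  whole <- matrix(TRUE, nrow(sim$pair$yfp), ncol(sim$pair$yfp))
  r_mask <- pearson_cc(sim$pair$yfp, sim$pair$cfp, m)
  r_whole <- pearson_cc(sim$pair$yfp, sim$pair$cfp, whole)
  expect_gt(abs(r_whole - r_mask), 0.01)
})

test_that("a single noise-free spot is found within half a pixel", {
  p <- noise_free(enrichment = 0, territory_count = 0L,
                  spot_position = c(60.3, 70.6), seed = 1)
  sim <- simulate_nucleus(p)
  m <- segment_nucleus(sim$pair$yfp)
  spots <- detect_spots(sim$pair$cfp, m)
  expect_identical(nrow(spots), 1L)
  expect_lt(sqrt((spots$row - 60.3)^2 + (spots$col - 70.6)^2), 0.5)
  expect_gt(spots$peak_intensity, 0)
  expect_gt(spots$scale_sigma, 0)
})

test_that("flat in-mask images yield no spots", {
  img <- matrix(7, 32, 32)
  m <- matrix(TRUE, 32, 32)
  expect_identical(nrow(detect_spots(img, m)), 0L)
})

test_that("two separated noise-free spots are both recovered", {
  img <- matrix(10, 96, 96)
  d2a <- outer(((1:96) - 41)^2, ((1:96) - 41)^2, `+`)
  img <- img + 200 * exp(-d2a / (2 * 4))
  d2b <- outer(((1:96) - 41)^2, ((1:96) - 51)^2, `+`)
  img <- img + 180 * exp(-d2b / (2 * 4))
  m <- matrix(TRUE, 96, 96)
  spots <- detect_spots(img, m)
  expect_identical(nrow(spots), 2L)
  got <- spots[order(spots$col), ]
  expect_lt(sqrt((got$row[1] - 40)^2 + (got$col[1] - 40)^2), 0.5)
  expect_lt(sqrt((got$row[2] - 40)^2 + (got$col[2] - 50)^2), 0.5)
})

test_that("spot centroids always lie inside the mask", {
  for (seed in c(3, 4, 5)) {
    sim <- simulate_nucleus(preset_params("her1", seed = seed))
    m <- segment_nucleus(sim$pair$yfp)
    sp <- detect_spots(sim$pair$cfp, m)
    for (i in seq_len(nrow(sp))) {
      expect_true(m$mask[round(sp$row[i]) + 1L, round(sp$col[i]) + 1L])
    }
  }
})

spot_row <- function(row, col, response = rep(1, length(row))) {
  data.frame(row = row, col = col, scale_sigma = rep(2, length(row)),
             response = response, peak_intensity = rep(100, length(row)))
}

test_that("the co-localization call follows the closed distance boundary", {
  a <- spot_row(10, 10)
  expect_identical(call_colocalization(a, a, 2)$call, TRUE)
  expect_equal(call_colocalization(a, a, 2)$pairs$distance_px, 0)
  # CFP spot with no YFP spots: the exclusion case
  none <- spot_row(numeric(0), numeric(0))
  expect_identical(call_colocalization(none, a, 2)$call, FALSE)
  # distance 2.5 > 2 is not a match
  far <- call_colocalization(spot_row(10, 12.5), a, 2)
  expect_identical(far$call, FALSE)
  expect_identical(nrow(far$pairs), 0L)
  # exactly at d_max counts (closed boundary)
  edge <- call_colocalization(spot_row(10, 12), a, 2)
  expect_identical(edge$call, TRUE)
  expect_equal(edge$pairs$distance_px, 2)
})

test_that("calls are monotone in the matching distance", {
  set.seed(9)
  for (i in 1:30) {
    ny <- sample(0:4, 1); nc_ <- sample(1:3, 1)
    ys <- spot_row(runif(ny, 0, 50), runif(ny, 0, 50), runif(ny))
    cs <- spot_row(runif(nc_, 0, 50), runif(nc_, 0, 50), runif(nc_))
    d <- sort(runif(2, 0.5, 20))
    c1 <- call_colocalization(ys, cs, d[1])$call
    c2 <- call_colocalization(ys, cs, d[2])$call
    expect_true(!c1 || c2)
  }
})

test_that("greedy matching uses each reporter spot at most once", {
  ys <- spot_row(10, 10)
  cs <- spot_row(c(10, 10.5), c(10, 10), response = c(2, 1))
  res <- call_colocalization(ys, cs, 2)
  expect_identical(nrow(res$pairs), 1L)
  expect_identical(res$pairs$cfp_index, 1L)
})

test_that("enriched nuclei are called and unenriched nuclei are not", {
  her <- simulate_cohort(list(cohort_group("h", preset_params("her1"), 50)),
                         seed = 1001)
  calls_h <- vapply(analyze_cohort(her), `[[`, TRUE, "coloc_call")
  expect_gte(mean(calls_h), 0.9)
  null <- simulate_cohort(list(cohort_group("n", preset_params("laco_only"),
                                            50)), seed = 1002)
  calls_n <- vapply(analyze_cohort(null), `[[`, TRUE, "coloc_call")
  expect_lte(mean(calls_n), 0.1)
})

test_that("failures surface as statuses, never as dropped nuclei", {
  flatpair <- structure(list(yfp = matrix(abs(rnorm(4096, 10, 2)), 64, 64),
                             cfp = matrix(10, 64, 64),
                             nucleus_id = "bg", group = "g", frame = 0L,
                             time_min = 0, params = NULL, truth = NULL),
                        class = "nucleus_pair")
  rec <- analyze_nucleus(flatpair)
  expect_identical(rec$status, "segmentation_failure")
  expect_identical(rec$coloc_call, FALSE)
  expect_true(is.na(rec$pcc))
  tab <- coloc_results(list(rec))
  expect_identical(nrow(tab), 1L)
  # zero-variance CFP channel: PCC undefined but spots/call still computed
  sim <- simulate_nucleus(noise_free(seed = 2))
  sim$pair$cfp <- matrix(10, 128, 128)
  rec2 <- analyze_nucleus(sim$pair)
  expect_identical(rec2$status, "undefined_pcc")
  expect_true(is.na(rec2$pcc))
  expect_false(is.null(rec2$cfp_spots))
})

test_that("results tables carry the documented per-nucleus columns", {
  sim <- simulate_nucleus(preset_params("her1", seed = 3))
  tab <- coloc_results(list(analyze_nucleus(sim$pair)))
  expect_named(tab, c("nucleus_id", "group", "frame", "time_min", "status",
                      "threshold_used", "area_px", "pcc", "n_cfp_spots",
                      "n_yfp_spots", "coloc_call", "min_pair_distance_px"))
  expect_identical(tab$status, "ok")
  expect_identical(tab$area_px, analyze_nucleus(sim$pair)$n_mask_px)
})
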