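bs6 <- function(v) channel(v, 325, "PpS6",
                           provenance = "rolling_ball(diameter=50)")

test_that("uniform P-pS6 gives equal whole, soma and dendrite means", {
  whole <- lq_mask(matrix(TRUE, 10, 10), "map2")
  soma <- lq_mask(matrix(rep(c(TRUE, FALSE), each = 50), 10, 10), "soma")
  fa <- field_activity(bs6(matrix(3.5, 10, 10)), whole, soma)
  expect_equal(fa$mean_whole, 3.5)
  expect_equal(fa$mean_soma, 3.5)
  expect_equal(fa$mean_dendrite, 3.5)
})

test_that("soma mask covering the whole neuron leaves dendrite undefined", {
  whole <- lq_mask(matrix(TRUE, 6, 6), "map2")
  fa <- field_activity(bs6(matrix(1, 6, 6)), whole, whole)
  expect_equal(fa$area_dendrite, 0)
  expect_true(is.na(fa$mean_dendrite))
  expect_true(fa$valid)
})

test_that("two-compartment arithmetic: whole mean is the area-weighted mean", {
  v <- matrix(0, 10, 10)
  m <- matrix(FALSE, 10, 10); m[1:100] <- TRUE
  s <- matrix(FALSE, 10, 10); s[1:30] <- TRUE
  v[1:30] <- 10; v[31:100] <- 4
  fa <- field_activity(bs6(v), lq_mask(m, "map2"), lq_mask(s, "soma"))
  expect_equal(fa$mean_whole, 5.8)
  expect_equal(fa$mean_soma, 10)
  expect_equal(fa$mean_dendrite, 4)
  expect_identical(fa$area_soma + fa$area_dendrite, fa$area_whole)
})

test_that("partition identity holds at machine precision on renders", {
  sim <- simulate_field(geometry_params(seed = 43),
                        photophysics_params(seed = 43))
  pps6 <- rolling_ball_subtract(get_channel(sim$image, "PpS6"), 50)
  map2 <- auto_threshold(get_channel(sim$image, "MAP2"), "mean")
  soma <- lq_mask(sim$truth$soma_labels$labels > 0L, "truth")
  fa <- field_activity(pps6, map2, soma)
  expect_identical(fa$area_soma + fa$area_dendrite, fa$area_whole)
  expect_equal((fa$mean_soma * fa$area_soma +
                  fa$mean_dendrite * fa$area_dendrite) / fa$area_whole,
               fa$mean_whole, tolerance = 1e-12)
  expect_gte(fa$mean_whole, min(fa$mean_soma, fa$mean_dendrite))
  expect_lte(fa$mean_whole, max(fa$mean_soma, fa$mean_dendrite))
})

test_that("empty MAP2 mask flags the field invalid", {
  fa <- field_activity(bs6(matrix(1, 5, 5)),
                       lq_mask(matrix(FALSE, 5, 5), "map2"),
                       lq_mask(matrix(FALSE, 5, 5), "soma"))
  expect_false(fa$valid)
  expect_equal(fa$reason, "no-neurons")
})

test_that("soma vs dendrite intensity contrast is recovered on renders", {
  # soma intensity k times the proximal-dendrite plateau: use a long decay
  # so dendrites are nearly flat at ~ soma/k
  g <- geometry_params(image_shape = c(300L, 300L), pixel_size = 325,
                       n_neurons = 6, soma_radius_range = c(10, 14),
                       dendrites_per_neuron = 3,
                       dendrite_length_range = c(40, 80),
                       dendrite_width_range = c(2, 4),
                       n_les_per_100um_dendrite = 0, n_les_per_soma = 0,
                       seed = 47)
  sim <- simulate_field(g, photophysics_params(
    pps6_soma_intensity = 600, pps6_dendrite_decay_length = 1e6,
    psf_sigma = 0, poisson_noise = TRUE, gaussian_read_noise_sd = 3,
    shading_amplitude = 0, seed = 47))
  pps6 <- rolling_ball_subtract(get_channel(sim$image, "PpS6"), 50)
  map2 <- auto_threshold(get_channel(sim$image, "MAP2"), "mean")
  soma <- lq_mask(sim$truth$soma_labels$labels > 0L, "truth")
  fa <- field_activity(pps6, map2, soma)
  # infinite decay length: soma and dendrite share the same truth intensity
  expect_equal(fa$mean_soma / fa$mean_dendrite, 1, tolerance = 0.1)
})

test_that("segment_somas: blank image, two disks, synthetic field", {
  blank <- segment_somas(bs6(matrix(0, 40, 40)),
                         lq_mask(matrix(TRUE, 40, 40), "m"))
  expect_equal(nrow(blank$objects), 0)
  v <- matrix(0, 80, 80)
  v[10:30, 10:30] <- 100
  v[50:75, 45:75] <- 120
  two <- segment_somas(bs6(v), lq_mask(matrix(TRUE, 80, 80), "m"),
                       min_soma_area = 100)
  expect_equal(nrow(two$objects), 2)

  g <- geometry_params(image_shape = c(320L, 320L), pixel_size = 325,
                       n_neurons = 12, soma_radius_range = c(9, 12),
                       dendrites_per_neuron = 2,
                       dendrite_length_range = c(30, 60),
                       dendrite_width_range = c(2, 3),
                       n_les_per_100um_dendrite = 0, n_les_per_soma = 0,
                       seed = 53)
  sim <- simulate_field(g, photophysics_params(psf_sigma = 1, seed = 53))
  pps6 <- rolling_ball_subtract(get_channel(sim$image, "PpS6"), 50)
  map2 <- auto_threshold(get_channel(sim$image, "MAP2"), "mean")
  somas <- segment_somas(pps6, map2, min_soma_area = 150)
  truth <- sim$truth$soma_labels$objects
  expect_equal(nrow(somas$objects), 12)
  # one label per soma: every truth soma center falls in a distinct
  # segmented object (blobs may include bright proximal dendrite stubs)
  hit <- somas$labels[cbind(round(truth$centroid_row),
                            round(truth$centroid_col))]
  expect_true(all(hit > 0L))
  expect_equal(length(unique(hit)), 12)
})

test_that("per-soma records report footprint means", {
  lab <- matrix(0L, 20, 20)
  lab[3:6, 3:6] <- 1L; lab[12:16, 12:16] <- 2L
  somas <- labeled_objects(lab, 325)
  v <- matrix(0, 20, 20); v[lab == 1L] <- 7; v[lab == 2L] <- 11
  rec <- per_soma_intensities(bs6(v), somas, image_id = "f1",
                              condition = "ctrl")
  expect_equal(nrow(rec), 2)
  expect_equal(rec$mean_intensity, c(7, 11))
  expect_equal(rec$area, c(16, 25))
  empty <- per_soma_intensities(bs6(v), labeled_objects(matrix(0L, 20, 20),
                                                        325))
  expect_equal(nrow(empty), 0)
})

test_that("percentile shift reproduces the worked example and edge cases", {
  ps <- percentile_shift(1:100, c(80, 90, 10), q = 75)
  expect_equal(ps$threshold, 75.25)
  expect_equal(ps$fraction_above, 2 / 3)
  # self-comparison: fraction near (100 - q)/100
  set.seed(61)
  x <- rnorm(400, 100, 15)
  self <- percentile_shift(x, x, q = 75)
  expect_lt(abs(self$fraction_above - 0.25), 2 / length(x))
  # all-below case
  expect_equal(percentile_shift(11:20, c(1, 2, 3))$fraction_above, 0)
  expect_error(percentile_shift(numeric(0), 1:3), "control")
  expect_error(percentile_shift(1:3, numeric(0)), "treated")
  expect_error(percentile_shift(1:3, 1:3, q = 100), "strictly")
})
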