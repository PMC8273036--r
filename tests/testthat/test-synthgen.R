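test_that("empty field: zero neurons give empty masks and no LEs", {
  g <- geometry_params(n_neurons = 0, seed = 1)
  t0 <- make_geometry(g)
  expect_false(any(t0$map2_mask$values))
  expect_equal(nrow(t0$soma_labels$objects), 0)
  expect_equal(nrow(t0$le_labels$objects), 0)
})

test_that("geometry is bit-for-bit deterministic for a fixed seed", {
  g <- geometry_params(seed = 42)
  t1 <- make_geometry(g)
  t2 <- make_geometry(g)
  expect_identical(t1$map2_mask$values, t2$map2_mask$values)
  expect_identical(t1$soma_labels$labels, t2$soma_labels$labels)
  expect_identical(t1$le_labels$labels, t2$le_labels$labels)
  expect_identical(t1$dendrite_centerlines, t2$dendrite_centerlines)
})

test_that("soma count matches an independent flood-fill component count", {
  g <- geometry_params(image_shape = c(360L, 360L), pixel_size = 325,
                       n_neurons = 12, soma_radius_range = c(9, 13),
                       dendrites_per_neuron = 4,
                       dendrite_length_range = c(30, 60),
                       dendrite_width_range = c(2, 3),
                       n_les_per_100um_dendrite = 0, n_les_per_soma = 0,
                       seed = 8)
  tr <- make_geometry(g)
  expect_equal(nrow(tr$soma_labels$objects), 12)
  soma_mask <- tr$soma_labels$labels > 0L
  expect_equal(oracle_count_components(soma_mask), 12)
})

test_that("geometry invariants hold: LEs inside MAP2, somata inside MAP2", {
  tr <- make_geometry(geometry_params(seed = 3))
  expect_true(all(tr$map2_mask$values[tr$soma_labels$labels > 0L]))
  ids <- tr$le_labels$objects$id
  expect_identical(ids, seq_along(ids))
  # LE centers lie inside the MAP2 mask by construction
  ctr <- round(cbind(tr$le_labels$objects$centroid_row,
                     tr$le_labels$objects$centroid_col))
  expect_true(all(tr$map2_mask$values[ctr]))
})

test_that("soma radius larger than the field is rejected", {
  expect_error(geometry_params(image_shape = c(64L, 64L),
                               soma_radius_range = c(40, 50)),
               "does not fit")
})

test_that("no-recruitment render is uniform over the neuronal surface", {
  g <- geometry_params(seed = 5)
  sim <- simulate_field(g, clean_phys(mtor_enrichment = 1))
  mtor <- sim$image$channels$mTOR
  inside <- mtor[sim$truth$map2_mask$values]
  expect_equal(length(unique(inside)), 1)
  le_px <- sim$truth$le_labels$labels > 0L
  expect_equal(mean(mtor[le_px]),
               mean(mtor[sim$truth$map2_mask$values & !le_px]))
})

test_that("enrichment 2 doubles LE-interior mTOR signal exactly", {
  g <- geometry_params(seed = 5)
  phys <- clean_phys(mtor_enrichment = 2, background_level = 0)
  sim <- simulate_field(g, phys)
  mtor <- sim$image$channels$mTOR
  le_px <- sim$truth$le_labels$labels > 0L
  cyto <- sim$truth$map2_mask$values & !le_px
  expect_equal(mean(mtor[le_px]) / mean(mtor[cyto]), 2)
})

test_that("noise-free mTOR intensity mass matches the closed form", {
  g <- geometry_params(seed = 9)
  phys <- clean_phys(mtor_enrichment = 3, background_level = 50)
  sim <- simulate_field(g, phys)
  tr <- sim$truth
  n_px <- prod(dim(tr$map2_mask$values))
  area_map2 <- sum(tr$map2_mask$values)
  le_in <- tr$le_labels$labels > 0L & tr$map2_mask$values
  expected <- 50 * n_px + 300 * area_map2 + 300 * (3 - 1) * sum(le_in)
  expect_equal(sum(sim$image$channels$mTOR), expected)
})

test_that("Poisson noise gives per-pixel variance close to the mean", {
  g <- geometry_params(seed = 11)
  tr <- make_geometry(g)
  tr <- assign_enrichment(tr, 1)
  stack <- sapply(1:20, function(s) {
    phys <- photophysics_params(psf_sigma = 0, shading_amplitude = 0,
                                poisson_noise = TRUE,
                                gaussian_read_noise_sd = 0, seed = s)
    as.vector(render(tr, phys)$channels$mTOR[tr$le_labels$labels > 0L])
  })
  m <- rowMeans(stack)
  v <- apply(stack, 1, var)
  # variance/mean ratio concentrates around 1 for Poisson pixels
  expect_equal(mean(v / m), 1, tolerance = 0.15)
})

test_that("fixtures round-trip: channels bit-for-bit, truth map identical", {
  g <- geometry_params(seed = 13)
  phys <- photophysics_params(seed = 13, mtor_enrichment = 1.5)
  sim <- simulate_field(g, phys, image_id = "rt")
  # quantize before writing so the round trip is exact
  sim$image$channels <- lapply(sim$image$channels,
                               function(x) pmin(round(x), 65535))
  dir <- make_tempdir()
  write_fixture(sim$image, sim$truth, dir, stem = "rt")
  back <- read_fixture(dir, "rt")
  expect_identical(back$image$channels$mTOR, sim$image$channels$mTOR + 0)
  expect_identical(back$image$channels$MAP2, sim$image$channels$MAP2 + 0)
  expect_equal(back$truth$per_le_enrichment, sim$truth$per_le_enrichment)
  expect_identical(back$truth$le_labels$labels, sim$truth$le_labels$labels)
  expect_identical(back$truth$soma_labels$labels, sim$truth$soma_labels$labels)
})

test_that("16-bit saturating intensities are clipped with a warning", {
  img <- mc_image(list(A = matrix(c(70000, 10, 20, 30), 2, 2)), 65, "sat")
  dir <- make_tempdir()
  expect_warning(write_fixture(img, NULL, dir, stem = "sat"), "clipping")
  back <- read_fixture(dir, "sat")
  expect_equal(back$image$channels$A[1, 1], 65535)
  expect_equal(back$image$channels$A[2, 2], 30)
})

test_that("per-channel-file layout round-trips like the multipage layout", {
  img <- mc_image(list(X = matrix(1:12 * 100, 3, 4),
                       Y = matrix(12:1 * 50, 3, 4)), 65, "pc")
  dir <- make_tempdir()
  write_fixture(img, NULL, dir, stem = "pc", multipage = FALSE)
  back <- read_fixture(dir, "pc")
  expect_equal(back$image$channels$X, matrix(1:12 * 100, 3, 4))
  expect_equal(back$image$channels$Y, matrix(12:1 * 50, 3, 4))
})
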