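blank_channel <- function(v, name = "LAMP1") {
  channel(v, 65, name, provenance = "rolling_ball(diameter=75)")
}

test_that("blank channel segments to zero objects", {
  les <- segment_les(blank_channel(matrix(0, 32, 32)))
  expect_equal(nrow(les$objects), 0)
})

test_that("size filter is strictly 'above': area 25 rejected, 26 retained", {
  mk <- function(area) {
    v <- matrix(0, 40, 80)
    v[cbind(5 + (seq_len(area) - 1) %% 5, 5 + (seq_len(area) - 1) %/% 5)] <- 100
    v
  }
  les25 <- segment_les(blank_channel(mk(25)))
  les26 <- segment_les(blank_channel(mk(26)))
  expect_equal(nrow(les25$objects), 0)
  expect_equal(nrow(les26$objects), 1)
  expect_equal(les26$objects$area, 26)
})

test_that("of two disks areas 20 and 30, only the larger survives", {
  v <- matrix(0, 60, 60)
  d20 <- stamp <- function(r0, c0, n) {
    # n pixels in a compact blob
    px <- expand.grid(r = r0 + (-4:4), c = c0 + (-4:4))
    px$d <- (px$r - r0)^2 + (px$c - c0)^2
    px <- px[order(px$d), ][seq_len(n), ]
    cbind(px$r, px$c)
  }
  v[stamp(15, 15, 20)] <- 100
  v[stamp(40, 40, 30)] <- 100
  les <- segment_les(blank_channel(v))
  expect_equal(nrow(les$objects), 1)
  expect_equal(les$objects$area, 30)
  expect_equal(les$objects$centroid_row, 40, tolerance = 0.5)
})

test_that("segmentation recovers ground-truth LEs with 1-px centroids", {
  sim <- simulate_field(geometry_params(seed = 19), clean_phys())
  lamp1 <- channel(sim$image$channels$LAMP1, 65, "LAMP1",
                   provenance = "rolling_ball(diameter=75)")
  les <- segment_les(lamp1)
  truth <- sim$truth$le_labels$objects
  truth_big <- truth[truth$area > 25, ]
  expect_equal(nrow(les$objects), nrow(truth_big))
  for (i in seq_len(nrow(truth_big))) {
    d <- sqrt((les$objects$centroid_row - truth_big$centroid_row[i])^2 +
                (les$objects$centroid_col - truth_big$centroid_col[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("missing background-subtraction provenance warns", {
  v <- matrix(0, 32, 32); v[10:16, 10:16] <- 50
  expect_warning(segment_les(channel(v, 65, "LAMP1")), "provenance")
})

test_that("single-pixel ring count matches brute-force lattice enumeration", {
  lab <- matrix(0L, 41, 41); lab[21, 21] <- 1L
  les <- labeled_objects(lab, 65)
  dend <- lq_mask(matrix(TRUE, 41, 41), "all")
  masks <- build_in_out(les, dend, gap = 6, width = 4)
  # count lattice points at distance (6, 10] from the center by brute force
  g <- expand.grid(r = 1:41, c = 1:41)
  d <- sqrt((g$r - 21)^2 + (g$c - 21)^2)
  expect_equal(sum(masks$out_mask$values), sum(d > 6 & d <= 10))
})

test_that("ring mask equals the exact-distance oracle on multi-object masks", {
  set.seed(33)
  for (i in 1:3) {
    lab <- matrix(0L, 48, 48)
    for (k in 1:3) {
      r0 <- sample(8:40, 1); c0 <- sample(8:40, 1)
      px <- stamp_px <- expand.grid(r = r0 + (-2:2), c = c0 + (-2:2))
      keep <- (px$r - r0)^2 + (px$c - c0)^2 <= 4
      lab[cbind(px$r[keep], px$c[keep])] <- k
    }
    les <- labeled_objects(lab, 65)
    dend <- lq_mask(matrix(TRUE, 48, 48), "all")
    masks <- build_in_out(les, dend, gap = 6, width = 4)
    expect_identical(masks$out_mask$values, oracle_ring(lab > 0, 6, 4))
  }
})

test_that("rings of close objects merge, stay disjoint from objects", {
  lab <- matrix(0L, 40, 40)
  lab[20, 16] <- 1L; lab[20, 24] <- 2L  # 8 px apart
  les <- labeled_objects(lab, 65)
  masks <- build_in_out(les, lq_mask(matrix(TRUE, 40, 40), "all"))
  expect_false(any(masks$out_mask$values & lab > 0))
  expect_false(any(masks$in_mask$values & masks$out_mask$values))
  # merged region between them: counted once (mask is boolean by nature)
  expect_identical(masks$out_mask$values, oracle_ring(lab > 0, 6, 4))
})

test_that("an all-false dendrite mask empties both masks", {
  lab <- matrix(0L, 30, 30); lab[15, 15] <- 1L
  les <- labeled_objects(lab, 65)
  masks <- build_in_out(les, lq_mask(matrix(FALSE, 30, 30), "none"))
  expect_false(any(masks$in_mask$values))
  expect_false(any(masks$out_mask$values))
})

test_that("ring construction is equivariant under translation and rotation", {
  lab <- matrix(0L, 32, 32)
  lab[10:12, 14:17] <- 1L
  dend <- lq_mask(matrix(TRUE, 32, 32), "all")
  ring <- build_in_out(labeled_objects(lab, 65), dend)$out_mask$values
  # translate by (3, 2)
  lab_t <- matrix(0L, 32, 32); lab_t[13:15, 16:19] <- 1L
  ring_t <- build_in_out(labeled_objects(lab_t, 65), dend)$out_mask$values
  expect_identical(ring_t[14:28, 10:30], ring[11:25, 8:28])
  # rotate 90 degrees
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  ring_r <- build_in_out(labeled_objects(rot90(lab), 65), dend)$out_mask$values
  expect_identical(ring_r, rot90(ring))
})

test_that("per-object rings tile the union ring and resolve ties to lower id", {
  lab <- matrix(0L, 40, 40)
  lab[20, 14] <- 1L; lab[20, 26] <- 2L
  les <- labeled_objects(lab, 65)
  masks <- build_in_out(les, lq_mask(matrix(TRUE, 40, 40), "all"),
                        per_object = TRUE)
  u <- masks$per_object_rings[["1"]] | masks$per_object_rings[["2"]]
  expect_identical(u, masks$out_mask$values)
  expect_false(any(masks$per_object_rings[["1"]] &
                     masks$per_object_rings[["2"]]))
  # the equidistant column belongs to object 1 (lower id)
  eq_col <- masks$out_mask$values[, 20] & TRUE
  expect_true(all(masks$per_object_rings[["1"]][, 20][eq_col]))
})

test_that("invalid ring parameters error", {
  lab <- matrix(0L, 10, 10); lab[5, 5] <- 1L
  les <- labeled_objects(lab, 65)
  dend <- lq_mask(matrix(TRUE, 10, 10), "all")
  expect_error(build_in_out(les, dend, gap = -1), "gap")
  expect_error(build_in_out(les, dend, width = 0), "width")
})

test_that("remove_somas handles full, empty and synthetic cases", {
  m <- lq_mask(matrix(TRUE, 20, 20), "x")
  all_soma <- labeled_objects(matrix(1L, 20, 20), 65)
  expect_false(any(remove_somas(m, all_soma)$values))
  no_soma <- labeled_objects(matrix(0L, 20, 20), 65)
  expect_identical(remove_somas(m, no_soma)$values, m$values)
  tr <- make_geometry(geometry_params(seed = 23))
  dm <- remove_somas(tr$map2_mask, tr$soma_labels)
  expect_equal(sum(dm$values),
               sum(tr$map2_mask$values) - sum(tr$soma_labels$labels > 0L),
               tolerance = 0.02 * sum(tr$map2_mask$values))
})

test_that("surviving object count is non-increasing in min_area", {
  sim <- simulate_field(geometry_params(seed = 29), clean_phys())
  lamp1 <- channel(sim$image$channels$LAMP1, 65, "LAMP1",
                   provenance = "rolling_ball(diameter=75)")
  counts <- vapply(c(0, 10, 25, 40, 80),
                   function(a) nrow(segment_les(lamp1, min_area = a)$objects),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})
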