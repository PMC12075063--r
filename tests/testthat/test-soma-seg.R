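test_that("median filter preserves constants and removes outliers", {
  st <- image_stack(array(5, c(6, 6, 6)), 1)
  expect_identical(median_filter(st, 1)$data, st$data)
  a <- array(0, c(7, 7, 7)); a[4, 4, 4] <- 10
  expect_true(all(median_filter(image_stack(a, 1), 1)$data == 0))
  expect_error(median_filter(st, 0), "radius")
})

test_that("median filter erodes tubes but spares soma plateaus", {
  d <- c(48, 48, 96)
  soma <- ball_mask(d, c(24, 24, 24), 12)
  tube <- tube_mask(d, c(24, 24, 40), c(24, 24, 90), 1.5)
  img <- array(0, d)
  img[soma] <- 200
  img[tube & !soma] <- 100
  filt <- median_filter(image_stack(img, 1), 2)$data
  tube_only <- tube & !soma
  # tube voxels above half-peak drop by >= 80 %
  expect_lte(sum(filt[tube_only] >= 50), 0.2 * sum(tube_only))
  # soma voxels above half-peak drop by <= 10 %
  expect_gte(sum(filt[soma] >= 100), 0.9 * sum(soma))
})

test_that("hysteresis thresholding follows the dual-threshold contract", {
  st <- image_stack(array(rep(0:9), c(10, 4, 4)), 1)  # ramp along z
  expect_false(any(hysteresis_threshold(st, 3, 100)$data))  # high > max
  expect_identical(hysteresis_threshold(st, 4, 4)$data, st$data >= 4)
  m <- hysteresis_threshold(st, 3, 7)
  expect_identical(which(m$data[, 1, 1]), 4:10)  # >= 3, connected to >= 7
  # weak island not connected to any strong voxel stays background
  a <- array(0, c(9, 9, 9))
  a[2, 2, 2] <- 5          # isolated weak voxel
  a[7, 7, 7] <- 9; a[7, 7, 6] <- 5
  m2 <- hysteresis_threshold(image_stack(a, 1), 4, 8)
  expect_false(m2$data[2, 2, 2])
  expect_true(m2$data[7, 7, 6])
  expect_error(hysteresis_threshold(st, 5, 3), "low <= high")
})

test_that("gradient magnitude works in physical units", {
  expect_true(all(gradient_magnitude(
    image_stack(array(3, c(8, 8, 8)), 1), 1)$data < 1e-9))
  # ramp of slope s per um, anisotropic spacing
  s <- 2
  sp <- c(2, 1, 1)
  ramp <- array(rep((0:11) * s * sp[1]), c(12, 8, 8))  # varies along z
  g <- gradient_magnitude(image_stack(ramp, sp), 0)
  expect_equal(max(abs(g$data[3:10, 3:6, 3:6] - s)), 0, tolerance = 1e-9)
  # two abutting plateaus: per-slice gradient argmax on the contact plane +- 1
  a <- array(100, c(8, 8, 20)); a[, , 11:20] <- 200
  g2 <- gradient_magnitude(image_stack(a, 1), 1)
  for (z in 3:6) {
    am <- which.max(g2$data[z, 4, ])
    expect_lte(abs(am - 10.5), 1.5)
  }
  expect_error(gradient_magnitude(image_stack(a, 1), -1), "sigma")
})

test_that("seed detection finds one seed per soma body", {
  d <- c(40, 40, 40)
  m <- binary_mask(ball_mask(d, c(20, 20, 20), 11), 1)
  s <- detect_seeds(m)
  expect_identical(s$count, 1L)
  expect_lte(max(abs(as.numeric(s$peaks[1, c("cz_um", "cy_um", "cx_um")]) -
                       c(20, 20, 20))), 1)

  # two spheres fused by a neck narrower than either radius
  d2 <- c(40, 40, 72)
  fused <- ball_mask(d2, c(20, 20, 24), 11) | ball_mask(d2, c(20, 20, 40), 11)
  s2 <- detect_seeds(binary_mask(fused, 1))
  expect_identical(s2$count, 2L)

  # empty mask: zero seeds, not an error
  s0 <- detect_seeds(binary_mask(array(FALSE, c(8, 8, 8)), 1))
  expect_identical(s0$count, 0L)
})

test_that("watershed inside mask is a partition assigned to seeds", {
  d <- c(40, 40, 72)
  fused <- ball_mask(d, c(20, 20, 24), 11) | ball_mask(d, c(20, 20, 40), 11)
  m <- binary_mask(fused, 1)
  img <- image_stack(array(as.numeric(fused) * 100, d), 1)
  g <- gradient_magnitude(img, 1)
  seeds <- detect_seeds(m)
  ws <- watershed_inside_mask(g, seeds, m)
  # partition invariant: label voxel counts sum to the mask voxel count
  expect_identical(sum(ws$data > 0), sum(fused))
  # each truth sphere >= 90 % one label
  for (ctr in list(c(20, 20, 24), c(20, 20, 40))) {
    ids <- ws$data[ball_mask(d, ctr, 9)]
    expect_gte(max(table(ids)) / length(ids), 0.9)
  }
  j <- mean_instance_jaccard(
    array(as.integer(ball_mask(d, c(20, 20, 24), 11)) +
            2L * as.integer(ball_mask(d, c(20, 20, 40), 11) &
                              !ball_mask(d, c(20, 20, 24), 11)), d),
    ws$data)
  expect_true(all(j >= 0.8))
})

test_that("one seed floods any mask, including seedless components", {
  d <- c(20, 20, 40)
  two_cc <- ball_mask(d, c(10, 10, 10), 6) | ball_mask(d, c(10, 10, 30), 6)
  m <- binary_mask(two_cc, 1)
  markers <- array(0L, d); markers[11, 11, 11] <- 1L
  ws <- watershed_inside_mask(image_stack(array(0, d), 1),
                              label_volume(markers, 1), m)
  expect_identical(ws$data > 0L, m$data)  # label = mask
  expect_true(all(ws$data[m$data] == 1L))

  # a seed outside the mask is an error naming the seed
  markers2 <- markers; markers2[1, 1, 1] <- 2L
  expect_error(watershed_inside_mask(image_stack(array(0, d), 1),
                                     label_volume(markers2, 1), m),
               "seed.*2.*outside")
})

test_that("filter_labels removes out-of-range instances and relabels", {
  d <- c(24, 24, 48)
  lab <- array(0L, d)
  lab[ball_mask(d, c(12, 12, 12), 8)] <- 1L   # ~2145 um3
  lab[ball_mask(d, c(12, 12, 36), 3)] <- 2L   # ~113 um3 speck
  lv <- label_volume(lab, 1)
  f <- filter_labels(lv, 500, 60000)
  expect_identical(n_labels(f), 1L)
  expect_identical(attr(f, "removed")$old_id, 2L)
  # all within bounds: identity up to relabelling
  f2 <- filter_labels(lv, 0, Inf)
  expect_identical(f2$data, lv$data)
  expect_error(filter_labels(lv, 10, 5), "min_volume")
})

test_that("segment_somata composes deterministically and handles empties", {
  spec <- soma_field_spec(grid_shape = c(128, 128, 128), spacing_um = 1.5,
                          n_somata = 10, min_gap_um = 25, seed = 31)
  sim <- generate_soma_field(spec)
  lab1 <- segment_somata(sim$stack)
  lab2 <- segment_somata(sim$stack)
  expect_identical(lab1$data, lab2$data)  # idempotent in parameters
  expect_identical(n_labels(lab1), 10L)
  expect_lte(n_labels(lab1), attr(lab1, "seeds"))
  j <- mean_instance_jaccard(sim$truth$label_volume$data, lab1$data)
  expect_gte(mean(j), 0.7)

  # an external mask provider is honoured
  ext <- binary_mask(sim$truth$label_volume$data > 0L, spec$spacing_um)
  lab3 <- segment_somata(sim$stack, mask = ext)
  expect_identical(sum(lab3$data > 0L), sum(ext$data))

  # empty stack: 0 instances, clean exit
  flat <- image_stack(array(7, c(32, 32, 32)), 1.5)
  lab0 <- segment_somata(flat)
  expect_identical(n_labels(lab0), 0L)
})

test_that("stage failures carry the stage name", {
  spec <- soma_field_spec(grid_shape = c(64, 64, 64), spacing_um = 1.5,
                          n_somata = 2, min_gap_um = 25, seed = 8)
  sim <- generate_soma_field(spec)
  expect_error(segment_somata(sim$stack, params = list(median_radius_vox = 0)),
               "stage 'median_filter'")
  expect_error(segment_somata(sim$stack,
                              params = list(min_volume_um3 = 10,
                                            max_volume_um3 = 5)),
               "stage 'filter_labels'")
})
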