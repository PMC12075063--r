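test_that("mixture sampling draws from the indicated components", {
  # zero-variance single component: degenerate draws are exact
  d <- sample_volume_mixture(5, list(mean = 10000, sd = 0))
  expect_identical(d$volume_um3, rep(10000, 5))

  # binomial oracle on the component flags
  d <- sample_volume_mixture(10000, list(w = 0.3, mean1 = 4000, sd1 = 1200,
                                         mean2 = 15000, sd2 = 4000),
                             seed = 11)
  frac <- mean(d$component == "small")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))

  # law-of-large-numbers oracle on the mean
  mix <- list(w = 0.3, mean1 = 4000, sd1 = 1200, mean2 = 15000, sd2 = 4000)
  d <- sample_volume_mixture(2000, mix, seed = 12)
  mu <- 0.3 * 4000 + 0.7 * 15000
  varmix <- 0.3 * (1200^2 + 4000^2) + 0.7 * (4000^2 + 15000^2) - mu^2
  expect_lt(abs(mean(d$volume_um3) - mu), 3 * sqrt(varmix / 2000))

  # all draws positive even with a component hugging zero
  d <- sample_volume_mixture(500, list(mean = 300, sd = 400), seed = 13)
  expect_true(all(d$volume_um3 > 0))
})

test_that("mixture parameters are validated", {
  expect_error(sample_volume_mixture(0, list(mean = 1, sd = 1)), "n must")
  expect_error(sample_volume_mixture(5, list(w = 1.5, mean1 = 1, sd1 = 1,
                                             mean2 = 2, sd2 = 1)), "weight")
  expect_error(sample_volume_mixture(5, list(w = 0.5, mean1 = 5, sd1 = 1,
                                             mean2 = 2, sd2 = 1)),
               "mean1 < mean2")
  expect_error(soma_field_spec(n_somata = 0), "n_somata")
})

test_that("a single synthetic sphere matches its analytic volume", {
  spec <- soma_field_spec(grid_shape = c(48, 48, 48), spacing_um = 1,
                          n_somata = 1,
                          mixture = list(mean = 4188.79, sd = 0),
                          min_gap_um = 1, noise_sd = 0, seed = 7)
  sim <- generate_soma_field(spec)
  expect_equal(sim$truth$truth_table$volume_um3, 4188.79)
  vox_vol <- sum(sim$truth$label_volume$data == 1)  # 1 um^3 voxels
  expect_lt(abs(vox_vol - 4188.79) / 4188.79, 0.05)
})

test_that("soma fields honour min_gap and label every soma", {
  spec <- soma_field_spec(grid_shape = c(192, 192, 192),
                          spacing_um = 1.5, n_somata = 50,
                          min_gap_um = 20, seed = 21)
  sim <- generate_soma_field(spec)
  tt <- sim$truth$truth_table
  ctr <- as.matrix(tt[, c("cz_um", "cy_um", "cx_um")])
  expect_gte(min(dist(ctr)), 20)
  present <- sort(unique(as.integer(sim$truth$label_volume$data)))
  expect_identical(present, 0:50)  # consecutive ids, background 0
  expect_true(all(c("small", "large") %in% tt$subtype))
})

test_that("an unplaceable field fails naming the achievable count", {
  spec <- soma_field_spec(grid_shape = c(64, 64, 64), spacing_um = 1,
                          n_somata = 30, min_gap_um = 40,
                          mixture = list(mean = 4000, sd = 0), seed = 3)
  expect_error(generate_soma_field(spec), "could only place")
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- soma_field_spec(grid_shape = c(64, 64, 64), spacing_um = 1.5,
                          n_somata = 5, min_gap_um = 20, seed = 5)
  a <- generate_soma_field(spec)
  b <- generate_soma_field(spec)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$label_volume$data, b$truth$label_volume$data)
  expect_identical(a$truth$truth_table, b$truth$truth_table)
})

test_that("half-peak thresholding recovers a noise-free soma", {
  spec <- soma_field_spec(grid_shape = c(48, 48, 48), spacing_um = 1,
                          n_somata = 1, mixture = list(mean = 4188.79, sd = 0),
                          min_gap_um = 1, noise_sd = 0, seed = 7)
  sim <- generate_soma_field(spec)
  half <- (spec$background_intensity + spec$soma_peak_intensity) / 2
  truth_vox <- sim$truth$label_volume$data == 1
  recovered <- mean(sim$stack$data[truth_vox] >= half)
  expect_gte(recovered, 0.95)
})

test_that("neuron trees honour branching parameters", {
  # wiggle 0: straight branches, tortuosity exactly 1
  s0 <- neuron_spec(grid_shape = c(128, 128, 128), spacing_um = 1.5,
                    n_primary = 3, max_order = 2, branch_prob_per_order = 1,
                    segment_length_um = c(12, 2), wiggle = 0, seed = 2)
  sim0 <- generate_neuron_stack(s0)
  expect_true(all(abs(sim0$truth$truth_skeleton$branches$tortuosity - 1) < 1e-9))

  # no branching: exactly n_primary branches, all order 1
  s1 <- neuron_spec(grid_shape = c(128, 128, 128), spacing_um = 1.5,
                    n_primary = 4, max_order = 6, branch_prob_per_order = 0,
                    segment_length_um = c(12, 2), wiggle = 0.1, seed = 2)
  br1 <- generate_neuron_stack(s1)$truth$truth_skeleton$branches
  expect_identical(nrow(br1), 4L)
  expect_true(all(br1$order == 1L))

  # always branching to max_order 6: all orders present
  s2 <- neuron_spec(grid_shape = c(224, 224, 224), spacing_um = 1.5,
                    n_primary = 2, max_order = 6, branch_prob_per_order = 1,
                    segment_length_um = c(10, 0), wiggle = 0.05, seed = 4)
  br2 <- generate_neuron_stack(s2)$truth$truth_skeleton$branches
  expect_identical(sort(unique(br2$order)), 1:6)
  expect_identical(as.integer(table(br2$order)), as.integer(2 * 2^(0:5)))

  expect_error(neuron_spec(max_order = 0), "max_order")
  expect_error(neuron_spec(dendrite_intensity_ratio = 1.5), "ratio")
})

test_that("rendered neuron stacks are deterministic and ground-truthed", {
  sp <- neuron_spec(grid_shape = c(96, 96, 96), spacing_um = 1.5,
                    n_primary = 2, max_order = 2, branch_prob_per_order = 1,
                    segment_length_um = c(10, 2), seed = 9)
  a <- generate_neuron_stack(sp)
  b <- generate_neuron_stack(sp)
  expect_identical(a$stack$data, b$stack$data)
  # soma is brighter than dendrites by 1/dendrite_intensity_ratio
  root <- as.numeric(a$truth$truth_table[1, c("cz_um", "cy_um", "cx_um")])
  ri <- round(root / sp$spacing_um) + 1
  expect_gt(a$stack$data[ri[1], ri[2], ri[3]],
            0.9 * sp$soma_peak_intensity)
  # rendered tubes follow the skeleton: every node sits inside the label
  sk <- a$truth$truth_skeleton
  idx <- round(as.matrix(sk$nodes[, c("z_um", "y_um", "x_um")]) /
                 rep(sp$spacing_um, each = nrow(sk$nodes))) + 1
  lab <- a$truth$label_volume$data
  inside <- vapply(seq_len(nrow(idx)), function(i)
    lab[idx[i, 1], idx[i, 2], idx[i, 3]] > 0, TRUE)
  expect_gte(mean(inside), 0.99)
})
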