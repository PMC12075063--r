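test_that("rod and ball enhancement separate tubes from blobs", {
  d <- c(48, 48, 96)
  img <- array(0, d)
  img[tube_mask(d, c(24, 24, 10), c(24, 24, 86), 1.5)] <- 100
  img[ball_mask(d, c(24, 24, 48), 10)] <- 100  # blob embedded mid-tube
  st <- image_stack(img, 1)
  rod <- rod_enhance(st)
  ball <- ball_enhance(st)
  # on-axis tube response dwarfs off-axis response
  on_axis <- mean(rod$data[24, 24, c(15:30, 66:80)])
  off_axis <- mean(rod$data[24, 29, c(15:30, 66:80)])  # 5 um off axis
  expect_gte(on_axis, 5 * off_axis)
  # blob interior is less tubular than the tube axis
  expect_lt(rod$data[24, 24, 48], on_axis)
  # blob centre out-blobs every tube voxel
  tube_only <- tube_mask(d, c(24, 24, 10), c(24, 24, 86), 1.5) &
    !ball_mask(d, c(24, 24, 48), 12)
  expect_gt(ball$data[24, 24, 48], max(ball$data[tube_only]))
  # uniform volume: zero response
  flat <- image_stack(array(50, c(24, 24, 24)), 1)
  expect_lt(max(rod_enhance(flat)$data), 1e-9)
  expect_lt(max(ball_enhance(flat)$data), 1e-9)
  expect_error(rod_enhance(st, numeric(0)), "scale")
  expect_error(ball_enhance(st, -1), "scale")
})

test_that("scale selection attenuates mismatched blobs", {
  d <- c(40, 40, 40)
  img <- array(0, d)
  img[ball_mask(d, c(20, 20, 20), 10)] <- 100
  st <- image_stack(img, 1)
  matched <- ball_enhance(st, 8)$data[20, 20, 20]
  off <- ball_enhance(st, 1.5)$data[20, 20, 20]
  expect_gt(matched, off)
})

test_that("global threshold is a plain cutoff with trivial extremes", {
  st <- image_stack(array(runif(8^3), c(8, 8, 8)), 1)
  expect_true(all(global_threshold(st, -Inf)$data))
  expect_false(any(global_threshold(st, 2)$data))
})

test_that("fused-response threshold covers soma and dendrites", {
  spec <- neuron_spec(grid_shape = c(128, 128, 128), spacing_um = 1,
                      max_order = 3, n_primary = 4,
                      branch_prob_per_order = 1,
                      segment_length_um = c(14, 3), wiggle = 0.1, seed = 11)
  sim <- generate_neuron_stack(spec)
  fused <- fuse_responses(rod_enhance(sim$stack), ball_enhance(sim$stack))
  mask <- global_threshold(fused, 0.05)
  lab <- sim$truth$label_volume$data > 0L
  root <- as.numeric(sim$truth$truth_table[1, c("cz_um", "cy_um", "cx_um")])
  ai <- arrayInd(which(lab), dim(lab))
  dctr <- sqrt(rowSums(sweep(ai - 1, 2, root)^2))
  soma_vox <- which(lab)[dctr <= spec$soma_radius_um]
  tube_vox <- which(lab)[dctr > spec$soma_radius_um + 2]
  expect_gte(mean(mask$data[soma_vox]), 0.95)
  expect_gte(mean(mask$data[tube_vox]), 0.80)
})

test_that("label_neurons separates arbors by their soma markers", {
  d <- c(20, 20, 44)
  # single neuron: one label equal to the mask
  one <- tube_mask(d, c(10, 10, 6), c(10, 10, 38), 2)
  markers <- array(0L, d); markers[11, 11, 7] <- 1L
  fused <- image_stack(array(as.numeric(one), d), 1)
  l1 <- label_neurons(binary_mask(one, 1), label_volume(markers, 1), fused)
  expect_identical(l1$data > 0L, one)
  expect_identical(n_labels(l1), 1L)

  # interdigitating but non-touching arbors: labels equal components
  two <- tube_mask(d, c(5, 10, 6), c(5, 10, 38), 1.5) |
    tube_mask(d, c(14, 10, 6), c(14, 10, 38), 1.5)
  mk2 <- array(0L, d); mk2[6, 11, 8] <- 1L; mk2[15, 11, 8] <- 2L
  l2 <- label_neurons(binary_mask(two, 1), label_volume(mk2, 1),
                      image_stack(array(as.numeric(two), d), 1))
  cc <- array(mnmorph:::cpp_conncomp3d(two, d, 26L), d)
  expect_identical(l2$data > 0L, two)
  expect_true(all(tapply(l2$data[two], cc[cc > 0], function(x)
    length(unique(x))) == 1L))
})

test_that("touching arbors split at their contact surface", {
  sp1 <- neuron_spec(grid_shape = c(96, 96, 144), spacing_um = 1,
                     n_primary = 3, max_order = 2, branch_prob_per_order = 1,
                     segment_length_um = c(14, 2), wiggle = 0.1,
                     root_um = c(48, 48, 40), noise_sd = 0, seed = 41)
  sp2 <- sp1; sp2$root_um <- c(48, 48, 100); sp2$seed <- 42L
  a <- generate_neuron_stack(sp1)
  b <- generate_neuron_stack(sp2)
  img <- image_stack(pmax(a$stack$data, b$stack$data), 1)
  mask <- binary_mask(a$truth$label_volume$data > 0L |
                        b$truth$label_volume$data > 0L, 1)
  mk <- array(0L, dim(mask$data))
  mk[49, 49, 41] <- 1L; mk[49, 49, 101] <- 2L
  fused <- fuse_responses(rod_enhance(img), ball_enhance(img))
  lab <- label_neurons(mask, label_volume(mk, 1), fused)
  for (truth in list(a$truth$label_volume$data > 0L,
                     b$truth$label_volume$data > 0L)) {
    own <- lab$data[truth]
    expect_gte(max(table(own[own > 0])) / sum(truth), 0.85)
  }
})

test_that("centerlines of simple shapes match their geometry", {
  # straight tube, 100 um long
  d <- c(9, 9, 110)
  tube <- tube_mask(d, c(4, 4, 4), c(4, 4, 104), 2.2)
  sk <- extract_centerline(binary_mask(tube, 1))
  rt <- root_and_order(sk, c(4, 4, 0))
  expect_identical(nrow(rt$branches), 1L)
  expect_lt(abs(sum(rt$branches$path_length_um) - 100), 3)

  # solid sphere collapses to a few central voxels
  ds <- c(32, 32, 32)
  sph <- extract_centerline(binary_mask(ball_mask(ds, c(16, 16, 16), 11), 1))
  expect_lte(nrow(sph$nodes), 10)
  ctr_dist <- sqrt(rowSums(sweep(as.matrix(sph$nodes[, 2:4]), 2,
                                 c(16, 16, 16))^2))
  expect_lt(max(ctr_dist), 6)

  # Y-shaped tube pair: one branchpoint, three tips
  dy <- c(60, 60, 60)
  y <- tube_mask(dy, c(30, 30, 5), c(30, 30, 30), 2.2) |
    tube_mask(dy, c(30, 30, 30), c(15, 30, 55), 2.2) |
    tube_mask(dy, c(30, 30, 30), c(45, 30, 55), 2.2)
  sky <- prune_spurs(extract_centerline(binary_mask(y, 1)), 5)
  deg <- lengths(mnmorph:::chain_neighbours(sky))
  expect_identical(sum(deg >= 3), 1L)
  expect_identical(sum(deg == 1), 3L)

  # disconnected masks are rejected with guidance
  two <- ball_mask(ds, c(8, 8, 8), 4) | ball_mask(ds, c(24, 24, 24), 4)
  expect_error(extract_centerline(binary_mask(two, 1)), "label_neurons")
})

test_that("spur pruning removes short tips, is idempotent, keeps stems", {
  # 100 um path with a 1 um spur off its middle
  nodes <- data.frame(id = 1:13,
                      z_um = c(seq(0, 100, by = 10), 50, 51),
                      y_um = c(rep(0, 11), 1, 1.5),
                      x_um = 0)
  edges <- data.frame(from = c(1:10, 6, 12), to = c(2:11, 12, 13))
  sk <- skeleton_graph(nodes, edges = edges)
  pr <- prune_spurs(sk, 5)
  expect_identical(nrow(pr$nodes), 11L)
  expect_identical(nrow(pr$edges), 10L)
  pr2 <- prune_spurs(pr, 5)
  expect_identical(pr2$nodes, pr$nodes)  # fixpoint
  # nothing shorter than min_len: identity
  expect_identical(nrow(prune_spurs(sk, 0.5)$nodes), 13L)
})

test_that("rooting assigns centrifugal orders", {
  star <- star_skeleton(4, 30)
  expect_identical(nrow(star$branches), 4L)
  expect_true(all(star$branches$order == 1L))

  bt <- binary_tree_skeleton(6)
  expect_identical(sort(unique(bt$branches$order)), 1:6)
  expect_identical(as.integer(table(bt$branches$order)), as.integer(2^(0:5)))

  # truth skeletons re-derive their own orders from geometry alone
  tt <- small_truth_skeleton(seed = 6)
  re <- root_and_order(mnmorph:::unroot_skeleton(tt),
                       as.numeric(tt$nodes[1, c("z_um", "y_um", "x_um")]))
  agree <- mean(re$nodes$order[match(tt$nodes$id, re$nodes$id)] ==
                  tt$nodes$order)
  expect_gte(agree, 0.95)
})

test_that("SWC export and import round-trip exactly", {
  tt <- small_truth_skeleton(seed = 8)
  tt <- mark_axon_candidate(tt, min_len_um = 10000)  # no axon at this size
  f <- tempfile(fileext = ".swc")
  write_swc(tt, f)
  back <- read_swc(f)
  expect_identical(nrow(back$nodes), nrow(tt$nodes))
  expect_identical(as.matrix(back$nodes[, c("z_um", "y_um", "x_um")]),
                   as.matrix(tt$nodes[, c("z_um", "y_um", "x_um")]))
  # identical topology: same parent structure under the id remap
  remap <- match(tt$nodes$id, tt$nodes$id)
  expect_identical(is.na(back$parent), is.na(tt$parent))
  expect_identical(back$branches$order, tt$branches$order)
  expect_identical(back$branches$path_length_um, tt$branches$path_length_um)
  expect_error(write_swc(mnmorph:::unroot_skeleton(tt), f), "rooted")
})

test_that("the axon candidate is the longest far-reaching stem", {
  star <- star_skeleton(3, 40)
  none <- mark_axon_candidate(star, min_len_um = 500)
  expect_true(is.na(none$axon_branch))
  long <- star_skeleton(3, 40)
  # stretch one ray to 600 um
  ray3 <- long$nodes$branch_id == 3
  long$nodes$x_um[ray3] <- long$nodes$x_um[ray3] * 15
  long$nodes$y_um[ray3] <- long$nodes$y_um[ray3] * 15
  long$nodes$z_um[ray3] <- long$nodes$z_um[ray3] * 15
  long$branches <- branch_table(long)
  long <- mnmorph:::annotate_nodes(long)
  ax <- mark_axon_candidate(long, min_len_um = 500)
  expect_identical(ax$axon_branch, 3L)
  expect_true(any(ax$nodes$type == 2L))
})

test_that("tracing a rendered neuron recovers its total dendritic length", {
  spec <- neuron_spec(grid_shape = c(128, 128, 128), spacing_um = 1,
                      max_order = 3, n_primary = 4,
                      branch_prob_per_order = 1,
                      segment_length_um = c(14, 3), wiggle = 0.1, seed = 11)
  sim <- generate_neuron_stack(spec)
  skel <- trace_neuron(sim$stack)
  truth_len <- sum(sim$truth$truth_skeleton$branches$path_length_um)
  traced_len <- sum(skel$branches$path_length_um)
  expect_lt(abs(traced_len - truth_len) / truth_len, 0.10)
  expect_gte(nrow(skel$branches), 0.8 * nrow(sim$truth$truth_skeleton$branches))
})
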