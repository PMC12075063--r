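# Ground-truthed synthetic volumes: dense ellipsoidal soma fields whose
# volumes follow a one- or two-component Gaussian mixture, and single-neuron
# stacks with tube-rendered dendritic trees. These emulate the statistical
# structure the analysis assumes (crowded somata, uni- to bimodal volume
# distributions, a 2-3x soma/dendrite intensity difference) so that every
# downstream stage can be tested against known truth.

validate_mixture <- function(mixture) {
  if (!is.list(mixture)) stop_param("mixture must be a list")
  if (!is.null(mixture$w)) {
    need <- c("w", "mean1", "sd1", "mean2", "sd2")
    if (!all(need %in% names(mixture)))
      stop_param("two-component mixture needs fields ", paste(need, collapse = ", "))
    if (mixture$w < 0 || mixture$w > 1) stop_param("mixture weight w must be in [0, 1]")
    if (mixture$mean1 >= mixture$mean2)
      stop_param("two-component mixture requires mean1 < mean2")
    if (mixture$sd1 < 0 || mixture$sd2 < 0) stop_param("mixture sds must be >= 0")
  } else {
    if (!all(c("mean", "sd") %in% names(mixture)))
      stop_param("single-component mixture needs fields mean, sd")
    if (mixture$sd < 0) stop_param("mixture sd must be >= 0")
  }
  invisible(mixture)
}

#' Sample soma volumes from a Gaussian mixture
#'
#' Draws `n` volumes (µm³) from a one- or two-component Gaussian mixture.
#' Negative or zero draws are rejected and redrawn from the same component,
#' so the effective distribution is truncated at zero. The true component of
#' each draw is recorded, which is the ground truth against which size-based
#' subtype classification is scored.
#'
#' @param n number of volumes to draw (>= 1).
#' @param mixture either `list(mean=, sd=)` (one component) or
#'   `list(w=, mean1=, sd1=, mean2=, sd2=)` where `w` is the weight of the
#'   small-mean component and `mean1 < mean2`.
#' @param seed optional RNG seed; when `NULL` the current RNG stream is used.
#' @return data.frame with columns `volume_um3` and `component`
#'   (`"small"`/`"large"`; all `"small"` for a single component).
#' @export
sample_volume_mixture <- function(n, mixture, seed = NULL) {
  if (n < 1) stop_param("n must be >= 1")
  validate_mixture(mixture)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mixture$w)) {
    comp <- rep(1L, n)
    means <- mixture$mean; sds <- mixture$sd
  } else {
    comp <- ifelse(rbinom(n, 1L, mixture$w) == 1L, 1L, 2L)
    means <- c(mixture$mean1, mixture$mean2)
    sds <- c(mixture$sd1, mixture$sd2)
  }
  v <- rnorm(n, means[comp], sds[comp])
  bad <- which(v <= 0)
  while (length(bad) > 0) {
    v[bad] <- rnorm(length(bad), means[comp[bad]], sds[comp[bad]])
    bad <- bad[v[bad] <= 0]
  }
  data.frame(volume_um3 = v,
             component = factor(c("small", "large")[comp],
                                levels = c("small", "large")))
}

#' Specification of a synthetic soma field
#'
#' Defaults describe the canonical crowded-field condition used throughout
#' the test suite: a 256³ voxel stack at 1.5 µm isotropic spacing holding 50
#' ellipsoidal somata whose volumes follow a well-separated two-component
#' mixture (30 % small), with a plateau-plus-blurred-edge intensity profile
#' and additive Gaussian noise.
#'
#' @param grid_shape voxels per axis (z, y, x).
#' @param spacing_um voxel size per axis (µm).
#' @param n_somata number of somata (>= 1).
#' @param mixture volume mixture, see [sample_volume_mixture()].
#' @param min_gap_um minimum pairwise centroid separation (µm).
#' @param soma_peak_intensity,background_intensity,noise_sd intensity model
#'   (arbitrary units).
#' @param seed root RNG seed; all randomness derives from it.
#' @return validated `soma_field_spec` object.
#' @export
soma_field_spec <- function(grid_shape = c(256, 256, 256),
                            spacing_um = c(1.5, 1.5, 1.5),
                            n_somata = 50,
                            mixture = list(w = 0.3, mean1 = 4000, sd1 = 1200,
                                           mean2 = 15000, sd2 = 4000),
                            min_gap_um = 25,
                            soma_peak_intensity = 200,
                            background_intensity = 20,
                            noise_sd = 10,
                            seed = 1L) {
  if (n_somata < 1) stop_param("n_somata must be >= 1")
  validate_mixture(mixture)
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing_um = as_spacing(spacing_um),
               n_somata = as.integer(n_somata), mixture = mixture,
               min_gap_um = min_gap_um,
               soma_peak_intensity = soma_peak_intensity,
               background_intensity = background_intensity,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "soma_field_spec"
  spec
}

# semi-axes with mild random ratios, constrained to 0.8-1.25x the
# sphere-equivalent radius, normalised so the analytic volume is preserved
sample_semiaxes <- function(r_um) {
  repeat {
    f <- exp(runif(3, log(0.85), log(1.2)))
    f <- f / prod(f)^(1 / 3)
    if (all(f >= 0.8 & f <= 1.25)) return(r_um * f)
  }
}

gaussian_kernel1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

blur3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  v <- as.numeric(arr)
  for (ax in 1:3) {
    k <- gaussian_kernel1d(sigma_vox[ax])
    if (length(k) > 1) v <- cpp_convolve_axis(v, d, k, ax)
  }
  array(v, d)
}

# paint an ellipsoid into intensity and label arrays (modified in place via
# returned copies); centre in um (z,y,x), semi-axes in um
ellipsoid_box <- function(center_um, semi_um, grid_shape, spacing_um) {
  lo <- pmax(1L, floor(center_um / spacing_um - semi_um / spacing_um) + 1L)
  hi <- pmin(grid_shape, ceiling(center_um / spacing_um + semi_um / spacing_um) + 1L)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Generate a ground-truthed synthetic soma field
#'
#' Places `n_somata` axis-aligned ellipsoids (volumes drawn from the spec's
#' mixture, semi-axes within 0.8-1.25x the sphere-equivalent radius but
#' normalised to preserve the sampled volume exactly) at centroids separated
#' by at least `min_gap_um`, renders a plateau intensity profile with a one
#' voxel Gaussian-blurred edge, and adds Gaussian noise. The returned truth
#' holds the label volume, the analytic per-soma volumes, centroids and true
#' mixture components.
#'
#' @param spec a [soma_field_spec()].
#' @return list with `stack` (an [image_stack()]) and `truth`
#'   (list: `label_volume`, `truth_table`, `truth_skeleton = NULL`).
#' @export
generate_soma_field <- function(spec) {
  stopifnot(inherits(spec, "soma_field_spec"))
  set.seed(spec$seed)
  n <- spec$n_somata
  sp <- spec$spacing_um
  gs <- spec$grid_shape
  extent <- (gs - 1) * sp
  draws <- sample_volume_mixture(n, spec$mixture)
  r <- (3 * draws$volume_um3 / (4 * pi))^(1 / 3)
  semis <- t(vapply(r, sample_semiaxes, numeric(3)))
  margin <- apply(semis, 1, max) + 2 * max(sp)
  if (min(extent) <= 2 * max(margin))
    stop_data("grid too small for the requested soma sizes")
  centers <- matrix(NA_real_, n, 3)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 1000L * n
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- vapply(1:3, function(a)
      runif(1, margin[placed + 1L], extent[a] - margin[placed + 1L]), 0)
    ok <- placed == 0L ||
      min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))) >=
        spec$min_gap_um
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  if (placed < n)
    stop_data(sprintf(
      "could only place %d of %d somata at min_gap_um = %g in this grid",
      placed, n, spec$min_gap_um))
  img <- array(spec$background_intensity, gs)
  lab <- array(0L, gs)
  ax_um <- lapply(1:3, function(a) ((seq_len(gs[a])) - 1) * sp[a])
  for (i in seq_len(n)) {
    bx <- ellipsoid_box(centers[i, ], semis[i, ], gs, sp)
    zi <- bx$lo[1]:bx$hi[1]; yi <- bx$lo[2]:bx$hi[2]; xi <- bx$lo[3]:bx$hi[3]
    uz <- (ax_um[[1]][zi] - centers[i, 1]) / semis[i, 1]
    uy <- (ax_um[[2]][yi] - centers[i, 2]) / semis[i, 2]
    ux <- (ax_um[[3]][xi] - centers[i, 3]) / semis[i, 3]
    u <- outer(outer(uz^2, uy^2, `+`), ux^2, `+`)
    inside <- u <= 1
    sub_lab <- lab[zi, yi, xi]
    sub_lab[inside & sub_lab == 0L] <- i
    lab[zi, yi, xi] <- sub_lab
    sub_img <- img[zi, yi, xi]
    sub_img[inside] <- spec$soma_peak_intensity
    img[zi, yi, xi] <- sub_img
  }
  img <- blur3d(img, rep(1, 3))
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
  two <- !is.null(spec$mixture$w)
  truth_table <- data.frame(
    id = seq_len(n),
    volume_um3 = draws$volume_um3,
    cz_um = centers[, 1], cy_um = centers[, 2], cx_um = centers[, 3],
    subtype = if (two) as.character(draws$component) else NA_character_)
  list(stack = image_stack(img, sp),
       truth = list(label_volume = label_volume(lab, sp),
                    truth_table = truth_table,
                    truth_skeleton = NULL))
}

#' Specification of a synthetic single-neuron stack
#'
#' The dendrite/soma intensity ratio defaults to 1/3, reflecting the 2-3x
#' intensity difference between soma and distal dendrites seen in
#' retrogradely labelled motoneurons.
#'
#' @param soma_radius_um soma ball radius (µm).
#' @param n_primary number of order-1 dendrites (>= 1).
#' @param max_order maximum centrifugal branch order (>= 1).
#' @param branch_prob_per_order probability that a branch bifurcates at its
#'   end (per order, until `max_order`).
#' @param segment_length_um c(mean, sd) of branch segment lengths (µm).
#' @param wiggle per-step angular jitter (radians-scale, 0 = straight
#'   branches with tortuosity exactly 1).
#' @param dendrite_intensity_ratio dendrite/soma intensity in (0, 1].
#' @param dendrite_radius_um rendered tube radius (µm).
#' @param grid_shape,spacing_um output geometry.
#' @param soma_peak_intensity,background_intensity,noise_sd intensity model.
#' @param root_um soma centre (z,y,x µm); default grid centre.
#' @param seed root RNG seed.
#' @return validated `neuron_spec` object.
#' @export
neuron_spec <- function(soma_radius_um = 10,
                        n_primary = 4,
                        max_order = 6,
                        branch_prob_per_order = 0.85,
                        segment_length_um = c(18, 4),
                        wiggle = 0.15,
                        dendrite_intensity_ratio = 1 / 3,
                        dendrite_radius_um = 1.5,
                        grid_shape = c(192, 192, 192),
                        spacing_um = c(1, 1, 1),
                        soma_peak_intensity = 300,
                        background_intensity = 10,
                        noise_sd = 5,
                        root_um = NULL,
                        seed = 1L) {
  if (max_order < 1) stop_param("max_order must be >= 1")
  if (n_primary < 1) stop_param("n_primary must be >= 1")
  if (dendrite_intensity_ratio <= 0 || dendrite_intensity_ratio > 1)
    stop_param("dendrite_intensity_ratio must be in (0, 1]")
  spec <- list(soma_radius_um = soma_radius_um, n_primary = as.integer(n_primary),
               max_order = as.integer(max_order),
               branch_prob_per_order = branch_prob_per_order,
               segment_length_um = segment_length_um, wiggle = wiggle,
               dendrite_intensity_ratio = dendrite_intensity_ratio,
               dendrite_radius_um = dendrite_radius_um,
               grid_shape = as.integer(grid_shape),
               spacing_um = as_spacing(spacing_um),
               soma_peak_intensity = soma_peak_intensity,
               background_intensity = background_intensity,
               noise_sd = noise_sd, root_um = root_um, seed = as.integer(seed))
  class(spec) <- "neuron_spec"
  spec
}

normalize3 <- function(v) v / sqrt(sum(v^2))

# roughly spread unit vectors for the primary dendrites
primary_directions <- function(k) {
  golden <- pi * (3 - sqrt(5))
  t(vapply(seq_len(k), function(i) {
    z <- 1 - 2 * (i - 0.5) / k
    rr <- sqrt(max(0, 1 - z^2))
    th <- golden * i + runif(1, 0, 0.3)
    c(z, rr * cos(th), rr * sin(th))
  }, numeric(3)))
}

#' Generate a ground-truthed synthetic neuron stack
#'
#' Grows a rooted dendritic tree (branches bifurcate with probability
#' `branch_prob_per_order` up to `max_order`), renders it as constant-radius
#' tubes plus a soma ball whose intensity is `1/dendrite_intensity_ratio`
#' times the dendrite intensity, blurs by one voxel and adds noise. Branch
#' directions are reflected at the volume walls so the tree stays inside the
#' grid. The truth skeleton is a rooted `skeleton_graph` with per-node
#' centrifugal branch orders.
#'
#' @param spec a [neuron_spec()].
#' @return list with `stack` and `truth` (list: `label_volume`,
#'   `truth_table`, `truth_skeleton`).
#' @export
generate_neuron_stack <- function(spec) {
  stopifnot(inherits(spec, "neuron_spec"))
  set.seed(spec$seed)
  sp <- spec$spacing_um
  gs <- spec$grid_shape
  extent <- (gs - 1) * sp
  root <- if (is.null(spec$root_um)) extent / 2 else spec$root_um
  wall_lo <- rep(2 * max(sp), 3)
  wall_hi <- extent - 2 * max(sp)
  step_um <- 2
  # growing node buffers (id = position)
  nz <- root[1]; ny <- root[2]; nx <- root[3]
  nparent <- NA_integer_; norder <- 0L; nbranch <- 0L
  next_branch <- 0L
  grow <- function(start_id, dir, order) {
    # one branch: a run of jittered steps; may bifurcate at its end
    L <- max(step_um, rnorm(1, spec$segment_length_um[1], spec$segment_length_um[2]))
    nsteps <- max(2L, round(L / step_um))
    next_branch <<- next_branch + 1L
    bid <- next_branch
    cur <- c(nz[start_id], ny[start_id], nx[start_id])
    prev_id <- start_id
    for (s in seq_len(nsteps)) {
      if (spec$wiggle > 0) dir <- normalize3(dir + rnorm(3, 0, spec$wiggle))
      nxt <- cur + dir * step_um
      refl <- nxt < wall_lo | nxt > wall_hi
      if (any(refl)) {
        dir[refl] <- -dir[refl]
        nxt <- cur + dir * step_um
      }
      cur <- nxt
      nz[length(nz) + 1L] <<- cur[1]
      ny[length(ny) + 1L] <<- cur[2]
      nx[length(nx) + 1L] <<- cur[3]
      nparent[length(nparent) + 1L] <<- prev_id
      norder[length(norder) + 1L] <<- as.integer(order)
      nbranch[length(nbranch) + 1L] <<- bid
      prev_id <- length(nz)
    }
    if (order < spec$max_order && runif(1) < spec$branch_prob_per_order) {
      for (child in 1:2) {
        cd <- normalize3(dir + rnorm(3, 0, 0.6))
        grow(prev_id, cd, order + 1L)
      }
    }
  }
  dirs <- primary_directions(spec$n_primary)
  for (p in seq_len(spec$n_primary)) grow(1L, dirs[p, ], 1L)
  nodes <- data.frame(id = seq_along(nz), z_um = nz, y_um = ny, x_um = nx,
                      parent = nparent, order = norder, branch_id = nbranch)

  # render: soma ball at root + tubes along every edge
  img <- array(spec$background_intensity, gs)
  lab <- array(0L, gs)
  dend_int <- spec$soma_peak_intensity * spec$dendrite_intensity_ratio
  paint_ball <- function(center_um, r_um, value) {
    bx <- ellipsoid_box(center_um, rep(r_um, 3), gs, sp)
    zi <- bx$lo[1]:bx$hi[1]; yi <- bx$lo[2]:bx$hi[2]; xi <- bx$lo[3]:bx$hi[3]
    uz <- ((zi - 1) * sp[1] - center_um[1])^2
    uy <- ((yi - 1) * sp[2] - center_um[2])^2
    ux <- ((xi - 1) * sp[3] - center_um[3])^2
    inside <- outer(outer(uz, uy, `+`), ux, `+`) <= r_um^2
    sub <- img[zi, yi, xi]
    sub[inside] <- pmax(sub[inside], value)
    img[zi, yi, xi] <<- sub
    sl <- lab[zi, yi, xi]
    sl[inside] <- 1L
    lab[zi, yi, xi] <<- sl
  }
  paint_ball(root, spec$soma_radius_um, spec$soma_peak_intensity)
  dend_step <- min(sp) / 2
  for (e in which(!is.na(nodes$parent))) {
    p <- nodes$parent[e]
    a <- c(nz[p], ny[p], nx[p])
    b <- c(nz[e], ny[e], nx[e])
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / dend_step) + 1L))
    for (t in ts) paint_ball(a + t * (b - a), spec$dendrite_radius_um, dend_int)
  }
  img <- blur3d(img, rep(1, 3))
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))

  skel <- skeleton_graph(nodes[, c("id", "z_um", "y_um", "x_um")],
                         parent = nodes$parent, root = 1L)
  skel$nodes$order <- nodes$order
  skel$nodes$branch_id <- nodes$branch_id
  skel$branches <- branch_table(skel)
  truth_table <- data.frame(
    id = 1L, volume_um3 = 4 / 3 * pi * spec$soma_radius_um^3,
    cz_um = root[1], cy_um = root[2], cx_um = root[3],
    subtype = NA_character_)
  list(stack = image_stack(img, sp),
       truth = list(label_volume = label_volume(lab, sp),
                    truth_table = truth_table,
                    truth_skeleton = skel))
}

#' Write a synthetic data set to disk
#'
#' Writes the stack as multi-page TIFF, truth labels as integer TIFF, the
#' truth table as CSV and (when present) the truth skeleton as SWC.
#'
#' @param sim result of [generate_soma_field()] or [generate_neuron_stack()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the vector of files written.
#' @export
write_synthetic <- function(sim, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    stack = file.path(dir, paste0(prefix, "_stack.tif")),
    labels = file.path(dir, paste0(prefix, "_truth_labels.tif")),
    table = file.path(dir, paste0(prefix, "_truth.csv")))
  write_stack(sim$stack, files[["stack"]])
  write_labels(sim$truth$label_volume, files[["labels"]])
  write.csv(sim$truth$truth_table, files[["table"]], row.names = FALSE)
  if (!is.null(sim$truth$truth_skeleton)) {
    f <- file.path(dir, paste0(prefix, "_truth.swc"))
    write_swc(sim$truth$truth_skeleton, f)
    files <- c(files, skeleton = f)
  }
  invisible(files)
}
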