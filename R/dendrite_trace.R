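# Hessian structure enhancement for dendrite extraction. Bright tubes have
# two strongly negative Hessian eigenvalues and one near zero (rod model);
# bright blobs have all three strongly negative (ball model). Responses use
# gamma-normalised scales (Hessian scaled by sigma^2) and take the maximum
# over a scale list, computed in physical units so anisotropic spacing is
# handled.

hessian_components <- function(stack, sigma_um) {
  d <- dim(stack$data)
  sp <- stack$spacing_um
  x <- as.numeric(stack$data)
  comp <- list()
  pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (pr in pairs) {
    v <- x
    for (ax in 1:3) {
      ord <- sum(pr == ax)
      k <- deriv_kernel(sigma_um / sp[ax], sp[ax], ord)
      v <- cpp_convolve_axis(v, d, k, ax)
    }
    comp[[paste(pr, collapse = "")]] <- v * sigma_um^2  # gamma normalisation
  }
  comp
}

# eigenvalues of symmetric 3x3 matrices, vectorised (trigonometric method),
# returned sorted by increasing absolute value (|l1| <= |l2| <= |l3|)
symmetric_eigenvalues <- function(h11, h22, h33, h12, h13, h23) {
  p1 <- h12^2 + h13^2 + h23^2
  q <- (h11 + h22 + h33) / 3
  p2 <- (h11 - q)^2 + (h22 - q)^2 + (h33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  safe <- p > 1e-12
  pp <- ifelse(safe, p, 1)
  b11 <- (h11 - q) / pp; b22 <- (h22 - q) / pp; b33 <- (h33 - q) / pp
  b12 <- h12 / pp; b13 <- h13 / pp; b23 <- h23 / pp
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!safe] <- q[!safe]; e2[!safe] <- q[!safe]; e3[!safe] <- q[!safe]
  # sort by |.| with a 3-element bubble
  swp <- function(a, b) {
    sw <- abs(a) > abs(b)
    t <- a[sw]; a[sw] <- b[sw]; b[sw] <- t
    list(a, b)
  }
  s <- swp(e1, e2); e1 <- s[[1]]; e2 <- s[[2]]
  s <- swp(e2, e3); e2 <- s[[1]]; e3 <- s[[2]]
  s <- swp(e1, e2); e1 <- s[[1]]; e2 <- s[[2]]
  list(l1 = e1, l2 = e2, l3 = e3)
}

frangi_response <- function(ev, s2_floor, alpha = 0.5, beta = 0.5) {
  bright <- ev$l2 < 0 & ev$l3 < 0
  Ra2 <- ifelse(bright, (ev$l2 / ev$l3)^2, 0)
  Rb2 <- ifelse(bright, ev$l1^2 / pmax(abs(ev$l2 * ev$l3), 1e-30), 0)
  S2 <- ev$l1^2 + ev$l2^2 + ev$l3^2
  c2 <- (0.5 * sqrt(max(S2)))^2
  if (c2 <= s2_floor) return(numeric(length(ev$l1)))
  v <- (1 - exp(-Ra2 / (2 * alpha^2))) * exp(-Rb2 / (2 * beta^2)) *
    (1 - exp(-S2 / (2 * c2)))
  ifelse(bright & S2 > s2_floor, v, 0)
}

blob_response <- function(ev, s2_floor) {
  allneg <- ev$l1 < 0 & ev$l2 < 0 & ev$l3 < 0
  Rb <- ifelse(allneg, abs(ev$l1) / sqrt(pmax(abs(ev$l2 * ev$l3), 1e-30)), 0)
  S2 <- ev$l1^2 + ev$l2^2 + ev$l3^2
  c2 <- (0.5 * sqrt(max(S2)))^2
  if (c2 <= s2_floor) return(numeric(length(ev$l1)))
  ifelse(allneg & S2 > s2_floor, pmin(Rb, 1) * (1 - exp(-S2 / (2 * c2))), 0)
}

multiscale_response <- function(stack, scales_um, response_fun) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(scales_um) == 0) stop_param("empty scale list")
  if (any(scales_um <= 0)) stop_param("scales must be > 0")
  d <- dim(stack$data)
  # absolute floor on the Hessian norm: suppresses the numerical residue a
  # flat volume leaves in the second-derivative convolutions
  s2_floor <- (1e-8 * (1 + max(abs(stack$data))))^2
  best <- numeric(prod(d))
  for (s in scales_um) {
    h <- hessian_components(stack, s)
    ev <- symmetric_eigenvalues(h[["11"]], h[["22"]], h[["33"]],
                                h[["12"]], h[["13"]], h[["23"]])
    best <- pmax(best, response_fun(ev, s2_floor))
  }
  image_stack(array(best, d), stack$spacing_um)
}

#' Rod-model structure enhancement
#'
#' Multiscale Hessian tubularity (Frangi vesselness for bright curvilinear
#' structures), maximum over scales. Highlights dendrites against both
#' background and blob-like somata.
#'
#' @param stack an [image_stack()].
#' @param scales_um positive scale list (µm); default `c(1, 1.5, 2, 3)`.
#' @return an [image_stack()] of tubularity responses in `[0, 1]`.
#' @export
rod_enhance <- function(stack, scales_um = c(1, 1.5, 2, 3)) {
  multiscale_response(stack, scales_um, frangi_response)
}

#' Ball-model structure enhancement
#'
#' Multiscale Hessian blobness (all three eigenvalues strongly negative for
#' bright blobs), maximum over scales. Highlights somata; the default
#' scales are soma-sized.
#'
#' @param stack an [image_stack()].
#' @param scales_um positive scale list (µm); default `c(4, 6, 8)`.
#' @return an [image_stack()] of blobness responses.
#' @export
ball_enhance <- function(stack, scales_um = c(4, 6, 8)) {
  multiscale_response(stack, scales_um, blob_response)
}

#' Fuse rod and ball responses
#'
#' Normalises each response to `[0, 1]` by its maximum and takes the
#' voxelwise maximum, so soma and dendrites enter one foreground map.
#'
#' @param rod,ball [image_stack()] responses over the same grid.
#' @return fused [image_stack()].
#' @export
fuse_responses <- function(rod, ball) {
  check_same_shape(rod, ball, "fuse_responses")
  nr <- if (max(rod$data) > 0) rod$data / max(rod$data) else rod$data
  nb <- if (max(ball$data) > 0) ball$data / max(ball$data) else ball$data
  image_stack(pmax(nr, nb), rod$spacing_um)
}

#' Global threshold of a response volume
#'
#' @param stack an [image_stack()] (typically the fused rod/ball response).
#' @param t threshold; voxels with value >= `t` become foreground.
#' @return a [binary_mask()].
#' @export
global_threshold <- function(stack, t) {
  stopifnot(inherits(stack, "image_stack"))
  binary_mask(stack$data >= t, stack$spacing_um)
}

#' Label individual neurons inside a mask
#'
#' Marker-based watershed of the inverted fused response restricted to the
#' mask: one label per neuron, soma plus its dendrites.
#'
#' @param mask a [binary_mask()] of the fused neuron foreground.
#' @param soma_seeds a `seed_set` or marker [label_volume()] (one marker per
#'   soma).
#' @param fused the fused response [image_stack()] used as (inverted)
#'   elevation.
#' @return a [label_volume()].
#' @export
label_neurons <- function(mask, soma_seeds, fused) {
  elev <- image_stack(max(fused$data) - fused$data, fused$spacing_um)
  watershed_inside_mask(elev, soma_seeds, mask)
}

#' Trace one neuron from a stack to a rooted skeleton
#'
#' Convenience composition of the tracing chain for a sparsely labelled
#' single-neuron stack: rod + ball enhancement, fused-response thresholding,
#' largest-component selection, centerline extraction, spur pruning, and
#' rooting at the brightest-blob centre (or a supplied soma centroid).
#'
#' @param stack an [image_stack()].
#' @param rod_scales_um,ball_scales_um Hessian scale lists (µm).
#' @param threshold fused-response threshold in `[0, 1]` (default 0.05).
#' @param close_vox radius (voxels) of the morphological closing applied to
#'   the thresholded mask (default 2). Hessian responses vanish right at
#'   soma-dendrite attachments and branchpoints, which can split one neuron
#'   into several mask components; closing bridges those few-voxel gaps.
#' @param prune_um spur-pruning length (µm), default 4.
#' @param soma_centroid_um optional soma centre (z, y, x µm); default the
#'   argmax of the ball response.
#' @param soma_radius_um contraction radius for rooting; default estimated
#'   as the mask's maximum inscribed-ball radius at the soma centre.
#' @return rooted, ordered `skeleton_graph`.
#' @export
trace_neuron <- function(stack, rod_scales_um = c(1, 1.5, 2, 3),
                         ball_scales_um = c(4, 6, 8), threshold = 0.05,
                         close_vox = 2, prune_um = 4, soma_centroid_um = NULL,
                         soma_radius_um = NULL) {
  rod <- rod_enhance(stack, rod_scales_um)
  ball <- ball_enhance(stack, ball_scales_um)
  fused <- fuse_responses(rod, ball)
  mask <- global_threshold(fused, threshold)
  d <- dim(mask$data)
  if (close_vox > 0) {
    r <- rep(as.integer(close_vox), 3)
    dil <- cpp_maxfilter3d(as.numeric(mask$data), d, r) > 0
    ero <- !(cpp_maxfilter3d(as.numeric(!dil), d, r) > 0)
    mask <- binary_mask(array(ero, d), mask$spacing_um)
  }
  cc <- cpp_conncomp3d(as.logical(mask$data), d, 26L)
  if (max(cc) == 0L) stop_data("threshold left no foreground")
  main <- which.max(tabulate(cc[cc > 0L], nbins = max(cc)))
  mask <- binary_mask(array(cc == main, d), mask$spacing_um)
  if (is.null(soma_centroid_um)) {
    ctr_idx <- which.max(ball$data)
    soma_centroid_um <- as.numeric(index_to_um(arrayInd(ctr_idx, d),
                                               stack$spacing_um))
  }
  if (is.null(soma_radius_um)) {
    edt <- array(cpp_edt3d(as.logical(mask$data), d, mask$spacing_um), d)
    ci <- round(soma_centroid_um / mask$spacing_um) + 1
    ci <- pmin(pmax(ci, 1), d)
    soma_radius_um <- max(edt[ci[1], ci[2], ci[3]], 2 * min(mask$spacing_um))
  }
  skel <- extract_centerline(mask)
  skel <- prune_spurs(skel, prune_um)
  root_and_order(skel, soma_centroid_um, soma_radius_um)
}
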