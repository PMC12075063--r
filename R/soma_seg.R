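# Instance segmentation of somata: distance-transform h-maxima seeding and
# marker-based watershed of the gradient image restricted to a mask. The
# mask provider is pluggable: by default a hysteresis threshold of the
# median-filtered stack, but any externally produced binary mask (for
# example from a trained segmentation network) can be injected.

#' Detect soma seeds from a binary mask
#'
#' Computes the Euclidean distance transform of the mask in physical µm,
#' extracts its h-maxima (domes of prominence >= `h_um`, via grayscale
#' reconstruction), and greedily suppresses peaks closer than
#' `min_seed_distance_um` (keeping the deeper peak). Each surviving dome
#' becomes one connected marker.
#'
#' @param mask a [binary_mask()].
#' @param min_seed_distance_um minimum separation between seeds (µm).
#' @param h_um minimum dome prominence of the distance map (µm).
#' @return a `seed_set`: list with `markers` (a [label_volume()]), `count`,
#'   and `peaks` (data.frame id, cz_um, cy_um, cx_um, distance_um). An empty
#'   mask yields `count = 0`.
#' @export
detect_seeds <- function(mask, min_seed_distance_um = 8, h_um = 2) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  sp <- mask$spacing_um
  empty <- function() {
    structure(list(markers = label_volume(array(0L, d), sp), count = 0L,
                   peaks = data.frame(id = integer(), cz_um = numeric(),
                                      cy_um = numeric(), cx_um = numeric(),
                                      distance_um = numeric())),
              class = "seed_set")
  }
  if (!any(mask$data)) return(empty())
  edt <- cpp_edt3d(as.logical(mask$data), d, sp)
  recon <- cpp_reconstruct3d(pmax(edt - h_um, 0), edt, d)
  mx <- cpp_maxfilter3d(recon, d, c(1L, 1L, 1L))
  cand <- (recon >= mx - 1e-9) & as.logical(mask$data) & (edt > 0)
  if (!any(cand)) return(empty())
  caps <- cpp_conncomp3d(cand, d, 26L)
  ncap <- max(caps)
  idx <- which(caps > 0L)
  capid <- caps[idx]
  # peak voxel (max distance) per cap
  ord <- order(capid, -edt[idx])
  first <- ord[!duplicated(capid[ord])]
  peak_idx <- idx[first]
  peak_cap <- capid[first]
  peak_val <- edt[peak_idx]
  pos <- index_to_um(arrayInd(peak_idx, d), sp)
  # greedy distance suppression, deepest peaks first
  keep <- integer(0)
  for (i in order(-peak_val)) {
    if (length(keep) == 0 ||
        min(sqrt(colSums((t(pos[keep, , drop = FALSE]) - pos[i, ])^2))) >=
          min_seed_distance_um) {
      keep <- c(keep, i)
    }
  }
  keep <- sort(keep)
  relab <- integer(ncap + 1L)
  relab[peak_cap[keep] + 1L] <- seq_along(keep)
  markers <- array(0L, d)
  markers[idx] <- relab[capid + 1L]
  structure(list(markers = label_volume(markers, sp),
                 count = length(keep),
                 peaks = data.frame(id = seq_along(keep),
                                    cz_um = pos[keep, 1], cy_um = pos[keep, 2],
                                    cx_um = pos[keep, 3],
                                    distance_um = peak_val[keep])),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d seeds\n", x$count))
  invisible(x)
}

#' Marker-based watershed inside a mask
#'
#' Floods the elevation image (typically the gradient magnitude) from the
#' seed markers, restricted to the mask, so that every mask voxel receives
#' exactly one seed id and background stays 0. Mask components that contain
#' no seed are assigned the label of the nearest seed.
#'
#' @param gradient an [image_stack()] elevation image.
#' @param seeds a `seed_set` from [detect_seeds()], or a [label_volume()] of
#'   markers.
#' @param mask a [binary_mask()].
#' @return a [label_volume()] partitioning the mask.
#' @export
watershed_inside_mask <- function(gradient, seeds, mask) {
  stopifnot(inherits(gradient, "image_stack"), inherits(mask, "binary_mask"))
  markers <- if (inherits(seeds, "seed_set")) seeds$markers else seeds
  stopifnot(inherits(markers, "label_volume"))
  check_same_shape(gradient, mask, "watershed")
  check_same_shape(markers, mask, "watershed")
  outside <- markers$data > 0L & !mask$data
  if (any(outside)) {
    bad <- sort(unique(markers$data[outside]))
    stop_param("seed(s) ", paste(bad, collapse = ", "), " lie outside the mask")
  }
  d <- dim(mask$data)
  lab <- cpp_watershed3d(as.numeric(gradient$data), as.integer(markers$data),
                         as.logical(mask$data), d)
  resid <- mask$data & lab == 0L
  if (any(resid)) {
    # seedless mask components: adopt the nearest seed's label
    comp <- cpp_conncomp3d(as.logical(resid), d, 26L)
    seed_idx <- which(markers$data > 0L)
    seed_pos <- index_to_um(arrayInd(seed_idx, d), mask$spacing_um)
    seed_lab <- markers$data[seed_idx]
    for (cc in seq_len(max(comp))) {
      vox <- which(comp == cc)
      ctr <- colMeans(index_to_um(arrayInd(vox, d), mask$spacing_um))
      nearest <- which.min(colSums((t(seed_pos) - ctr)^2))
      lab[vox] <- seed_lab[nearest]
    }
  }
  label_volume(array(lab, d), mask$spacing_um)
}

#' Remove instances outside a volume range
#'
#' Instances with physical volume outside `[min_volume_um3, max_volume_um3]`
#' are set to background; survivors are relabelled consecutively (in
#' increasing original id order). The removal log is attached as attribute
#' `"removed"` (data.frame old_id, volume_um3).
#'
#' @param labels a [label_volume()].
#' @param min_volume_um3,max_volume_um3 inclusive bounds (µm³).
#' @return filtered [label_volume()].
#' @export
filter_labels <- function(labels, min_volume_um3 = 500, max_volume_um3 = 60000) {
  stopifnot(inherits(labels, "label_volume"))
  if (min_volume_um3 > max_volume_um3) stop_param("min_volume_um3 > max_volume_um3")
  vv <- voxel_volume_um3(labels$spacing_um)
  m <- max(labels$data)
  if (m == 0L) {
    out <- labels
    attr(out, "removed") <- data.frame(old_id = integer(), volume_um3 = numeric())
    return(out)
  }
  counts <- tabulate(labels$data[labels$data > 0L], nbins = m)
  vol <- counts * vv
  present <- counts > 0L
  keep <- present & vol >= min_volume_um3 & vol <= max_volume_um3
  removed <- data.frame(old_id = which(present & !keep),
                        volume_um3 = vol[present & !keep])
  relab <- integer(m + 1L)
  relab[which(keep) + 1L] <- seq_len(sum(keep))
  out <- label_volume(array(relab[labels$data + 1L], dim(labels$data)),
                      labels$spacing_um)
  attr(out, "removed") <- removed
  out
}

#' Segment somata from a 3D stack
#'
#' The full instance-segmentation chain: median filter, mask provider
#' (hysteresis threshold by default, or an injected [binary_mask()]),
#' gradient magnitude, distance-transform h-maxima seeding, marker-based
#' watershed inside the mask, and volume-range filtering. Deterministic
#' given the stack and parameters; errors are re-raised with the failing
#' stage name attached.
#'
#' @param stack an [image_stack()].
#' @param params named list overriding defaults: `median_radius_vox` (2);
#'   `low_frac` (0.5) and `high_frac` (0.75), the hysteresis thresholds as
#'   fractions of the robust intensity range of the median-filtered stack
#'   (background = median, peak = `top_quantile` = 0.999 quantile), so
#'   `low` sits at the half-peak boundary regardless of how sparsely the
#'   volume is filled; absolute `low`/`high` override them; `refine_mask`
#'   (TRUE) re-thresholds the original stack within `refine_dilate_vox` (2)
#'   voxels of the median-image mask, undoing the box median's erosion of
#'   convex soma boundaries; `sigma_um` (1),
#'   `min_seed_distance_um` (8), `h_um` (2), `min_volume_um3` (500),
#'   `max_volume_um3` (60000).
#' @param mask optional externally produced [binary_mask()]; replaces the
#'   hysteresis stage.
#' @return a [label_volume()] with attributes `"seeds"` (the seed count) and
#'   `"report"` (per-stage data.frame of parameters and counts).
#' @export
segment_somata <- function(stack, params = list(), mask = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  p <- utils::modifyList(list(
    median_radius_vox = 2L, low_frac = 0.5, high_frac = 0.75,
    top_quantile = 0.999, low = NULL, high = NULL, refine_mask = TRUE,
    refine_dilate_vox = 2L, sigma_um = 1,
    min_seed_distance_um = 8, h_um = 2, min_volume_um3 = 500,
    max_volume_um3 = 60000), params)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  report <- list()
  med <- stage("median_filter", median_filter(stack, p$median_radius_vox))
  if (is.null(mask)) {
    bg <- median(med$data)
    pk <- quantile(med$data, p$top_quantile, names = FALSE)
    lo <- if (!is.null(p$low)) p$low else bg + p$low_frac * (pk - bg)
    hi <- if (!is.null(p$high)) p$high else bg + p$high_frac * (pk - bg)
    mask <- stage("hysteresis_threshold", hysteresis_threshold(med, lo, hi))
    if (isTRUE(p$refine_mask) && any(mask$data)) {
      # the box median erodes convex boundaries (curvature bias); recover
      # the unbiased half-peak boundary by re-thresholding the original
      # stack inside a small dilation of the median-image mask (neurites
      # stay excluded: they lie outside the dilated soma mask)
      mask <- stage("refine_mask", {
        d <- dim(stack$data)
        near <- cpp_maxfilter3d(as.numeric(mask$data), d,
                                rep(as.integer(p$refine_dilate_vox), 3)) > 0
        fine <- hysteresis_threshold(stack, lo, hi)
        binary_mask(fine$data & array(near, d), stack$spacing_um)
      })
    }
    report$threshold <- data.frame(stage = "hysteresis_threshold",
                                   low = lo, high = hi)
  } else {
    stopifnot(inherits(mask, "binary_mask"))
    stage("mask_provider", check_same_shape(mask, stack, "external mask"))
  }
  empty_out <- function(seed_count) {
    out <- label_volume(array(0L, dim(stack$data)), stack$spacing_um)
    attr(out, "seeds") <- seed_count
    attr(out, "report") <- do.call(rbind, lapply(report, function(x)
      data.frame(stage = x$stage[1])))
    out
  }
  if (!any(mask$data)) return(empty_out(0L))
  grad <- stage("gradient_magnitude", gradient_magnitude(med, p$sigma_um))
  seeds <- stage("detect_seeds",
                 detect_seeds(mask, p$min_seed_distance_um, p$h_um))
  if (seeds$count == 0L) return(empty_out(0L))
  ws <- stage("watershed", watershed_inside_mask(grad, seeds, mask))
  out <- stage("filter_labels",
               filter_labels(ws, p$min_volume_um3, p$max_volume_um3))
  attr(out, "seeds") <- seeds$count
  attr(out, "report") <- data.frame(
    stage = c("median_filter", "mask", "detect_seeds", "watershed",
              "filter_labels"),
    count = c(NA, sum(mask$data), seeds$count, n_labels(ws), n_labels(out)))
  out
}
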