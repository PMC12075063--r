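# Per-soma morphometry. Volumes are measured in the cleared (expanded)
# imaging frame and corrected back to the tissue frame by the cube of the
# linear clearing-expansion factor (default 1.2, i.e. corrected volumes are
# 1.728 times smaller than measured). Both frames are reported.

#' Clearing-expansion specification
#' @param linear_factor isotropic linear expansion of the cleared tissue
#'   relative to the native tissue (dimensionless, > 0). Default 1.2.
#' @return an `expansion_spec` object.
#' @export
expansion_spec <- function(linear_factor = 1.2) {
  if (!is.numeric(linear_factor) || linear_factor <= 0)
    stop_param("linear expansion factor must be > 0")
  structure(list(linear_factor = linear_factor), class = "expansion_spec")
}

#' Volumetric expansion factor
#'
#' The factor by which measured (expanded-frame) volumes exceed real
#' volumes: the cube of the linear expansion factor. 1.2 gives 1.728.
#'
#' @param expansion an [expansion_spec()] or a bare numeric linear factor.
#' @return dimensionless volume factor.
#' @export
expansion_volume_factor <- function(expansion) {
  f <- if (inherits(expansion, "expansion_spec")) expansion$linear_factor
       else expansion
  if (!is.numeric(f) || f <= 0) stop_param("linear expansion factor must be > 0")
  f^3
}

#' Measure per-instance soma morphometry
#'
#' One record per nonzero label: voxel count, raw volume (voxel count times
#' voxel volume, in the expanded imaging frame), expansion-corrected volume,
#' centroid (µm, expanded frame) and bounding box (0-based voxel index
#' ranges).
#'
#' @param labels a [label_volume()].
#' @param expansion an [expansion_spec()]; factor 1 makes both volumes equal.
#' @return data.frame with columns id, voxel_count, volume_raw_um3,
#'   volume_um3, cz_um, cy_um, cx_um, z0, z1, y0, y1, x0, x1. Empty label
#'   volume gives zero rows.
#' @export
measure_somas <- function(labels, expansion = expansion_spec(1.2)) {
  stopifnot(inherits(labels, "label_volume"))
  vf <- expansion_volume_factor(expansion)
  vv <- voxel_volume_um3(labels$spacing_um)
  idx <- which(labels$data > 0L)
  empty <- data.frame(id = integer(), voxel_count = integer(),
                      volume_raw_um3 = numeric(), volume_um3 = numeric(),
                      cz_um = numeric(), cy_um = numeric(), cx_um = numeric(),
                      z0 = integer(), z1 = integer(), y0 = integer(),
                      y1 = integer(), x0 = integer(), x1 = integer())
  if (length(idx) == 0L) return(empty)
  lv <- labels$data[idx]
  ids <- sort(unique(lv))
  ai <- arrayInd(idx, dim(labels$data))
  pos <- index_to_um(ai, labels$spacing_um)
  cnt <- as.integer(tabulate(lv, nbins = max(ids))[ids])
  csum <- rowsum(pos, lv)
  ctr <- csum / cnt
  bb <- function(col, f) as.integer(vapply(split(ai[, col], lv), f, 0) - 1L)
  data.frame(id = ids, voxel_count = cnt,
             volume_raw_um3 = cnt * vv,
             volume_um3 = cnt * vv / vf,
             cz_um = ctr[, 1], cy_um = ctr[, 2], cx_um = ctr[, 3],
             z0 = bb(1, min), z1 = bb(1, max),
             y0 = bb(2, min), y1 = bb(2, max),
             x0 = bb(3, min), x1 = bb(3, max))
}

#' Soma-size histogram on the standard grid
#'
#' Left-closed right-open bins of width 1,000 µm³ from 0 to 38,000 µm³
#' (38 bins); volumes at or above 38,000 µm³ are tallied in `n_above`.
#'
#' @param volumes numeric soma volumes (µm³), all >= 0.
#' @param ids optional ids used in error messages for negative volumes.
#' @return a `size_histogram`: list with `bin_edges` (length 39), `counts`
#'   (length 38), `n_below`, `n_above`, `n`.
#' @export
histogram_volumes <- function(volumes, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(volumes)
  neg <- which(volumes < 0)
  if (length(neg) > 0)
    stop_data("negative volume for id(s) ", paste(ids[neg], collapse = ", "))
  width <- 1000
  nbins <- 38L
  k <- floor(volumes / width)
  inr <- k < nbins
  counts <- tabulate(k[inr] + 1L, nbins = nbins)
  structure(list(bin_edges = seq(0, nbins * width, by = width),
                 counts = as.integer(counts),
                 n_below = 0L,
                 n_above = sum(!inr),
                 n = length(volumes)),
            class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  cat(sprintf("<size_histogram> %d somata in %d bins (%d above range)\n",
              x$n, length(x$counts), x$n_above))
  invisible(x)
}

#' 2D-projection equivalent diameters within a slab
#'
#' Cross-check of the 3D volumes against projected 2D sizes: takes a slab of
#' given thickness along z, keeps only instances fully contained in the slab
#' (instances touching the slab faces are excluded), projects each along z
#' and reports the equivalent-circle diameter of the projected area.
#' Instances whose projections overlap another eligible instance are flagged
#' `merged` for QC.
#'
#' @param labels a [label_volume()].
#' @param slab_thickness_um slab thickness along z (µm); must fit in the
#'   volume.
#' @param z_start_um slab start (µm), default 0.
#' @return data.frame with columns id, area_um2, equiv_diameter_um, merged.
#' @export
project_and_measure_diameters <- function(labels, slab_thickness_um = 100,
                                          z_start_um = 0) {
  stopifnot(inherits(labels, "label_volume"))
  sp <- labels$spacing_um
  d <- dim(labels$data)
  z_extent <- (d[1] - 1) * sp[1]
  if (slab_thickness_um > z_extent)
    stop_param("slab thicker than the volume (", z_extent, " um)")
  zc <- (seq_len(d[1]) - 1) * sp[1]
  in_slab <- which(zc >= z_start_um & zc <= z_start_um + slab_thickness_um)
  if (length(in_slab) < 2) stop_param("slab contains fewer than 2 z-slices")
  sub <- labels$data[in_slab, , , drop = FALSE]
  empty <- data.frame(id = integer(), area_um2 = numeric(),
                      equiv_diameter_um = numeric(), merged = logical())
  if (all(sub == 0L)) return(empty)
  # eligible: all voxels of the instance inside the slab interior
  m <- max(labels$data)
  ids_all <- which(tabulate(labels$data[labels$data > 0L], nbins = m) > 0L)
  cnt_all <- tabulate(labels$data[labels$data > 0L], nbins = m)
  interior <- in_slab[-c(1L, length(in_slab))]
  sub_int <- labels$data[interior, , , drop = FALSE]
  cnt_int <- tabulate(sub_int[sub_int > 0L], nbins = m)
  eligible <- ids_all[cnt_int[ids_all] == cnt_all[ids_all]]
  if (length(eligible) == 0L) return(empty)
  # project eligible instances along z: distinct (y,x) columns per id
  idx <- which(sub_int > 0L & array(sub_int %in% eligible, dim(sub_int)))
  lv <- sub_int[idx]
  ai <- arrayInd(idx, dim(sub_int))
  pix <- (ai[, 2] - 1) + dim(sub_int)[2] * (ai[, 3] - 1)
  key <- !duplicated(data.frame(lv, pix))
  lvp <- lv[key]; pixp <- pix[key]
  area_pix <- tabulate(lvp, nbins = m)[eligible]
  pix_area <- sp[2] * sp[3]
  area <- area_pix * pix_area
  # merged flag: a projected pixel claimed by >1 eligible id
  dup_pix <- unique(pixp[duplicated(pixp)])
  merged_ids <- unique(lvp[pixp %in% dup_pix])
  data.frame(id = eligible, area_um2 = area,
             equiv_diameter_um = 2 * sqrt(area / pi),
             merged = eligible %in% merged_ids)
}
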