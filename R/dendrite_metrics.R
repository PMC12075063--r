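# Quantification of rooted skeletons: Sholl intersection profiles
# (concentric spheres about the root, 3D Euclidean distance), crossings
# attributed to centrifugal branch order, per-order branch lengths, and
# tortuosity. Edges are densified to <= 1 um sub-segments before crossing
# counts so long polyline edges cannot hide double crossings.

# densified sub-segments: data.frame(d0, d1, order) of root distances at
# sub-segment endpoints plus the branch order of the parent edge
densified_segments <- function(skel, exclude_axon = FALSE, max_seg_um = 1) {
  stopifnot(is_rooted(skel))
  xyz <- node_xyz(skel)
  ids <- skel$nodes$id
  rootxyz <- xyz[match(skel$root, ids), ]
  pid <- match(skel$parent, ids)
  e <- which(!is.na(pid))
  if (exclude_axon && !is.null(skel$nodes$type))
    e <- e[skel$nodes$type[e] != 2L]
  if (length(e) == 0)
    return(data.frame(d0 = numeric(), d1 = numeric(), order = integer()))
  ords <- if (!is.null(skel$nodes$order)) skel$nodes$order[e]
          else rep(NA_integer_, length(e))
  res <- vector("list", length(e))
  for (k in seq_along(e)) {
    a <- xyz[pid[e[k]], ]
    b <- xyz[e[k], ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / max_seg_um))
    ts <- seq(0, 1, length.out = nseg + 1L)
    pts <- outer(1 - ts, a) + outer(ts, b)
    dd <- sqrt(rowSums(sweep(pts, 2, rootxyz)^2))
    res[[k]] <- data.frame(d0 = dd[-length(dd)], d1 = dd[-1],
                           order = ords[k])
  }
  do.call(rbind, res)
}

crossing_counts <- function(segs, radii) {
  vapply(radii, function(r)
    sum((segs$d0 < r & segs$d1 >= r) | (segs$d0 > r & segs$d1 <= r)),
    0L)
}

#' Sholl intersection profile
#'
#' Counts skeleton crossings of concentric spheres of radius `r_step_um`,
#' `2 r_step_um`, ... centred at the root, using 3D Euclidean distance. A
#' sub-segment crosses radius `r` when its endpoint distances straddle `r`;
#' an endpoint exactly at `r` is assigned to the sub-segment that ends
#' there, so each true crossing counts once.
#'
#' @param skel rooted `skeleton_graph`.
#' @param r_step_um radius step (µm), > 0; default 25.
#' @param exclude_axon drop sub-segments on the flagged axon candidate.
#' @return data.frame (class `sholl_profile`) with `radius_um`,
#'   `crossings`; zero beyond the maximal node distance.
#' @export
sholl <- function(skel, r_step_um = 25, exclude_axon = FALSE) {
  stopifnot(inherits(skel, "skeleton_graph"))
  if (!is_rooted(skel)) stop_param("Sholl analysis requires a rooted skeleton")
  if (r_step_um <= 0) stop_param("r_step_um must be > 0")
  segs <- densified_segments(skel, exclude_axon)
  maxd <- if (nrow(segs) > 0) max(segs$d1, segs$d0) else 0
  radii <- seq(r_step_um, by = r_step_um,
               length.out = max(1L, ceiling(maxd / r_step_um)))
  out <- data.frame(radius_um = radii,
                    crossings = crossing_counts(segs, radii))
  class(out) <- c("sholl_profile", "data.frame")
  out
}

#' Sholl crossings attributed to branch order
#'
#' Each sphere crossing is attributed to the centrifugal order of the
#' crossed branch; per-order totals over all radii partition the total
#' Sholl counts.
#'
#' @inheritParams sholl
#' @return data.frame with `radius_um`, `order`, `crossings` (orders with
#'   zero crossings at a radius are omitted).
#' @export
crossings_by_order <- function(skel, r_step_um = 25, exclude_axon = FALSE) {
  stopifnot(inherits(skel, "skeleton_graph"))
  if (!is_rooted(skel)) stop_param("Sholl analysis requires a rooted skeleton")
  if (is.null(skel$nodes$order))
    stop_param("skeleton has no branch orders; run root_and_order first")
  segs <- densified_segments(skel, exclude_axon)
  maxd <- if (nrow(segs) > 0) max(segs$d1, segs$d0) else 0
  radii <- seq(r_step_um, by = r_step_um,
               length.out = max(1L, ceiling(maxd / r_step_um)))
  res <- list()
  for (o in sort(unique(segs$order))) {
    so <- segs[segs$order == o, ]
    cnt <- crossing_counts(so, radii)
    nz <- cnt > 0
    if (any(nz))
      res[[length(res) + 1L]] <- data.frame(radius_um = radii[nz], order = o,
                                            crossings = cnt[nz])
  }
  out <- if (length(res) > 0) do.call(rbind, res)
         else data.frame(radius_um = numeric(), order = integer(),
                         crossings = integer())
  rownames(out) <- NULL
  out
}

sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_

#' Branch lengths by centrifugal order
#'
#' Mean and SEM (n-1 denominator) of branch path lengths for orders 1 to
#' `max_order`; deeper branches are summarised in a single extra row with
#' `order = NA` rather than silently dropped.
#'
#' @param skel rooted, ordered `skeleton_graph`.
#' @param max_order deepest order reported individually (default 6).
#' @param exclude_axon drop branches on the flagged axon candidate.
#' @return data.frame: order, n, mean_length_um, sem_length_um,
#'   mean_tortuosity, sem_tortuosity.
#' @export
branch_lengths_by_order <- function(skel, max_order = 6, exclude_axon = FALSE) {
  stopifnot(inherits(skel, "skeleton_graph"), !is.null(skel$branches))
  br <- skel$branches
  if (exclude_axon && !is.null(skel$axon_branch) && !is.na(skel$axon_branch)) {
    stem <- function(b) {
      while (!is.na(br$parent_branch[b])) b <- br$parent_branch[b]
      b
    }
    br <- br[vapply(seq_len(nrow(br)), stem, 0L) != skel$axon_branch, ]
  }
  row_for <- function(sel, o) {
    data.frame(order = o, n = sum(sel),
               mean_length_um = if (any(sel)) mean(br$path_length_um[sel]) else NA_real_,
               sem_length_um = sem(br$path_length_um[sel]),
               mean_tortuosity = if (any(sel)) mean(br$tortuosity[sel]) else NA_real_,
               sem_tortuosity = sem(br$tortuosity[sel]))
  }
  out <- do.call(rbind, lapply(seq_len(max_order), function(o)
    row_for(br$order == o, o)))
  if (any(br$order > max_order))
    out <- rbind(out, row_for(br$order > max_order, NA_integer_))
  out
}

#' Tortuosity of a polyline branch
#'
#' Ratio of curve length (sum of segment lengths) to chord length
#' (straight-line distance between the endpoints); always >= 1, equal to 1
#' iff the polyline is straight.
#'
#' @param coords_um numeric matrix of ordered polyline points (rows), any
#'   fixed 3-column coordinate order.
#' @return dimensionless tortuosity.
#' @export
tortuosity <- function(coords_um) {
  coords_um <- as.matrix(coords_um)
  if (nrow(coords_um) < 2) stop_param("a branch needs >= 2 points")
  path <- sum(sqrt(rowSums((coords_um[-1, , drop = FALSE] -
                              coords_um[-nrow(coords_um), , drop = FALSE])^2)))
  chord <- sqrt(sum((coords_um[nrow(coords_um), ] - coords_um[1, ])^2))
  if (chord == 0) stop_data("zero chord length (closed loop?)")
  path / chord
}

#' Tidy per-branch report for one neuron
#'
#' One row per branch (id, order, path length, chord length, tortuosity)
#' plus the Sholl profile; group-level statistics are downstream of this
#' table.
#'
#' @param skel rooted, ordered `skeleton_graph`.
#' @param neuron_id identifier copied into the table.
#' @param r_step_um Sholl step (µm).
#' @param exclude_axon drop the flagged axon candidate from both outputs.
#' @return list with `branches` (data.frame) and `sholl` (data.frame).
#' @export
neuron_report <- function(skel, neuron_id = 1L, r_step_um = 25,
                          exclude_axon = FALSE) {
  stopifnot(inherits(skel, "skeleton_graph"), !is.null(skel$branches))
  br <- skel$branches
  if (exclude_axon && !is.null(skel$axon_branch) && !is.na(skel$axon_branch)) {
    stem <- function(b) {
      while (!is.na(br$parent_branch[b])) b <- br$parent_branch[b]
      b
    }
    br <- br[vapply(seq_len(nrow(br)), stem, 0L) != skel$axon_branch, ]
  }
  branches <- data.frame(neuron = rep(neuron_id, nrow(br)),
                         branch_id = br$branch_id,
                         order = br$order,
                         path_length_um = br$path_length_um,
                         chord_length_um = br$chord_length_um,
                         tortuosity = br$tortuosity)
  list(branches = branches,
       sholl = sholl(skel, r_step_um, exclude_axon))
}
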