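# Rooted skeleton trees. A skeleton_graph holds a node table (id, physical
# coordinates in um, SWC structure type) plus either an undirected edge
# list (unrooted, fresh from thinning) or a parent vector (rooted). Branch
# decomposition cuts the rooted tree at branchpoints and assigns
# centrifugal orders: root-attached branches are order 1, each child branch
# is its parent's order + 1.

#' Construct a skeleton graph
#'
#' @param nodes data.frame with columns id, z_um, y_um, x_um (ids unique).
#' @param edges undirected edge data.frame (from, to), for unrooted graphs.
#' @param parent integer parent id per node (`NA` for the root), for rooted
#'   graphs; exactly one of `edges`/`parent` must be given.
#' @param root root node id (required with `parent`).
#' @return a `skeleton_graph`.
#' @export
skeleton_graph <- function(nodes, edges = NULL, parent = NULL, root = NULL) {
  stopifnot(all(c("id", "z_um", "y_um", "x_um") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop_param("node ids must be unique")
  if (is.null(parent) == is.null(edges))
    stop_param("give exactly one of `edges` or `parent`")
  g <- list(nodes = nodes[, c("id", "z_um", "y_um", "x_um"),
                          drop = FALSE])
  if (!is.null(parent)) {
    if (is.null(root)) stop_param("rooted graph needs `root`")
    if (sum(is.na(parent)) != 1L) stop_param("exactly one node may lack a parent")
    g$parent <- as.integer(parent)
    g$root <- as.integer(root)
  } else {
    g$edges <- data.frame(from = as.integer(edges$from),
                          to = as.integer(edges$to))
    g$root <- NULL
  }
  class(g) <- "skeleton_graph"
  g
}

is_rooted <- function(skel) !is.null(skel$root)

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %s\n", nrow(x$nodes),
              if (is_rooted(x)) sprintf("rooted at node %d", x$root)
              else "unrooted"))
  if (!is.null(x$branches))
    cat(sprintf("  %d branches, orders 1..%d\n", nrow(x$branches),
                max(x$branches$order)))
  invisible(x)
}

node_xyz <- function(skel) {
  as.matrix(skel$nodes[, c("z_um", "y_um", "x_um")])
}

skel_igraph <- function(skel) {
  if (is_rooted(skel)) {
    e <- cbind(skel$parent, skel$nodes$id)
    e <- e[!is.na(e[, 1]), , drop = FALSE]
  } else {
    e <- as.matrix(skel$edges)
  }
  igraph::graph_from_data_frame(
    data.frame(from = as.character(e[, 1]), to = as.character(e[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(skel$nodes$id)))
}

edge_lengths_um <- function(skel) {
  stopifnot(is_rooted(skel))
  xyz <- node_xyz(skel)
  pid <- match(skel$parent, skel$nodes$id)
  len <- sqrt(rowSums((xyz - xyz[pid, , drop = FALSE])^2))
  len[is.na(skel$parent)] <- 0
  len
}

#' Decompose a rooted skeleton into ordered branches
#'
#' Branches are maximal paths between consecutive branchpoints (or the root
#' / a tip). Each branch row reports its centrifugal order, path length
#' (sum of edge lengths), chord length (straight-line distance between its
#' endpoints) and tortuosity (path / chord).
#'
#' @param skel a rooted `skeleton_graph`.
#' @return data.frame: branch_id, order, parent_branch, n_edges,
#'   path_length_um, chord_length_um, tortuosity, start_node, end_node.
#' @export
branch_table <- function(skel) {
  stopifnot(inherits(skel, "skeleton_graph"))
  if (!is_rooted(skel)) stop_param("branch decomposition requires a rooted skeleton")
  ids <- skel$nodes$id
  pid <- match(skel$parent, ids)
  n <- length(ids)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pid[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  xyz <- node_xyz(skel)
  rooti <- match(skel$root, ids)
  res <- list()
  bid <- 0L
  # stack of (start node index, first child index, order, parent branch)
  stack <- lapply(children[[rooti]], function(ch)
    list(start = rooti, child = ch, order = 1L, pb = NA_integer_))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    bid <- bid + 1L
    path <- c(fr$start, fr$child)
    cur <- fr$child
    while (length(children[[cur]]) == 1L) {
      cur <- children[[cur]][1]
      path <- c(path, cur)
    }
    seg <- xyz[path, , drop = FALSE]
    plen <- sum(sqrt(rowSums((seg[-1, , drop = FALSE] -
                                seg[-nrow(seg), , drop = FALSE])^2)))
    clen <- sqrt(sum((seg[nrow(seg), ] - seg[1, ])^2))
    res[[bid]] <- data.frame(
      branch_id = bid, order = fr$order, parent_branch = fr$pb,
      n_edges = length(path) - 1L,
      path_length_um = plen, chord_length_um = clen,
      tortuosity = if (clen > 0) plen / clen else NA_real_,
      start_node = ids[path[1]], end_node = ids[path[length(path)]])
    for (ch in children[[cur]])
      stack[[length(stack) + 1L]] <- list(start = cur, child = ch,
                                          order = fr$order + 1L, pb = bid)
  }
  if (length(res) == 0)
    return(data.frame(branch_id = integer(), order = integer(),
                      parent_branch = integer(), n_edges = integer(),
                      path_length_um = numeric(), chord_length_um = numeric(),
                      tortuosity = numeric(), start_node = integer(),
                      end_node = integer()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# per-node branch id / order from a branch table (root gets order 0)
annotate_nodes <- function(skel) {
  br <- skel$branches
  ids <- skel$nodes$id
  pid <- match(skel$parent, ids)
  ord <- integer(length(ids))
  bidv <- integer(length(ids))
  # walk each branch path: nodes after the start carry the branch id
  for (b in seq_len(nrow(br))) {
    cur <- match(br$end_node[b], ids)
    stopn <- match(br$start_node[b], ids)
    while (!is.na(cur) && cur != stopn) {
      ord[cur] <- br$order[b]
      bidv[cur] <- br$branch_id[b]
      cur <- pid[cur]
    }
  }
  skel$nodes$order <- ord
  skel$nodes$branch_id <- bidv
  skel
}

#' Extract the centerline skeleton of a binary mask
#'
#' Resamples the mask to isotropic voxels at the smallest spacing
#' (trilinear), thins it to a one-voxel-wide curve skeleton by sequential
#' topological thinning with endpoint preservation, and converts the
#' 26-adjacent skeleton voxels to a graph whose edges form the geometric
#' minimum spanning tree (guaranteeing an acyclic skeleton).
#'
#' @param mask a [binary_mask()] containing exactly one connected component.
#' @return an unrooted `skeleton_graph` with nodes at skeleton voxel
#'   centres (µm).
#' @export
extract_centerline <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  if (!any(mask$data)) stop_data("empty mask")
  cc <- cpp_conncomp3d(as.logical(mask$data), d, 26L)
  if (max(cc) > 1L)
    stop_data("mask has ", max(cc),
              " connected components; run label_neurons first and pass one instance")
  s <- min(mask$spacing_um)
  rs <- cpp_resample3d(as.numeric(mask$data), d, mask$spacing_um, rep(s, 3))
  iso <- rs$data >= 0.5
  di <- rs$dim
  if (!any(iso)) stop_data("mask vanished under resampling")
  sk <- cpp_thin3d(iso, di)
  vox <- which(sk)
  if (length(vox) == 0L) vox <- which(iso)[which.max(cpp_edt3d(iso, di, rep(s, 3))[iso])]
  ai <- arrayInd(vox, di)
  nodes <- data.frame(id = seq_along(vox),
                      z_um = (ai[, 1] - 1) * s,
                      y_um = (ai[, 2] - 1) * s,
                      x_um = (ai[, 3] - 1) * s)
  if (length(vox) == 1L)
    return(skeleton_graph(nodes, edges = data.frame(from = integer(),
                                                    to = integer())))
  # adjacency: 26-neighbour pairs among skeleton voxels (forward offsets)
  key <- sort(vox)
  pos <- match(vox, key)  # not needed; build via lookup below
  lut <- integer(0)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[offs$dz != 0 | offs$dy != 0 | offs$dx != 0, ]
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 |
                 (offs$dy == 0 & offs$dx > 0))), ]  # forward half
  id_of <- integer(prod(di))
  id_of[vox] <- seq_along(vox)
  for (r in seq_len(nrow(offs))) {
    dz <- offs$dz[r]; dy <- offs$dy[r]; dx <- offs$dx[r]
    j1 <- ai[, 1] + dz; j2 <- ai[, 2] + dy; j3 <- ai[, 3] + dx
    ok <- j1 >= 1 & j1 <= di[1] & j2 >= 1 & j2 <= di[2] & j3 >= 1 & j3 <= di[3]
    lin <- (j1[ok] - 1) + di[1] * ((j2[ok] - 1) + di[2] * (j3[ok] - 1)) + 1
    hit <- id_of[lin] > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, id_of[lin[hit]])
    wt <- c(wt, rep(sqrt(dz^2 + dy^2 + dx^2) * s, sum(hit)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to), weight = wt),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id)))
  mstg <- igraph::mst(g)
  el <- igraph::as_edgelist(mstg)
  skeleton_graph(nodes, edges = data.frame(from = as.integer(el[, 1]),
                                           to = as.integer(el[, 2])))
}

chain_neighbours <- function(skel) {
  n <- nrow(skel$nodes)
  adj <- vector("list", n)
  e <- skel$edges
  f <- match(e$from, skel$nodes$id)
  t <- match(e$to, skel$nodes$id)
  for (i in seq_along(f)) {
    adj[[f[i]]] <- c(adj[[f[i]]], t[i])
    adj[[t[i]]] <- c(adj[[t[i]]], f[i])
  }
  adj
}

#' Prune short terminal spurs
#'
#' Iteratively removes tip-terminated chains shorter than `min_len_um`
#' (thinning artefacts), repeating to a fixpoint. On a rooted skeleton,
#' chains attached directly to the root (order-1 stems) are preserved.
#'
#' @param skel a `skeleton_graph` (rooted or unrooted).
#' @param min_len_um minimum terminal chain length to keep (µm).
#' @return pruned `skeleton_graph` (same class of rootedness).
#' @export
prune_spurs <- function(skel, min_len_um) {
  stopifnot(inherits(skel, "skeleton_graph"))
  rooted <- is_rooted(skel)
  if (rooted) skel <- unroot_skeleton(skel)
  root_id <- attr(skel, "was_root")
  repeat {
    adj <- chain_neighbours(skel)
    deg <- lengths(adj)
    xyz <- node_xyz(skel)
    ids <- skel$nodes$id
    tips <- which(deg == 1L)
    drop <- integer(0)
    for (tp in tips) {
      if (!is.null(root_id) && ids[tp] == root_id) next
      chain <- tp
      prev <- 0L
      cur <- tp
      len <- 0
      repeat {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) != 1L) break
        len <- len + sqrt(sum((xyz[nxt, ] - xyz[cur, ])^2))
        if (deg[nxt] >= 3L || (!is.null(root_id) && ids[nxt] == root_id)) {
          if (len < min_len_um) drop <- c(drop, chain)
          break
        }
        prev <- cur
        cur <- nxt
        chain <- c(chain, cur)
        if (deg[cur] == 1L) break  # isolated path: keep whole
      }
    }
    drop <- unique(drop)
    if (length(drop) == 0L) break
    keep_ids <- ids[-drop]
    skel$nodes <- skel$nodes[skel$nodes$id %in% keep_ids, , drop = FALSE]
    skel$edges <- skel$edges[skel$edges$from %in% keep_ids &
                               skel$edges$to %in% keep_ids, , drop = FALSE]
  }
  if (rooted) skel <- root_and_order(skel, root_hint(skel, root_id))
  skel
}

unroot_skeleton <- function(skel) {
  e <- data.frame(from = skel$parent, to = skel$nodes$id)
  e <- e[!is.na(e$from), , drop = FALSE]
  out <- skeleton_graph(skel$nodes[, c("id", "z_um", "y_um", "x_um")],
                        edges = e)
  attr(out, "was_root") <- skel$root
  out
}

root_hint <- function(skel, root_id) {
  i <- match(root_id, skel$nodes$id)
  as.numeric(skel$nodes[i, c("z_um", "y_um", "x_um")])
}

#' Root a skeleton and assign centrifugal branch orders
#'
#' The root is the skeleton node nearest the soma centroid (ties broken by
#' lowest node id). All edges are oriented away from the root, the tree is
#' cut into branches at branchpoints, and centrifugal orders are assigned
#' (root-attached branches are order 1). When `soma_radius_um` is given,
#' every skeleton node within that distance of the centroid is contracted
#' into the root first, so the thinning remnant of the soma body does not
#' inflate branch orders.
#'
#' @param skel a `skeleton_graph` (unrooted or rooted).
#' @param soma_centroid_um numeric (z, y, x) soma centre in µm.
#' @param soma_radius_um optional contraction radius (µm).
#' @return rooted `skeleton_graph` with `$branches` (see [branch_table()])
#'   and per-node `order`/`branch_id` columns.
#' @export
root_and_order <- function(skel, soma_centroid_um, soma_radius_um = NULL) {
  stopifnot(inherits(skel, "skeleton_graph"))
  if (is_rooted(skel)) skel <- unroot_skeleton(skel)
  xyz <- node_xyz(skel)
  d2 <- colSums((t(xyz) - soma_centroid_um)^2)
  nearest <- which(d2 == min(d2))
  rooti <- nearest[which.min(skel$nodes$id[nearest])]
  root_id <- skel$nodes$id[rooti]
  nodes <- skel$nodes
  edges <- skel$edges
  if (!is.null(soma_radius_um)) {
    inside <- which(sqrt(d2) <= soma_radius_um)
    if (length(inside) > 1) {
      inside_ids <- nodes$id[inside]
      # re-route edges touching the soma ball to the root, drop internal ones
      f_in <- edges$from %in% inside_ids
      t_in <- edges$to %in% inside_ids
      edges$from[f_in] <- root_id
      edges$to[t_in] <- root_id
      edges <- edges[edges$from != edges$to, , drop = FALSE]
      edges <- edges[!duplicated(edges), , drop = FALSE]
      keep <- !(nodes$id %in% setdiff(inside_ids, root_id))
      nodes <- nodes[keep, , drop = FALSE]
    }
  }
  # orient away from root by BFS
  n <- nrow(nodes)
  f <- match(edges$from, nodes$id)
  t <- match(edges$to, nodes$id)
  adj <- vector("list", n)
  for (i in seq_along(f)) {
    adj[[f[i]]] <- c(adj[[f[i]]], t[i])
    adj[[t[i]]] <- c(adj[[t[i]]], f[i])
  }
  rooti <- match(root_id, nodes$id)
  parent <- rep(NA_integer_, n)
  visited <- logical(n)
  visited[rooti] <- TRUE
  queue <- rooti
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        parent[nb] <- nodes$id[cur]
        queue <- c(queue, nb)
      }
    }
  }
  if (!all(visited))
    stop_data("skeleton is disconnected (", sum(!visited),
              " unreachable nodes); extract one component first")
  out <- skeleton_graph(nodes, parent = parent, root = root_id)
  out$branches <- branch_table(out)
  out <- annotate_nodes(out)
  out
}

#' Flag the axon candidate
#'
#' Motoneuron reconstructions include the axon; dendritic statistics should
#' be able to exclude it. The order-1 branch whose subtree reaches the
#' greatest root-to-tip path distance is flagged as the axon candidate if
#' that distance exceeds `min_len_um`; all nodes in its subtree get SWC
#' type 2.
#'
#' @param skel a rooted, ordered `skeleton_graph`.
#' @param min_len_um minimum root-to-tip path length to call an axon (µm).
#' @return the skeleton with `$axon_branch` (branch_id or NA) and per-node
#'   `type` column (1 root, 2 axon candidate, 3 dendrite).
#' @export
mark_axon_candidate <- function(skel, min_len_um = 500) {
  stopifnot(is_rooted(skel), !is.null(skel$branches))
  br <- skel$branches
  # subtree path depth per order-1 branch
  top <- function(b) {
    while (!is.na(br$parent_branch[b])) b <- br$parent_branch[b]
    b
  }
  stem <- vapply(seq_len(nrow(br)), top, 0L)
  depth <- numeric(nrow(br))
  for (b in order(br$order)) {
    depth[b] <- br$path_length_um[b] +
      if (is.na(br$parent_branch[b])) 0 else depth[br$parent_branch[b]]
  }
  reach <- tapply(depth, stem, max)
  best <- as.integer(names(reach)[which.max(reach)])
  skel$nodes$type <- ifelse(skel$nodes$id == skel$root, 1L, 3L)
  skel$axon_branch <- NA_integer_
  if (max(reach) > min_len_um) {
    skel$axon_branch <- best
    ax_branches <- which(stem == best)
    skel$nodes$type[skel$nodes$branch_id %in% ax_branches] <- 2L
  }
  skel
}

#' Write a skeleton to SWC
#'
#' Standard SWC: 1-based consecutive node ids, columns
#' id/type/x/y/z/radius/parent, root parent -1. Types: 1 soma (root), 3
#' dendrite, 2 axon candidate. Coordinates are physical µm; full double
#' precision is written so a round-trip is exact.
#'
#' @param skel a rooted `skeleton_graph` (unrooted graphs are rejected).
#' @param path output file.
#' @param radius_um constant node radius column (µm); informational only.
#' @return invisibly, `path`.
#' @export
write_swc <- function(skel, path, radius_um = 1) {
  stopifnot(inherits(skel, "skeleton_graph"))
  if (!is_rooted(skel)) stop_param("SWC export requires a rooted skeleton")
  ids <- skel$nodes$id
  remap <- seq_along(ids)
  names(remap) <- as.character(ids)
  parent_out <- ifelse(is.na(skel$parent), -1L,
                       remap[as.character(skel$parent)])
  type <- if (!is.null(skel$nodes$type)) skel$nodes$type
          else ifelse(ids == skel$root, 1L, 3L)
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   remap, type,
                   skel$nodes$x_um, skel$nodes$y_um, skel$nodes$z_um,
                   radius_um, parent_out)
  writeLines(c("# SWC export (x y z in um; type 1=soma 2=axon-candidate 3=dendrite)",
               lines), path)
  invisible(path)
}

#' Read an SWC skeleton
#'
#' @param path SWC file (comment lines starting with `#` are skipped).
#' @return rooted `skeleton_graph` with per-node `type`, plus `$branches`.
#' @export
read_swc <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (length(ln) == 0) stop_data("empty SWC file: ", path)
  m <- do.call(rbind, lapply(strsplit(trimws(ln), "\\s+"), as.numeric))
  if (ncol(m) != 7) stop_data("SWC must have 7 columns")
  nodes <- data.frame(id = as.integer(m[, 1]),
                      z_um = m[, 5], y_um = m[, 4], x_um = m[, 3])
  parent <- as.integer(m[, 7])
  parent[parent == -1L] <- NA_integer_
  root <- nodes$id[is.na(parent)]
  if (length(root) != 1) stop_data("SWC must have exactly one root (parent -1)")
  out <- skeleton_graph(nodes, parent = parent, root = root)
  out$nodes$type <- as.integer(m[, 2])
  out$branches <- branch_table(out)
  out <- annotate_nodes(out)
  out
}
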