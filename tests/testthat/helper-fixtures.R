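# Shared fixture builders. Everything is generated in code; no binary data.

# boolean ball in a (z,y,x) grid, unit spacing unless given
ball_mask <- function(dim, center, radius, spacing = c(1, 1, 1)) {
  ai <- arrayInd(seq_len(prod(dim)), dim)
  pos <- sweep(ai - 1, 2, spacing, `*`)
  array(sqrt(rowSums(sweep(pos, 2, center)^2)) <= radius, dim)
}

# boolean capsule (tube with hemispherical caps) between two points
tube_mask <- function(dim, a, b, radius, spacing = c(1, 1, 1)) {
  ai <- arrayInd(seq_len(prod(dim)), dim)
  pos <- sweep(ai - 1, 2, spacing, `*`)
  ab <- b - a
  t <- pmax(0, pmin(1, (sweep(pos, 2, a) %*% ab) / sum(ab^2)))
  proj <- outer(as.numeric(t), ab) + rep(a, each = nrow(pos))
  array(sqrt(rowSums((pos - proj)^2)) <= radius, dim)
}

# mean per-instance Jaccard of predicted labels against truth labels,
# matching each truth instance to its modal predicted id
mean_instance_jaccard <- function(truth, pred) {
  js <- vapply(seq_len(max(truth)), function(i) {
    ti <- truth == i
    ids <- pred[ti]
    ids <- ids[ids > 0]
    if (length(ids) == 0) return(0)
    best <- as.integer(names(which.max(table(ids))))
    pi <- pred == best
    sum(ti & pi) / sum(ti | pi)
  }, 0)
  js
}

# hand-built rooted star skeleton: k straight rays of length L from origin
star_skeleton <- function(k, L, n_pts = 11) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))[seq_len(k), , drop = FALSE]
  nodes <- data.frame(id = 1L, z_um = 0, y_um = 0, x_um = 0)
  parent <- NA_integer_
  nid <- 1L
  for (r in seq_len(k)) {
    prev <- 1L
    for (s in seq_len(n_pts - 1)) {
      nid <- nid + 1L
      p <- dirs[r, ] * L * s / (n_pts - 1)
      nodes <- rbind(nodes, data.frame(id = nid, z_um = p[1], y_um = p[2],
                                       x_um = p[3]))
      parent <- c(parent, prev)
      prev <- nid
    }
  }
  sk <- skeleton_graph(nodes, parent = parent, root = 1L)
  sk$branches <- branch_table(sk)
  mnmorph:::annotate_nodes(sk)
}

# binary tree skeleton: one stem (order 1) bifurcating at every level, so
# order k holds 2^(k-1) branches; every branch is one straight edge
binary_tree_skeleton <- function(depth, branch_len = 10) {
  nodes <- data.frame(id = 1L, z_um = 0, y_um = 0, x_um = 0)
  parent <- NA_integer_
  nid <- 1L
  branch <- function(pid, pos, dy, d) {
    nid <<- nid + 1L
    me <- nid  # snapshot: nid keeps advancing through the subtrees below
    np <- pos + c(branch_len, dy, 0.01 * me)
    nodes <<- rbind(nodes, data.frame(id = me, z_um = np[1], y_um = np[2],
                                      x_um = np[3]))
    parent <<- c(parent, pid)
    if (d < depth) {
      spread <- 2^(depth - d)
      branch(me, np, -spread, d + 1L)
      branch(me, np, spread, d + 1L)
    }
  }
  branch(1L, c(0, 0, 0), 0, 1L)
  sk <- skeleton_graph(nodes, parent = parent, root = 1L)
  sk$branches <- branch_table(sk)
  mnmorph:::annotate_nodes(sk)
}

# exact sphere-crossing count for a polyline tree: per edge, solve
# |a + t (b - a)| = r analytically on (0, 1]; independent of the package's
# densify-and-sign-change path
brute_force_sholl <- function(skel, radii) {
  xyz <- as.matrix(skel$nodes[, c("z_um", "y_um", "x_um")])
  ids <- skel$nodes$id
  root <- xyz[match(skel$root, ids), ]
  pid <- match(skel$parent, ids)
  e <- which(!is.na(pid))
  counts <- integer(length(radii))
  for (k in e) {
    a <- xyz[pid[k], ] - root
    b <- xyz[k, ] - root
    d <- b - a
    A <- sum(d^2); B <- 2 * sum(a * d)
    for (ri in seq_along(radii)) {
      C <- sum(a^2) - radii[ri]^2
      disc <- B^2 - 4 * A * C
      if (disc < 0 || A == 0) next
      for (t in c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A))) {
        if (t > 0 && t <= 1) counts[ri] <- counts[ri] + 1L
      }
    }
  }
  counts
}

# a small traced-neuron style truth skeleton for metric tests
small_truth_skeleton <- function(seed = 5, wiggle = 0.3, max_order = 3) {
  spec <- neuron_spec(grid_shape = c(128, 128, 128), spacing_um = 1,
                      n_primary = 3, max_order = max_order,
                      branch_prob_per_order = 1,
                      segment_length_um = c(14, 3), wiggle = wiggle,
                      seed = seed)
  generate_neuron_stack(spec)$truth$truth_skeleton
}
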