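# kd-tree fixed-radius neighbour search.
#
# The admissible-distance graph is the complement of the "close pair" set
# (pairs closer than d_min), and on realistic candidate shells the close
# pairs are few, so they are what the spatial index is asked for.

kd_build <- function(pts, idx = seq_len(nrow(pts)), depth = 0L, leaf_size = 16L) {
  if (length(idx) <= leaf_size) return(list(leaf = TRUE, idx = idx))
  d <- depth %% ncol(pts) + 1L
  vals <- pts[idx, d]
  cut <- stats::median(vals)
  left <- idx[vals <= cut]
  right <- idx[vals > cut]
  if (length(left) == 0L || length(right) == 0L) {
    # all values tied on this dimension
    return(list(leaf = TRUE, idx = idx))
  }
  list(leaf = FALSE, dim = d, cut = cut,
       left = kd_build(pts, left, depth + 1L, leaf_size),
       right = kd_build(pts, right, depth + 1L, leaf_size))
}

# indices of points strictly within radius r of query q
kd_radius <- function(node, pts, q, r) {
  if (node$leaf) {
    d2 <- colSums((t(pts[node$idx, , drop = FALSE]) - q)^2)
    return(node$idx[d2 < r * r])
  }
  delta <- q[node$dim] - node$cut
  out <- integer(0)
  if (delta <= r) out <- c(out, kd_radius(node$left, pts, q, r))
  if (delta > -r) out <- c(out, kd_radius(node$right, pts, q, r))
  out
}

# all unordered pairs (i < j) with Euclidean distance < r, as a 2-col matrix
kd_close_pairs <- function(pts, r) {
  n <- nrow(pts)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  tree <- kd_build(pts)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- kd_radius(tree, pts, pts[i, ], r)
    nb <- nb[nb > i]
    if (length(nb) > 0L) pairs[[i]] <- cbind(i, sort(nb))
  }
  out <- do.call(rbind, pairs)
  if (is.null(out)) matrix(integer(0), ncol = 2L) else out
}
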