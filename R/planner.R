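#' Clinical constraint configuration
#'
#' Thresholds governing fiducial-set admissibility: minimum inter-marker
#' distance (18 mm), minimum triangle angle (30 degrees; the vendor manual
#' floor of 15 degrees is available via `preset = "manual-floor"`), maximum
#' marker-to-tumor-centroid distance (50 mm), the 20-30 mm implantation
#' depth band measured to the tumor surface, the Z-axis candidate band, the
#' set size (at least 3 markers), the two oblique imaging view angles and
#' the projected overlap extent.
#'
#' @param d_min Minimum pairwise inter-marker distance, mm (inclusive).
#' @param theta_min Minimum triangle interior angle, degrees (inclusive);
#'   must lie in (0, 60\].
#' @param d_tumor_max Maximum marker-to-tumor-centroid distance, mm.
#' @param band Depth band `(lo, hi)` in mm to the tumor surface within
#'   which candidates are retained.
#' @param z_half_width Half-width (mm) of the Z-axis filter band; `NULL`
#'   means auto (half the tumor Z extent plus 10 mm); `Inf` disables it.
#' @param set_size Number of markers per set, >= 3.
#' @param strict_paper_cliques If `TRUE`, report only maximal cliques of
#'   size exactly `set_size` (the literal published pseudocode); default
#'   reports every valid `set_size`-clique.
#' @param view_angles Imaging view rotations about Z, degrees.
#' @param overlap_extent Projected 2-D distance (mm) below which two
#'   markers are considered overlapping (strict `<`).
#' @param literal_projection If `TRUE`, project onto the X-Y plane after
#'   rotation (the literal published recipe, which is rotation-invariant);
#'   default projects onto the rotated X-Z plane (beam along rotated Y).
#' @param strict_rubric If `TRUE`, the scoring rubric applies strict
#'   inequalities at the 18 mm / 30 degree / 50 mm boundaries.
#' @param preset `"default"` or `"manual-floor"` (angle threshold 15
#'   degrees per the vendor manual).
#' @return An object of class `constraint_config`.
#' @export
constraint_config <- function(d_min = 18, theta_min = 30, d_tumor_max = 50,
                              band = c(20, 30), z_half_width = NULL,
                              set_size = 3L, strict_paper_cliques = FALSE,
                              view_angles = c(45, -45), overlap_extent = 5,
                              literal_projection = FALSE, strict_rubric = FALSE,
                              preset = c("default", "manual-floor")) {
  preset <- match.arg(preset)
  if (preset == "manual-floor" && missing(theta_min)) theta_min <- 15
  if (d_min <= 0) stop("d_min must be > 0")
  if (theta_min <= 0 || theta_min > 60) {
    stop("theta_min must lie in (0, 60]: three angles >= theta_min requires theta_min <= 60")
  }
  if (d_tumor_max <= 0) stop("d_tumor_max must be > 0")
  if (length(band) != 2L || band[1L] < 0 || band[1L] > band[2L]) {
    stop("band must satisfy 0 <= lo <= hi")
  }
  if (set_size < 3L) stop("set_size must be >= 3")
  if (!is.null(z_half_width) && z_half_width <= 0) stop("z_half_width must be > 0 (or NULL/Inf)")
  if (overlap_extent < 0) stop("overlap_extent must be >= 0")
  structure(list(d_min = d_min, theta_min = theta_min, d_tumor_max = d_tumor_max,
                 band = as.numeric(band), z_half_width = z_half_width,
                 set_size = as.integer(set_size),
                 strict_paper_cliques = isTRUE(strict_paper_cliques),
                 view_angles = as.numeric(view_angles),
                 overlap_extent = overlap_extent,
                 literal_projection = isTRUE(literal_projection),
                 strict_rubric = isTRUE(strict_rubric)),
            class = "constraint_config")
}

#' Filter candidates to a Z-axis band
#'
#' Retains candidates with `|z - z_center| <= half_width` (inclusive),
#' preserving order. The band restricts implantation sites to the axial
#' neighbourhood of the tumor, where skin access is realistic.
#'
#' @param candidates A `candidate_set`.
#' @param z_center Band centre (mm), typically the tumor Z midpoint.
#' @param half_width Band half-width in mm; `Inf` returns the input
#'   unchanged.
#' @return The filtered `candidate_set`.
#' @export
filter_z_band <- function(candidates, z_center, half_width) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (!is.finite(half_width)) return(candidates)
  if (half_width <= 0) stop("half_width must be > 0 (use Inf for unbounded)")
  keep <- abs(candidates$points[, 3L] - z_center) <= half_width
  if (!any(keep)) message("Z-band filter removed every candidate")
  cs_subset(candidates, keep)
}

# min Euclidean distance from each row of A to the rows of B
point_to_cloud_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Filter candidates by tumor proximity
#'
#' Retains candidates whose distance to the tumor centroid is at most
#' `d_tumor_max` (tracking-accuracy rule) and whose distance to the tumor
#' surface (minimum distance to the tumor cloud) lies inside the
#' implantation depth band `[lo, hi]`, all bounds inclusive. Both distances
#' are cached on the returned set.
#'
#' @param candidates A `candidate_set`.
#' @param tumor Tumor-surface [point_cloud].
#' @param tumor_centroid Tumor centroid (mm); default [centroid()] of
#'   `tumor`.
#' @param config A [constraint_config].
#' @return The filtered, distance-annotated `candidate_set`.
#' @export
filter_tumor_proximity <- function(candidates, tumor,
                                   tumor_centroid = centroid(tumor),
                                   config = constraint_config()) {
  stopifnot(inherits(candidates, "candidate_set"))
  tpts <- as_points(tumor)
  if (nrow(tpts) < 1L) stop("tumor cloud must be non-empty")
  P <- candidates$points
  dc <- sqrt(rowSums(sweep(P, 2L, tumor_centroid)^2))
  ds <- point_to_cloud_dist(P, tpts)
  cs <- candidate_set(P, candidates$params, dc, ds)
  keep <- dc <= config$d_tumor_max &
    ds >= config$band[1L] & ds <= config$band[2L]
  cs_subset(cs, keep)
}

#' Build the admissible inter-marker distance graph
#'
#' Undirected simple graph over candidate indices with an edge wherever the
#' Euclidean distance is at least `d_min` (inclusive). Close pairs
#' (distance < `d_min`) are found with a kd-tree fixed-radius query and the
#' edge set is their complement, which equals the all-pairs construction
#' exactly.
#'
#' @param candidates A `candidate_set`.
#' @param d_min Minimum admissible distance in mm.
#' @return An `igraph` undirected graph with one vertex per candidate.
#' @export
build_distance_graph <- function(candidates, d_min = 18) {
  stopifnot(inherits(candidates, "candidate_set"))
  n <- nrow(candidates$points)
  if (n < 2L) {
    message("fewer than 2 candidates: returning an edgeless graph")
    return(igraph::make_empty_graph(n, directed = FALSE))
  }
  close <- kd_close_pairs(candidates$points, d_min)
  g_close <- igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE),
                               as.vector(t(close)))
  igraph::complementer(g_close)
}

#' Interior angles of the triangle formed by three markers
#'
#' Angles at `g1`, `g2`, `g3` in degrees, each computed as
#' acos(a . b / (|a| |b|)) from the edge vectors at that vertex. Collinear
#' (but distinct) points yield angles (0, 0, 180); coincident points are a
#' degenerate-geometry error.
#'
#' @param g1,g2,g3 Length-3 numeric marker coordinates (mm).
#' @return Numeric length-3 vector: the angles at `g1`, `g2`, `g3`,
#'   summing to 180 degrees.
#' @examples
#' triangle_angles(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' @export
triangle_angles <- function(g1, g2, g3) {
  P <- rbind(g1, g2, g3)
  if (min(stats::dist(P)) == 0) {
    stop("degenerate geometry: coincident marker points")
  }
  ang <- triangle_angles_many(P[1L, , drop = FALSE],
                              P[2L, , drop = FALSE],
                              P[3L, , drop = FALSE])
  as.numeric(ang)
}

# vectorized: rows of P1, P2, P3 are triples; returns n x 3 angles (deg)
triangle_angles_many <- function(P1, P2, P3) {
  vang <- function(A, B, C) {
    # angle at A
    u <- B - A; v <- C - A
    cosv <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
    acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
  }
  cbind(vang(P1, P2, P3), vang(P2, P3, P1), vang(P3, P1, P2))
}

#' Enumerate fiducial sets satisfying the geometric constraints
#'
#' Extracts marker sets from the admissible-distance graph. In the default
#' mode every `set_size`-clique of the graph (equivalently, every
#' `set_size`-subset of a maximal clique) whose triangle angles are all at
#' least `theta_min` is returned. With `strict_paper_cliques` only maximal
#' cliques of size exactly `set_size` are considered, reproducing the
#' published pseudocode literally; its output is always a subset of the
#' default mode's. Results are deduplicated and sorted lexicographically by
#' candidate index.
#'
#' @param graph Graph from [build_distance_graph()] over the same
#'   candidates.
#' @param candidates The `candidate_set` the graph was built from.
#' @param config A [constraint_config].
#' @return A `fiducial_sets` data frame: columns `m1..mk` (candidate
#'   indices), pairwise distances, triangle angles, per-marker centroid
#'   distances and `min_pair_dist` / `min_angle` / `max_centroid_dist`
#'   summaries.
#' @export
enumerate_valid_sets <- function(graph, candidates, config = constraint_config()) {
  stopifnot(inherits(candidates, "candidate_set"))
  k <- config$set_size
  if (igraph::vcount(graph) != nrow(candidates$points)) {
    stop("graph was not built from these candidates (vertex count mismatch)")
  }
  if (config$strict_paper_cliques) {
    cl <- igraph::max_cliques(graph, min = k, max = k)
    if (length(cl) == 0L) return(empty_fiducial_sets(k))
    idx <- matrix(unlist(lapply(cl, as.integer)), ncol = k, byrow = TRUE)
    idx <- t(apply(idx, 1L, sort))
  } else if (k == 3L) {
    # all triangles of the graph, listed from its adjacency structure
    # (equivalent to the 3-subsets of all maximal cliques, without the
    # exponential maximal-clique enumeration on near-complete graphs)
    idx <- graph_triangles(graph)
    if (nrow(idx) == 0L) return(empty_fiducial_sets(k))
  } else {
    cl <- igraph::cliques(graph, min = k, max = k)
    if (length(cl) == 0L) return(empty_fiducial_sets(k))
    idx <- matrix(unlist(lapply(cl, as.integer)), ncol = k, byrow = TRUE)
    idx <- t(apply(idx, 1L, sort))
  }
  # angle filter over every 3-subset
  keep <- rep(TRUE, nrow(idx))
  for (tri in triple_subsets(k)) {
    ang <- triangle_angles_many(candidates$points[idx[, tri[1L]], , drop = FALSE],
                                candidates$points[idx[, tri[2L]], , drop = FALSE],
                                candidates$points[idx[, tri[3L]], , drop = FALSE])
    mn <- ang[cbind(seq_len(nrow(ang)), max.col(-ang))]
    keep <- keep & !is.na(mn) & mn >= config$theta_min
  }
  idx <- idx[keep, , drop = FALSE]
  fiducial_table(idx, candidates)
}

# i < j < k triangle listing over the adjacency matrix
graph_triangles <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 3L) return(matrix(integer(0), ncol = 3L))
  A <- as.matrix(igraph::as_adjacency_matrix(graph)) > 0
  vid <- seq_len(n)
  out <- vector("list", n)
  for (i in seq_len(n - 2L)) {
    js <- which(A[i, ] & vid > i)
    if (length(js) == 0L) next
    blocks <- lapply(js, function(j) {
      ks <- which(A[i, ] & A[j, ] & vid > j)
      if (length(ks) == 0L) return(NULL)
      cbind(i, j, ks, deparse.level = 0L)
    })
    out[[i]] <- do.call(rbind, blocks)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(integer(0), ncol = 3L) else res
}

triple_subsets <- function(k) {
  m <- utils::combn(k, 3L)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Exhaustive brute-force fiducial-set search (oracle)
#'
#' Systematically enumerates every `set_size`-subset of the candidates and
#' applies the distance and angle constraints directly (angles via the law
#' of cosines rather than the planner's dot-product route). Serves as the
#' correctness oracle for [enumerate_valid_sets()] in its default mode.
#'
#' @param candidates A `candidate_set`.
#' @param config A [constraint_config].
#' @return A `fiducial_sets` data frame, same layout and ordering as
#'   [enumerate_valid_sets()].
#' @export
brute_force_plan <- function(candidates, config = constraint_config()) {
  stopifnot(inherits(candidates, "candidate_set"))
  n <- nrow(candidates$points)
  k <- config$set_size
  if (n < k) return(empty_fiducial_sets(k))
  idx <- t(utils::combn(n, k))
  P <- candidates$points
  pair_cols <- utils::combn(k, 2L)
  keep <- rep(TRUE, nrow(idx))
  D <- matrix(NA_real_, nrow(idx), ncol(pair_cols))
  for (j in seq_len(ncol(pair_cols))) {
    a <- idx[, pair_cols[1L, j]]
    b <- idx[, pair_cols[2L, j]]
    D[, j] <- sqrt(rowSums((P[a, , drop = FALSE] - P[b, , drop = FALSE])^2))
    keep <- keep & D[, j] >= config$d_min
  }
  # law-of-cosines angle check on each 3-subset of the surviving rows
  for (tri in triple_subsets(k)) {
    pc <- function(a, b) {
      j <- which(pair_cols[1L, ] == min(a, b) & pair_cols[2L, ] == max(a, b))
      D[, j]
    }
    a <- pc(tri[2L], tri[3L]); b <- pc(tri[1L], tri[3L]); cc <- pc(tri[1L], tri[2L])
    ang_at <- function(opp, s1, s2) {
      cosv <- (s1^2 + s2^2 - opp^2) / (2 * s1 * s2)
      acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
    }
    A1 <- ang_at(a, b, cc); A2 <- ang_at(b, a, cc); A3 <- ang_at(cc, a, b)
    mn <- pmin(A1, A2, A3)
    keep <- keep & !is.na(mn) & mn >= config$theta_min
  }
  fiducial_table(idx[keep, , drop = FALSE], candidates)
}

empty_fiducial_sets <- function(k) {
  cols <- fiducial_set_colnames(k)
  df <- as.data.frame(matrix(numeric(0), nrow = 0L, ncol = length(cols)))
  names(df) <- cols
  class(df) <- c("fiducial_sets", "data.frame")
  df
}

fiducial_set_colnames <- function(k) {
  pair_cols <- utils::combn(k, 2L)
  c(paste0("m", seq_len(k)),
    paste0("d_", pair_cols[1L, ], "_", pair_cols[2L, ]),
    if (k == 3L) c("ang_1", "ang_2", "ang_3"),
    paste0("dc_", seq_len(k)),
    "min_pair_dist", "min_angle", "max_centroid_dist")
}

# Cached-metric table for accepted sets; rows sorted lexicographically.
fiducial_table <- function(idx, candidates) {
  k <- ncol(idx)
  if (nrow(idx) == 0L) return(empty_fiducial_sets(k))
  ord <- do.call(order, lapply(seq_len(k), function(j) idx[, j]))
  idx <- idx[ord, , drop = FALSE]
  P <- candidates$points
  pair_cols <- utils::combn(k, 2L)
  D <- sapply(seq_len(ncol(pair_cols)), function(j) {
    a <- idx[, pair_cols[1L, j]]; b <- idx[, pair_cols[2L, j]]
    sqrt(rowSums((P[a, , drop = FALSE] - P[b, , drop = FALSE])^2))
  })
  if (nrow(idx) == 1L) D <- matrix(D, nrow = 1L)
  min_angle <- rep(Inf, nrow(idx))
  ang3 <- NULL
  for (tri in triple_subsets(k)) {
    ang <- triangle_angles_many(P[idx[, tri[1L]], , drop = FALSE],
                                P[idx[, tri[2L]], , drop = FALSE],
                                P[idx[, tri[3L]], , drop = FALSE])
    if (k == 3L) ang3 <- ang
    min_angle <- pmin(min_angle, ang[, 1L], ang[, 2L], ang[, 3L])
  }
  dc <- candidates$d_centroid
  DC <- sapply(seq_len(k), function(j) dc[idx[, j]])
  if (nrow(idx) == 1L) DC <- matrix(DC, nrow = 1L)
  df <- data.frame(idx, D,
                   if (k == 3L) ang3,
                   DC,
                   apply(D, 1L, min),
                   min_angle,
                   if (all(is.na(DC))) NA_real_ else apply(DC, 1L, max))
  names(df) <- fiducial_set_colnames(k)
  rownames(df) <- NULL
  class(df) <- c("fiducial_sets", "data.frame")
  df
}

# n x k index matrix accessor
set_indices <- function(sets) {
  k <- sum(grepl("^m[0-9]+$", names(sets)))
  as.matrix(sets[, paste0("m", seq_len(k)), drop = FALSE])
}
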