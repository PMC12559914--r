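#' Tensor-product B-spline surface
#'
#' The candidate-site surface S(u,v) = sum_i sum_j N_i,p(u) N_j,q(v) P_ij,
#' defined by an (m+1) x (n+1) control-point grid, clamped knot vectors and
#' degrees (p, q).
#'
#' @param control_points Numeric array of dim `c(m+1, n+1, 3)` or a matrix
#'   of `(m+1)*(n+1)` rows (u-index varying fastest) by 3 columns.
#' @param knots_u,knots_v Nondecreasing knot vectors; must be clamped
#'   (first/last `degree+1` knots repeated) with lengths
#'   `(m+1) + degree_u + 1` and `(n+1) + degree_v + 1`.
#' @param degree_u,degree_v Spline degrees p and q.
#' @return An object of class `bspline_surface`.
#' @export
bspline_surface <- function(control_points, knots_u, knots_v,
                            degree_u = 3L, degree_v = 3L) {
  if (is.matrix(control_points)) {
    nu <- length(knots_u) - degree_u - 1L
    nv <- length(knots_v) - degree_v - 1L
    if (nrow(control_points) != nu * nv || ncol(control_points) != 3L) {
      stop("control_points matrix must be (m+1)*(n+1) x 3 with the stated knots")
    }
    control_points <- array(control_points, dim = c(nu, nv, 3L))
  }
  d <- dim(control_points)
  if (length(d) != 3L || d[3L] != 3L) {
    stop("control_points must be an (m+1) x (n+1) x 3 array")
  }
  check_knots <- function(knots, degree, ncp, nm) {
    if (length(knots) != ncp + degree + 1L) {
      stop(sprintf("length(%s) must equal (number of %s control points) + degree + 1", nm, nm))
    }
    if (is.unsorted(knots)) stop(sprintf("%s must be nondecreasing", nm))
    p1 <- degree + 1L
    if (diff(range(knots[seq_len(p1)])) != 0 ||
        diff(range(knots[(length(knots) - degree):length(knots)])) != 0) {
      stop(sprintf("%s must be clamped (first and last degree+1 knots repeated)", nm))
    }
    if (ncp < degree + 1L) {
      stop("control grid must have at least degree+1 points in each direction")
    }
  }
  check_knots(knots_u, degree_u, d[1L], "knots_u")
  check_knots(knots_v, degree_v, d[2L], "knots_v")
  structure(list(control_points = control_points,
                 knots_u = as.numeric(knots_u), knots_v = as.numeric(knots_v),
                 degree_u = as.integer(degree_u), degree_v = as.integer(degree_v)),
            class = "bspline_surface")
}

#' @export
print.bspline_surface <- function(x, ...) {
  d <- dim(x$control_points)
  cat(sprintf("<bspline_surface> %d x %d control points, degrees (%d, %d)\n",
              d[1L], d[2L], x$degree_u, x$degree_v))
  invisible(x)
}

# clamped knot vector on [0,1] with uniform interior knots
clamped_uniform_knots <- function(n_ctrl, degree) {
  n_int <- n_ctrl - degree - 1L
  interior <- if (n_int > 0L) seq_len(n_int) / (n_int + 1L) else numeric(0)
  c(rep(0, degree + 1L), interior, rep(1, degree + 1L))
}

#' B-spline basis function (Cox-de Boor recursion)
#'
#' Value of the i-th basis function of the given degree at parameter(s)
#' `u`, computed by the Cox-de Boor recursion with the 0/0 -> 0 convention.
#' The rightmost nonempty degree-0 interval is treated as closed so that
#' the basis is well defined at the end of the domain.
#'
#' @param i Basis index, 1-based, in `1:(length(knots) - degree - 1)`.
#' @param degree Spline degree p >= 0.
#' @param u Parameter value(s); must lie in
#'   `[knots[degree + 1], knots[length(knots) - degree]]`.
#' @param knots Nondecreasing knot vector.
#' @return Numeric vector of basis values, same length as `u`.
#' @examples
#' bspline_basis(1, 0, 0.5, c(0, 1))
#' sapply(1:4, bspline_basis, degree = 3, u = 0.5, knots = c(0, 0, 0, 0, 1, 1, 1, 1))
#' @export
bspline_basis <- function(i, degree, u, knots) {
  nb <- length(knots) - degree - 1L
  if (nb < 1L || i < 1L || i > nb) stop("basis index out of range")
  lo <- knots[degree + 1L]
  hi <- knots[length(knots) - degree]
  if (any(u < lo | u > hi)) {
    stop(sprintf("parameter outside the basis domain [%g, %g]", lo, hi))
  }
  vapply(u, cox_de_boor, numeric(1), i = i, p = degree, knots = knots, umax = hi)
}

cox_de_boor <- function(u, i, p, knots, umax) {
  if (p == 0L) {
    inside <- (u >= knots[i] && u < knots[i + 1L]) ||
      (u == umax && knots[i] < knots[i + 1L] && knots[i + 1L] == umax)
    return(as.numeric(inside))
  }
  den1 <- knots[i + p] - knots[i]
  den2 <- knots[i + p + 1L] - knots[i + 1L]
  a <- if (den1 > 0) (u - knots[i]) / den1 * cox_de_boor(u, i, p - 1L, knots, umax) else 0
  b <- if (den2 > 0) (knots[i + p + 1L] - u) / den2 * cox_de_boor(u, i + 1L, p - 1L, knots, umax) else 0
  a + b
}

# span s such that knots[s] <= u < knots[s+1] (last nonempty span at u = max)
find_span <- function(u, degree, knots) {
  nb <- length(knots) - degree - 1L
  if (u >= knots[nb + 1L]) return(nb)
  findInterval(u, knots, rightmost.closed = FALSE)
}

# The p+1 nonzero basis values at u (iterative triangular scheme).
basis_funs <- function(span, u, p, knots) {
  N <- numeric(p + 1L)
  N[1L] <- 1
  if (p == 0L) return(N)
  left <- numeric(p)
  right <- numeric(p)
  for (j in seq_len(p)) {
    left[j] <- u - knots[span + 1L - j]
    right[j] <- knots[span + j] - u
    saved <- 0
    for (r in seq_len(j)) {
      temp <- N[r] / (right[r] + left[j - r + 1L])
      N[r] <- saved + right[r] * temp
      saved <- left[j - r + 1L] * temp
    }
    N[j + 1L] <- saved
  }
  N
}

# Dense collocation matrix: length(u) x n_basis.
basis_matrix <- function(u, degree, knots) {
  nb <- length(knots) - degree - 1L
  lo <- knots[degree + 1L]
  hi <- length(knots) - degree
  hi <- knots[hi]
  if (any(u < lo | u > hi)) {
    stop(sprintf("parameter outside the basis domain [%g, %g]", lo, hi))
  }
  B <- matrix(0, nrow = length(u), ncol = nb)
  for (k in seq_along(u)) {
    s <- find_span(u[k], degree, knots)
    B[k, (s - degree):s] <- basis_funs(s, u[k], degree, knots)
  }
  B
}

#' Evaluate a B-spline surface
#'
#' Tensor-product evaluation S(u,v) = sum_ij N_i,p(u) N_j,q(v) P_ij at one
#' or more parameter pairs.
#'
#' @param surface A [bspline_surface].
#' @param u,v Parameter vectors of equal length, inside the knot domain.
#' @return An n x 3 matrix of surface points (mm).
#' @export
evaluate_surface <- function(surface, u, v) {
  stopifnot(inherits(surface, "bspline_surface"), length(u) == length(v))
  Bu <- basis_matrix(u, surface$degree_u, surface$knots_u)
  Bv <- basis_matrix(v, surface$degree_v, surface$knots_v)
  cp <- surface$control_points
  out <- matrix(0, nrow = length(u), ncol = 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  for (c in 1:3) {
    out[, c] <- rowSums((Bu %*% cp[, , c]) * Bv)
  }
  out
}

#' Cylindrical (u, v) parameterization of a scattered cloud
#'
#' Maps each point to `u` = azimuth / 2*pi about the given axis through the
#' centroid and `v` = normalized coordinate along the axis, both in
#' \[0, 1\]. The azimuth reference direction is the coordinate axis least
#' aligned with `axis` (projected orthogonal to it), so the mapping is
#' deterministic. Points lying exactly on the axis get `u = 0` with a
#' warning.
#'
#' @param cloud A [point_cloud] or n x 3 matrix.
#' @param centroid Axis base point (mm); defaults to the cloud centroid.
#' @param axis Unit direction of the cylindrical axis; defaults to the
#'   cloud's first principal component.
#' @return An n x 2 matrix with columns `u`, `v`.
#' @export
parameterize_cloud <- function(cloud, centroid = NULL, axis = NULL) {
  pts <- as_points(cloud)
  if (is.null(centroid)) centroid <- colMeans(pts)
  if (is.null(axis)) axis <- principal_axis(pts)
  w <- axis / sqrt(sum(axis^2))
  # reference direction: global axis least aligned with w
  ref <- diag(3)[, which.min(abs(w))]
  e1 <- ref - sum(ref * w) * w
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(w[2L] * e1[3L] - w[3L] * e1[2L],
          w[3L] * e1[1L] - w[1L] * e1[3L],
          w[1L] * e1[2L] - w[2L] * e1[1L])
  q <- sweep(pts, 2L, centroid)
  t_ax <- as.numeric(q %*% w)
  x1 <- as.numeric(q %*% e1)
  x2 <- as.numeric(q %*% e2)
  rad2 <- x1^2 + x2^2
  on_axis <- rad2 < .Machine$double.eps
  az <- atan2(x2, x1)
  az[az < 0] <- az[az < 0] + 2 * pi
  u <- az / (2 * pi)
  if (any(on_axis)) {
    warning(sprintf("%d point(s) lie exactly on the parameterization axis; assigned u = 0",
                    sum(on_axis)))
    u[on_axis] <- 0
  }
  rng <- range(t_ax)
  v <- if (diff(rng) > 0) (t_ax - rng[1L]) / diff(rng) else rep(0.5, length(t_ax))
  cbind(u = u, v = v)
}

# first principal component, sign fixed so the largest-magnitude entry is positive
principal_axis <- function(pts) {
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  a <- pc$rotation[, 1L]
  if (a[which.max(abs(a))] < 0) a <- -a
  a
}

#' Least-squares fit of a B-spline surface to a parameterized cloud
#'
#' Solves the linear least-squares problem
#' min sum_k || P_k - S(u_k, v_k) ||^2 for the control points, given the
#' data parameterization, degrees and control-grid size. An optional
#' Tikhonov penalty (weight `smoothing` on the second differences of the
#' control grid in both directions) regularizes rank-deficient fits. The
#' reported residual excludes the penalty.
#'
#' @param cloud A [point_cloud] or n x 3 matrix of data points P_k (mm).
#' @param params K x 2 matrix of `(u, v)` in \[0,1\]^2, e.g. from
#'   [parameterize_cloud()].
#' @param degree_u,degree_v Spline degrees (default cubic).
#' @param grid Control-grid size `c(m+1, n+1)`.
#' @param smoothing Nonnegative Tikhonov weight; default 0 (pure least
#'   squares, which errors on rank deficiency).
#' @return An object of class `bspline_fit`: list with `surface`
#'   ([bspline_surface]), `residual_E` (sum of squared distances, mm^2) and
#'   `per_point_residuals` (mm).
#' @export
fit_surface <- function(cloud, params, degree_u = 3L, degree_v = 3L,
                        grid = c(8L, 8L), smoothing = 0) {
  pts <- as_points(cloud)
  params <- as.matrix(params)
  stopifnot(ncol(params) == 2L, nrow(params) == nrow(pts))
  if (any(params < 0 | params > 1)) stop("params must lie in [0,1]^2")
  nu <- as.integer(grid[1L]); nv <- as.integer(grid[2L])
  if (nu < degree_u + 1L || nv < degree_v + 1L) {
    stop("grid must be at least degree+1 in each direction")
  }
  K <- nrow(pts)
  if (K < nu * nv) {
    stop(sprintf(paste0("underdetermined fit: %d data points for %d control points; ",
                        "use a smaller grid or smoothing > 0"), K, nu * nv))
  }
  ku <- clamped_uniform_knots(nu, degree_u)
  kv <- clamped_uniform_knots(nv, degree_v)
  Bu <- basis_matrix(params[, 1L], degree_u, ku)
  Bv <- basis_matrix(params[, 2L], degree_v, kv)
  # column (j-1)*nu + i  <->  control point (i, j)
  B <- Bu[, rep(seq_len(nu), times = nv), drop = FALSE] *
    Bv[, rep(seq_len(nv), each = nu), drop = FALSE]
  if (smoothing > 0) {
    L <- grid_second_difference(nu, nv)
    A <- rbind(B, sqrt(smoothing) * L)
    rhs <- rbind(pts, matrix(0, nrow(L), 3L))
  } else {
    A <- B
    rhs <- pts
  }
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    stop(paste0("rank-deficient fit (data do not constrain every control point); ",
                "use a smaller grid or smoothing > 0"))
  }
  cp <- qr.coef(qrA, rhs)
  surface <- bspline_surface(cp, ku, kv, degree_u, degree_v)
  fitted <- B %*% cp
  rk <- sqrt(rowSums((pts - fitted)^2))
  structure(list(surface = surface, residual_E = sum(rk^2),
                 per_point_residuals = rk),
            class = "bspline_fit")
}

#' @export
print.bspline_fit <- function(x, ...) {
  cat(sprintf("<bspline_fit> residual E = %.6g mm^2 over %d points\n",
              x$residual_E, length(x$per_point_residuals)))
  print(x$surface)
  invisible(x)
}

# rows: 1 -2 1 second differences along each grid direction
grid_second_difference <- function(nu, nv) {
  rows <- list()
  idx <- function(i, j) (j - 1L) * nu + i
  for (j in seq_len(nv)) {
    for (i in seq_len(nu - 2L) + 1L) {
      r <- numeric(nu * nv)
      r[idx(i - 1L, j)] <- 1; r[idx(i, j)] <- -2; r[idx(i + 1L, j)] <- 1
      rows[[length(rows) + 1L]] <- r
    }
  }
  for (i in seq_len(nu)) {
    for (j in seq_len(nv - 2L) + 1L) {
      r <- numeric(nu * nv)
      r[idx(i, j - 1L)] <- 1; r[idx(i, j)] <- -2; r[idx(i, j + 1L)] <- 1
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

#' Sample a fitted surface into a candidate set
#'
#' Evaluates the surface on a uniform `n_u` x `n_v` grid of `(u, v)`
#' parameters over the full domain. Distance annotations are filled later
#' by [filter_tumor_proximity()].
#'
#' @param surface A [bspline_surface].
#' @param n_u,n_v Grid resolution, both >= 2.
#' @return A `candidate_set`: list with `points` (n x 3), `params` (n x 2),
#'   `d_centroid`, `d_surface` (NA until annotated).
#' @export
sample_surface <- function(surface, n_u = 12L, n_v = 12L) {
  if (n_u < 2L || n_v < 2L) stop("n_u and n_v must be >= 2")
  u <- seq(0, 1, length.out = n_u)
  v <- seq(0, 1, length.out = n_v)
  grid <- expand.grid(u = u, v = v, KEEP.OUT.ATTRS = FALSE)  # u varies fastest
  pts <- evaluate_surface(surface, grid$u, grid$v)
  candidate_set(pts, cbind(u = grid$u, v = grid$v))
}

candidate_set <- function(points, params,
                          d_centroid = rep(NA_real_, nrow(points)),
                          d_surface = rep(NA_real_, nrow(points))) {
  stopifnot(nrow(points) == nrow(params),
            length(d_centroid) == nrow(points),
            length(d_surface) == nrow(points))
  structure(list(points = points, params = params,
                 d_centroid = d_centroid, d_surface = d_surface),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d candidate sites%s\n", nrow(x$points),
              if (all(is.na(x$d_surface))) "" else " (distance-annotated)"))
  invisible(x)
}

cs_subset <- function(cs, keep) {
  candidate_set(cs$points[keep, , drop = FALSE],
                cs$params[keep, , drop = FALSE],
                cs$d_centroid[keep], cs$d_surface[keep])
}

#' Serialize / restore a B-spline surface as JSON
#'
#' @param surface A [bspline_surface].
#' @param path Output (input) path of the JSON document.
#' @return `write_surface_json`: `path`, invisibly. `read_surface_json`:
#'   the restored [bspline_surface].
#' @export
write_surface_json <- function(surface, path) {
  stopifnot(inherits(surface, "bspline_surface"))
  d <- dim(surface$control_points)
  doc <- list(
    degree_u = surface$degree_u, degree_v = surface$degree_v,
    grid = d[1:2], knots_u = surface$knots_u, knots_v = surface$knots_v,
    control_points = matrix(surface$control_points, nrow = d[1L] * d[2L])
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surface_json
#' @export
read_surface_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  bspline_surface(matrix(doc$control_points, ncol = 3L),
                  doc$knots_u, doc$knots_v,
                  as.integer(doc$degree_u), as.integer(doc$degree_v))
}
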