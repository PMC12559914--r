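# Shared fixtures, built in code.

default_phantom <- function(seed = 42L, ...) {
  generate_phantom(phantom_spec(seed = seed, ...))
}

# random candidate set inside a cube of the given edge (mm)
random_candidates <- function(n, seed, edge = 60, annotate_from = NULL) {
  set.seed(seed)
  pts <- matrix(runif(3L * n, 0, edge), ncol = 3L)
  cs <- fidplan:::candidate_set(pts, matrix(runif(2L * n), ncol = 2L))
  if (!is.null(annotate_from)) {
    cs$d_centroid <- sqrt(rowSums(sweep(pts, 2L, annotate_from)^2))
  }
  cs
}

# numeric point-to-ellipsoid distance oracle: nearest surface point found by
# optimizing over spherical parameters (independent of the generator's
# normal-offset construction)
point_to_ellipsoid_dist <- function(p, centroid, semi_axes) {
  obj <- function(ang) {
    s <- centroid + semi_axes * c(cos(ang[1]) * cos(ang[2]),
                                  cos(ang[1]) * sin(ang[2]),
                                  sin(ang[1]))
    sum((p - s)^2)
  }
  q <- p - centroid
  start <- c(asin(max(-1, min(1, q[3] / sqrt(sum(q^2))))), atan2(q[2], q[1]))
  res <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  sqrt(res$value)
}

# an equilateral triangle of the given side in the z = 0 plane, centred at c0
equilateral_triple <- function(side = 20, c0 = c(0, 0, 0)) {
  r <- side / sqrt(3)
  th <- c(90, 210, 330) * pi / 180
  sweep(cbind(r * cos(th), r * sin(th), 0), 2L, c0, `+`)
}

make_candidates <- function(pts, centroid = NULL) {
  cs <- fidplan:::candidate_set(as.matrix(pts),
                                matrix(0, nrow(as.matrix(pts)), 2L))
  if (!is.null(centroid)) {
    cs$d_centroid <- sqrt(rowSums(sweep(as.matrix(pts), 2L, centroid)^2))
  }
  cs
}

# random clamped surface with the given grid (control points ~ U[-s, s])
random_surface <- function(nu = 6L, nv = 6L, p = 3L, q = 3L, seed = 1L, s = 30) {
  set.seed(seed)
  cp <- array(runif(nu * nv * 3L, -s, s), dim = c(nu, nv, 3L))
  bspline_surface(cp,
                  fidplan:::clamped_uniform_knots(nu, p),
                  fidplan:::clamped_uniform_knots(nv, q),
                  p, q)
}
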