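#' Synthetic superficial-tumor phantom specification
#'
#' Describes an ellipsoidal tumor plus an offset candidate shell emulating a
#' superficial tumor lying 20-50 mm beneath the epidermis: the shell band is
#' the layer of tissue, measured outward from the tumor surface, in which
#' markers can be placed.
#'
#' @param centroid Tumor centre (x, y, z) in mm.
#' @param semi_axes Ellipsoid semi-axes (a, b, c) in mm, all > 0.
#' @param n_points Number of surface points generated for the tumor cloud
#'   (and for the shell cloud); at least 4.
#' @param offset_band Depth band `(lo, hi)` in mm of the candidate shell,
#'   measured outward from the tumor surface along the local normal.
#' @param noise_sd Isotropic Gaussian noise (mm) added to every generated
#'   point; default 0.
#' @param seed Integer RNG seed; the generator is a pure function of the
#'   spec, seed included.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(centroid = c(0, 0, 0), semi_axes = c(15, 15, 15),
                         n_points = 500L, offset_band = c(20, 30),
                         noise_sd = 0, seed = 1L) {
  stopifnot(length(centroid) == 3L, length(semi_axes) == 3L,
            length(offset_band) == 2L, length(noise_sd) == 1L)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0)) {
    stop("semi_axes must all be > 0")
  }
  if (offset_band[1L] < 0 || offset_band[1L] > offset_band[2L]) {
    stop("offset_band must satisfy 0 <= lo <= hi")
  }
  if (n_points < 4L) stop("n_points must be >= 4")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(centroid = as.numeric(centroid),
                 semi_axes = as.numeric(semi_axes),
                 n_points = as.integer(n_points),
                 offset_band = as.numeric(offset_band),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic tumor + candidate-shell phantom
#'
#' Samples `n_points` directions uniformly on the unit sphere and maps them
#' to the ellipsoid surface to form the tumor cloud. Each shell point is the
#' corresponding surface point pushed outward along the ellipsoid's outward
#' normal by an offset drawn uniformly from `offset_band`; for a convex
#' surface that offset is exactly the point-to-surface distance, so with
#' zero noise every shell point lies in the stated depth band. Gaussian
#' noise of sd `noise_sd` is then added independently to both clouds.
#'
#' @param spec A [phantom_spec].
#' @return A list with elements `tumor` and `shell` ([point_cloud]s) and
#'   `centroid` (the specified tumor centre).
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 42L))
#' range(sqrt(rowSums(sweep(ph$tumor$points, 2, ph$centroid)^2)))
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_points
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(spec$seed)
    code
  }
  withr_seed({
    # uniform directions on the unit sphere
    dirs <- matrix(stats::rnorm(3L * n), ncol = 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    ax <- spec$semi_axes
    surf <- sweep(dirs, 2L, ax, `*`)                 # on the ellipsoid, centred
    # outward normal of x^2/a^2 + y^2/b^2 + z^2/c^2 = 1 at surf
    nrm <- sweep(surf, 2L, ax^2, `/`)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    off <- stats::runif(n, spec$offset_band[1L], spec$offset_band[2L])
    shell <- surf + nrm * off
    if (spec$noise_sd > 0) {
      surf <- surf + matrix(stats::rnorm(3L * n, sd = spec$noise_sd), ncol = 3L)
      shell <- shell + matrix(stats::rnorm(3L * n, sd = spec$noise_sd), ncol = 3L)
    }
    tumor <- sweep(surf, 2L, spec$centroid, `+`)
    shell <- sweep(shell, 2L, spec$centroid, `+`)
    list(tumor = point_cloud(tumor, label = "tumor-surface"),
         shell = point_cloud(shell, label = "body-surface"),
         centroid = spec$centroid)
  })
}
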