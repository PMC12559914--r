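#' Rotate a point about the Z axis
#'
#' Applies the rotation matrix R_z(angle) to one point or to the rows of a
#' point matrix; Z coordinates are unchanged and norms preserved.
#'
#' @param point Length-3 vector or n x 3 matrix (mm).
#' @param angle Rotation angle in degrees (counter-clockwise about +Z).
#' @return Rotated point(s), same shape as the input.
#' @examples
#' rotate_z(c(1, 0, 0), 45)
#' @export
rotate_z <- function(point, angle) {
  vec <- is.null(dim(point))
  P <- as_points(point)
  th <- angle * pi / 180
  # rows are points, so right-multiply by t(R_z)
  out <- P %*% rbind(c(cos(th), sin(th), 0),
                     c(-sin(th), cos(th), 0),
                     c(0, 0, 1))
  colnames(out) <- c("x", "y", "z")
  if (vec) as.numeric(out) else out
}

#' Project markers into one oblique imaging view
#'
#' Translates the markers so the tumor centroid is the origin, rotates by
#' `view_angle` about Z, then projects orthographically. By default the
#' imager beam runs along the rotated Y axis, so the view plane keeps the
#' rotated X and the (unchanged) Z coordinate; this makes the +45 and -45
#' degree views genuinely stereoscopic. With `literal = TRUE` the rotated Z
#' is dropped instead (projection onto the X-Y plane), a mode retained for
#' fidelity to the published recipe even though a Z-rotation is an isometry
#' of that plane.
#'
#' @param markers n x 3 matrix (or list of points) of marker coordinates
#'   (mm).
#' @param centroid Tumor centroid used as projection origin.
#' @param view_angle View rotation about Z in degrees.
#' @param literal Use the X-Y-plane projection mode.
#' @return An object of class `projected_view`: list with `view_angle`,
#'   `origin`, `coords2d` (n x 2, mm) and `beam_axis_convention`.
#' @export
project_view <- function(markers, centroid, view_angle, literal = FALSE) {
  P <- as_points(markers)
  Q <- rotate_z(sweep(P, 2L, centroid), view_angle)
  coords2d <- if (literal) Q[, c(1L, 2L), drop = FALSE] else Q[, c(1L, 3L), drop = FALSE]
  colnames(coords2d) <- c("h", "w")
  structure(list(view_angle = view_angle, origin = centroid,
                 coords2d = coords2d,
                 beam_axis_convention = if (literal) "drop-z-literal" else "beam-along-rotated-y"),
            class = "projected_view")
}

#' @export
print.projected_view <- function(x, ...) {
  cat(sprintf("<projected_view> %g deg, %d markers (%s)\n",
              x$view_angle, nrow(x$coords2d), x$beam_axis_convention))
  invisible(x)
}

#' Check marker overlap within one projected view
#'
#' Two markers overlap when their 2-D projected distance is strictly less
#' than `overlap_extent`; projections exactly `overlap_extent` apart
#' ("touching") pass.
#'
#' @param view A [project_view()] result with >= 2 markers.
#' @param overlap_extent Overlap threshold in mm.
#' @return List with `overlap_free` (flag) and `offending_pairs`
#'   (p x 2 index matrix, possibly empty).
#' @export
check_overlap <- function(view, overlap_extent = 5) {
  stopifnot(inherits(view, "projected_view"))
  C <- view$coords2d
  n <- nrow(C)
  if (n < 2L) stop("overlap checking needs at least 2 projected markers")
  pr <- t(utils::combn(n, 2L))
  d <- sqrt(rowSums((C[pr[, 1L], , drop = FALSE] - C[pr[, 2L], , drop = FALSE])^2))
  bad <- d < overlap_extent
  list(overlap_free = !any(bad),
       offending_pairs = pr[bad, , drop = FALSE])
}

#' Reject fiducial sets with overlapping projections
#'
#' Retains sets whose markers are pairwise non-overlapping in every
#' configured view; per-view pass flags are cached as columns
#' `view_ok_<angle>` on the returned table, order preserved.
#'
#' @param sets A `fiducial_sets` table from [enumerate_valid_sets()] or
#'   [brute_force_plan()].
#' @param candidates The `candidate_set` the sets index into.
#' @param centroid Tumor centroid (projection origin).
#' @param config A [constraint_config] (view angles, overlap extent,
#'   projection mode).
#' @return The filtered `fiducial_sets` table with per-view flag columns.
#' @export
drr_filter <- function(sets, candidates, centroid, config = constraint_config()) {
  stopifnot(inherits(candidates, "candidate_set"))
  idx <- set_indices(sets)
  k <- ncol(idx)
  pair_cols <- utils::combn(k, 2L)
  keep_all <- rep(TRUE, nrow(sets))
  flags <- list()
  for (ang in config$view_angles) {
    pv <- project_view(candidates$points, centroid, ang,
                       literal = config$literal_projection)
    C <- pv$coords2d
    ok <- rep(TRUE, nrow(sets))
    if (nrow(sets) > 0L) {
      for (j in seq_len(ncol(pair_cols))) {
        a <- idx[, pair_cols[1L, j]]; b <- idx[, pair_cols[2L, j]]
        d <- sqrt(rowSums((C[a, , drop = FALSE] - C[b, , drop = FALSE])^2))
        ok <- ok & d >= config$overlap_extent
      }
    }
    flags[[sprintf("view_ok_%g", ang)]] <- ok
    keep_all <- keep_all & ok
  }
  out <- sets
  for (nm in names(flags)) out[[nm]] <- flags[[nm]]
  out <- out[keep_all, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fiducial_sets", "data.frame")
  out
}
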