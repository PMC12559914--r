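#' Surface fitting and sampling settings
#'
#' @param degree_u,degree_v Spline degrees (default cubic).
#' @param grid Control-grid size `c(m+1, n+1)`.
#' @param n_u,n_v Candidate sampling resolution.
#' @param smoothing Tikhonov weight for [fit_surface()].
#' @param offset Outward radial offset (mm) applied to sampled candidates
#'   when the fitted cloud is the tumor surface itself; `NULL` means
#'   automatic (mid depth band when no shell cloud is supplied, 0
#'   otherwise).
#' @return A plain list of settings.
#' @export
surface_settings <- function(degree_u = 3L, degree_v = 3L, grid = c(8L, 8L),
                             n_u = 12L, n_v = 12L, smoothing = 0,
                             offset = NULL) {
  list(degree_u = as.integer(degree_u), degree_v = as.integer(degree_v),
       grid = as.integer(grid), n_u = as.integer(n_u), n_v = as.integer(n_v),
       smoothing = smoothing, offset = offset)
}

#' Plan fiducial marker placement
#'
#' Runs the full planning pipeline: fit a B-spline surface to the
#' candidate-source cloud (the offset shell when supplied, otherwise the
#' tumor surface with an outward offset applied to the samples), sample it
#' uniformly, filter candidates by the Z-axis band and tumor proximity,
#' build the admissible-distance graph with a kd-tree fixed-radius query,
#' enumerate constraint-satisfying marker sets, reject sets whose
#' projections overlap in either oblique view, and score the result with
#' the 10-point rubric.
#'
#' @param tumor Tumor-surface [point_cloud].
#' @param shell Optional [point_cloud] of the implantation shell around the
#'   tumor; when `NULL`, candidates are generated by offsetting the fitted
#'   tumor surface outward by `surface$offset` (default: the middle of the
#'   depth band).
#' @param config A [constraint_config].
#' @param surface A [surface_settings()] list.
#' @param verbose Log stage counts with [message()].
#' @return An object of class `fiducial_plan`: list with the config echo,
#'   surface settings, `fit` ([fit_surface()] result), `candidates` (the
#'   annotated, filtered `candidate_set`), `stage_counts`, `sets` (the
#'   final `fiducial_sets` table with a `total_score` column), and
#'   `best_score` (the full `rubric_score` of the first set, or `NULL`).
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 42L))
#' plan <- plan_fiducials(ph$tumor, ph$shell)
#' plan
#' @export
plan_fiducials <- function(tumor, shell = NULL, config = constraint_config(),
                           surface = surface_settings(), verbose = FALSE) {
  log_ <- function(...) if (verbose) message(sprintf(...))
  tpts <- as_points(tumor)
  tumor_centroid <- centroid(tumor)
  fit_cloud <- if (is.null(shell)) tumor else shell
  fitted_cloud <- if (is.null(shell)) "tumor-surface" else "offset-shell"
  offset <- surface$offset
  if (is.null(offset)) offset <- if (is.null(shell)) mean(config$band) else 0

  params <- parameterize_cloud(fit_cloud, centroid = tumor_centroid)
  fit <- fit_surface(fit_cloud, params,
                     degree_u = surface$degree_u, degree_v = surface$degree_v,
                     grid = surface$grid, smoothing = surface$smoothing)
  log_("surface fit: residual E = %.4g mm^2", fit$residual_E)
  cands <- sample_surface(fit$surface, surface$n_u, surface$n_v)
  if (offset != 0) {
    dirs <- sweep(cands$points, 2L, tumor_centroid)
    nrm <- sqrt(rowSums(dirs^2))
    nrm[nrm == 0] <- 1
    cands$points <- cands$points + dirs / nrm * offset
  }
  n0 <- nrow(cands$points)

  z_half <- config$z_half_width
  if (is.null(z_half)) z_half <- diff(range(tpts[, 3L])) / 2 + 10
  z_center <- mean(range(tpts[, 3L]))
  cands <- filter_z_band(cands, z_center, z_half)
  n1 <- nrow(cands$points)
  log_("Z-band filter (center %.1f, half-width %.1f mm): %d -> %d candidates",
       z_center, z_half, n0, n1)

  cands <- filter_tumor_proximity(cands, tumor, tumor_centroid, config)
  n2 <- nrow(cands$points)
  log_("proximity filter (<= %g mm centroid, band [%g, %g] mm): %d -> %d",
       config$d_tumor_max, config$band[1L], config$band[2L], n1, n2)

  g <- build_distance_graph(cands, config$d_min)
  log_("distance graph: %d vertices, %d edges", igraph::vcount(g), igraph::ecount(g))
  sets <- enumerate_valid_sets(g, cands, config)
  n3 <- nrow(sets)
  log_("geometric sets (distance + angle): %d", n3)
  sets <- drr_filter(sets, cands, tumor_centroid, config)
  n4 <- nrow(sets)
  log_("after DRR overlap filter (%s views, extent %g mm): %d",
       paste(config$view_angles, collapse = "/"), config$overlap_extent, n4)

  best <- NULL
  if (n4 > 0L) {
    sets$total_score <- score_sets_vectorized(sets, config)
    g1 <- cands$points[as.integer(set_indices(sets)[1L, ]), , drop = FALSE]
    views <- lapply(config$view_angles, function(a) {
      project_view(g1, tumor_centroid, a, literal = config$literal_projection)
    })
    best <- score_plan(g1, tumor_centroid, views, config)
  }

  structure(list(config = config, surface_settings = surface,
                 fitted_cloud = fitted_cloud, tumor_centroid = tumor_centroid,
                 fit = fit, candidates = cands,
                 stage_counts = list(sampled = n0, after_z_band = n1,
                                     after_proximity = n2,
                                     geometric_sets = n3, final_sets = n4),
                 sets = sets, best_score = best),
            class = "fiducial_plan")
}

# rubric totals from the cached set metrics (planner-accepted sets only)
score_sets_vectorized <- function(sets, config) {
  k <- ncol(set_indices(sets))
  dc_cols <- as.matrix(sets[, paste0("dc_", seq_len(k)), drop = FALSE])
  strict <- config$strict_rubric
  ge <- function(x, t) if (strict) x > t else x >= t
  le <- function(x, t) if (strict) x < t else x <= t
  c1 <- pmin(rowSums(le(dc_cols, config$d_tumor_max)), 3L)
  c2 <- ifelse(ge(sets$min_angle, config$theta_min), 2L, 0L)
  c3 <- ifelse(ge(sets$min_pair_dist, config$d_min), 2L, 0L)
  view_cols <- grep("^view_ok_", names(sets), value = TRUE)
  ok_all <- if (length(view_cols) > 0L) {
    Reduce(`&`, lapply(view_cols, function(cn) sets[[cn]]))
  } else rep(TRUE, nrow(sets))
  c4 <- ifelse(ok_all, pmin(k, 3L), 0L)  # retained sets are fully overlap-free
  as.integer(c1 + c2 + c3 + c4)
}

#' @export
print.fiducial_plan <- function(x, ...) {
  cat("<fiducial_plan>\n")
  cat(sprintf("  fitted cloud: %s; surface residual E = %.4g mm^2\n",
              x$fitted_cloud, x$fit$residual_E))
  sc <- x$stage_counts
  cat(sprintf("  candidates: %d sampled -> %d in Z band -> %d in proximity band\n",
              sc$sampled, sc$after_z_band, sc$after_proximity))
  cat(sprintf("  sets: %d geometric -> %d after DRR overlap filter\n",
              sc$geometric_sets, sc$final_sets))
  if (!is.null(x$best_score)) {
    cat(sprintf("  best set rubric total: %d / 10\n", x$best_score$total))
  } else {
    cat("  no feasible fiducial set under the current constraints\n")
  }
  invisible(x)
}

#' Marker coordinates of one planned set
#'
#' @param plan A `fiducial_plan`.
#' @param which Row of `plan$sets` to extract (default 1).
#' @return k x 3 matrix of marker coordinates (mm).
#' @export
plan_markers <- function(plan, which = 1L) {
  stopifnot(inherits(plan, "fiducial_plan"))
  if (nrow(plan$sets) < which) stop("no such set in this plan")
  plan$candidates$points[as.integer(set_indices(plan$sets)[which, ]), , drop = FALSE]
}
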