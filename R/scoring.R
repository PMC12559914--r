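#' Score a fiducial set with the 10-point clinical rubric
#'
#' Four criteria, maximum 10 points: (1) number of markers within 50 mm of
#' the tumor centroid (1 -> 1, 2 -> 2, >= 3 -> 3); (2) 2 points if every
#' triangle angle meets the 30-degree threshold, else 0; (3) 2 points if
#' every pairwise distance meets the 18 mm threshold, else 0; (4) number of
#' markers free of projection overlap in every view (1 -> 1, 2 -> 2,
#' >= 3 -> 3). By default meeting a threshold exactly earns the points, so
#' planner-accepted sets always score 10; `strict_rubric` in the config
#' switches criteria 1-3 to strict inequalities. Zero qualifying markers
#' for criteria 1/4 (a case the rubric does not tabulate) scores 0 with a
#' warning, as does a set too small to define angles or distances.
#'
#' @param markers n x 3 marker matrix (or list of points), n >= 1.
#' @param tumor_centroid Tumor centroid (mm).
#' @param views List of [project_view()] results computed for these
#'   markers (possibly empty).
#' @param config A [constraint_config].
#' @return An object of class `rubric_score`: list with `c1_proximity`,
#'   `c2_angle`, `c3_distance`, `c4_nonoverlap`, `total` and a `detail`
#'   list of the measured quantities.
#' @examples
#' g <- rbind(c(40, 0, 0), c(-20, 34.6, 0), c(-20, -34.6, 0))
#' views <- lapply(c(45, -45), function(a) project_view(g, c(0, 0, 0), a))
#' score_plan(g, c(0, 0, 0), views)
#' @export
score_plan <- function(markers, tumor_centroid, views = list(),
                       config = constraint_config()) {
  P <- as_points(markers)
  n <- nrow(P)
  if (n < 1L) stop("at least one marker is required")
  strict <- config$strict_rubric
  meets <- function(x, thr, dir) {
    if (dir == "ge") { if (strict) x > thr else x >= thr }
    else { if (strict) x < thr else x <= thr }
  }
  count_points <- function(cnt, what) {
    if (cnt == 0L) {
      warning(sprintf("no %s markers: criterion not tabulated by the rubric, scored 0", what))
      return(0L)
    }
    min(cnt, 3L)
  }

  dc <- sqrt(rowSums(sweep(P, 2L, tumor_centroid)^2))
  c1 <- count_points(sum(meets(dc, config$d_tumor_max, "le")), "in-range")

  if (n >= 2L) {
    pd <- as.numeric(stats::dist(P))
    c3 <- if (all(meets(pd, config$d_min, "ge"))) 2L else 0L
  } else {
    warning("fewer than 2 markers: pairwise-distance criterion scored 0")
    pd <- numeric(0)
    c3 <- 0L
  }

  if (n >= 3L) {
    min_angle <- Inf
    for (tri in triple_subsets(n)) {
      a <- triangle_angles_many(P[tri[1L], , drop = FALSE],
                                P[tri[2L], , drop = FALSE],
                                P[tri[3L], , drop = FALSE])
      min_angle <- min(min_angle, a)
    }
    c2 <- if (meets(min_angle, config$theta_min, "ge")) 2L else 0L
  } else {
    warning("fewer than 3 markers: angle criterion scored 0")
    min_angle <- NA_real_
    c2 <- 0L
  }

  overlapping <- rep(FALSE, n)
  if (n >= 2L) {
    for (vw in views) {
      res <- check_overlap(vw, config$overlap_extent)
      if (nrow(res$offending_pairs) > 0L) {
        overlapping[unique(as.vector(res$offending_pairs))] <- TRUE
      }
    }
  }
  c4 <- count_points(sum(!overlapping), "non-overlapping")

  structure(list(c1_proximity = c1, c2_angle = c2, c3_distance = c3,
                 c4_nonoverlap = c4, total = c1 + c2 + c3 + c4,
                 detail = list(centroid_distances = dc,
                               pairwise_distances = pd,
                               min_angle = min_angle,
                               overlapping = overlapping)),
            class = "rubric_score")
}

#' @export
print.rubric_score <- function(x, ...) {
  cat("Fiducial plan rubric score\n")
  cat(sprintf("  1. markers within 50 mm of tumor centroid : %d\n", x$c1_proximity))
  cat(sprintf("  2. angle between markers meets 30 deg     : %d\n", x$c2_angle))
  cat(sprintf("  3. distance between markers meets 18 mm   : %d\n", x$c3_distance))
  cat(sprintf("  4. non-overlapping markers in the DRRs    : %d\n", x$c4_nonoverlap))
  cat(sprintf("  total: %d / 10\n", x$total))
  invisible(x)
}

rubric_as_list <- function(x) {
  list(c1_proximity = x$c1_proximity, c2_angle = x$c2_angle,
       c3_distance = x$c3_distance, c4_nonoverlap = x$c4_nonoverlap,
       total = x$total)
}

#' Write a plan report
#'
#' Emits the configuration echo, per-stage candidate counts, and every
#' reported set's cached metrics and rubric score as JSON (lossless round
#' trip), CSV (sets table), or human-readable Markdown.
#'
#' @param plan A `fiducial_plan` from [plan_fiducials()].
#' @param path Output path.
#' @param format `"json"`, `"csv"` or `"md"`.
#' @param max_sets Cap on the number of sets written (ranked as returned);
#'   `Inf` writes all.
#' @return `path`, invisibly.
#' @export
render_report <- function(plan, path, format = c("json", "csv", "md"),
                          max_sets = 1000L) {
  format <- match.arg(format)
  stopifnot(inherits(plan, "fiducial_plan"))
  if (!dir.exists(dirname(path))) {
    stop(sprintf("directory does not exist: '%s'", dirname(path)))
  }
  sets <- utils::head(as.data.frame(plan$sets), max_sets)
  if (format == "json") {
    doc <- list(config = unclass(plan$config),
                surface_settings = plan$surface_settings,
                fitted_cloud = plan$fitted_cloud,
                stage_counts = plan$stage_counts,
                n_sets_total = nrow(plan$sets),
                sets = sets,
                best_score = if (!is.null(plan$best_score)) rubric_as_list(plan$best_score))
    jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, null = "null")
  } else if (format == "csv") {
    utils::write.csv(sets, path, row.names = FALSE)
  } else {
    lines <- c("# Fiducial marker placement plan", "",
               sprintf("- fitted cloud: %s", plan$fitted_cloud),
               "", "## Stage counts", "",
               sprintf("- %s: %d", names(plan$stage_counts),
                       unlist(plan$stage_counts)),
               "", sprintf("## Sets (%d total, %d shown)", nrow(plan$sets), nrow(sets)), "")
    if (nrow(sets) > 0L) {
      lines <- c(lines, paste(names(sets), collapse = " | "),
                 paste(rep("---", ncol(sets)), collapse = " | "),
                 apply(sets, 1L, function(r) paste(format(r, digits = 6), collapse = " | ")))
    }
    if (!is.null(plan$best_score)) {
      b <- rubric_as_list(plan$best_score)
      lines <- c(lines, "", "## Best-set rubric score", "",
                 sprintf("- %s: %d", names(b), unlist(b)))
    }
    writeLines(lines, path)
  }
  invisible(path)
}
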