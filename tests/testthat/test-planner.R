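test_that("Z-band filter is inclusive at its boundaries and matches a linear scan", {
  set.seed(12)
  n <- 100
  pts <- cbind(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 100))
  cs <- make_candidates(pts)
  expect_identical(filter_z_band(cs, 50, Inf)$points, cs$points)

  edge <- make_candidates(rbind(c(0, 0, 30), c(0, 0, 70), c(0, 0, 70.001)))
  kept <- filter_z_band(edge, 50, 20)
  expect_equal(nrow(kept$points), 2L)  # both exact boundaries retained

  half <- 20  # band covers 40% of the z range
  got <- filter_z_band(cs, 50, half)
  expect_equal(nrow(got$points), sum(abs(pts[, 3] - 50) <= half))
  expect_identical(got$points, cs$points[abs(pts[, 3] - 50) <= half, ])
})

test_that("tumor proximity filter applies inclusive centroid and band rules", {
  # tumor: dense sphere of radius 15 at the origin
  ph <- default_phantom(seed = 2L)
  cfg <- constraint_config()
  # candidate exactly 50 mm from the centroid, 35 mm from the surface: the
  # band rule (20-30 mm) must reject it; at 40 mm (25 mm deep) it stays
  cs <- make_candidates(rbind(c(50, 0, 0), c(40, 0, 0), c(51, 0, 0)))
  kept <- filter_tumor_proximity(cs, ph$tumor, c(0, 0, 0), cfg)
  expect_equal(nrow(kept$points), 1L)
  expect_equal(unname(kept$points[1, ]), c(40, 0, 0))
  expect_equal(kept$d_centroid[1], 40, tolerance = 1e-6)

  # boundary case: exactly 50 mm from centroid with in-band surface distance
  ph2 <- generate_phantom(phantom_spec(semi_axes = c(25, 25, 25), seed = 3L))
  kept2 <- filter_tumor_proximity(make_candidates(rbind(c(50, 0, 0))),
                                  ph2$tumor, c(0, 0, 0), cfg)
  expect_equal(nrow(kept2$points), 1L)  # d_centroid = 50 (inclusive), depth 25

  # noise-free phantom shell: all within band; shifted band: none
  shell_cs <- make_candidates(ph$shell$points)
  all_kept <- filter_tumor_proximity(shell_cs, ph$tumor, c(0, 0, 0), cfg)
  expect_equal(nrow(all_kept$points), nrow(ph$shell$points))
  none <- filter_tumor_proximity(shell_cs, ph$tumor, c(0, 0, 0),
                                 constraint_config(band = c(30.5, 40),
                                                   d_tumor_max = 100))
  expect_equal(nrow(none$points), 0L)
  expect_error(filter_tumor_proximity(shell_cs, matrix(numeric(0), ncol = 3)),
               "non-empty|empty")
})

test_that("distance graph edges follow the inclusive 18 mm rule", {
  near <- make_candidates(rbind(c(0, 0, 0), c(17.9, 0, 0)))
  g <- build_distance_graph(near, 18)
  expect_equal(igraph::ecount(g), 0)
  exact <- make_candidates(rbind(c(0, 0, 0), c(18, 0, 0)))
  expect_equal(igraph::ecount(build_distance_graph(exact, 18)), 1)
})

test_that("kd-tree graph construction equals the all-pairs double loop", {
  for (seed in c(7L, 8L)) {
    cs <- random_candidates(100, seed = seed, edge = 60)
    g <- build_distance_graph(cs, 18)
    el <- igraph::as_edgelist(g)
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    D <- as.matrix(dist(cs$points))
    brute <- which(upper.tri(D) & D >= 18, arr.ind = TRUE)
    brute <- brute[order(brute[, 1], brute[, 2]), , drop = FALSE]
    expect_equal(unname(el), unname(cbind(brute[, 1], brute[, 2])))
  }
})

test_that("kd-tree close-pair query matches brute force, ties and duplicates included", {
  set.seed(99)
  pts <- matrix(runif(3 * 120, 0, 40), ncol = 3)
  pts <- rbind(pts, pts[1:5, ], pts[7, ] + c(10, 0, 0))  # exact duplicates + exact-radius pair
  got <- fidplan:::kd_close_pairs(pts, 10)
  got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  D <- as.matrix(dist(pts))
  want <- which(upper.tri(D) & D < 10, arr.ind = TRUE)
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(cbind(want[, 1], want[, 2])))
})

test_that("triangle angles match closed forms and always sum to 180", {
  eq <- equilateral_triple(20)
  expect_equal(triangle_angles(eq[1, ], eq[2, ], eq[3, ]), c(60, 60, 60),
               tolerance = 1e-9)
  a <- triangle_angles(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(sort(a), c(45, 45, 90), tolerance = 1e-9)
  expect_equal(triangle_angles(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)),
               c(0, 180, 0), tolerance = 1e-9)
  expect_error(triangle_angles(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               "degenerate|coincident")
  set.seed(5)
  for (i in 1:1000) {
    P <- matrix(rnorm(9, sd = 30), ncol = 3)
    expect_lt(abs(sum(triangle_angles(P[1, ], P[2, ], P[3, ])) - 180), 1e-6)
  }
})

test_that("a compliant equilateral triple yields exactly one set with its metrics", {
  cs <- make_candidates(equilateral_triple(20), centroid = c(0, 0, 0))
  cfg <- constraint_config()
  g <- build_distance_graph(cs, cfg$d_min)
  sets <- enumerate_valid_sets(g, cs, cfg)
  expect_equal(nrow(sets), 1L)
  expect_equal(unname(unlist(sets[1, c("m1", "m2", "m3")])), c(1, 2, 3))
  expect_equal(sets$min_angle, 60, tolerance = 1e-9)
  expect_equal(sets$min_pair_dist, 20, tolerance = 1e-9)
})

test_that("well-spaced but flat triples are rejected by the angle rule", {
  # pairwise distances all >= 18 mm but nearly collinear (min angle << 30)
  flat <- make_candidates(rbind(c(0, 0, 0), c(20, 1, 0), c(40, 0, 0)))
  cfg <- constraint_config()
  g <- build_distance_graph(flat, cfg$d_min)
  expect_gte(igraph::ecount(g), 3)
  sets <- enumerate_valid_sets(g, flat, cfg)
  expect_equal(nrow(sets), 0L)
  expect_equal(nrow(brute_force_plan(flat, cfg)), 0L)
})

test_that("planner output equals the brute-force oracle on random instances", {
  cfg <- constraint_config()
  for (seed in 1:6) {
    n <- c(20, 35, 50, 50, 80, 120)[seed]
    cs <- random_candidates(n, seed = seed, edge = 70,
                            annotate_from = c(35, 35, 35))
    g <- build_distance_graph(cs, cfg$d_min)
    fast <- enumerate_valid_sets(g, cs, cfg)
    slow <- brute_force_plan(cs, cfg)
    expect_equal(as.data.frame(fast), as.data.frame(slow), tolerance = 1e-12)
  }
})

test_that("shell candidates: planner and oracle agree on a realistic instance", {
  ph <- default_phantom(seed = 3L, n_points = 50L)
  cs <- filter_tumor_proximity(make_candidates(ph$shell$points), ph$tumor,
                               c(0, 0, 0), constraint_config())
  cfg <- constraint_config()
  g <- build_distance_graph(cs, cfg$d_min)
  fast <- enumerate_valid_sets(g, cs, cfg)
  slow <- brute_force_plan(cs, cfg)
  expect_gt(nrow(fast), 0L)
  expect_equal(as.data.frame(fast), as.data.frame(slow), tolerance = 1e-12)
})

test_that("every returned set satisfies the constraint invariants exactly", {
  cfg <- constraint_config()
  cs <- random_candidates(80, seed = 17, edge = 70, annotate_from = c(35, 35, 35))
  g <- build_distance_graph(cs, cfg$d_min)
  sets <- enumerate_valid_sets(g, cs, cfg)
  expect_gt(nrow(sets), 0L)
  expect_true(all(sets$min_pair_dist >= cfg$d_min))
  expect_true(all(sets$min_angle >= cfg$theta_min))
  # recompute one row's metrics from scratch
  i <- as.integer(fidplan:::set_indices(sets)[1, ])
  P <- cs$points[i, ]
  expect_equal(sets$min_pair_dist[1], min(dist(P)), tolerance = 1e-12)
  expect_equal(sets$min_angle[1],
               min(triangle_angles(P[1, ], P[2, ], P[3, ])), tolerance = 1e-12)
})

test_that("strict-paper clique mode returns a subset of default mode", {
  cfg <- constraint_config()
  cfg_strict <- constraint_config(strict_paper_cliques = TRUE)
  for (seed in c(3L, 23L)) {
    cs <- random_candidates(40, seed = seed, edge = 55)
    g <- build_distance_graph(cs, cfg$d_min)
    dft <- do.call(paste, as.data.frame(fidplan:::set_indices(enumerate_valid_sets(g, cs, cfg))))
    strict <- do.call(paste, as.data.frame(fidplan:::set_indices(enumerate_valid_sets(g, cs, cfg_strict))))
    expect_true(all(strict %in% dft))
  }
})

test_that("raising thresholds never increases the number of sets", {
  cs <- random_candidates(60, seed = 29, edge = 70)
  count <- function(d_min = 18, theta = 30) {
    cfg <- constraint_config(d_min = d_min, theta_min = theta)
    nrow(enumerate_valid_sets(build_distance_graph(cs, d_min), cs, cfg))
  }
  base <- count()
  expect_lte(count(d_min = 25), base)
  expect_lte(count(theta = 45), base)
  expect_lte(count(d_min = 25, theta = 45), count(d_min = 25))
})

test_that("planning is invariant under rigid motions of the candidates", {
  cfg <- constraint_config()
  cs <- random_candidates(50, seed = 31, edge = 70)
  g <- build_distance_graph(cs, cfg$d_min)
  ref <- enumerate_valid_sets(g, cs, cfg)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- fidplan:::candidate_set(cs$points %*% t(R) +
                                     matrix(rep(c(12, -5, 40), each = 50), ncol = 3),
                                   cs$params)
  got <- enumerate_valid_sets(build_distance_graph(moved, cfg$d_min), moved, cfg)
  expect_identical(fidplan:::set_indices(got), fidplan:::set_indices(ref))
  expect_equal(got$min_pair_dist, ref$min_pair_dist, tolerance = 1e-9)
  expect_equal(got$min_angle, ref$min_angle, tolerance = 1e-9)
})

test_that("constraint_config validates its invariants", {
  expect_error(constraint_config(d_min = 0), "d_min")
  expect_error(constraint_config(theta_min = 61), "theta_min")
  expect_error(constraint_config(theta_min = 0), "theta_min")
  expect_error(constraint_config(set_size = 2), "set_size")
  expect_error(constraint_config(band = c(30, 20)), "band")
  expect_equal(constraint_config(preset = "manual-floor")$theta_min, 15)
})
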