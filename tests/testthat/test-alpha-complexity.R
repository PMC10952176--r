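test_that("delaunay tetrahedralization matches closed forms and the empty-circumsphere property", {
  # regular tetrahedron, edge 1: single tet, circumradius sqrt(3/8)
  reg <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                           c(0.5, sqrt(3) / 6, sqrt(2 / 3))))
  tc <- delaunay_tetrahedralize(reg)
  expect_equal(nrow(tc$tets), 1)
  expect_equal(tc$circumradius, sqrt(3 / 8), tolerance = 1e-12)

  # unit cube: the tetrahedra partition the hull, total volume 1
  cube <- point_cloud(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  tcc <- suppressWarnings(delaunay_tetrahedralize(cube))
  expect_equal(sum(tcc$volume), 1, tolerance = 1e-9)

  # every circumsphere is empty of all non-member points (brute force)
  pc <- random_cloud(40, 11)
  tc40 <- delaunay_tetrahedralize(pc)
  for (t in seq_len(nrow(tc40$tets))) {
    sph <- circumsphere_oracle(tc40$points[tc40$tets[t, ], ])
    d <- sqrt(colSums((t(tc40$points) - sph$centre)^2))
    inside <- which(d < sph$radius - 1e-9)
    expect_length(setdiff(inside, tc40$tets[t, ]), 0)
  }

  # circumradii agree with an independent linear solve per tet
  expect_equal(tc40$circumradius, brute_circumradii(tc40$points, tc40$tets),
               tolerance = 1e-9)

  expect_error(delaunay_tetrahedralize(point_cloud(cbind(runif(10), runif(10), 0))),
               class = "osteoshape_error_degenerate_geometry")
})

test_that("alpha shape membership, limits and regions follow the circumradius rule", {
  pc <- random_cloud(60, 21)
  tc <- delaunay_tetrahedralize(pc)

  # hull limit: all tets kept, one region
  hull <- alpha_shape(tc, max(tc$circumradius))
  expect_true(all(hull$member))
  expect_equal(hull$n_regions, 1L)
  expect_true(hull$covers_all_points)

  # below the minimum circumradius: empty shape
  empty <- alpha_shape(tc, min(tc$circumradius) * 0.99)
  expect_equal(empty$volume, 0)
  expect_equal(empty$n_regions, 0L)

  # membership at mid-range alphas equals an independent circumradius filter
  r_oracle <- brute_circumradii(tc$points, tc$tets)
  set.seed(31)
  for (a in runif(5, min(r_oracle), max(r_oracle))) {
    sh <- alpha_shape(tc, a)
    expect_identical(sh$member, r_oracle <= a)
    expect_equal(sh$volume, sum(tc$volume[r_oracle <= a]), tolerance = 1e-12)
  }

  # monotonicity of the member set
  a1 <- alpha_shape(tc, stats::quantile(r_oracle, 0.3))
  a2 <- alpha_shape(tc, stats::quantile(r_oracle, 0.7))
  expect_true(all(a2$member[a1$member]))
})

test_that("critical alpha is the exact break-down radius", {
  # single tetrahedron: the only candidate
  reg <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                           c(0.5, sqrt(3) / 6, sqrt(2 / 3))))
  tc <- delaunay_tetrahedralize(reg)
  expect_equal(critical_alpha(tc), tc$circumradius[1])

  # two separated clusters: just below the critical alpha the shape has
  # multiple regions or orphaned points
  set.seed(41)
  cl <- rbind(matrix(runif(60), ncol = 3),
              matrix(runif(60), ncol = 3) + c(4, 0, 0))
  tc2 <- delaunay_tetrahedralize(point_cloud(cl))
  ac <- critical_alpha(tc2)
  at_crit <- alpha_shape(tc2, ac)
  expect_equal(at_crit$n_regions, 1L)
  expect_true(at_crit$covers_all_points)
  below <- max(tc2$circumradius[tc2$circumradius < ac])
  sh_below <- alpha_shape(tc2, below)
  expect_true(sh_below$n_regions != 1L || !sh_below$covers_all_points)

  # cube corners: critical alpha recovers the full hull volume
  cube <- point_cloud(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  tcc <- suppressWarnings(delaunay_tetrahedralize(cube))
  expect_equal(alpha_shape(tcc, critical_alpha(tcc))$volume, 1, tolerance = 1e-9)

  # exhaustive scan over every candidate radius agrees with the search
  for (seed in c(51, 52)) {
    pc <- random_cloud(40, seed)
    tcr <- delaunay_tetrahedralize(pc)
    cands <- sort(unique(tcr$circumradius))
    ok <- vapply(cands, function(a) {
      sh <- alpha_shape(tcr, a)
      sh$n_regions == 1L && sh$covers_all_points
    }, logical(1))
    expect_equal(critical_alpha(tcr), cands[which(ok)[1]])
  }
})

test_that("complexity profiles score concavity and respect invariances", {
  # dense convex cloud: all scores near zero
  set.seed(61)
  g <- as.matrix(expand.grid(1:5, 1:5, 1:5)) + matrix(rnorm(375, 0, 0.02), ncol = 3)
  convex <- normalize_size(point_cloud(g))
  prof <- complexity_profile(convex, species_id = "cube")
  expect_true(all(prof$score_volume <= 0.05))
  expect_true(all(prof$score_volume >= 0))

  # hooked rod scores above straight rod at the finest coefficient
  hooked <- make_baculum(baculum_params(hook = TRUE, bend_angle_deg = 100, seed = 3),
                         n_t = 30, n_theta = 18, n_cloud_points = 400)
  straight <- make_baculum(baculum_params(seed = 3), n_t = 30, n_theta = 18,
                           n_cloud_points = 400)
  ph <- suppressWarnings(complexity_profile(normalize_size(hooked$cloud)))
  ps <- suppressWarnings(complexity_profile(normalize_size(straight$cloud)))
  expect_gt(ph$score_volume[1], ps$score_volume[1])

  # scores non-increasing in the coefficient, for any cloud
  for (seed in c(62, 63)) {
    pc <- normalize_size(random_cloud(80, seed))
    pr <- complexity_profile(pc)
    expect_true(all(diff(pr$score_volume) <= 1e-12))
  }

  # rigid invariance: rotation + translation leaves scores unchanged
  pc <- normalize_size(random_cloud(60, 64))
  R <- random_rotation(65)
  moved <- point_cloud(sweep(pc$points %*% R, 2, c(3, -1, 2), `+`))
  moved <- point_cloud(sweep(moved$points, 2, colMeans(moved$points)))
  pr0 <- complexity_profile(pc)
  pr1 <- complexity_profile(moved)
  expect_equal(pr1$score_volume, pr0$score_volume, tolerance = 1e-9)

  # scale invariance via normalisation of the raw cloud
  raw <- random_cloud(60, 66)
  pr_a <- complexity_profile(normalize_size(raw))
  pr_b <- complexity_profile(normalize_size(point_cloud(raw$points * 123.4)))
  expect_equal(pr_a$score_volume, pr_b$score_volume, tolerance = 1e-9)

  # unnormalised input is rejected
  expect_error(complexity_profile(raw), class = "osteoshape_error_parameter")
  expect_error(complexity_profile(pc, coefficients = c(2, 1, 4)),
               class = "osteoshape_error_parameter")
})
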