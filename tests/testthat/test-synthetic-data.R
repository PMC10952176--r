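test_that("generated bones are watertight with the declared character mapping", {
  rod <- make_baculum(baculum_params(seed = 1), n_t = 24, n_theta = 16,
                      n_cloud_points = 200)
  expect_true(mesh_is_watertight(rod$mesh))
  expect_equal(as.integer(rod$characters[1, c("H1", "H2", "S1", "S2", "T1",
                                              "T2", "T3", "T4", "T5")]),
               c(0L, 0L, 2L, 0L, 0L, 0L, 0L, 0L, 0L))

  bent <- make_baculum(baculum_params(bend_angle_deg = 90, seed = 1),
                       n_t = 24, n_theta = 16, n_cloud_points = 200)
  expect_equal(bent$characters$T1, 2L)
  expect_equal(bent$characters$T2, 0L)

  # independent re-derivation of the mapping over random parameter draws
  set.seed(33)
  for (i in 1:40) {
    p <- baculum_params(
      head_bulb_factor = 1 + runif(1, 0, 0.5),
      bend_angle_deg = runif(1, 0, 120),
      hook = runif(1) < 0.3,
      bifurcated_tip = runif(1) < 0.3,
      groove_fraction = sample(c(0, runif(1)), 1),
      n_tip_projections = sample(0:3, 1),
      cross_section = sample(c("round", "triangular"), 1),
      asymmetry = runif(1) < 0.3,
      seed = i
    )
    b <- make_baculum(p, n_t = 16, n_theta = 12, n_cloud_points = 50)
    expect_true(mesh_is_watertight(b$mesh))
    ch <- b$characters
    expect_equal(ch$H1, if (p$head_bulb_factor < 1.1) 0L else if (p$head_bulb_factor <= 1.3) 1L else 2L)
    expect_equal(ch$S1, if (p$cross_section == "triangular") 0L else 2L)
    expect_equal(ch$S2, if (p$groove_fraction == 0) 0L else if (p$groove_fraction <= 0.5) 1L else 2L)
    expect_equal(ch$T1, if (p$bend_angle_deg < 15) 0L else if (p$bend_angle_deg <= 60) 1L else 2L)
    expect_equal(ch$T2, as.integer(p$hook))
    expect_equal(ch$T3, as.integer(p$bifurcated_tip))
    expect_equal(ch$T4, as.integer(p$asymmetry))
    expect_equal(ch$T5, as.integer(p$n_tip_projections > 0))
  }

  expect_error(baculum_params(bend_angle_deg = 150),
               class = "osteoshape_error_validation")
  expect_error(baculum_params(shaft_radius = 15),
               class = "osteoshape_error_validation")
})

test_that("Yule tree simulation is reproducible and matches the depth expectation", {
  tr <- simulate_tree(3, 1, seed = 2)
  expect_equal(tr$Nnode, 2)
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_lt(diff(range(depths)), 1e-9)

  expect_identical(ape::write.tree(simulate_tree(20, 1, seed = 7)),
                   ape::write.tree(simulate_tree(20, 1, seed = 7)))

  b <- 1
  n <- 200
  depths <- vapply(1:100, function(r) {
    tr <- simulate_tree(n, b, seed = 100 + r)
    mean(ape::node.depth.edgelength(tr)[seq_len(n)])
  }, numeric(1))
  expected <- sum(1 / (b * (2:n)))
  expect_equal(mean(depths), expected, tolerance = 0.15)
})

test_that("trait simulation follows the lambda-scaled Brownian covariance", {
  tr <- simulate_tree(5, 1, seed = 3)
  V <- phylo_vcv(tr)

  # lambda = 0: independent tips with root-to-tip variances
  draws <- sapply(1:2000, function(r) simulate_traits(tr, 0, 1, seed = 10000 + r))
  S <- stats::cov(t(draws))
  expect_equal(unname(diag(S)), unname(diag(V)), tolerance = 0.15)
  cors <- stats::cov2cor(S)
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.1))

  # lambda = 1: sibling tips correlate more than distant tips
  sib <- which(V == max(V[upper.tri(V)]), arr.ind = TRUE)[1, ]
  far <- which(V == min(V[upper.tri(V) | lower.tri(V)]), arr.ind = TRUE)[1, ]
  draws1 <- sapply(1:2000, function(r) simulate_traits(tr, 1, 1, seed = 20000 + r))
  C1 <- stats::cor(t(draws1))
  expect_gt(C1[sib[1], sib[2]], C1[far[1], far[2]])

  # vanishing rate: every tip collapses to the root state
  tiny <- simulate_traits(tr, 1, 1e-12, seed = 5, root = 3.5)
  expect_true(all(abs(tiny - 3.5) < 1e-5))
})

test_that("whole studies regenerate bit-identically from one seed", {
  s1 <- build_study(n_species = 12, seed = 9)
  s2 <- build_study(n_species = 12, seed = 9)
  expect_identical(s1$life, s2$life)
  expect_identical(s1$characters, s2$characters)
  expect_identical(s1$meshes, s2$meshes)
  expect_identical(s1$clouds[[5]], s2$clouds[[5]])
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(s1, d1)
  write_study(s2, d2)
  for (f in c("life.csv", "chars.csv", "tree.nwk", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_true(all(s1$species %in% s1$tree$tip.label))
  expect_identical(s1$characters$species, s1$species)
})

test_that("feature-rich bones rank above plain rods on both metrics", {
  alpha_fine <- function(b) {
    suppressWarnings(complexity_profile(normalize_size(b$cloud)))$score_volume[1]
  }
  aria_fine <- function(b) {
    suppressWarnings(ariadne_profile(prepare_mesh(b$mesh)))$score[2]  # 0.04
  }
  seeds <- 1:10
  mk <- function(kind, seed) {
    p <- switch(kind,
      rod = baculum_params(noise_sd = 0.01, seed = seed),
      bent = baculum_params(bend_angle_deg = 80, noise_sd = 0.01, seed = seed),
      hooked = baculum_params(bend_angle_deg = 110, hook = TRUE,
                              n_tip_projections = 3, noise_sd = 0.01,
                              seed = seed)
    )
    make_baculum(p, n_t = 30, n_theta = 18, n_cloud_points = 400)
  }
  a_rod <- mean(vapply(seeds, function(s) alpha_fine(mk("rod", s)), numeric(1)))
  a_bent <- mean(vapply(seeds, function(s) alpha_fine(mk("bent", s)), numeric(1)))
  a_hook <- mean(vapply(seeds, function(s) alpha_fine(mk("hooked", s)), numeric(1)))
  expect_lt(a_rod, a_bent)
  expect_lt(a_bent, a_hook)

  d_rod <- mean(vapply(seeds, function(s) aria_fine(mk("rod", s)), numeric(1)))
  d_hook <- mean(vapply(seeds, function(s) aria_fine(mk("hooked", s)), numeric(1)))
  expect_lt(d_rod, d_hook)
})
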