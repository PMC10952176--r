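#' Parameter set for a synthetic baculum-like bone
#'
#' The generator sweeps a tube along a centerline (straight shaft plus a
#' distal circular arc) and modulates the cross-section radius to add the
#' discrete features of the ordinal character schema: a proximal head bulb,
#' a rounded-triangular cross-section with dorsal crest, a ventral urethral
#' groove over part of the length, hemispherical bosses ("additional
#' projections") near the tip, a lateral pinch producing a bifurcated tip,
#' and tip asymmetry. A hook is a distal arc of at least 150 degrees; when
#' `hook = TRUE` the swept arc is raised to that range internally even
#' though `bend_angle_deg` itself stays within `[0, 120]`.
#'
#' @param length overall bone length (mm).
#' @param shaft_radius tube radius (mm), must be < length / 4.
#' @param head_bulb_factor radial bulge factor at the proximal head (>= 1).
#' @param bend_angle_deg distal bend, degrees in `[0, 120]`.
#' @param hook curl the distal tip through >= 150 degrees.
#' @param bifurcated_tip pinch the tip into two prongs.
#' @param groove_fraction fraction of the length (from the distal end)
#'   carrying a ventral groove, in `[0, 1]`.
#' @param groove_depth_fraction groove depth as a fraction of local radius,
#'   in `[0, 0.5]`.
#' @param n_tip_projections number of hemispherical bosses at the tip.
#' @param cross_section `"round"` or `"triangular"` (pronounced dorsal
#'   crest).
#' @param asymmetry skew the distal tip laterally.
#' @param noise_sd relative radial surface noise (smooth random harmonics).
#' @param seed seed for projection placement and surface noise.
#' @return A validated `baculum_params` list.
#' @export
baculum_params <- function(length = 40, shaft_radius = 1.6,
                           head_bulb_factor = 1, bend_angle_deg = 0,
                           hook = FALSE, bifurcated_tip = FALSE,
                           groove_fraction = 0, groove_depth_fraction = 0.25,
                           n_tip_projections = 0,
                           cross_section = c("round", "triangular"),
                           asymmetry = FALSE, noise_sd = 0, seed = 1) {
  cross_section <- match.arg(cross_section)
  if (length <= 0 || shaft_radius <= 0) stop_os("length and radius must be > 0", "validation")
  if (shaft_radius * max(1, head_bulb_factor) >= length / 4) {
    stop_os("radii must stay below length / 4", "validation")
  }
  if (bend_angle_deg < 0 || bend_angle_deg > 120) {
    stop_os("bend_angle_deg must be in [0, 120]", "validation")
  }
  if (groove_fraction < 0 || groove_fraction > 1) {
    stop_os("groove_fraction must be in [0, 1]", "validation")
  }
  if (groove_depth_fraction < 0 || groove_depth_fraction > 0.5) {
    stop_os("groove_depth_fraction must be in [0, 0.5]", "validation")
  }
  if (n_tip_projections < 0) stop_os("n_tip_projections must be >= 0", "validation")
  if (head_bulb_factor < 1) stop_os("head_bulb_factor must be >= 1", "validation")
  if (noise_sd < 0) stop_os("noise_sd must be >= 0", "validation")
  structure(list(length = length, shaft_radius = shaft_radius,
                 head_bulb_factor = head_bulb_factor,
                 bend_angle_deg = bend_angle_deg, hook = hook,
                 bifurcated_tip = bifurcated_tip,
                 groove_fraction = groove_fraction,
                 groove_depth_fraction = groove_depth_fraction,
                 n_tip_projections = as.integer(n_tip_projections),
                 cross_section = cross_section, asymmetry = asymmetry,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "baculum_params")
}

# smooth step in [0, 1]
.sstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# centerline position and frame at arclength fraction s (vectorised)
.centerline <- function(s, L, arc_deg, s0 = 0.7) {
  phi_tot <- arc_deg * pi / 180
  out_pos <- matrix(0, length(s), 3)
  out_n1 <- matrix(rep(c(0, 0, 1), each = length(s)), ncol = 3)
  out_d <- matrix(rep(c(1, 0, 0), each = length(s)), ncol = 3)
  straight <- s <= s0 | phi_tot < 1e-9
  out_pos[straight, 1] <- s[straight] * L
  if (any(!straight)) {
    u <- (s[!straight] - s0) * L
    R_arc <- (1 - s0) * L / phi_tot
    phi <- u / R_arc
    out_pos[!straight, 1] <- s0 * L + R_arc * sin(phi)
    out_pos[!straight, 3] <- R_arc * (1 - cos(phi))
    out_d[!straight, ] <- cbind(cos(phi), 0, sin(phi))
    out_n1[!straight, ] <- cbind(-sin(phi), 0, cos(phi))
  }
  list(pos = out_pos, d = out_d, n1 = out_n1, b = cbind(0, 1, 0)[rep(1, length(s)), ])
}

# local radius function encoding every discrete feature; vectorised over
# equal-length s and theta
.radius_field <- function(p, s, theta, harmonics) {
  r <- rep(p$shaft_radius, length(s))
  # proximal head bulb
  r <- r * (1 + (p$head_bulb_factor - 1) * exp(-((s - 0.08) / 0.07)^2))
  # distal taper
  r <- r * (1 - 0.35 * .sstep((s - 0.88) / 0.12))
  # rounded-triangular cross-section with dorsal crest at theta = 0
  if (p$cross_section == "triangular") r <- r * (1 + 0.18 * cos(3 * theta))
  # ventral urethral groove: 60-degree sector centred at theta = pi over the
  # distal groove_fraction of the length
  if (p$groove_fraction > 0) {
    dtheta <- abs(((theta - pi + pi) %% (2 * pi)) - pi)
    in_sector <- dtheta < pi / 6
    along <- .sstep((s - (1 - p$groove_fraction)) / 0.05)
    depth <- p$groove_depth_fraction * cos(dtheta * 3)^2
    r <- r * (1 - ifelse(in_sector, along * depth, 0))
  }
  # bifurcated tip: pinch the dorsoventral midline so two lateral prongs remain
  if (p$bifurcated_tip) {
    r <- r * (1 - 0.55 * .sstep((s - 0.85) / 0.08) * cos(theta)^2)
  }
  # lateral skew of the tip
  if (p$asymmetry) {
    r <- r * (1 + 0.3 * .sstep((s - 0.8) / 0.15) * sin(theta))
  }
  # hemispherical bosses near the tip
  if (p$n_tip_projections > 0) {
    for (k in seq_len(p$n_tip_projections)) {
      sk <- harmonics$proj_s[k]
      tk <- harmonics$proj_theta[k]
      dth <- abs(((theta - tk + pi) %% (2 * pi)) - pi)
      r <- r + 0.55 * p$shaft_radius *
        exp(-((s - sk) / 0.03)^2 - (dth / 0.55)^2)
    }
  }
  # smooth surface noise from fixed random harmonics
  if (p$noise_sd > 0) {
    h <- harmonics
    for (k in seq_along(h$amp)) {
      r <- r * (1 + h$amp[k] * cos(2 * pi * h$fs[k] * s + h$ps[k]) *
                  cos(h$ft[k] * theta + h$pt[k]))
    }
  }
  pmax(r, 0.05 * p$shaft_radius)
}

.feature_randoms <- function(p) {
  with_seed(p$seed, {
    n_h <- 6
    list(
      proj_s = runif(max(1, p$n_tip_projections), 0.86, 0.95),
      proj_theta = runif(max(1, p$n_tip_projections), 0, 2 * pi),
      amp = rnorm(n_h, 0, p$noise_sd / sqrt(n_h)),
      fs = sample(2:8, n_h, replace = TRUE),
      ft = sample(2:7, n_h, replace = TRUE),
      ps = runif(n_h, 0, 2 * pi),
      pt = runif(n_h, 0, 2 * pi)
    )
  })
}

#' Generate a synthetic baculum: mesh, point cloud and character row
#'
#' Builds a watertight triangulated tube mesh from a [baculum_params()],
#' samples a point cloud from the enclosed solid, and derives the ordinal
#' character row deterministically from the parameters: T1 = 0/1/2 for a
#' bend below 15 / up to 60 / above 60 degrees; T2 = hook; T3 = bifurcated
#' tip; T4 = asymmetry; T5 = any tip projections; S1 = 0 (triangular,
#' crested) or 2 (round); S2 = 0/1/2 for a groove over none / up to half /
#' more than half the length; H1 = 0/1/2 for a head bulb factor below 1.1 /
#' up to 1.3 / above 1.3; H2 = 0.
#'
#' @param p a [baculum_params()].
#' @param species_id label for the character row.
#' @param n_t,n_theta sweep resolution: rings along the bone and vertices
#'   per ring. The default gives roughly 20k faces.
#' @param n_cloud_points solid points to sample.
#' @return list with `mesh` ([tri_mesh()]), `cloud` ([point_cloud()]),
#'   `characters` (1-row tibble), `params`.
#' @export
make_baculum <- function(p, species_id = "specimen", n_t = 116, n_theta = 88,
                         n_cloud_points = 5000) {
  stopifnot(inherits(p, "baculum_params"))
  arc <- if (p$hook) max(p$bend_angle_deg, 155) else p$bend_angle_deg
  har <- .feature_randoms(p)

  s_grid <- seq(0, 1, length.out = n_t + 1)
  th_grid <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ss <- rep(s_grid, each = n_theta)
  tt <- rep(th_grid, times = n_t + 1)
  cl <- .centerline(ss, p$length, arc)
  rr <- .radius_field(p, ss, tt, har)
  V <- cl$pos + rr * (cos(tt) * cl$n1 + sin(tt) * cl$b)

  # pole vertices capping the two ends
  cl0 <- .centerline(c(0, 1), p$length, arc)
  pole0 <- cl0$pos[1, ] - 0.02 * p$length * cl0$d[1, ]
  pole1 <- cl0$pos[2, ] + 0.02 * p$length * cl0$d[2, ]
  V <- rbind(V, pole0, pole1)
  i_p0 <- nrow(V) - 1L
  i_p1 <- nrow(V)

  idx <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  quads <- expand.grid(i = seq_len(n_t), j = seq_len(n_theta))
  F1 <- cbind(idx(quads$i, quads$j), idx(quads$i + 1L, quads$j),
              idx(quads$i, quads$j + 1L))
  F2 <- cbind(idx(quads$i + 1L, quads$j), idx(quads$i + 1L, quads$j + 1L),
              idx(quads$i, quads$j + 1L))
  j <- seq_len(n_theta)
  cap0 <- cbind(i_p0, idx(1L, j + 1L), idx(1L, j))
  cap1 <- cbind(i_p1, idx(n_t + 1L, j), idx(n_t + 1L, j + 1L))
  mesh <- tri_mesh(V, rbind(F1, F2, cap0, cap1))

  cloud <- with_seed(p$seed + 1L, {
    sc <- runif(n_cloud_points)
    thc <- runif(n_cloud_points, 0, 2 * pi)
    uc <- sqrt(runif(n_cloud_points))
    clc <- .centerline(sc, p$length, arc)
    rc <- uc * .radius_field(p, sc, thc, har)
    point_cloud(clc$pos + rc * (cos(thc) * clc$n1 + sin(thc) * clc$b))
  })

  characters <- tibble(
    species = species_id,
    H1 = if (p$head_bulb_factor < 1.1) 0L else if (p$head_bulb_factor <= 1.3) 1L else 2L,
    H2 = 0L,
    S1 = if (p$cross_section == "triangular") 0L else 2L,
    S2 = if (p$groove_fraction == 0) 0L else if (p$groove_fraction <= 0.5) 1L else 2L,
    T1 = if (p$bend_angle_deg < 15) 0L else if (p$bend_angle_deg <= 60) 1L else 2L,
    T2 = as.integer(p$hook),
    T3 = as.integer(p$bifurcated_tip),
    T4 = as.integer(p$asymmetry),
    T5 = as.integer(p$n_tip_projections > 0)
  )
  list(mesh = mesh, cloud = cloud, characters = characters, params = p)
}

#' Is a mesh watertight?
#'
#' @param m a [tri_mesh()].
#' @return TRUE if every edge belongs to exactly two faces.
#' @export
mesh_is_watertight <- function(m) {
  e <- rbind(m$faces[, c(1, 2)], m$faces[, c(2, 3)], m$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate speciation rate.
#' @param seed RNG seed; the same seed gives an identical tree.
#' @return An ultrametric `phylo` with tips `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1) {
  if (n_tips < 3) stop_os("n_tips must be >= 3", "parameter")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree
}

#' Simulate trait values under lambda-scaled Brownian motion
#'
#' A multivariate normal draw with covariance
#' `sigma2 * lambda_transform(vcv(tree), lambda)`: `lambda = 1` is Brownian
#' motion, `lambda = 0` independent tips with root-to-tip variances.
#'
#' @param tree a `phylo`.
#' @param lambda phylogenetic signal in `[0, 1]`.
#' @param sigma2 evolutionary rate (> 0).
#' @param seed RNG seed.
#' @param root root state added to every tip.
#' @return named numeric vector in `tree$tip.label` order.
#' @export
simulate_traits <- function(tree, lambda = 1, sigma2 = 1, seed = 1, root = 0) {
  if (sigma2 <= 0) stop_os("sigma2 must be > 0", "parameter")
  V <- lambda_transform(phylo_vcv(tree), lambda)
  L <- chol(sigma2 * V)
  z <- with_seed(seed, rnorm(nrow(V)))
  setNames(root + as.vector(crossprod(L, z)), rownames(V))
}

#' Build a complete synthetic comparative study
#'
#' Simulates a Yule tree and log-scale life-history traits under Brownian
#' motion, plants linear effects of the selection proxies on a latent
#' complexity driver, maps the driver monotonically onto tip geometry
#' (bend angle, hook, projections, groove), and generates a mesh, a point
#' cloud and a ground-truth character row per species. The mapping from
#' driver to geometry is monotone but nonlinear, so downstream checks test
#' sign and significance recovery rather than exact slopes.
#'
#' @param n_species number of species (>= 10).
#' @param effects list with `beta_intromission`, `beta_testes`, `beta_ssd`:
#'   planted effects (per standard deviation of the log proxy) on the
#'   latent driver.
#' @param noise_sd driver noise standard deviation.
#' @param missing_rate fraction of intromission and testes records set to
#'   NA, emulating sparsely reported life-history data.
#' @param seed master seed; regeneration with the same seed is identical.
#' @param resolution `"study"` (fast desk-scale geometry) or `"full"`
#'   (approximately 20k-face meshes and 5k-point clouds).
#' @return A `synthetic_study` list: `species`, `meshes`, `clouds`, `tree`,
#'   `life`, `characters`, `params`, `effects`, `driver`, `seed`.
#' @export
build_study <- function(n_species = 60,
                        effects = list(beta_intromission = 2, beta_testes = 0,
                                       beta_ssd = 0),
                        noise_sd = 0.5, missing_rate = 0.1, seed = 1,
                        resolution = c("study", "full")) {
  resolution <- match.arg(resolution)
  if (n_species < 10) stop_os("n_species must be >= 10", "parameter")
  effects <- utils::modifyList(
    list(beta_intromission = 0, beta_testes = 0, beta_ssd = 0), effects
  )
  sub <- function(k) (seed * 131 + k) %% 2147483647L
  tree <- simulate_tree(n_species, birth_rate = 1, seed = sub(1))
  sp <- tree$tip.label

  ln_int <- simulate_traits(tree, 1, 0.6, seed = sub(2), root = log(20))
  ln_male <- simulate_traits(tree, 1, 1.2, seed = sub(3), root = log(800))
  ln_ssd <- 0.25 + simulate_traits(tree, 1, 0.02, seed = sub(4))
  ln_testes <- -3.5 + 0.75 * ln_male + simulate_traits(tree, 1, 0.25, seed = sub(5))

  rel_testes <- stats::resid(stats::lm(ln_testes ~ ln_male))
  driver <- effects$beta_intromission * as.vector(scale(ln_int)) +
    effects$beta_testes * as.vector(scale(rel_testes)) +
    effects$beta_ssd * as.vector(scale(ln_ssd)) +
    with_seed(sub(6), rnorm(n_species, 0, noise_sd))
  u <- (rank(driver) - 0.5) / n_species

  extra <- with_seed(sub(7), list(
    bulb = runif(n_species, 0, 0.45),
    asym = rbinom(n_species, 1, 0.25 * (u > 0.5)) == 1
  ))

  res <- switch(resolution,
    study = list(n_t = 30, n_theta = 18, n_cloud = 400),
    full = list(n_t = 116, n_theta = 88, n_cloud = 5000)
  )

  meshes <- vector("list", n_species)
  clouds <- vector("list", n_species)
  chars <- vector("list", n_species)
  params <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    p <- baculum_params(
      length = 40, shaft_radius = 1.6,
      head_bulb_factor = 1 + extra$bulb[i],
      bend_angle_deg = 110 * u[i],
      hook = u[i] > 0.75,
      bifurcated_tip = u[i] > 0.9,
      groove_fraction = if (u[i] > 0.3) 0.8 * (u[i] - 0.3) / 0.7 else 0,
      n_tip_projections = if (u[i] > 0.6) round(1 + 3 * (u[i] - 0.6) / 0.4) else 0,
      cross_section = if (u[i] > 0.55) "triangular" else "round",
      asymmetry = extra$asym[i],
      noise_sd = 0.015,
      seed = sub(100 + i)
    )
    b <- make_baculum(p, species_id = sp[i], n_t = res$n_t,
                      n_theta = res$n_theta, n_cloud_points = res$n_cloud)
    meshes[[i]] <- b$mesh
    clouds[[i]] <- b$cloud
    chars[[i]] <- b$characters
    params[[i]] <- p
  }
  names(meshes) <- names(clouds) <- names(params) <- sp

  life <- tibble(
    species = sp,
    male_mass = exp(ln_male),
    female_mass = exp(ln_male - ln_ssd),
    testes_mass = exp(ln_testes),
    intromission_duration = exp(ln_int)
  )
  if (missing_rate > 0) {
    na_idx <- with_seed(sub(8), list(
      int = runif(n_species) < missing_rate,
      tes = runif(n_species) < missing_rate
    ))
    life$intromission_duration[na_idx$int] <- NA
    life$testes_mass[na_idx$tes] <- NA
  }

  structure(list(
    species = sp, meshes = meshes, clouds = clouds, tree = tree,
    life = life, characters = dplyr::bind_rows(chars), params = params,
    effects = effects, driver = setNames(driver, sp), seed = seed
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", length(x$species), " species, seed ", x$seed,
      "; planted effects: intromission ", x$effects$beta_intromission,
      ", testes ", x$effects$beta_testes, ", ssd ", x$effects$beta_ssd,
      "\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits per-species mesh and cloud PLYs, `life.csv`, `chars.csv`,
#' `tree.nwk`, `manifest.csv` and `truth.json` (planted effects, driver,
#' seed) under `outdir`.
#'
#' @param study a [build_study()] result.
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mesh_dir <- file.path(outdir, "meshes")
  cloud_dir <- file.path(outdir, "clouds")
  dir.create(mesh_dir, showWarnings = FALSE)
  dir.create(cloud_dir, showWarnings = FALSE)
  for (spn in study$species) {
    write_mesh(study$meshes[[spn]], file.path(mesh_dir, paste0(spn, ".ply")))
    write_pointcloud(study$clouds[[spn]], file.path(cloud_dir, paste0(spn, ".ply")))
  }
  write.csv(study$life, file.path(outdir, "life.csv"), row.names = FALSE)
  write.csv(study$characters, file.path(outdir, "chars.csv"), row.names = FALSE)
  ape::write.tree(study$tree, file.path(outdir, "tree.nwk"))
  manifest <- data.frame(
    species = study$species,
    geometry_path = file.path("meshes", paste0(study$species, ".ply")),
    geometry_kind = "mesh",
    cloud_path = file.path("clouds", paste0(study$species, ".ply"))
  )
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = study$seed, effects = study$effects,
         driver = as.list(study$driver)),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(outdir)
}
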