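# Independent oracles and small geometry builders used across the suite.
# Everything here is deliberately written without touching the package's
# computational paths (no tet_complex internals, no C++ calls).

# circumcentre/radius of one tetrahedron by a direct linear solve
circumsphere_oracle <- function(P) {
  A <- 2 * sweep(P[2:4, , drop = FALSE], 2, P[1, ])
  b <- rowSums(P[2:4, , drop = FALSE]^2) - sum(P[1, ]^2)
  centre <- solve(A, b)
  list(centre = centre, radius = sqrt(sum((P[1, ] - centre)^2)))
}

# circumradius of every tet computed independently from the point coordinates
brute_circumradii <- function(pts, tets) {
  vapply(seq_len(nrow(tets)), function(t) {
    circumsphere_oracle(pts[tets[t, ], , drop = FALSE])$radius
  }, numeric(1))
}

random_cloud <- function(n, seed) {
  set.seed(seed)
  point_cloud(matrix(runif(3 * n), ncol = 3))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3)))
}

# flat triangulated grid in the z = 0 plane
grid_mesh <- function(nx = 15, ny = 15, spacing = 0.05) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  V <- cbind((g$x - 1) * spacing, (g$y - 1) * spacing, 0)
  idx <- function(i, j) (j - 1) * nx + i
  q <- expand.grid(i = seq_len(nx - 1), j = seq_len(ny - 1))
  F1 <- cbind(idx(q$i, q$j), idx(q$i + 1, q$j), idx(q$i, q$j + 1))
  F2 <- cbind(idx(q$i + 1, q$j), idx(q$i + 1, q$j + 1), idx(q$i, q$j + 1))
  tri_mesh(V, rbind(F1, F2))
}

# latitude-longitude sphere with ~2 * n_lat * n_lon faces
uv_sphere <- function(n_lat = 40, n_lon = 60, radius = 1, bumps = 0,
                      bump_amp = 0, seed = 1) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 2)[2:(n_lat + 1)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  g <- expand.grid(lon = lon, lat = lat)
  r <- rep(radius, nrow(g))
  if (bumps > 0) {
    set.seed(seed)
    cl <- matrix(rnorm(3 * bumps), ncol = 3)
    cl <- cl / sqrt(rowSums(cl^2))
    P <- cbind(cos(g$lat) * cos(g$lon), cos(g$lat) * sin(g$lon), sin(g$lat))
    for (k in seq_len(bumps)) {
      ang <- acos(pmin(1, pmax(-1, P %*% cl[k, ])))
      r <- r + bump_amp * radius * exp(-(ang / 0.15)^2)
    }
  }
  V <- cbind(r * cos(g$lat) * cos(g$lon), r * cos(g$lat) * sin(g$lon),
             r * sin(g$lat))
  V <- rbind(V, c(0, 0, -radius), c(0, 0, radius))
  ip0 <- nrow(V) - 1L; ip1 <- nrow(V)
  idx <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  q <- expand.grid(i = seq_len(n_lat - 1), j = seq_len(n_lon))
  F1 <- cbind(idx(q$i, q$j), idx(q$i + 1, q$j), idx(q$i, q$j + 1))
  F2 <- cbind(idx(q$i + 1, q$j), idx(q$i + 1, q$j + 1), idx(q$i, q$j + 1))
  j <- seq_len(n_lon)
  cap0 <- cbind(ip0, idx(1L, j + 1L), idx(1L, j))
  cap1 <- cbind(ip1, idx(n_lat, j), idx(n_lat, j + 1L))
  tri_mesh(V, rbind(F1, F2, cap0, cap1))
}

# dense local-covariance curvature with no kernel cutoff (all vertices)
dense_curvature_oracle <- function(m, vertex_index, eps) {
  V <- m$vertices
  d2 <- rowSums(sweep(V, 2, V[vertex_index, ])^2)
  w <- exp(-d2 / eps^2)
  mu <- colSums(V * w) / sum(w)
  X <- sweep(V, 2, mu)
  C <- crossprod(X * sqrt(w)) / sum(w)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  max(0, min(ev)) / sum(ev)
}

# tie-corrected Kruskal-Wallis H from the textbook rank formula
kw_oracle <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  R <- rank(values)  # mid-ranks
  Rj <- tapply(R, groups, sum)
  nj <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# root-to-tip and shared-path depths by explicit traversal of the edge list
vcv_oracle <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  # depth of every node from the root
  depth <- numeric(max(tree$edge))
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    depth[ord$edge[e, 2]] <- depth[ord$edge[e, 1]] + ord$edge.length[e]
  }
  # ancestor chains
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  chain <- function(tip) {
    out <- tip
    while (tip != root) {
      tip <- parent[tip]
      out <- c(out, tip)
    }
    out
  }
  chains <- lapply(seq_len(n), chain)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      mrca <- intersect(chains[[i]], chains[[j]])[1]
      V[i, j] <- depth[mrca]
    }
  }
  diag(V) <- depth[seq_len(n)]
  V
}

# random valid character-score table
random_character_table <- function(n, seed) {
  set.seed(seed)
  sch <- character_schema()
  out <- tibble::tibble(species = sprintf("sp%03d", seq_len(n)))
  for (i in seq_len(nrow(sch))) {
    out[[sch$character[i]]] <- sample(sch$levels[[i]], n, replace = TRUE)
  }
  out
}
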