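make_cm <- function(X, metric = "alpha") {
  df <- tibble::as_tibble(as.data.frame(X))
  names(df) <- paste0("k", seq_len(ncol(X)))
  structure(dplyr::bind_cols(tibble::tibble(species = sprintf("s%d", seq_len(nrow(X)))), df),
            metric_name = metric, class = c("complexity_matrix", "tbl_df", "tbl", "data.frame"))
}

test_that("correlation PCA recovers correlation structure with a fixed sign convention", {
  set.seed(1)
  base <- rnorm(200)
  X <- cbind(base + rnorm(200, 0, 0.01), base + rnorm(200, 0, 0.01),
             matrix(rnorm(200 * 4), ncol = 4))
  r <- pca_correlation(make_cm(X))
  # the perfectly correlated pair loads PC1 with equal signs
  expect_equal(sign(r$loadings[1, 1]), sign(r$loadings[2, 1]))
  # sign convention: largest-|loading| positive in every component
  for (j in seq_len(ncol(r$loadings))) {
    lj <- r$loadings[, j]
    expect_gt(lj[which.max(abs(lj))], 0)
  }

  # six independent noise columns: variance fractions near uniform
  set.seed(2)
  r6 <- pca_correlation(make_cm(matrix(rnorm(500 * 6), ncol = 6)))
  expect_true(all(abs(r6$variance_fractions - 1 / 6) < 0.05))

  # scores reconstruct as standardised data times loadings
  set.seed(3)
  X10 <- matrix(rnorm(60), ncol = 6)
  r10 <- pca_correlation(make_cm(X10))
  Z <- scale(X10)
  attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
  expect_equal(unname(as.matrix(r10$scores[, -1])), unname(Z %*% r10$loadings),
               tolerance = 1e-8)
})

test_that("variance summaries match the eigenvalue ratios", {
  set.seed(4)
  X <- matrix(rnorm(40 * 6), ncol = 6)
  r <- pca_correlation(make_cm(X))
  expect_equal(summarise_variance(r, 6), 100, tolerance = 1e-9)
  expect_equal(sum(r$variance_fractions), 1, tolerance = 1e-9)

  ev <- eigen(cor(X), only.values = TRUE)$values
  for (k in 1:6) {
    expect_equal(summarise_variance(r, k), 100 * sum(ev[1:k]) / sum(ev),
                 tolerance = 1e-8)
  }

  # near rank-1 input: first component dominates
  sig <- rnorm(50)
  X1 <- sapply(1:6, function(i) sig + rnorm(50, 0, 0.01))
  r1 <- pca_correlation(make_cm(X1))
  expect_gt(summarise_variance(r1, 1), 99)

  expect_error(summarise_variance(r, 7), class = "osteoshape_error_parameter")
  expect_error(summarise_variance(r, 0), class = "osteoshape_error_parameter")
})

test_that("correlation PCA is invariant to column rescaling and rejects constants", {
  set.seed(5)
  X <- matrix(rnorm(30 * 6), ncol = 6)
  r_a <- pca_correlation(make_cm(X))
  r_b <- pca_correlation(make_cm(sweep(X, 2, c(1, 10, 100, 0.1, 5, 2), `*`)))
  expect_equal(r_a$variance_fractions, r_b$variance_fractions, tolerance = 1e-9)
  expect_equal(unname(as.matrix(r_a$scores[, -1])), unname(as.matrix(r_b$scores[, -1])),
               tolerance = 1e-8)

  Xc <- X
  Xc[, 3] <- 2
  err <- tryCatch(pca_correlation(make_cm(Xc)), error = identity)
  expect_s3_class(err, "osteoshape_error_degenerate_column")
  expect_match(conditionMessage(err), "k3")
})

test_that("complexity_matrix pivots profiles and tidy/glance methods are consistent", {
  study <- build_study(n_species = 10, seed = 2, missing_rate = 0)
  prof <- dplyr::bind_rows(lapply(study$species, function(sp) {
    suppressWarnings(complexity_profile(normalize_size(study$clouds[[sp]]),
                                        species_id = sp))
  }))
  cm <- complexity_matrix(prof, "alpha")
  expect_equal(dim(cm), c(10, 7))
  r <- pca_correlation(cm)
  td <- tidy(r)
  expect_equal(nrow(td), 36)
  gl <- glance(r)
  expect_equal(gl$two_pc_total_pct,
               100 * sum(r$variance_fractions[1:2]), tolerance = 1e-12)
  expect_s3_class(autoplot(r), "ggplot")
})
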