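test_that("scalar life-history transforms follow their formulas", {
  expect_equal(ssd(2000, 1000), 2)
  expect_equal(ssd(750, 750), 1)
  set.seed(1)
  m <- runif(20, 100, 5000); f <- runif(20, 100, 5000)
  expect_equal(ssd(m, f), m / f)
  expect_error(ssd(-1, 2), class = "osteoshape_error_data")

  expect_equal(testes_mass_from_volume(10, 0.81), 8.1)
  expect_equal(testes_mass_from_volume(1, 1), 1)
  v <- runif(20, 0.1, 50); d <- runif(20, 0.5, 1.5)
  expect_equal(testes_mass_from_volume(v, d), v * d)
  expect_error(testes_mass_from_volume(0), class = "osteoshape_error_data")
})

test_that("phylogenetic covariances equal shared path lengths", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(unname(phylo_vcv(star)), diag(4), ignore_attr = TRUE)

  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V3 <- phylo_vcv(tr3, c("A", "B", "C"))
  expect_equal(V3["A", "B"], 1)
  expect_equal(V3["A", "C"], 0)
  expect_equal(unname(diag(V3)), rep(2, 3))

  tr <- simulate_tree(20, 1, seed = 3)
  V <- phylo_vcv(tr)
  expect_equal(unname(V), unname(vcv_oracle(tr)[rownames(V), colnames(V)]),
               tolerance = 1e-10, ignore_attr = TRUE)

  err <- tryCatch(phylo_vcv(tr3, c("A", "Z")), error = identity)
  expect_s3_class(err, "osteoshape_error_name_mismatch")
  expect_match(conditionMessage(err), "Z")
})

test_that("the lambda transform scales only the off-diagonals", {
  tr <- simulate_tree(10, 1, seed = 5)
  V <- phylo_vcv(tr)
  expect_equal(lambda_transform(V, 0), diag(diag(V)), ignore_attr = TRUE)
  expect_equal(unname(lambda_transform(V, 1)), unname(V))
  Vh <- lambda_transform(V, 0.5)
  off <- upper.tri(V)
  expect_equal(Vh[off], V[off] / 2)
  expect_equal(diag(Vh), diag(V))
  expect_true(all(eigen(Vh, only.values = TRUE)$values > 0))
  expect_error(lambda_transform(V, 1.2), class = "osteoshape_error_parameter")
})

test_that("GLS reduces to OLS at identity covariance and matches direct formulas", {
  set.seed(7)
  n <- 30
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- 1 + 2 * X[, 1] - 0.5 * X[, 2] + rnorm(n)
  fit <- gls_fit(y, X, diag(n))
  ols <- summary(stats::lm(y ~ X))
  expect_equal(fit$coefficients$estimate, unname(ols$coefficients[, 1]),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$std_error, unname(ols$coefficients[, 2]),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$p_value, unname(ols$coefficients[, 4]),
               tolerance = 1e-8)
  expect_equal(fit$adjusted_r_squared, ols$adj.r.squared, tolerance = 1e-8)
  expect_equal(fit$f_statistic, unname(ols$fstatistic[1]), tolerance = 1e-8)

  # exact linear response: R^2 = 1, zero residuals under any PD covariance
  A <- matrix(rnorm(n * n), n)
  V <- crossprod(A) + n * diag(n)
  y_lin <- 3 + 1.5 * X[, 1]
  fit_lin <- gls_fit(y_lin, X[, 1, drop = FALSE], V)
  expect_equal(fit_lin$r_squared, 1, tolerance = 1e-9)

  # whitening result equals the direct (X'V^-1X)^-1 X'V^-1 y solve
  y2 <- 1 + 2 * X[, 1] + as.vector(t(chol(V)) %*% rnorm(n))
  fit2 <- gls_fit(y2, X, V)
  Xi <- cbind(1, X)
  Vi <- solve(V)
  beta_direct <- solve(t(Xi) %*% Vi %*% Xi, t(Xi) %*% Vi %*% y2)
  expect_equal(fit2$coefficients$estimate, as.vector(beta_direct), tolerance = 1e-8)

  expect_error(gls_fit(y, cbind(X, x3 = X[, 1]), diag(n)),
               class = "osteoshape_error_collinearity")
})

test_that("ML lambda profiling dominates a grid and agrees with an independent PGLS", {
  tr <- simulate_tree(60, 1, seed = 11)
  x <- simulate_traits(tr, 1, 1, seed = 12)
  y <- 1 + 2 * x + 0.8 * simulate_traits(tr, 0.6, 1, seed = 13)
  C <- phylo_vcv(tr)
  fit <- profile_lambda_ml(y, cbind(x = x), C)

  grid <- seq(0, 1, length.out = 101)
  ll <- vapply(grid, function(l) {
    gls_fit(y, cbind(x = x), lambda_transform(C, l))$log_likelihood
  }, numeric(1))
  expect_true(all(fit$log_likelihood >= ll - 1e-6))

  skip_if_not_installed("nlme")
  dat <- data.frame(y = y, x = x, sp = names(x))
  cp <- ape::corPagel(0.5, phy = tr, form = ~sp)
  ref <- nlme::gls(y ~ x, data = dat, correlation = cp, method = "ML")
  lam_ref <- unname(coef(ref$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(fit$lambda_hat, lam_ref, tolerance = 0.01)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-3)
})

test_that("the model suite mirrors the published table structure", {
  study <- build_study(n_species = 40, effects = list(beta_intromission = 2),
                       missing_rate = 0, seed = 21)
  # responses simulated directly to keep this fast: drive PCs from the truth
  set.seed(22)
  sc <- tibble::tibble(species = study$species,
                       PC1 = as.vector(scale(study$driver)),
                       PC2 = rnorm(40))
  suite <- model_suite(sc, sc, study$life, study$tree)
  expect_equal(nrow(suite), 4 * 3 * 3)
  expect_setequal(unique(suite$lambda_mode), c("0", "ML", "1"))
  expect_true(all(suite$df2 == suite$n_used - suite$df1 - 1))
  # testes models carry two coefficient rows
  co <- suite$coefficients[[which(suite$proxy == "testes")[1]]]
  expect_equal(nrow(co), 2)

  # planted intromission effect: lambda = 0 slope positive and significant
  row0 <- suite[suite$proxy == "intromission" & suite$response == "alphaPC1" &
                  suite$lambda_mode == "0", ]
  expect_lt(row0$model_p, 0.05)
  expect_gt(row0$coefficients[[1]]$estimate[1], 0)

  # lambda = 0 PGLS is exactly the uncorrected linear model
  life <- study$life
  d <- data.frame(y = sc$PC1, x = log(life$intromission_duration))
  lmfit <- summary(stats::lm(y ~ x, data = d))
  expect_equal(row0$f_statistic, unname(lmfit$fstatistic[1]), tolerance = 1e-8)

  # star phylogeny: all lambda modes coincide
  star <- ape::read.tree(text = paste0("(",
    paste(sprintf("%s:1", study$species), collapse = ","), ");"))
  suite_star <- model_suite(sc, sc, life, star)
  slopes <- vapply(split(suite_star, suite_star$lambda_mode), function(s) {
    s$coefficients[[1]]$estimate[1]
  }, numeric(1))
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-8)
})
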