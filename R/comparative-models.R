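#' Sexual size dimorphism ratio
#'
#' @param male_mass,female_mass body masses (same units, both > 0);
#'   vectorised.
#' @return male mass divided by female mass.
#' @export
ssd <- function(male_mass, female_mass) {
  if (any(male_mass <= 0, na.rm = TRUE) || any(female_mass <= 0, na.rm = TRUE)) {
    stop_os("masses must be positive", "data")
  }
  male_mass / female_mass
}

#' Testes mass from volume
#'
#' Converts a measured testes volume to mass under an assumed average
#' density (default 0.81 g/cm^3, i.e. 810 kg/m^3).
#'
#' @param volume testes volume in cm^3 (> 0).
#' @param density assumed density in g/cm^3 (> 0).
#' @return mass in grams.
#' @export
testes_mass_from_volume <- function(volume, density = 0.81) {
  if (any(volume <= 0, na.rm = TRUE) || any(density <= 0)) {
    stop_os("volume and density must be positive", "data")
  }
  volume * density
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the shared root-to-MRCA branch length of tips i and j;
#' the diagonal holds root-to-tip distances. The tree is pruned to `tips`
#' preserving path lengths.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param tips species to keep, in the row/column order wanted.
#' @return n x n covariance matrix with `lambda = 1` attribute.
#' @export
phylo_vcv <- function(tree, tips = tree$tip.label) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) > 0) {
    stop_os(paste0("tips absent from tree: ", paste(missing, collapse = ", ")),
            "name_mismatch")
  }
  if (length(tips) < 3) stop_os("need at least 3 tips", "parameter")
  pruned <- ape::keep.tip(tree, tips)
  V <- ape::vcv(pruned)
  V <- V[tips, tips]
  attr(V, "lambda") <- 1
  V
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' untouched: `lambda = 0` removes all phylogenetic signal (independent
#' tips), `lambda = 1` is the Brownian-motion covariance.
#'
#' @param V covariance matrix from [phylo_vcv()].
#' @param lambda scalar in `[0, 1]`.
#' @return transformed matrix with `lambda` attribute updated.
#' @export
lambda_transform <- function(V, lambda) {
  if (lambda < 0 || lambda > 1) stop_os("lambda must be in [0, 1]", "parameter")
  d <- diag(V)
  out <- V * lambda
  diag(out) <- d
  attr(out, "lambda") <- lambda
  out
}

#' Generalized least squares with a known error covariance
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma^2 V)` by whitening with the
#' Cholesky factor of `V`. Coefficient covariance is
#' `sigmahat^2 (X' V^-1 X)^-1` with `sigmahat^2 = e' V^-1 e / (n - p - 1)`;
#' R^2 is computed against the GLS intercept-only fit, and the reported
#' log-likelihood is the ML profile value used for lambda estimation.
#'
#' @param y numeric response, named by species (names must match `V`'s
#'   dimnames if both are present).
#' @param X predictor matrix (no intercept column; one is added), with
#'   column names as term labels.
#' @param V positive-definite error covariance aligned with `y`.
#' @param lambda_mode,lambda_hat metadata recorded in the fit.
#' @return A `pgls_fit` object; see [tidy.pgls_fit()] and
#'   [glance.pgls_fit()].
#' @export
gls_fit <- function(y, X, V, lambda_mode = NA_character_, lambda_hat = NA_real_) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n) stop_os("y, X, V dimensions disagree", "parameter")
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi) - 1L
  L <- tryCatch(chol(V), error = function(e) {
    stop_os("V is not positive-definite", "covariance")
  })
  # whiten: chol returns upper triangular U with U'U = V
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, Xi, transpose = TRUE)
  qr_x <- qr(Xw)
  if (qr_x$rank < ncol(Xw)) stop_os("collinear predictors (X'V^-1X singular)", "collinearity")
  beta <- qr.coef(qr_x, yw)
  resid_w <- yw - Xw %*% beta
  rss <- sum(resid_w^2)
  df2 <- n - p - 1L
  sigma2 <- rss / df2
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df2, lower.tail = FALSE)
  # null model: GLS intercept-only
  X0 <- Xw[, 1, drop = FALSE]
  b0 <- sum(X0 * yw) / sum(X0^2)
  rss0 <- sum((yw - X0 * b0)^2)
  r2 <- 1 - rss / rss0
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df2
  Fstat <- if (p > 0) (r2 / p) / ((1 - r2) / df2) else NA_real_
  model_p <- if (p > 0) pf(Fstat, p, df2, lower.tail = FALSE) else NA_real_
  sigma2_ml <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  structure(list(
    coefficients = tibble(term = colnames(Xi), estimate = as.vector(beta),
                          std_error = se, statistic = as.vector(tval),
                          p_value = as.vector(pval)),
    lambda_mode = lambda_mode, lambda_hat = lambda_hat,
    r_squared = r2, adjusted_r_squared = adj_r2,
    f_statistic = Fstat, df1 = p, df2 = df2, model_p = model_p,
    n_used = n, sigma2 = sigma2, log_likelihood = ll
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("<pgls_fit> lambda_mode ", x$lambda_mode, " (lambda_hat ",
      signif(x$lambda_hat, 4), "), n ", x$n_used, ", adj R2 ",
      signif(x$adjusted_r_squared, 4), ", F(", x$df1, ",", x$df2, ") ",
      signif(x$f_statistic, 5), ", p ", signif(x$model_p, 4), "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @describeIn gls_fit tidy(): per-term coefficient table.
#' @param x a `pgls_fit`.
#' @param ... ignored.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' @describeIn gls_fit glance(): one-row model summary.
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(lambda_mode = x$lambda_mode, lambda_hat = x$lambda_hat,
         r_squared = x$r_squared, adj_r_squared = x$adjusted_r_squared,
         f_statistic = x$f_statistic, df1 = x$df1, df2 = x$df2,
         p_value = x$model_p, n_used = x$n_used,
         log_likelihood = x$log_likelihood)
}

#' PGLS with maximum-likelihood Pagel's lambda
#'
#' Profiles the ML log-likelihood
#' `l(lambda) = -1/2 [n ln(2 pi sigma2(lambda)) + ln|V(lambda)| + n]`
#' over `lambda` in `[0, 1]` by bounded scalar optimisation (tolerance
#' 1e-6) with explicit endpoint checks at 0 and 1 (boundary estimates are
#' admissible), and returns the GLS fit at the maximiser.
#'
#' @param y,X as in [gls_fit()].
#' @param C the `lambda = 1` phylogenetic covariance from [phylo_vcv()].
#' @return A `pgls_fit` with `lambda_hat` set and `lambda_mode = "ML"`.
#' @export
profile_lambda_ml <- function(y, X, C) {
  ll <- function(lam) gls_fit(y, X, lambda_transform(C, lam))$log_likelihood
  opt <- optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(0, opt$maximum, 1)
  vals <- c(ll(0), opt$objective, ll(1))
  lam_hat <- cand[which.max(vals)]
  gls_fit(y, X, lambda_transform(C, lam_hat),
          lambda_mode = "ML", lambda_hat = lam_hat)
}

#' Fit the full regression suite of complexity on selection proxies
#'
#' For every response (alpha PC1/PC2, ariaDNE PC1/PC2), proxy set
#' (ln intromission duration; ln SSD; ln male mass + ln testes mass) and
#' lambda mode (0 = phylogenetically uncorrected, ML, 1 = Brownian), the
#' complete-case species subset is taken, the tree pruned, and a GLS fit
#' emitted. Life-history predictors are natural-log transformed. Models
#' with fewer than 3 complete cases are skipped with a message.
#'
#' @param pca_alpha,pca_ariadne `shape_pca` objects (or their `$scores`
#'   tibbles with a `species` column).
#' @param life life-history tibble: `species`, `male_mass`, `female_mass`,
#'   `testes_mass`, `intromission_duration` (NAs allowed).
#' @param tree a rooted `phylo` covering the species.
#' @param lambda_modes subset of `c("0", "ML", "1")`.
#' @return A tibble with one row per model (response x proxy x lambda mode):
#'   `proxy`, `response`, `lambda_mode`, `model_p`, `adjusted_r2`,
#'   `f_statistic`, `df1`, `df2`, `lambda_hat`, `n_used`, and a nested
#'   list-column `coefficients` (term, estimate, std_error, statistic,
#'   p_value per predictor). `tidyr::unnest(suite, coefficients)` yields the
#'   term-level long form.
#' @export
model_suite <- function(pca_alpha, pca_ariadne, life, tree,
                        lambda_modes = c("0", "ML", "1")) {
  scores_of <- function(p) if (inherits(p, "shape_pca")) p$scores else as_tibble(p)
  responses <- list(
    alphaPC1 = scores_of(pca_alpha)[c("species", "PC1")],
    alphaPC2 = scores_of(pca_alpha)[c("species", "PC2")],
    ariaPC1 = scores_of(pca_ariadne)[c("species", "PC1")],
    ariaPC2 = scores_of(pca_ariadne)[c("species", "PC2")]
  )
  life <- as_tibble(life)
  predictors <- list(
    intromission = function(d) {
      stats::na.omit(data.frame(species = d$species,
                                ln_intromission = log(d$intromission_duration)))
    },
    ssd = function(d) {
      stats::na.omit(data.frame(species = d$species,
                                ln_ssd = log(ssd(d$male_mass, d$female_mass))))
    },
    testes = function(d) {
      stats::na.omit(data.frame(species = d$species,
                                ln_male_mass = log(d$male_mass),
                                ln_testes_mass = log(d$testes_mass)))
    }
  )
  rows <- list()
  for (resp_name in names(responses)) {
    resp <- responses[[resp_name]]
    names(resp)[2] <- "y"
    for (proxy in names(predictors)) {
      pred <- predictors[[proxy]](life)
      dat <- dplyr::inner_join(resp, pred, by = "species")
      dat <- dat[dat$species %in% tree$tip.label, , drop = FALSE]
      p_terms <- setdiff(names(dat), c("species", "y"))
      if (nrow(dat) < max(3, length(p_terms) + 2)) {
        inform(sprintf("skipping %s ~ %s: only %d complete cases",
                       resp_name, proxy, nrow(dat)))
        next
      }
      V1 <- phylo_vcv(tree, dat$species)
      X <- as.matrix(dat[p_terms])
      for (mode in lambda_modes) {
        fit <- switch(mode,
          "0" = gls_fit(dat$y, X, lambda_transform(V1, 0),
                        lambda_mode = "0", lambda_hat = 0),
          "1" = gls_fit(dat$y, X, V1, lambda_mode = "1", lambda_hat = 1),
          "ML" = profile_lambda_ml(dat$y, X, V1),
          stop_os(paste0("unknown lambda mode: ", mode), "parameter")
        )
        co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
        rows[[length(rows) + 1]] <- tibble(
          proxy = proxy, response = resp_name, lambda_mode = mode,
          model_p = fit$model_p, adjusted_r2 = fit$adjusted_r_squared,
          f_statistic = fit$f_statistic, df1 = fit$df1, df2 = fit$df2,
          lambda_hat = fit$lambda_hat, n_used = fit$n_used,
          coefficients = list(co)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
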