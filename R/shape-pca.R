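#' Assemble a species-by-parameter complexity matrix
#'
#' Pivots a long profile table (one row per species and coefficient or
#' bandwidth) into the wide matrix consumed by [pca_correlation()].
#'
#' @param profiles tibble with columns `species`, a parameter column, and a
#'   score column; typically row-bound [complexity_profile()] or
#'   [ariadne_profile()] outputs.
#' @param metric `"alpha"` or `"ariadne"`; selects the default parameter and
#'   score columns (`coefficient`/`score_volume` and `bandwidth`/`score`).
#' @param parameter,score column names overriding the metric defaults.
#' @return A `complexity_matrix`: tibble with `species` plus one column per
#'   parameter value; attribute `metric_name`.
#' @export
complexity_matrix <- function(profiles, metric = c("alpha", "ariadne"),
                              parameter = NULL, score = NULL) {
  metric <- match.arg(metric)
  parameter <- parameter %||% switch(metric, alpha = "coefficient", ariadne = "bandwidth")
  score <- score %||% switch(metric, alpha = "score_volume", ariadne = "score")
  wide <- tidyr::pivot_wider(
    dplyr::select(as_tibble(profiles), "species",
                  dplyr::all_of(c(parameter, score))),
    names_from = dplyr::all_of(parameter), values_from = dplyr::all_of(score)
  )
  if (anyNA(wide)) stop_os("complexity matrix has missing cells", "parameter")
  if (nrow(wide) < 3) stop_os("need at least 3 species", "parameter")
  structure(wide, metric_name = metric,
            class = c("complexity_matrix", class(wide)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation-matrix PCA of complexity scores
#'
#' Columns are standardised to zero mean and unit variance (n - 1
#' denominator) and the eigendecomposition of the resulting correlation
#' matrix taken; components are sorted by descending eigenvalue. Sign
#' convention: each component is oriented so that its largest-magnitude
#' loading is positive, making downstream regression slopes interpretable.
#'
#' @param cm a [complexity_matrix()], or any tibble/data.frame whose first
#'   column is `species` and remaining columns are numeric scores.
#' @return A `shape_pca`: list with `scores` (tibble, species + PC columns),
#'   `loadings` (matrix, parameters x PCs), `variance_fractions`,
#'   `metric_name`, `sdev`, `center`, `scale`.
#' @export
pca_correlation <- function(cm) {
  metric <- attr(cm, "metric_name") %||% "complexity"
  df <- as.data.frame(cm)
  species <- df$species
  X <- as.matrix(df[setdiff(names(df), "species")])
  storage.mode(X) <- "double"
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stop_os(paste0("zero-variance column(s): ",
                   paste(colnames(X)[sds == 0], collapse = ", ")),
            "degenerate_column")
  }
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  # orient each component so its largest-|loading| is positive
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    lj <- p$rotation[, j]
    sign(lj[which.max(abs(lj))])
  }, numeric(1))
  p$rotation <- sweep(p$rotation, 2, flip, `*`)
  p$x <- sweep(p$x, 2, flip, `*`)
  vf <- p$sdev^2 / sum(p$sdev^2)
  scores <- as_tibble(as.data.frame(p$x))
  names(scores) <- paste0("PC", seq_along(scores))
  scores <- dplyr::bind_cols(tibble(species = species), scores)
  structure(list(scores = scores, loadings = p$rotation,
                 variance_fractions = vf, metric_name = metric,
                 sdev = p$sdev, center = p$center, scale = p$scale),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("<shape_pca> metric '", x$metric_name, "', ", nrow(x$scores),
      " species, PC1 ", sprintf("%.1f%%", 100 * x$variance_fractions[1]),
      ", PC2 ", sprintf("%.1f%%", 100 * x$variance_fractions[2]), "\n", sep = "")
  invisible(x)
}

#' Cumulative variance captured by leading components
#'
#' @param r a `shape_pca`.
#' @param n_components how many leading components to sum (1 to the number
#'   of columns).
#' @return percentage of total variance, in percent (0-100).
#' @export
summarise_variance <- function(r, n_components) {
  k <- length(r$variance_fractions)
  if (n_components < 1 || n_components > k) {
    stop_os(sprintf("n_components must be in 1..%d", k), "parameter")
  }
  100 * sum(r$variance_fractions[seq_len(n_components)])
}

#' @describeIn pca_correlation tidy(): loadings in long form with the
#'   variance fraction of each component.
#' @param x a `shape_pca`.
#' @param ... ignored.
#' @method tidy shape_pca
#' @export
tidy.shape_pca <- function(x, ...) {
  L <- x$loadings
  tibble(
    parameter = rep(rownames(L), times = ncol(L)),
    component = rep(colnames(L), each = nrow(L)),
    loading = as.vector(L),
    variance_fraction = rep(x$variance_fractions, each = nrow(L))
  )
}

#' @describeIn pca_correlation glance(): one row with the leading variance
#'   fractions and the two-component total (in percent).
#' @method glance shape_pca
#' @export
glance.shape_pca <- function(x, ...) {
  tibble(
    metric = x$metric_name,
    n_species = nrow(x$scores),
    pc1_pct = 100 * x$variance_fractions[1],
    pc2_pct = 100 * x$variance_fractions[2],
    two_pc_total_pct = summarise_variance(x, 2)
  )
}

#' @describeIn pca_correlation autoplot(): PC1-PC2 score scatter.
#' @param object a `shape_pca`.
#' @method autoplot shape_pca
#' @export
autoplot.shape_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_fractions[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_fractions[2]),
      title = paste0(object$metric_name, " complexity PCA")
    ) +
    ggplot2::theme_minimal()
}
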