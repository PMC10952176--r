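#' The nine-character ordinal scoring schema
#'
#' Two head characters (H1 pronounced head 0/1/2, H2 opening on head 0/1),
#' two shaft characters (S1 mid-shaft cross-section 0 = triangular with
#' pronounced dorsal crest .. 2 = rounded, S2 urethral groove 0 = absent,
#' 1 = short/distal, 2 = long) and five distal-tip characters (T1 abrupt
#' upward bend 0/1/2, T2 hook 0/1, T3 ventral subdivision 0/1, T4 asymmetry
#' 0/1, T5 additional projections 0/1).
#'
#' @return A tibble with columns `character`, `region`, `levels`
#'   (list-column of allowed integer levels).
#' @export
character_schema <- function() {
  tibble(
    character = c("H1", "H2", "S1", "S2", "T1", "T2", "T3", "T4", "T5"),
    region = c("head", "head", "shaft", "shaft", rep("tip", 5)),
    levels = list(0:2, 0:1, 0:2, 0:2, 0:2, 0:1, 0:1, 0:1, 0:1)
  )
}

#' Validate an ordinal character-score table
#'
#' Checks that all nine character columns are present and that every value
#' lies within its character's allowed levels; violations are reported with
#' species and character.
#'
#' @param raw data frame with `species` plus the nine character columns.
#' @param schema a [character_schema()] tibble.
#' @return The validated tibble (integer character columns).
#' @export
validate_scores <- function(raw, schema = character_schema()) {
  raw <- as_tibble(raw)
  missing <- setdiff(c("species", schema$character), names(raw))
  if (length(missing) > 0) {
    stop_os(paste0("missing required columns: ", paste(missing, collapse = ", ")),
            "schema")
  }
  if (anyDuplicated(raw$species)) stop_os("duplicate species", "validation")
  for (i in seq_len(nrow(schema))) {
    ch <- schema$character[i]
    vals <- raw[[ch]]
    bad <- !is.na(vals) & !(vals %in% schema$levels[[i]])
    if (any(bad)) {
      stop_os(sprintf("invalid level for %s in species %s: %s",
                      ch, raw$species[which(bad)[1]], vals[which(bad)[1]]),
              "validation")
    }
    raw[[ch]] <- as.integer(vals)
  }
  raw
}

#' Tie-corrected Kruskal-Wallis test
#'
#' Wraps the standard rank-based test (mid-ranks for ties, chi-square
#' reference with groups - 1 degrees of freedom). The degenerate case in
#' which every observation is identical — where the tie correction divides
#' by zero — is defined explicitly as H = 0, p = 1.
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor; empty levels dropped).
#' @return A tibble: `H`, `df`, `p_value`, `n`, `group_sizes` (list-column).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups[!is.na(values)])
  values <- values[!is.na(values)]
  if (nlevels(groups) < 2) stop_os("need at least 2 non-empty groups", "parameter")
  if (length(values) < 3) stop_os("need at least 3 observations", "parameter")
  sizes <- as.integer(table(groups))
  if (length(unique(values)) == 1) {
    return(tibble(H = 0, df = nlevels(groups) - 1L, p_value = 1,
                  n = length(values), group_sizes = list(sizes)))
  }
  kt <- stats::kruskal.test(values, groups)
  tibble(H = unname(kt$statistic), df = as.integer(unname(kt$parameter)),
         p_value = kt$p.value, n = length(values), group_sizes = list(sizes))
}

#' Pairwise Wilcoxon rank-sum tests across group levels
#'
#' One rank-sum test per pair of levels: the exact distribution is
#' enumerated when both groups have at most 8 observations and no ties are
#' present, otherwise the normal approximation with continuity correction
#' and tie-adjusted variance is used. P-values are adjusted across pairs by
#' Holm step-down (default); `adjust_method = "none"` reproduces raw
#' values. Pairs involving an empty group are skipped with a message.
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param adjust_method a [stats::p.adjust] method name.
#' @return A tibble: `group1`, `group2`, `p_value` (adjusted), `p_raw`,
#'   `adjust_method`.
#' @export
pairwise_wilcoxon <- function(values, groups, adjust_method = "holm") {
  groups <- factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  lv <- levels(groups)
  if (length(lv) < 2) stop_os("need at least 2 groups", "parameter")
  pairs <- utils::combn(lv, 2)
  raw <- apply(pairs, 2, function(pr) {
    a <- values[groups == pr[1]]
    b <- values[groups == pr[2]]
    if (length(a) == 0 || length(b) == 0) {
      inform(sprintf("skipping pair %s-%s: empty group", pr[1], pr[2]))
      return(NA_real_)
    }
    exact <- length(a) <= 8 && length(b) <= 8 &&
      !any(duplicated(c(a, b)))
    suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
    )
  })
  adj <- stats::p.adjust(raw, method = adjust_method)
  tibble(group1 = pairs[1, ], group2 = pairs[2, ],
         p_value = adj, p_raw = raw, adjust_method = adjust_method)
}

#' Character-state association tests for complexity PC scores
#'
#' For each response column and each of the nine ordinal characters, the PC
#' score is tested across character levels with a Kruskal-Wallis test;
#' where that is significant at `alpha`, pairwise Wilcoxon comparisons are
#' attached. No correction is applied across the nine per-character tests
#' (noted in the output). Characters with a single observed level are
#' skipped with a message.
#'
#' @param pc_scores tibble with `species` and one or more response columns
#'   (e.g. the `$scores` of a [pca_correlation()] restricted to PC1).
#' @param scores validated character-score tibble ([validate_scores()]).
#' @param responses names of response columns in `pc_scores` to test.
#' @param alpha significance threshold gating the pairwise follow-up.
#' @param adjust_method multiplicity adjustment for the pairwise tests.
#' @return A tibble with one row per response x character: KW columns plus
#'   a `pairwise` list-column (NULL where not run); attribute
#'   `multiple_testing = "none across characters"`.
#' @export
character_suite <- function(pc_scores, scores, responses = "PC1",
                            alpha = 0.05, adjust_method = "holm") {
  pc_scores <- as_tibble(pc_scores)
  scores <- validate_scores(scores)
  dat <- dplyr::inner_join(pc_scores, scores, by = "species")
  if (nrow(dat) < 3) stop_os("fewer than 3 species shared between inputs", "parameter")
  chars <- character_schema()$character
  rows <- list()
  for (resp in responses) {
    for (ch in chars) {
      lvls <- dat[[ch]][!is.na(dat[[ch]])]
      if (length(unique(lvls)) < 2) {
        inform(sprintf("skipping %s for %s: single observed level", ch, resp))
        next
      }
      kw <- kruskal_wallis(dat[[resp]], dat[[ch]])
      pw <- if (kw$p_value < alpha) {
        list(pairwise_wilcoxon(dat[[resp]], dat[[ch]], adjust_method))
      } else {
        list(NULL)
      }
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(response = resp, character = ch), kw, tibble(pairwise = pw)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "multiple_testing") <- "none across characters"
  out
}

#' Interobserver percent agreement
#'
#' Per-character percentage of species on which two observers assigned the
#' same level.
#'
#' @param scores_a,scores_b validated character tables over the same
#'   species set.
#' @return A tibble: `character`, `percent_agreement`.
#' @export
percent_agreement <- function(scores_a, scores_b) {
  scores_a <- validate_scores(scores_a)
  scores_b <- validate_scores(scores_b)
  if (!setequal(scores_a$species, scores_b$species)) {
    stop_os("observer tables cover different species sets", "alignment")
  }
  scores_b <- scores_b[match(scores_a$species, scores_b$species), ]
  chars <- character_schema()$character
  tibble(
    character = chars,
    percent_agreement = vapply(chars, function(ch) {
      100 * mean(scores_a[[ch]] == scores_b[[ch]])
    }, numeric(1), USE.NAMES = FALSE)
  )
}
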