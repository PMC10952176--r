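test_that("score validation enforces the nine-character schema", {
  tab <- random_character_table(20, 11)
  out <- validate_scores(tab)
  expect_equal(nrow(out), 20)
  expect_true(all(vapply(out[character_schema()$character], is.integer, logical(1))))

  tab$T2[1] <- 1L
  expect_silent(validate_scores(tab))

  bad <- tab
  bad$H1[3] <- 3L
  err <- tryCatch(validate_scores(bad), error = identity)
  expect_s3_class(err, "osteoshape_error_validation")
  expect_match(conditionMessage(err), "H1")
  expect_match(conditionMessage(err), bad$species[3])

  expect_error(validate_scores(tab[-2]), class = "osteoshape_error_schema")
})

test_that("Kruskal-Wallis H matches the rank formula, including ties and degeneracy", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  expect_equal(kw$df, 1L)

  kw0 <- kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p_value, 1)

  set.seed(13)
  for (i in 1:5) {
    vals <- sample(1:6, 30, replace = TRUE)  # heavy ties
    grp <- sample(c("a", "b", "c"), 30, replace = TRUE)
    kw_i <- kruskal_wallis(vals, grp)
    expect_equal(kw_i$H, kw_oracle(vals, grp), tolerance = 1e-10)
    expect_equal(kw_i$p_value, pchisq(kw_i$H, kw_i$df, lower.tail = FALSE),
                 tolerance = 1e-12)
  }

  # rank-based: invariant to strictly monotone transforms
  set.seed(14)
  v <- rnorm(24)
  g <- rep(c("a", "b", "c"), 8)
  expect_equal(kruskal_wallis(exp(v), g)$H, kruskal_wallis(v, g)$H,
               tolerance = 1e-12)

  # with 2 tie-free groups, H equals the squared normal Wilcoxon statistic
  set.seed(15)
  v2 <- rnorm(14)
  g2 <- rep(c("a", "b"), c(6, 8))
  W <- sum(rank(v2)[g2 == "a"]) - 6 * 7 / 2
  z <- (W - 6 * 8 / 2) / sqrt(6 * 8 * 15 / 12)
  expect_equal(kruskal_wallis(v2, g2)$H, z^2, tolerance = 1e-9)
})

test_that("pairwise Wilcoxon uses exact enumeration when possible and Holm adjustment", {
  pw <- pairwise_wilcoxon(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(pw$p_raw, 0.1, tolerance = 1e-9)  # 2 * 1/choose(6,3)

  same <- pairwise_wilcoxon(rep(c(1, 2), 6), rep(c("a", "b"), each = 6))
  expect_equal(same$p_value, 1)

  set.seed(16)
  vals <- rnorm(30)
  grp <- rep(c("a", "b", "c"), 10)
  pw3 <- pairwise_wilcoxon(vals, grp)
  expect_true(all(pw3$p_value >= pw3$p_raw))
  expect_equal(pw3$p_value, stats::p.adjust(pw3$p_raw, "holm"), tolerance = 1e-12)
  raw <- pairwise_wilcoxon(vals, grp, adjust_method = "none")
  expect_equal(raw$p_value, raw$p_raw)
})

test_that("the character suite tests each character and follows up significant ones", {
  # planted effect: hook state shifts the PC score strongly
  tab <- random_character_table(40, 3)
  set.seed(3)
  pc <- tibble::tibble(species = tab$species,
                       PC1 = rnorm(40) + 3 * (tab$T2 == 1))
  suite <- suppressMessages(character_suite(pc, tab, responses = "PC1"))
  expect_lte(nrow(suite), 9)
  t2 <- suite[suite$character == "T2", ]
  expect_lt(t2$p_value, 0.05)
  expect_false(is.null(t2$pairwise[[1]]))

  # shuffled response: near-nominal false positive rate
  set.seed(5)
  n_sig <- 0L
  n_tot <- 0L
  for (r in 1:100) {
    perm <- sample(pc$PC1)
    for (ch in c("T1", "T2", "S1")) {
      if (length(unique(tab[[ch]])) < 2) next
      n_tot <- n_tot + 1L
      if (kruskal_wallis(perm, tab[[ch]])$p_value < 0.05) n_sig <- n_sig + 1L
    }
  }
  expect_lte(n_sig / n_tot, 0.10)

  # 9 characters x 1 response when every character varies
  tab9 <- random_character_table(60, 9)
  set.seed(9)
  pc9 <- tibble::tibble(species = tab9$species, PC1 = rnorm(60))
  suite9 <- suppressMessages(character_suite(pc9, tab9, responses = "PC1"))
  expect_equal(nrow(suite9), 9)
})

test_that("percent agreement counts per-character matches", {
  a <- random_character_table(32, 21)
  expect_true(all(percent_agreement(a, a)$percent_agreement == 100))

  b <- a
  b$T1[5] <- (b$T1[5] + 1L) %% 3L
  pa <- percent_agreement(a, b)
  expect_equal(pa$percent_agreement[pa$character == "T1"], 96.875)
  expect_true(all(pa$percent_agreement[pa$character != "T1"] == 100))

  expect_error(percent_agreement(a, b[-1, ]), class = "osteoshape_error_alignment")

  # independent uniform scorings of 3-level characters agree about a third
  # of the time
  agree <- replicate(300, {
    x <- random_character_table(32, sample.int(1e6, 1))
    y <- random_character_table(32, sample.int(1e6, 1))
    pa <- percent_agreement(x, y)
    mean(pa$percent_agreement[pa$character %in% c("H1", "S1", "S2", "T1")])
  })
  expect_equal(mean(agree), 100 / 3, tolerance = 2)
})
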