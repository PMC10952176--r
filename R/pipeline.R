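#' Assemble and validate a study configuration
#'
#' A configuration names the input files (specimen manifest, life-history
#' CSV, Newick tree, character CSV) and the analysis parameters. It can be
#' given as a YAML file or a named list. All referenced paths are checked
#' up front so a bad manifest fails before any geometry is processed.
#'
#' @param config path to a YAML file or a named list with fields
#'   `manifest`, `life`, `tree`, `characters`, and optionally
#'   `coefficients`, `bandwidths`, `points_target`, `faces_target`, `seed`,
#'   `lambda_modes`, `outdir`.
#' @return A validated `study_config` list with defaults filled in.
#' @export
study_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    coefficients = c(1, 2, 4, 8, 16, 32),
    bandwidths = c(0.02, 0.04, 0.06, 0.08, 0.10, 0.12),
    points_target = 100000, faces_target = 30000,
    seed = 20230301, lambda_modes = c("0", "ML", "1"), outdir = "results"
  )
  cfg <- utils::modifyList(defaults, config)
  for (field in c("manifest", "life", "tree", "characters")) {
    if (is.null(cfg[[field]])) stop_os(paste0("config lacks ", field), "parameter")
    if (!file.exists(cfg[[field]])) {
      stop_os(paste0("config path does not exist: ", cfg[[field]]), "io")
    }
  }
  if (length(cfg$coefficients) < 2 || length(cfg$bandwidths) < 2) {
    stop_os("need at least 2 coefficients and 2 bandwidths", "parameter")
  }
  manifest <- read_table(cfg$manifest, "specimen_manifest")
  base <- dirname(cfg$manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  manifest$geometry_path <- resolve(manifest$geometry_path)
  if ("cloud_path" %in% names(manifest)) {
    manifest$cloud_path <- resolve(manifest$cloud_path)
  }
  bad <- !file.exists(manifest$geometry_path)
  if (any(bad)) {
    stop_os(paste0("missing geometry for specimen(s): ",
                   paste(manifest$species[bad], collapse = ", ")), "io")
  }
  cfg$manifest_table <- manifest
  class(cfg) <- "study_config"
  cfg
}

.stage_cache <- function(outdir) file.path(outdir, "stage_hashes.json")

.cache_hit <- function(outdir, stage, hash, files) {
  path <- .stage_cache(outdir)
  if (!file.exists(path)) return(FALSE)
  hashes <- jsonlite::read_json(path)
  identical(hashes[[stage]], hash) && all(file.exists(file.path(outdir, files)))
}

.cache_store <- function(outdir, stage, hash) {
  path <- .stage_cache(outdir)
  hashes <- if (file.exists(path)) jsonlite::read_json(path) else list()
  hashes[[stage]] <- hash
  jsonlite::write_json(hashes, path, auto_unbox = TRUE)
}

.log_line <- function(con, level, msg) {
  writeLines(sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                     level, msg), con)
}

#' Run the full complexity study from one configuration
#'
#' Orchestrates geometry ingestion, both complexity metrics, the two PCAs,
#' the regression suite and the character tests, writing
#' `alpha_scores.csv`, `ariadne_scores.csv`, `alpha_pca.csv`,
#' `ariadne_pca.csv`, `variance.csv`, `table2.csv`, `kw_results.csv`,
#' `pairwise_wilcoxon.csv`, `run_log.txt` and `run_manifest.json` under the
#' configured output directory. Stages are cached on a hash of their inputs:
#' rerunning an unchanged configuration reuses the written CSVs.
#'
#' @param config a [study_config()] (or anything it accepts).
#' @return Invisibly, a list of the result tibbles.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "study_config")) config else study_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(cfg$outdir, "run_log.txt"), "a")
  on.exit(close(log_con))
  manifest <- cfg$manifest_table

  geom_hash <- rlang::hash(list(manifest, cfg$coefficients, cfg$bandwidths,
                                cfg$points_target, cfg$faces_target, cfg$seed,
                                lapply(manifest$geometry_path, function(p) {
                                  file.info(p)$size
                                })))

  load_cloud <- function(row) {
    if ("cloud_path" %in% names(manifest) && !is.na(row$cloud_path)) {
      return(read_pointcloud(row$cloud_path))
    }
    switch(row$geometry_kind,
      volume = volume_to_pointcloud(read_raw_volume(row$geometry_path)),
      mesh = point_cloud(read_mesh(row$geometry_path)$vertices),
      cloud = read_pointcloud(row$geometry_path),
      stop_os(paste0("unknown geometry_kind for ", row$species), "parameter")
    )
  }

  if (.cache_hit(cfg$outdir, "alpha", geom_hash, "alpha_scores.csv")) {
    .log_line(log_con, "INFO", "alpha stage cached; reusing alpha_scores.csv")
    alpha_scores <- as_tibble(read.csv(file.path(cfg$outdir, "alpha_scores.csv")))
  } else {
    .log_line(log_con, "INFO", "stage alpha: start")
    alpha_scores <- dplyr::bind_rows(lapply(seq_len(nrow(manifest)), function(i) {
      row <- manifest[i, ]
      tryCatch({
        pc <- load_cloud(row) |>
          decimate_pointcloud(cfg$points_target, seed = cfg$seed) |>
          normalize_size()
        complexity_profile(pc, cfg$coefficients, species_id = row$species)
      }, error = function(e) {
        stop_os(sprintf("stage alpha, specimen %s: %s", row$species,
                        conditionMessage(e)), "stage")
      })
    }))
    write.csv(alpha_scores, file.path(cfg$outdir, "alpha_scores.csv"),
              row.names = FALSE)
    .cache_store(cfg$outdir, "alpha", geom_hash)
    .log_line(log_con, "INFO", "stage alpha: done")
  }

  if (.cache_hit(cfg$outdir, "ariadne", geom_hash, "ariadne_scores.csv")) {
    .log_line(log_con, "INFO", "ariadne stage cached; reusing ariadne_scores.csv")
    ariadne_scores <- as_tibble(read.csv(file.path(cfg$outdir, "ariadne_scores.csv")))
  } else {
    .log_line(log_con, "INFO", "stage ariadne: start")
    ariadne_scores <- dplyr::bind_rows(lapply(seq_len(nrow(manifest)), function(i) {
      row <- manifest[i, ]
      tryCatch({
        m <- read_mesh(row$geometry_path) |>
          decimate_mesh(cfg$faces_target) |>
          prepare_mesh()
        ariadne_profile(m, cfg$bandwidths, species_id = row$species)
      }, error = function(e) {
        stop_os(sprintf("stage ariadne, specimen %s: %s", row$species,
                        conditionMessage(e)), "stage")
      })
    }))
    write.csv(ariadne_scores, file.path(cfg$outdir, "ariadne_scores.csv"),
              row.names = FALSE)
    .cache_store(cfg$outdir, "ariadne", geom_hash)
    .log_line(log_con, "INFO", "stage ariadne: done")
  }

  .log_line(log_con, "INFO", "stage pca: start")
  pca_alpha <- pca_correlation(complexity_matrix(alpha_scores, "alpha"))
  pca_aria <- pca_correlation(complexity_matrix(ariadne_scores, "ariadne"))
  write.csv(pca_alpha$scores, file.path(cfg$outdir, "alpha_pca.csv"),
            row.names = FALSE)
  write.csv(pca_aria$scores, file.path(cfg$outdir, "ariadne_pca.csv"),
            row.names = FALSE)
  variance <- dplyr::bind_rows(glance(pca_alpha), glance(pca_aria))
  write.csv(variance, file.path(cfg$outdir, "variance.csv"), row.names = FALSE)

  .log_line(log_con, "INFO", "stage regress: start")
  life <- read_table(cfg$life, "life_history")
  tree <- ape::read.tree(cfg$tree)
  suite <- withCallingHandlers(
    model_suite(pca_alpha, pca_aria, life, tree, cfg$lambda_modes),
    message = function(m) {
      .log_line(log_con, "WARNING", conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  table2 <- tidyr::unnest(suite, "coefficients")
  write.csv(table2, file.path(cfg$outdir, "table2.csv"), row.names = FALSE)

  .log_line(log_con, "INFO", "stage characters: start")
  chars <- read_table(cfg$characters, "character_scores")
  implicated <- unique(suite$response[!is.na(suite$model_p) & suite$model_p < 0.05])
  if (length(implicated) == 0) implicated <- c("alphaPC1", "ariaPC1")
  pc_tabs <- list(
    alphaPC1 = dplyr::rename(pca_alpha$scores[c("species", "PC1")], alphaPC1 = "PC1"),
    alphaPC2 = dplyr::rename(pca_alpha$scores[c("species", "PC2")], alphaPC2 = "PC2"),
    ariaPC1 = dplyr::rename(pca_aria$scores[c("species", "PC1")], ariaPC1 = "PC1"),
    ariaPC2 = dplyr::rename(pca_aria$scores[c("species", "PC2")], ariaPC2 = "PC2")
  )
  pc_all <- Reduce(function(a, b) dplyr::inner_join(a, b, by = "species"), pc_tabs)
  kw <- withCallingHandlers(
    character_suite(pc_all, chars, responses = intersect(implicated, names(pc_all))),
    message = function(m) {
      .log_line(log_con, "WARNING", conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  kw_flat <- dplyr::select(kw, -"pairwise", -"group_sizes")
  write.csv(kw_flat, file.path(cfg$outdir, "kw_results.csv"), row.names = FALSE)
  pw <- dplyr::bind_rows(lapply(seq_len(nrow(kw)), function(i) {
    if (is.null(kw$pairwise[[i]])) return(NULL)
    dplyr::bind_cols(tibble(response = kw$response[i], character = kw$character[i]),
                     kw$pairwise[[i]])
  }))
  write.csv(if (nrow(pw) == 0) {
    data.frame(response = character(), character = character(),
               group1 = character(), group2 = character(),
               p_value = numeric(), p_raw = numeric(),
               adjust_method = character())
  } else pw,
  file.path(cfg$outdir, "pairwise_wilcoxon.csv"), row.names = FALSE)

  run_manifest <- list(
    package_version = as.character(utils::packageVersion("osteoshape")),
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "manifest_table")]),
    seed = cfg$seed,
    coefficients = cfg$coefficients,
    bandwidths = cfg$bandwidths,
    points_target = cfg$points_target,
    faces_target = cfg$faces_target,
    lambda_modes = cfg$lambda_modes,
    n_specimens = nrow(manifest)
  )
  jsonlite::write_json(run_manifest, file.path(cfg$outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_line(log_con, "INFO", "pipeline complete")
  invisible(list(alpha_scores = alpha_scores, ariadne_scores = ariadne_scores,
                 pca_alpha = pca_alpha, pca_ariadne = pca_aria,
                 variance = variance, table2 = table2, kw = kw))
}
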