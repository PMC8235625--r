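#' Pipeline configuration
#'
#' All analysis settings in one validated list. Defaults are the study
#' settings: three sliding iterations, principal components retained up to
#' 95% of total variance, 10,000 permutations for signal/permutation tests,
#' 1000 Brownian simulations for the phylogenetic ANOVA, clade sizes between
#' 2 tips and half the tree for the rate-shift search.
#'
#' @param landmarks,tree,traits,meshes_dir,out_dir input paths (`landmarks`,
#'   `tree`, `traits` may be omitted when `dataset` is given).
#' @param dataset optionally an in-memory `synthetic_dataset` instead of
#'   paths.
#' @param stages named logical vector toggling stages: `slide`, `size`,
#'   `signal`, `mancova`, `bgpca`, `phylomorphospace`, `rates`, `asr`,
#'   `simmap`.
#' @param slide_iterations,pc_threshold,n_perm,n_sim,n_rand analysis
#'   parameters (defaults are the study settings).
#' @param simmap_nsim stochastic maps to draw when the `simmap` stage is on.
#' @param paired_log_cs optional named vector of a second bone's species log
#'   centroid sizes; when given, a per-species size-ratio table
#'   (log CS / paired log CS) is emitted.
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(landmarks = NULL, tree = NULL, traits = NULL,
                            meshes_dir = NULL, out_dir = tempfile("mrate_"),
                            dataset = NULL,
                            stages = NULL,
                            slide_iterations = 3L, pc_threshold = 0.95,
                            n_perm = 10000L, n_sim = 1000L, n_rand = 1000L,
                            simmap_nsim = 1000L,
                            paired_log_cs = NULL, seed = 1L) {
  default_stages <- c(slide = TRUE, size = TRUE, signal = TRUE,
                      mancova = TRUE, bgpca = TRUE,
                      phylomorphospace = TRUE, rates = TRUE, asr = TRUE,
                      simmap = FALSE)
  if (!is.null(stages)) default_stages[names(stages)] <- stages
  if (is.null(dataset) && (is.null(landmarks) || is.null(tree) ||
                           is.null(traits)))
    stop("either a `dataset` or landmark/tree/trait paths are required",
         call. = FALSE)
  structure(list(landmarks = landmarks, tree = tree, traits = traits,
                 meshes_dir = meshes_dir, out_dir = out_dir,
                 dataset = dataset, stages = default_stages,
                 slide_iterations = as.integer(slide_iterations),
                 pc_threshold = pc_threshold, n_perm = as.integer(n_perm),
                 n_sim = as.integer(n_sim), n_rand = as.integer(n_rand),
                 simmap_nsim = as.integer(simmap_nsim),
                 paired_log_cs = paired_log_cs, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [pipeline_config] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$stages)) args$stages <- unlist(args$stages)
  do.call(pipeline_config, args)
}

config_header <- function(config) {
  c(paste0("# morphorate ",
           as.character(utils::packageVersion("morphorate"))),
    paste0("# seed: ", config$seed),
    paste0("# slide_iterations: ", config$slide_iterations),
    paste0("# pc_threshold: ", config$pc_threshold),
    paste0("# n_perm: ", config$n_perm, "; n_sim: ", config$n_sim,
           "; n_rand: ", config$n_rand))
}

write_report_csv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

stage_seed <- function(config, offset) (config$seed + offset) %% 2147483647L

#' Run the full analysis pipeline
#'
#' Executes, on one bone dataset: semilandmark sliding against the
#' Procrustes consensus, GPA, species mean forms, size statistics (t-test +
#' phylogenetic ANOVA on log centroid size), phylogenetic signal (K on size,
#' Kmult on shape), MANCOVA on retained PCs, between-group PCA with
#' cross-validated typicality classification and a permutation test,
#' phylomorphospace, phylogenetic ridge-regression rates with the clade
#' shift search (on shape and on size), and parsimony (optionally stochastic
#' mapping) ancestral-state reconstruction of the locomotor character. Every
#' stochastic stage is seeded from the master seed, and machine-readable
#' reports (CSV tables with a commented header, JSON) are written to
#' `out_dir`.
#'
#' @param config a [pipeline_config].
#' @return the report bundle (named list of all stage results), invisibly;
#'   files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  on <- config$stages
  bundle <- list(config = config[setdiff(names(config), "dataset")])
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- inputs ----
  if (!is.null(config$dataset)) {
    configs <- config$dataset$configs
    tree <- config$dataset$tree
    traits <- config$dataset$traits
  } else {
    configs <- run_stage("input", read_landmark_csv(config$landmarks))
    tree <- run_stage("input", read_newick(config$tree))
    tr <- utils::read.csv(config$traits, stringsAsFactors = FALSE)
    traits <- stats::setNames(tr$category, tr$species_id)
    if (!is.null(config$meshes_dir)) {
      for (id in names(configs)) {
        f <- file.path(config$meshes_dir, paste0(id, ".ply"))
        if (file.exists(f)) configs[[id]]$mesh <- read_ply(f)
      }
    }
  }

  # ---- sliding ----
  if (on[["slide"]]) {
    slid <- run_stage("slide",
      relax_to_consensus(configs, iterations = config$slide_iterations,
                         trace_file = file.path(config$out_dir,
                                                "sliding_trace.json")))
    configs <- slid$configs
    bundle$sliding_trace <- slid$trace
  } else {
    warning("sliding stage off: downstream results use unslid semilandmarks")
  }

  # ---- superimposition and species means ----
  aligned <- run_stage("gpa", gpa(configs))
  species <- vapply(configs, function(cf) cf$species_id, "")
  means <- run_stage("species_means", species_mean_forms(configs, species))
  flat <- flatten_species_means(means)
  Y <- flat$shapes
  log_cs <- flat$log_cs
  bundle$aligned <- aligned
  bundle$species_means <- means
  groups <- traits[rownames(Y)]
  if (anyNA(groups)) stop("trait table does not cover all species",
                          call. = FALSE)

  # ---- size ----
  if (on[["size"]]) {
    bundle$size <- run_stage("size",
      size_comparison(log_cs, groups, tree, n_sim = config$n_sim,
                      seed = stage_seed(config, 11L)))
    sz <- data.frame(species_id = names(log_cs), log_cs = unname(log_cs),
                     category = unname(groups))
    if (!is.null(config$paired_log_cs)) {
      sz$log_cs_paired <- unname(config$paired_log_cs[sz$species_id])
      sz$size_ratio <- sz$log_cs / sz$log_cs_paired
    }
    write_report_csv(sz, file.path(config$out_dir, "size_table.csv"),
                     config)
    bundle$size_table <- sz
  }

  # ---- phylogenetic signal ----
  if (on[["signal"]]) {
    bundle$signal_size <- run_stage("signal",
      blomberg_k(tree, log_cs, n_perm = config$n_perm,
                 seed = stage_seed(config, 23L)))
    bundle$signal_shape <- run_stage("signal",
      k_mult(tree, Y, n_perm = config$n_perm,
             seed = stage_seed(config, 29L)))
  }

  # ---- MANCOVA on retained PCs ----
  pcs <- run_stage("pca", retain_pcs(Y, config$pc_threshold))
  bundle$retained_pcs <- pcs["n_axes"]
  if (on[["mancova"]]) {
    bundle$mancova <- run_stage("mancova",
      mancova_pillai(pcs$scores, log_cs[rownames(Y)], groups))
    write_report_csv(bundle$mancova,
                     file.path(config$out_dir, "mancova.csv"), config)
  }

  # ---- between-group PCA, classification, permutation ----
  if (on[["bgpca"]]) {
    cls <- run_stage("bgpca",
      bg_classify(pcs$scores, groups, cross_validate = TRUE))
    bg <- cls$ordination
    perm <- run_stage("bgpca",
      permutation_group_distance(Y, groups, n_perm = config$n_perm,
                                 seed = stage_seed(config, 37L)))
    bundle$bgpca <- bg
    bundle$classification <- cls
    bundle$group_permutation <- perm
    jsonlite::write_json(
      list(accuracy = cls$accuracy, cross_validated = cls$cross_validated,
           permutation_distance = perm$distance, permutation_p = perm$p,
           table = cls$table),
      file.path(config$out_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA)
  }

  # ---- phylomorphospace ----
  if (on[["phylomorphospace"]]) {
    pca <- run_stage("phylomorphospace", shape_pca(Y))
    bundle$phylomorphospace <- run_stage("phylomorphospace",
      phylomorphospace(tree, pca))
    sc <- data.frame(species_id = rownames(pca$scores),
                     category = unname(groups),
                     pca$scores[, seq_len(min(4L, ncol(pca$scores))),
                                drop = FALSE])
    write_report_csv(sc, file.path(config$out_dir, "pca_scores.csv"),
                     config)
  }

  # ---- evolutionary rates and clade shifts ----
  if (on[["rates"]]) {
    rf_shape <- run_stage("rates", rr_rates(tree, Y))
    shifts_shape <- run_stage("rates",
      search_shift_clades(tree, rf_shape, n_rand = config$n_rand,
                          seed = stage_seed(config, 41L)))
    rf_size <- run_stage("rates", rr_rates(tree, log_cs))
    shifts_size <- run_stage("rates",
      search_shift_clades(tree, rf_size, n_rand = config$n_rand,
                          seed = stage_seed(config, 43L)))
    bundle$rates_shape <- rf_shape
    bundle$shifts_shape <- shifts_shape
    bundle$rates_size <- rf_size
    bundle$shifts_size <- shifts_size
    write_report_csv(shifts_shape,
                     file.path(config$out_dir, "rate_shifts_shape.csv"),
                     config)
    write_report_csv(shifts_size,
                     file.path(config$out_dir, "rate_shifts_size.csv"),
                     config)
  }

  # ---- ancestral states ----
  if (on[["asr"]]) {
    bundle$asr_parsimony <- run_stage("asr", asr_parsimony(tree, traits))
    if (on[["simmap"]])
      bundle$asr_simmap <- run_stage("asr",
        simmap_er(tree, traits, nsim = config$simmap_nsim,
                  seed = stage_seed(config, 47L)))
  }

  # ---- reproducibility metadata ----
  meta <- list(package = "morphorate",
               version = as.character(utils::packageVersion("morphorate")),
               seed = config$seed,
               stages = as.list(config$stages),
               parameters = list(slide_iterations = config$slide_iterations,
                                 pc_threshold = config$pc_threshold,
                                 n_perm = config$n_perm,
                                 n_sim = config$n_sim,
                                 n_rand = config$n_rand))
  jsonlite::write_json(meta, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(bundle)
}
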