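#' Pipeline configuration
#'
#' Collects file paths and stage parameters for [run_pipeline()]. All
#' randomness in the pipeline flows from the single `seed`.
#'
#' @param protein_matrix,protein_metadata protein intensity matrix and
#'   metadata files (see [read_feature_matrix()]).
#' @param mirna_counts,mirna_metadata miRNA count matrix and metadata
#'   files.
#' @param gmt pathway gene sets (GMT file), optional.
#' @param target_map miRNA-target map (TSV), optional.
#' @param univariate a [univariate_config()].
#' @param budget Ranking-PCA feature budget for the protein model.
#' @param n_pc,n_lv Ranking-PCA PCs and PLS-DA latent variables.
#' @param de_fdr FDR threshold for the miRNA DE stage.
#' @param min_presence protein presence rule for the integration merge.
#' @param integration_budget Ranking-PCA budget on the merged block.
#' @param seed global integer seed.
#' @param out_dir output directory for [run_pipeline()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(protein_matrix, protein_metadata,
                            mirna_counts = NULL, mirna_metadata = NULL,
                            gmt = NULL, target_map = NULL,
                            univariate = univariate_config(),
                            budget = 50L, n_pc = 1L, n_lv = 1L,
                            de_fdr = 0.05, min_presence = 2L,
                            integration_budget = 200L, seed = 1L,
                            out_dir = "vesicomics_out") {
  structure(list(protein_matrix = protein_matrix,
                 protein_metadata = protein_metadata,
                 mirna_counts = mirna_counts,
                 mirna_metadata = mirna_metadata,
                 gmt = gmt, target_map = target_map,
                 univariate = univariate,
                 budget = as.integer(budget), n_pc = as.integer(n_pc),
                 n_lv = as.integer(n_lv), de_fdr = de_fdr,
                 min_presence = as.integer(min_presence),
                 integration_budget = as.integer(integration_budget),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()];
#' `univariate` may be a nested mapping of [univariate_config()]
#' arguments.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$univariate))
    y$univariate <- do.call(univariate_config, y$univariate)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in analysis order: univariate protein
#' selection; Ranking-PCA + PLS-DA with leave-one-individual-out CV;
#' univariate/multivariate intersection; miRNA differential expression
#' (when count data are configured); miRNA/protein integration; pathway
#' coverage and over-representation (when pathway resources are
#' configured). Every table is written as TSV under `out_dir`, a JSON
#' summary collects the headline numbers, and a log records the seed and
#' per-stage feature counts. Given the same configuration and seed the
#' JSON summary is byte-identical across runs.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return (invisibly) list with the in-memory stage results and
#'   `summary` (what was written to `summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_digest <- sum(utf8ToInt(paste(unlist(config), collapse = "|"))) %%
    1e9
  log_lines <- c(sprintf("vesicomics pipeline | seed %d", config$seed),
                 sprintf("config digest %.0f", cfg_digest))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  outfile <- function(f) file.path(config$out_dir, f)
  wt <- function(df, f) utils::write.table(df, outfile(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)

  om <- stage("read_proteins",
              read_feature_matrix(config$protein_matrix,
                                  config$protein_metadata))
  log_lines <- c(log_lines, sprintf("proteins: %d features x %d observations",
                                    nrow(om$values), ncol(om$values)))

  uni <- stage("univariate", select_univariate(om, config$univariate))
  wt(uni, "univariate.tsv")
  log_lines <- c(log_lines, sprintf("univariate selected: %d",
                                    sum(uni$selected)))

  cv <- stage("multivariate",
              loo_cv_by_individual(om, budget = config$budget,
                                   n_pc = config$n_pc, n_lv = config$n_lv))
  wt(cv$predictions, "cv_predictions.tsv")
  rk_full <- data.frame(rank = seq_along(cv$selected_full),
                        feature = cv$selected_full,
                        stringsAsFactors = FALSE)
  wt(rk_full, "ranking.tsv")
  dirs <- coefficient_directions(cv$model_full)
  wt(dirs, "plsda_coefficients.tsv")

  inter <- stage("intersection",
                 intersect_selections(uni, cv$selected_full))
  wt(inter$features, "modulated_proteins.tsv")

  summary <- list(
    seed = config$seed,
    n_proteins = nrow(om$values),
    n_observations = ncol(om$values),
    univariate_selected = sum(uni$selected),
    multivariate_selected = length(cv$selected_full),
    final_modulated_proteins = nrow(inter$features),
    fitting = list(accuracy = unname(cv$metrics_fit["accuracy"]),
                   ner = unname(cv$metrics_fit["ner"])),
    cross_validation = list(accuracy = unname(cv$metrics_cv["accuracy"]),
                            ner = unname(cv$metrics_cv["ner"])))

  de <- NULL; merged <- NULL; integ <- NULL; cov <- NULL; ora <- NULL
  if (!is.null(config$mirna_counts)) {
    mir <- stage("read_mirna",
                 read_feature_matrix(config$mirna_counts,
                                     config$mirna_metadata))
    counts <- mir$values
    storage.mode(counts) <- "integer"
    de <- stage("mirna_de",
                nb_two_group_test(counts, obs_conditions(mir),
                                  fdr = config$de_fdr))
    wt(de, "mirna_de.tsv")
    summary$de_mirnas <- sum(de$significant)
    log_lines <- c(log_lines, sprintf("miRNA DE at FDR %.2f: %d",
                                      config$de_fdr, sum(de$significant)))

    merged <- stage("integration_merge",
                    merge_blocks(om, counts, mir$metadata,
                                 min_presence = config$min_presence))
    integ <- stage("integration_ranking",
                   integrated_ranking(merged,
                                      budget = config$integration_budget,
                                      n_pc = config$n_pc))
    wt(integ$loadings, "integration_loadings.tsv")
    summary$integration <- list(
      individuals = length(unique(merged$metadata$individual)),
      proteins_retained = sum(merged$block == "protein"),
      mirnas_retained = sum(merged$block == "mirna"),
      top_block_protein = unname(integ$block_composition["protein"]),
      top_block_mirna = unname(integ$block_composition["mirna"]))

    if (!is.null(config$gmt) && !is.null(config$target_map)) {
      db <- stage("read_pathways", read_gmt(config$gmt))
      tm <- stage("read_targets", read_target_map(config$target_map))
      de_list <- de$feature[de$significant]
      cov <- stage("coverage",
                   pathway_target_coverage(de_list, tm, db))
      wt(cov$table, "pathway_coverage.tsv")
      wt(chord_edges(cov), "chord_edges.tsv")
      ora <- stage("ora", hypergeometric_ora(unique(tm$gene[tm$mirna %in%
                                                              de_list]), db))
      wt(ora, "pathway_ora.tsv")
      summary$coverage <- stats::setNames(as.list(round(cov$table$coverage,
                                                        4)),
                                          cov$table$pathway)
    }
  }

  jsonlite::write_json(summary, outfile("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c(log_lines, "done"), outfile("pipeline.log"))
  invisible(list(univariate = uni, cv = cv, intersection = inter, de = de,
                 merged = merged, integration = integ, coverage = cov,
                 ora = ora, summary = summary))
}
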