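# Pipeline orchestration: one configuration object, staged execution in
# dependency order, and a manifest for reproducibility.

#' Pipeline run configuration
#'
#' Collects every analysis threshold with the defaults of the underlying
#' study design: association alpha 0.001 with 10,000 permutations,
#' imaging BH q 0.001, differential-expression alpha 0.01, interaction
#' score threshold 900, enrichment filters (0.01, count >= 3,
#' factor > 1.5), grid and sex-difference alphas 0.01. All randomness
#' flows from `seed` via named substreams per stage.
#'
#' @param seed Root integer seed.
#' @param alpha_assoc,n_perm Association selection threshold and
#'   permutation count.
#' @param bh_q Imaging BH threshold.
#' @param alpha_de Differential-expression threshold.
#' @param string_threshold Interaction score threshold.
#' @param enrich_alpha,enrich_min_count,enrich_min_factor Enrichment
#'   filters.
#' @param grid_alpha,sexdiff_alpha Overexpression-grid and sex-difference
#'   thresholds.
#' @param study A [study_config()] list for the simulation stage.
#' @param ... Unused; reserved.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, alpha_assoc = 0.001, n_perm = 10000L,
                       bh_q = 0.001, alpha_de = 0.01,
                       string_threshold = 900L, enrich_alpha = 0.01,
                       enrich_min_count = 3L, enrich_min_factor = 1.5,
                       grid_alpha = 0.01, sexdiff_alpha = 0.01,
                       study = study_config(), ...) {
  for (a in c(alpha_assoc, alpha_de, enrich_alpha, grid_alpha,
              sexdiff_alpha, bh_q))
    .check_prob(a, "alpha")
  if (n_perm < 1) .stopf("n_perm must be >= 1")
  structure(list(seed = seed, alpha_assoc = alpha_assoc, n_perm = n_perm,
                 bh_q = bh_q, alpha_de = alpha_de,
                 string_threshold = string_threshold,
                 enrich_alpha = enrich_alpha,
                 enrich_min_count = enrich_min_count,
                 enrich_min_factor = enrich_min_factor,
                 grid_alpha = grid_alpha, sexdiff_alpha = sexdiff_alpha,
                 study = study),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys override [run_config()] defaults; a `study` mapping
#' overrides [study_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  study <- do.call(study_config, as.list(y$study))
  y$study <- NULL
  do.call(run_config, c(y, list(study = study)))
}

#' Run the full analysis pipeline
#'
#' Simulates a study (or reuses one), then executes the stages in
#' dependency order: contrast maps, association and classification,
#' reference overlap and enrichment, network topology, temporal-spatial
#' specificity, and sex differences. Every stage's table is written under
#' `out_dir` together with `manifest.json` (configuration, package
#' version, file checksums). A rerun with the same configuration is
#' bit-identical.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @param study Optional pre-simulated study from [simulate_study()]; by
#'   default one is simulated from `config$study` and `config$seed` and
#'   its inputs are written under `out_dir/inputs`.
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir, study = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(study)) {
    study <- simulate_study(config$study, seed = config$seed)
    ind <- file.path(out_dir, "inputs")
    dir.create(ind, showWarnings = FALSE)
    write_expression_matrix(study$expr, file.path(ind, "expression.tsv"))
    for (ix in mdd_indices())
      write_imaging_dataset(study$imaging[[ix]],
                            file.path(ind, paste0("imaging_", ix, ".tsv")))
    write_dev_expression(study$dev, file.path(ind, "dev_expression.tsv"))
    write_edge_list(study$edges, file.path(ind, "edges.tsv"))
    write_gene_list(study$refs$risk, file.path(ind, "risk_genes.txt"))
    for (ts in names(study$refs$de_down))
      write_gene_list(study$refs$de_down[[ts]],
                      file.path(ind, paste0("de_down_", ts, ".txt")))
    write_gmt(study$terms, file.path(ind, "terms.gmt"))
    jsonlite::write_json(
      list(class1_genes = study$truth$class1_genes,
           class2_genes = study$truth$class2_genes,
           specific_genes = study$truth$specific_genes,
           sex_biased_genes = as.list(study$truth$sex_biased_genes),
           hub_genes = study$truth$hub_genes,
           effect_sizes = study$truth$effect_sizes),
      file.path(ind, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }

  # contrast stage
  maps <- difference_maps(study$imaging, q = config$bh_q)
  for (ix in mdd_indices())
    .write_tsv(maps[[ix]], file.path(out_dir,
                                     paste0("difference_map_", ix, ".tsv")))

  # associate + classify stage
  assoc <- identify_depression_genes(study$expr, maps,
                                     alpha = config$alpha_assoc,
                                     n_perm = config$n_perm,
                                     seed = config$seed)
  classes <- classify_directional(assoc$records, assoc$selected,
                                  alpha = config$alpha_assoc)
  .write_tsv(classes, file.path(out_dir, "classification.tsv"))

  # reference overlap + enrichment stage
  refs <- c(list(risk = study$refs$risk), study$refs$de_down)
  overlaps <- class_overlap_table(classes, refs)
  .write_tsv(overlaps, file.path(out_dir, "overlap.tsv"))
  selected <- classes$gene_id[classes$class %in% c("Class1", "Class2")]
  enrich <- hypergeometric_enrichment(
    selected, study$terms, study$truth$genes,
    alpha = config$enrich_alpha, min_count = config$enrich_min_count,
    min_factor = config$enrich_min_factor)
  .write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))

  # network stage
  g <- build_graph(study$edges, threshold = config$string_threshold)
  topo <- compute_topology(g)
  .write_tsv(topo, file.path(out_dir, "topology.tsv"))
  topo_tests <- compare_topology(topo, classes)
  .write_tsv(topo_tests, file.path(out_dir, "topology_tests.tsv"))

  # specificity stage
  spec <- class_dpi_comparison(study$dev, classes)
  .write_tsv(spec$dpi, file.path(out_dir, "dpi.tsv"))
  .write_tsv(spec$tests, file.path(out_dir, "dpi_tests.tsv"))
  controls <- classes$gene_id[classes$class == "control"]
  grid <- overexpression_grid(study$dev, selected, controls,
                              alpha = config$grid_alpha)
  .write_tsv(as.data.frame(grid$t), file.path(out_dir, "grid_t.tsv"),
             row_names = TRUE)
  .write_tsv(as.data.frame(grid$p), file.path(out_dir, "grid_p.tsv"),
             row_names = TRUE)

  # sexdiff stage
  sexrec <- sex_de_genes(study$dev, selected,
                         alpha = config$sexdiff_alpha)
  .write_tsv(sexrec, file.path(out_dir, "sexdiff.tsv"))
  sexpct <- sex_bias_percentages(
    sex_de_genes(study$dev, alpha = config$sexdiff_alpha), classes)
  .write_tsv(sexpct, file.path(out_dir, "sexdiff_percentages.tsv"))
  sexgrid <- if (nrow(sexrec) >= 2)
    sex_overexpression_grid(study$dev, sexrec$gene_id, controls,
                            alpha = config$sexdiff_alpha)
  else NULL
  if (!is.null(sexgrid)) {
    .write_tsv(as.data.frame(sexgrid$t),
               file.path(out_dir, "sexdiff_grid_t.tsv"), row_names = TRUE)
    .write_tsv(as.data.frame(sexgrid$p),
               file.path(out_dir, "sexdiff_grid_p.tsv"), row_names = TRUE)
  }

  # manifest
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.json")
  manifest <- list(
    package = "mddsig",
    version = as.character(utils::packageVersion("mddsig")),
    config = unclass(config),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(maps = maps, assoc = assoc, classes = classes,
                 overlaps = overlaps, enrichment = enrich,
                 topology = topo, topology_tests = topo_tests,
                 specificity = spec, grid = grid, sexdiff = sexrec,
                 sexdiff_percentages = sexpct, sexdiff_grid = sexgrid,
                 study = study))
}
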