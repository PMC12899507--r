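#' Run the full screening and integration pipeline
#'
#' Orchestrates every stage on a synthetic study bundle (or one assembled
#' from files with the same component names): germination screening and
#' tolerance grouping, trait summarisation, comprehensive evaluation,
#' DEG filtering and intersection, enrichment, co-expression network with
#' module-trait correlation, hub extraction, Mantel tests, and qPCR
#' concordance. Writes TSV outputs plus a JSON manifest of inputs, seeds and
#' thresholds when `out_dir` is given.
#'
#' @param study a study bundle as produced by [simulate_study()].
#' @param k tolerance groups for the germination screen.
#' @param lfc_cut,p_cut DEG thresholds.
#' @param beta,edge_threshold network parameters.
#' @param n_modules modules to cut (default: the generator's module count
#'   when available, else 6).
#' @param rho grey relational distinguishing coefficient.
#' @param n_perm Mantel/correlation permutations.
#' @param seed integer seed for all stochastic stages.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return a named list of stage results (`screen`, `grouping`, `traits`,
#'   `evaluation`, `degs`, `intersection`, `enrichment`, `network`,
#'   `module_trait`, `hubs`, `edges`, `mantel`, `qpcr`, `concordance`,
#'   `manifest`).
#' @export
run_pipeline <- function(study, k = 4, lfc_cut = 2, p_cut = 0.05, beta = 6,
                         edge_threshold = 0.8, n_modules = NULL, rho = 0.5,
                         n_perm = 999, seed = 1, out_dir = NULL) {
  stages_done <- character()
  step <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "droughtrank_pipeline_error")
    })
    stages_done <<- c(stages_done, name)
    res
  }
  n_modules <- n_modules %||% study$config$n_modules %||% 6

  # 1. germination screen
  indices <- step("screen", germination_indices(study$germination$counts,
                                                study$germination$seedlings))
  rel <- relative_germination_indices(indices)
  grouping <- step("grouping", cluster_tolerance_groups(rel, k = k, seed = seed))

  # 2. traits + comprehensive evaluation
  trait_summary <- step("traits", summarize_traits(study$traits$raw))
  responses <- trait_responses(trait_summary)
  evaluation <- step("evaluate", evaluate_varieties(
    dplyr::rename(responses$by_variety, value = "ratio"), rho = rho))

  # 3. DEG set logic + enrichment
  degs <- step("deg", filter_degs(study$de$tables, lfc_cut = lfc_cut,
                                  p_cut = p_cut))
  sets <- deg_sets(degs)
  intersection <- contrast_intersection(purrr::map(sets, "all"))
  enrichment <- step("enrich", hypergeometric_enrichment(
    intersection$shared, study$gene_sets))

  # 4. network: modules, module-trait, hubs, edges
  adj <- step("network", correlation_adjacency(study$expression$expr,
                                               beta = beta))
  assignment <- detect_modules(adj, n_modules = n_modules)
  eigen <- module_eigengenes(study$expression$expr, assignment)
  module_trait <- module_trait_correlation(eigen, study$expression$traits)
  hubs <- hub_genes(adj, assignment, top_k = 5,
                    edge_threshold = edge_threshold)
  edges <- export_edge_list(adj, threshold = edge_threshold,
                            genes = hubs$gene)

  # 5. Mantel: hub expression distance vs physiological distance
  hub_expr <- expr_as_matrix(study$expression$expr)[hubs$gene, , drop = FALSE]
  d_expr <- standardized_dist(t(log2(hub_expr + 1)))
  d_trait <- standardized_dist(study$expression$traits)
  mantel <- step("mantel", mantel_test(d_expr, d_trait, n_perm = n_perm,
                                       seed = seed))

  # 6. qPCR concordance
  fold <- step("qpcr", delta_delta_ct(study$qpcr$ct,
                                      reference_gene = study$qpcr$reference_gene,
                                      calibrator = "CK"))
  concord <- concordance_with_rnaseq(
    dplyr::filter(fold, .data$treatment == "PEG"),
    study$qpcr$planted
  )

  manifest <- list(
    stages = stages_done,
    seed = seed,
    thresholds = list(lfc_cut = lfc_cut, p_cut = p_cut, beta = beta,
                      edge_threshold = edge_threshold, rho = rho,
                      n_modules = n_modules, n_perm = n_perm, k = k),
    generator_seed = study$config$seed %||% NA,
    package_version = as.character(utils::packageVersion("droughtrank"))
  )

  result <- list(
    screen = indices, relative = rel, grouping = grouping,
    traits = trait_summary, evaluation = evaluation,
    degs = degs, intersection = intersection, enrichment = enrichment,
    network = adj, modules = assignment, eigengenes = eigen,
    module_trait = module_trait, hubs = hubs, edges = edges,
    mantel = mantel, qpcr = fold, concordance = concord,
    manifest = manifest
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(indices, file.path(out_dir, "germination_indices.tsv"))
    write_table(rel, file.path(out_dir, "relative_indices.tsv"))
    write_table(tidy(grouping), file.path(out_dir, "tolerance_groups.tsv"))
    write_table(trait_summary, file.path(out_dir, "trait_summary.tsv"))
    write_table(tidy(evaluation), file.path(out_dir, "evaluation.tsv"))
    write_table(degs, file.path(out_dir, "degs.tsv"))
    write_table(dplyr::select(enrichment, -"genes"),
                file.path(out_dir, "enrichment.tsv"))
    write_table(module_trait, file.path(out_dir, "module_trait.tsv"))
    write_table(hubs, file.path(out_dir, "hub_genes.tsv"))
    write_table(edges, file.path(out_dir, "hub_edges.tsv"))
    write_table(fold, file.path(out_dir, "qpcr_fold_changes.tsv"))
    jsonlite::write_json(
      list(shared_degs = intersection$shared, manifest = manifest,
           mantel = tidy(mantel), concordance = concord),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA
    )
  }
  result
}
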