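#' Run the full screen on synthetic repertoires
#'
#' Convenience driver that exercises every pipeline stage end to end on
#' simulated data: repertoire + expression simulation, TMM/exact-test DE,
#' effector calling, all-vs-all similarity graph and Markov clustering with
#' core and pioneer labelling, RBBH orthologue grouping, and the NG86
#' positive-selection screen on effector-containing groups.
#'
#' @param sim_cfg A [sim_config()].
#' @param cfg A [pipeline_config()] of analysis thresholds.
#' @return A list with the simulation (`sim`, `counts`), per-stage results
#'   (`de`, `effector_calls`, `edges`, `clusters`, `cluster_labels`,
#'   `pioneers`, `rbbh`, `groups`, `screen`) and summary tables
#'   (`repertoire`, `selection`).
#' @export
run_synthetic_pipeline <- function(sim_cfg = sim_config(),
                                   cfg = pipeline_config()) {
  sim <- simulate_repertoires(sim_cfg)
  counts <- simulate_expression(sim$truth, sim_cfg)

  de <- list()
  calls <- list()
  for (ds in names(counts)) {
    de[[ds]] <- exact_test_de(counts[[ds]], alpha = cfg$alpha)
    calls[[ds]] <- call_effectors(de[[ds]], sim$annotations, dataset = ds)
  }
  de_all <- do.call(rbind, c(de, list(make.row.names = FALSE)))
  calls_all <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  effector_ids <- calls_all$id[calls_all$category == "putative_effector"]

  edges <- emit_similarity_edges(sim$records)
  dataset_of <- stats::setNames(sim$records$dataset, sim$records$id)
  graph <- build_graph(edges, nodes = sim$records$id,
                       evalue_threshold = cfg$evalue_threshold)
  clusters <- mcl_cluster(graph, mcl_params(inflation = cfg$inflation))
  labels <- label_and_find_core(
    clusters, effector_ids, dataset_of,
    aphid_datasets = sim$truth$datasets$dataset,
    min_datasets = cfg$core_min_datasets)
  species_of <- stats::setNames(sim$truth$datasets$species,
                                sim$truth$datasets$dataset)
  genus_of <- stats::setNames(sim$truth$datasets$genus,
                              sim$truth$datasets$dataset)
  pioneers <- find_pioneers(clusters, sim$annotations, effector_ids,
                            dataset_of, species_of, genus_of,
                            db_evalue = cfg$pioneer_db_evalue)

  datasets <- sim$truth$datasets$dataset
  pair_list <- list()
  for (i in seq_along(datasets)) {
    for (j in seq_along(datasets)) {
      if (i >= j) next
      a <- datasets[i]; b <- datasets[j]
      eab <- edges[dataset_of[edges$query] == a &
                     dataset_of[edges$subject] == b, , drop = FALSE]
      eba <- edges[dataset_of[edges$query] == b &
                     dataset_of[edges$subject] == a, , drop = FALSE]
      pair_list[[paste(a, b)]] <-
        rbbh_pairs(eab, eba, min_identity = cfg$rbbh_identity,
                   min_coverage = cfg$rbbh_coverage)
    }
  }
  pairs <- do.call(rbind, c(pair_list, list(make.row.names = FALSE)))
  groups <- rbbh_groups(pairs, effector_ids,
                        mcl_params(inflation = cfg$inflation))
  ginfo <- attr(groups, "groups")

  cds_of <- stats::setNames(sim$records$cds, sim$records$id)
  eff_groups <- ginfo$group[ginfo$contains_effector & ginfo$n_members >= 2L]
  alignments <- lapply(eff_groups, function(g) {
    m <- groups$member[groups$group == g]
    structure(cds_of[m], class = "codon_alignment")
  })
  names(alignments) <- as.character(eff_groups)
  screen <- if (length(alignments)) screen_groups(alignments) else NULL

  list(sim = sim, counts = counts, de = de_all, effector_calls = calls_all,
       edges = edges, clusters = clusters, cluster_labels = labels,
       pioneers = pioneers, rbbh = pairs, groups = groups, screen = screen,
       repertoire = repertoire_summary(calls_all),
       selection = if (!is.null(screen)) selection_summary(screen) else NULL,
       config = cfg)
}
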