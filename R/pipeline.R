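# Helper: planted differential tables in the layout screen_differential emits.

#' Ground-truth differential records
#'
#' Converts the generator's planted-DE truth into the record layout used
#' by [assemble_cerna()] (useful for construction-guarantee tests that
#' bypass the stochastic screen).
#'
#' @param truth the `truth` element of [simulate_discovery_profile()].
#' @return list with `dels` and `dems` data.frames.
#' @export
truth_differentials <- function(truth) {
  list(
    dels = data.frame(feature_id = truth$de_lncrna$id, feature_class = "lncRNA",
                      trend = truth$de_lncrna$trend),
    dems = data.frame(feature_id = truth$de_mrna$id, feature_class = "mRNA",
                      trend = truth$de_mrna$trend))
}

#' Run the full discovery-to-classification pipeline on synthetic data
#'
#' Generates the synthetic study (discovery profile, evidence table,
#' interactions, PPI edges, validation cohort), then executes every stage:
#' differential screen, miRNA evidence pooling, ceRNA assembly, PPI
#' filtering with MCODE complexes and degree hubs, the m6A correlation
#' screen, subnetwork annotation, four-node module extraction, enrichment
#' of the network mRNAs, and the module SVM classifier on the cohort.
#' Stage cardinalities are logged; results are optionally written as JSON
#' (byte-identical across runs with the same parameters and seed).
#'
#' @param params a [simulation_params()].
#' @param config a [threshold_config()].
#' @param enforce_trend passed to [assemble_cerna()].
#' @param out_path optional path for the result JSON.
#' @param verbose log stage cardinalities (default `TRUE`).
#' @return list of class `pipeline_result` with all stage outputs and
#'   `truth`.
#' @export
run_pipeline <- function(params = simulation_params(),
                         config = threshold_config(seed = params$seed),
                         enforce_trend = FALSE, out_path = NULL,
                         verbose = TRUE) {
  disc <- simulate_discovery_profile(params)
  truth <- disc$truth
  de <- screen_differential(disc$profile, config)
  dels <- de[de$feature_class == "lncRNA", , drop = FALSE]
  dems <- de[de$feature_class == "mRNA", , drop = FALSE]
  msg_stage(verbose, "differential screen: %d DELs, %d DEMs", nrow(dels), nrow(dems))

  evidence <- simulate_evidence(params)
  demis <- pool_mirna_evidence(evidence, config)
  msg_stage(verbose, "evidence pooling: %d records -> %d consensus DEMis",
            nrow(evidence), nrow(demis))

  inter <- simulate_interactions(params, truth)
  network <- assemble_cerna(dels, demis, dems, inter$interactions,
                            enforce_trend = enforce_trend)
  nt <- table(factor(network$nodes$type, levels = c("lncRNA", "miRNA", "mRNA")))
  msg_stage(verbose, "ceRNA network: %d lncRNA, %d miRNA, %d mRNA nodes, %d edges",
            nt[["lncRNA"]], nt[["miRNA"]], nt[["mRNA"]], nrow(network$edges))

  ppi_edges <- simulate_ppi(params, truth)
  ppi <- filter_ppi(ppi_edges, config)
  complexes <- mcode_find_complexes(ppi, config)
  hubs <- hub_genes(ppi, config)
  msg_stage(verbose, "PPI: %d nodes, %d edges; %d MCODE complexes; %d hubs",
            igraph::vcount(ppi), igraph::ecount(ppi), length(complexes), nrow(hubs))

  correlations <- suppressWarnings(
    screen_m6a_lncrnas(disc$profile, dels, m6a_regulators(), config))
  msg_stage(verbose, "m6A screen: %d retained lncRNA-regulator pairs",
            nrow(correlations))

  net_lnc <- network$nodes$id[network$nodes$type == "lncRNA"]
  core_lnc <- intersect(unique(correlations$lncrna), net_lnc)
  subnetwork <- if (length(core_lnc) > 0) {
    attach_regulators(extract_subnetwork(network, core_lnc), correlations)
  } else {
    empty_cerna()
  }
  # at n = 3 per group the screen can drop every mRNA (or every m6A-related
  # lncRNA) in unlucky draws; the orchestrator then reports no module rather
  # than aborting the run
  module <- tryCatch(
    extract_m6a_module(network, ppi_degree_table(ppi), correlations),
    error = function(e) {
      warning(sprintf("module extraction skipped: %s", conditionMessage(e)))
      NULL
    })
  if (is.null(module)) {
    msg_stage(verbose, "module: none extracted")
  } else {
    msg_stage(verbose, "module: %s / %s / %s / %s",
              module$lncrna, module$regulator, module$mirna, module$mrna)
  }

  sets <- simulate_gene_sets(params, truth)
  net_mrna <- network$nodes$id[network$nodes$type == "mRNA"]
  enrichment <- if (length(net_mrna) > 0) {
    overrepresentation(net_mrna, sets, config)
  } else {
    NULL
  }

  if (!is.null(module)) {
    module_features <- c(module$lncrna, module$regulator, module$mirna,
                         module$mrna)
    cohort <- simulate_cohort(params, module_features)
    ids <- colnames(cohort$profile$values)
    split <- split_cohort(ids, unname(cohort$profile$groups),
                          train_fraction = 2 / 3, seed = config$seed)
    clf <- train_module_classifier(cohort$profile, module_features, split$train,
                                   seed = config$seed)
    res_train <- evaluate(clf, cohort$profile, split$train, split = "train")
    res_test <- evaluate(clf, cohort$profile, split$test, split = "test")
    msg_stage(verbose, "classifier: train %.2f%% (%d/%d), test %.2f%% (%d/%d)",
              res_train$accuracy, res_train$correct, res_train$n,
              res_test$accuracy, res_test$correct, res_test$n)
    cohort_profile <- cohort$profile
  } else {
    cohort_profile <- NULL; split <- NULL; clf <- NULL
    res_train <- NULL; res_test <- NULL
    msg_stage(verbose, "classifier: skipped (no module)")
  }

  result <- structure(
    list(params = params, config = config, truth = truth,
         profile = disc$profile, differential = de, demis = demis,
         network = network, ppi = ppi, complexes = complexes, hubs = hubs,
         correlations = correlations, subnetwork = subnetwork, module = module,
         enrichment = enrichment, cohort = cohort_profile, split = split,
         classifier = clf, train_result = res_train, test_result = res_test),
    class = "pipeline_result")
  if (!is.null(out_path)) write_pipeline_json(result, out_path)
  result
}

#' Write a deterministic JSON summary of a pipeline run
#'
#' @param result a `pipeline_result`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_json <- function(result, path) {
  top <- if (length(result$complexes) > 0) result$complexes[[1]] else NULL
  out <- list(
    seed = result$config$seed,
    counts = list(
      dels = sum(result$differential$feature_class == "lncRNA"),
      dems = sum(result$differential$feature_class == "mRNA"),
      demis = nrow(result$demis),
      cerna_nodes = nrow(result$network$nodes),
      cerna_edges = nrow(result$network$edges),
      ppi_nodes = igraph::vcount(result$ppi),
      ppi_edges = igraph::ecount(result$ppi),
      complexes = length(result$complexes),
      hubs = nrow(result$hubs),
      m6a_pairs_retained = nrow(result$correlations)),
    dels = sort(result$differential$feature_id[
      result$differential$feature_class == "lncRNA"]),
    dems = sort(result$differential$feature_id[
      result$differential$feature_class == "mRNA"]),
    demis = sort(result$demis$feature_id),
    hubs = result$hubs,
    top_complex = if (is.null(top)) NULL else
      list(members = top$members, score = top$score, n = top$n),
    module = if (is.null(result$module)) NULL else
      result$module[c("lncrna", "regulator", "mirna", "mrna", "pcc",
                      "lncrna_cerna_degree", "mrna_ppi_degree")],
    classifier = if (is.null(result$train_result)) NULL else list(
      train = result$train_result[c("n", "correct", "accuracy")],
      test = result$test_result[c("n", "correct", "accuracy")]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
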