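#' Simulation parameters for the synthetic study
#'
#' Defaults emulate the study conditions the pipeline targets: a 3 vs 3
#' discovery profile (case vs control placentas) carrying lncRNAs, mRNAs
#' and the 21 m6A regulators, and a 63-sample validation cohort (32 case /
#' 31 control). Planted effects: a 3 log2-unit differential shift, a 0.98
#' lncRNA-regulator correlation, 12 ceRNA triangles against 30 decoy
#' interactions, and a 6-node PPI clique over sparse background.
#'
#' @param n_case,n_control discovery-profile group sizes.
#' @param cohort_case,cohort_control validation-cohort group sizes.
#' @param n_lncrna,n_mrna,n_mirna feature counts (miRNAs live in the
#'   literature-evidence table, not the expression profile).
#' @param n_de_each planted differential features per class (half up,
#'   half down).
#' @param de_shift planted log2 shift in cases.
#' @param noise_sd within-group sd on the log2 scale.
#' @param n_m6a_pairs planted lncRNA-regulator correlated pairs (the
#'   paired lncRNAs are the first planted up-regulated lncRNAs).
#' @param target_r planted correlation of the bivariate log2 noise.
#' @param n_triangles planted ceRNA triangles.
#' @param decoy_interactions interaction records that each violate at
#'   least one ceRNA condition.
#' @param ppi_clique_size planted near-clique size in the PPI layer.
#' @param ppi_background_p background edge probability.
#' @param ppi_weak_frac fraction of background edges assigned a
#'   sub-threshold confidence (< 0.4) to exercise filtering.
#' @param n_ppi_nodes number of PPI nodes (planted plus background mRNAs).
#' @param cohort_shift module-gene class separation in sd units in the
#'   validation cohort.
#' @param cohort_noise_sd within-class sd of the cohort on the log2 scale.
#' @param n_cohort_background non-module background features in the cohort.
#' @param seed integer random seed.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_case = 3L, n_control = 3L,
                              cohort_case = 32L, cohort_control = 31L,
                              n_lncrna = 80L, n_mrna = 240L, n_mirna = 30L,
                              n_de_each = 24L, de_shift = 3, noise_sd = 0.5,
                              n_m6a_pairs = 4L, target_r = 0.98,
                              n_triangles = 12L, decoy_interactions = 30L,
                              ppi_clique_size = 6L, ppi_background_p = 0.02,
                              ppi_weak_frac = 0.15, n_ppi_nodes = 100L,
                              cohort_shift = 3, cohort_noise_sd = 1,
                              n_cohort_background = 50L, seed = 1L) {
  p <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
            cohort_case = as.integer(cohort_case),
            cohort_control = as.integer(cohort_control),
            n_lncrna = as.integer(n_lncrna), n_mrna = as.integer(n_mrna),
            n_mirna = as.integer(n_mirna), n_de_each = as.integer(n_de_each),
            de_shift = de_shift, noise_sd = noise_sd,
            n_m6a_pairs = as.integer(n_m6a_pairs), target_r = target_r,
            n_triangles = as.integer(n_triangles),
            decoy_interactions = as.integer(decoy_interactions),
            ppi_clique_size = as.integer(ppi_clique_size),
            ppi_background_p = ppi_background_p,
            ppi_weak_frac = ppi_weak_frac, n_ppi_nodes = as.integer(n_ppi_nodes),
            cohort_shift = cohort_shift, cohort_noise_sd = cohort_noise_sd,
            n_cohort_background = as.integer(n_cohort_background),
            seed = as.integer(seed))
  counts <- c("n_case", "n_control", "cohort_case", "cohort_control", "n_lncrna",
              "n_mrna", "n_mirna", "n_de_each", "n_m6a_pairs", "n_triangles",
              "decoy_interactions", "ppi_clique_size", "n_ppi_nodes",
              "n_cohort_background")
  if (any(vapply(p[counts], function(v) v < 0, logical(1)))) {
    stop_("all counts must be >= 0")
  }
  if (abs(p$target_r) >= 1) stop_("target_r must lie in (-1, 1)")
  if (p$ppi_background_p < 0 || p$ppi_background_p > 1 ||
      p$ppi_weak_frac < 0 || p$ppi_weak_frac > 1) {
    stop_("probabilities must lie in [0, 1]")
  }
  if ((p$n_lncrna > 0 && p$n_de_each > p$n_lncrna) ||
      (p$n_mrna > 0 && p$n_de_each > p$n_mrna)) {
    stop_("n_de_each exceeds the feature pool")
  }
  structure(p, class = "simulation_params")
}

sim_ids <- function(params) {
  list(lncrna = sprintf("LNC%03d", seq_len(params$n_lncrna)),
       mrna = sprintf("GENE%04d", seq_len(params$n_mrna)),
       mirna = sprintf("miR-%d", 100 + seq_len(params$n_mirna)),
       regulators = m6a_regulators()$gene)
}

# Planted ground truth that is fixed by the parameters alone (no RNG):
# which features are differential, which lncRNA/regulator pairs are
# correlated, the triangle layout, and the PPI clique membership.
planted_truth <- function(params) {
  ids <- sim_ids(params)
  plant_class <- function(pool) {
    n_de <- if (length(pool) == 0) 0L else params$n_de_each
    n_up <- ceiling(n_de / 2)
    data.frame(id = pool[seq_len(n_de)],
               trend = c(rep("up", n_up), rep("down", n_de - n_up)))
  }
  de_lnc <- plant_class(ids$lncrna)
  de_mrna <- plant_class(ids$mrna)
  n_up <- sum(de_lnc$trend == "up")
  if (params$n_m6a_pairs > n_up) stop_("n_m6a_pairs exceeds the planted up-lncRNA pool")
  pairs <- data.frame(
    lncrna = ids$lncrna[seq_len(params$n_m6a_pairs)],
    regulator = sort(ids$regulators)[seq_len(params$n_m6a_pairs)])

  # triangle layout: pair lncRNAs get the most triangles (front-loaded),
  # every lncRNA's first triangle uses the shared hub miRNA
  up_lnc <- de_lnc$id[de_lnc$trend == "up"]
  up_mrna <- de_mrna$id[de_mrna$trend == "up"]
  if (params$n_triangles > length(up_mrna)) {
    stop_("not enough planted up-regulated mRNAs for the requested triangles")
  }
  base_counts <- c(4L, 3L, 2L, 2L)
  mult <- integer(0); remaining <- params$n_triangles
  i <- 1L
  while (remaining > 0) {
    take <- min(if (i <= length(base_counts)) base_counts[i] else 1L, remaining)
    mult <- c(mult, take); remaining <- remaining - take; i <- i + 1L
  }
  if (length(mult) > length(up_lnc)) stop_("not enough planted up-regulated lncRNAs")
  pool <- ids$mirna[seq_len(min(4L, params$n_mirna))]
  tri <- NULL
  g <- 0L
  for (j in seq_along(mult)) {
    for (t in seq_len(mult[j])) {
      g <- g + 1L
      mir <- if (t == 1L || length(pool) < 2L) {
        pool[1]
      } else {
        pool[1 + ((t - 2L) %% (length(pool) - 1L)) + 1L]
      }
      tri <- rbind(tri, data.frame(lncrna = up_lnc[j], mirna = mir,
                                   mrna = up_mrna[g]))
    }
  }
  if (is.null(tri)) {
    tri <- data.frame(lncrna = character(), mirna = character(),
                      mrna = character())
  }
  if (nrow(tri) > 0) {
    first_tri_mrna <- vapply(split(tri, tri$lncrna)[unique(tri$lncrna)],
                             function(d) d$mrna[1], character(1))
    clique <- unique(c(
      unname(first_tri_mrna[pairs$lncrna[pairs$lncrna %in% tri$lncrna]]),
      tri$mrna))
    clique <- clique[seq_len(min(params$ppi_clique_size, length(clique)))]
    hub <- clique[1]
  } else {
    clique <- character(0)
    hub <- NA_character_
  }
  list(de_lncrna = de_lnc, de_mrna = de_mrna, m6a_pairs = pairs,
       triangles = tri, mirna_pool = pool, ppi_clique = clique, ppi_hub = hub)
}

#' Simulate the two-group discovery expression profile
#'
#' Log2 baselines are uniform on (4, 12) per feature; within-group noise is
#' Gaussian with sd `noise_sd` on the log2 scale; planted differential
#' features are shifted by `±de_shift` in cases; each planted
#' lncRNA-regulator pair shares its lncRNA's case shift and its log2 noise
#' is drawn from a bivariate Gaussian with correlation `target_r` across
#' all samples. Values are exported on the linear scale (`2^x`).
#'
#' @param params a [simulation_params()].
#' @return list with `profile` (an [expression_profile()]) and `truth`
#'   (planted DE tables, m6A pairs, triangle layout, PPI clique).
#' @export
simulate_discovery_profile <- function(params = simulation_params()) {
  n_up <- ceiling(params$n_de_each / 2)
  if (params$n_de_each > 0 && (params$n_case < 1 || params$n_control < 1)) {
    stop_("planted differential features require samples in both groups")
  }
  ids <- sim_ids(params)
  truth <- planted_truth(params)
  feats <- c(ids$lncrna, ids$mrna, ids$regulators)
  cls <- c(rep("lncRNA", params$n_lncrna), rep("mRNA", params$n_mrna),
           rep("m6A-regulator", length(ids$regulators)))
  samples <- c(sprintf("GDM_%02d", seq_len(params$n_case)),
               sprintf("NGT_%02d", seq_len(params$n_control)))
  groups <- stats::setNames(c(rep("case", params$n_case),
                              rep("control", params$n_control)), samples)
  n_s <- length(samples)
  shift <- stats::setNames(numeric(length(feats)), feats)
  for (d in list(truth$de_lncrna, truth$de_mrna)) {
    shift[d$id] <- ifelse(d$trend == "up", params$de_shift, -params$de_shift)
  }
  shift[truth$m6a_pairs$regulator] <- shift[truth$m6a_pairs$lncrna]

  vals <- with_seed(params$seed, {
    base <- stats::setNames(stats::runif(length(feats), 4, 12), feats)
    noise <- matrix(stats::rnorm(length(feats) * n_s, 0, params$noise_sd),
                    nrow = length(feats), dimnames = list(feats, samples))
    # couple each planted pair's noise at the target correlation
    for (i in seq_len(nrow(truth$m6a_pairs))) {
      l <- truth$m6a_pairs$lncrna[i]; r <- truth$m6a_pairs$regulator[i]
      z <- stats::rnorm(n_s)
      noise[r, ] <- params$target_r * noise[l, ] +
        sqrt(1 - params$target_r^2) * z * params$noise_sd
    }
    log2x <- base + noise
    log2x[, groups == "case"] <- log2x[, groups == "case"] + shift[feats]
    2^log2x
  })
  profile <- expression_profile(vals, stats::setNames(cls, feats), groups)
  list(profile = profile, truth = truth)
}

#' Simulate the literature miRNA-evidence table
#'
#' Deterministic given the parameters: the triangle-pool miRNAs are
#' reported down-regulated by two concordant studies; further miRNAs are
#' consistent two-study reports (alternating trend), single-study reports,
#' or contradictory reports, exercising every pooling rule.
#'
#' @param params a [simulation_params()].
#' @return data.frame with columns `mirna`, `study`, `location`, `trend`.
#' @export
simulate_evidence <- function(params = simulation_params()) {
  ids <- sim_ids(params)$mirna
  n <- length(ids)
  n_pool <- min(4L, n)
  n_contra <- min(3L, max(0L, n - n_pool - 1L))
  n_single <- min(3L, max(0L, n - n_pool - n_contra))
  rows <- list()
  add <- function(mirna, study, trend) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mirna = mirna, study = study, location = "placenta", trend = trend)
  }
  for (i in seq_len(n)) {
    id <- ids[i]
    if (i <= n_pool) {
      add(id, "StudyA", "down"); add(id, "StudyB", "down")
    } else if (i <= n_pool + n_contra) {
      add(id, "StudyA", "up"); add(id, "StudyB", "down")
    } else if (i <= n_pool + n_contra + n_single) {
      add(id, "StudyC", if (i %% 2 == 0) "up" else "down")
    } else {
      tr <- if (i %% 2 == 0) "up" else "down"
      add(id, "StudyA", tr); add(id, "StudyB", tr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the miRNA-target interaction table
#'
#' Emits one lncRNA-miRNA and one miRNA-mRNA record per planted triangle,
#' plus `decoy_interactions` records that each violate at least one ceRNA
#' condition: a consensus miRNA targeting a non-differential lncRNA or
#' mRNA, a non-consensus miRNA targeting planted features, or a consensus
#' miRNA given only a lncRNA-side record (so the sharing condition prunes
#' it).
#'
#' @param params a [simulation_params()].
#' @param truth the `truth` element of [simulate_discovery_profile()].
#' @return list with `interactions` (the table) and `truth_edges` (the
#'   planted edge set the assembled network must recover exactly).
#' @export
simulate_interactions <- function(params, truth) {
  tri <- truth$triangles
  if (is.null(tri) || nrow(tri) == 0) {
    return(list(interactions = data.frame(mirna = character(), target = character(),
                                          target_class = character(),
                                          source = character()),
                truth_edges = data.frame(from = character(), to = character(),
                                         label = character())))
  }
  ids <- sim_ids(params)
  planted <- rbind(
    data.frame(mirna = tri$mirna, target = tri$lncrna, target_class = "lncRNA",
               source = "planted"),
    data.frame(mirna = tri$mirna, target = tri$mrna, target_class = "mRNA",
               source = "planted"))
  # decoy construction pools
  non_de_lnc <- setdiff(ids$lncrna, truth$de_lncrna$id)
  non_de_mrna <- setdiff(ids$mrna, truth$de_mrna$id)
  down_lnc <- truth$de_lncrna$id[truth$de_lncrna$trend == "down"]
  evid <- pool_mirna_evidence(simulate_evidence(params),
                              threshold_config(min_support = 2))
  consensus <- setdiff(evid$feature_id, truth$mirna_pool)
  lonely <- consensus[seq_along(consensus) %% 2 == 1L]   # lncRNA-side-only decoys
  paired <- setdiff(consensus, lonely)
  outside <- setdiff(ids$mirna, evid$feature_id)
  if (length(paired) == 0) paired <- consensus
  if (length(outside) == 0) outside <- "miR-unknown"
  decoys <- vector("list", params$decoy_interactions)
  for (j in seq_len(params$decoy_interactions)) {
    type <- (j - 1L) %% 4L
    decoys[[j]] <- switch(
      as.character(type),
      "0" = data.frame(mirna = paired[1 + (j %% length(paired))],
                       target = non_de_lnc[1 + (j %% length(non_de_lnc))],
                       target_class = "lncRNA", source = "decoy"),
      "1" = data.frame(mirna = paired[1 + (j %% length(paired))],
                       target = non_de_mrna[1 + (j %% length(non_de_mrna))],
                       target_class = "mRNA", source = "decoy"),
      "2" = data.frame(mirna = outside[1 + (j %% length(outside))],
                       target = tri$lncrna[1 + (j %% nrow(tri))],
                       target_class = "lncRNA", source = "decoy"),
      "3" = data.frame(mirna = lonely[1 + (j %% max(1L, length(lonely)))],
                       target = down_lnc[1 + (j %% max(1L, length(down_lnc)))],
                       target_class = "lncRNA", source = "decoy"))
  }
  tab <- validate_interaction_table(rbind(planted, do.call(rbind, decoys)))
  truth_edges <- unique(rbind(
    data.frame(from = tri$lncrna, to = tri$mirna, label = "lnc-mi"),
    data.frame(from = tri$mirna, to = tri$mrna, label = "mi-mrna")))
  list(interactions = tab, truth_edges = truth_edges)
}

#' Simulate the confidence-weighted PPI edge list
#'
#' Plants a clique (confidence 0.9) on the truth's clique members, a hub
#' spoke set from the first clique member to every triangle mRNA, sparse
#' Erdos-Renyi background edges (confidence uniform 0.41-0.9, a fraction
#' of them sub-threshold at < 0.4), over `n_ppi_nodes` mRNA nodes.
#'
#' @param params a [simulation_params()].
#' @param truth the `truth` element of [simulate_discovery_profile()].
#' @param nodes optional node set; defaults to the first `n_ppi_nodes`
#'   mRNA IDs (always including the planted members).
#' @return data.frame with columns `protein_a`, `protein_b`, `confidence`.
#' @export
simulate_ppi <- function(params, truth, nodes = NULL) {
  ids <- sim_ids(params)
  clique <- truth$ppi_clique
  if (length(clique) < params$ppi_clique_size) {
    stop_("planted clique larger than the available mRNA pool")
  }
  if (is.null(nodes)) {
    nodes <- unique(c(truth$triangles$mrna,
                      ids$mrna[seq_len(min(params$n_ppi_nodes, length(ids$mrna)))]))
    nodes <- nodes[seq_len(min(params$n_ppi_nodes, length(nodes)))]
    nodes <- unique(c(truth$triangles$mrna, nodes))
  }
  if (!all(clique %in% nodes)) stop_("clique members must be PPI nodes")
  with_seed(params$seed + 2L, {
    cl <- t(utils::combn(sort(clique), 2))
    edges <- data.frame(protein_a = cl[, 1], protein_b = cl[, 2], confidence = 0.9)
    spokes <- setdiff(intersect(truth$triangles$mrna, nodes),
                      c(truth$ppi_hub, clique))
    if (length(spokes) > 0) {
      edges <- rbind(edges, data.frame(protein_a = truth$ppi_hub,
                                       protein_b = spokes, confidence = 0.9))
    }
    if (length(nodes) >= 2 && params$ppi_background_p > 0) {
      all_pairs <- t(utils::combn(sort(nodes), 2))
      pick <- stats::runif(nrow(all_pairs)) < params$ppi_background_p
      bg <- all_pairs[pick, , drop = FALSE]
      if (nrow(bg) > 0) {
        conf <- stats::runif(nrow(bg), 0.41, 0.9)
        weak <- stats::runif(nrow(bg)) < params$ppi_weak_frac
        conf[weak] <- stats::runif(sum(weak), 0.05, 0.39)
        edges <- rbind(edges, data.frame(protein_a = bg[, 1], protein_b = bg[, 2],
                                         confidence = conf))
      }
    }
    rownames(edges) <- NULL
    edges
  })
}

#' Simulate the labelled validation cohort
#'
#' Labelled samples (`cohort_case` vs `cohort_control`) over the module
#' features plus exchangeable background features; module features are
#' separated between classes by `cohort_shift` within-class standard
#' deviations (miRNA-class module features shift down, the others up),
#' all on the log2 scale, exported linear.
#'
#' @param params a [simulation_params()].
#' @param module_features character vector of module feature IDs.
#' @param module_classes optional classes for the module features
#'   (defaults to inferring miRNAs from a `miR` prefix).
#' @return list with `profile` (an [expression_profile()]) and `truth`
#'   (the class labels).
#' @export
simulate_cohort <- function(params, module_features,
                            module_classes = NULL) {
  stopifnot(length(module_features) >= 1)
  if (is.null(module_classes)) {
    module_classes <- ifelse(grepl("^miR", module_features), "miRNA", "mRNA")
  }
  bg <- sprintf("BG%04d", seq_len(params$n_cohort_background))
  feats <- c(module_features, bg)
  cls <- stats::setNames(c(module_classes, rep("mRNA", length(bg))), feats)
  samples <- c(sprintf("V_GDM_%02d", seq_len(params$cohort_case)),
               sprintf("V_NGT_%02d", seq_len(params$cohort_control)))
  groups <- stats::setNames(c(rep("case", params$cohort_case),
                              rep("control", params$cohort_control)), samples)
  shift <- stats::setNames(rep(0, length(feats)), feats)
  sign_m <- ifelse(module_classes == "miRNA", -1, 1)
  shift[module_features] <- sign_m * params$cohort_shift * params$cohort_noise_sd
  vals <- with_seed(params$seed + 3L, {
    base <- stats::runif(length(feats), 4, 12)
    log2x <- base + matrix(stats::rnorm(length(feats) * length(samples), 0,
                                        params$cohort_noise_sd),
                           nrow = length(feats),
                           dimnames = list(feats, samples))
    log2x[, groups == "case"] <- log2x[, groups == "case"] + shift
    2^log2x
  })
  list(profile = expression_profile(vals, cls, groups),
       truth = list(labels = groups))
}

#' Simulate a gene-set collection for enrichment
#'
#' One set is the planted triangle mRNAs (over-represented by construction
#' in any query built from the recovered network), alongside random sets
#' drawn from the mRNA universe.
#'
#' @param params a [simulation_params()].
#' @param truth the `truth` element of [simulate_discovery_profile()].
#' @param n_random number of random background sets.
#' @param set_size size of each random set.
#' @return A [gene_set_collection()] with the full mRNA universe declared.
#' @export
simulate_gene_sets <- function(params, truth, n_random = 5L, set_size = 25L) {
  ids <- sim_ids(params)
  sets <- list(planted_triangle_genes = unique(truth$triangles$mrna))
  with_seed(params$seed + 4L, {
    for (i in seq_len(n_random)) {
      sets[[sprintf("random_set_%02d", i)]] <-
        sample(ids$mrna, min(set_size, length(ids$mrna)))
    }
  })
  gene_set_collection(sets,
                      descriptions = stats::setNames(
                        c("planted ceRNA triangle genes",
                          rep("random background set", n_random)), names(sets)),
                      universe = ids$mrna)
}

#' Write the full synthetic input bundle to a directory
#'
#' Generates and writes every file the pipeline consumes: discovery
#' expression TSV + metadata + feature classes, cohort TSV likewise,
#' interaction TSV, PPI edge TSV, evidence TSV, a GMT collection, and a
#' ground-truth JSON. Byte-reproducible for a fixed seed.
#'
#' @param params a [simulation_params()].
#' @param dir output directory (created if absent).
#' @param module_features features for the cohort matrix; defaults to the
#'   planted module configuration (first pair lncRNA + regulator, hub
#'   miRNA, hub mRNA).
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_bundle <- function(params = simulation_params(), dir,
                            module_features = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  disc <- simulate_discovery_profile(params)
  truth <- disc$truth
  inter <- simulate_interactions(params, truth)
  ppi <- simulate_ppi(params, truth)
  evid <- simulate_evidence(params)
  sets <- simulate_gene_sets(params, truth)
  if (is.null(module_features)) {
    module_features <- c(truth$m6a_pairs$lncrna[1], truth$m6a_pairs$regulator[1],
                         truth$mirna_pool[1], truth$ppi_hub)
  }
  cohort <- simulate_cohort(params, module_features)
  paths <- list(
    discovery_matrix = file.path(dir, "discovery_expression.tsv"),
    discovery_meta = file.path(dir, "discovery_samples.tsv"),
    discovery_features = file.path(dir, "discovery_features.tsv"),
    cohort_matrix = file.path(dir, "cohort_expression.tsv"),
    cohort_meta = file.path(dir, "cohort_samples.tsv"),
    cohort_features = file.path(dir, "cohort_features.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    evidence = file.path(dir, "mirna_evidence.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "ground_truth.json"))
  write_expression_profile(disc$profile, paths$discovery_matrix,
                           paths$discovery_meta, paths$discovery_features)
  write_expression_profile(cohort$profile, paths$cohort_matrix,
                           paths$cohort_meta, paths$cohort_features)
  utils::write.table(inter$interactions, paths$interactions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ppi, paths$ppi, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(evid, paths$evidence, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(sets, paths$gmt)
  jsonlite::write_json(
    list(de_lncrna = truth$de_lncrna, de_mrna = truth$de_mrna,
         m6a_pairs = truth$m6a_pairs, triangles = truth$triangles,
         mirna_pool = truth$mirna_pool, ppi_clique = truth$ppi_clique,
         ppi_hub = truth$ppi_hub, module_features = module_features,
         cohort_labels = as.list(cohort$truth$labels)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
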