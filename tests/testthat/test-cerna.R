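test_that("the minimal ceRNA motif assembles and its degrees are correct", {
  net <- minimal_motif()
  expect_equal(nrow(net$nodes), 4L)
  expect_equal(nrow(net$edges), 3L)
  tab <- node_degree_table(net)
  expect_equal(tab$id[1], "m1")
  expect_equal(tab$degree, c(3L, 1L, 1L, 1L))
  # handshake lemma
  expect_equal(sum(tab$degree), 2L * nrow(net$edges))
  expect_equal(top_degree_node(net, "miRNA"), "m1")
})

test_that("a miRNA lacking one side is pruned and its lncRNA orphaned", {
  dels <- data.frame(feature_id = "L1", feature_class = "lncRNA", trend = "up")
  demis <- data.frame(feature_id = "m1", feature_class = "miRNA", trend = "down")
  dems <- data.frame(feature_id = "G1", feature_class = "mRNA", trend = "up")
  inter <- data.frame(mirna = "m1", target = "L1", target_class = "lncRNA",
                      source = "x")
  net <- assemble_cerna(dels, demis, dems, inter)
  expect_equal(nrow(net$nodes), 0L)
  expect_equal(nrow(net$edges), 0L)
})

test_that("planted triangles are recovered exactly against decoys", {
  params <- simulation_params(seed = 31L)
  sim <- simulate_discovery_profile(params)
  inter <- simulate_interactions(params, sim$truth)
  td <- truth_differentials(sim$truth)
  demis <- pool_mirna_evidence(simulate_evidence(params), threshold_config())
  net <- assemble_cerna(td$dels, demis, td$dems, inter$interactions)
  got <- net$edges[, c("from", "to", "label")]
  want <- inter$truth_edges
  expect_setequal(paste(got$from, got$to, got$label),
                  paste(want$from, want$to, want$label))
  # node set = exactly the triangle participants
  tri <- sim$truth$triangles
  expect_setequal(net$nodes$id, unique(c(tri$lncrna, tri$mirna, tri$mrna)))
})

test_that("assembly output always satisfies the tripartite invariants", {
  set.seed(17)
  for (rep in 1:15) {
    n_l <- sample(2:5, 1); n_m <- sample(2:5, 1); n_g <- sample(2:6, 1)
    dels <- data.frame(feature_id = paste0("L", 1:n_l), feature_class = "lncRNA",
                       trend = sample(c("up", "down"), n_l, TRUE))
    demis <- data.frame(feature_id = paste0("m", 1:n_m), feature_class = "miRNA",
                        trend = sample(c("up", "down"), n_m, TRUE))
    dems <- data.frame(feature_id = paste0("G", 1:n_g), feature_class = "mRNA",
                       trend = sample(c("up", "down"), n_g, TRUE))
    k <- sample(5:15, 1)
    inter <- data.frame(
      mirna = sample(paste0("m", 1:(n_m + 2)), k, TRUE),
      target = sample(c(paste0("L", 1:(n_l + 2)), paste0("G", 1:(n_g + 2))), k, TRUE),
      source = "r")
    inter$target_class <- ifelse(grepl("^L", inter$target), "lncRNA", "mRNA")
    net <- assemble_cerna(dels, demis, dems, inter)
    expect_silent(m6acerna:::validate_cerna(net))
    # idempotence: reassembling from the network's own edges reproduces it
    if (nrow(net$edges) > 0) {
      own <- data.frame(
        mirna = ifelse(net$edges$label == "lnc-mi", net$edges$to, net$edges$from),
        target = ifelse(net$edges$label == "lnc-mi", net$edges$from, net$edges$to),
        source = "self")
      own$target_class <- ifelse(net$edges$label == "lnc-mi", "lncRNA", "mRNA")
      net2 <- assemble_cerna(dels, demis, dems, own)
      expect_equal(net2$edges[, c("from", "to", "label")],
                   net$edges[, c("from", "to", "label")])
    }
  }
})

test_that("trend enforcement only removes edges", {
  params <- simulation_params(seed = 37L)
  sim <- simulate_discovery_profile(params)
  inter <- simulate_interactions(params, sim$truth)
  td <- truth_differentials(sim$truth)
  demis <- pool_mirna_evidence(simulate_evidence(params), threshold_config())
  net_off <- assemble_cerna(td$dels, demis, td$dems, inter$interactions)
  net_on <- assemble_cerna(td$dels, demis, td$dems, inter$interactions,
                           enforce_trend = TRUE)
  key <- function(n) paste(n$edges$from, n$edges$to, n$edges$label)
  expect_true(all(key(net_on) %in% key(net_off)))
  # planted triangles are trend-opposed, so they all survive enforcement
  expect_setequal(key(net_on),
                  paste(inter$truth_edges$from, inter$truth_edges$to,
                        inter$truth_edges$label))
})

test_that("top-degree ties break lexicographically", {
  dels <- data.frame(feature_id = c("La", "Lb"), feature_class = "lncRNA",
                     trend = "up")
  demis <- data.frame(feature_id = "m1", feature_class = "miRNA", trend = "down")
  dems <- data.frame(feature_id = "G1", feature_class = "mRNA", trend = "up")
  inter <- data.frame(mirna = "m1", target = c("La", "Lb", "G1"),
                      target_class = c("lncRNA", "lncRNA", "mRNA"), source = "x")
  net <- assemble_cerna(dels, demis, dems, inter)
  expect_equal(top_degree_node(net, "lncRNA"), "La")
  expect_error(top_degree_node(net, "m6A-regulator"), "no node")
})

test_that("subnetwork extraction is a 2-hop closure from the seeds", {
  # two disjoint motifs
  dels <- data.frame(feature_id = c("L1", "L2"), feature_class = "lncRNA",
                     trend = "up")
  demis <- data.frame(feature_id = c("m1", "m2"), feature_class = "miRNA",
                      trend = "down")
  dems <- data.frame(feature_id = c("G1", "G2"), feature_class = "mRNA",
                     trend = "up")
  inter <- data.frame(
    mirna = c("m1", "m1", "m2", "m2"),
    target = c("L1", "G1", "L2", "G2"),
    target_class = c("lncRNA", "mRNA", "lncRNA", "mRNA"), source = "x")
  net <- assemble_cerna(dels, demis, dems, inter)
  sub <- extract_subnetwork(net, "L1")
  expect_setequal(sub$nodes$id, c("L1", "m1", "G1"))
  # seeding with every lncRNA returns the whole network
  all_sub <- extract_subnetwork(net, c("L1", "L2"))
  expect_equal(all_sub$edges, net$edges)
  expect_error(extract_subnetwork(net, "L9"), "L9")
})

test_that("subnetwork node counts match a breadth-limited traversal oracle", {
  params <- simulation_params(seed = 43L)
  sim <- simulate_discovery_profile(params)
  inter <- simulate_interactions(params, sim$truth)
  td <- truth_differentials(sim$truth)
  demis <- pool_mirna_evidence(simulate_evidence(params), threshold_config())
  net <- assemble_cerna(td$dels, demis, td$dems, inter$interactions)
  seeds <- sim$truth$m6a_pairs$lncrna
  seeds <- seeds[seeds %in% net$nodes$id]
  sub <- extract_subnetwork(net, seeds)
  # oracle: 2-hop BFS over the undirected edge list
  adj <- rbind(net$edges[, c("from", "to")],
               setNames(net$edges[, c("to", "from")], c("from", "to")))
  typ <- setNames(net$nodes$type, net$nodes$id)
  hop1 <- unique(adj$to[adj$from %in% seeds])          # miRNAs by construction
  hop2 <- unique(adj$to[adj$from %in% hop1])
  hop2 <- hop2[typ[hop2] == "mRNA"]                    # typed 2-hop closure
  expect_setequal(sub$nodes$id, union(seeds, union(hop1, hop2)))
})
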