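#' Construct a ceRNA network object
#'
#' Internal-facing constructor for the typed tripartite network. Nodes carry
#' a type (`lncRNA`, `miRNA`, `mRNA`, optionally `m6A-regulator` after
#' [attach_regulators()]) and a trend (`up`/`down`, `NA` for regulators);
#' edges are unordered and typed (`lnc-mi`, `mi-mrna`, `correlated`).
#'
#' @param nodes data.frame with columns `id`, `type`, `trend`.
#' @param edges data.frame with columns `from`, `to`, `label` (and
#'   optionally `pcc` for correlated edges).
#' @param check validate the tripartite/sharing invariants (default TRUE;
#'   regulator-annotated networks are exempt from the sharing check).
#' @return An object of class `cerna_network`.
#' @export
cerna_network <- function(nodes, edges, check = TRUE) {
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(edges) > 0) {
    edges <- edges[order(edges$label, edges$from, edges$to), , drop = FALSE]
  }
  rownames(edges) <- NULL
  net <- structure(list(nodes = nodes, edges = edges), class = "cerna_network")
  if (check) validate_cerna(net)
  net
}

validate_cerna <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  if (anyDuplicated(nodes$id)) stop_("duplicate node IDs in ceRNA network")
  typ <- stats::setNames(nodes$type, nodes$id)
  if (nrow(edges) > 0) {
    ft <- typ[edges$from]; tt <- typ[edges$to]
    ok <- (ft == "lncRNA" & tt == "miRNA" & edges$label == "lnc-mi") |
      (ft == "miRNA" & tt == "mRNA" & edges$label == "mi-mrna") |
      (tt == "m6A-regulator" & edges$label == "correlated")
    if (!all(ok)) stop_("ceRNA network has a non-tripartite or mislabelled edge")
  }
  core <- nodes$id[nodes$type %in% c("lncRNA", "miRNA", "mRNA")]
  deg <- cerna_degrees(net)
  orphan <- core[deg[core] == 0]
  if (length(orphan) > 0) stop_("orphan node(s) in ceRNA network: %s",
                                paste(utils::head(orphan, 5), collapse = ", "))
  for (m in nodes$id[nodes$type == "miRNA"]) {
    has_l <- any(edges$label == "lnc-mi" & edges$to == m)
    has_g <- any(edges$label == "mi-mrna" & edges$from == m)
    if (!has_l || !has_g) stop_("miRNA '%s' violates the ceRNA sharing condition", m)
  }
  invisible(net)
}

cerna_degrees <- function(net) {
  deg <- stats::setNames(integer(nrow(net$nodes)), net$nodes$id)
  if (nrow(net$edges) > 0) {
    tab <- table(c(net$edges$from, net$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

empty_cerna <- function() {
  cerna_network(
    data.frame(id = character(), type = character(), trend = character()),
    data.frame(from = character(), to = character(), label = character()),
    check = FALSE)
}

#' @export
print.cerna_network <- function(x, ...) {
  tt <- table(factor(x$nodes$type, levels = c("lncRNA", "miRNA", "mRNA", "m6A-regulator")))
  cat(sprintf("cerna_network: %d lncRNA, %d miRNA, %d mRNA, %d regulator nodes; %d edges\n",
              tt[["lncRNA"]], tt[["miRNA"]], tt[["mRNA"]], tt[["m6A-regulator"]],
              nrow(x$edges)))
  invisible(x)
}

#' Assemble the lncRNA-miRNA-mRNA ceRNA network
#'
#' Builds candidate lncRNA-miRNA edges from interactions whose miRNA is a
#' consensus DEMi and whose lncRNA-class target is a DEL, and candidate
#' miRNA-mRNA edges likewise from DEMs; then iteratively prunes miRNAs that
#' lack a neighbour on either side and orphaned lncRNA/mRNA nodes until the
#' sharing condition holds everywhere.
#'
#' @param dels,dems data.frames as returned by [screen_differential()]
#'   (columns `feature_id`, `trend`).
#' @param demis data.frame as returned by [pool_mirna_evidence()].
#' @param interactions interaction table (see [read_interaction_table()]).
#' @param enforce_trend if `TRUE`, keep a candidate edge only when the miRNA
#'   trend is opposite to its target's trend.
#' @return A `cerna_network`.
#' @export
assemble_cerna <- function(dels, demis, dems, interactions, enforce_trend = FALSE) {
  if (nrow(dels) == 0 || nrow(dems) == 0 || nrow(demis) == 0) {
    warning("empty DEL, DEM, or DEMi set: returning an empty ceRNA network")
    return(empty_cerna())
  }
  trend_of <- c(stats::setNames(dels$trend, dels$feature_id),
                stats::setNames(dems$trend, dems$feature_id),
                stats::setNames(demis$trend, demis$feature_id))
  it <- validate_interaction_table(interactions)
  keep_mi <- it$mirna %in% demis$feature_id
  is_l <- it$target_class == "lncRNA" & it$target %in% dels$feature_id
  is_g <- it$target_class == "mRNA" & it$target %in% dems$feature_id
  cand <- it[keep_mi & (is_l | is_g), , drop = FALSE]
  if (isTRUE(enforce_trend) && nrow(cand) > 0) {
    opp <- trend_of[cand$mirna] != trend_of[cand$target]
    cand <- cand[opp, , drop = FALSE]
  }
  if (nrow(cand) == 0) return(empty_cerna())
  edges <- data.frame(
    from = ifelse(cand$target_class == "lncRNA", cand$target, cand$mirna),
    to = ifelse(cand$target_class == "lncRNA", cand$mirna, cand$target),
    label = ifelse(cand$target_class == "lncRNA", "lnc-mi", "mi-mrna"))
  edges <- edges[!duplicated(paste(edges$from, edges$to, edges$label)), , drop = FALSE]

  # prune to the ceRNA fixed point
  repeat {
    mi <- unique(c(edges$to[edges$label == "lnc-mi"],
                   edges$from[edges$label == "mi-mrna"]))
    bad_mi <- mi[!(mi %in% edges$to[edges$label == "lnc-mi"] &
                     mi %in% edges$from[edges$label == "mi-mrna"])]
    if (length(bad_mi) == 0) break
    edges <- edges[!(edges$to %in% bad_mi & edges$label == "lnc-mi") &
                     !(edges$from %in% bad_mi & edges$label == "mi-mrna"), ,
                   drop = FALSE]
    if (nrow(edges) == 0) return(empty_cerna())
  }
  ids <- unique(c(edges$from, edges$to))
  mi <- unique(c(edges$to[edges$label == "lnc-mi"], edges$from[edges$label == "mi-mrna"]))
  lnc <- intersect(ids, dels$feature_id)
  gene <- intersect(ids, dems$feature_id)
  nodes <- rbind(
    data.frame(id = lnc, type = "lncRNA", trend = unname(trend_of[lnc])),
    data.frame(id = mi, type = "miRNA", trend = unname(trend_of[mi])),
    data.frame(id = gene, type = "mRNA", trend = unname(trend_of[gene])))
  cerna_network(nodes, edges)
}

#' Node degree table of a ceRNA network
#'
#' @param network a `cerna_network`.
#' @return data.frame with columns `id`, `type`, `degree`, `trend`, sorted
#'   by descending degree then ascending id.
#' @export
node_degree_table <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  deg <- cerna_degrees(network)
  out <- data.frame(id = network$nodes$id, type = network$nodes$type,
                    degree = as.integer(unname(deg[network$nodes$id])),
                    trend = network$nodes$trend)
  out <- out[order(-out$degree, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Highest-degree node of a given class
#'
#' Ties are broken by ascending lexicographic ID, making the choice
#' deterministic.
#'
#' @param network a `cerna_network`.
#' @param node_type one of `lncRNA`, `miRNA`, `mRNA`.
#' @return The node ID.
#' @export
top_degree_node <- function(network, node_type) {
  tab <- node_degree_table(network)
  tab <- tab[tab$type == node_type, , drop = FALSE]
  if (nrow(tab) == 0) stop_("network has no node of type '%s'", node_type)
  tab$id[1]
}

#' Extract the lncRNA-seeded ceRNA subnetwork
#'
#' Returns the induced subnetwork containing the seed lncRNAs, every miRNA
#' adjacent to a seed, and every mRNA adjacent to those miRNAs, with all
#' edges among the retained nodes.
#'
#' @param network a `cerna_network`.
#' @param seed_lncrnas character vector of lncRNA node IDs.
#' @return A `cerna_network`.
#' @export
extract_subnetwork <- function(network, seed_lncrnas) {
  stopifnot(inherits(network, "cerna_network"))
  lnc_ids <- network$nodes$id[network$nodes$type == "lncRNA"]
  missing <- setdiff(seed_lncrnas, lnc_ids)
  if (length(missing) > 0) {
    stop_("seed lncRNA(s) absent from network: %s", paste(missing, collapse = ", "))
  }
  e <- network$edges
  mi <- unique(e$to[e$label == "lnc-mi" & e$from %in% seed_lncrnas])
  g <- unique(e$to[e$label == "mi-mrna" & e$from %in% mi])
  keep <- c(seed_lncrnas, mi, g)
  sub_e <- e[(e$label == "lnc-mi" & e$from %in% seed_lncrnas & e$to %in% mi) |
               (e$label == "mi-mrna" & e$from %in% mi & e$to %in% g), , drop = FALSE]
  sub_n <- network$nodes[network$nodes$id %in% keep, , drop = FALSE]
  if (nrow(sub_e) == 0) return(empty_cerna())
  cerna_network(sub_n, sub_e)
}
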