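#' Filter a weighted PPI edge list into a network
#'
#' Keeps edges with confidence strictly above `ppi_conf`, drops self-loops,
#' collapses duplicate pairs keeping the maximum confidence, and drops
#' isolated nodes.
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`,
#'   `confidence` (0-1 scale).
#' @param config a [threshold_config()].
#' @param string_scale if `TRUE`, confidences are on the 0-1000 STRING
#'   export convention and are divided by 1000 at ingestion.
#' @return An undirected [igraph::graph] with a `confidence` edge attribute.
#' @export
filter_ppi <- function(edges, config = threshold_config(), string_scale = FALSE) {
  need <- c("protein_a", "protein_b", "confidence")
  if (!all(need %in% names(edges))) {
    stop_("PPI edge table needs columns: %s", paste(need, collapse = ", "))
  }
  conf <- as.numeric(edges$confidence)
  if (isTRUE(string_scale)) conf <- conf / 1000
  if (any(!is.finite(conf)) || any(conf < 0 | conf > 1)) {
    stop_("PPI confidences must lie in [0, 1]")
  }
  a <- as.character(edges$protein_a); b <- as.character(edges$protein_b)
  keep <- conf > config$ppi_conf & a != b
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  o <- order(key, -conf)
  first <- !duplicated(key[o])
  df <- data.frame(from = lo[o][first], to = hi[o][first],
                   confidence = conf[o][first])
  igraph::graph_from_data_frame(df, directed = FALSE)
}

# Highest k-core of a graph: the non-empty k-core with maximal k.
# Returns list(k, vids). Single vertices have k = 0.
highest_kcore <- function(g) {
  if (igraph::vcount(g) == 0) return(list(k = 0L, vids = integer(0)))
  core <- igraph::coreness(g)
  k <- max(core)
  list(k = k, vids = which(core >= k))
}

graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' For each vertex `v`, the induced subgraph on the closed neighbourhood of
#' `v` is reduced to its highest k-core; the weight of `v` is
#' `k * density(highest k-core)`. Isolated vertices have weight 0.
#'
#' @param network an undirected igraph (confidences, if present, are ignored).
#' @return Named numeric vector of vertex weights.
#' @export
mcode_vertex_weights <- function(network) {
  n <- igraph::vcount(network)
  w <- stats::setNames(numeric(n), igraph::V(network)$name)
  if (n == 0) return(w)
  for (i in seq_len(n)) {
    nb <- igraph::neighbors(network, i)
    if (length(nb) == 0) next
    sub <- igraph::induced_subgraph(network, c(i, nb))
    hk <- highest_kcore(sub)
    core <- igraph::induced_subgraph(sub, hk$vids)
    w[i] <- hk$k * graph_density(core)
  }
  w
}

#' MCODE dense-complex detection
#'
#' Seeds are unvisited vertices in descending weight order (vertices of
#' degree < 2 are given seed weight 0 and never start a complex); from each
#' seed, neighbours whose weight is at least `(1 - mcode_vwp) * seed weight`
#' are included transitively, never revisiting vertices across complexes.
#' With `haircut`, members with fewer than 2 intra-complex neighbours are
#' removed. Complexes of fewer than 2 connected members are discarded.
#' The complex score is `density * n`, the usual MCODE convention.
#'
#' @param network an undirected igraph.
#' @param config a [threshold_config()]; `mcode_vwp` is used.
#' @param haircut remove weakly attached members (default `TRUE`).
#' @param fluff not implemented beyond the default off (kept for interface
#'   parity with the original plug-in).
#' @return A list of complexes, each a list with `members` (character),
#'   `n`, `edges`, `density`, and `score`, sorted by descending score then
#'   size.
#' @export
mcode_find_complexes <- function(network, config = threshold_config(),
                                 haircut = TRUE, fluff = FALSE) {
  if (isTRUE(fluff)) stop_("fluff expansion is not implemented")
  n <- igraph::vcount(network)
  if (n == 0) return(list())
  w <- mcode_vertex_weights(network)
  deg <- igraph::degree(network)
  seed_w <- ifelse(deg < 2, 0, w)
  ord <- order(-seed_w, igraph::V(network)$name)
  visited <- rep(FALSE, n)
  complexes <- list()
  for (s in ord) {
    if (visited[s] || seed_w[s] <= 0) next
    thresh <- (1 - config$mcode_vwp) * w[s]
    members <- integer(0)
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (visited[v]) next
      visited[v] <- TRUE
      members <- c(members, v)
      nb <- as.integer(igraph::neighbors(network, v))
      nb <- nb[!visited[nb] & w[nb] >= thresh]
      queue <- c(queue, nb)
    }
    if (isTRUE(haircut) && length(members) > 1) {
      sub <- igraph::induced_subgraph(network, members)
      keep <- igraph::degree(sub) >= 2
      members <- members[keep]
    }
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(network, members)
    if (!igraph::is_connected(sub)) next
    dens <- graph_density(sub)
    complexes[[length(complexes) + 1]] <- list(
      members = sort(igraph::V(network)$name[members]),
      n = length(members),
      edges = igraph::ecount(sub),
      density = dens,
      score = dens * length(members))
  }
  if (length(complexes) == 0) return(complexes)
  o <- order(-vapply(complexes, `[[`, numeric(1), "score"),
             -vapply(complexes, `[[`, numeric(1), "n"),
             vapply(complexes, function(x) x$members[1], character(1)))
  complexes[o]
}

#' Degree hubs of a PPI network
#'
#' Nodes whose degree is at least `hub_min_degree` (inclusive), sorted by
#' descending degree then ascending ID.
#'
#' @param network an undirected igraph.
#' @param config a [threshold_config()].
#' @return data.frame with columns `gene`, `degree`.
#' @export
hub_genes <- function(network, config = threshold_config()) {
  deg <- igraph::degree(network)
  out <- data.frame(gene = igraph::V(network)$name, degree = as.integer(deg))
  out <- out[out$degree >= config$hub_min_degree, , drop = FALSE]
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full degree table of a PPI network
#'
#' @param network an undirected igraph.
#' @return data.frame with columns `gene`, `degree`, sorted by descending
#'   degree then ascending ID.
#' @export
ppi_degree_table <- function(network) {
  out <- data.frame(gene = igraph::V(network)$name,
                    degree = as.integer(igraph::degree(network)))
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a PPI edge TSV
#'
#' @param path TSV with columns `protein_a`, `protein_b`, `confidence`.
#' @return data.frame as read (unfiltered).
#' @export
read_ppi_edges <- function(path) {
  tab <- utils::read.delim(path)
  need <- c("protein_a", "protein_b", "confidence")
  if (!all(need %in% names(tab))) {
    stop_("PPI file needs columns: %s", paste(need, collapse = ", "))
  }
  tab
}
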