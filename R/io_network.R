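#' Export a ceRNA network
#'
#' Writes the network in one of three dialects: `SIF` (node, interaction
#' label, node), `GraphML` (with node `type`/`trend` and edge `label`/`pcc`
#' attributes), or `edge-TSV` (from, to, label, pcc).
#'
#' @param network a `cerna_network`.
#' @param path output file path.
#' @param dialect one of `"SIF"`, `"GraphML"`, `"edge-TSV"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(network, path, dialect = c("SIF", "GraphML", "edge-TSV")) {
  stopifnot(inherits(network, "cerna_network"))
  if (length(dialect) > 1) dialect <- dialect[1]
  if (!dialect %in% c("SIF", "GraphML", "edge-TSV")) {
    stop_("unknown network dialect: %s", dialect)
  }
  e <- network$edges
  if (dialect == "SIF") {
    lines <- if (nrow(e) > 0) sprintf("%s\t%s\t%s", e$from, e$label, e$to) else character()
    writeLines(lines, path)
  } else if (dialect == "edge-TSV") {
    out <- e
    if (!"pcc" %in% names(out)) out$pcc <- NA_real_
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- cerna_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a ceRNA network written by [export_network()]
#'
#' @param path file path.
#' @param dialect the dialect the file was written in.
#' @param nodes optional node table (`id`, `type`, `trend`) for the SIF and
#'   edge-TSV dialects, which do not carry node attributes themselves; if
#'   omitted, node types are inferred from the edge labels and trends are NA.
#' @return A `cerna_network`.
#' @export
import_network <- function(path, dialect = c("SIF", "GraphML", "edge-TSV"),
                           nodes = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "GraphML") {
    g <- igraph::read_graph(path, format = "graphml")
    return(igraph_to_cerna(g))
  }
  if (dialect == "SIF") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      e <- data.frame(from = character(), to = character(), label = character())
    } else {
      parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
      e <- data.frame(from = parts[, 1], to = parts[, 3], label = parts[, 2])
    }
  } else {
    e <- utils::read.delim(path, colClasses = c(from = "character", to = "character",
                                                label = "character"))
    if (all(is.na(e$pcc))) e$pcc <- NULL
  }
  if (is.null(nodes)) nodes <- infer_nodes_from_edges(e)
  cerna_network(nodes, e, check = FALSE)
}

infer_nodes_from_edges <- function(e) {
  ids <- character(); types <- character()
  add <- function(id, type) {
    new <- !(id %in% ids)
    ids <<- c(ids, id[new]); types <<- c(types, rep(type, sum(new)))
  }
  add(e$from[e$label == "lnc-mi"], "lncRNA")
  add(e$to[e$label == "lnc-mi"], "miRNA")
  add(e$from[e$label == "mi-mrna"], "miRNA")
  add(e$to[e$label == "mi-mrna"], "mRNA")
  add(e$from[e$label == "correlated"], "lncRNA")
  add(e$to[e$label == "correlated"], "m6A-regulator")
  data.frame(id = ids, type = types, trend = rep(NA_character_, length(ids)))
}

cerna_to_igraph <- function(network) {
  v <- network$nodes
  names(v)[names(v) == "id"] <- "name"
  e <- network$edges
  if (!"pcc" %in% names(e)) e$pcc <- NA_real_
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

igraph_to_cerna <- function(g) {
  v <- igraph::as_data_frame(g, what = "vertices")
  e <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(id = v$name, type = v$type,
                      trend = if ("trend" %in% names(v)) v$trend else NA_character_)
  edges <- data.frame(from = e$from, to = e$to, label = e$label)
  if ("pcc" %in% names(e) && !all(is.na(e$pcc))) edges$pcc <- e$pcc
  # GraphML loses edge orientation relative to our lnc->mi convention; restore it
  typ <- stats::setNames(nodes$type, nodes$id)
  flip <- (edges$label == "lnc-mi" & typ[edges$from] == "miRNA") |
    (edges$label == "mi-mrna" & typ[edges$from] == "mRNA") |
    (edges$label == "correlated" & typ[edges$from] == "m6A-regulator")
  tmp <- edges$from[flip]
  edges$from[flip] <- edges$to[flip]
  edges$to[flip] <- tmp
  cerna_network(nodes, edges, check = FALSE)
}
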