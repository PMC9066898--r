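#' The 21 m6A regulators
#'
#' The fixed catalogue of N6-methyladenosine regulators used by the
#' correlation screen: 8 writers (methyltransferase complex), 11 readers
#' (binding effectors), and 2 erasers (demethylases). Shipped as a packaged
#' TSV with a `role` column.
#'
#' @return data.frame with columns `gene`, `role`.
#' @export
m6a_regulators <- function() {
  path <- system.file("extdata", "m6a_regulators.tsv", package = "m6acerna",
                      mustWork = TRUE)
  reg <- utils::read.delim(path, colClasses = "character")
  stopifnot(nrow(reg) == 21L,
            identical(as.integer(table(reg$role)[c("writer", "reader", "eraser")]),
                      c(8L, 11L, 2L)))
  reg
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_("x and y must have equal length")
  if (length(x) < 3) stop_("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_("correlation undefined for a zero-variance vector")
  }
  stats::cor(x, y)
}

#' Two-sided P value for a Pearson correlation
#'
#' Uses the t transform `t = r * sqrt((n - 2) / (1 - r^2))` referred to a
#' t distribution with `n - 2` degrees of freedom; `|r| = 1` gives P = 0.
#'
#' @param r correlation coefficient, `|r| <= 1`.
#' @param n number of paired observations, `>= 3`.
#' @return Two-sided P value.
#' @export
pearson_p <- function(r, n) {
  if (n < 3) stop_("need n >= 3 for a correlation P value")
  if (abs(r) > 1) stop_("|r| must be <= 1")
  if (abs(r) == 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Screen lncRNAs for correlation with m6A regulators
#'
#' Tests every (DEL, regulator) pair by Pearson correlation across all
#' samples (both groups pooled); a pair is retained iff `|PCC| > pcc_cut`
#' and `P < pcc_alpha` (both strict). Regulators absent from the profile or
#' with constant expression are skipped with a warning.
#'
#' @param profile an [expression_profile()] containing the DEL rows and the
#'   regulator rows.
#' @param dels data.frame from [screen_differential()] (lncRNA rows are used).
#' @param regulators data.frame as from [m6a_regulators()].
#' @param config a [threshold_config()].
#' @param retain_only if `FALSE`, return all tested pairs with a `pass`
#'   column.
#' @return data.frame with columns `lncrna`, `regulator`, `pcc`, `p_value`,
#'   `n` (and `pass` when `retain_only = FALSE`).
#' @export
screen_m6a_lncrnas <- function(profile, dels, regulators = m6a_regulators(),
                               config = threshold_config(), retain_only = TRUE) {
  stopifnot(inherits(profile, "expression_profile"))
  n <- ncol(profile$values)
  if (n < 3) stop_("need at least 3 samples for the correlation screen")
  lnc <- dels$feature_id[dels$feature_class %in% "lncRNA"]
  lnc <- intersect(lnc, rownames(profile$values))
  regs <- intersect(regulators$gene, rownames(profile$values))
  absent <- setdiff(regulators$gene, regs)
  if (length(absent) > 0) {
    warning(sprintf("regulator(s) absent from profile, skipped: %s",
                    paste(absent, collapse = ", ")))
  }
  const <- regs[apply(profile$values[regs, , drop = FALSE], 1, stats::sd) == 0]
  if (length(const) > 0) {
    warning(sprintf("constant-expression regulator(s) skipped: %s",
                    paste(const, collapse = ", ")))
    regs <- setdiff(regs, const)
  }
  lnc <- lnc[apply(profile$values[lnc, , drop = FALSE], 1, stats::sd) > 0]
  if (length(lnc) > 0 && length(regs) > 0) {
    cm <- stats::cor(t(profile$values[lnc, , drop = FALSE]),
                     t(profile$values[regs, , drop = FALSE]))
    r <- as.vector(cm)  # column-major: lncRNA index varies fastest
    pv <- ifelse(abs(r) >= 1, 0,
                 2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2))
    out <- data.frame(lncrna = rep(lnc, times = length(regs)),
                      regulator = rep(regs, each = length(lnc)),
                      pcc = r, p_value = pv, n = n)
    out <- out[order(out$lncrna, out$regulator), , drop = FALSE]
  } else {
    out <- data.frame(lncrna = character(), regulator = character(),
                      pcc = numeric(), p_value = numeric(), n = integer())
  }
  out$pass <- abs(out$pcc) > config$pcc_cut & out$p_value < config$pcc_alpha
  if (retain_only) {
    out <- out[out$pass, , drop = FALSE]
    out$pass <- NULL
  }
  rownames(out) <- NULL
  out
}

#' Extract the four-node m6A-related module
#'
#' The module consists of (i) the highest-degree lncRNA among the network's
#' m6A-related lncRNAs, (ii) the highest-PPI-degree gene among the
#' network's mRNAs, (iii) a miRNA adjacent to both in the ceRNA network
#' (ties broken lexicographically), and (iv) the retained regulator with
#' the largest |PCC| for the chosen lncRNA.
#'
#' @param cerna a non-empty `cerna_network`.
#' @param ppi_degrees data.frame with columns `gene`, `degree` (e.g. from
#'   [ppi_degree_table()]).
#' @param correlations retained pairs from [screen_m6a_lncrnas()].
#' @return A list of class `m6a_module` with elements `lncrna`,
#'   `regulator`, `mirna`, `mrna`, `pcc`, `lncrna_cerna_degree`,
#'   `mrna_ppi_degree`.
#' @export
extract_m6a_module <- function(cerna, ppi_degrees, correlations) {
  stopifnot(inherits(cerna, "cerna_network"))
  if (nrow(cerna$nodes) == 0) stop_("ceRNA network is empty")
  if (nrow(correlations) == 0) stop_("no retained m6A correlations")
  deg_tab <- node_degree_table(cerna)
  lnc_tab <- deg_tab[deg_tab$type == "lncRNA" &
                       deg_tab$id %in% correlations$lncrna, , drop = FALSE]
  if (nrow(lnc_tab) == 0) stop_("no m6A-related lncRNA present in the ceRNA network")
  lnc <- lnc_tab$id[1]

  net_mrna <- cerna$nodes$id[cerna$nodes$type == "mRNA"]
  pd <- ppi_degrees[ppi_degrees$gene %in% net_mrna, , drop = FALSE]
  if (nrow(pd) == 0) stop_("PPI degree table covers no mRNA of the network")
  pd <- pd[order(-pd$degree, pd$gene), , drop = FALSE]
  gene <- pd$gene[1]

  e <- cerna$edges
  mi_l <- e$to[e$label == "lnc-mi" & e$from == lnc]
  mi_g <- e$from[e$label == "mi-mrna" & e$to == gene]
  shared <- sort(intersect(mi_l, mi_g))
  if (length(shared) == 0) {
    stop_("no miRNA shared between lncRNA '%s' and mRNA '%s'", lnc, gene)
  }
  cc <- correlations[correlations$lncrna == lnc, , drop = FALSE]
  cc <- cc[order(-abs(cc$pcc), cc$regulator), , drop = FALSE]
  structure(list(lncrna = lnc, regulator = cc$regulator[1], mirna = shared[1],
                 mrna = gene, pcc = cc$pcc[1],
                 lncrna_cerna_degree = lnc_tab$degree[1],
                 mrna_ppi_degree = pd$degree[1]),
            class = "m6a_module")
}

#' @export
print.m6a_module <- function(x, ...) {
  cat(sprintf(paste0("m6A-related module: lncRNA %s (ceRNA degree %d) / regulator %s ",
                     "(PCC %.3f) / miRNA %s / mRNA %s (PPI degree %d)\n"),
              x$lncrna, x$lncrna_cerna_degree, x$regulator, x$pcc,
              x$mirna, x$mrna, x$mrna_ppi_degree))
  invisible(x)
}

#' Attach correlated m6A regulators to a ceRNA subnetwork
#'
#' Adds one regulator node per retained (lncRNA, regulator) pair whose
#' lncRNA is in the subnetwork, with a `correlated` edge carrying the PCC.
#' Regulator nodes are typed `m6A-regulator`, distinct from mRNAs.
#'
#' @param subnetwork a `cerna_network`.
#' @param correlations retained pairs from [screen_m6a_lncrnas()].
#' @return A `cerna_network` with regulator nodes and `correlated` edges.
#' @export
attach_regulators <- function(subnetwork, correlations) {
  stopifnot(inherits(subnetwork, "cerna_network"))
  lnc <- subnetwork$nodes$id[subnetwork$nodes$type == "lncRNA"]
  cc <- correlations[correlations$lncrna %in% lnc, , drop = FALSE]
  if (nrow(cc) == 0) return(subnetwork)
  regs <- sort(unique(cc$regulator))
  nodes <- rbind(subnetwork$nodes,
                 data.frame(id = setdiff(regs, subnetwork$nodes$id),
                            type = "m6A-regulator", trend = NA_character_))
  e <- subnetwork$edges
  if (!"pcc" %in% names(e)) e$pcc <- NA_real_
  e <- rbind(e, data.frame(from = cc$lncrna, to = cc$regulator,
                           label = "correlated", pcc = cc$pcc))
  cerna_network(nodes, e, check = FALSE)
}
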