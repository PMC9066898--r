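#' Read a GMT gene-set file
#'
#' Standard tab-separated gene-set format: set name, description, then the
#' member gene IDs. Gene membership is parsed with [fgsea::gmtPathways()];
#' the description field is retained from a second pass over the lines.
#'
#' @param path GMT file path.
#' @param universe optional declared background universe; defaults to all
#'   genes appearing in any set.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  desc <- vapply(strsplit(lines, "\t", fixed = TRUE),
                 function(f) f[2], character(1))
  names(desc) <- vapply(strsplit(lines, "\t", fixed = TRUE),
                        function(f) f[1], character(1))
  gene_set_collection(sets, descriptions = desc[names(sets)], universe = universe)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene IDs), all non-empty.
#' @param descriptions optional named character vector of set descriptions.
#' @param universe optional background universe; when declared, every set
#'   must be a subset of it. Defaults to the union of all sets.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (length(sets) == 0 || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_("sets must be a non-empty named list")
  }
  if (any(lengths(sets) == 0)) stop_("every gene set must be non-empty")
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets)))
  } else {
    universe <- sort(unique(as.character(universe)))
    stray <- setdiff(unlist(sets), universe)
    if (length(stray) > 0) {
      stop_("set gene(s) outside the declared universe: %s",
            paste(utils::head(stray, 5), collapse = ", "))
    }
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions, universe = universe),
            class = "gene_set_collection")
}

#' Upper-tail hypergeometric P value
#'
#' `P(X >= k)` where `X` counts how many of `n` genes drawn without
#' replacement from a universe of `N` fall into a set of size `K`.
#'
#' @param k observed overlap count.
#' @param K set size.
#' @param n query size.
#' @param N universe size.
#' @return The over-representation P value.
#' @examples
#' hypergeometric_p(5, 5, 5, 10)  # 1/252
#' @export
hypergeometric_p <- function(k, K, n, N) {
  if (!(k >= 0 && k <= min(K, n) && K <= N && n <= N)) {
    stop_("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' One hypergeometric upper-tail test per set against the declared
#' universe; rows with raw P below `enrich_alpha` are retained (the raw-P
#' cutoff convention), with BH-adjusted P values reported alongside.
#'
#' @param query character vector of gene IDs; genes outside the universe
#'   are dropped with a warning.
#' @param sets a `gene_set_collection`.
#' @param config a [threshold_config()].
#' @param retain_only if `FALSE`, return all sets with a `retained` column.
#' @return data.frame with columns `set`, `description`, `k`, `K`, `n`,
#'   `N`, `p_raw`, `p_adj`, `overlap` (`;`-separated gene IDs), sorted by
#'   ascending P.
#' @export
overrepresentation <- function(query, sets, config = threshold_config(),
                               retain_only = TRUE) {
  stopifnot(inherits(sets, "gene_set_collection"))
  query <- unique(as.character(query))
  stray <- setdiff(query, sets$universe)
  if (length(stray) > 0) {
    warning(sprintf("%d query gene(s) outside the universe dropped", length(stray)))
    query <- setdiff(query, stray)
  }
  if (length(query) == 0) stop_("query is empty after universe filtering")
  N <- length(sets$universe)
  n <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    s <- sets$sets[[nm]]
    ov <- intersect(query, s)
    data.frame(set = nm, description = unname(sets$descriptions[nm]),
               k = length(ov), K = length(s), n = n, N = N,
               p_raw = hypergeometric_p(length(ov), length(s), n, N),
               overlap = paste(sort(ov), collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out <- out[order(out$p_raw, out$set), , drop = FALSE]
  retained <- out$p_raw < config$enrich_alpha
  if (retain_only) {
    out <- out[retained, , drop = FALSE]
  } else {
    out$retained <- retained
  }
  rownames(out) <- NULL
  out[, c("set", "description", "k", "K", "n", "N", "p_raw", "p_adj", "overlap",
          if (!retain_only) "retained")]
}

#' Write a gene-set collection to GMT
#'
#' @param sets a `gene_set_collection`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets$sets), function(nm) {
    paste(c(nm, sets$descriptions[nm], sets$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
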