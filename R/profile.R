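#' Expression profile container
#'
#' A features-by-samples matrix of non-negative linear-scale expression
#' values, together with a feature class for every row (`lncRNA`, `mRNA`,
#' `miRNA`, or `m6A-regulator`) and a group label for every column (`case`
#' or `control`).
#'
#' @param values numeric matrix, rows = features, columns = samples, with
#'   row and column names.
#' @param feature_class named character vector mapping every feature ID to
#'   one of `lncRNA`, `mRNA`, `miRNA`, `m6A-regulator`.
#' @param groups named character vector mapping every sample ID to `case`
#'   or `control`.
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(values, feature_class, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_("expression values must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) stop_("expression matrix needs row and column names")
  if (anyDuplicated(fid)) stop_("duplicate feature IDs: %s",
                                paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid)) stop_("duplicate sample IDs: %s",
                                paste(unique(sid[duplicated(sid)]), collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_("non-numeric or negative expression value at feature '%s', sample '%s'",
          fid[bad[1, 1]], sid[bad[1, 2]])
  }
  missing_f <- setdiff(fid, names(feature_class))
  if (length(missing_f) > 0) stop_("feature(s) without a class: %s",
                                   paste(utils::head(missing_f, 5), collapse = ", "))
  feature_class <- feature_class[fid]
  ok_classes <- c("lncRNA", "mRNA", "miRNA", "m6A-regulator")
  if (!all(feature_class %in% ok_classes)) {
    stop_("unknown feature class: %s",
          paste(setdiff(unique(feature_class), ok_classes), collapse = ", "))
  }
  missing_s <- setdiff(sid, names(groups))
  if (length(missing_s) > 0) stop_("sample(s) missing from metadata: %s",
                                   paste(missing_s, collapse = ", "))
  groups <- groups[sid]
  if (!all(groups %in% c("case", "control"))) {
    stop_("group labels must be 'case' or 'control', got: %s",
          paste(setdiff(unique(groups), c("case", "control")), collapse = ", "))
  }
  if (!all(c("case", "control") %in% groups)) stop_("both groups must be non-empty")
  structure(list(values = values, feature_class = feature_class, groups = groups),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("expression_profile: %d features x %d samples (%d case / %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  print(table(x$feature_class))
  invisible(x)
}

#' Read an expression profile from TSV files
#'
#' The matrix file is tab-separated with a `feature_id` first column and one
#' column per sample. The metadata file has columns `sample_id` and `group`;
#' the feature sidecar has columns `feature_id` and `class`.
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @param feature_path path to the feature-class sidecar TSV.
#' @param alias_path optional path to a two-column TSV (`alias`, `symbol`)
#'   applied to feature IDs at ingestion (approved-symbol normalisation).
#' @return An [expression_profile()].
#' @export
read_expression_profile <- function(matrix_path, metadata_path, feature_path,
                                    alias_path = NULL) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE, colClasses = "character")
  if (names(raw)[1] != "feature_id") stop_("matrix file must start with a 'feature_id' column")
  fid <- raw[[1]]
  num <- raw[, -1, drop = FALSE]
  vals <- suppressWarnings(vapply(num, as.numeric, numeric(nrow(num))))
  if (nrow(num) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(num)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(num) > 0 && length(bad) > 0 && nrow(bad) > 0) {
    stop_("non-numeric cell at feature '%s', column '%s'",
          fid[bad[1, 1]], colnames(vals)[bad[1, 2]])
  }
  rownames(vals) <- fid
  meta <- utils::read.delim(metadata_path, colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop_("metadata file needs columns sample_id and group")
  }
  feats <- utils::read.delim(feature_path, colClasses = "character")
  if (!all(c("feature_id", "class") %in% names(feats))) {
    stop_("feature file needs columns feature_id and class")
  }
  if (!is.null(alias_path)) {
    al <- utils::read.delim(alias_path, colClasses = "character")
    if (!all(c("alias", "symbol") %in% names(al))) {
      stop_("alias file needs columns alias and symbol")
    }
    map <- stats::setNames(al$symbol, al$alias)
    hit <- rownames(vals) %in% names(map)
    rownames(vals)[hit] <- unname(map[rownames(vals)[hit]])
    hitf <- feats$feature_id %in% names(map)
    feats$feature_id[hitf] <- unname(map[feats$feature_id[hitf]])
  }
  expression_profile(vals,
                     stats::setNames(feats$class, feats$feature_id),
                     stats::setNames(meta$group, meta$sample_id))
}

#' Write an expression profile to TSV files
#'
#' Inverse of [read_expression_profile()]; the three files round-trip the
#' profile exactly.
#'
#' @param profile an [expression_profile()].
#' @param matrix_path,metadata_path,feature_path output paths.
#' @return Invisibly, the three paths.
#' @export
write_expression_profile <- function(profile, matrix_path, metadata_path, feature_path) {
  stopifnot(inherits(profile, "expression_profile"))
  df <- data.frame(feature_id = rownames(profile$values), profile$values,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(profile$groups), group = unname(profile$groups)),
    metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature_id = names(profile$feature_class),
               class = unname(profile$feature_class)),
    feature_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, metadata_path, feature_path))
}

#' Read a miRNA-target interaction table
#'
#' Expects a TSV with columns `mirna`, `target`, `target_class` (`lncRNA` or
#' `mRNA`) and `source`. Duplicate (miRNA, target) pairs are collapsed into
#' one record with the source labels concatenated (`;`-separated).
#'
#' @param path path to the interaction TSV.
#' @return A data.frame with columns `mirna`, `target`, `target_class`,
#'   `source`, one row per unique pair.
#' @export
read_interaction_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("mirna", "target", "target_class", "source")
  if (!all(need %in% names(tab))) {
    stop_("interaction file needs columns: %s", paste(need, collapse = ", "))
  }
  validate_interaction_table(tab[need])
}

#' Validate and deduplicate an interaction table
#'
#' @param tab data.frame with columns `mirna`, `target`, `target_class`, `source`.
#' @return The validated, deduplicated table.
#' @export
validate_interaction_table <- function(tab) {
  if (nrow(tab) == 0) {
    return(data.frame(mirna = character(), target = character(),
                      target_class = character(), source = character()))
  }
  bad <- setdiff(unique(tab$target_class), c("lncRNA", "mRNA"))
  if (length(bad) > 0) stop_("unknown target_class: %s", paste(bad, collapse = ", "))
  cls <- tapply(tab$target_class, tab$target, function(v) length(unique(v)))
  if (any(cls > 1)) {
    stop_("target(s) assigned to two classes: %s",
          paste(names(cls)[cls > 1], collapse = ", "))
  }
  key <- paste(tab$mirna, tab$target, sep = "\r")
  src <- tapply(tab$source, key, function(s) paste(sort(unique(s)), collapse = ";"))
  first <- tab[!duplicated(key), , drop = FALSE]
  first$source <- unname(src[paste(first$mirna, first$target, sep = "\r")])
  rownames(first) <- NULL
  first
}
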