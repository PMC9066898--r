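#' Log2 fold change between two groups
#'
#' `log2((mean(case) + pseudocount) / (mean(control) + pseudocount))`, the
#' ratio-of-means fold change used by the differential screen.
#'
#' @param case_values,control_values non-negative numeric vectors.
#' @param pseudocount small non-negative constant added to both means.
#' @return The log2 fold change (case vs control).
#' @examples
#' log2_fold_change(c(8, 8), c(2, 2))  # 2
#' @export
log2_fold_change <- function(case_values, control_values, pseudocount = 1) {
  if (length(case_values) == 0 || length(control_values) == 0) {
    stop_("both groups must be non-empty")
  }
  stopifnot(all(case_values >= 0), all(control_values >= 0), pseudocount >= 0)
  log2((mean(case_values) + pseudocount) / (mean(control_values) + pseudocount))
}

#' Benjamini-Hochberg adjusted P values
#'
#' Step-up false-discovery-rate adjustment; output order matches input
#' order and values are capped at 1.
#'
#' @param p_values numeric vector of P values in `[0, 1]`.
#' @return Adjusted P values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_("P values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Vectorised Welch two-sample t test on the rows of two matrices
# (log2-scale values). Returns raw two-sided P values. Degenerate rows
# (zero variance in both groups): p = 1 when the means agree, 0 otherwise.
welch_row_p <- function(case_mat, ctrl_mat) {
  n1 <- ncol(case_mat); n2 <- ncol(ctrl_mat)
  m1 <- rowMeans(case_mat); m2 <- rowMeans(ctrl_mat)
  v1 <- apply(case_mat, 1, stats::var); v2 <- apply(ctrl_mat, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(NA_real_, length(m1))
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  ok <- !degen
  tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(-abs(tstat), df)
  p
}

#' Screen differentially expressed features
#'
#' Per feature: ratio-of-means log2 fold change on the linear scale, a
#' Welch unequal-variance t test on `log2(value + pseudocount)`, and BH
#' adjustment applied within each feature class separately (lncRNAs and
#' mRNAs are screened as separate families). A feature is retained iff
#' `|log2FC| > lfc_cut` and `p_adj < de_alpha` (both strict).
#'
#' @param profile an [expression_profile()] with at least 2 samples per group.
#' @param config a [threshold_config()].
#' @param pseudocount constant for the log transform and fold change.
#' @param classes feature classes to screen (default lncRNA and mRNA).
#' @param retain_only if `FALSE`, return statistics for every screened
#'   feature with a logical `retained` column.
#' @return data.frame with columns `feature_id`, `feature_class`, `log2fc`,
#'   `p_raw`, `p_adj`, `trend` (`up`/`down`), and `retained` when
#'   `retain_only = FALSE`.
#' @export
screen_differential <- function(profile, config = threshold_config(),
                                pseudocount = 1,
                                classes = c("lncRNA", "mRNA"),
                                retain_only = TRUE) {
  stopifnot(inherits(profile, "expression_profile"))
  case_id <- names(profile$groups)[profile$groups == "case"]
  ctrl_id <- names(profile$groups)[profile$groups == "control"]
  if (length(case_id) < 2 || length(ctrl_id) < 2) {
    stop_("need at least 2 samples per group for the differential screen")
  }
  keep <- names(profile$feature_class)[profile$feature_class %in% classes]
  if (length(keep) == 0) {
    out <- data.frame(feature_id = character(), feature_class = character(),
                      log2fc = numeric(), p_raw = numeric(), p_adj = numeric(),
                      trend = character())
    if (!retain_only) out$retained <- logical()
    return(out)
  }
  vals <- profile$values[keep, , drop = FALSE]
  case <- vals[, case_id, drop = FALSE]
  ctrl <- vals[, ctrl_id, drop = FALSE]
  lfc <- log2((rowMeans(case) + pseudocount) / (rowMeans(ctrl) + pseudocount))
  p_raw <- welch_row_p(log2(case + pseudocount), log2(ctrl + pseudocount))
  cls <- unname(profile$feature_class[keep])
  p_adj <- stats::ave(p_raw, cls, FUN = bh_adjust)
  out <- data.frame(feature_id = keep, feature_class = cls, log2fc = lfc,
                    p_raw = p_raw, p_adj = p_adj,
                    trend = ifelse(lfc > 0, "up", "down"),
                    row.names = NULL)
  retained <- abs(out$log2fc) > config$lfc_cut & out$p_adj < config$de_alpha
  if (retain_only) {
    out <- out[retained, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    out$retained <- retained
    out
  }
}

#' Pool literature miRNA evidence into a consensus dysregulated list
#'
#' Evidence records are grouped by miRNA. A miRNA reported both up and down
#' across records is excluded as contradictory; a consistent miRNA is
#' retained with its shared trend when it has at least `min_support`
#' supporting records.
#'
#' @param evidence data.frame with columns `mirna`, `study`, `location`,
#'   `trend`. Trends may be written `up`/`down`, `+`/`-`, or the en-dash
#'   variants found in published tables.
#' @param config a [threshold_config()]; `min_support` is used.
#' @return data.frame with columns `feature_id`, `feature_class`
#'   (`"miRNA"`), `trend`, `n_support` — the consensus DEMi list.
#' @export
pool_mirna_evidence <- function(evidence, config = threshold_config()) {
  need <- c("mirna", "study", "trend")
  if (!all(need %in% names(evidence))) {
    stop_("evidence table needs columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(evidence) == 0) {
    return(data.frame(feature_id = character(), feature_class = character(),
                      trend = character(), n_support = integer()))
  }
  tr <- normalise_trend(evidence$trend)
  key <- paste(evidence$mirna, evidence$study, sep = "\r")
  if (anyDuplicated(key)) {
    stop_("duplicate (mirna, study) evidence records: %s",
          paste(unique(evidence$mirna[duplicated(key)]), collapse = ", "))
  }
  ids <- sort(unique(evidence$mirna))
  rows <- lapply(ids, function(id) {
    tri <- tr[evidence$mirna == id]
    if (length(unique(tri)) > 1) return(NULL)          # contradictory: excluded
    if (length(tri) < config$min_support) return(NULL) # insufficient support
    data.frame(feature_id = id, feature_class = "miRNA",
               trend = tri[1], n_support = length(tri))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature_id = character(), feature_class = character(),
                      trend = character(), n_support = integer())
  }
  rownames(out) <- NULL
  out
}

normalise_trend <- function(x) {
  x <- trimws(x)
  up <- x %in% c("up", "Up", "UP", "+")
  dn <- x %in% c("down", "Down", "DOWN", "-", "–", "−")
  if (any(!up & !dn)) {
    stop_("unrecognised trend value(s): %s",
          paste(unique(x[!up & !dn]), collapse = ", "))
  }
  ifelse(up, "up", "down")
}

#' Packaged literature miRNA evidence table
#'
#' The curated table of placenta-associated miRNA dysregulation reports in
#' gestational diabetes (study, miRNA, tissue, trend) shipped with the
#' package, in the layout accepted by [pool_mirna_evidence()].
#'
#' @return data.frame with columns `mirna`, `study`, `location`, `trend`.
#' @export
gdm_mirna_evidence <- function() {
  path <- system.file("extdata", "gdm_mirna_evidence.tsv", package = "m6acerna",
                      mustWork = TRUE)
  utils::read.delim(path, colClasses = "character")
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes `dCt = Ct(target) - Ct(reference)` within case and control and
#' returns `2^-(dCt_case - dCt_control)`, the fold change of the target in
#' case relative to control after reference-gene normalisation.
#'
#' @param ct_target_case,ct_ref_case,ct_target_control,ct_ref_control
#'   finite threshold-cycle values (cycles).
#' @return Fold change (dimensionless).
#' @examples
#' ddct_fold_change(20, 15, 24, 16)  # 8
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    stop_("Ct values must be finite and positive")
  }
  d_case <- ct_target_case - ct_ref_case
  d_ctrl <- ct_target_control - ct_ref_control
  2^-(d_case - d_ctrl)
}
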