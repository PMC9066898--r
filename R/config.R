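#' Pipeline threshold configuration
#'
#' Collects every screening cutoff used by the pipeline in one validated
#' object. Defaults are the conventional published values for this type of
#' analysis: an absolute log2 fold-change cutoff of 1 with BH-adjusted
#' significance 0.05 for the differential screen, at least 2 supporting
#' experiments for a pooled literature miRNA, |PCC| > 0.9 with P < 0.01 for
#' the m6A-regulator correlation screen, PPI edge confidence > 0.4, a hub
#' degree cutoff of 15 (inclusive, so that degree-15 genes are hubs), an
#' MCODE vertex weight percentage of 0.2, and a raw enrichment P cutoff of
#' 0.05.
#'
#' @param lfc_cut absolute log2 fold-change cutoff (strict `>`).
#' @param de_alpha BH-adjusted P cutoff for the differential screen (strict `<`).
#' @param min_support minimum supporting evidence records for a pooled miRNA.
#' @param pcc_cut absolute Pearson correlation cutoff (strict `>`).
#' @param pcc_alpha correlation P cutoff (strict `<`).
#' @param ppi_conf minimum PPI edge confidence (strict `>`).
#' @param hub_min_degree hub-gene degree cutoff (inclusive `>=`).
#' @param mcode_vwp MCODE vertex weight percentage in `[0, 1)`.
#' @param enrich_alpha raw enrichment P cutoff (strict `<`).
#' @param seed integer random seed used by seeded stages.
#' @return An object of class `threshold_config` (a named list).
#' @examples
#' cfg <- threshold_config(hub_min_degree = 10)
#' cfg$hub_min_degree
#' @export
threshold_config <- function(lfc_cut = 1,
                             de_alpha = 0.05,
                             min_support = 2L,
                             pcc_cut = 0.9,
                             pcc_alpha = 0.01,
                             ppi_conf = 0.4,
                             hub_min_degree = 15L,
                             mcode_vwp = 0.2,
                             enrich_alpha = 0.05,
                             seed = 1L) {
  cfg <- list(
    lfc_cut = lfc_cut, de_alpha = de_alpha, min_support = as.integer(min_support),
    pcc_cut = pcc_cut, pcc_alpha = pcc_alpha, ppi_conf = ppi_conf,
    hub_min_degree = as.integer(hub_min_degree), mcode_vwp = mcode_vwp,
    enrich_alpha = enrich_alpha, seed = as.integer(seed)
  )
  validate_threshold_config(cfg)
  structure(cfg, class = "threshold_config")
}

validate_threshold_config <- function(cfg) {
  chk <- function(ok, what) if (!isTRUE(ok)) stop_("invalid threshold_config: %s", what)
  chk(cfg$lfc_cut >= 0, "lfc_cut must be >= 0")
  for (a in c("de_alpha", "pcc_alpha", "enrich_alpha")) {
    chk(cfg[[a]] > 0 && cfg[[a]] < 1, sprintf("%s must be in (0, 1)", a))
  }
  chk(cfg$pcc_cut > 0 && cfg$pcc_cut <= 1, "pcc_cut must be in (0, 1]")
  chk(cfg$ppi_conf >= 0 && cfg$ppi_conf <= 1, "ppi_conf must be in [0, 1]")
  chk(cfg$mcode_vwp >= 0 && cfg$mcode_vwp < 1, "mcode_vwp must be in [0, 1)")
  chk(cfg$min_support >= 1L, "min_support must be >= 1")
  chk(cfg$hub_min_degree >= 0L, "hub_min_degree must be >= 0")
  chk(is.finite(cfg$seed), "seed must be finite")
  invisible(cfg)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("Pipeline thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
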