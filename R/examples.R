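#' Known ETT/ARF4 target patterns
#'
#' A small curated table of Arabidopsis genes with published ETT/ARF4
#' regulation patterns in the gynoecium, encoded as per-contrast log2 fold
#' changes and significance flags. Ten genes (CLE19, NTT, YAB5, FAMA, YAB2,
#' ATMYC1, TAA1, ATHB-51, WOX9, TMM) are redundantly regulated: significant
#' only in the double mutant, in both treatments. Eight genes (CRC, AGO9,
#' STK, ELIP1, SAUR63, JAG, ELIP2, IND) are ETT-specific: significant in
#' ett and in the double mutant in both treatments. None is
#' auxin-responsive. CRC illustrates the twofold inclusion rule: its ett
#' change (-0.44) is sub-twofold but its double-mutant change (-1.12)
#' qualifies it.
#'
#' @return data.frame with columns \code{gene_id}, \code{name},
#'   \code{expected_label}, the six genotype-vs-WT log2FCs
#'   (\code{lfc_<contrast>}) and significance flags
#'   (\code{sig_<contrast>}).
#' @export
example_target_patterns <- function() {
  redundant <- data.frame(
    gene_id = c("AT3G24225", "AT3G57670", "AT2G26580", "AT3G24140",
                "AT1G08465", "AT4G00480", "AT1G70560", "AT5G03790",
                "AT2G33880", "AT1G80080"),
    name = c("CLE19", "NTT", "YAB5", "FAMA", "YAB2", "ATMYC1", "TAA1",
             "ATHB-51", "WOX9", "TMM"),
    lfc_double_mock = c(2.39, 1.01, -1.6, 1.66, -1.94, -1.29, 1.61, 1.15,
                        1.66, -1.04),
    lfc_double_IAA = c(2.27, 1.22, -1.7, 1.57, -2.04, -1.46, 1.34, 1.13,
                       1.90, -1.09),
    stringsAsFactors = FALSE
  )
  ett_specific <- data.frame(
    gene_id = c("AT1G69180", "AT5G21150", "AT4G09960", "AT3G22840",
                "AT1G29440", "AT1G68480", "AT4G14690", "AT4G00120"),
    name = c("CRC", "AGO9", "STK", "ELIP1", "SAUR63", "JAG", "ELIP2", "IND"),
    lfc_ett_mock = c(-0.44, -1.87, -0.60, 1.63, -1.18, -0.96, 1.54, -2.82),
    lfc_ett_IAA = c(-0.42, -1.78, -0.68, 1.75, -1.43, -0.72, 1.13, -1.38),
    lfc_double_mock = c(-1.12, -0.82, 1.27, 1.41, -1.08, -2.97, 1.56, -3.03),
    lfc_double_IAA = c(-1.02, -0.83, 1.21, 1.35, -1.15, -1.88, 1.14, -3.61),
    stringsAsFactors = FALSE
  )
  mk <- function(df, label, sig_ett) {
    out <- data.frame(
      gene_id = df$gene_id, name = df$name, expected_label = label,
      lfc_ett_vs_WT_mock = if (sig_ett) df$lfc_ett_mock else 0,
      lfc_ett_vs_WT_IAA = if (sig_ett) df$lfc_ett_IAA else 0,
      lfc_arf4_vs_WT_mock = 0, lfc_arf4_vs_WT_IAA = 0,
      lfc_ett_arf4_vs_WT_mock = df$lfc_double_mock,
      lfc_ett_arf4_vs_WT_IAA = df$lfc_double_IAA,
      sig_ett_vs_WT_mock = sig_ett, sig_ett_vs_WT_IAA = sig_ett,
      sig_arf4_vs_WT_mock = FALSE, sig_arf4_vs_WT_IAA = FALSE,
      sig_ett_arf4_vs_WT_mock = TRUE, sig_ett_arf4_vs_WT_IAA = TRUE,
      stringsAsFactors = FALSE
    )
    out
  }
  rbind(mk(redundant, "redundant", FALSE),
        mk(ett_specific, "ETT_specific", TRUE))
}

#' Encode significance patterns as classifier-ready contrast tables
#'
#' Turns a pattern table (per-contrast log2FC and significance flags, as in
#' [example_target_patterns()]) into the ten contrast tables the classifiers
#' consume: significant entries get padj = \code{sig_padj}, the rest
#' \code{ns_padj}. Auxin-response contrasts absent from the pattern table
#' are filled as non-significant with zero fold change.
#'
#' @param patterns data.frame with \code{gene_id} plus \code{lfc_<contrast>}
#'   and \code{sig_<contrast>} columns for any of the ten canonical
#'   contrasts.
#' @param sig_padj,ns_padj Adjusted p assigned to significant /
#'   non-significant entries (defaults 0.001 and 0.9).
#' @return Named list of ten contrast tables.
#' @export
patterns_to_contrasts <- function(patterns, sig_padj = 0.001, ns_padj = 0.9) {
  stopifnot("gene_id" %in% names(patterns))
  all_names <- c(GENOTYPE_CONTRASTS, AUXIN_CONTRASTS)
  out <- lapply(stats::setNames(all_names, all_names), function(nm) {
    lfc_col <- paste0("lfc_", nm)
    sig_col <- paste0("sig_", nm)
    lfc <- if (lfc_col %in% names(patterns)) patterns[[lfc_col]] else 0
    sig <- if (sig_col %in% names(patterns)) patterns[[sig_col]] else FALSE
    padj <- ifelse(sig, sig_padj, ns_padj)
    data.frame(
      gene_id = patterns$gene_id,
      baseMean = 100,
      log2FC = lfc,
      stat = 0,
      pvalue = padj,
      padj = padj,
      stringsAsFactors = FALSE
    )
  })
  out
}
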