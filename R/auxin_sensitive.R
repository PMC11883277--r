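#' Build the four within-genotype auxin-response DEG lists
#'
#' One list per genotype (WT, ett, arf4, double) from the IAA-vs-mock
#' contrasts, with \code{padj < fdr} and, when \code{apply_lfc_gate} is TRUE
#' (default), \code{|log2FC| > lfc}. The fold gate is a flag so the analysis
#' can also be run on significance alone.
#'
#' @param contrasts Named list of the four auxin-response contrast tables
#'   (names \code{AUXIN_CONTRASTS}).
#' @param fdr Adjusted-p threshold (default 0.05).
#' @param lfc Log2 fold-change gate (default 1).
#' @param apply_lfc_gate Apply the fold gate (default TRUE).
#' @return Named list of four [deg_set()]s, names \code{WT}, \code{ett},
#'   \code{arf4}, \code{double}.
#' @export
build_four_lists <- function(contrasts, fdr = 0.05, lfc = 1,
                             apply_lfc_gate = TRUE) {
  if (!setequal(names(contrasts), AUXIN_CONTRASTS)) {
    stop("contrasts must be named: ", paste(AUXIN_CONTRASTS, collapse = ", "))
  }
  genos <- c(WT = "IAA_vs_mock_WT", ett = "IAA_vs_mock_ett",
             arf4 = "IAA_vs_mock_arf4", double = "IAA_vs_mock_ett_arf4")
  lapply(genos, function(nm) {
    deg_set(contrasts[[nm]], fdr = fdr,
            lfc = if (apply_lfc_gate) lfc else NULL, contrast = nm)
  })
}

# The three highlighted A-B ARF antagonism models, keyed by the four-way
# Venn segment (bitmask order WT, ett, arf4, double) predicted by each:
#  - redundant_prevention: auxin-sensitive only in the double mutant;
#  - heterodimer: auxin-sensitive in all three mutants but not WT;
#  - ARF4_specific_prevention: auxin-sensitive in arf4 and the double, not
#    WT and (strict reading) not ett.
ANTAGONISM_MODELS <- c(
  redundant_prevention = "double",
  heterodimer = "ett+arf4+double",
  ARF4_specific_prevention = "arf4+double"
)

#' Score conformance to A-B ARF antagonism models
#'
#' For each highlighted model segment of the four-way auxin-response
#' partition, tallies member genes and how many conform to the model's
#' predicted behaviour: auxin-insensitive in WT (guaranteed by the segment)
#' and UPregulated upon auxin in every member genotype. Genes whose member
#' directions disagree are counted in \code{n_total} and flagged discordant,
#' excluded from both the up and down tallies.
#'
#' @param partition A four-way \code{venn_partition} from
#'   [four_way_partition()].
#' @param strict_arf4_prevention If TRUE (default), the ARF4-specific
#'   prevention model counts only the \code{arf4+double} segment; if FALSE
#'   it additionally admits \code{ett+arf4+double} (permissive reading).
#' @return List with \code{models} (data.frame: model, segment, n_total,
#'   n_up, n_down, n_discordant, n_conforming) and \code{genes} (per-gene
#'   model membership, directions and conformance flag).
#' @export
score_antagonism <- function(partition, strict_arf4_prevention = TRUE) {
  sn <- attr(partition, "set_names")
  if (!identical(sn, c("WT", "ett", "arf4", "double"))) {
    stop("partition must be a four-way partition over WT, ett, arf4, double")
  }
  model_segments <- lapply(ANTAGONISM_MODELS, identity)
  if (!strict_arf4_prevention) {
    model_segments$ARF4_specific_prevention <-
      c("arf4+double", "ett+arf4+double")
  }
  dirs <- as.matrix(partition[paste0("dir_", sn)])
  genes_out <- list()
  rows <- lapply(names(model_segments), function(model) {
    segs <- model_segments[[model]]
    in_model <- partition$segment %in% segs
    n_total <- sum(in_model)
    if (n_total == 0) {
      genes_out[[model]] <<- NULL
      return(data.frame(model = model, segment = paste(segs, collapse = "|"),
                        n_total = 0L, n_up = 0L, n_down = 0L,
                        n_discordant = 0L, n_conforming = 0L,
                        stringsAsFactors = FALSE))
    }
    d <- dirs[in_model, , drop = FALSE]
    all_up <- apply(d, 1, function(x) all(x[!is.na(x)] == 1L))
    all_down <- apply(d, 1, function(x) all(x[!is.na(x)] == -1L))
    discordant <- !all_up & !all_down
    genes_out[[model]] <<- data.frame(
      gene_id = partition$gene_id[in_model],
      segment = partition$segment[in_model],
      model = model,
      dir_WT = d[, "dir_WT"], dir_ett = d[, "dir_ett"],
      dir_arf4 = d[, "dir_arf4"], dir_double = d[, "dir_double"],
      discordant = discordant,
      conforming = all_up,
      stringsAsFactors = FALSE
    )
    data.frame(model = model, segment = paste(segs, collapse = "|"),
               n_total = n_total, n_up = sum(all_up),
               n_down = sum(all_down), n_discordant = sum(discordant),
               n_conforming = sum(all_up), stringsAsFactors = FALSE)
  })
  list(models = do.call(rbind, rows),
       genes = do.call(rbind, genes_out))
}

#' Full auxin-sensitive target analysis
#'
#' Chains [build_four_lists()], [four_way_partition()] and
#' [score_antagonism()].
#'
#' @param contrasts Named list containing the four auxin-response contrast
#'   tables (as from [run_contrasts()]).
#' @param fdr,lfc,apply_lfc_gate Passed to [build_four_lists()].
#' @param strict_arf4_prevention Passed to [score_antagonism()].
#' @return List with \code{partition}, \code{conformance} and
#'   \code{deg_sets}.
#' @export
auxin_sensitive_analysis <- function(contrasts, fdr = 0.05, lfc = 1,
                                     apply_lfc_gate = TRUE,
                                     strict_arf4_prevention = TRUE) {
  four <- build_four_lists(contrasts[AUXIN_CONTRASTS], fdr = fdr, lfc = lfc,
                           apply_lfc_gate = apply_lfc_gate)
  part <- four_way_partition(four$WT, four$ett, four$arf4, four$double)
  conf <- score_antagonism(part,
                           strict_arf4_prevention = strict_arf4_prevention)
  list(partition = part, conformance = conf, deg_sets = four)
}
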