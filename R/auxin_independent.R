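#' Build the six genotype-vs-WT DEG lists
#'
#' Membership in each list requires \code{padj < fdr} in that contrast.
#' A global inclusion filter then keeps only genes at least twofold up- or
#' downregulated in at least one background: \code{|log2FC| > lfc} in at
#' least one of the six contrasts (significant or not). A gene significant
#' in one background with a sub-twofold change is therefore retained as long
#' as any background shows a twofold change.
#'
#' @param contrasts Named list of the six genotype-vs-WT contrast tables;
#'   names must be \code{GENOTYPE_CONTRASTS}.
#' @param fdr Adjusted-p threshold (default 0.05).
#' @param lfc Twofold inclusion threshold in log2 units (default 1).
#' @return Named list of six [deg_set()] objects.
#' @export
build_six_lists <- function(contrasts, fdr = 0.05, lfc = 1) {
  if (!setequal(names(contrasts), GENOTYPE_CONTRASTS)) {
    stop("contrasts must be named: ",
         paste(GENOTYPE_CONTRASTS, collapse = ", "))
  }
  contrasts <- contrasts[GENOTYPE_CONTRASTS]
  # max |log2FC| per gene across the six contrasts
  all_ids <- unique(unlist(lapply(contrasts, `[[`, "gene_id")))
  max_lfc <- stats::setNames(rep(0, length(all_ids)), all_ids)
  for (ct in contrasts) {
    idx <- match(ct$gene_id, all_ids)
    max_lfc[idx] <- pmax(max_lfc[idx], abs(ct$log2FC))
  }
  passing <- names(max_lfc)[max_lfc > lfc]
  lapply(stats::setNames(GENOTYPE_CONTRASTS, GENOTYPE_CONTRASTS), function(nm) {
    s <- deg_set(contrasts[[nm]], fdr = fdr, lfc = NULL, contrast = nm)
    s[s$gene_id %in% passing, , drop = FALSE]
  })
}

#' Match Venn segments across mock and auxin treatments
#'
#' Keeps genes mis-regulated in the same manner under both treatments:
#' identical Venn segment in the mock and IAA partitions AND identical
#' direction sign in every member contrast.
#'
#' @param mock,iaa \code{venn_partition} objects over the same three sets
#'   (ett, arf4, double) built from the mock and IAA DEG lists.
#' @return data.frame of matched genes: \code{gene_id}, \code{segment},
#'   \code{dir_ett}, \code{dir_arf4}, \code{dir_double}.
#' @export
cross_treatment_match <- function(mock, iaa) {
  sn <- attr(mock, "set_names")
  if (!identical(sn, attr(iaa, "set_names"))) {
    stop("partitions must be over the same sets")
  }
  common <- intersect(mock$gene_id, iaa$gene_id)
  mi <- match(common, mock$gene_id)
  ii <- match(common, iaa$gene_id)
  same_seg <- mock$segment[mi] == iaa$segment[ii]
  same_dir <- rep(TRUE, length(common))
  for (nm in sn) {
    dm <- mock[[paste0("dir_", nm)]][mi]
    di <- iaa[[paste0("dir_", nm)]][ii]
    # non-members have NA on both sides when segments agree
    same_dir <- same_dir & (is.na(dm) & is.na(di) |
                            (!is.na(dm) & !is.na(di) & dm == di))
  }
  keep <- same_seg & same_dir
  out <- data.frame(gene_id = common[keep],
                    segment = mock$segment[mi][keep],
                    stringsAsFactors = FALSE)
  for (nm in sn) out[[paste0("dir_", nm)]] <- mock[[paste0("dir_", nm)]][mi][keep]
  out
}

# Map a three-way segment pattern to its regulatory-model label.
segment_model_label <- function(segment) {
  labels <- c(
    "ett+double" = "ETT_specific",
    "arf4+double" = "ARF4_specific",
    "double" = "redundant"
  )
  out <- labels[segment]
  unnamed <- is.na(out)
  out[unnamed] <- paste0("segment_", segment[unnamed])
  unname(out)
}

#' Classify auxin-independent regulatory targets
#'
#' Final stage of the auxin-independent analysis: genes matched across
#' treatments are screened against the four within-genotype auxin-response
#' DEG sets; any gene significantly auxin-responsive (twofold) in at least
#' one genotype is flagged and removed. Survivors are labelled by their Venn
#' segment: \code{ett+double} is ETT-specific, \code{arf4+double} is
#' ARF4-specific, \code{double} alone is redundant regulation; the remaining
#' segments carry pattern-derived labels.
#'
#' @param matched Output of [cross_treatment_match()].
#' @param auxin_sets Named list of the four auxin-response [deg_set()]s
#'   (names \code{AUXIN_CONTRASTS}), built with \code{padj < 0.05} and
#'   \code{|log2FC| > 1}.
#' @return data.frame with \code{gene_id}, \code{segment_mock},
#'   \code{segment_iaa}, \code{direction} ("up"/"down"),
#'   \code{removed_auxin_sensitive}, \code{model_label} (NA for removed
#'   genes) and the per-contrast direction columns.
#' @export
classify_auxin_independent <- function(matched, auxin_sets) {
  if (!setequal(names(auxin_sets), AUXIN_CONTRASTS)) {
    stop("auxin_sets must be named: ", paste(AUXIN_CONTRASTS, collapse = ", "))
  }
  sensitive <- unique(unlist(lapply(auxin_sets, `[[`, "gene_id")))
  removed <- matched$gene_id %in% sensitive
  # headline direction: the double-mutant contrast when it is a member,
  # otherwise the first member in (ett, arf4, double) order
  dirs <- cbind(matched$dir_double, matched$dir_ett, matched$dir_arf4)
  lead <- apply(dirs, 1, function(d) d[!is.na(d)][1])
  out <- data.frame(
    gene_id = matched$gene_id,
    segment_mock = matched$segment,
    segment_iaa = matched$segment,
    direction = ifelse(lead > 0, "up", "down"),
    removed_auxin_sensitive = removed,
    model_label = ifelse(removed, NA_character_,
                         segment_model_label(matched$segment)),
    dir_ett = matched$dir_ett,
    dir_arf4 = matched$dir_arf4,
    dir_double = matched$dir_double,
    stringsAsFactors = FALSE
  )
  out
}

#' Full auxin-independent target analysis
#'
#' Convenience wrapper chaining [build_six_lists()], the two
#' [three_way_partition()]s, [cross_treatment_match()] and
#' [classify_auxin_independent()].
#'
#' @param contrasts Named list of all ten contrast tables (as from
#'   [run_contrasts()]); the six genotype-vs-WT and four auxin-response
#'   tables are taken by name.
#' @param fdr,lfc Thresholds passed to the DEG-set builders.
#' @return List with \code{assignments} (the classification table),
#'   \code{partition_mock}, \code{partition_iaa} and \code{deg_sets}.
#' @export
auxin_independent_analysis <- function(contrasts, fdr = 0.05, lfc = 1) {
  six <- build_six_lists(contrasts[GENOTYPE_CONTRASTS], fdr = fdr, lfc = lfc)
  part_mock <- three_way_partition(six$ett_vs_WT_mock, six$arf4_vs_WT_mock,
                                   six$ett_arf4_vs_WT_mock)
  part_iaa <- three_way_partition(six$ett_vs_WT_IAA, six$arf4_vs_WT_IAA,
                                  six$ett_arf4_vs_WT_IAA)
  matched <- cross_treatment_match(part_mock, part_iaa)
  auxin_sets <- lapply(stats::setNames(AUXIN_CONTRASTS, AUXIN_CONTRASTS),
                       function(nm) deg_set(contrasts[[nm]], fdr = fdr,
                                            lfc = lfc, contrast = nm))
  assignments <- classify_auxin_independent(matched, auxin_sets)
  list(assignments = assignments, partition_mock = part_mock,
       partition_iaa = part_iaa, deg_sets = six, auxin_sets = auxin_sets)
}
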