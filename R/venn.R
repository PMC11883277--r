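#' Partition the union of DEG sets into Venn segments
#'
#' Assigns every gene in the union of the supplied DEG sets to exactly one
#' segment, identified by the "+"-joined names of the sets it belongs to in
#' the fixed order given by \code{names(sets)}. Membership direction signs
#' are carried along (+1 up, -1 down, NA when not a member).
#'
#' @param sets Named list of [deg_set()] objects (or data.frames with
#'   \code{gene_id} and \code{direction}).
#' @return A \code{venn_partition}: data.frame with \code{gene_id},
#'   \code{segment}, one logical \code{in_<set>} and one integer
#'   \code{dir_<set>} column per set; attribute \code{set_names}.
#' @export
venn_partition <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a named list")
  }
  set_names <- names(sets)
  universe <- unique(unlist(lapply(sets, function(s) s$gene_id)))
  out <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (nm in set_names) {
    s <- sets[[nm]]
    idx <- match(universe, s$gene_id)
    out[[paste0("in_", nm)]] <- !is.na(idx)
    dir <- ifelse(s$direction[idx] == "up", 1L, -1L)
    out[[paste0("dir_", nm)]] <- dir
  }
  memb <- as.matrix(out[paste0("in_", set_names)])
  out$segment <- apply(memb, 1, function(b) {
    paste(set_names[b], collapse = "+")
  })
  out <- out[c("gene_id", "segment", paste0("in_", set_names),
               paste0("dir_", set_names))]
  structure(out, set_names = set_names,
            class = c("venn_partition", "data.frame"))
}

#' Three-way Venn partition of genotype DEG sets
#'
#' Partitions the union of the ett, arf4 and double-mutant (vs WT) DEG sets
#' from one treatment into the 7 non-empty membership segments.
#'
#' @param set_ett,set_arf4,set_double [deg_set()] objects for the three
#'   genotype-vs-WT contrasts of one treatment.
#' @return A \code{venn_partition} over sets \code{ett}, \code{arf4},
#'   \code{double}.
#' @export
three_way_partition <- function(set_ett, set_arf4, set_double) {
  venn_partition(list(ett = set_ett, arf4 = set_arf4, double = set_double))
}

#' Four-way Venn partition of auxin-response DEG sets
#'
#' Partitions the union of the four within-genotype auxin-response DEG sets
#' (WT, ett, arf4, double) into the 15 non-empty membership segments, in the
#' fixed bitmask order (WT, ett, arf4, double).
#'
#' @param set_wt,set_ett,set_arf4,set_double [deg_set()] objects for the
#'   four IAA-vs-mock contrasts.
#' @return A \code{venn_partition} over sets \code{WT}, \code{ett},
#'   \code{arf4}, \code{double}.
#' @export
four_way_partition <- function(set_wt, set_ett, set_arf4, set_double) {
  venn_partition(list(WT = set_wt, ett = set_ett, arf4 = set_arf4,
                      double = set_double))
}

#' Segment counts of a Venn partition
#'
#' @param partition A \code{venn_partition}.
#' @return Named integer vector of gene counts per non-empty segment.
#' @export
segment_counts <- function(partition) {
  tab <- table(partition$segment)
  stats::setNames(as.integer(tab), names(tab))
}
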