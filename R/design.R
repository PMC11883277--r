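#' @keywords internal
"_PACKAGE"

#' Factor vocabularies of the 4 x 2 factorial design
#' @format Character vectors.
#' @export
GENOTYPES <- c("WT", "ett", "arf4", "ett_arf4")

#' @rdname GENOTYPES
#' @export
TREATMENTS <- c("mock", "IAA")

#' Canonical contrast names
#'
#' Six genotype-vs-WT contrasts (one per mutant and treatment) and four
#' within-genotype auxin-response contrasts; log2FC orientation is mutant
#' relative to WT and IAA relative to mock.
#' @format Character vectors.
#' @export
GENOTYPE_CONTRASTS <- c(
  "ett_vs_WT_mock", "arf4_vs_WT_mock", "ett_arf4_vs_WT_mock",
  "ett_vs_WT_IAA", "arf4_vs_WT_IAA", "ett_arf4_vs_WT_IAA"
)

#' @rdname GENOTYPE_CONTRASTS
#' @export
AUXIN_CONTRASTS <- c(
  "IAA_vs_mock_WT", "IAA_vs_mock_ett",
  "IAA_vs_mock_arf4", "IAA_vs_mock_ett_arf4"
)

#' Generate the factorial sample design
#'
#' Builds the full 4 genotype x 2 treatment grid with a fixed number of
#' biological replicates per cell, deterministically ordered and named
#' (\code{<genotype>_<treatment>_<replicate>}).
#'
#' @param n_replicates Number of biological replicates per design cell
#'   (default 3, matching a typical bulk RNA-seq factorial experiment).
#' @return A data.frame with columns \code{sample_id}, \code{genotype},
#'   \code{treatment}, \code{replicate}.
#' @examples
#' d <- generate_design(3)
#' nrow(d) # 24
#' @export
generate_design <- function(n_replicates = 3) {
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 ||
      is.na(n_replicates) || n_replicates < 1 || n_replicates != round(n_replicates)) {
    stop("n_replicates must be a positive integer")
  }
  n_replicates <- as.integer(n_replicates)
  grid <- expand.grid(
    replicate = seq_len(n_replicates),
    treatment = TREATMENTS,
    genotype = GENOTYPES,
    stringsAsFactors = FALSE
  )
  design <- data.frame(
    sample_id = paste(grid$genotype, grid$treatment, grid$replicate, sep = "_"),
    genotype = factor(grid$genotype, levels = GENOTYPES),
    treatment = factor(grid$treatment, levels = TREATMENTS),
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
  design
}

#' Select the sample ids of one or more design cells
#'
#' @param design A design data.frame as from [generate_design()].
#' @param genotype Genotype level(s) to select; NULL keeps all.
#' @param treatment Treatment level(s) to select; NULL keeps all.
#' @return Character vector of sample ids.
#' @export
design_cells <- function(design, genotype = NULL, treatment = NULL) {
  validate_design(design, require_full_grid = FALSE)
  keep <- rep(TRUE, nrow(design))
  if (!is.null(genotype)) {
    if (!all(genotype %in% GENOTYPES)) stop("unknown genotype: ",
      paste(setdiff(genotype, GENOTYPES), collapse = ", "))
    keep <- keep & design$genotype %in% genotype
  }
  if (!is.null(treatment)) {
    if (!all(treatment %in% TREATMENTS)) stop("unknown treatment: ",
      paste(setdiff(treatment, TREATMENTS), collapse = ", "))
    keep <- keep & design$treatment %in% treatment
  }
  design$sample_id[keep]
}

# Internal validation shared by readers and analysis entry points.
validate_design <- function(design, require_full_grid = TRUE) {
  req <- c("sample_id", "genotype", "treatment", "replicate")
  if (!is.data.frame(design) || !all(req %in% names(design))) {
    stop("design must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicated sample id: ",
         design$sample_id[duplicated(design$sample_id)][1])
  }
  bad_g <- setdiff(as.character(design$genotype), GENOTYPES)
  if (length(bad_g)) stop("unknown genotype label: ", bad_g[1])
  bad_t <- setdiff(as.character(design$treatment), TREATMENTS)
  if (length(bad_t)) stop("unknown treatment label: ", bad_t[1])
  if (require_full_grid) {
    cells <- table(factor(design$genotype, GENOTYPES),
                   factor(design$treatment, TREATMENTS))
    if (any(cells == 0)) {
      miss <- which(cells == 0, arr.ind = TRUE)[1, ]
      stop("design is missing the factorial cell ",
           GENOTYPES[miss[1]], " / ", TREATMENTS[miss[2]])
    }
  }
  invisible(design)
}

validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene ids as rownames and sample ids as colnames")
  }
  if (anyNA(counts)) stop("counts contain missing values")
  frac <- which(counts != round(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(frac)) {
    stop("non-integer or negative count for gene ",
         rownames(counts)[frac[1, 1]], " in sample ",
         colnames(counts)[frac[1, 2]])
  }
  invisible(counts)
}

check_counts_design <- function(counts, design, require_full_grid = TRUE) {
  validate_counts(counts)
  validate_design(design, require_full_grid = require_full_grid)
  if (!setequal(colnames(counts), design$sample_id)) {
    stop("sample ids in counts and design do not match")
  }
  counts[, design$sample_id, drop = FALSE]
}
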