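#' PCA quality control of the factorial experiment
#'
#' Principal components of \code{log2(normalized count + 1)} across samples,
#' with a grouping diagnostic comparing between-genotype and
#' between-treatment separation in the PC1/PC2 plane. In this study design
#' genotype effects are expected to dominate the auxin treatment, so the
#' spread ratio should exceed 1. Component signs are fixed by convention:
#' the largest-magnitude loading of each component is made positive, so the
#' result is deterministic.
#'
#' @param counts Gene x sample count matrix.
#' @param design Design data.frame.
#' @param factors Size factors; computed with [size_factors()] when NULL.
#' @param n_components Number of components to return (default 2).
#' @return List with \code{coords} (data.frame: sample_id, genotype,
#'   treatment, PC1, PC2, ...), \code{var_explained} (fractions, one per
#'   returned component, non-increasing), \code{genotype_spread},
#'   \code{treatment_spread} (mean pairwise distance between group centroids
#'   on PC1/PC2) and \code{spread_ratio} (genotype over treatment).
#' @export
qc_pca <- function(counts, design, factors = NULL, n_components = 2) {
  counts <- check_counts_design(counts, design, require_full_grid = FALSE)
  if (ncol(counts) < 3) stop("PCA needs at least 3 samples")
  if (is.null(factors)) factors <- size_factors(counts)
  x <- log2(sweep(counts, 2, factors[colnames(counts)], "/") + 1)
  x <- x[apply(x, 1, stats::var) > 0, , drop = FALSE]
  if (!nrow(x)) stop("count matrix is constant; PCA is degenerate")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  n_components <- min(max(n_components, 2), ncol(pc$x))
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest-|loading| positive per component
  for (j in seq_len(n_components)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  var_explained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  coords <- data.frame(
    sample_id = design$sample_id,
    genotype = as.character(design$genotype),
    treatment = as.character(design$treatment),
    scores[design$sample_id, , drop = FALSE],
    row.names = NULL, stringsAsFactors = FALSE
  )
  centroid_spread <- function(group) {
    xy <- coords[, c("PC1", "PC2"), drop = FALSE]
    cent <- stats::aggregate(xy, list(group = group), mean)
    if (nrow(cent) < 2) return(0)
    mean(stats::dist(as.matrix(cent[, c("PC1", "PC2")])))
  }
  g_spread <- centroid_spread(coords$genotype)
  t_spread <- centroid_spread(coords$treatment)
  list(
    coords = coords,
    var_explained = var_explained,
    genotype_spread = g_spread,
    treatment_spread = t_spread,
    spread_ratio = g_spread / t_spread
  )
}
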