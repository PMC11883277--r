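#' Median-of-ratios size factors
#'
#' Per-sample normalization constants in the median-of-ratios convention:
#' for every gene with nonzero counts in all samples, form the ratio of its
#' count to its geometric mean across samples; the sample's size factor is
#' the median of these ratios. Factors are rescaled so their geometric mean
#' is 1.
#'
#' @param counts Gene x sample count matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  log_gm <- rowMeans(log(counts))
  ok <- is.finite(log_gm)
  if (!any(ok)) stop("no gene has nonzero counts in all samples")
  s <- apply(counts[ok, , drop = FALSE], 2,
             function(cl) stats::median(exp(log(cl) - log_gm[ok])))
  s / exp(mean(log(s)))
}

#' FPKM matrix
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' \code{FPKM = count * 1e9 / (length_bp * total_count_of_sample)}.
#'
#' @param counts Gene x sample count matrix.
#' @param gene_lengths Named numeric vector of transcript lengths in bp
#'   covering every gene in \code{counts}.
#' @return Numeric matrix of FPKM values, same dimensions as \code{counts}.
#' @export
compute_fpkm <- function(counts, gene_lengths) {
  validate_counts(counts)
  miss <- setdiff(rownames(counts), names(gene_lengths))
  if (length(miss)) stop("missing gene length for: ", miss[1])
  len <- gene_lengths[rownames(counts)]
  if (any(!is.finite(len) | len <= 0)) stop("gene lengths must be positive")
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("zero-total sample: ", colnames(counts)[totals <= 0][1])
  }
  sweep(counts / len, 2, totals, "/") * 1e9
}

#' Method-of-moments dispersion estimates
#'
#' Per-gene negative-binomial dispersion alpha (variance = mu + alpha mu^2)
#' from the within-cell mean and variance of normalized counts, pooled over
#' all design cells with at least two replicates, floored at \code{floor}.
#' For a cell with mean m of normalized counts, the Poisson component of the
#' variance is \code{m * mean(1/s_j)} over the cell's size factors; the
#' pooled ratio of excess variance to squared mean estimates alpha. The
#' squared-mean denominator uses the unbiased moment \code{m^2 - v/n} so the
#' estimator is not systematically attenuated at small replicate numbers.
#'
#' With few replicates the per-gene estimates are noisy, which inflates the
#' Wald statistic for genes whose dispersion happens to be underestimated.
#' By default the raw estimates are therefore moderated: shrunk toward the
#' across-gene median with weight \code{prior_df / (prior_df + df)}, in the
#' spirit of empirical-Bayes variance moderation, and the t reference for
#' the Wald test gains the prior degrees of freedom. \code{moderate = FALSE}
#' returns the raw per-gene estimates.
#'
#' @param counts Gene x sample count matrix.
#' @param design Design data.frame.
#' @param factors Size factors as from [size_factors()].
#' @param floor Lower bound for the estimates (default 1e-8).
#' @param moderate Shrink per-gene estimates toward the across-gene median
#'   (default TRUE).
#' @param prior_df Weight of the shrinkage target in degrees of freedom;
#'   defaults to the pooled residual df (equal-weight moderation).
#' @return List with \code{alpha} (named per-gene vector, moderated when
#'   requested), \code{alpha_raw} (unmoderated method-of-moments
#'   estimates) and \code{df} (degrees of freedom for the Wald t reference:
#'   residual df plus \code{prior_df} when moderated).
#' @export
estimate_dispersion <- function(counts, design, factors, floor = 1e-8,
                                moderate = TRUE, prior_df = NULL) {
  counts <- check_counts_design(counts, design, require_full_grid = FALSE)
  cells <- interaction(design$genotype, design$treatment, drop = TRUE)
  reps <- table(cells)
  if (all(reps < 2)) stop("no design cell has replication")
  norm <- sweep(counts, 2, factors[colnames(counts)], "/")
  num <- den <- numeric(nrow(counts))
  df <- 0L
  for (cell in names(reps)[reps >= 2]) {
    j <- cells == cell
    n <- sum(j)
    m <- rowMeans(norm[, j, drop = FALSE])
    v <- apply(norm[, j, drop = FALSE], 1, stats::var)
    inv_s <- mean(1 / factors[colnames(counts)][j])
    num <- num + (n - 1) * (v - m * inv_s)
    den <- den + (n - 1) * pmax(m^2 - v / n, 0)
    df <- df + (n - 1L)
  }
  alpha_raw <- pmax(num / pmax(den, .Machine$double.xmin), floor)
  names(alpha_raw) <- rownames(counts)
  if (moderate) {
    if (is.null(prior_df)) prior_df <- df
    centre <- stats::median(alpha_raw)
    alpha <- pmax((df * alpha_raw + prior_df * centre) / (df + prior_df),
                  floor)
    list(alpha = alpha, alpha_raw = alpha_raw, df = df + prior_df)
  } else {
    list(alpha = alpha_raw, alpha_raw = alpha_raw, df = df)
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; the single BH routine used by
#' the contrast tests and the enrichment module.
#'
#' @param p Numeric vector of raw p-values (NA allowed, passed through).
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald contrast
#'
#' Moment-based Wald test of group A versus group B on normalized counts.
#' Per gene, the group means of normalized counts estimate the underlying
#' expression levels; \code{log2FC = log2(mean_A) - log2(mean_B)}. The
#' standard error comes from the NB variance function
#' \code{var = mu + alpha mu^2} evaluated at the pooled (null) mean, mapped
#' to the log2 scale by the delta method. p-values use a Student-t reference
#' with the pooled residual degrees of freedom from the dispersion fit
#' (small-sample calibration; \code{df = Inf} gives the standard-normal
#' tail). BH adjustment is applied over all tested genes; genes with zero
#' counts in every sample of both groups are excluded from testing and from
#' BH (padj = NA).
#'
#' When one group's mean is zero the log2FC is computed from a floor of half
#' a normalized count and capped at \code{±lfc_cap}, preserving direction
#' without infinities.
#'
#' @param counts Gene x sample count matrix.
#' @param design Design data.frame.
#' @param factors Size factors.
#' @param dispersions Result of [estimate_dispersion()], or a named numeric
#'   vector of per-gene alphas (then \code{df} defaults to Inf).
#' @param groupA,groupB Character vectors of sample ids (disjoint,
#'   non-empty); see [design_cells()].
#' @param lfc_cap Cap on |log2FC| when a group mean is zero (default 30).
#' @param df Degrees of freedom for the t reference; defaults to the
#'   dispersion fit's pooled residual df.
#' @return A contrast table: data.frame with \code{gene_id},
#'   \code{baseMean} (mean normalized count over both groups),
#'   \code{log2FC}, \code{stat}, \code{pvalue}, \code{padj}.
#' @export
nb_wald_contrast <- function(counts, design, factors, dispersions,
                             groupA, groupB, lfc_cap = 30, df = NULL) {
  counts <- check_counts_design(counts, design, require_full_grid = FALSE)
  if (!length(groupA) || !length(groupB)) stop("both groups must be non-empty")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  miss <- setdiff(c(groupA, groupB), colnames(counts))
  if (length(miss)) stop("unknown sample id: ", miss[1])
  if (is.list(dispersions)) {
    alpha <- dispersions$alpha
    if (is.null(df)) df <- dispersions$df
  } else {
    alpha <- dispersions
    if (is.null(df)) df <- Inf
  }
  alpha <- alpha[rownames(counts)]
  if (anyNA(alpha)) stop("dispersions missing for some genes")

  sA <- factors[groupA]; sB <- factors[groupB]
  nA <- length(groupA); nB <- length(groupB)
  normA <- sweep(counts[, groupA, drop = FALSE], 2, sA, "/")
  normB <- sweep(counts[, groupB, drop = FALSE], 2, sB, "/")
  qA <- rowMeans(normA)
  qB <- rowMeans(normB)
  q0 <- (nA * qA + nB * qB) / (nA + nB)

  tested <- q0 > 0
  qmin <- 0.5 / mean(c(sA, sB))
  lfc <- log2(pmax(qA, qmin)) - log2(pmax(qB, qmin))
  lfc <- pmin(pmax(lfc, -lfc_cap), lfc_cap)
  lfc[!tested] <- 0

  # variance of each group mean under the pooled mean, delta method to log2
  vA <- (q0 * sum(1 / sA) + nA * alpha * q0^2) / nA^2
  vB <- (q0 * sum(1 / sB) + nB * alpha * q0^2) / nB^2
  se_log2 <- sqrt(vA + vB) / (pmax(q0, .Machine$double.xmin) * log(2))
  stat <- ifelse(tested, lfc / se_log2, NA_real_)
  pvalue <- 2 * stats::pt(-abs(stat), df = df)
  padj <- rep(NA_real_, length(pvalue))
  padj[tested] <- bh_adjust(pvalue[tested])

  data.frame(
    gene_id = rownames(counts),
    baseMean = q0,
    log2FC = lfc,
    stat = stat,
    pvalue = pvalue,
    padj = padj,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Differentially expressed gene set for one contrast
#'
#' Members have \code{padj < fdr} and, when \code{lfc} is given,
#' \code{|log2FC| > lfc}; direction is the sign of log2FC.
#'
#' @param table A contrast table from [nb_wald_contrast()].
#' @param fdr Adjusted-p threshold in (0, 1] (default 0.05).
#' @param lfc Optional log2 fold-change threshold (e.g. 1 for twofold);
#'   NULL applies no fold filter.
#' @param contrast Optional contrast id recorded on the result.
#' @return A \code{deg_set}: data.frame with \code{gene_id},
#'   \code{direction} ("up"/"down") and \code{log2FC}; attributes
#'   \code{contrast}, \code{fdr}, \code{lfc}.
#' @export
deg_set <- function(table, fdr = 0.05, lfc = NULL, contrast = NULL) {
  if (!is.numeric(fdr) || fdr <= 0 || fdr > 1) stop("fdr must be in (0, 1]")
  keep <- !is.na(table$padj) & table$padj < fdr
  if (!is.null(lfc)) keep <- keep & abs(table$log2FC) > lfc
  out <- data.frame(
    gene_id = table$gene_id[keep],
    direction = ifelse(table$log2FC[keep] > 0, "up", "down"),
    log2FC = table$log2FC[keep],
    stringsAsFactors = FALSE
  )
  structure(out, contrast = contrast, fdr = fdr, lfc = lfc,
            class = c("deg_set", "data.frame"))
}

#' Run the ten canonical contrasts of the factorial design
#'
#' Six genotype-vs-WT contrasts (each mutant against WT within mock and
#' within IAA) and four within-genotype auxin-response contrasts (IAA vs
#' mock per genotype), each tested with [nb_wald_contrast()].
#'
#' @inheritParams nb_wald_contrast
#' @return Named list of ten contrast tables (names
#'   \code{GENOTYPE_CONTRASTS} then \code{AUXIN_CONTRASTS}).
#' @export
run_contrasts <- function(counts, design, factors, dispersions) {
  counts <- check_counts_design(counts, design)
  out <- list()
  for (geno in GENOTYPES[-1]) {
    for (tr in TREATMENTS) {
      nm <- paste0(geno, "_vs_WT_", tr)
      out[[nm]] <- nb_wald_contrast(
        counts, design, factors, dispersions,
        groupA = design_cells(design, geno, tr),
        groupB = design_cells(design, "WT", tr)
      )
    }
  }
  for (geno in GENOTYPES) {
    nm <- paste0("IAA_vs_mock_", geno)
    out[[nm]] <- nb_wald_contrast(
      counts, design, factors, dispersions,
      groupA = design_cells(design, geno, "IAA"),
      groupB = design_cells(design, geno, "mock")
    )
  }
  out[c(GENOTYPE_CONTRASTS, AUXIN_CONTRASTS)]
}
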