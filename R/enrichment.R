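#' Over-representation analysis against an expressed-gene background
#'
#' Flat hypergeometric enrichment of a gene list against a background
#' universe (all genes expressed/tested in the experiment). For each term
#' with at least one gene in the list, the upper-tail probability
#' \eqn{P(X \ge k)} of drawing \code{k} annotated genes in a list of size
#' \code{n} from a universe of \code{N} genes of which \code{K} carry the
#' term, and the fold enrichment \code{(k/n)/(K/N)}. BH FDR is computed over
#' the reported terms; rows with \code{FDR < fdr_cutoff} are flagged
#' significant.
#'
#' @param gene_set Character vector of gene ids; must be a subset of
#'   \code{background}.
#' @param background Character vector: the expressed-gene universe.
#' @param annotation A [term_annotation()] (or named list of gene-id
#'   vectors). Annotations are intersected with the background before
#'   testing.
#' @param fdr_cutoff Significance threshold on the BH FDR (default 0.05).
#' @param min_term_size,max_term_size Term-size filter applied after
#'   intersection with the background (defaults 1 and Inf: permissive).
#' @return data.frame sorted by FDR: \code{term}, \code{label}, \code{k},
#'   \code{n}, \code{K}, \code{N}, \code{fold}, \code{pvalue}, \code{fdr},
#'   \code{significant}.
#' @export
enrich <- function(gene_set, background, annotation, fdr_cutoff = 0.05,
                   min_term_size = 1, max_term_size = Inf) {
  background <- unique(as.character(background))
  gene_set <- unique(as.character(gene_set))
  if (!length(background)) stop("background must be non-empty")
  out_of_bg <- setdiff(gene_set, background)
  if (length(out_of_bg)) {
    stop("gene_set is not a subset of background (e.g. ", out_of_bg[1], ")")
  }
  if (!inherits(annotation, "term_annotation")) {
    annotation <- term_annotation(annotation)
  }
  terms <- lapply(annotation$terms, intersect, background)
  K <- lengths(terms)
  keep <- K >= min_term_size & K <= min(max_term_size, length(background))
  terms <- terms[keep]
  K <- K[keep]
  N <- length(background)
  n <- length(gene_set)
  k <- vapply(terms, function(g) length(intersect(g, gene_set)), 1L)
  tested <- k >= 1
  if (!any(tested)) {
    return(data.frame(term = character(), label = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold = numeric(), pvalue = numeric(),
                      fdr = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  k <- k[tested]; K <- K[tested]; term_ids <- names(terms)[tested]
  pvalue <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- (k / n) / (K / N)
  fdr <- bh_adjust(pvalue)
  out <- data.frame(
    term = term_ids,
    label = unname(annotation$labels[term_ids]),
    k = k, n = n, K = K, N = N,
    fold = fold, pvalue = pvalue, fdr = fdr,
    significant = fdr < fdr_cutoff,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$fdr, out$pvalue, out$term), , drop = FALSE]
}
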