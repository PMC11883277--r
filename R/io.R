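#' Write a simulated fixture to TSV files
#'
#' Writes \code{counts.tsv} (gene_id + one column per sample),
#' \code{design.tsv} (sample_id, genotype, treatment, replicate, and the true
#' size_factor when present) and \code{truth.tsv} to \code{directory}.
#' Read-back with [read_counts()] / [read_design()] / [read_truth()]
#' round-trips losslessly.
#'
#' @param counts Integer gene x sample matrix.
#' @param design Design data.frame.
#' @param truth Ground-truth data.frame (may be NULL).
#' @param directory Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(counts, design, truth, directory) {
  if (is.null(dim(counts)) || nrow(counts) == 0) {
    stop("counts must contain at least one gene")
  }
  counts <- check_counts_design(counts, design, require_full_grid = FALSE)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory)
  }
  paths <- c(
    counts = file.path(directory, "counts.tsv"),
    design = file.path(directory, "design.tsv"),
    truth = file.path(directory, "truth.tsv")
  )
  cdf <- data.frame(gene_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cdf, paths["counts"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(design, paths["design"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    if (nrow(truth) != nrow(counts)) {
      stop("truth table must have one row per gene")
    }
    utils::write.table(truth, paths["truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    paths <- paths[c("counts", "design")]
  }
  invisible(paths)
}

#' Read a count matrix from TSV/CSV
#'
#' Expects a header row of sample ids and a first column of gene ids. Counts
#' must be non-negative integers; violations are reported with the offending
#' gene and sample.
#'
#' @param path File path (tab- or comma-separated, inferred from extension).
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("count file needs a gene id column plus samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated gene id: ", ids[duplicated(ids)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("counts must be numeric")
  rownames(m) <- ids
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

#' Read a sample design table from TSV/CSV
#'
#' @param path File path.
#' @param require_full_grid Error when any of the 8 factorial cells
#'   (4 genotypes x 2 treatments) is absent (default TRUE; the classifiers
#'   need the full grid).
#' @return Validated design data.frame.
#' @export
read_design <- function(path, require_full_grid = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  design <- utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE, comment.char = "#")
  validate_design(design, require_full_grid = require_full_grid)
  design$genotype <- factor(design$genotype, levels = GENOTYPES)
  design$treatment <- factor(design$treatment, levels = TREATMENTS)
  design
}

#' Read a simulation ground-truth table
#'
#' @param path File path to a truth.tsv written by [write_fixture()].
#' @return data.frame.
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
}

#' Read a flat gene-to-term annotation table
#'
#' Two-column TSV (gene id, term id), optional third column with a term
#' label. Duplicate gene/term pairs are de-duplicated; malformed lines are
#' reported with their line numbers.
#'
#' @param path File path.
#' @return A \code{term_annotation}: list with \code{terms} (named list of
#'   gene-id character vectors) and \code{labels} (named character vector).
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines) || all(!nzchar(lines))) {
    warning("empty annotation file: ", path)
    return(term_annotation(list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nzchar(lines) & nf < 2)
  if (length(bad)) {
    stop("malformed annotation line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  keep <- nzchar(lines)
  gene <- vapply(parts[keep], `[[`, "", 1)
  term <- vapply(parts[keep], `[[`, "", 2)
  label <- vapply(parts[keep], function(p) if (length(p) >= 3) p[[3]] else "",
                  "")
  dup <- duplicated(paste(gene, term, sep = "\r"))
  gene <- gene[!dup]; term <- term[!dup]; label <- label[!dup]
  terms <- split(gene, term)
  labels <- vapply(split(label, term), function(x) {
    x <- x[nzchar(x)]; if (length(x)) x[1] else ""
  }, "")
  term_annotation(terms, labels)
}

#' Construct a term annotation object
#'
#' @param terms Named list mapping term id to a character vector of gene ids.
#' @param labels Optional named character vector of term labels.
#' @return A \code{term_annotation} list.
#' @export
term_annotation <- function(terms, labels = NULL) {
  terms <- lapply(terms, function(g) unique(as.character(g)))
  empty <- lengths(terms) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty term(s)")
    terms <- terms[!empty]
  }
  if (is.null(labels)) labels <- stats::setNames(rep("", length(terms)),
                                                 names(terms))
  labels <- labels[names(terms)]
  structure(list(terms = terms, labels = labels), class = "term_annotation")
}
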