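# Write a TSV with a provenance header (tool version, seed, thresholds).
write_output_tsv <- function(df, path, seed, fdr, lfc) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# arfclass %s; seed=%s; fdr=%s; lfc=%s",
                     as.character(utils::packageVersion("arfclass")),
                     ifelse(is.null(seed), "NA", seed), fdr, lfc), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Summarize Venn partitions and class assignments as count tables
#'
#' @param independent Result of [auxin_independent_analysis()] (or NULL).
#' @param sensitive Result of [auxin_sensitive_analysis()] (or NULL).
#' @return Nested list of counts suitable for JSON serialization: 7-segment
#'   counts per treatment, post-filter class counts split by direction, the
#'   15-segment auxin-response counts and per-model conformance tallies.
#' @export
summarize_venn <- function(independent = NULL, sensitive = NULL) {
  out <- list()
  if (!is.null(independent)) {
    asg <- independent$assignments
    kept <- asg[!asg$removed_auxin_sensitive, , drop = FALSE]
    class_counts <- if (nrow(kept)) {
      tab <- table(kept$model_label, factor(kept$direction, c("up", "down")))
      lapply(stats::setNames(rownames(tab), rownames(tab)), function(cl) {
        list(up = unname(tab[cl, "up"]), down = unname(tab[cl, "down"]),
             total = unname(sum(tab[cl, ])))
      })
    } else list()
    out$auxin_independent <- list(
      segments_mock = as.list(segment_counts(independent$partition_mock)),
      segments_iaa = as.list(segment_counts(independent$partition_iaa)),
      n_matched = nrow(asg),
      n_removed_auxin_sensitive = sum(asg$removed_auxin_sensitive),
      classes = class_counts
    )
  }
  if (!is.null(sensitive)) {
    mod <- sensitive$conformance$models
    out$auxin_sensitive <- list(
      segments = as.list(segment_counts(sensitive$partition)),
      models = lapply(stats::setNames(seq_len(nrow(mod)), mod$model),
        function(i) list(segment = mod$segment[i],
                         n_total = mod$n_total[i], n_up = mod$n_up[i],
                         n_down = mod$n_down[i],
                         n_discordant = mod$n_discordant[i],
                         n_conforming = mod$n_conforming[i]))
    )
  }
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis on a count matrix and design:
#' normalization, dispersion estimation, the ten canonical contrasts, the
#' auxin-independent and auxin-sensitive classifiers, optional enrichment of
#' every labelled class against the expressed-gene background, PCA QC, and a
#' JSON run manifest. All outputs are TSV/JSON files under
#' \code{output_dir}; every TSV carries a header comment with the package
#' version, seed and thresholds. Genes untestable in any contrast (zero
#' counts throughout both groups) are listed in \code{exclusions.tsv}.
#'
#' @param counts Count matrix or path to a counts TSV/CSV.
#' @param design Design data.frame or path to a design TSV/CSV.
#' @param output_dir Output directory (created if needed).
#' @param gene_lengths Optional named vector of lengths (bp) or path to a
#'   two-column TSV; when given an FPKM matrix is written.
#' @param annotation Optional [term_annotation()] or path to a gene-term
#'   TSV; when given, enrichment tables are written per labelled class.
#' @param fdr,lfc Significance and fold thresholds (defaults 0.05 and 1).
#' @param apply_lfc_gate_sensitive Apply the fold gate to the four
#'   auxin-response lists (default TRUE).
#' @param strict_arf4_prevention Strict segment reading for the
#'   ARF4-specific prevention model (default TRUE).
#' @param seed Seed recorded in output headers and the manifest (the
#'   pipeline itself is deterministic given its inputs).
#' @return Invisibly, a list with all intermediate objects (contrasts,
#'   analyses, qc, summary, manifest).
#' @export
run_pipeline <- function(counts, design, output_dir,
                         gene_lengths = NULL, annotation = NULL,
                         fdr = 0.05, lfc = 1,
                         apply_lfc_gate_sensitive = TRUE,
                         strict_arf4_prevention = TRUE,
                         seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.character(counts)) counts <- stage("read", read_counts(counts))
  if (is.character(design)) design <- stage("read", read_design(design))
  if (is.character(annotation)) {
    annotation <- stage("read", read_annotation(annotation))
  }
  if (is.character(gene_lengths)) {
    gl <- utils::read.table(gene_lengths, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    gene_lengths <- stats::setNames(gl[[2]], gl[[1]])
  }
  counts <- stage("validate", check_counts_design(counts, design))
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  wt <- function(df, name) {
    write_output_tsv(df, file.path(output_dir, name), seed, fdr, lfc)
  }

  factors <- stage("normalize", size_factors(counts))
  dispersions <- stage("dispersion",
                       estimate_dispersion(counts, design, factors))
  contrasts <- stage("contrasts",
                     run_contrasts(counts, design, factors, dispersions))
  dir.create(file.path(output_dir, "contrasts"), showWarnings = FALSE)
  for (nm in names(contrasts)) {
    wt(contrasts[[nm]], file.path("contrasts", paste0(nm, ".tsv")))
  }
  excluded <- rownames(counts)[rowSums(counts) == 0]
  wt(data.frame(gene_id = excluded,
                reason = rep("zero counts in all samples", length(excluded)),
                stringsAsFactors = FALSE), "exclusions.tsv")

  independent <- stage("classify_independent",
                       auxin_independent_analysis(contrasts, fdr, lfc))
  wt(independent$assignments, "auxin_independent_assignments.tsv")
  sensitive <- stage("classify_sensitive",
    auxin_sensitive_analysis(contrasts, fdr, lfc,
                             apply_lfc_gate = apply_lfc_gate_sensitive,
                             strict_arf4_prevention = strict_arf4_prevention))
  wt(sensitive$conformance$genes, "auxin_sensitive_genes.tsv")
  wt(sensitive$conformance$models, "auxin_sensitive_models.tsv")

  if (!is.null(gene_lengths)) {
    fpkm <- stage("fpkm", compute_fpkm(counts, gene_lengths))
    wt(data.frame(gene_id = rownames(fpkm), fpkm, check.names = FALSE),
       "fpkm.tsv")
  }

  background <- contrasts[[1]]$gene_id[!is.na(contrasts[[1]]$padj)]
  if (!is.null(annotation)) {
    asg <- independent$assignments
    kept <- asg[!asg$removed_auxin_sensitive, , drop = FALSE]
    dir.create(file.path(output_dir, "enrichment"), showWarnings = FALSE)
    for (cl in unique(kept$model_label)) {
      genes <- intersect(kept$gene_id[kept$model_label == cl], background)
      if (!length(genes)) next
      et <- stage("enrich", enrich(genes, background, annotation, fdr))
      wt(et, file.path("enrichment", paste0(gsub("[^A-Za-z0-9_]+", "_", cl),
                                            ".tsv")))
    }
  }

  qc <- stage("qc", qc_pca(counts, design, factors))
  wt(qc$coords, "qc_pca.tsv")

  summary <- summarize_venn(independent, sensitive)
  jsonlite::write_json(summary, file.path(output_dir, "venn_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    tool = "arfclass",
    version = as.character(utils::packageVersion("arfclass")),
    seed = seed,
    thresholds = list(fdr = fdr, lfc = lfc,
                      apply_lfc_gate_sensitive = apply_lfc_gate_sensitive,
                      strict_arf4_prevention = strict_arf4_prevention),
    n_genes = nrow(counts), n_samples = ncol(counts),
    n_excluded = length(excluded),
    n_background = length(background),
    contrasts = names(contrasts),
    input_checksums = list(
      counts = unname(sum(as.numeric(counts))),
      design = paste(design$sample_id, collapse = ",")
    ),
    qc = list(genotype_spread = qc$genotype_spread,
              treatment_spread = qc$treatment_spread,
              spread_ratio = qc$spread_ratio,
              var_explained = qc$var_explained)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(factors = factors, dispersions = dispersions,
                 contrasts = contrasts, independent = independent,
                 sensitive = sensitive, qc = qc, summary = summary,
                 manifest = manifest))
}
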