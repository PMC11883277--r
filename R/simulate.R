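#' Regulatory-class templates
#'
#' Each planted class places effects on the log2 mean scale:
#' \code{genotype} lists the genotypes carrying a constitutive
#' (auxin-independent) effect relative to WT, present under both treatments;
#' \code{auxin} lists the genotypes in which the gene responds to auxin.
#' The auxin-independent classes mirror the three named segments of the
#' three-way genotype Venn diagram; the auxin-sensitive classes mirror the
#' A-B ARF antagonism models, where loss of a repressor unmasks auxin
#' induction, so their planted direction is always up (\code{signed} is
#' FALSE).
#' @format Named list of class templates.
#' @export
CLASS_TEMPLATES <- list(
  redundant = list(genotype = "ett_arf4", auxin = character(), signed = TRUE),
  ETT_specific = list(genotype = c("ett", "ett_arf4"), auxin = character(), signed = TRUE),
  ARF4_specific = list(genotype = c("arf4", "ett_arf4"), auxin = character(), signed = TRUE),
  redundant_prevention = list(genotype = character(), auxin = "ett_arf4", signed = FALSE),
  heterodimer = list(genotype = character(),
                     auxin = c("ett", "arf4", "ett_arf4"), signed = FALSE),
  ARF4_specific_prevention = list(genotype = character(),
                                  auxin = c("arf4", "ett_arf4"), signed = FALSE)
)

#' Simulation configuration
#'
#' Parameters of the negative-binomial count simulator. Defaults emulate the
#' study design this package targets: a 4 genotype x 2 treatment factorial
#' with 3 biological replicates, genotype effects (2 log2 units) larger than
#' auxin-response effects (1.5 log2 units), moderate biological dispersion,
#' and 200 genes planted in each of the six regulatory-model classes on top
#' of 2000 null genes.
#'
#' @param n_genes Total number of genes.
#' @param n_replicates Replicates per design cell.
#' @param baseline_mean_range Range of expected baseline counts; baselines
#'   are drawn log-uniformly over this range.
#' @param dispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2).
#' @param genotype_lfc Magnitude (log2 units) of planted genotype-vs-WT
#'   effects.
#' @param auxin_lfc Magnitude (log2 units) of planted auxin-response effects.
#' @param library_size_factor_range Range of per-sample library size factors,
#'   drawn uniformly.
#' @param class_fractions Named numeric vector mapping class labels (names of
#'   \code{CLASS_TEMPLATES}) to the fraction of genes planted in each class;
#'   must be non-negative and sum to at most 1. The remainder are null genes.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_genes = 3200L,
                              n_replicates = 3L,
                              baseline_mean_range = c(20, 2000),
                              dispersion = 0.1,
                              genotype_lfc = 2.0,
                              auxin_lfc = 1.5,
                              library_size_factor_range = c(0.7, 1.3),
                              class_fractions = c(
                                redundant = 200 / 3200,
                                ETT_specific = 200 / 3200,
                                ARF4_specific = 200 / 3200,
                                redundant_prevention = 200 / 3200,
                                heterodimer = 200 / 3200,
                                ARF4_specific_prevention = 200 / 3200
                              ),
                              seed = 1L) {
  stopifnot(is.numeric(n_genes), length(n_genes) == 1, n_genes >= 1)
  if (n_replicates < 1 || n_replicates != round(n_replicates)) {
    stop("n_replicates must be a positive integer")
  }
  check_range <- function(r, what) {
    if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2]) {
      stop(what, " must be a pair of positive reals with low <= high")
    }
  }
  check_range(baseline_mean_range, "baseline_mean_range")
  check_range(library_size_factor_range, "library_size_factor_range")
  if (!is.finite(dispersion) || dispersion <= 0) stop("dispersion must be > 0")
  if (length(class_fractions)) {
    if (is.null(names(class_fractions)) ||
        !all(names(class_fractions) %in% names(CLASS_TEMPLATES))) {
      stop("class_fractions names must be among: ",
           paste(names(CLASS_TEMPLATES), collapse = ", "))
    }
    if (any(class_fractions < 0)) stop("class fractions must be non-negative")
    if (sum(class_fractions) > 1 + 1e-12) stop("class fractions sum to > 1")
  }
  cfg <- list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    baseline_mean_range = as.numeric(baseline_mean_range),
    dispersion = as.numeric(dispersion),
    genotype_lfc = as.numeric(genotype_lfc),
    auxin_lfc = as.numeric(auxin_lfc),
    library_size_factor_range = as.numeric(library_size_factor_range),
    class_fractions = class_fractions,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

# Run expr with a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate factorial counts with planted regulatory classes
#'
#' Draws a gene x sample negative-binomial count matrix over the full
#' factorial design. For gene i in sample j (genotype g, treatment t) the
#' mean is
#' \deqn{\mu_{ij} = b_i \, 2^{G_i(g) + [t = IAA] A_i(g)} \, s_j}
#' with baseline \eqn{b_i}, constitutive genotype effect \eqn{G_i},
#' auxin-response effect \eqn{A_i} and library size factor \eqn{s_j};
#' the variance is \eqn{\mu + \alpha \mu^2}. Effects are placed according to
#' each gene's planted regulatory class (see \code{CLASS_TEMPLATES}).
#'
#' @param config A [simulation_config()].
#' @return List with \code{counts} (integer matrix), \code{design}
#'   (data.frame, including the true \code{size_factor} per sample) and
#'   \code{truth} (data.frame: \code{gene_id}, \code{class_label},
#'   \code{direction} in \{-1, 0, 1\}, \code{baseline_mean}, and the ten true
#'   per-contrast log2 fold changes named after the canonical contrasts).
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be created by simulation_config()")
  }
  with_seed(config$seed, {
    design <- generate_design(config$n_replicates)
    design$size_factor <- stats::runif(nrow(design),
                                       config$library_size_factor_range[1],
                                       config$library_size_factor_range[2])
    n <- config$n_genes
    gene_ids <- sprintf("gene%05d", seq_len(n))

    # contiguous class blocks, remainder null
    n_per <- floor(config$class_fractions * n)
    class_label <- rep("null", n)
    at <- 1L
    for (cl in names(n_per)) {
      k <- n_per[[cl]]
      if (k > 0) {
        class_label[at:(at + k - 1L)] <- cl
        at <- at + k
      }
    }

    baseline <- exp(stats::runif(n, log(config$baseline_mean_range[1]),
                                 log(config$baseline_mean_range[2])))
    direction <- integer(n)
    # per-gene effect matrices: G (genotype x 1) and A over genotypes
    G <- matrix(0, n, length(GENOTYPES), dimnames = list(NULL, GENOTYPES))
    A <- matrix(0, n, length(GENOTYPES), dimnames = list(NULL, GENOTYPES))
    for (cl in names(CLASS_TEMPLATES)) {
      idx <- which(class_label == cl)
      if (!length(idx)) next
      tpl <- CLASS_TEMPLATES[[cl]]
      dir <- if (tpl$signed) sample(c(-1L, 1L), length(idx), replace = TRUE)
             else rep(1L, length(idx))
      direction[idx] <- dir
      if (length(tpl$genotype)) {
        G[idx, tpl$genotype] <- dir * config$genotype_lfc
      }
      if (length(tpl$auxin)) {
        A[idx, tpl$auxin] <- dir * config$auxin_lfc
      }
    }

    g <- as.character(design$genotype)
    iaa <- design$treatment == "IAA"
    log2mu <- log2(baseline) +
      G[, g, drop = FALSE] +
      sweep(A[, g, drop = FALSE], 2, as.numeric(iaa), "*")
    mu <- sweep(2^log2mu, 2, design$size_factor, "*")
    counts <- matrix(
      stats::rnbinom(n * nrow(design), mu = mu, size = 1 / config$dispersion),
      nrow = n, dimnames = list(gene_ids, design$sample_id)
    )
    storage.mode(counts) <- "integer"

    truth <- data.frame(
      gene_id = gene_ids, class_label = class_label,
      direction = direction, baseline_mean = baseline,
      stringsAsFactors = FALSE
    )
    # true genotype-vs-WT log2FC within each treatment, and true auxin
    # responses per genotype
    for (geno in GENOTYPES[-1]) {
      truth[[paste0("lfc_", geno, "_vs_WT_mock")]] <- G[, geno]
      truth[[paste0("lfc_", geno, "_vs_WT_IAA")]] <-
        G[, geno] + A[, geno] - A[, "WT"]
    }
    for (geno in GENOTYPES) {
      truth[[paste0("lfc_IAA_vs_mock_", geno)]] <- A[, geno]
    }
    list(counts = counts, design = design, truth = truth)
  })
}
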