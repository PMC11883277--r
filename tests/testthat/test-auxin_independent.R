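# Build the six genotype-vs-WT contrast tables from a compact spec:
# each element gives per-gene log2FC and padj for one contrast.
six_tables <- function(genes, lfc, padj) {
  lapply(stats::setNames(GENOTYPE_CONTRASTS, GENOTYPE_CONTRASTS),
         function(nm) data.frame(
           gene_id = genes, baseMean = 50,
           log2FC = lfc[[nm]], stat = 0,
           pvalue = padj[[nm]], padj = padj[[nm]],
           stringsAsFactors = FALSE))
}

test_that("the twofold inclusion rule retains sub-twofold members via other backgrounds", {
  genes <- c("CRC_like", "weak", "strong")
  lfc <- list(); padj <- list()
  for (nm in GENOTYPE_CONTRASTS) { lfc[[nm]] <- c(0, 0, 0); padj[[nm]] <- c(1, 1, 1) }
  # CRC-like: significant in ett (|lfc| < 1) and in the double (|lfc| > 1)
  for (tr in c("mock", "IAA")) {
    lfc[[paste0("ett_vs_WT_", tr)]] <- c(-0.44, 0.8, 2.5)
    padj[[paste0("ett_vs_WT_", tr)]] <- c(0.01, 0.01, 0.01)
    lfc[[paste0("ett_arf4_vs_WT_", tr)]] <- c(-1.12, 0.7, 2.4)
    padj[[paste0("ett_arf4_vs_WT_", tr)]] <- c(0.01, 0.01, 0.01)
  }
  sets <- build_six_lists(six_tables(genes, lfc, padj))
  # retained in the ett list although its own ett change is sub-twofold
  expect_true("CRC_like" %in% sets$ett_vs_WT_mock$gene_id)
  expect_true("CRC_like" %in% sets$ett_arf4_vs_WT_mock$gene_id)
  # max |log2FC| = 0.8 across all six: excluded everywhere despite significance
  for (s in sets) expect_false("weak" %in% s$gene_id)
  expect_true("strong" %in% sets$ett_vs_WT_IAA$gene_id)

  # no significant genes -> six empty sets
  for (nm in GENOTYPE_CONTRASTS) padj[[nm]] <- c(1, 1, 1)
  empty <- build_six_lists(six_tables(genes, lfc, padj))
  expect_true(all(vapply(empty, nrow, 1L) == 0))

  expect_error(build_six_lists(six_tables(genes, lfc, padj)[1:5]),
               "must be named")
})

test_that("three-way partition equals the per-gene membership oracle", {
  s_ett <- make_deg(c("a", "b", "d"), c("up", "down", "up"))
  s_arf4 <- make_deg(c("b", "c"), c("down", "up"))
  s_dbl <- make_deg(c("a", "b", "c", "e"), c("up", "down", "down", "down"))
  part <- three_way_partition(s_ett, s_arf4, s_dbl)
  expect_equal(part$segment[part$gene_id == "e"], "double")
  expect_equal(part$segment[part$gene_id == "b"], "ett+arf4+double")
  expect_equal(part$segment[part$gene_id == "d"], "ett")
  # disjoint and exhaustive over the union
  expect_setequal(part$gene_id, c("a", "b", "c", "d", "e"))
  expect_false(anyDuplicated(part$gene_id) > 0)

  set.seed(61)
  pool <- sprintf("g%03d", 1:40)
  for (rep in 1:25) {
    sets <- random_deg_sets(c("ett", "arf4", "double"), pool)
    if (!length(unlist(lapply(sets, `[[`, "gene_id")))) next
    part <- three_way_partition(sets$ett, sets$arf4, sets$double)
    oracle <- oracle_partition(sets)
    expect_setequal(part$gene_id, names(oracle))
    for (g in part$gene_id) {
      expect_identical(part$segment[part$gene_id == g], oracle[[g]]$segment)
    }
    # segment sizes sum to the union size
    expect_equal(sum(segment_counts(part)), length(oracle))
  }
})

test_that("cross-treatment matching requires identical segment and directions", {
  mock <- three_way_partition(
    make_deg(character()), make_deg(character()),
    make_deg(c("CLE19", "flip", "drift"), c("up", "up", "up"))
  )
  iaa <- three_way_partition(
    make_deg("drift", "up"), make_deg(character()),
    make_deg(c("CLE19", "flip", "drift"), c("up", "down", "up"))
  )
  m <- cross_treatment_match(mock, iaa)
  # same segment {double}, same direction in both treatments
  expect_setequal(m$gene_id, "CLE19")
  # "flip": same segment but direction reverses -> rejected
  # "drift": segment gains ett membership under IAA -> rejected
  expect_false(any(c("flip", "drift") %in% m$gene_id))
})

test_that("classification maps segments to regulatory models and removes auxin-sensitive genes", {
  empty_auxin <- lapply(stats::setNames(AUXIN_CONTRASTS, AUXIN_CONTRASTS),
                        function(nm) make_deg(character()))
  matched <- data.frame(
    gene_id = c("IND_like", "NTT_like", "CLE19_like", "aux"),
    segment = c("ett+double", "double", "double", "double"),
    dir_ett = c(-1L, NA, NA, NA),
    dir_arf4 = c(NA_integer_, NA, NA, NA),
    dir_double = c(-1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  auxin <- empty_auxin
  auxin$IAA_vs_mock_WT <- make_deg("aux", "up")
  asg <- classify_auxin_independent(matched, auxin)
  expect_equal(asg$model_label[asg$gene_id == "IND_like"], "ETT_specific")
  expect_equal(asg$direction[asg$gene_id == "IND_like"], "down")
  expect_equal(asg$model_label[asg$gene_id == "NTT_like"], "redundant")
  expect_equal(asg$direction[asg$gene_id == "NTT_like"], "up")
  expect_true(asg$removed_auxin_sensitive[asg$gene_id == "aux"])
  expect_true(is.na(asg$model_label[asg$gene_id == "aux"]))
  expect_error(classify_auxin_independent(matched, auxin[1:3]),
               "must be named")
})

test_that("classifier output equals exhaustive truth-table evaluation", {
  # enumerate every (segment x member-direction x auxin-sensitivity) pattern
  segs <- list("ett", "arf4", "double", c("ett", "arf4"), c("ett", "double"),
               c("arf4", "double"), c("ett", "arf4", "double"))
  rows <- list(); gid <- 0
  for (seg in segs) {
    dir_grid <- expand.grid(rep(list(c(1L, -1L)), length(seg)))
    for (r in seq_len(nrow(dir_grid))) {
      for (sens in c(FALSE, TRUE)) {
        gid <- gid + 1
        rows[[gid]] <- list(id = sprintf("tt%03d", gid), seg = seg,
                            dirs = unlist(dir_grid[r, ]), sens = sens)
      }
    }
  }
  mk_sets <- function() {
    sets <- list(ett = list(), arf4 = list(), double = list())
    for (rw in rows) {
      for (k in seq_along(rw$seg)) {
        sets[[rw$seg[k]]][[rw$id]] <- rw$dirs[k]
      }
    }
    lapply(sets, function(s) make_deg(names(s),
      ifelse(unlist(s) > 0, "up", "down")))
  }
  sets <- mk_sets()
  part <- three_way_partition(sets$ett, sets$arf4, sets$double)
  matched <- cross_treatment_match(part, part)
  expect_setequal(matched$gene_id, vapply(rows, `[[`, "", "id"))
  auxin <- lapply(stats::setNames(AUXIN_CONTRASTS, AUXIN_CONTRASTS),
                  function(nm) make_deg(character()))
  sens_ids <- vapply(rows[vapply(rows, `[[`, TRUE, "sens")], `[[`, "", "id")
  auxin$IAA_vs_mock_ett_arf4 <- make_deg(sens_ids)
  asg <- classify_auxin_independent(matched, auxin)

  for (rw in rows) {
    row <- asg[asg$gene_id == rw$id, ]
    expect_equal(row$removed_auxin_sensitive, rw$sens)
    if (rw$sens) next
    # independent rule evaluation
    key <- paste(sort(rw$seg), collapse = ",")
    expected <- if (key == "double") "redundant"
      else if (key == "double,ett") "ETT_specific"
      else if (key == "arf4,double") "ARF4_specific"
      else paste0("segment_", row$segment_mock)
    expect_equal(row$model_label, expected)
    lead <- if ("double" %in% rw$seg) rw$dirs[match("double", rw$seg)]
      else rw$dirs[1]
    expect_equal(row$direction, if (lead > 0) "up" else "down")
  }
})

test_that("label soundness: specific classes are absent from the other single-mutant set", {
  sim <- quick_sim(seed = 71)
  f <- size_factors(sim$counts)
  d <- estimate_dispersion(sim$counts, sim$design, f)
  ct <- run_contrasts(sim$counts, sim$design, f, d)
  ai <- auxin_independent_analysis(ct)
  kept <- ai$assignments[!ai$assignments$removed_auxin_sensitive, ]
  ett_specific <- kept$gene_id[kept$model_label == "ETT_specific"]
  redundant <- kept$gene_id[kept$model_label == "redundant"]
  # by construction of the segments
  expect_false(any(ett_specific %in% ai$deg_sets$arf4_vs_WT_mock$gene_id))
  expect_false(any(redundant %in% ai$deg_sets$ett_vs_WT_mock$gene_id))
  expect_false(any(redundant %in% ai$deg_sets$arf4_vs_WT_IAA$gene_id))
})
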