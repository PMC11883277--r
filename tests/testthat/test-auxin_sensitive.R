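four_tables <- function(genes, lfc, padj) {
  lapply(stats::setNames(AUXIN_CONTRASTS, AUXIN_CONTRASTS),
         function(nm) data.frame(
           gene_id = genes, baseMean = 50,
           log2FC = lfc[[nm]], stat = 0,
           pvalue = padj[[nm]], padj = padj[[nm]],
           stringsAsFactors = FALSE))
}

test_that("the four auxin-response lists honour their thresholds and the fold gate flag", {
  genes <- c("wt_only", "everywhere_ns", "sub_twofold")
  lfc <- list(); padj <- list()
  for (nm in AUXIN_CONTRASTS) { lfc[[nm]] <- c(0, 0.5, 0.8); padj[[nm]] <- c(1, 0.2, 0.01) }
  lfc$IAA_vs_mock_WT <- c(1.5, 0.5, 0.8)
  padj$IAA_vs_mock_WT <- c(0.01, 0.2, 0.01)
  sets <- build_four_lists(four_tables(genes, lfc, padj))
  expect_setequal(sets$WT$gene_id, "wt_only")
  expect_equal(sets$WT$direction, "up")
  for (g in c("ett", "arf4", "double")) expect_equal(nrow(sets[[g]]), 0)
  # padj 0.2 everywhere -> no set; sub-twofold significant excluded by gate
  expect_false(any(vapply(sets, function(s) "everywhere_ns" %in% s$gene_id, TRUE)))
  expect_false(any(vapply(sets, function(s) "sub_twofold" %in% s$gene_id, TRUE)))
  # gate off: sub-twofold significant genes enter
  nogate <- build_four_lists(four_tables(genes, lfc, padj),
                             apply_lfc_gate = FALSE)
  expect_true("sub_twofold" %in% nogate$WT$gene_id)
  expect_error(build_four_lists(four_tables(genes, lfc, padj)[1:3]),
               "must be named")
})

test_that("planted WT auxin responders are recovered at a well-powered effect size", {
  # strong responders (sixfold) so list-building, not engine power, is tested;
  # planted in all mutants and checked in each member list
  sim <- quick_sim(seed = 81, n_genes = 2000, auxin_lfc = 2.5,
                   class_fractions = c(heterodimer = 0.1))
  f <- size_factors(sim$counts)
  d <- estimate_dispersion(sim$counts, sim$design, f)
  ct <- run_contrasts(sim$counts, sim$design, f, d)
  sets <- build_four_lists(ct[AUXIN_CONTRASTS])
  planted <- sim$truth$gene_id[sim$truth$class_label == "heterodimer"]
  for (g in c("ett", "arf4", "double")) {
    expect_gt(mean(planted %in% sets[[g]]$gene_id), 0.85)
  }
  # and they are not auxin-responsive in WT
  expect_lt(mean(planted %in% sets$WT$gene_id), 0.05)
})

test_that("four-way partition equals the membership oracle", {
  sets <- list(
    WT = make_deg("w"),
    ett = make_deg(c("w", "x", "z")),
    arf4 = make_deg(c("x", "z")),
    double = make_deg(c("x", "y", "z"))
  )
  part <- four_way_partition(sets$WT, sets$ett, sets$arf4, sets$double)
  expect_equal(part$segment[part$gene_id == "x"], "ett+arf4+double")
  expect_equal(part$segment[part$gene_id == "y"], "double")
  expect_equal(part$segment[part$gene_id == "w"], "WT+ett")

  set.seed(91)
  pool <- sprintf("g%03d", 1:30)
  for (rep in 1:25) {
    rs <- random_deg_sets(c("WT", "ett", "arf4", "double"), pool)
    part <- four_way_partition(rs$WT, rs$ett, rs$arf4, rs$double)
    oracle <- oracle_partition(rs)
    expect_setequal(part$gene_id, names(oracle))
    for (g in part$gene_id) {
      expect_identical(part$segment[part$gene_id == g], oracle[[g]]$segment)
    }
    expect_equal(sum(segment_counts(part)), length(oracle))
  }
})

test_that("antagonism tallies match a brute-force count and the model definitions", {
  part <- four_way_partition(
    make_deg(character()),
    make_deg(c("h1", "h2", "h3"), c("up", "up", "down")),
    make_deg(c("h1", "h2", "h3", "a1", "a2"),
             c("up", "up", "down", "up", "down")),
    make_deg(c("h1", "h2", "h3", "a1", "a2", "r1", "r2"),
             c("up", "down", "down", "up", "down", "down", "up"))
  )
  conf <- score_antagonism(part)
  mod <- conf$models
  het <- mod[mod$model == "heterodimer", ]
  # h1 up everywhere: conforming; h2 discordant; h3 down everywhere
  expect_equal(het$n_total, 3)
  expect_equal(het$n_up, 1)
  expect_equal(het$n_down, 1)
  expect_equal(het$n_discordant, 1)
  expect_equal(het$n_conforming, 1)
  arf <- mod[mod$model == "ARF4_specific_prevention", ]
  expect_equal(arf$n_total, 2)
  expect_equal(arf$n_up, 1)
  expect_equal(arf$n_down, 1)
  red <- mod[mod$model == "redundant_prevention", ]
  expect_equal(red$n_total, 2)
  expect_equal(red$n_up, 1)
  expect_equal(red$n_down, 1)
  expect_equal(red$n_conforming, 1)
  # n_up + n_down + n_discordant = n_total
  expect_true(all(mod$n_up + mod$n_down + mod$n_discordant == mod$n_total))

  # empty partition -> all tallies zero
  ep <- four_way_partition(make_deg(character()), make_deg(character()),
                           make_deg(character()), make_deg(character()))
  e <- score_antagonism(ep)$models
  expect_true(all(e$n_total == 0 & e$n_conforming == 0))

  # brute force on random inputs
  set.seed(93)
  pool <- sprintf("g%03d", 1:60)
  for (rep in 1:20) {
    rs <- random_deg_sets(c("WT", "ett", "arf4", "double"), pool)
    part <- four_way_partition(rs$WT, rs$ett, rs$arf4, rs$double)
    conf <- score_antagonism(part)$models
    oracle <- oracle_partition(rs)
    for (model in conf$model) {
      seg <- switch(model, redundant_prevention = "double",
                    heterodimer = "ett+arf4+double",
                    ARF4_specific_prevention = "arf4+double")
      in_seg <- Filter(function(o) o$segment == seg, oracle)
      n_up <- sum(vapply(in_seg, function(o) {
        d <- o$dirs[!is.na(o$dirs)]; all(d == 1)
      }, TRUE))
      n_down <- sum(vapply(in_seg, function(o) {
        d <- o$dirs[!is.na(o$dirs)]; all(d == -1)
      }, TRUE))
      row <- conf[conf$model == model, ]
      expect_equal(row$n_total, length(in_seg))
      expect_equal(row$n_up, n_up)
      expect_equal(row$n_down, n_down)
      expect_equal(row$n_conforming, n_up)
    }
  }
})

test_that("conformance is monotone: adding an up-responder increments totals by one", {
  base_sets <- list(
    WT = make_deg(character()),
    ett = make_deg(c("h1", "h2")),
    arf4 = make_deg(c("h1", "h2")),
    double = make_deg(c("h1", "h2"))
  )
  p1 <- four_way_partition(base_sets$WT, base_sets$ett, base_sets$arf4,
                           base_sets$double)
  c1 <- score_antagonism(p1)$models
  added <- lapply(base_sets, function(s) s)
  for (nm in c("ett", "arf4", "double")) {
    added[[nm]] <- make_deg(c(added[[nm]]$gene_id, "new"), rep("up", 3))
  }
  p2 <- four_way_partition(added$WT, added$ett, added$arf4, added$double)
  c2 <- score_antagonism(p2)$models
  h1 <- c1[c1$model == "heterodimer", ]; h2 <- c2[c2$model == "heterodimer", ]
  expect_equal(h2$n_total, h1$n_total + 1)
  expect_equal(h2$n_conforming, h1$n_conforming + 1)
})

test_that("the strict/permissive ARF4-prevention segment flag changes membership", {
  part <- four_way_partition(
    make_deg(character()), make_deg("h"),
    make_deg(c("h", "a")), make_deg(c("h", "a"))
  )
  strict <- score_antagonism(part, strict_arf4_prevention = TRUE)$models
  perm <- score_antagonism(part, strict_arf4_prevention = FALSE)$models
  expect_equal(strict[strict$model == "ARF4_specific_prevention", "n_total"], 1)
  expect_equal(perm[perm$model == "ARF4_specific_prevention", "n_total"], 2)
})
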