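test_that("overlap percentages reproduce the worked arithmetic", {
  expect_equal(overlap_percentage(547, 767), 71.3)
  expect_equal(overlap_percentage(57, 70), 81.4)
  expect_error(overlap_percentage(5, 3), "exceed")
})

test_that("DMP-in-DMR overlap uses inclusive interval boundaries", {
  dmps <- data.frame(probe_id = c("a", "b", "c", "d"),
                     chromosome = c("chr1", "chr1", "chr1", "chr2"),
                     position = c(100, 200, 201, 150),
                     gene = c("G1", "G2;G3", "G4", ""))
  dmrs <- data.frame(chromosome = "chr1", start = 100, end = 200)
  ov <- overlap_dmps_dmrs(dmps, dmrs)
  expect_setequal(ov$overlap_ids, c("a", "b")) # start and end inclusive
  expect_equal(ov$percentage, 50)
  expect_setequal(ov$genes, c("G1", "G2", "G3"))
  # invariant to row order
  ov2 <- overlap_dmps_dmrs(dmps[4:1, ], dmrs)
  expect_equal(ov2$n_overlap, ov$n_overlap)
  expect_setequal(ov2$overlap_ids, ov$overlap_ids)
})

test_that("most planted DMPs overlap the called DMRs on the default simulation", {
  scan <- run_dmp_scan(fx_processed())
  dmr <- run_dmr_scan(fx_processed())
  ov <- overlap_dmps_dmrs(scan, dmr)
  expect_gt(ov$percentage, 50)
  expect_lte(ov$n_overlap, ov$n_dmps)
  expect_true(length(ov$genes) > 0)
})

test_that("Fisher enrichment equals the exhaustive hypergeometric oracle", {
  set.seed(7)
  tables <- cbind(a = sample(0:15, 60, TRUE), b = sample(0:15, 60, TRUE),
                  c = sample(0:15, 60, TRUE), d = sample(0:15, 60, TRUE))
  tables <- tables[rowSums(tables) > 0, ]
  for (i in seq_len(nrow(tables))) {
    tb <- tables[i, ]
    p_pkg <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, fx_fisher_oracle(tb["a"], tb["b"], tb["c"], tb["d"]),
                 tolerance = 1e-10)
  }
})

test_that("annotation enrichment detects a planted island excess", {
  manifest <- data.frame(
    probe_id = sprintf("p%03d", 1:100),
    chromosome = "chr1", position = 1:100,
    cpg_context = rep(c("island", "open-sea"), each = 50))
  dmps <- sprintf("p%03d", 1:10) # all in islands, background 50% islands
  res <- annotation_enrichment(dmps, manifest$probe_id, manifest,
                               "cpg_context")
  isl <- res[res$category == "island", ]
  expect_gt(isl$odds_ratio, 1)
  expect_equal(isl$a + isl$b, 10)
  # oracle check of the exact p for this table: a=10,b=0,c=40,d=50
  expect_equal(isl$p, fx_fisher_oracle(10, 0, 40, 50), tolerance = 1e-12)
  expect_equal(isl$call, "enriched")
  # matched composition: no signal
  dmps2 <- sprintf("p%03d", c(1:5, 51:55))
  res2 <- annotation_enrichment(dmps2, manifest$probe_id, manifest,
                                "cpg_context")
  expect_true(all(res2$p > 0.9))
  # zero cell: no DMP in category -> OR 0, flagged, finite p
  dmps3 <- sprintf("p%03d", 51:60)
  res3 <- annotation_enrichment(dmps3, manifest$probe_id, manifest,
                                "cpg_context")
  isl3 <- res3[res3$category == "island", ]
  expect_equal(isl3$odds_ratio, 0)
  expect_equal(isl3$flag, "zero_cell")
  expect_true(is.finite(isl3$p))
})

test_that("TFBS enrichment applies exact Bonferroni arithmetic", {
  set.seed(15)
  bg <- sprintf("p%04d", 1:4000)
  sets <- lapply(1:161, function(i) sample(bg, 200))
  names(sets) <- sprintf("TF%03d", 1:161)
  dmps <- sample(bg, 300)
  res <- tfbs_enrichment(dmps, bg, sets)
  expect_equal(nrow(res), 161L)
  expect_equal(res$p_adjusted, pmin(1, res$p * 161))
  expect_true(all(res$call[res$p_adjusted >= 0.05] == "ns"))
  # monotone in p
  o <- order(res$p)
  expect_true(all(diff(res$p_adjusted[o]) >= -1e-12))
})

test_that("a TFBS with planted 3x DMP rate is the one called enriched", {
  hits <- vapply(1:10, function(s) {
    set.seed(700 + s)
    bg <- sprintf("p%04d", 1:5000)
    sets <- lapply(1:10, function(i) sample(bg, 250))
    names(sets) <- sprintf("TF%02d", 1:10)
    w <- ifelse(bg %in% sets[["TF01"]], 3, 1)
    dmps <- sample(bg, 400, prob = w)
    res <- tfbs_enrichment(dmps, bg, sets)
    target <- res$p_adjusted[res$category == "TF01"] < 0.05
    others <- all(res$p_adjusted[res$category != "TF01"] >= 0.05)
    target && others
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("gene-set enrichment matches the closed-form extreme case", {
  genes <- sprintf("G%02d", 1:5)
  universe <- sprintf("G%02d", 1:100)
  sets <- list(all5 = genes, none = sprintf("X%02d", 1:5))
  res <- gene_set_enrichment(genes, sets, universe)
  # all 5 of 5 drawn from a 5-gene set in a universe of 100
  expect_equal(res$p[res$category == "all5"], 1 / choose(100, 5),
               tolerance = 1e-12)
  expect_equal(res$p[res$category == "none"], 1)
  expect_equal(res$neg_log10_p[res$category == "none"], 0)
  # -log10 formatting round-trip
  expect_equal(10^(-3.98), 1.047129e-4, tolerance = 1e-6)
  expect_error(gene_set_enrichment(genes, sets, character(0)), "empty")
})

test_that("disease mapping keeps scores strictly above the threshold", {
  tab <- data.frame(gene = c("LEP", "LEP", "PON1", "OPCML"),
                    disease = c("obesity", "diabetes", "cvd", "cvd"),
                    score = c(0.41, 0.1, 0.2, 0.35))
  out <- disease_mapping(c("LEP", "PON1"), tab)
  expect_setequal(out$disease, c("obesity", "cvd"))
  expect_false(any(out$score == 0.1)) # exactly 0.1 excluded
  expect_equal(nrow(disease_mapping(character(0), tab)), 0L)
})
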