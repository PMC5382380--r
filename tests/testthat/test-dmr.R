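test_that("per-CpG contrast stats handle equal groups and degenerate variance", {
  means <- matrix(rep(0.4, 4), nrow = 1)
  ds <- fx_toy_dataset(means, noise_sd = 0)
  st <- per_cpg_contrast_stats(ds, "unexposed-QQ")
  expect_equal(st$t, 0)
  expect_equal(st$p, 1)
  expect_equal(st$flag, "zero_variance")
  # identical means but real noise: t near 0 on average, p in (0,1]
  ds2 <- fx_toy_dataset(means[rep(1, 50), ], noise_sd = 0.02, seed = 5)
  st2 <- per_cpg_contrast_stats(ds2, "unexposed-QQ")
  expect_true(all(st2$p > 0 & st2$p <= 1))
  expect_equal(st2$df[1], 2 + 2 - 2)
})

test_that("group sizes below two are rejected", {
  means <- matrix(rep(0.4, 4), nrow = 1)
  ds <- fx_toy_dataset(means, noise_sd = 0.01)
  ds2 <- gxewas:::.subset_samples(ds, ds$samples$sample_id[-5])
  expect_error(per_cpg_contrast_stats(ds2, "unexposed-carrier"),
               "at least 2 samples")
})

test_that("kernel smoothing matches the hand-computed weighted mean", {
  pos <- c(100, 400, 800, 1500, 2600)
  t <- c(2, -1, 3, 0.5, 1)
  sm <- smooth_and_score(t, pos, df = 22, lambda_bp = 1000, C = 2)
  # independent evaluation of the truncated Gaussian weighted mean
  sigma <- 500
  expected <- vapply(seq_along(pos), function(i) {
    d <- abs(pos - pos[i])
    nb <- which(d <= 1000)
    w <- exp(-d[nb]^2 / (2 * sigma^2))
    sum(w * t[nb]^2) / sum(w)
  }, numeric(1))
  expect_equal(sm$score, expected, tolerance = 1e-12)
  # isolated probe keeps its own squared statistic
  expect_equal(sm$score[5], 1)
  # constant squared statistic across a dense window stays put
  sm2 <- smooth_and_score(rep(2, 6), seq(0, 1000, by = 200), df = 22)
  expect_equal(sm2$score, rep(4, 6))
  expect_error(smooth_and_score(t, rev(pos), df = 22), "sorted")
})

test_that("BH adjustment is monotone and probabilities are valid", {
  set.seed(21)
  pos <- sort(sample(1:1e6, 400))
  t <- rt(400, df = 22)
  sm <- smooth_and_score(t, pos, df = 22)
  expect_true(all(sm$p >= 0 & sm$p <= 1))
  expect_true(all(sm$padj >= sm$p - 1e-15))
  expect_true(all(diff(sm$padj[order(sm$p)]) >= -1e-12))
})

test_that("gap rule: isolated significant probes cannot form regions", {
  means <- matrix(rep(c(0.3, 0.3, 0.3, 0.5), each = 2), nrow = 2,
                  byrow = FALSE)
  ds <- fx_toy_dataset(means, noise_sd = 0.01, seed = 3)
  ds$manifest$position <- c(1000, 11000) # 10x lambda apart
  scored <- data.frame(probe_id = rownames(ds$beta),
                       chromosome = "chr1",
                       position = ds$manifest$position,
                       padj = c(0.001, 0.001))
  expect_equal(nrow(call_regions(scored, ds, min_cpgs = 2)), 0L)
  # with min_cpgs = 1 both become (single-probe) regions
  expect_equal(nrow(call_regions(scored, ds, min_cpgs = 1)), 2L)
})

test_that("regions where the exposed-carrier group is intermediate are excluded", {
  means <- rbind(c(0.2, 0.6, 0.3, 0.5), c(0.2, 0.6, 0.3, 0.5))
  ds <- fx_toy_dataset(means, noise_sd = 0.005, seed = 4)
  scored <- data.frame(probe_id = rownames(ds$beta), chromosome = "chr1",
                       position = ds$manifest$position,
                       padj = c(0.001, 0.001))
  expect_equal(nrow(call_regions(scored, ds)), 0L)
  # flip: exposed-carrier strictly highest -> one hyper region
  means2 <- rbind(c(0.2, 0.35, 0.3, 0.6), c(0.2, 0.35, 0.3, 0.6))
  ds2 <- fx_toy_dataset(means2, noise_sd = 0.005, seed = 4)
  rg <- call_regions(scored, ds2)
  expect_equal(nrow(rg), 1L)
  expect_equal(rg$direction, "hyper")
  expect_equal(rg$n_cpgs, 2L)
})

test_that("planted DMRs are recovered with the right span and direction", {
  sim <- fx_default_sim()
  dmr <- run_dmr_scan(fx_processed())
  tr <- sim$truth$planted_dmr_intervals
  for (i in seq_len(nrow(tr))) {
    planted_ids <- strsplit(tr$probe_ids[i], ";")[[1]]
    cand <- dmr$regions[dmr$regions$chromosome == tr$chromosome[i], ,
                        drop = FALSE]
    covered <- vapply(seq_len(nrow(cand)), function(k) {
      sum(planted_ids %in% strsplit(cand$probe_ids[k], ";")[[1]])
    }, numeric(1))
    best <- which.max(covered)
    expect_gte(covered[best], 6) # >= 6 of the 8 planted probes
    expect_equal(cand$direction[best], tr$direction[i])
  }
  expect_gte(min(fx_dmr_jaccard(tr, dmr$regions)), 0.6)
})

test_that("region boundaries stay inside the span of member probes", {
  dmr <- run_dmr_scan(fx_processed())
  ds <- fx_processed()
  for (k in seq_len(nrow(dmr$regions))) {
    ids <- strsplit(dmr$regions$probe_ids[k], ";")[[1]]
    pos <- ds$manifest[ids, "position"]
    expect_equal(dmr$regions$start[k], min(pos))
    expect_equal(dmr$regions$end[k], max(pos))
    expect_gte(dmr$regions$n_cpgs[k], dmr$params$min_cpgs)
  }
  expect_true(all(dmr$regions$start <= dmr$regions$end))
  expect_true(all(dmr$regions$p_adj >= 0 & dmr$regions$p_adj < 0.05))
})

test_that("BED export uses 0-based half-open coordinates and capped scores", {
  dmr <- run_dmr_scan(fx_processed())
  path <- tempfile(fileext = ".bed")
  bed <- write_dmr_bed(dmr, path)
  expect_true(file.exists(path))
  expect_equal(bed$start, dmr$regions$start - 1L)
  expect_equal(bed$end, dmr$regions$end)
  expect_true(all(bed$score <= 1000))
  expect_true(all(grepl("\\|(hyper|hypo)$", bed$name)))
})
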