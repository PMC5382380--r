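test_that("beta/M transform hits the textbook values and round-trips", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  x <- seq(1e-6, 1 - 1e-6, length.out = 201)
  expect_equal(m_to_beta(beta_to_m(x)), x, tolerance = 1e-12)
  expect_true(all(diff(beta_to_m(x)) > 0)) # strictly monotone
  expect_error(beta_to_m(1.2), "\\[0, 1\\]")
  expect_error(beta_to_m(-0.1), "\\[0, 1\\]")
})

test_that("greedycut removes by highest failure fraction, probe before sample", {
  # P1 fails in 3/4 samples (0.75); sample A fails 2/5 probes (0.40).
  # Greedy order: P1 (0.75), then P2 vs A tie at 0.25 -> probe first.
  dp <- matrix(0.001, nrow = 5, ncol = 4,
               dimnames = list(paste0("P", 1:5), LETTERS[1:4]))
  dp["P1", c("A", "B", "C")] <- 0.5
  dp["P2", "A"] <- 0.5
  gc <- greedycut(dp, 0.01)
  expect_equal(gc$removed_probes, c("P1", "P2"))
  expect_equal(gc$removed_samples, character(0))
  expect_equal(gc$steps$fail_fraction, c(0.75, 0.25))

  # a sample failing 4/5 probes beats any probe failing 1/4 samples
  dp2 <- matrix(0.001, nrow = 5, ncol = 4,
                dimnames = list(paste0("P", 1:5), LETTERS[1:4]))
  dp2[1:4, "D"] <- 0.5
  gc2 <- greedycut(dp2, 0.01)
  expect_equal(gc2$removed_samples, "D")
  expect_equal(gc2$removed_probes, character(0))
})

test_that("pre-norm filter removes SNP/greedycut/missing probes with one reason each", {
  sim <- fx_default_sim()
  ds <- sim$dataset
  # plant a missing value on a clean probe
  clean <- setdiff(rownames(ds$beta),
                   c(ds$manifest$probe_id[ds$manifest$snp_within_3bp],
                     sim$truth$bad_detection_ids))
  ds$beta[clean[1], 3] <- NA
  res <- filter_probes_pre_norm(ds)
  rep <- res$report
  expect_s3_class(rep, "filter_report")
  # every SNP-flagged probe removed with that reason
  snp_ids <- ds$manifest$probe_id[ds$manifest$snp_within_3bp]
  expect_setequal(rep$removed$probe_id[rep$removed$reason == "snp_within_3bp"],
                  snp_ids)
  expect_true(clean[1] %in%
                rep$removed$probe_id[rep$removed$reason == "missing_value"])
  # one reason per probe; counts add up; removed disjoint from retained
  expect_equal(anyDuplicated(rep$removed$probe_id), 0L)
  expect_equal(nrow(rep$removed) + rep$n_retained, nrow(ds$beta))
  expect_length(intersect(rep$removed$probe_id,
                          rownames(res$dataset$beta)), 0)
  # greedycut-flagged bad probes are gone
  expect_length(intersect(sim$truth$bad_detection_ids,
                          rownames(res$dataset$beta)), 0)
})

test_that("clean datasets pass the pre-norm filter unchanged", {
  ds <- fx_toy_dataset(matrix(c(0.3, 0.3, 0.3, 0.3), nrow = 1))
  ds$detection_p <- matrix(0.001, nrow = 1, ncol = 8,
                           dimnames = dimnames(ds$beta))
  res <- filter_probes_pre_norm(ds)
  expect_identical(res$dataset$beta, ds$beta)
  expect_equal(nrow(res$report$removed), 0L)
})

test_that("post-norm filter drops non-CpG probes and all sex-chromosome aliases", {
  beta <- matrix(0.5, nrow = 6, ncol = 8)
  dimnames(beta) <- list(paste0("p", 1:6), sprintf("T%02d", 1:8))
  manifest <- data.frame(
    probe_id = rownames(beta),
    chromosome = c("chr1", "X", "chrX", "23", "y", "chr2"),
    position = 1:6, probe_class = c("cg", "cg", "cg", "cg", "cg", "ch"),
    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(beta),
                        exposure = rep(0:1, 4), carrier = rep(0:1, each = 4),
                        sex = 0)
  ds <- methylation_dataset(beta, manifest, samples)
  res <- filter_probes_post_norm(ds)
  expect_setequal(rownames(res$dataset$beta), "p1")
  expect_setequal(
    res$report$removed$probe_id[res$report$removed$reason == "sex_chromosome"],
    c("p2", "p3", "p4", "p5"))
  expect_equal(res$report$removed$reason[res$report$removed$probe_id == "p6"],
               "non_cpg")
})

test_that("filtering is idempotent", {
  sim <- fx_default_sim()
  r1 <- filter_probes_pre_norm(sim$dataset)
  r2 <- filter_probes_pre_norm(r1$dataset)
  expect_identical(r2$dataset$beta, r1$dataset$beta)
  expect_equal(nrow(r2$report$removed), 0L)
  p1 <- filter_probes_post_norm(r1$dataset)
  p2 <- filter_probes_post_norm(p1$dataset)
  expect_identical(p2$dataset$beta, p1$dataset$beta)
})

test_that("PCA diagnostics detect a planted batch shift", {
  sim <- generate_dataset(simulation_config(n_probes = 4000, batch_shift = 1,
                                            batch_levels = 2, seed = 31))
  bd <- batch_diagnostics(sim$dataset, covariates = c("batch", "exposure"))
  expect_equal(ncol(bd$pc_scores), 8L)
  pb <- bd$association_p[bd$association_p$covariate == "batch", ]
  expect_lt(min(pb$p), 0.05)
  expect_true(all(bd$association_p$p >= 0 & bd$association_p$p <= 1,
                  na.rm = TRUE))
})

test_that("single-level covariates are flagged, not tested", {
  sim <- fx_default_sim()
  ds <- sim$dataset
  ds$samples$flat <- 1
  expect_warning(bd <- batch_diagnostics(ds, covariates = "flat"),
                 "single level")
  expect_true(all(is.na(bd$association_p$p)))
  expect_true(all(bd$association_p$flag == "single_level"))
})

test_that("batch adjustment equalises batch means and is near-identity without batch effects", {
  # planted shift: residual batch means equalised afterwards
  sim <- generate_dataset(simulation_config(n_probes = 2000, batch_shift = 1,
                                            batch_levels = 2, seed = 41))
  adj <- adjust_batch(sim$dataset)
  b <- factor(adj$samples$batch)
  Z <- stats::model.matrix(~ exposure + carrier + sex, data = adj$samples)
  H <- Z %*% solve(crossprod(Z)) %*% t(Z)
  resid <- adj$m - adj$m %*% H
  bm <- vapply(levels(b), function(lv) {
    rowMeans(resid[, b == lv, drop = FALSE])
  }, numeric(nrow(resid)))
  expect_lt(max(abs(bm[, 1] - bm[, 2])), 1e-8)

  # protected-covariate coefficients refit on adjusted data equal the
  # joint-fit estimates exactly
  sm <- adj$samples
  for (i in c(2, 17, 101)) {
    cj <- stats::coef(stats::lm(sim$dataset$m[i, ] ~ exposure + carrier +
                                  sex + factor(batch), data = sm))
    ca <- stats::coef(stats::lm(adj$m[i, ] ~ exposure + carrier + sex,
                                data = sm))
    expect_equal(unname(ca["exposure"]), unname(cj["exposure"]),
                 tolerance = 1e-10)
    expect_equal(unname(ca["carrier"]), unname(cj["carrier"]),
                 tolerance = 1e-10)
  }
})

test_that("adjusting a batch-free dataset leaves planted DMP recovery intact", {
  cfg <- simulation_config(n_probes = 6000, batch_shift = 0, seed = 61)
  sim <- generate_dataset(cfg)
  recov <- function(d) {
    tab <- run_dmp_scan(d)$table
    tr <- sim$truth
    pl <- tab[match(intersect(tr$planted_dmp_ids, tab$probe_id),
                    tab$probe_id), ]
    sum(pl$sig_model_A & pl$direction ==
          tr$dmp_direction[match(pl$probe_id, tr$planted_dmp_ids)])
  }
  r_raw <- recov(sim$dataset)
  r_adj <- recov(adjust_batch(sim$dataset))
  expect_lte(abs(r_adj - r_raw) / length(sim$truth$planted_dmp_ids), 0.02)
})

test_that("planted batch association vanishes after adjustment", {
  ok <- vapply(1:10, function(s) {
    sim <- generate_dataset(simulation_config(n_probes = 2000,
                                              batch_shift = 1,
                                              batch_levels = 2,
                                              seed = 500 + s))
    pre <- batch_diagnostics(sim$dataset, covariates = "batch")
    worst <- which.min(pre$association_p$p)
    post <- batch_diagnostics(adjust_batch(sim$dataset),
                              covariates = "batch")
    pre$association_p$p[worst] < 0.05 &&
      post$association_p$p[1] > 0.05 # PC1 no longer batch-driven
  }, logical(1))
  expect_gte(sum(ok), 8)
})

test_that("degenerate batch structures are rejected", {
  ds <- fx_toy_dataset(matrix(rep(0.4, 4), nrow = 1), noise_sd = 0.01)
  ds$samples$batch <- c(1, 1, 1, 1, 1, 1, 1, 2) # singleton batch
  expect_error(adjust_batch(ds), "at least 2 samples")
  # batch identical to a protected covariate
  sim <- generate_dataset(simulation_config(n_probes = 1000,
                                            batch_confounded = TRUE,
                                            batch_levels = 2, seed = 8))
  expect_error(adjust_batch(sim$dataset), "confounded")
})
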