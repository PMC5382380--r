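test_that("ACME equals the product of the model-2 and model-4 coefficients", {
  md <- simulate_mediation_data(n = 40, a = 1, b = 0.8, c_prime = 0.3,
                                seed = 2)
  bk <- baron_kenny(md$mark, md$outcome, md$exposure, sex = md$sex,
                    adjust_sex = TRUE)
  expect_equal(bk$acme,
               unname(bk$model2["coef"] * bk$model4_mark["coef"]),
               tolerance = 1e-12)
  bt <- bootstrap_acme(md$mark, md$outcome, md$exposure,
                       covariates = data.frame(sex = md$sex),
                       n_boot = 300, seed = 5)
  expect_equal(bt$acme, bk$acme, tolerance = 1e-10)
  # seeded determinism of the bootstrap interval
  bt2 <- bootstrap_acme(md$mark, md$outcome, md$exposure,
                        covariates = data.frame(sex = md$sex),
                        n_boot = 300, seed = 5)
  expect_identical(bt$ci, bt2$ci)
  expect_identical(bt$p, bt2$p)
  expect_lte(bt$ci[1], bt$ci[2])
  expect_gte(bt$p, 2 / 300)
})

test_that("a broken a-path yields classification none", {
  md <- simulate_mediation_data(n = 40, a = 0, b = 1, c_prime = 1, seed = 3)
  bk <- baron_kenny(md$mark, md$outcome, md$exposure)
  expect_equal(bk$classification, "none")
  expect_gt(bk$model2["p"], 0.05)
})

test_that("planted partial mediation attenuates the model-4 exposure effect", {
  ok <- vapply(1:50, function(s) {
    md <- simulate_mediation_data(n = 24, a = 1, b = 0.8, c_prime = 0.5,
                                  seed = 100 + s)
    bk <- baron_kenny(md$mark, md$outcome, md$exposure)
    abs(bk$model4_exposure["coef"]) < abs(bk$model1["coef"])
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("the model-4 exposure coefficient vanishes with n under full mediation", {
  med_abs <- vapply(c(24, 96, 384), function(n) {
    stats::median(vapply(1:21, function(s) {
      md <- simulate_mediation_data(n = n, a = 1, b = 1, c_prime = 0,
                                    seed = 2000 + 31 * n + s)
      abs(baron_kenny(md$mark, md$outcome,
                      md$exposure)$model4_exposure["coef"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_abs) < 0))
})

test_that("bootstrap interval width shrinks with sample size", {
  width <- vapply(c(24, 96, 384), function(n) {
    stats::median(vapply(1:11, function(s) {
      md <- simulate_mediation_data(n = n, a = 1, b = 1, c_prime = 0,
                                    seed = 3000 + 17 * n + s)
      bt <- bootstrap_acme(md$mark, md$outcome, md$exposure, n_boot = 200,
                           seed = s)
      diff(bt$ci)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(width) < 0))
})

test_that("degenerate inputs are caught", {
  md <- simulate_mediation_data(n = 24, seed = 4)
  expect_error(baron_kenny(md$mark[1:8], md$outcome[1:8], md$exposure[1:8]),
               "at least 10")
  expect_warning(out <- baron_kenny(rep(1, 24), md$outcome, md$exposure),
                 "zero-variance")
  expect_null(out)
  expect_error(bootstrap_acme(md$mark, md$outcome, md$exposure,
                              n_boot = 50), "at least 200")
  expect_error(ln_leptin(c(1, 0)), "positive")
})

test_that("the screen finds planted mediators among noise candidates", {
  set.seed(71)
  n <- 48
  n_noise <- 100
  exposure <- rep(0:1, each = n / 2)
  sex <- rep_len(0:1, n)
  m_noise <- matrix(rnorm(n_noise * n, 0, 0.4), n_noise)
  m_med <- t(vapply(1:3, function(i) 1.5 * exposure + rnorm(n, 0, 0.25),
                    numeric(n)))
  M <- rbind(m_med, m_noise)
  rownames(M) <- c(sprintf("med%d", 1:3), sprintf("n%03d", seq_len(n_noise)))
  colnames(M) <- sprintf("S%02d", 1:n)
  ln_lep <- 0.3 * exposure + 1.2 * colSums(m_med) + 0.1 * sex +
    rnorm(n, 0, 0.25)
  samples <- data.frame(sample_id = colnames(M), exposure = exposure,
                        carrier = 1, sex = sex, leptin = exp(ln_lep),
                        bmi_z = rnorm(n))
  manifest <- data.frame(probe_id = rownames(M), chromosome = "chr1",
                         position = seq_len(nrow(M)) * 500)
  ds <- methylation_dataset(m_to_beta(M), manifest, samples)
  ds$m <- M
  scr <- mediation_screen(ds, candidates = rownames(M),
                          outcomes = c("leptin", "bmi_z"))
  tab <- scr$table
  lep <- tab[tab$outcome == "leptin", ]
  found <- lep$mark[lep$classification %in% c("partial", "full")]
  expect_gte(sum(sprintf("med%d", 1:3) %in% found), 2)
  expect_lte(sum(!grepl("^med", found)), 5)
  # an outcome with no exposure effect produces no mediators
  bz <- tab[tab$outcome == "bmi_z", ]
  expect_true(all(bz$classification == "none"))
})

test_that("the screen is restricted to the candidate subset and carrier scope", {
  sim <- fx_default_sim()
  ds <- sim$dataset
  marks <- sim$truth$true_mediation_paths$mark
  other <- setdiff(rownames(ds$m), marks)[1:5]
  scr <- mediation_screen(ds, candidates = c(marks[1], other),
                          outcomes = "leptin")
  expect_false(marks[2] %in% scr$table$mark) # not a candidate, never tested
  expect_true(all(scr$table$mark %in% c(marks[1], other)))
  expect_equal(unique(scr$table$n), sum(ds$samples$carrier == 1))
  expect_error(mediation_screen(ds, candidates = character(0)), "empty")
})
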