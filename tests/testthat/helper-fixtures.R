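# Shared fixtures, built in code and cached across test files.

.fx <- new.env(parent = emptyenv())

# Mediation structure with nothing planted.
fx_no_mediation <- function() {
  data.frame(mark = integer(), outcome = character(), a = numeric(),
             b = numeric(), c_prime = numeric())
}

# Zero-effect configuration: nothing planted, no batch shift.
fx_null_config <- function(seed, n_probes = 20000) {
  simulation_config(n_probes = n_probes, n_dmp_planted = 0, dmp_effect = 0,
                    n_dmr_planted = 1, snp_effect_per_allele = 0,
                    batch_shift = 0, seed = seed,
                    mediation_spec = fx_no_mediation())
}

# Default-condition simulation used by several files (planted effects).
fx_default_sim <- function() {
  if (is.null(.fx$default)) {
    .fx$default <- generate_dataset(simulation_config(n_probes = 6000,
                                                      seed = 101))
  }
  .fx$default
}

# The same simulation taken through the preprocessing stages.
fx_processed <- function() {
  if (is.null(.fx$processed)) {
    sim <- fx_default_sim()
    ds <- filter_probes_pre_norm(sim$dataset)$dataset
    ds <- filter_probes_post_norm(normalize_dataset(ds))$dataset
    .fx$processed <- adjust_batch(ds)
  }
  .fx$processed
}

# Tiny dataset with hand-set group means: 8 samples, 2 per design cell.
# `means` is a 4-vector (unexposed-QQ, exposed-QQ, unexposed-carrier,
# exposed-carrier) of beta-scale means per probe row of `means_matrix`.
fx_toy_dataset <- function(means_matrix, noise_sd = 0, seed = 1) {
  n_probes <- nrow(means_matrix)
  samples <- data.frame(
    sample_id = sprintf("T%02d", 1:8),
    exposure = c(0, 0, 1, 1, 0, 0, 1, 1),
    carrier = c(0, 0, 0, 0, 1, 1, 1, 1),
    sex = rep(c(0, 1), 4))
  grp <- 1 + samples$exposure + 2 * samples$carrier
  set.seed(seed)
  beta <- means_matrix[, grp, drop = FALSE] +
    matrix(stats::rnorm(n_probes * 8, 0, noise_sd), n_probes)
  beta <- pmin(pmax(beta, 0.01), 0.99)
  dimnames(beta) <- list(sprintf("p%03d", seq_len(n_probes)),
                         samples$sample_id)
  manifest <- data.frame(probe_id = rownames(beta), chromosome = "chr1",
                         position = seq_len(n_probes) * 500,
                         probe_class = "cg", snp_within_3bp = FALSE,
                         gene = "G1", stringsAsFactors = FALSE)
  methylation_dataset(beta, manifest, samples)
}

# Independent two-sided Fisher oracle: exhaustive hypergeometric tail sum
# over all tables with the observed margins, summing probabilities at most
# that of the observed table (with the conventional relative tolerance).
fx_fisher_oracle <- function(a, b, c, d) {
  # X = count in cell (1,1) with margins (a+b), (c+d), first-column total
  # a+c: P(X=x) = dhyper(x, a+b, c+d, a+c)
  support <- max(0L, (a + c) - (c + d)):min(a + b, a + c)
  probs <- stats::dhyper(support, a + b, c + d, a + c)
  p_obs <- stats::dhyper(a, a + b, c + d, a + c)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Interval Jaccard on 1-based inclusive intervals.
fx_jaccard <- function(a1, b1, a2, b2) {
  inter <- max(0, min(b1, b2) - max(a1, a2) + 1)
  inter / (max(b1, b2) - min(a1, a2) + 1)
}

# Best-candidate Jaccard of each planted DMR against a called region set.
fx_dmr_jaccard <- function(truth_intervals, regions) {
  vapply(seq_len(nrow(truth_intervals)), function(i) {
    ti <- truth_intervals[i, ]
    cand <- regions[regions$chromosome == ti$chromosome, , drop = FALSE]
    if (nrow(cand) == 0) return(0)
    max(vapply(seq_len(nrow(cand)), function(k) {
      fx_jaccard(ti$start, ti$end, cand$start[k], cand$end[k])
    }, numeric(1)))
  }, numeric(1))
}
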