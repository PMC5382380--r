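#' Configuration for the synthetic 450K-style data generator
#'
#' Captures every knob of the simulated study: a four-cell prenatal
#' exposure-by-PON1-genotype design, beta-distributed probe noise around a
#' bimodal baseline, a six-cell-type mixture, planted interaction DMPs and
#' DMRs in which the exposed R-allele carrier group is the most extreme,
#' batch shifts on the M scale, a cis-SNP additively driving a promoter
#' probe cluster, and outcomes partially mediated by specific methylation
#' marks.
#'
#' @param n_probes Number of probes.
#' @param group_sizes Named counts for the four design cells; the default
#'   `c(11, 13, 12, 12)` (unexposed-QQ, exposed-QQ, unexposed-carrier,
#'   exposed-carrier) mirrors a 48-child cohort layout.
#' @param n_dmp_planted Number of isolated interaction DMPs to plant.
#' @param dmp_effect Beta-scale shift applied to the exposed-carrier group
#'   at planted DMP and DMR probes (sign drawn per probe/region).
#' @param n_dmr_planted Number of planted DMRs (runs of adjacent probes
#'   with a coherent shift).
#' @param dmr_width_probes Probes per planted DMR.
#' @param probe_spacing_bp Mean spacing between adjacent probes (jittered
#'   +/- 25%).
#' @param noise_dispersion Beta-distribution precision `phi`: sample betas
#'   are drawn `Beta(mu * phi, (1 - mu) * phi)` around the sample mean `mu`.
#' @param n_celltypes Number of leukocyte reference types (fixed at 6:
#'   granulocyte, CD4T, CD8T, B, monocyte, NK).
#' @param batch_levels Number of batches, assigned round-robin.
#' @param batch_shift M-scale offset per unit batch level (offsets are
#'   centred across levels).
#' @param snp_cluster_size Probes in the cis-SNP-driven promoter cluster.
#' @param snp_effect_per_allele Beta-scale shift per minor (T) allele at
#'   cluster probes.
#' @param mediation_spec Data frame with columns `mark` (index of the
#'   planted mediator probe), `outcome` (one of `leptin`, `body_fat_pct`,
#'   `delta_bmi_z`, `bmi_z`), and path coefficients `a` (exposure -> mark,
#'   M units), `b` (mark -> outcome per M unit), `c_prime` (direct
#'   exposure -> outcome). See [default_mediation_spec()].
#' @param seed Master seed; fully determines the generated dataset.
#' @param batch_confounded If `TRUE`, batch is assigned by exposure group
#'   instead of round-robin (for exercising the PCA diagnostic).
#' @param force_identical_celltypes Debug flag: makes the CD8T reference
#'   methylome identical to CD4T so downstream deconvolution must flag
#'   collinearity.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_probes = 20000,
                              group_sizes = c("unexposed-QQ" = 11,
                                              "exposed-QQ" = 13,
                                              "unexposed-carrier" = 12,
                                              "exposed-carrier" = 12),
                              n_dmp_planted = 50,
                              dmp_effect = 0.15,
                              n_dmr_planted = 5,
                              dmr_width_probes = 8,
                              probe_spacing_bp = 500,
                              noise_dispersion = 50,
                              n_celltypes = 6,
                              batch_levels = 4,
                              batch_shift = 0.5,
                              snp_cluster_size = 9,
                              snp_effect_per_allele = 0.1,
                              mediation_spec = default_mediation_spec(),
                              seed = 1,
                              batch_confounded = FALSE,
                              force_identical_celltypes = FALSE) {
  cfg <- list(n_probes = as.integer(n_probes),
              group_sizes = group_sizes,
              n_dmp_planted = as.integer(n_dmp_planted),
              dmp_effect = dmp_effect,
              n_dmr_planted = as.integer(n_dmr_planted),
              dmr_width_probes = as.integer(dmr_width_probes),
              probe_spacing_bp = probe_spacing_bp,
              noise_dispersion = noise_dispersion,
              n_celltypes = as.integer(n_celltypes),
              batch_levels = as.integer(batch_levels),
              batch_shift = batch_shift,
              snp_cluster_size = as.integer(snp_cluster_size),
              snp_effect_per_allele = snp_effect_per_allele,
              mediation_spec = mediation_spec,
              seed = as.integer(seed),
              batch_confounded = isTRUE(batch_confounded),
              force_identical_celltypes = isTRUE(force_identical_celltypes))
  cfg$n_samples <- sum(group_sizes)
  .validate_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

.validate_config <- function(cfg) {
  counts <- c(cfg$n_probes, cfg$group_sizes, cfg$n_samples,
              cfg$dmr_width_probes, cfg$snp_cluster_size,
              cfg$batch_levels, cfg$n_celltypes)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$n_dmp_planted < 0 || cfg$n_dmr_planted < 0) {
    stop("planted feature counts must be non-negative")
  }
  if (length(cfg$group_sizes) != 4) {
    stop("group_sizes must give counts for the 4 exposure x carrier cells")
  }
  if (cfg$n_celltypes != 6) stop("n_celltypes is fixed at 6")
  if (cfg$dmp_effect < 0 || cfg$snp_effect_per_allele < 0) {
    stop("effect sizes must be non-negative")
  }
  # Planted baselines live in [0.30, 0.65]; shifts must keep the planted
  # group means inside the open unit interval with margin.
  if (0.65 + cfg$dmp_effect >= 0.98 || 0.30 - cfg$dmp_effect <= 0.02) {
    stop("dmp_effect pushes planted group means outside (0, 1)")
  }
  if (0.65 + 2 * cfg$snp_effect_per_allele >= 0.98) {
    stop("snp_effect_per_allele pushes cluster means outside (0, 1)")
  }
  if (cfg$noise_dispersion <= 2) stop("noise_dispersion must exceed 2")
  invisible(cfg)
}

#' Default planted mediation structure
#'
#' Three mediator marks: one partially mediating the exposure effect on
#' (ln) leptin, one on body-fat percentage, one on the change in BMI Z
#' score. Path coefficients are on the analysis scales (`a` in M units per
#' exposure, `b` in outcome units per M unit, `c_prime` in outcome units).
#'
#' @return Data frame with columns `mark`, `outcome`, `a`, `b`, `c_prime`.
#' @export
default_mediation_spec <- function() {
  data.frame(mark = 1:3,
             outcome = c("leptin", "body_fat_pct", "delta_bmi_z"),
             a = c(1.2, 1.2, 1.2),
             b = c(0.4, 2.0, 0.35),
             c_prime = c(0.2, 1.5, 0.2),
             stringsAsFactors = FALSE)
}

# Deterministic layout shared by generate_dataset() and
# generate_reference_methylomes(): manifest, baseline methylation, planted
# probe sets and the cell-type reference matrix. Must be called inside
# .with_seed(cfg$seed, ...) and consumes a fixed number of RNG draws for a
# given config.
.generate_layout <- function(cfg) {
  n <- cfg$n_probes
  probe_id <- sprintf("cg%08d", seq_len(n))

  # One synthetic chromosome per 10,000 probes; trailing ~2% relabelled chrX
  # so the sex-chromosome filter has work to do. Positions 1-based, spaced
  # probe_spacing_bp +/- 25% jitter.
  n_chr <- max(1L, ceiling(n / 10000))
  chrom <- paste0("chr", rep(seq_len(n_chr), each = 10000)[seq_len(n)])
  n_x <- max(1L, round(0.02 * n))
  chrom[(n - n_x + 1L):n] <- "chrX"
  gaps <- round(cfg$probe_spacing_bp * stats::runif(n, 0.75, 1.25))
  position <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    position[idx] <- 10000L + cumsum(gaps[idx])
  }

  probe_class <- sample(c("cg", "ch", "rs"), n, replace = TRUE,
                        prob = c(0.985, 0.012, 0.003))
  snp_within_3bp <- stats::runif(n) < 0.02

  # Genes in blocks of 10 probes; ~35% of blocks intergenic.
  block <- (seq_len(n) - 1L) %/% 10L
  block_gene <- ifelse(stats::runif(max(block) + 1L) < 0.35, "",
                       sprintf("G%05d", seq_len(max(block) + 1L)))
  gene <- block_gene[block + 1L]
  elements <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR")
  gene_element <- ifelse(gene == "", "intergenic",
                         sample(elements, n, replace = TRUE,
                                prob = c(0.12, 0.12, 0.09, 0.06, 0.52, 0.09)))
  cpg_context <- sample(c("island", "shore", "shelf", "open-sea"), n,
                        replace = TRUE, prob = c(0.30, 0.23, 0.10, 0.37))
  chromatin_state <- sample(c("Active promoter", "Strong enhancer",
                              "Transcribed", "Heterochromatin",
                              "Polycomb repressed"), n,
                            replace = TRUE,
                            prob = c(0.15, 0.10, 0.30, 0.35, 0.10))
  tf_labels <- sprintf("TF%03d", seq_len(20))
  tf_member <- matrix(stats::runif(n * length(tf_labels)) < 0.03, nrow = n)
  tfbs <- apply(tf_member, 1L,
                function(r) paste(tf_labels[r], collapse = ";"))

  # Bimodal, boundary-heavy baseline means (mixture of betas), clamped away
  # from the boundary so beta draws stay strictly inside (0, 1).
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  m0 <- numeric(n)
  m0[comp == 1] <- stats::rbeta(sum(comp == 1), 1.5, 8)
  m0[comp == 2] <- stats::rbeta(sum(comp == 2), 8, 1.5)
  m0[comp == 3] <- stats::rbeta(sum(comp == 3), 5, 5)
  m0 <- pmin(pmax(m0, 0.03), 0.97)

  # Probes failing detection in most samples (Greedycut fodder).
  usable <- probe_class == "cg" & !snp_within_3bp & !.is_sex_chromosome(chrom)
  bad_detection <- sort(sample(which(usable), max(1L, round(0.002 * n))))
  clean <- usable
  clean[bad_detection] <- FALSE

  # Planted features: DMR runs first (need adjacency), then the SNP promoter
  # cluster, then isolated DMPs and mediator marks. All planted probes get
  # mid-range baselines so beta-scale shifts stay inside (0, 1), and are
  # excluded from cell-type signatures (no mixture signal on top of the
  # planted contrast).
  taken <- logical(n)
  pick_run <- function(width) {
    ok <- clean & !taken
    # candidate start: `width` consecutive clean untaken probes on one chrom
    runs <- which(vapply(seq_len(n - width + 1L), function(i) {
      all(ok[i:(i + width - 1L)]) && chrom[i] == chrom[i + width - 1L]
    }, logical(1)))
    if (length(runs) == 0) stop("not enough clean probes to plant a region")
    start <- sample(runs, 1L)
    idx <- start:(start + width - 1L)
    # keep a buffer of 4 probes either side untouchable so planted regions
    # never merge with one another
    buf <- max(1L, start - 4L):min(n, start + width + 3L)
    taken[buf] <<- TRUE
    idx
  }
  dmr_idx <- lapply(seq_len(cfg$n_dmr_planted),
                    function(i) pick_run(cfg$dmr_width_probes))
  snp_idx <- pick_run(cfg$snp_cluster_size)
  n_marks <- if (nrow(cfg$mediation_spec)) max(cfg$mediation_spec$mark) else 0L
  free <- which(clean & !taken)
  singles <- sample(free, cfg$n_dmp_planted + n_marks)
  dmp_idx <- singles[seq_len(cfg$n_dmp_planted)]
  mark_idx <- if (n_marks > 0) singles[cfg$n_dmp_planted + seq_len(n_marks)]
              else integer(0)
  taken[singles] <- TRUE
  planted_all <- c(unlist(dmr_idx), snp_idx, dmp_idx, mark_idx)
  m0[planted_all] <- stats::runif(length(planted_all), 0.30, 0.65)

  # Cell-type reference methylomes: 600 signature probes per type with a
  # +/-0.6 (clipped) offset from the shared baseline; all other probes are
  # identical across types.
  types <- c("granulocyte", "CD4T", "CD8T", "B", "monocyte", "NK")
  reference <- matrix(m0, nrow = n, ncol = length(types),
                      dimnames = list(probe_id, types))
  sig_pool <- which(clean & !taken)
  n_sig <- 600L
  if (length(sig_pool) < n_sig * length(types)) {
    n_sig <- max(1L, length(sig_pool) %/% length(types))
  }
  sig_ids <- vector("list", length(types))
  for (k in seq_along(types)) {
    ids <- sample(sig_pool, n_sig)
    sig_pool <- setdiff(sig_pool, ids)
    sig_ids[[k]] <- ids
    offset <- stats::runif(length(ids), 0.35, 0.55)
    reference[ids, k] <- ifelse(m0[ids] < 0.5,
                                pmin(0.95, m0[ids] + offset),
                                pmax(0.05, m0[ids] - offset))
  }
  if (cfg$force_identical_celltypes) reference[, "CD8T"] <- reference[, "CD4T"]

  manifest <- data.frame(probe_id = probe_id, chromosome = chrom,
                         position = position, probe_class = probe_class,
                         snp_within_3bp = snp_within_3bp, gene = gene,
                         gene_element = gene_element,
                         cpg_context = cpg_context,
                         chromatin_state = chromatin_state, tfbs = tfbs,
                         stringsAsFactors = FALSE)
  list(manifest = manifest, m0 = m0, reference = reference,
       bad_detection = bad_detection, dmr_idx = dmr_idx, snp_idx = snp_idx,
       dmp_idx = dmp_idx, mark_idx = mark_idx, signature_idx = sig_ids)
}

#' Generate synthetic cell-type reference methylomes
#'
#' Stand-in for a sorted-leukocyte reference panel: one column per cell type
#' (granulocyte, CD4T, CD8T, B, monocyte, NK), each with at least 500
#' signature probes whose beta values differ from the other types by at
#' least 0.3. Deterministic given `config$seed` and consistent with the
#' reference used inside [generate_dataset()].
#'
#' @param config A [simulation_config()].
#' @return Numeric matrix (probes x 6 cell types) of reference betas.
#' @export
generate_reference_methylomes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, .generate_layout(config))$reference
}

#' Generate a synthetic methylation dataset with known ground truth
#'
#' Produces a complete 450K-style dataset — beta matrix, manifest, sample
#' sheet with covariates and outcomes, detection p-values — together with
#' the ground truth of everything planted: interaction DMPs and DMRs where
#' only the exposed R-allele carrier group is shifted (so that group is the
#' most extreme of the four), per-sample cell-type mixing weights, a
#' SNP-driven promoter cluster, and mediated outcomes. Betas are convex
#' combinations of the six reference methylomes with beta-distributed probe
#' noise; batch offsets are added on the M scale.
#'
#' @param config A [simulation_config()].
#' @return List with elements `dataset` (a [methylation_dataset()]),
#'   `truth` (class `ground_truth`: `planted_dmp_ids`, `dmp_direction`,
#'   `planted_dmr_intervals`, `true_cell_proportions`,
#'   `true_mediation_paths`, `snp_cluster_ids`, `signature_ids`) and
#'   `reference` (the cell-type reference matrix).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, .generate_dataset_impl(config))
}

.generate_dataset_impl <- function(cfg) {
  lay <- .generate_layout(cfg)
  n <- cfg$n_probes
  ns <- cfg$n_samples
  probe_id <- lay$manifest$probe_id
  sample_id <- sprintf("S%02d", seq_len(ns))

  # Sample sheet: groups in blocks, balanced sex within group, round-robin
  # batch (orthogonal to the design unless confounded mode is on).
  grp <- rep(names(cfg$group_sizes), cfg$group_sizes)
  exposure <- as.integer(grepl("^exposed", grp))
  carrier <- as.integer(grepl("carrier", grp))
  sex <- unlist(lapply(cfg$group_sizes, function(g) {
    sample(rep_len(0:1, g))
  }), use.names = FALSE)
  age <- round(stats::runif(ns, 6, 11), 1)
  batch <- if (cfg$batch_confounded) {
    1L + exposure %% cfg$batch_levels
  } else {
    rep_len(seq_len(cfg$batch_levels), ns)
  }
  pon1_108 <- sample(c("CC", "CT", "TT"), ns, replace = TRUE,
                     prob = c(0.3, 0.5, 0.2))
  t_alleles <- c(CC = 0, CT = 1, TT = 2)[pon1_108]

  # Per-sample expected betas: mixture over cell types, then planted
  # shifts. Granulocyte-dominant whole-blood composition with realistic
  # inter-individual spread (sd of the granulocyte fraction ~0.085).
  W <- .rdirichlet(ns, c(18, 3, 3, 3, 3, 3))
  colnames(W) <- colnames(lay$reference)
  rownames(W) <- sample_id
  mu <- lay$reference %*% t(W)
  ec <- which(exposure == 1 & carrier == 1)

  dmp_sign <- sample(c(-1, 1), cfg$n_dmp_planted, replace = TRUE)
  for (i in seq_along(lay$dmp_idx)) {
    mu[lay$dmp_idx[i], ec] <- mu[lay$dmp_idx[i], ec] +
      dmp_sign[i] * cfg$dmp_effect
  }
  dmr_sign <- sample(c(-1, 1), cfg$n_dmr_planted, replace = TRUE)
  for (i in seq_along(lay$dmr_idx)) {
    mu[lay$dmr_idx[[i]], ec] <- mu[lay$dmr_idx[[i]], ec] +
      dmr_sign[i] * cfg$dmp_effect
  }
  mu[lay$snp_idx, ] <- mu[lay$snp_idx, ] +
    rep(cfg$snp_effect_per_allele * t_alleles, each = length(lay$snp_idx))
  if (any(mu <= 0.02 | mu >= 0.98)) {
    stop("planted effect sizes push expected betas outside (0, 1)")
  }

  phi <- cfg$noise_dispersion
  beta <- matrix(stats::rbeta(n * ns, c(mu) * phi, (1 - c(mu)) * phi),
                 nrow = n, dimnames = list(probe_id, sample_id))

  # M-scale edits: mediator marks gain a*exposure; batch offsets (centred
  # across levels) shift every probe.
  m <- beta_to_m(beta)
  med <- cfg$mediation_spec
  for (i in seq_len(nrow(med))) {
    j <- lay$mark_idx[med$mark[i]]
    m[j, ] <- m[j, ] + med$a[i] * exposure
  }
  offsets <- cfg$batch_shift * (seq_len(cfg$batch_levels) -
                                  (cfg$batch_levels + 1) / 2)
  m <- m + rep(offsets[batch], each = n)
  beta <- m_to_beta(m)

  # Detection p-values: clean probes well below 0.01; the designated bad
  # probes fail in ~80% of samples.
  detection_p <- matrix(stats::runif(n * ns, 1e-4, 0.005), nrow = n,
                        dimnames = list(probe_id, sample_id))
  for (j in lay$bad_detection) {
    hit <- stats::runif(ns) < 0.8
    detection_p[j, hit] <- stats::runif(sum(hit), 0.011, 0.5)
  }

  # Outcomes. Leptin is planted on the ln scale (the analysis scale) and
  # stored raw; BMI-Z outcomes carry no sex term (Z scores are already
  # sex-standardised).
  out <- list(
    leptin = 0.7 + 0.2 * sex + stats::rnorm(ns, 0, 0.35),
    body_fat_pct = 16 + 1.5 * sex + stats::rnorm(ns, 0, 2.5),
    delta_bmi_z = stats::rnorm(ns, 0, 0.5),
    bmi_z = stats::rnorm(ns, 0, 0.9)
  )
  for (i in seq_len(nrow(med))) {
    j <- lay$mark_idx[med$mark[i]]
    oc <- med$outcome[i]
    out[[oc]] <- out[[oc]] + med$c_prime[i] * exposure +
      med$b[i] * (m[j, ] - mean(m[j, ]))
  }
  out$leptin <- exp(out$leptin)
  promoter_m <- m[lay$snp_idx[1], ]
  pon1_activity <- 28 + 30 * carrier - 3 * promoter_m +
    stats::rnorm(ns, 0, 2.5)

  samples <- data.frame(sample_id = sample_id, exposure = exposure,
                        carrier = carrier,
                        pon1_192 = ifelse(carrier == 1, "QR/RR", "QQ"),
                        pon1_108 = pon1_108, sex = sex, age = age,
                        batch = batch, leptin = out$leptin,
                        body_fat_pct = out$body_fat_pct,
                        bmi_z = out$bmi_z, delta_bmi_z = out$delta_bmi_z,
                        pon1_activity = pon1_activity,
                        stringsAsFactors = FALSE)

  dmr_intervals <- do.call(rbind, lapply(seq_along(lay$dmr_idx), function(i) {
    idx <- lay$dmr_idx[[i]]
    data.frame(dmr = i,
               chromosome = lay$manifest$chromosome[idx[1]],
               start = min(lay$manifest$position[idx]),
               end = max(lay$manifest$position[idx]),
               n_probes = length(idx),
               direction = ifelse(dmr_sign[i] > 0, "hyper", "hypo"),
               probe_ids = paste(probe_id[idx], collapse = ";"),
               stringsAsFactors = FALSE)
  }))

  truth <- structure(list(
    planted_dmp_ids = probe_id[lay$dmp_idx],
    dmp_direction = ifelse(dmp_sign > 0, "hyper", "hypo"),
    planted_dmr_intervals = dmr_intervals,
    true_cell_proportions = W,
    true_mediation_paths = data.frame(
      mark = probe_id[lay$mark_idx[med$mark]],
      outcome = med$outcome, a = med$a, b = med$b, c_prime = med$c_prime,
      stringsAsFactors = FALSE),
    snp_cluster_ids = probe_id[lay$snp_idx],
    signature_ids = lapply(lay$signature_idx, function(i) probe_id[i]),
    bad_detection_ids = probe_id[lay$bad_detection]
  ), class = "ground_truth")

  list(dataset = methylation_dataset(beta, lay$manifest, samples,
                                     detection_p),
       truth = truth,
       reference = lay$reference)
}

#' Simulate a single mediation triple
#'
#' Draws exposure (balanced 0/1), a mediator mark on the M scale
#' (`mark = a * exposure + noise`) and an outcome
#' (`outcome = c_prime * exposure + b * mark + sex_effect * sex + noise`),
#' the structural model under which [baron_kenny()] and [bootstrap_acme()]
#' are validated.
#'
#' @param n Number of cases (even).
#' @param a,b,c_prime Path coefficients.
#' @param sd_mark,sd_outcome Residual standard deviations.
#' @param sex_effect Coefficient of the balanced 0/1 sex covariate.
#' @param seed Optional seed.
#' @return Data frame with columns `exposure`, `sex`, `mark`, `outcome`.
#' @export
simulate_mediation_data <- function(n = 24, a = 1, b = 1, c_prime = 0,
                                    sd_mark = 0.35, sd_outcome = 0.35,
                                    sex_effect = 0, seed = NULL) {
  draw <- function() {
    exposure <- rep(0:1, length.out = n)
    sex <- sample(rep_len(0:1, n))
    mark <- a * exposure + stats::rnorm(n, 0, sd_mark)
    outcome <- c_prime * exposure + b * mark + sex_effect * sex +
      stats::rnorm(n, 0, sd_outcome)
    data.frame(exposure = exposure, sex = sex, mark = mark,
               outcome = outcome)
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d planted DMPs, %d planted DMRs, %d-probe SNP cluster, %d mediation paths\n",
              length(x$planted_dmp_ids),
              if (is.null(x$planted_dmr_intervals)) 0L
              else nrow(x$planted_dmr_intervals),
              length(x$snp_cluster_ids),
              nrow(x$true_mediation_paths)))
  invisible(x)
}
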