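#' Greedycut-style pruning of unreliable probes and samples
#'
#' Iteratively removes the probe or sample with the highest fraction of
#' detection p-value failures (p > `threshold`) until no failing entry
#' remains. Ties are broken probe-before-sample, then by lexical id. This
#' is a transparent greedy analogue of the iterative quality pruning used
#' on 450K arrays.
#'
#' @param detection_p Matrix of detection p-values with probe rownames and
#'   sample colnames.
#' @param threshold Detection p-value above which a measurement counts as
#'   unreliable (default 0.01).
#' @return List with `removed_probes`, `removed_samples` (in removal
#'   order) and `steps` (a data frame logging each removal with its failure
#'   fraction).
#' @export
greedycut <- function(detection_p, threshold = 0.01) {
  fail <- detection_p > threshold
  removed_probes <- character(0)
  removed_samples <- character(0)
  steps <- list()
  while (any(fail)) {
    pf <- rowMeans(fail)
    sf <- colMeans(fail)
    best_p <- max(pf)
    best_s <- max(sf)
    if (best_p >= best_s) {
      id <- sort(rownames(fail)[pf == best_p])[1]
      removed_probes <- c(removed_probes, id)
      steps[[length(steps) + 1L]] <- data.frame(
        kind = "probe", id = id, fail_fraction = best_p,
        stringsAsFactors = FALSE)
      fail <- fail[rownames(fail) != id, , drop = FALSE]
    } else {
      id <- sort(colnames(fail)[sf == best_s])[1]
      removed_samples <- c(removed_samples, id)
      steps[[length(steps) + 1L]] <- data.frame(
        kind = "sample", id = id, fail_fraction = best_s,
        stringsAsFactors = FALSE)
      fail <- fail[, colnames(fail) != id, drop = FALSE]
    }
    if (nrow(fail) == 0 || ncol(fail) == 0) break
  }
  list(removed_probes = removed_probes, removed_samples = removed_samples,
       steps = if (length(steps)) do.call(rbind, steps) else
         data.frame(kind = character(), id = character(),
                    fail_fraction = numeric()))
}

.filter_report <- function(stage, removed, removed_samples, n_retained) {
  structure(list(stage = stage, removed = removed,
                 removed_samples = removed_samples,
                 n_retained = n_retained),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report (%s): %d probes removed, %d retained\n",
              x$stage, nrow(x$removed), x$n_retained))
  if (nrow(x$removed)) print(table(x$removed$reason))
  if (length(x$removed_samples)) {
    cat("samples removed:", paste(x$removed_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pre-normalisation probe filtering
#'
#' Applies the pre-normalisation filters in order of reason priority:
#' probes with a SNP within 3 bp of the interrogated CpG, probes (and
#' samples) failing the Greedycut pruning at the detection p-value
#' threshold, and probes with a missing value in at least one sample. Each
#' removed probe carries exactly one reason (snp > greedycut > missing).
#'
#' @param ds A [methylation_dataset()].
#' @param detection_threshold Detection p-value threshold (default 0.01).
#' @return List with `dataset` (filtered) and `report` (a `filter_report`
#'   with columns `probe_id`, `reason` in
#'   `{snp_within_3bp, greedycut, missing_value}` plus any removed sample
#'   ids).
#' @export
filter_probes_pre_norm <- function(ds, detection_threshold = 0.01) {
  stopifnot(inherits(ds, "methylation_dataset"))
  removed <- data.frame(probe_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  removed_samples <- character(0)

  snp_ids <- if ("snp_within_3bp" %in% names(ds$manifest)) {
    ds$manifest$probe_id[ds$manifest$snp_within_3bp %in% TRUE]
  } else character(0)
  if (length(snp_ids)) {
    removed <- rbind(removed, data.frame(probe_id = snp_ids,
                                         reason = "snp_within_3bp",
                                         stringsAsFactors = FALSE))
    ds <- .subset_probes(ds, setdiff(rownames(ds$beta), snp_ids))
  }

  if (!is.null(ds$detection_p)) {
    gc <- greedycut(ds$detection_p, detection_threshold)
    if (length(gc$removed_probes)) {
      removed <- rbind(removed, data.frame(probe_id = gc$removed_probes,
                                           reason = "greedycut",
                                           stringsAsFactors = FALSE))
      ds <- .subset_probes(ds, setdiff(rownames(ds$beta), gc$removed_probes))
    }
    if (length(gc$removed_samples)) {
      removed_samples <- gc$removed_samples
      ds <- .subset_samples(ds, setdiff(colnames(ds$beta),
                                        gc$removed_samples))
    }
  }

  miss <- rownames(ds$beta)[rowSums(is.na(ds$beta)) > 0]
  if (length(miss)) {
    removed <- rbind(removed, data.frame(probe_id = miss,
                                         reason = "missing_value",
                                         stringsAsFactors = FALSE))
    ds <- .subset_probes(ds, setdiff(rownames(ds$beta), miss))
  }

  if (nrow(ds$beta) == 0) stop("no probes remain after pre-norm filtering")
  list(dataset = ds,
       report = .filter_report("pre_norm", removed, removed_samples,
                               nrow(ds$beta)))
}

#' Post-normalisation probe filtering
#'
#' Removes probes not measuring CpG methylation (probe class `ch`/`rs`) and
#' probes on the sex chromosomes. Chromosome labels `X`, `chrX`, `23` (and
#' the `Y` analogues) are treated as sex chromosomes, case-insensitively.
#'
#' @param ds A [methylation_dataset()].
#' @return List with `dataset` and `report` (reasons
#'   `{non_cpg, sex_chromosome}`).
#' @export
filter_probes_post_norm <- function(ds) {
  stopifnot(inherits(ds, "methylation_dataset"))
  mf <- ds$manifest
  non_cpg <- mf$probe_id[!is.na(mf$probe_class) & mf$probe_class != "cg"]
  sex_chr <- setdiff(mf$probe_id[.is_sex_chromosome(mf$chromosome)], non_cpg)
  removed <- rbind(
    if (length(non_cpg)) data.frame(probe_id = non_cpg, reason = "non_cpg",
                                    stringsAsFactors = FALSE),
    if (length(sex_chr)) data.frame(probe_id = sex_chr,
                                    reason = "sex_chromosome",
                                    stringsAsFactors = FALSE))
  if (is.null(removed)) {
    removed <- data.frame(probe_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  }
  ds <- .subset_probes(ds, setdiff(rownames(ds$beta), removed$probe_id))
  list(dataset = ds,
       report = .filter_report("post_norm", removed, character(0),
                               nrow(ds$beta)))
}

#' Within-array normalisation (pass-through or quantile)
#'
#' The beta-mixture quantile dilation used on real arrays is published
#' machinery outside this package's scope; the default here is an explicit
#' pass-through, with a rank-based quantile option (via
#' [limma::normalizeQuantiles()]) for users who want the sample
#' distributions equalised. The chosen method is recorded on the dataset.
#'
#' @param ds A [methylation_dataset()].
#' @param method `"none"` (default) or `"quantile"`.
#' @return The dataset, normalised if requested, with attribute
#'   `normalization`.
#' @export
normalize_dataset <- function(ds, method = c("none", "quantile")) {
  method <- match.arg(method)
  if (method == "quantile") {
    b <- limma::normalizeQuantiles(ds$beta)
    dimnames(b) <- dimnames(ds$beta)
    ds$beta <- .clamp_beta(b)
    ds$m <- beta_to_m(ds$beta)
  }
  attr(ds, "normalization") <- method
  ds
}

#' Principal-component batch diagnostics
#'
#' Computes sample scores on the first eight principal components of the M
#' matrix and tests each against candidate batch/biological covariates:
#' Kruskal-Wallis for factors with more than two levels, two-sided Wilcoxon
#' rank-sum for two-level factors. Covariates with a single level are
#' flagged and not tested.
#'
#' @param ds A [methylation_dataset()].
#' @param covariates Character vector of sample-sheet column names.
#' @param n_pc Number of components (default 8; reduced and flagged when
#'   rank-limited).
#' @return Object of class `batch_diagnostics` with `pc_scores`
#'   (samples x PCs), `association_p` (data frame: pc, covariate, test, p),
#'   `var_explained`, and `rank_limited`.
#' @export
batch_diagnostics <- function(ds, covariates = c("batch", "exposure",
                                                 "carrier"),
                              n_pc = 8) {
  stopifnot(inherits(ds, "methylation_dataset"))
  if (ncol(ds$m) < 3) stop("need at least 3 samples for PCA diagnostics")
  missing_cov <- setdiff(covariates, names(ds$samples))
  if (length(missing_cov)) {
    stop("covariates absent from sample sheet: ",
         paste(missing_cov, collapse = ", "))
  }
  pc <- stats::prcomp(t(ds$m), center = TRUE, scale. = FALSE)
  k <- min(n_pc, ncol(pc$x))
  rank_limited <- k < n_pc
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ve <- pc$sdev^2 / sum(pc$sdev^2)

  rows <- list()
  for (cov in covariates) {
    f <- factor(ds$samples[[cov]])
    nl <- nlevels(droplevels(f))
    for (i in seq_len(k)) {
      if (nl < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          pc = i, covariate = cov, test = "none", p = NA_real_,
          flag = "single_level", stringsAsFactors = FALSE)
        next
      }
      if (nl == 2) {
        p <- stats::wilcox.test(scores[, i] ~ f, exact = FALSE)$p.value
        test <- "wilcoxon"
      } else {
        p <- stats::kruskal.test(scores[, i], f)$p.value
        test <- "kruskal-wallis"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pc = i, covariate = cov, test = test, p = p, flag = "",
        stringsAsFactors = FALSE)
    }
    if (nl < 2) {
      warning(sprintf("covariate '%s' has a single level; not tested", cov))
    }
  }
  structure(list(pc_scores = scores,
                 association_p = do.call(rbind, rows),
                 var_explained = ve[seq_len(k)],
                 rank_limited = rank_limited),
            class = "batch_diagnostics")
}

#' @export
print.batch_diagnostics <- function(x, ...) {
  cat(sprintf("batch_diagnostics: %d PCs (%.1f%% variance)\n",
              ncol(x$pc_scores), 100 * sum(x$var_explained)))
  sig <- x$association_p[!is.na(x$association_p$p) &
                           x$association_p$p < 0.05, ]
  if (nrow(sig)) {
    cat("associations with p < 0.05:\n")
    print(sig[, c("pc", "covariate", "test", "p")], row.names = FALSE)
  } else {
    cat("no PC-covariate association with p < 0.05\n")
  }
  invisible(x)
}

#' Location-based batch adjustment on the M scale
#'
#' A transparent stand-in for empirical-Bayes batch correction: per probe,
#' an ordinary least-squares fit of the M values on the protected
#' covariates plus batch indicators estimates each batch's location
#' offset, and the mean-centred batch component is subtracted. Because the
#' joint-fit residuals are orthogonal to both design parts, the
#' batch-level means of the residuals (after projecting out the protected
#' covariates) are exactly equalised, and the protected-covariate
#' coefficient estimates refit on the adjusted data equal the joint-fit
#' estimates. No scale (variance) step is applied.
#'
#' @param ds A [methylation_dataset()].
#' @param batch Sample-sheet column holding the batch label.
#' @param protect Sample-sheet columns whose effects must be preserved
#'   (default exposure, carrier, sex).
#' @return The adjusted dataset (betas recomputed from adjusted M values).
#' @export
adjust_batch <- function(ds, batch = "batch",
                         protect = c("exposure", "carrier", "sex")) {
  stopifnot(inherits(ds, "methylation_dataset"))
  b <- factor(ds$samples[[batch]])
  if (nlevels(b) < 2) stop("need at least 2 batch levels")
  if (any(table(b) < 2)) stop("every batch must contain at least 2 samples")
  Z <- stats::model.matrix(~., data = ds$samples[, protect, drop = FALSE])
  D <- stats::model.matrix(~b)[, -1, drop = FALSE]
  if (qr(cbind(Z, D))$rank < ncol(Z) + ncol(D)) {
    stop(sprintf("batch '%s' is confounded with protected covariates (%s)",
                 batch, paste(protect, collapse = ", ")))
  }
  X <- cbind(Z, D)
  coef <- ds$m %*% X %*% chol2inv(chol(crossprod(X))) # probes x p
  gamma <- coef[, ncol(Z) + seq_len(ncol(D)), drop = FALSE]
  batch_part <- tcrossprod(gamma, D) # probes x samples
  batch_part <- batch_part - rowMeans(batch_part)
  .update_m(ds, ds$m - batch_part)
}
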