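#' Assemble a methylation dataset
#'
#' Bundles the three core inputs of a 450K-style analysis — the beta-value
#' matrix, the probe manifest and the sample sheet — plus an optional
#' detection p-value matrix, into the container every pipeline stage
#' consumes. M values (`log2(beta/(1-beta))`) are materialised alongside the
#' betas.
#'
#' @param beta Numeric matrix of beta values in `(0, 1)`, probes in rows
#'   (unique rownames = probe ids), samples in columns (unique colnames).
#' @param manifest Data frame of per-probe annotation with at least
#'   `probe_id`, `chromosome`, `position`; typically also `probe_class`
#'   (cg/ch/rs), `snp_within_3bp`, `gene`, `gene_element`, `cpg_context`,
#'   `chromatin_state`, `tfbs`. Must cover every beta row.
#' @param samples Data frame of per-sample records with `sample_id` matching
#'   the beta columns; typically `exposure` (0/1), `carrier` (PON1 Q192R
#'   R-allele carrier, 0/1), `sex` (0/1), `age`, `batch`, outcomes.
#' @param detection_p Optional matrix of detection p-values with the same
#'   dimnames as `beta`.
#' @return An object of class `methylation_dataset` with elements `beta`,
#'   `m`, `manifest`, `samples`, `detection_p`.
#' @export
methylation_dataset <- function(beta, manifest, samples, detection_p = NULL) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || anyDuplicated(rownames(beta))) {
    stop("beta must have unique rownames (probe ids)")
  }
  if (is.null(colnames(beta)) || anyDuplicated(colnames(beta))) {
    stop("beta must have unique colnames (sample ids)")
  }
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "chromosome", "position") %in% names(manifest))) {
    stop("manifest needs columns probe_id, chromosome, position")
  }
  if (anyDuplicated(manifest$probe_id)) {
    stop("manifest probe ids must be unique")
  }
  missing_probes <- setdiff(rownames(beta), manifest$probe_id)
  if (length(missing_probes) > 0) {
    stop(sprintf("manifest does not cover %d beta rows (e.g. %s)",
                 length(missing_probes), missing_probes[1]))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples)) {
    stop("sample sheet needs a sample_id column")
  }
  if (!setequal(samples$sample_id, colnames(beta)) ||
      nrow(samples) != ncol(beta)) {
    stop("sample sheet ids must match beta columns exactly")
  }
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  manifest <- manifest[match(rownames(beta), manifest$probe_id), , drop = FALSE]
  rownames(manifest) <- manifest$probe_id
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    detection_p <- detection_p[rownames(beta), colnames(beta), drop = FALSE]
  }
  structure(
    list(beta = beta, m = beta_to_m(beta), manifest = manifest,
         samples = samples, detection_p = detection_p),
    class = "methylation_dataset"
  )
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("methylation_dataset: %d probes x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  if (all(c("exposure", "carrier") %in% names(x$samples))) {
    tab <- table(sample_groups(x$samples))
    cat("design:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  cat(sprintf("detection p-values: %s\n",
              if (is.null(x$detection_p)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.methylation_dataset <- function(x) dim(x$beta)

#' Four-cell exposure-by-genotype group labels
#'
#' Crosses prenatal exposure (0/1) with PON1 192 R-allele carrier status
#' (0 = QQ, 1 = QR/RR) into the four design cells used throughout the
#' pipeline.
#'
#' @param samples Sample sheet with numeric 0/1 columns `exposure` and
#'   `carrier`.
#' @return Factor with levels `unexposed-QQ`, `exposed-QQ`,
#'   `unexposed-carrier`, `exposed-carrier`.
#' @export
sample_groups <- function(samples) {
  stopifnot(all(c("exposure", "carrier") %in% names(samples)))
  lev <- c("unexposed-QQ", "exposed-QQ", "unexposed-carrier",
           "exposed-carrier")
  idx <- 1 + samples$exposure + 2 * samples$carrier
  factor(lev[idx], levels = lev)
}

# Keep only the named probes, preserving their order in the dataset.
.subset_probes <- function(ds, keep_ids) {
  keep <- rownames(ds$beta) %in% keep_ids
  ds$beta <- ds$beta[keep, , drop = FALSE]
  ds$m <- ds$m[keep, , drop = FALSE]
  ds$manifest <- ds$manifest[keep, , drop = FALSE]
  if (!is.null(ds$detection_p)) {
    ds$detection_p <- ds$detection_p[keep, , drop = FALSE]
  }
  ds
}

.subset_samples <- function(ds, keep_ids) {
  keep <- colnames(ds$beta) %in% keep_ids
  ds$beta <- ds$beta[, keep, drop = FALSE]
  ds$m <- ds$m[, keep, drop = FALSE]
  ds$samples <- ds$samples[keep, , drop = FALSE]
  if (!is.null(ds$detection_p)) {
    ds$detection_p <- ds$detection_p[, keep, drop = FALSE]
  }
  ds
}

# Replace the M matrix (e.g. after batch adjustment) and refresh betas.
.update_m <- function(ds, m) {
  ds$m <- m
  ds$beta <- m_to_beta(m)
  ds
}
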