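# Design variables shared by the DMP and DMR modules: exposure, carrier
# (PON1 192 QR/RR pooled), sex, all numeric 0/1.
.design_vars <- function(samples) {
  need <- c("exposure", "carrier", "sex")
  missing <- setdiff(need, names(samples))
  if (length(missing)) {
    stop("sample sheet lacks columns: ", paste(missing, collapse = ", "))
  }
  out <- lapply(samples[need], function(x) {
    if (is.numeric(x)) x else as.integer(factor(x)) - 1L
  })
  if (any(vapply(out, function(x) any(!x %in% 0:1), logical(1)))) {
    stop("exposure, carrier and sex must be codable as 0/1")
  }
  out
}

.check_cells <- function(samples, min_per_cell = 2) {
  tab <- table(sample_groups(samples))
  if (any(tab < min_per_cell)) {
    stop(sprintf("each exposure x carrier cell needs >= %d samples (got %s)",
                 min_per_cell, paste(tab, collapse = "/")))
  }
  invisible(tab)
}

#' Genome-wide dual-model DMP scan
#'
#' Fits, per probe, two ordinary least-squares models of the M value:
#'
#' * Model A (interaction): `M ~ exposure + carrier + exposure:carrier +
#'   sex`. The interaction p-value comes from the cross-product term; the
#'   p-value of exposure *within carriers* comes from the t-test of the
#'   linear combination (exposure + interaction coefficients) using the
#'   full-model residual variance.
#' * Model B (no interaction): `M ~ exposure + carrier + sex`, giving the
#'   exposure and genotype main-effect p-values.
#'
#' A probe is a significant DMP under model A when `p_interaction <= p_int`
#' and `p_exposure_in_carriers <= p_exp_carriers`; under model B when
#' `p_exposure_main <= p_exp` and `p_genotype_main <= p_geno`. Both calls
#' additionally require the extreme-group filter: the exposed-carrier
#' group's mean beta must be strictly the highest (direction `hyper`) or
#' strictly the lowest (`hypo`) of the four design cells; ties fail the
#' filter. Group means are computed on the beta scale (interpretable
#' methylation); fits run on the M scale. No multiple-testing adjustment is
#' applied at this stage (raw-p criteria).
#'
#' Probes with zero M-value variance are excluded and listed in `flagged`.
#'
#' @param ds A preprocessed [methylation_dataset()].
#' @param p_int,p_exp_carriers Model-A thresholds (defaults 0.1, 0.001).
#' @param p_exp,p_geno Model-B thresholds (defaults 0.001, 0.1).
#' @param stratified Also compute the exposure-in-carriers p-value from a
#'   stratified fit (`M ~ exposure + sex` on carrier samples only), added
#'   as column `p_exposure_in_carriers_stratified`.
#' @return Object of class `dmp_scan`: `table` (one row per retained
#'   probe), `summary` (significant counts and hyper/hypo splits per
#'   model), `flagged`, `thresholds`.
#' @export
run_dmp_scan <- function(ds, p_int = 0.1, p_exp_carriers = 0.001,
                         p_exp = 0.001, p_geno = 0.1, stratified = FALSE) {
  stopifnot(inherits(ds, "methylation_dataset"))
  dv <- .design_vars(ds$samples)
  .check_cells(ds$samples)
  XA <- cbind(intercept = 1, exposure = dv$exposure, carrier = dv$carrier,
              interaction = dv$exposure * dv$carrier, sex = dv$sex)
  XB <- XA[, c("intercept", "exposure", "carrier", "sex")]

  invariant <- .row_vars(ds$m) < 1e-12
  flagged <- data.frame(probe_id = rownames(ds$m)[invariant],
                        reason = rep("invariant_probe", sum(invariant)),
                        stringsAsFactors = FALSE)
  M <- ds$m[!invariant, , drop = FALSE]
  beta <- ds$beta[!invariant, , drop = FALSE]
  if (nrow(M) == 0) stop("no probes with variance to fit")

  fitA <- .fit_ols_matrix(M, XA,
                          contrasts = list(exp_in_carriers = c(0, 1, 0, 1, 0)))
  fitB <- .fit_ols_matrix(M, XB)

  grp <- sample_groups(ds$samples)
  gm <- vapply(levels(grp), function(g) {
    rowMeans(beta[, grp == g, drop = FALSE])
  }, numeric(nrow(beta)))
  gm <- matrix(gm, nrow = nrow(beta),
               dimnames = list(rownames(beta), levels(grp)))
  ec <- gm[, "exposed-carrier"]
  others <- gm[, setdiff(colnames(gm), "exposed-carrier"), drop = FALSE]
  direction <- ifelse(ec > apply(others, 1, max), "hyper",
                      ifelse(ec < apply(others, 1, min), "hypo", "none"))
  extreme_flag <- direction != "none"

  tab <- data.frame(
    probe_id = rownames(M),
    chromosome = ds$manifest[rownames(M), "chromosome"],
    position = ds$manifest[rownames(M), "position"],
    gene = if ("gene" %in% names(ds$manifest)) {
      ds$manifest[rownames(M), "gene"]
    } else NA_character_,
    p_interaction = fitA$p[, "interaction"],
    p_exposure_in_carriers = fitA$contrast$exp_in_carriers$p,
    p_exposure_main = fitB$p[, "exposure"],
    p_genotype_main = fitB$p[, "carrier"],
    mean_unexposed_QQ = gm[, "unexposed-QQ"],
    mean_exposed_QQ = gm[, "exposed-QQ"],
    mean_unexposed_carrier = gm[, "unexposed-carrier"],
    mean_exposed_carrier = gm[, "exposed-carrier"],
    extreme_flag = extreme_flag,
    direction = direction,
    stringsAsFactors = FALSE)
  tab$sig_model_A <- tab$p_interaction <= p_int &
    tab$p_exposure_in_carriers <= p_exp_carriers & extreme_flag
  tab$sig_model_B <- tab$p_exposure_main <= p_exp &
    tab$p_genotype_main <= p_geno & extreme_flag
  rownames(tab) <- NULL

  if (stratified) {
    keep <- dv$carrier == 1
    Xs <- cbind(1, dv$exposure[keep], dv$sex[keep])
    fs <- .fit_ols_matrix(M[, keep, drop = FALSE], Xs)
    tab$p_exposure_in_carriers_stratified <- fs$p[, 2]
  }

  summarize <- function(sig) {
    d <- tab$direction[sig]
    c(direction_summary(sum(d == "hyper"), sum(d == "hypo")))
  }
  structure(list(
    table = tab,
    summary = list(n_probes = nrow(tab),
                   model_A = summarize(tab$sig_model_A),
                   model_B = summarize(tab$sig_model_B)),
    flagged = flagged,
    thresholds = c(p_int = p_int, p_exp_carriers = p_exp_carriers,
                   p_exp = p_exp, p_geno = p_geno)),
    class = "dmp_scan")
}

#' Fit the dual DMP models for a single probe
#'
#' Single-probe convenience wrapper around the matrix fit used by
#' [run_dmp_scan()]; takes one probe's M values and the sample sheet and
#' returns the one-row result.
#'
#' @param m_row Numeric vector of M values, one per sample.
#' @param samples Sample sheet with `exposure`, `carrier`, `sex`.
#' @param ... Passed to [run_dmp_scan()] (thresholds).
#' @return One-row data frame as in the `table` element of a `dmp_scan`,
#'   or `NULL` (with the probe flagged) for an invariant probe.
#' @export
fit_probe_models <- function(m_row, samples, ...) {
  beta <- m_to_beta(m_row)
  mat <- matrix(beta, nrow = 1,
                dimnames = list("probe", samples$sample_id))
  manifest <- data.frame(probe_id = "probe", chromosome = "chr1",
                         position = 1L, stringsAsFactors = FALSE)
  ds <- methylation_dataset(mat, manifest, samples)
  ds$m <- matrix(m_row, nrow = 1,
                 dimnames = list("probe", samples$sample_id))
  scan <- tryCatch(run_dmp_scan(ds, ...), error = function(e) e)
  if (inherits(scan, "error")) {
    if (grepl("no probes with variance", conditionMessage(scan))) {
      return(NULL)
    }
    stop(scan)
  }
  scan$table
}

#' Bookkeeping summary of direction-split significant counts
#'
#' @param n_hyper,n_hypo Counts of hyper- and hypomethylated significant
#'   features.
#' @return Named vector `c(hyper, hypo, total)` with
#'   `total = hyper + hypo`.
#' @export
direction_summary <- function(n_hyper, n_hypo) {
  c(hyper = n_hyper, hypo = n_hypo, total = n_hyper + n_hypo)
}

#' @export
print.dmp_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf("dmp_scan: %d probes tested (%d flagged)\n", s$n_probes,
              nrow(x$flagged)))
  cat(sprintf("model A (interaction):    %d sig-DMPs (%d hyper / %d hypo)\n",
              s$model_A["total"], s$model_A["hyper"], s$model_A["hypo"]))
  cat(sprintf("model B (no interaction): %d sig-DMPs (%d hyper / %d hypo)\n",
              s$model_B["total"], s$model_B["hyper"], s$model_B["hypo"]))
  invisible(x)
}
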