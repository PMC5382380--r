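.DMR_CONTRASTS <- c("unexposed-QQ", "exposed-QQ", "unexposed-carrier")

#' Per-CpG two-group contrast statistics
#'
#' Pooled-variance two-sample t statistics on M values comparing the
#' exposed R-allele carrier group against one of the other three design
#' cells, per probe. Probes with zero pooled variance get `t = 0`,
#' `p = 1` and a flag.
#'
#' @param ds A [methylation_dataset()].
#' @param contrast Name of the comparison group: `"unexposed-QQ"`,
#'   `"exposed-QQ"` or `"unexposed-carrier"`.
#' @return Data frame: `probe_id`, `chromosome`, `position`, `t`, `df`,
#'   `p`, `flag`.
#' @export
per_cpg_contrast_stats <- function(ds, contrast = .DMR_CONTRASTS) {
  stopifnot(inherits(ds, "methylation_dataset"))
  contrast <- match.arg(contrast)
  grp <- sample_groups(ds$samples)
  g1 <- which(grp == "exposed-carrier")
  g2 <- which(grp == contrast)
  if (length(g1) < 2 || length(g2) < 2) {
    stop("both contrast groups need at least 2 samples")
  }
  M1 <- ds$m[, g1, drop = FALSE]
  M2 <- ds$m[, g2, drop = FALSE]
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * .row_vars(M1) + (n2 - 1) * .row_vars(M2)) /
    (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- rowMeans(M1) - rowMeans(M2)
  zero <- se < 1e-12
  t <- ifelse(zero, 0, diff / ifelse(zero, 1, se))
  df <- n1 + n2 - 2
  p <- ifelse(zero, 1, 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  data.frame(probe_id = rownames(ds$m),
             chromosome = ds$manifest[rownames(ds$m), "chromosome"],
             position = ds$manifest[rownames(ds$m), "position"],
             t = t, df = df, p = p,
             flag = ifelse(zero, "zero_variance", ""),
             stringsAsFactors = FALSE)
}

# Exact first two moments of t^2 when t ~ t_df (df > 4).
.t2_moments <- function(df) {
  m1 <- df / (df - 2)
  m2 <- 3 * df^2 / ((df - 2) * (df - 4))
  c(mean = m1, var = m2 - m1^2)
}

#' Kernel-smoothed region scores
#'
#' For each probe, a Gaussian-kernel weighted average of the squared
#' contrast t statistics of the probes within `lambda_bp` on the same
#' chromosome (bandwidth `sigma = lambda_bp / C`, kernel truncated at
#' `lambda_bp`). Under the per-probe null the squared statistics have known
#' t-squared moments, so the smoothed score is referred to a scaled
#' chi-squared distribution with moments matched to the weighted mean
#' (Satterthwaite style); p-values are Benjamini-Hochberg adjusted across
#' all supplied probes.
#'
#' An isolated probe (no neighbour within `lambda_bp`) keeps its own
#' squared statistic as score; a constant squared statistic across a dense
#' window is returned unchanged (weighted mean of a constant).
#'
#' @param tstat Per-probe t statistics (from
#'   [per_cpg_contrast_stats()]).
#' @param positions 1-based probe positions, sorted increasingly within
#'   each chromosome (error otherwise).
#' @param df Degrees of freedom of the t statistics.
#' @param chromosome Chromosome label per probe (default: one chromosome).
#' @param lambda_bp Kernel truncation half-width in base pairs
#'   (default 1000).
#' @param C Bandwidth divisor, `sigma = lambda_bp / C` (default 2).
#' @return Data frame: `score`, `p`, `padj` (BH across all input probes).
#' @export
smooth_and_score <- function(tstat, positions, df,
                             chromosome = NULL, lambda_bp = 1000, C = 2) {
  n <- length(tstat)
  stopifnot(length(positions) == n)
  if (df <= 4) stop("need residual df > 4 for the moment-matched score")
  if (is.null(chromosome)) chromosome <- rep("chr1", n)
  sigma <- lambda_bp / C
  t2 <- tstat^2
  mom <- .t2_moments(df)
  score <- numeric(n)
  p <- numeric(n)
  for (ch in unique(chromosome)) {
    idx <- which(chromosome == ch)
    pos <- positions[idx]
    if (is.unsorted(pos, strictly = FALSE)) {
      stop("positions must be sorted within chromosome ", ch)
    }
    lo <- findInterval(pos - lambda_bp, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + lambda_bp, pos)
    for (i in seq_along(idx)) {
      nb <- lo[i]:hi[i]
      w <- exp(-((pos[nb] - pos[i])^2) / (2 * sigma^2))
      w <- w / sum(w)
      s <- sum(w * t2[idx[nb]])
      sumw2 <- sum(w^2)
      v <- mom["var"] * sumw2
      a <- v / (2 * mom["mean"])
      k <- 2 * mom["mean"]^2 / v
      score[idx[i]] <- s
      p[idx[i]] <- stats::pchisq(s / a, df = k, lower.tail = FALSE)
    }
  }
  data.frame(score = score, p = p, padj = stats::p.adjust(p, "BH"))
}

#' Group significant probes into candidate regions
#'
#' Probes with adjusted p below `alpha` are grouped when consecutive
#' significant probes on a chromosome are at most `lambda_bp` apart;
#' clusters with at least `min_cpgs` probes are kept. Each region then
#' passes the extreme-group direction filter: the exposed-carrier group's
#' region-mean beta must be strictly the maximum (`hyper`) or minimum
#' (`hypo`) of the four design cells, otherwise the region is dropped.
#' Region significance is the minimum member adjusted p.
#'
#' @param scored Data frame with columns `probe_id`, `chromosome`,
#'   `position`, `padj` (e.g. [per_cpg_contrast_stats()] columns plus
#'   [smooth_and_score()] output).
#' @param ds The [methylation_dataset()] (for region-mean betas and gene
#'   annotation).
#' @param contrast Label recorded on the output rows.
#' @param lambda_bp Maximum gap between consecutive significant probes.
#' @param min_cpgs Minimum probes per region (default 2).
#' @param alpha Adjusted-p threshold, strict (default 0.05).
#' @return Data frame of regions: `chromosome`, `start`, `end` (1-based
#'   inclusive), `n_cpgs`, `contrast`, `p_adj`, the four group region-mean
#'   betas, `direction`, `genes`, `probe_ids`.
#' @export
call_regions <- function(scored, ds, contrast = "", lambda_bp = 1000,
                         min_cpgs = 2, alpha = 0.05) {
  stopifnot(inherits(ds, "methylation_dataset"))
  sig <- scored[!is.na(scored$padj) & scored$padj < alpha, , drop = FALSE]
  empty <- data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0),
                      contrast = character(0), p_adj = numeric(0),
                      mean_unexposed_QQ = numeric(0),
                      mean_exposed_QQ = numeric(0),
                      mean_unexposed_carrier = numeric(0),
                      mean_exposed_carrier = numeric(0),
                      direction = character(0), genes = character(0),
                      probe_ids = character(0), stringsAsFactors = FALSE)
  if (nrow(sig) == 0) return(empty)
  sig <- sig[order(sig$chromosome, sig$position), , drop = FALSE]
  newclust <- c(TRUE, sig$chromosome[-1] != sig$chromosome[-nrow(sig)] |
                  diff(sig$position) > lambda_bp)
  sig$cluster <- cumsum(newclust)
  grp <- sample_groups(ds$samples)
  out <- lapply(split(sig, sig$cluster), function(cl) {
    if (nrow(cl) < min_cpgs) return(NULL)
    betas <- ds$beta[cl$probe_id, , drop = FALSE]
    gm <- vapply(levels(grp), function(g) {
      mean(betas[, grp == g, drop = FALSE])
    }, numeric(1))
    ec <- gm["exposed-carrier"]
    others <- gm[setdiff(names(gm), "exposed-carrier")]
    if (ec > max(others)) dir <- "hyper"
    else if (ec < min(others)) dir <- "hypo"
    else return(NULL)
    genes <- if ("gene" %in% names(ds$manifest)) {
      unique(unlist(strsplit(ds$manifest[cl$probe_id, "gene"], ";")))
    } else character(0)
    genes <- setdiff(genes, c("", NA))
    data.frame(chromosome = cl$chromosome[1],
               start = min(cl$position), end = max(cl$position),
               n_cpgs = nrow(cl), contrast = contrast,
               p_adj = min(cl$padj),
               mean_unexposed_QQ = gm["unexposed-QQ"],
               mean_exposed_QQ = gm["exposed-QQ"],
               mean_unexposed_carrier = gm["unexposed-carrier"],
               mean_exposed_carrier = gm["exposed-carrier"],
               direction = dir,
               genes = paste(genes, collapse = ";"),
               probe_ids = paste(cl$probe_id, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Genome-wide DMR scan over the three carrier contrasts
#'
#' Runs the kernel-smoothing DMR caller for the exposed-carrier group
#' against each of the other three design cells, reporting the union of
#' significant regions with per-contrast provenance. Each contrast is
#' smoothed and BH-adjusted genome-wide on its own.
#'
#' @param ds A preprocessed [methylation_dataset()].
#' @param lambda_bp Kernel half-width / maximum intra-region gap
#'   (default 1000).
#' @param C Bandwidth divisor (default 2).
#' @param min_cpgs Minimum CpGs per region (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Object of class `dmr_scan`: `regions` (all contrasts,
#'   row-bound), `summary` (hyper/hypo/total counts), `params`.
#' @export
run_dmr_scan <- function(ds, lambda_bp = 1000, C = 2, min_cpgs = 2,
                         alpha = 0.05) {
  stopifnot(inherits(ds, "methylation_dataset"))
  ord <- order(ds$manifest$chromosome, ds$manifest$position)
  ds <- .subset_probes(ds, ds$manifest$probe_id[ord])
  regions <- lapply(.DMR_CONTRASTS, function(ct) {
    st <- per_cpg_contrast_stats(ds, ct)
    sm <- smooth_and_score(st$t, st$position, df = st$df[1],
                           chromosome = st$chromosome,
                           lambda_bp = lambda_bp, C = C)
    call_regions(cbind(st, sm), ds, contrast = ct, lambda_bp = lambda_bp,
                 min_cpgs = min_cpgs, alpha = alpha)
  })
  regions <- do.call(rbind, regions)
  structure(list(
    regions = regions,
    summary = direction_summary(sum(regions$direction == "hyper"),
                                sum(regions$direction == "hypo")),
    params = list(lambda_bp = lambda_bp, C = C, min_cpgs = min_cpgs,
                  alpha = alpha)),
    class = "dmr_scan")
}

#' @export
print.dmr_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf("dmr_scan: %d sig-DMRs (%d hyper / %d hypo) at alpha = %g, min_cpgs = %d\n",
              s["total"], s["hyper"], s["hypo"], x$params$alpha,
              x$params$min_cpgs))
  invisible(x)
}

#' Export DMRs as a BED file
#'
#' Writes regions as BED (0-based, half-open): name is `gene|direction`
#' (first gene), score is `-10*log10(p_adj)` capped at 1000.
#'
#' @param x A `dmr_scan` or its `regions` data frame.
#' @param path Output file.
#' @return Invisibly, the BED data frame.
#' @export
write_dmr_bed <- function(x, path) {
  regions <- if (inherits(x, "dmr_scan")) x$regions else x
  first_gene <- vapply(strsplit(regions$genes, ";"), function(g) {
    if (length(g)) g[1] else "."
  }, character(1))
  bed <- data.frame(chrom = regions$chromosome,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = paste(first_gene, regions$direction, sep = "|"),
                    score = pmin(1000, round(-10 * log10(
                      pmax(regions$p_adj, 1e-100)))),
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
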