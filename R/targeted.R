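#' Promoter-cluster methylation versus cis-SNP genotype
#'
#' One-way ANOVA of each cluster probe's beta values across the promoter
#' SNP genotype groups (CC / CT / TT treated categorically), with the
#' additive trend direction taken as the sign of the TT - CC mean
#' difference. Genotype groups without samples are dropped and flagged.
#'
#' @param ds A [methylation_dataset()].
#' @param cluster_probes Probe ids of the promoter cluster.
#' @param genotype_column Sample-sheet column with the genotype labels
#'   (default `pon1_108`).
#' @return Data frame per probe: the per-genotype beta means, `f`, `p`,
#'   `trend` (+1 / -1 / 0) and `flag`.
#' @export
snp_cluster_anova <- function(ds, cluster_probes,
                              genotype_column = "pon1_108") {
  stopifnot(inherits(ds, "methylation_dataset"))
  g <- factor(ds$samples[[genotype_column]])
  counts <- table(g)
  flag <- if (any(counts == 0)) "empty_genotype_group" else ""
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("need at least 2 genotype groups")
  if (any(table(g) < 2)) stop("each genotype group needs >= 2 samples")
  cluster_probes <- intersect(cluster_probes, rownames(ds$beta))
  rows <- lapply(cluster_probes, function(pid) {
    b <- ds$beta[pid, ]
    means <- tapply(b, g, mean)
    if (stats::sd(b) < 1e-12) {
      f <- 0
      p <- 1
      flag <- "zero_variance"
    } else {
      fit <- summary(stats::aov(b ~ g))[[1]]
      f <- fit[["F value"]][1]
      p <- fit[["Pr(>F)"]][1]
    }
    trend <- if (all(c("CC", "TT") %in% names(means))) {
      sign(means[["TT"]] - means[["CC"]])
    } else NA_real_
    out <- data.frame(probe_id = pid, f = f, p = p, trend = trend,
                      flag = flag, stringsAsFactors = FALSE)
    for (lv in levels(g)) out[[paste0("mean_", lv)]] <- means[[lv]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enzyme activity versus promoter methylation model
#'
#' Ordinary least squares of `activity ~ M + genotype + sex`, the focused
#' model relating paraoxonase-type enzyme activity to promoter M values
#' while adjusting for the coding genotype and sex. Flags near-collinear
#' methylation and genotype.
#'
#' @param activity Numeric enzyme activity per sample.
#' @param m_values Promoter-probe M values (or a cluster-mean summary).
#' @param genotype Numeric genotype coding (e.g. carrier 0/1 or allele
#'   dosage).
#' @param sex 0/1 covariate.
#' @return Object of class `activity_model_result`: coefficient table
#'   (`estimate`, `se`, `t`, `p` for methylation, genotype, sex), `n`,
#'   `flag`.
#' @export
activity_model <- function(activity, m_values, genotype, sex) {
  keep <- stats::complete.cases(activity, m_values, genotype, sex)
  if (sum(keep) < 10) stop("need at least 10 complete cases")
  activity <- activity[keep]; m_values <- m_values[keep]
  genotype <- as.numeric(genotype)[keep]; sex <- sex[keep]
  flag <- ""
  r <- suppressWarnings(stats::cor(m_values, genotype))
  if (is.finite(r) && abs(r) > 0.99) flag <- "collinear_m_genotype"
  fit <- stats::lm(activity ~ m_values + genotype + sex)
  cf <- summary(fit)$coefficients
  tab <- data.frame(term = c("m_value", "genotype", "sex"),
                    estimate = cf[c("m_values", "genotype", "sex"),
                                  "Estimate"],
                    se = cf[c("m_values", "genotype", "sex"),
                            "Std. Error"],
                    t = cf[c("m_values", "genotype", "sex"), "t value"],
                    p = cf[c("m_values", "genotype", "sex"), "Pr(>|t|)"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(coefficients = tab, n = sum(keep), flag = flag),
            class = "activity_model_result")
}

#' @export
print.activity_model_result <- function(x, ...) {
  cat(sprintf("activity_model_result (n = %d)%s\n", x$n,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Array-versus-pyrosequencing validation correlations
#'
#' Pearson correlation (with two-sided p) between the array beta values
#' and pyrosequencing methylation percentages per probe; percentages are
#' divided by 100 first (correlation is scale-invariant, so this matters
#' only for plotting). Probes with zero variance on either axis are
#' flagged.
#'
#' @param array_betas Matrix of array betas (probes x samples).
#' @param pyro_percent Matrix of pyrosequencing percentages in `[0, 100]`
#'   with matching dimnames.
#' @return Data frame per probe: `r`, `p`, `n`, `flag`.
#' @export
pyro_validation <- function(array_betas, pyro_percent) {
  array_betas <- as.matrix(array_betas)
  pyro_percent <- as.matrix(pyro_percent)
  if (any(pyro_percent < 0 | pyro_percent > 100, na.rm = TRUE)) {
    stop("pyrosequencing values must be percentages in [0, 100]")
  }
  probes <- intersect(rownames(array_betas), rownames(pyro_percent))
  samples <- intersect(colnames(array_betas), colnames(pyro_percent))
  rows <- lapply(probes, function(pid) {
    x <- array_betas[pid, samples]
    y <- pyro_percent[pid, samples] / 100
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3) stop("need at least 3 paired samples per probe")
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
      return(data.frame(probe_id = pid, r = NA_real_, p = NA_real_,
                        n = length(x), flag = "zero_variance",
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(probe_id = pid, r = unname(ct$estimate), p = ct$p.value,
               n = length(x), flag = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
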