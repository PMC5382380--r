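#' Select cell-type signature probes
#'
#' Restricts to the `n_variable` probes with the largest beta-value
#' variance in the mixture data, then ranks those by how strongly they
#' discriminate the reference cell types and returns the top `n_top`. With
#' replicate reference columns per type the ranking statistic is the
#' one-way F statistic across types; with a single methylome per type
#' (no within-type replication) it reduces to the between-type mean square,
#' i.e. the variance of the reference betas across types. Both cutoffs are
#' capped at the available probe count, so the defaults (100,000 / 500)
#' degrade gracefully on small simulations.
#'
#' @param ds A [methylation_dataset()] of mixed (e.g. whole-blood) samples.
#' @param reference Matrix of reference betas, probes x reference columns.
#' @param n_variable Size of the variance pre-filter (default 100000).
#' @param n_top Number of signature probes returned (default 500), one
#'   overall ranked list across all cell types.
#' @param types Factor assigning each reference column to a cell type;
#'   defaults to one type per column (colnames).
#' @return Character vector of exactly `min(n_top, ...)` probe ids.
#' @export
select_signature_probes <- function(ds, reference, n_variable = 100000,
                                    n_top = 500, types = NULL) {
  stopifnot(inherits(ds, "methylation_dataset"))
  reference <- as.matrix(reference)
  if (is.null(types)) types <- factor(colnames(reference))
  types <- factor(types)
  n_variable <- min(n_variable, nrow(ds$beta))
  n_top <- min(n_top, n_variable)
  if (n_top < 1) stop("n_top must be at least 1")

  v <- .row_vars(ds$beta)
  candidates <- names(sort(v, decreasing = TRUE))[seq_len(n_variable)]
  covered <- candidates %in% rownames(reference)
  if (mean(!covered) > 0.05) {
    stop(sprintf("reference is missing %.1f%% of candidate probes (> 5%%)",
                 100 * mean(!covered)))
  }
  candidates <- candidates[covered]
  R <- reference[candidates, , drop = FALSE]

  if (any(table(types) > 1)) {
    # replicated reference: classic one-way F across types
    grand <- rowMeans(R)
    k <- nlevels(types)
    n <- ncol(R)
    group_means <- vapply(levels(types), function(tp) {
      rowMeans(R[, types == tp, drop = FALSE])
    }, numeric(nrow(R)))
    counts <- as.numeric(table(types))
    ssb <- rowSums(sweep((group_means - grand)^2, 2, counts, "*"))
    ssw <- rowSums((R - group_means[, as.integer(types), drop = FALSE])^2)
    score <- (ssb / (k - 1)) / (ssw / (n - k))
  } else {
    score <- .row_vars(R)
  }
  names(score) <- candidates
  names(sort(score, decreasing = TRUE))[seq_len(n_top)]
}

#' Estimate leukocyte proportions by constrained projection
#'
#' Reference-based deconvolution in the Houseman style: for each sample the
#' beta values at the signature probes are projected onto the reference
#' methylomes under non-negativity and a sum-to-one constraint, solved by
#' non-negative least squares with an appended heavily weighted equality
#' row followed by renormalisation.
#'
#' @param ds A [methylation_dataset()].
#' @param reference Matrix of reference betas (probes x cell types), one
#'   column per type.
#' @param signature Probe ids to fit on (from
#'   [select_signature_probes()]).
#' @return Object of class `cell_proportions`: `proportions` (samples x
#'   types, rows on the unit simplex) and `residual_norm` per sample.
#' @export
estimate_proportions <- function(ds, reference, signature) {
  stopifnot(inherits(ds, "methylation_dataset"))
  if (length(signature) == 0) stop("signature probe list is empty")
  reference <- as.matrix(reference)
  signature <- intersect(signature, rownames(reference))
  R <- reference[signature, , drop = FALSE]
  if (qr(R)$rank < ncol(R)) {
    cc <- stats::cor(R)
    pairs <- which(abs(cc) > 0.9999 & upper.tri(cc), arr.ind = TRUE)
    coll <- if (nrow(pairs)) {
      paste(colnames(R)[pairs[, 1]], colnames(R)[pairs[, 2]], sep = "~",
            collapse = ", ")
    } else "unknown pair"
    stop("reference is rank deficient on the signature probes; ",
         "collinear cell types: ", coll)
  }
  B <- ds$beta[signature, , drop = FALSE]
  A <- rbind(R, rep(1000, ncol(R)))
  W <- t(vapply(seq_len(ncol(B)), function(s) {
    w <- pracma::lsqnonneg(A, c(B[, s], 1000))$x
    w / sum(w)
  }, numeric(ncol(R))))
  dimnames(W) <- list(colnames(B), colnames(R))
  resid <- vapply(seq_len(nrow(W)),
                  function(s) sqrt(sum((B[, s] - R %*% W[s, ])^2)),
                  numeric(1))
  structure(list(proportions = W, residual_norm = resid,
                 signature = signature),
            class = "cell_proportions")
}

#' @export
print.cell_proportions <- function(x, ...) {
  cat(sprintf("cell_proportions: %d samples x %d cell types (%d signature probes)\n",
              nrow(x$proportions), ncol(x$proportions),
              length(x$signature)))
  cat("mean proportions:\n")
  print(round(colMeans(x$proportions), 3))
  invisible(x)
}

#' Associate cell proportions with groups and outcomes
#'
#' One-way ANOVA of each cell type's proportion against exposure and
#' genotype groups, and simple linear regression of each proportion on the
#' numeric outcomes (body fat %, BMI Z scores, leptin, age by default).
#' Constant proportion vectors are flagged and skipped.
#'
#' @param props A [estimate_proportions()] result.
#' @param samples Sample sheet aligned with the proportion rows.
#' @param outcomes Character vector of numeric sample-sheet columns.
#' @param groups Character vector of grouping columns (default exposure and
#'   carrier).
#' @return Data frame with one row per (cell type, variable) pair: `test`
#'   (`anova` or `regression`), `estimate` (regression slope, NA for
#'   ANOVA), `p`, and `flag`.
#' @export
proportion_associations <- function(props, samples,
                                    outcomes = c("body_fat_pct",
                                                 "delta_bmi_z", "bmi_z",
                                                 "leptin", "age"),
                                    groups = c("exposure", "carrier")) {
  stopifnot(inherits(props, "cell_proportions"))
  W <- props$proportions
  stopifnot(nrow(W) == nrow(samples))
  outcomes <- intersect(outcomes, names(samples))
  rows <- list()
  for (ct in colnames(W)) {
    w <- W[, ct]
    constant <- stats::sd(w) < 1e-12
    for (g in groups) {
      f <- factor(samples[[g]])
      if (any(table(f) == 0) || nlevels(droplevels(f)) < 2) {
        stop(sprintf("grouping '%s' has an empty or single group", g))
      }
      if (constant) {
        rows[[length(rows) + 1L]] <- data.frame(
          celltype = ct, variable = g, test = "anova", estimate = NA_real_,
          p = NA_real_, flag = "constant_proportion",
          stringsAsFactors = FALSE)
        next
      }
      p <- summary(stats::aov(w ~ f))[[1]][["Pr(>F)"]][1]
      rows[[length(rows) + 1L]] <- data.frame(
        celltype = ct, variable = g, test = "anova", estimate = NA_real_,
        p = p, flag = "", stringsAsFactors = FALSE)
    }
    for (oc in outcomes) {
      y <- samples[[oc]]
      if (constant) {
        rows[[length(rows) + 1L]] <- data.frame(
          celltype = ct, variable = oc, test = "regression",
          estimate = NA_real_, p = NA_real_, flag = "constant_proportion",
          stringsAsFactors = FALSE)
        next
      }
      fit <- summary(stats::lm(y ~ w))
      rows[[length(rows) + 1L]] <- data.frame(
        celltype = ct, variable = oc, test = "regression",
        estimate = fit$coefficients["w", "Estimate"],
        p = fit$coefficients["w", "Pr(>|t|)"], flag = "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
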