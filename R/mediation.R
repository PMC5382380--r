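#' Baron-Kenny four-model mediation analysis
#'
#' Fits the classical causal-steps models for exposure -> methylation mark
#' -> outcome:
#'
#' 1. outcome ~ exposure
#' 2. mark ~ exposure
#' 3. outcome ~ mark
#' 4. outcome ~ exposure + mark
#'
#' (each optionally sex-adjusted). Mediation requires models 1-3
#' significant, the mark significant in model 4, and the exposure effect
#' in model 4 smaller in magnitude than in model 1 (`partial`); when the
#' model-4 exposure effect is additionally not significant at `alpha`
#' (its confidence interval covers 0) the mediation is classified `full`.
#' The indirect-effect (ACME) point estimate is the product of the model-2
#' exposure coefficient and the model-4 mark coefficient.
#'
#' @param mark Numeric mediator values (M scale).
#' @param outcome Numeric outcome (ln-transform leptin upstream, see
#'   [ln_leptin()]).
#' @param exposure 0/1 exposure vector.
#' @param sex Optional 0/1 covariate.
#' @param adjust_sex Include sex in all four models (use `FALSE` for BMI-Z
#'   outcomes, which are already sex-standardised).
#' @param alpha Per-model significance cut-off (default 0.05).
#' @return Object of class `mediation_result` with per-model coefficient /
#'   p-value pairs, `classification` in `{none, partial, full}` and
#'   `acme`. Zero-variance marks or outcomes yield `NULL` with a warning.
#' @export
baron_kenny <- function(mark, outcome, exposure, sex = NULL,
                        adjust_sex = !is.null(sex), alpha = 0.05) {
  keep <- stats::complete.cases(mark, outcome, exposure,
                                if (adjust_sex) sex else NULL)
  mark <- mark[keep]; outcome <- outcome[keep]; exposure <- exposure[keep]
  if (adjust_sex) sex <- sex[keep]
  if (sum(keep) < 10) stop("need at least 10 complete cases")
  if (stats::sd(mark) < 1e-12 || stats::sd(outcome) < 1e-12) {
    warning("zero-variance mark or outcome; no mediation result")
    return(NULL)
  }
  covar <- if (adjust_sex) cbind(sex = sex) else NULL
  cf <- function(y, ...) {
    X <- cbind(intercept = 1, ...)
    if (!is.null(covar)) X <- cbind(X, covar)
    qx <- qr(X)
    if (qx$rank < ncol(X)) stop("singular mediation design")
    b <- qr.coef(qx, y)
    res <- y - X %*% b
    df <- length(y) - ncol(X)
    s2 <- sum(res^2) / df
    se <- sqrt(s2 * diag(chol2inv(qr.R(qx))))
    t <- b / se
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    list(coef = b, se = se, p = p, df = df)
  }
  m1 <- cf(outcome, exposure = exposure)
  m2 <- cf(mark, exposure = exposure)
  m3 <- cf(outcome, mark = mark)
  m4 <- cf(outcome, exposure = exposure, mark = mark)

  steps_ok <- m1$p["exposure"] < alpha && m2$p["exposure"] < alpha &&
    m3$p["mark"] < alpha && m4$p["mark"] < alpha &&
    abs(m4$coef["exposure"]) < abs(m1$coef["exposure"])
  classification <- if (!steps_ok) "none"
  else if (m4$p["exposure"] >= alpha) "full"
  else "partial"

  structure(list(
    n = sum(keep), adjust_sex = adjust_sex, alpha = alpha,
    model1 = c(coef = unname(m1$coef["exposure"]),
               p = unname(m1$p["exposure"])),
    model2 = c(coef = unname(m2$coef["exposure"]),
               p = unname(m2$p["exposure"])),
    model3 = c(coef = unname(m3$coef["mark"]), p = unname(m3$p["mark"])),
    model4_exposure = c(coef = unname(m4$coef["exposure"]),
                        p = unname(m4$p["exposure"])),
    model4_mark = c(coef = unname(m4$coef["mark"]),
                    p = unname(m4$p["mark"])),
    classification = classification,
    acme = unname(m2$coef["exposure"] * m4$coef["mark"])),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation_result (n = %d, %s):\n", x$n,
              if (x$adjust_sex) "sex-adjusted" else "unadjusted"))
  for (nm in c("model1", "model2", "model3", "model4_exposure",
               "model4_mark")) {
    cat(sprintf("  %-16s coef = %8.4f  p = %.4g\n", nm, x[[nm]]["coef"],
                x[[nm]]["p"]))
  }
  cat(sprintf("  classification: %s; ACME = %.4f", x$classification,
              x$acme))
  if (!is.null(x$acme_ci)) {
    cat(sprintf("  [%.4f, %.4f], p = %.4g (n_boot = %d)", x$acme_ci[1],
                x$acme_ci[2], x$acme_p, x$n_boot))
  }
  cat("\n")
  invisible(x)
}

#' Bootstrap the average causal mediation effect (ACME)
#'
#' Nonparametric case resampling: for each of `n_boot` resamples the
#' mediator model (mark ~ exposure [+ covariates]) and the outcome model
#' (outcome ~ exposure + mark [+ covariates]) are refit and the indirect
#' effect `a * b` recorded. The 95% interval is the percentile interval;
#' the two-sided p-value is `2 * min(frac <= 0, frac >= 0)` floored at
#' `2 / n_boot`. Resamples with a degenerate (single-level) exposure are
#' redrawn, with capped retries.
#'
#' @param mark,outcome,exposure As in [baron_kenny()].
#' @param covariates Optional numeric matrix/data frame of extra model
#'   covariates (e.g. sex).
#' @param n_boot Number of bootstrap resamples (minimum 200).
#' @param seed Seed for the resampling stream.
#' @param conf Confidence level (default 0.95).
#' @return List with `acme` (the original-data `a * b`), `ci`, `p`,
#'   `n_boot`, `seed`, `draws`.
#' @export
bootstrap_acme <- function(mark, outcome, exposure, covariates = NULL,
                           n_boot = 1000, seed = 1, conf = 0.95) {
  if (n_boot < 200) stop("n_boot must be at least 200")
  keep <- stats::complete.cases(mark, outcome, exposure, covariates)
  mark <- mark[keep]; outcome <- outcome[keep]; exposure <- exposure[keep]
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates)[keep, , drop = FALSE])
  }
  n <- length(mark)
  ab <- function(idx) {
    X2 <- cbind(1, exposure[idx])
    X4 <- cbind(1, exposure[idx], mark[idx])
    if (!is.null(covariates)) {
      X2 <- cbind(X2, covariates[idx, , drop = FALSE])
      X4 <- cbind(X4, covariates[idx, , drop = FALSE])
    }
    a <- stats::lm.fit(X2, mark[idx])$coefficients[2]
    b <- stats::lm.fit(X4, outcome[idx])$coefficients[3]
    a * b
  }
  point <- ab(seq_len(n))
  draws <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(exposure[idx])) > 1) return(ab(idx))
      }
      stop("could not draw a resample with both exposure levels")
    }, numeric(1))
  })
  lo <- (1 - conf) / 2
  ci <- unname(stats::quantile(draws, c(lo, 1 - lo), type = 7))
  p <- max(2 * min(mean(draws <= 0), mean(draws >= 0)), 2 / n_boot)
  list(acme = unname(point), ci = ci, p = min(p, 1), n_boot = n_boot,
       seed = seed, draws = draws)
}

#' Natural-log transform for leptin
#'
#' @param leptin Positive concentrations.
#' @return `log(leptin)`; errors on zero or negative values.
#' @export
ln_leptin <- function(leptin) {
  if (any(leptin <= 0, na.rm = TRUE)) {
    stop("leptin concentrations must be positive for the ln transform")
  }
  log(leptin)
}

#' Mediation screen over candidate methylation marks
#'
#' Runs the Baron-Kenny analysis (plus, optionally, the bootstrap ACME)
#' for every (candidate mark, outcome) pair. Candidates are meant to be
#' the probes in the sig-DMP / sig-DMR overlap (see
#' [overlap_dmps_dmrs()]); marks outside `candidates` are never tested.
#' By default the screen runs on R-allele carrier samples only (the
#' gene-environment framing); `scope = "all"` uses every sample. Leptin
#' is ln-transformed; BMI-Z outcomes are not sex-adjusted.
#'
#' @param ds A [methylation_dataset()] containing the candidate probes.
#' @param candidates Probe ids to test.
#' @param outcomes Sample-sheet outcome columns (default leptin,
#'   delta_bmi_z, body_fat_pct, bmi_z).
#' @param scope `"carriers"` (default) or `"all"`.
#' @param alpha Per-model significance threshold.
#' @param n_boot Bootstrap resamples per mark (0 skips the bootstrap).
#' @param seed Seed for the bootstrap streams.
#' @return Object of class `mediation_screen`: `table` (one row per mark
#'   x outcome with all four models' coefficients and p-values,
#'   classification, ACME and CI) and `summary` (marks classified
#'   partial-or-full per outcome).
#' @export
mediation_screen <- function(ds, candidates,
                             outcomes = c("leptin", "delta_bmi_z",
                                          "body_fat_pct", "bmi_z"),
                             scope = c("carriers", "all"), alpha = 0.05,
                             n_boot = 0, seed = 1) {
  stopifnot(inherits(ds, "methylation_dataset"))
  scope <- match.arg(scope)
  if (length(candidates) == 0) stop("candidate mark list is empty")
  candidates <- intersect(candidates, rownames(ds$m))
  if (scope == "carriers") {
    ds <- .subset_samples(ds,
                          ds$samples$sample_id[ds$samples$carrier == 1])
  }
  sm <- ds$samples
  rows <- list()
  for (oc in intersect(outcomes, names(sm))) {
    y <- if (oc == "leptin") ln_leptin(sm$leptin) else sm[[oc]]
    adjust_sex <- !grepl("bmi_z", oc)
    for (pid in candidates) {
      bk <- tryCatch(
        baron_kenny(ds$m[pid, ], y, sm$exposure, sex = sm$sex,
                    adjust_sex = adjust_sex, alpha = alpha),
        warning = function(w) NULL)
      if (is.null(bk)) next
      row <- data.frame(mark = pid, outcome = oc, n = bk$n,
                        coef_model1 = bk$model1["coef"],
                        p_model1 = bk$model1["p"],
                        coef_model2 = bk$model2["coef"],
                        p_model2 = bk$model2["p"],
                        coef_model3 = bk$model3["coef"],
                        p_model3 = bk$model3["p"],
                        coef_model4_exposure = bk$model4_exposure["coef"],
                        p_model4_exposure = bk$model4_exposure["p"],
                        coef_model4_mark = bk$model4_mark["coef"],
                        p_model4_mark = bk$model4_mark["p"],
                        classification = bk$classification,
                        acme = bk$acme, acme_lo = NA_real_,
                        acme_hi = NA_real_, acme_p = NA_real_,
                        stringsAsFactors = FALSE)
      if (n_boot > 0 && bk$classification != "none") {
        bt <- bootstrap_acme(ds$m[pid, ], y, sm$exposure,
                             covariates = if (adjust_sex) {
                               data.frame(sex = sm$sex)
                             } else NULL,
                             n_boot = n_boot,
                             seed = seed + length(rows))
        row$acme_lo <- bt$ci[1]
        row$acme_hi <- bt$ci[2]
        row$acme_p <- bt$p
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mark = character(0), outcome = character(0))
  rownames(tab) <- NULL
  mediators <- if (nrow(tab)) {
    tapply(tab$classification %in% c("partial", "full"), tab$outcome, sum)
  } else integer(0)
  structure(list(table = tab, summary = as.list(mediators),
                 scope = scope),
            class = "mediation_screen")
}

#' @export
print.mediation_screen <- function(x, ...) {
  cat(sprintf("mediation_screen (%s samples): %d mark x outcome pairs\n",
              x$scope, nrow(x$table)))
  for (oc in names(x$summary)) {
    cat(sprintf("  %s: %d partial-or-full mediators\n", oc,
                x$summary[[oc]]))
  }
  invisible(x)
}
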