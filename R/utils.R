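# Shared numerical helpers.

.EPS_BETA <- 1e-6

.clamp_beta <- function(beta, eps = .EPS_BETA) {
  pmin(pmax(beta, eps), 1 - eps)
}

#' Convert beta values to M values
#'
#' The M value is the log2-odds transform of the methylation fraction,
#' `M = log2(beta / (1 - beta))`, the preferred scale for linear modelling
#' of array methylation. Betas are clamped to `[1e-6, 1 - 1e-6]` before the
#' transform so boundary values stay finite.
#'
#' @param beta Numeric vector/matrix of beta values in `[0, 1]`.
#' @return Object of the same shape on the M scale.
#' @seealso [m_to_beta()]
#' @export
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8)) # -2, 0, 2
beta_to_m <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  b <- .clamp_beta(beta)
  log2(b / (1 - b))
}

#' Convert M values back to beta values
#'
#' Inverse of [beta_to_m()]: `beta = 1 / (1 + 2^-M)`.
#'
#' @param m Numeric vector/matrix of M values.
#' @return Betas in `(0, 1)`.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

# Case-insensitive sex-chromosome alias map: {X, chrX, 23} and {Y, chrY, 24}.
.is_sex_chromosome <- function(chrom) {
  tolower(trimws(as.character(chrom))) %in%
    c("x", "chrx", "23", "chr23", "y", "chry", "24", "chr24")
}

.row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

# Ordinary least squares for many response rows sharing one design matrix.
# Y: responses (rows = features, columns = observations); X: n x p design.
# Optional named list of contrast vectors c gives t-tests of c'beta using the
# full-model residual variance. Zero-residual rows get NaN p-values and are
# left to the caller to flag.
.fit_ols_matrix <- function(Y, X, contrasts = NULL) {
  stopifnot(ncol(Y) == nrow(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("design matrix is rank deficient; check covariate coding")
  }
  xtx_inv <- chol2inv(chol(crossprod(X)))
  B <- Y %*% X %*% xtx_inv # features x p
  colnames(B) <- colnames(X)
  res <- Y - tcrossprod(B, X)
  df <- nrow(X) - ncol(X)
  sigma2 <- rowSums(res^2) / df
  se <- sqrt(sigma2 %o% diag(xtx_inv))
  tstat <- B / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  out <- list(coef = B, se = se, t = tstat, p = pval,
              sigma2 = sigma2, df = df, xtx_inv = xtx_inv)
  if (!is.null(contrasts)) {
    out$contrast <- lapply(contrasts, function(cv) {
      est <- drop(B %*% cv)
      se_c <- sqrt(sigma2 * drop(t(cv) %*% xtx_inv %*% cv))
      tc <- est / se_c
      list(estimate = est, se = se_c, t = tc,
           p = 2 * stats::pt(abs(tc), df, lower.tail = FALSE))
    })
  }
  out
}

# Dirichlet draws via independent gammas.
.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
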