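#' Repair a covariance matrix to positive (semi-)definiteness
#'
#' Symmetrizes the input and clips tiny negative eigenvalues to zero.
#' Eigenvalues in `(-tol * lambda_max, 0)` are treated as numerical noise
#' (externally estimated covariance matrices, e.g. from LD-score regression,
#' are routinely indefinite at this level) and clipped with a warning; any
#' eigenvalue more negative than that is a hard error so genuinely broken
#' inputs are not silently rewritten.
#'
#' @param sigma square numeric matrix.
#' @param tol relative clipping tolerance on the most negative eigenvalue.
#' @param label name used in messages.
#' @return the repaired symmetric matrix.
#' @export
psd_repair <- function(sigma, tol = 1e-8, label = "sigma") {
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE)
  lmax <- max(ev$values, 0)
  bad <- ev$values < 0
  if (!any(bad)) return(sigma)
  if (min(ev$values) < -tol * max(lmax, 1)) {
    stop(sprintf("%s is not positive semi-definite: eigenvalue %.3e", label,
                 min(ev$values)))
  }
  warning(sprintf("%s: clipped %d negative eigenvalue(s) (min %.3e) to zero",
                  label, sum(bad), min(ev$values)))
  vals <- pmax(ev$values, 0)
  m <- ev$vectors %*% (vals * t(ev$vectors))
  (m + t(m)) / 2
}

#' Environmental covariance of z-scores from sample overlap
#'
#' Under the null a z-score has unit variance; two traits' z-scores covary
#' only through individuals measured for both, so the off-diagonal entries
#' are the environmental correlation weighted by the overlap fraction:
#' `Sigma_e[i,k] = n_shared[i,k] / sqrt(n[i] * n[k]) * rho_e[i,k]`.
#' The diagonal is forced to exactly 1.
#'
#' @param rho_e T x T environmental correlation matrix (unit diagonal).
#' @param n length-T per-trait sample sizes.
#' @param n_shared T x T matrix of pairwise overlapping sample counts;
#'   defaults to no overlap (identity environmental covariance).
#' @return T x T environmental covariance matrix of z-scores.
#' @export
build_sigma_e <- function(rho_e, n, n_shared = NULL) {
  T <- length(n)
  rho_e <- as.matrix(rho_e)
  stopifnot(nrow(rho_e) == T, ncol(rho_e) == T)
  if (max(abs(rho_e - t(rho_e))) > 1e-8)
    stop("rho_e must be symmetric")
  if (any(abs(rho_e) > 1 + 1e-12))
    stop("rho_e entries must lie in [-1, 1]")
  if (is.null(n_shared)) n_shared <- diag(n, T)
  n_shared <- as.matrix(n_shared)
  if (any(n_shared < 0)) stop("n_shared must be non-negative")
  if (any(n_shared > outer(n, n, pmin) + 1e-9))
    stop("n_shared[i,k] cannot exceed min(n[i], n[k])")
  se <- (n_shared / sqrt(outer(n, n))) * rho_e
  diag(se) <- 1
  psd_repair(se, label = "sigma_e")
}

#' Genetic covariance of z-scores
#'
#' Scales per-variant genetic (co)variances of effect sizes to the z-score
#' scale: `Sigma_g[i,k] = sqrt(n[i] * n[k]) * sigma_g[i,k]`. Sample overlap
#' does not enter; the unit null variance lives in the environmental part.
#'
#' @param sigma_g T x T per-variant genetic covariance matrix of effect
#'   sizes (diagonal: per-variant heritabilities).
#' @param n length-T per-trait sample sizes.
#' @return T x T genetic covariance matrix on the z-score scale.
#' @export
build_sigma_g_z <- function(sigma_g, n) {
  sigma_g <- as.matrix(sigma_g)
  T <- length(n)
  stopifnot(nrow(sigma_g) == T, ncol(sigma_g) == T)
  if (max(abs(sigma_g - t(sigma_g))) > 1e-8)
    stop("sigma_g must be symmetric")
  if (any(diag(sigma_g) < 0))
    stop("sigma_g has a negative diagonal entry")
  sqrt(outer(n, n)) * sigma_g
}

#' Assemble the covariance model for a set of traits
#'
#' Bundles sample sizes, overlap counts, environmental correlations and
#' per-variant genetic covariances, and derives the z-score-scale
#' environmental and genetic covariance matrices used by the test and by
#' the m-value machinery.
#'
#' @param n length-T per-trait sample sizes (positive).
#' @param sigma_g T x T per-variant genetic covariance matrix.
#' @param rho_e T x T environmental correlation matrix; defaults to identity.
#' @param n_shared T x T overlap counts; defaults to no overlap.
#' @param trait_names optional character vector of length T.
#' @return an object of class `cov_model` with elements `T`, `n`,
#'   `n_shared`, `rho_e`, `sigma_g`, `sigma_e`, `sigma_g_z`, `trait_names`.
#' @export
cov_model <- function(n, sigma_g, rho_e = NULL, n_shared = NULL,
                      trait_names = NULL) {
  n <- as.numeric(n)
  T <- length(n)
  if (T < 1 || any(n <= 0)) stop("n must be positive sample sizes")
  if (is.null(rho_e)) rho_e <- diag(T)
  if (is.null(n_shared)) n_shared <- diag(n, T)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(T))
  sigma_e <- build_sigma_e(rho_e, n, n_shared)
  sigma_g_z <- build_sigma_g_z(sigma_g, n)
  # the alternative covariance must be usable everywhere downstream
  chol(psd_repair(sigma_e + sigma_g_z, label = "sigma_e + sigma_g"))
  structure(list(T = T, n = n, n_shared = as.matrix(n_shared),
                 rho_e = as.matrix(rho_e), sigma_g = as.matrix(sigma_g),
                 sigma_e = sigma_e, sigma_g_z = sigma_g_z,
                 trait_names = trait_names),
            class = "cov_model")
}

#' @export
print.cov_model <- function(x, ...) {
  cat(sprintf("Covariance model: %d trait(s)\n", x$T))
  cat("  n:", paste(format(x$n, big.mark = ","), collapse = ", "), "\n")
  cat("  sigma_e off-diagonal range:",
      if (x$T > 1) sprintf("[%.4g, %.4g]",
                           min(x$sigma_e[upper.tri(x$sigma_e)]),
                           max(x$sigma_e[upper.tri(x$sigma_e)])) else "-",
      "\n")
  cat("  sigma_g_z diagonal:",
      paste(sprintf("%.4g", diag(x$sigma_g_z)), collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate effect configurations
#'
#' Each configuration is a binary vector over traits indicating which carry
#' a true effect; all `2^T` configurations are enumerated (including the
#' all-zero global null).
#'
#' @param T number of traits (guarded at T <= 15).
#' @return a `2^T` x T 0/1 integer matrix, one row per configuration; row
#'   order is by binary index with trait 1 the least-significant bit.
#' @export
configurations <- function(T) {
  stopifnot(T >= 1)
  if (T > 15) stop("configuration enumeration guarded at T <= 15")
  idx <- 0:(2^T - 1)
  m <- sapply(seq_len(T), function(i) bitwAnd(idx, bitwShiftL(1L, i - 1L)) > 0)
  m <- matrix(as.integer(m), nrow = 2^T, ncol = T)
  colnames(m) <- paste0("c", seq_len(T))
  m
}

#' Mask the genetic covariance by an effect configuration
#'
#' Keeps entry (i, k) iff traits i and k both carry an effect under `config`;
#' all other entries are zeroed. The all-ones configuration returns the
#' matrix unchanged, the all-zero configuration returns the zero matrix.
#'
#' @param sigma_g_z T x T genetic covariance (z-score scale).
#' @param config length-T 0/1 vector.
#' @return the masked T x T matrix.
#' @export
masked_sigma_g <- function(sigma_g_z, config) {
  config <- as.numeric(config)
  stopifnot(length(config) == ncol(sigma_g_z))
  sigma_g_z * outer(config, config)
}

#' Zero-mean multivariate normal log-density
#'
#' Evaluates `log N(S; 0, Sigma)` via the Cholesky factor. Accepts a single
#' vector or a matrix of row vectors; the factorization is computed once.
#'
#' @param S length-T vector, or M x T matrix (one row per observation).
#' @param sigma T x T positive-definite covariance matrix.
#' @param chol_sigma optional precomputed `chol(sigma)` (upper triangular);
#'   when supplied, `sigma` may be missing.
#' @return numeric vector of log-densities (length 1 for a vector input).
#' @export
mvn_logpdf <- function(S, sigma = NULL, chol_sigma = NULL) {
  if (is.null(chol_sigma)) {
    sigma <- as.matrix(sigma)
    chol_sigma <- tryCatch(chol(sigma), error = function(e) {
      chol(psd_repair(sigma, label = "sigma") + diag(1e-12, nrow(sigma)))
    })
  }
  T <- ncol(chol_sigma)
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  if (ncol(S) != T) stop("dimension mismatch between S and sigma")
  # solve R' q = S' row-wise; quadratic form = colSums(q^2)
  q <- backsolve(chol_sigma, t(S), transpose = TRUE)
  qf <- if (T == 1) as.numeric(q^2) else colSums(q^2)
  as.numeric(-0.5 * T * log(2 * pi) - sum(log(diag(chol_sigma))) - 0.5 * qf)
}

# log(sum(exp(x))) along rows of a matrix, guarded against overflow
logsumexp_rows <- function(L) {
  m <- apply(L, 1, max)
  m + log(rowSums(exp(L - m)))
}
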