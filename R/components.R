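#' MDL model-order selection from an eigenvalue spectrum
#'
#' Chooses the number of retained components for a participants x features
#' matrix with the classic minimum-description-length criterion of
#' Wax & Kailath: for each candidate order k, the negative log-likelihood
#' of an isotropic-residual Gaussian model (a function of the arithmetic
#' and geometric means of the trailing eigenvalues) plus half the free
#' parameter count times `log(samples)`. The smaller matrix dimension is
#' treated as the signal dimension and the larger as the sample count.
#'
#' @param matrix participants x features numeric matrix (>= 6 rows).
#' @param k_max largest candidate order (default dimension - 1).
#' @return Selected order K (integer >= 1).
#' @examples
#' set.seed(1)
#' A <- matrix(rnorm(40), 20, 2) %*% matrix(rnorm(60), 2, 30)
#' mdl_order(A + 0.05 * matrix(rnorm(600), 20, 30))  # 2
#' @export
mdl_order <- function(matrix, k_max = NULL) {
  X <- as.matrix(matrix)
  if (nrow(X) < 6L) stop("need at least 6 participants")
  if (nrow(X) < ncol(X)) X <- t(X)   # rows = samples, cols = dimensions
  N <- nrow(X); p <- ncol(X)
  X <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(X) / N, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (sum(ev > 1e-12 * ev[1]) < 2L) stop("degenerate covariance")
  if (is.null(k_max)) k_max <- p - 1L
  k_max <- min(k_max, p - 1L)
  mdl <- numeric(k_max)
  for (k in seq_len(k_max)) {
    tailev <- ev[(k + 1):p]
    tailev <- pmax(tailev, 1e-300)
    gm <- exp(mean(log(tailev)))
    am <- mean(tailev)
    loglik <- -N * (p - k) * log(gm / am)
    params <- 0.5 * k * (2 * p - k + 1)
    mdl[k] <- loglik + params * log(N)
  }
  which.min(mdl)
}

#' MDL-ordered ICA decomposition of a participants x features matrix
#'
#' PCA-whitens the matrix to K dimensions, then runs fixed-point ICA
#' (tanh contrast, symmetric decorrelation, tolerance 1e-6, up to 1000
#' iterations, seeded). On non-convergence the fit is restarted from a
#' fresh seeded rotation, relaxing the tolerance tenfold after every two
#' failed attempts (small-sample symmetric ICA can cycle just above a
#' tight tolerance); eight attempts in all before a convergence error.
#' Components
#' are ordered by explained variance, each source map's sign is fixed so
#' its skewness is positive, and mixing columns (participant loadings) are
#' z-scored.
#'
#' @param matrix participants x features.
#' @param K number of components; taken from [mdl_order()] when `NULL`.
#' @param seed integer seed (initial rotation is drawn from R's RNG).
#' @param method `"ica"` (default) or `"pca"` (no rotation beyond PCA).
#' @param tol fixed-point convergence tolerance for the first attempts.
#' @param maxit maximum fixed-point iterations per attempt.
#' @return list of class `component_model`: `mixing` (participants x K,
#'   z-scored columns), `sources` (K x features), `order`, `method`,
#'   `seed`.
#' @export
ica_decompose <- function(matrix, K = NULL, seed = 1L,
                          method = c("ica", "pca"), tol = 1e-6,
                          maxit = 1000L) {
  method <- match.arg(method)
  X <- as.matrix(matrix)
  n <- nrow(X); m <- ncol(X)
  if (is.null(K)) K <- mdl_order(X)
  if (K > min(n, m) - 1L) stop("K exceeds min(participants, features) - 1")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = K, nv = K)
  if (method == "pca") {
    mixing <- sv$u %*% diag(sv$d[seq_len(K)], K)
    sources <- t(sv$v)
  } else {
    # spatial ICA: sources independent across features; features are the
    # samples, so icafast sees the transposed top-K subspace
    Z <- sv$v                           # m x K, orthonormal columns
    set.seed(seed)
    fit <- NULL
    for (attempt in seq_len(8L)) {
      R0 <- qr.Q(qr(matrix(stats::rnorm(K * K), K)))
      tol_k <- tol * 10^((attempt - 1L) %/% 2L)
      # no feature-wise centering here: sources must stay inside the
      # top-K PCA subspace so mixing %*% sources reconstructs it
      cand <- ica::icafast(Z, nc = K, center = FALSE, maxit = maxit,
                           tol = tol_k, Rmat = R0, alg = "par",
                           fun = "logcosh", alpha = 1)
      if (isTRUE(cand$converged)) { fit <- cand; break }
    }
    if (is.null(fit)) {
      stop("convergence error: ICA failed to converge after 8 restarts; ",
           "try another seed or a smaller K")
    }
    sources <- t(fit$S)                 # K x m
    sources <- sources / apply(sources, 1, stats::sd)
    mixing <- Xc %*% t(sources) %*% solve(tcrossprod(sources))
  }
  # deterministic ordering (explained variance) and sign (source skewness)
  expl <- colSums(mixing^2) * rowSums(sources^2)
  ord <- order(expl, decreasing = TRUE)
  mixing <- mixing[, ord, drop = FALSE]
  sources <- sources[ord, , drop = FALSE]
  for (k in seq_len(K)) {
    sk <- mean((sources[k, ] - mean(sources[k, ]))^3)
    if (sk < 0) { sources[k, ] <- -sources[k, ]; mixing[, k] <- -mixing[, k] }
  }
  mixing <- apply(mixing, 2, zscore)
  structure(list(mixing = mixing, sources = sources, order = K,
                 method = method, seed = as.integer(seed)),
            class = "component_model")
}

#' Correlate component loadings with age
#'
#' @param model a [ica_decompose()] result.
#' @param cohort cohort table aligned with the mixing rows (needs `age`).
#' @return data.frame with one row per component: `component`, `r`, `p`
#'   (two-sided Pearson test).
#' @export
loading_age_stats <- function(model, cohort) {
  stopifnot(inherits(model, "component_model"))
  if (nrow(model$mixing) != nrow(cohort)) {
    stop("cohort not aligned with mixing rows")
  }
  res <- lapply(seq_len(ncol(model$mixing)), function(k) {
    ct <- stats::cor.test(model$mixing[, k], cohort$age)
    data.frame(component = k, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}
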