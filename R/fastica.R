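# FastICA fixed-point algorithm (symmetric/parallel extraction, logcosh
# contrast, whitening by eigen-decomposition of the sample second-moment
# matrix). Input X is observations x variables; for expression data the
# observations are features (genes/miRNAs) and the variables are samples,
# so the extracted sources are metagenes.
#
# Returns K (whitening, k x p), W (unmixing in whitened space, k x k),
# S (sources, n x k), A (mixing, k x p) with X ~ S %*% A, plus a
# convergence flag. Deterministic given w.init.
fastica_core <- function(X, k, w.init, alpha = 1, tol = 1e-6, maxit = 1000L) {
  n <- nrow(X)  # observations
  p <- ncol(X)  # mixed signals
  if (k > min(n, p)) stop("k must not exceed min(dim(X))")
  Xt <- t(X)                               # p x n
  V <- Xt %*% t(Xt) / n                    # p x p second moments
  s <- La.svd(V)
  D <- diag(1 / sqrt(s$d), length(s$d))
  K <- (D %*% t(s$u))[seq_len(k), , drop = FALSE]   # k x p
  Z <- K %*% Xt                            # k x n, whitened

  sym_decorrelate <- function(W) {
    sW <- La.svd(W)
    sW$u %*% diag(1 / sW$d, k) %*% t(sW$u) %*% W
  }
  W <- sym_decorrelate(w.init)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    wx <- W %*% Z
    gwx <- tanh(alpha * wx)
    v1 <- gwx %*% t(Z) / n
    gdot <- alpha * (1 - gwx^2)
    v2 <- diag(rowMeans(gdot), k) %*% W
    W1 <- sym_decorrelate(v1 - v2)
    lim <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (lim < tol) { converged <- TRUE; break }
  }
  w <- W %*% K                             # k x p unmixing
  S <- t(w %*% Xt)                         # n x k sources
  A <- solve(crossprod(S), crossprod(S, X))  # k x p mixing, least squares

  list(K = K, W = W, S = S, A = A, converged = converged, iterations = it)
}
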