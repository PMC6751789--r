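# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# Benjamini-Hochberg step-up rule written directly from its definition:
# adjusted p for the i-th order statistic is min over j >= i of p_(j)*n/j,
# capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    adj_sorted[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  adj <- numeric(n)
  adj[o] <- adj_sorted
  adj
}

# Upper-tail hypergeometric p by exhaustive enumeration of every possible
# signature draw from the background (feasible for backgrounds <= 12).
hyper_oracle <- function(signature, gene_set, background) {
  n_sig <- length(signature)
  obs <- length(intersect(signature, gene_set))
  draws <- utils::combn(background, n_sig, simplify = FALSE)
  hits <- vapply(draws, function(d)
    length(intersect(d, gene_set)) >= obs, logical(1))
  mean(hits)
}

# All permutations of 1..k (k small), for exhaustive component matching.
all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# Best total |r| achievable by any one-to-one assignment of run components
# to standard components.
exhaustive_match_total <- function(S_std, S_run) {
  k <- ncol(S_std)
  A <- abs(stats::cor(S_std, S_run))
  best <- -Inf
  for (p in all_perms(k)) {
    tot <- sum(A[cbind(seq_len(k), p)])
    if (tot > best) best <- tot
  }
  best
}

# Standard Laplace draws (inverse-CDF), for building identifiable sources.
rlaplace_test <- function(n) {
  u <- stats::runif(n, -0.5, 0.5)
  -sign(u) * log(1 - 2 * abs(u))
}

# Minimal stand-in for a fitted decomposition when only the weight matrix
# matters (survival screen, linking): stability fixed at 1.
fake_fit <- function(M, S = NULL, stability = rep(1, nrow(M))) {
  k <- nrow(M)
  if (is.null(S)) {
    S <- matrix(stats::rnorm(10 * k), 10, k,
                dimnames = list(paste0("g", 1:10), rownames(M)))
  }
  structure(list(S = S, M = M,
                 stability = stats::setNames(stability, rownames(M)),
                 center = rep(0, nrow(S)), k = k, nt = 2L, seed = 1L,
                 n_converged = 2L, feature_ids = rownames(S),
                 sample_ids = colnames(M)),
            class = "consica")
}

named_mat <- function(data, n, m, fprefix = "g", sprefix = "s") {
  matrix(data, n, m, dimnames = list(paste0(fprefix, seq_len(n)),
                                     paste0(sprefix, seq_len(m))))
}

# Pairwise concordance of two continuous scores: fraction of pairs ranked
# the same way (Harrell's C against a noiseless predictor).
concordance_pairs <- function(x, y) {
  n <- length(x)
  num <- 0L; den <- 0L
  for (i in seq_len(n - 1)) {
    dx <- x[i] - x[(i + 1):n]
    dy <- y[i] - y[(i + 1):n]
    keep <- dx != 0 & dy != 0
    num <- num + sum(sign(dx[keep]) == sign(dy[keep]))
    den <- den + sum(keep)
  }
  num / den
}
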