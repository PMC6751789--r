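#' Single ICA run on an expression matrix
#'
#' Decomposes a features-by-samples matrix into `k` independent source
#' columns (metagenes) and mixing rows (sample weights) with one FastICA
#' run. The matrix is centred per feature internally; the centring offsets
#' are returned so that `S %*% M + offsets` reconstructs the input up to the
#' unexplained subspace. Deterministic given `seed`.
#'
#' @param E `expr_matrix` (or bare named numeric matrix), features x samples.
#' @param k number of components, `k < min(n, m)`.
#' @param seed integer seed for the random initialisation.
#' @param tol convergence tolerance of the fixed-point iteration.
#' @param maxit maximum fixed-point iterations.
#' @return list with `S` (n x k), `M` (k x m), `center` (per-feature
#'   offsets), `converged`, `seed`.
#' @export
run_single_ica <- function(E, k, seed = 1L, tol = 1e-4, maxit = 1000L) {
  X <- unclass(E)
  if (!is.matrix(X) || !is.numeric(X)) stop("'E' must be a numeric matrix")
  n <- nrow(X); m <- ncol(X)
  if (k >= min(n, m)) stop("k must be < min(n features, m samples)")
  ctr <- rowMeans(X)
  Xc <- X - ctr
  rs <- local({ set.seed(seed); matrix(stats::rnorm(k * k), k, k) })
  fit <- fastica_core(Xc, k, w.init = rs, tol = tol, maxit = maxit)
  S <- fit$S
  M <- fit$A
  cn <- paste0("IC", seq_len(k))
  dimnames(S) <- list(rownames(X), cn)
  dimnames(M) <- list(cn, colnames(X))
  list(S = S, M = M, center = ctr, converged = fit$converged, seed = seed)
}

#' Least-squares projection of samples onto a metagene basis
#'
#' Solves `min_W ||E_centred - S W||_F` so that every sample gets a full
#' weight vector even if it was excluded from the run that produced `S`.
#' Exact when the centred matrix lies in the span of `S`.
#'
#' @param S metagene matrix (features x k), full column rank.
#' @param E expression matrix over the same features (features x m).
#' @param center per-feature offsets to subtract; defaults to the row means
#'   of `E`.
#' @return k x m weight matrix.
#' @export
project_weights <- function(S, E, center = rowMeans(unclass(E))) {
  X <- unclass(E) - center
  qrS <- qr(S)
  if (qrS$rank < ncol(S)) stop("metagene matrix is rank deficient")
  W <- qr.coef(qrS, X)
  dimnames(W) <- list(colnames(S), colnames(E))
  W
}

#' Match components of one run to a standard decomposition
#'
#' Resolves ICA's permutation and sign ambiguity: components of `S_run` are
#' assigned to components of `S_std` greedily by descending absolute Pearson
#' correlation of the metagenes (ties broken by lower component index), and
#' signs are chosen so matched correlations are positive.
#'
#' @param S_std,S_run metagene matrices of equal dimension (features x k).
#' @return list with `perm` (index into `S_run` columns such that
#'   `S_run[, perm]` aligns with `S_std`), `sign` (per aligned column) and
#'   `r` (the matched correlations, after sign flip).
#' @export
match_components <- function(S_std, S_run) {
  stopifnot(identical(dim(S_std), dim(S_run)))
  k <- ncol(S_std)
  R <- stats::cor(S_std, S_run)
  A <- abs(R)
  perm <- integer(k); sgn <- numeric(k); rr <- numeric(k)
  for (step in seq_len(k)) {
    idx <- which(A == max(A), arr.ind = TRUE)
    # ties: lowest standard index, then lowest run index
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    i <- idx[1]; j <- idx[2]
    perm[i] <- j
    sgn[i] <- if (R[i, j] >= 0) 1 else -1
    rr[i] <- abs(R[i, j])
    A[i, ] <- -Inf; A[, j] <- -Inf
  }
  list(perm = perm, sign = sgn, r = rr)
}

#' Consensus independent component analysis
#'
#' Decomposes an expression matrix `E` (features x samples) into `k`
#' statistically independent metagenes `S` and sample weights `M`,
#' `E ~ S %*% M` after per-feature centring, by running FastICA `nt` times,
#' each time on the matrix with one uniformly chosen sample left out.
#' Run 1 is the "standard": every other run is aligned to it by
#' [match_components()], each run's weights are completed for all samples by
#' [project_weights()], the aligned metagenes are averaged into a consensus
#' `S` (columns rescaled to unit standard deviation), and the consensus `M`
#' is the least-squares projection of the full matrix onto the consensus
#' metagenes. The stability of component i is the mean over runs of the
#' squared Pearson correlation between the aligned run metagene and the
#' consensus metagene.
#'
#' @param E `expr_matrix` or named numeric matrix, features x samples.
#' @param k number of components (`k < min(n, m - 1)`).
#' @param nt number of resampled runs (>= 2). Hundreds to a thousand runs
#'   are typical for production use; tests use tens.
#' @param seed master seed; governs both the FastICA initialisations and the
#'   leave-one-out sequence through independent sub-streams.
#' @param standard `"first"` uses run 1 as the alignment standard;
#'   `"best"` uses the run with highest mean absolute correlation to all
#'   other runs (O(nt^2) correlations).
#' @param use_runs `"all"` (default) averages every run: a run that stops at
#'   `maxit` still carries a decorrelated basis, and any instability it
#'   introduces is exactly what the stability metric is designed to expose
#'   (deliberate over-decomposition would otherwise abort). `"converged"`
#'   discards runs that hit `maxit` and errors when more than half do.
#' @param tol,maxit passed to the FastICA core.
#' @return object of class `consica`: list with `S` (n x k, unit-sd
#'   columns), `M` (k x m), `stability` (length k, in [0, 1]), `center`,
#'   `k`, `nt`, `seed`, `n_converged`, `feature_ids`, `sample_ids`.
#' @export
#' @examples
#' sim <- simulate_mixture(synthetic_scenario(n = 300, m = 40, k_true = 3,
#'                                            seed = 7))
#' fit <- consica(sim$E, k = 3, nt = 5, seed = 7)
#' fit
consica <- function(E, k, nt = 100L, seed = 1L, standard = c("first", "best"),
                    use_runs = c("all", "converged"),
                    tol = 1e-4, maxit = 1000L) {
  standard <- match.arg(standard)
  use_runs <- match.arg(use_runs)
  k <- as.integer(k); nt <- as.integer(nt); seed <- as.integer(seed)
  X <- unclass(E)
  n <- nrow(X); m <- ncol(X)
  if (nt < 2L) stop("'nt' must be >= 2")
  if (k >= min(n, m - 1L)) stop("k must be < min(n, m - 1)")
  set.seed(seed)
  excluded <- sample.int(m, nt, replace = TRUE)
  run_seeds <- sample.int(.Machine$integer.max, nt)

  ctr <- rowMeans(X)
  runs <- vector("list", nt)
  for (t in seq_len(nt)) {
    Et <- X[, -excluded[t], drop = FALSE]
    r <- run_single_ica(Et, k, seed = run_seeds[t], tol = tol, maxit = maxit)
    runs[[t]] <- r
  }
  conv <- vapply(runs, `[[`, logical(1), "converged")
  if (use_runs == "converged") {
    if (mean(conv) < 0.5)
      stop("more than 50% of ICA runs failed to converge")
    runs <- runs[conv]
  } else if (!any(conv)) {
    warning("no ICA run converged within maxit; components are likely ",
            "unstable (check the stability values)")
  }

  S_runs <- lapply(runs, `[[`, "S")
  std_idx <- 1L
  if (standard == "best" && length(runs) > 2L) {
    mean_r <- vapply(seq_along(S_runs), function(i) {
      mean(vapply(seq_along(S_runs), function(j) {
        if (i == j) return(NA_real_)
        mean(match_components(S_runs[[i]], S_runs[[j]])$r)
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    std_idx <- which.max(mean_r)
  }
  S_std <- S_runs[[std_idx]]
  aligned <- lapply(S_runs, function(Sr) {
    mm <- match_components(S_std, Sr)
    sweep(Sr[, mm$perm, drop = FALSE], 2, mm$sign, `*`)
  })

  S_sum <- Reduce(`+`, aligned)
  S_cons <- S_sum / length(aligned)
  sds <- apply(S_cons, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate consensus metagene (zero variance)")
  S_cons <- sweep(S_cons, 2, sds, `/`)
  colnames(S_cons) <- paste0("IC", seq_len(k))
  M_cons <- project_weights(S_cons, X, center = ctr)

  stability <- vapply(seq_len(k), function(i) {
    mean(vapply(aligned, function(Sa) stats::cor(Sa[, i], S_cons[, i])^2,
                numeric(1)))
  }, numeric(1))
  names(stability) <- colnames(S_cons)

  structure(list(S = S_cons, M = M_cons, stability = stability,
                 center = ctr, k = k, nt = nt, seed = seed,
                 n_converged = sum(conv),
                 feature_ids = rownames(X), sample_ids = colnames(X)),
            class = "consica")
}

#' @export
print.consica <- function(x, ...) {
  cat(sprintf(
    "Consensus ICA decomposition: %d features x %d samples, k = %d\n",
    length(x$feature_ids), length(x$sample_ids), x$k))
  cat(sprintf("  runs: %d (%d converged), seed %d\n",
              x$nt, x$n_converged, x$seed))
  cat(sprintf("  stability R^2: min %.3f / median %.3f / max %.3f\n",
              min(x$stability), stats::median(x$stability), max(x$stability)))
  invisible(x)
}

#' @export
summary.consica <- function(object, ...) {
  out <- data.frame(component = names(object$stability),
                    stability = unname(object$stability),
                    weight_mean = rowMeans(object$M),
                    weight_sd = apply(object$M, 1, stats::sd),
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.consica", "data.frame")
  out
}

#' @export
print.summary.consica <- function(x, ...) {
  cat("Per-component summary (stability = mean squared correlation of run\n")
  cat("metagenes with the consensus metagene):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Reconstruct the expression matrix from a decomposition
#'
#' Returns `S %*% M` plus the stored per-feature centring offsets.
#'
#' @param object a `consica` fit.
#' @param ... unused.
#' @return numeric matrix, features x samples.
#' @export
fitted.consica <- function(object, ...) {
  object$S %*% object$M + object$center
}

#' @export
residuals.consica <- function(object, E, ...) {
  unclass(E) - fitted(object)
}

#' Project new samples onto fitted metagenes
#'
#' Computes weights for new samples by least-squares projection onto the
#' consensus metagenes, using the training per-feature centring offsets.
#'
#' @param object a `consica` fit.
#' @param newdata expression matrix over the same features (any order;
#'   matched by feature id). Defaults to reproducing the training weights.
#' @param ... unused.
#' @return k x m_new weight matrix.
#' @export
predict.consica <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$M)
  X <- unclass(newdata)
  miss <- setdiff(object$feature_ids, rownames(X))
  if (length(miss) > 0L)
    stop("newdata lacks ", length(miss), " training features")
  X <- X[object$feature_ids, , drop = FALSE]
  project_weights(object$S, X, center = object$center)
}

#' @export
plot.consica <- function(x, ...) {
  graphics::barplot(x$stability, las = 2, ylim = c(0, 1),
                    ylab = expression(stability ~ R^2),
                    main = "Component stability", ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Serialise / restore a decomposition
#'
#' Writes `S.tsv`, `M.tsv`, `stability.tsv` and a JSON sidecar
#' (`decomposition.json` with k, nt, seed, convergence count, centring
#' offsets) into a directory; `read_decomposition()` restores the fit.
#'
#' @param fit a `consica` object.
#' @param dir output directory (created if needed).
#' @return `write_decomposition()` returns `dir` invisibly;
#'   `read_decomposition()` returns a `consica` object.
#' @export
write_decomposition <- function(fit, dir) {
  stopifnot(inherits(fit, "consica"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f, id) {
    df <- data.frame(rownames(m), m, check.names = FALSE)
    colnames(df) <- c(id, colnames(m))
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(fit$S, "S.tsv", "feature_id")
  wr(fit$M, "M.tsv", "component_id")
  utils::write.table(
    data.frame(component_id = names(fit$stability),
               stability = unname(fit$stability)),
    file.path(dir, "stability.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(k = fit$k, nt = fit$nt, seed = fit$seed,
         n_converged = fit$n_converged,
         center = as.list(stats::setNames(fit$center, fit$feature_ids))),
    file.path(dir, "decomposition.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(dir) {
  rd <- function(f) {
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    m
  }
  S <- rd("S.tsv"); M <- rd("M.tsv")
  st <- utils::read.delim(file.path(dir, "stability.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "decomposition.json"),
                              simplifyVector = TRUE)
  structure(list(S = S, M = M,
                 stability = stats::setNames(st$stability, st$component_id),
                 center = unlist(meta$center), k = meta$k, nt = meta$nt,
                 seed = meta$seed, n_converged = meta$n_converged,
                 feature_ids = rownames(S), sample_ids = colnames(M)),
            class = "consica")
}
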