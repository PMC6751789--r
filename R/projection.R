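#' Ranking score of a new sample's component weight
#'
#' Component weights are neither centred nor scaled, so the raw weight of a
#' component in a new sample is hard to read. The ranking score expresses it
#' as a quantile position within the discovery cohort: the fraction of
#' discovery weights below the new weight (mid-rank convention for ties,
#' denominator m). A new weight below the discovery minimum scores 0, above
#' the maximum scores 1, and a weight near the discovery median scores
#' about 0.5.
#'
#' @param discovery_weights numeric vector (length >= 2), one component's
#'   weights over the discovery samples.
#' @param w_new numeric scalar or vector of new weights.
#' @return score(s) in [0, 1]; monotone non-decreasing in `w_new`.
#' @export
ranking_score <- function(discovery_weights, w_new) {
  if (length(discovery_weights) < 2L)
    stop("discovery weights must have length >= 2")
  if (any(!is.finite(discovery_weights))) stop("non-finite discovery weights")
  m <- length(discovery_weights)
  lo <- min(discovery_weights); hi <- max(discovery_weights)
  vapply(w_new, function(w) {
    if (w < lo) return(0)
    if (w > hi) return(1)
    (sum(discovery_weights < w) + 0.5 * sum(discovery_weights == w)) / m
  }, numeric(1))
}

#' Ranking-score profile of new samples
#'
#' Applies [ranking_score()] to every component of a fitted decomposition:
#' new-sample weights are obtained by projection onto the consensus
#' metagenes and ranked against the discovery weight rows.
#'
#' @param fit a `consica` object (the discovery decomposition).
#' @param E_new expression matrix of the new samples over the training
#'   features, or a precomputed k x m_new weight matrix via `M_new`.
#' @param M_new optional weight matrix (bypasses projection).
#' @return samples x components numeric matrix of scores in [0, 1], class
#'   `rank_profile`.
#' @export
rank_profile <- function(fit, E_new = NULL, M_new = NULL) {
  stopifnot(inherits(fit, "consica"))
  if (is.null(M_new)) {
    if (is.null(E_new)) stop("supply E_new or M_new")
    M_new <- predict(fit, E_new)
  }
  out <- vapply(seq_len(fit$k), function(i)
    ranking_score(fit$M[i, ], M_new[i, ]), numeric(ncol(M_new)))
  out <- matrix(out, nrow = ncol(M_new), ncol = fit$k,
                dimnames = list(colnames(M_new), rownames(fit$M)))
  structure(out, class = c("rank_profile", "matrix", "array"))
}

#' @export
print.rank_profile <- function(x, ...) {
  cat(sprintf("Ranking-score profile: %d samples x %d components (0-1 scale)\n",
              nrow(x), ncol(x)))
  print(round(unclass(x), 3))
  invisible(x)
}
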