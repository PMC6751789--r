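#' Significantly contributing features of a metagene
#'
#' Most entries of a metagene are background noise, approximately normal;
#' the few features that drive the component sit far in the tails. Each
#' feature gets a z-score against a normal model with robust parameters,
#' `z = (s - median(s)) / (1.4826 * MAD(s))`, a two-sided normal p-value,
#' and Benjamini-Hochberg adjustment across all features of the component.
#' Features with adjusted p below `alpha` are reported, split by the sign
#' of z into positively and negatively contributing lists.
#'
#' @param s numeric vector, one metagene (a column of `S`), named by
#'   feature id; length >= 10.
#' @param alpha significance threshold on the adjusted p-value
#'   (default 0.01).
#' @return object of class `component_signature`: list with `positive` and
#'   `negative` data.frames (feature_id, z, adj_p), `alpha`, `n_features`.
#' @export
top_contributors <- function(s, alpha = 0.01) {
  if (length(s) < 10L) stop("metagene must have length >= 10")
  if (is.null(names(s)) && !is.null(rownames(s))) {
    nm <- rownames(s); s <- as.vector(s); names(s) <- nm
  }
  med <- stats::median(s)
  scl <- stats::mad(s)  # already scaled by 1.4826 for normal consistency
  if (scl == 0) stop("degenerate metagene: MAD is zero")
  z <- (s - med) / scl
  p <- 2 * stats::pnorm(-abs(z))
  adj <- stats::p.adjust(p, method = "BH")
  sig <- which(adj < alpha)
  mk <- function(idx) {
    idx <- idx[order(adj[idx], -abs(z[idx]))]
    data.frame(feature_id = if (is.null(names(s))) as.character(idx)
               else names(s)[idx],
               z = unname(z[idx]), adj_p = unname(adj[idx]),
               stringsAsFactors = FALSE)
  }
  structure(list(positive = mk(sig[z[sig] > 0]),
                 negative = mk(sig[z[sig] < 0]),
                 alpha = alpha, n_features = length(s)),
            class = "component_signature")
}

#' @export
print.component_signature <- function(x, ...) {
  cat(sprintf(
    "Component signature (alpha = %g): %d positive, %d negative of %d features\n",
    x$alpha, nrow(x$positive), nrow(x$negative), x$n_features))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a validated front end to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, monotone in the input order statistics and
#'   capped at 1.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and within [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Signatures for every component of a decomposition
#'
#' @param fit a `consica` object.
#' @param alpha adjusted-p threshold (default 0.01).
#' @return named list of `component_signature` objects, one per component.
#' @export
component_signatures <- function(fit, alpha = 0.01) {
  stopifnot(inherits(fit, "consica"))
  out <- lapply(seq_len(fit$k), function(i) {
    s <- fit$S[, i]; names(s) <- fit$feature_ids
    top_contributors(s, alpha = alpha)
  })
  names(out) <- colnames(fit$S)
  out
}

#' Orient components so the informative tail is positive
#'
#' The sign of an independent component is arbitrary. For interpretability
#' each component is oriented so that its most significant contributors sit
#' on the positive side: with gene-set enrichment results supplied, the side
#' whose best enrichment p-value is smaller goes positive; without them, the
#' side with more significant top contributors goes positive. Flipping
#' negates the metagene column and its weight row together, so the
#' reconstruction `S %*% M` is unchanged. Idempotent.
#'
#' @param fit a `consica` object.
#' @param enrichment optional per-component list, each element a list with
#'   numeric `best_p_positive` and `best_p_negative` (e.g. from
#'   [enrich_signature()] applied to each side).
#' @param alpha threshold used for the fallback tail-count rule.
#' @return the reoriented `consica` object, with attribute `flipped`
#'   (logical per component).
#' @export
orient_components <- function(fit, enrichment = NULL, alpha = 0.01) {
  stopifnot(inherits(fit, "consica"))
  flip <- logical(fit$k)
  for (i in seq_len(fit$k)) {
    if (!is.null(enrichment)) {
      e <- enrichment[[i]]
      flip[i] <- isTRUE(e$best_p_negative < e$best_p_positive)
    } else {
      s <- fit$S[, i]; names(s) <- fit$feature_ids
      sig <- top_contributors(s, alpha = alpha)
      flip[i] <- nrow(sig$negative) > nrow(sig$positive)
    }
  }
  fit$S[, flip] <- -fit$S[, flip, drop = FALSE]
  fit$M[flip, ] <- -fit$M[flip, , drop = FALSE]
  attr(fit, "flipped") <- flip
  fit
}

#' Orient miRNA components by their linked mRNA components
#'
#' miRNA components cannot be oriented by gene-set enrichment. Instead, each
#' miRNA component is compared to every mRNA component by Pearson
#' correlation of the weight rows over shared samples; if its most
#' correlated mRNA component is strongly negatively correlated
#' (`r < -threshold`), the miRNA component is flipped.
#'
#' @param fit_mirna,fit_mrna `consica` fits sharing sample ids.
#' @param threshold magnitude of negative correlation that triggers a flip
#'   (default 0.5).
#' @return the reoriented miRNA `consica` object with attribute `flipped`.
#' @export
orient_mirna_by_link <- function(fit_mirna, fit_mrna, threshold = 0.5) {
  shared <- intersect(fit_mirna$sample_ids, fit_mrna$sample_ids)
  if (length(shared) < 3L) stop("no (or too few) shared samples")
  Wa <- fit_mirna$M[, shared, drop = FALSE]
  Wb <- fit_mrna$M[, shared, drop = FALSE]
  R <- stats::cor(t(Wa), t(Wb))
  flip <- apply(R, 1, function(r) {
    best <- which.max(abs(r))
    r[best] < -threshold
  })
  fit_mirna$S[, flip] <- -fit_mirna$S[, flip, drop = FALSE]
  fit_mirna$M[flip, ] <- -fit_mirna$M[flip, , drop = FALSE]
  attr(fit_mirna, "flipped") <- unname(flip)
  fit_mirna
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least the actual overlap between a
#' signature and a gene set when drawing the signature uniformly from the
#' background. Used for GMT gene sets and for cytoband sets of miRNA
#' locations alike; adjust across sets with [benjamini_hochberg()].
#'
#' @param signature,gene_set character vectors of feature ids, both subsets
#'   of `background`.
#' @param background character vector, the universe of testable features.
#' @return p-value.
#' @export
hypergeometric_enrichment <- function(signature, gene_set, background) {
  if (length(background) == 0L) stop("empty background")
  background <- unique(background)
  signature <- unique(intersect(signature, background))
  gene_set <- unique(intersect(gene_set, background))
  q <- length(intersect(signature, gene_set))
  stats::phyper(q - 1, length(gene_set),
                length(background) - length(gene_set),
                length(signature), lower.tail = FALSE)
}

#' Enrichment of a signature against a gene-set collection
#'
#' @param signature character vector of feature ids.
#' @param collection named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background universe of feature ids.
#' @return data.frame (set, overlap, set_size, p, adj_p) sorted by p; BH
#'   adjustment across the sets of the collection.
#' @export
enrich_signature <- function(signature, collection, background) {
  p <- vapply(collection, function(gs)
    hypergeometric_enrichment(signature, gs, background), numeric(1))
  ov <- vapply(collection, function(gs)
    length(intersect(intersect(signature, background),
                     intersect(gs, background))), integer(1))
  out <- data.frame(set = names(collection), overlap = ov,
                    set_size = vapply(collection, function(gs)
                      length(intersect(gs, background)), integer(1)),
                    p = p, adj_p = benjamini_hochberg(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p), ]
}

#' Best-matching reference profile per component
#'
#' Associates each component with the column of a reference signature matrix
#' (e.g. an immune cell-type profile matrix) maximising the absolute Pearson
#' correlation between metagene and profile over shared features.
#'
#' @param fit a `consica` object.
#' @param reference numeric matrix, features x reference profiles, with
#'   unique column names; >= 3 shared features required.
#' @return data.frame (component, match, r).
#' @export
best_signature_match <- function(fit, reference) {
  stopifnot(inherits(fit, "consica"))
  if (anyDuplicated(colnames(reference))) stop("duplicate profile names")
  shared <- intersect(fit$feature_ids, rownames(reference))
  if (length(shared) < 3L) stop("fewer than 3 shared features")
  S <- fit$S[match(shared, fit$feature_ids), , drop = FALSE]
  R <- stats::cor(S, reference[shared, , drop = FALSE])
  best <- apply(R, 1, function(r) which.max(abs(r)))
  data.frame(component = colnames(fit$S),
             match = colnames(reference)[best],
             r = R[cbind(seq_len(nrow(R)), best)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited format: set name, description, then member ids.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  stats::setNames(lapply(parts, function(x) unique(x[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1))
}

#' Write component signatures as TSV
#'
#' One row per significant feature: component, feature_id, side, z, adj_p.
#'
#' @param sigs named list of `component_signature` objects.
#' @param path output file.
#' @export
write_signatures <- function(sigs, path) {
  rows <- lapply(names(sigs), function(cid) {
    s <- sigs[[cid]]
    rbind(
      if (nrow(s$positive)) cbind(component = cid, s$positive, side = "positive"),
      if (nrow(s$negative)) cbind(component = cid, s$negative, side = "negative"))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(component = character(), feature_id = character(),
                     z = numeric(), adj_p = numeric(), side = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
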