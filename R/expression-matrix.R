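#' Expression matrix container
#'
#' A light container for a features-by-samples numeric matrix together with a
#' tag recording the value scale. All decomposition and preprocessing
#' functions in the package accept and return this class.
#'
#' @param values numeric matrix, features in rows and samples in columns.
#'   Row and column names are the feature and sample identifiers and must be
#'   unique and non-empty.
#' @param scale character scalar, one of `"raw_count"`, `"log2"`,
#'   `"ct_inverted"`, `"harmonised"`.
#' @param allow_na logical; permit missing entries (only sensible for raw Ct
#'   tables, where missingness has a defined meaning — see [invert_ct()]).
#'
#' @return An object of class `expr_matrix`: the numeric matrix with a
#'   `scale` attribute.
#' @export
#' @examples
#' x <- matrix(rpois(12, 50), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' expr_matrix(x, "raw_count")
expr_matrix <- function(values, scale = c("raw_count", "log2", "ct_inverted",
                                          "harmonised"),
                        allow_na = FALSE) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("'values' must carry feature ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(fid)) stop("duplicate feature ids")
  if (anyDuplicated(sid)) stop("duplicate sample ids")
  if (!allow_na && any(!is.finite(values)))
    stop("non-finite values in expression matrix; missing values are only ",
         "accepted in Ct tables (use allow_na = TRUE)")
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples [scale: %s]\n",
              nrow(x), ncol(x), attr(x, "scale")))
  nr <- min(5L, nrow(x)); nc <- min(5L, ncol(x))
  print(unclass(x)[seq_len(nr), seq_len(nc), drop = FALSE])
  if (nrow(x) > nr || ncol(x) > nc) cat("...\n")
  invisible(x)
}

#' @export
as.matrix.expr_matrix <- function(x, ...) {
  m <- unclass(x)
  attr(m, "scale") <- NULL
  attr(m, "a") <- NULL
  attr(m, "b") <- NULL
  m
}

em_scale <- function(E) attr(E, "scale")

# rebuild the class after matrix subsetting (base `[` drops attributes)
em_like <- function(values, template, scale = em_scale(template),
                    allow_na = FALSE) {
  expr_matrix(values, scale = scale, allow_na = allow_na)
}

#' Read / write expression matrices as TSV
#'
#' The TSV dialect is: header row of sample ids, first column of feature ids,
#' tab separated, UTF-8. `write_expr_matrix()` mirrors the reader so that a
#' round-trip reproduces the file.
#'
#' @param path file path.
#' @param scale value-scale tag to attach (the file format does not carry it).
#' @param allow_na permit missing entries (Ct tables).
#' @return [read_expr_matrix()] returns an `expr_matrix`.
#' @export
read_expr_matrix <- function(path, scale = "log2", allow_na = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("expression TSV must have a feature-id column and ",
                          "at least one sample column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  expr_matrix(m, scale = scale, allow_na = allow_na)
}

#' @param E an `expr_matrix`.
#' @param id_col name for the feature-id column in the written file.
#' @rdname read_expr_matrix
#' @export
write_expr_matrix <- function(E, path, id_col = "feature_id") {
  df <- data.frame(rownames(E), unclass(E), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(E))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Soft count filter
#'
#' Keeps features whose raw count exceeds `min_value` (strictly) in at least
#' `min_samples` samples. With the defaults used for mRNA data
#' (`min_value = 1000`, `min_samples = 1`) this is the soft filter that keeps
#' genes with more than 1000 counts in at least one sample; for miRNA counts
#' use `min_value = 0` (at least one read present).
#'
#' @param E `expr_matrix` on the raw-count scale.
#' @param min_value strict lower threshold on the count value.
#' @param min_samples minimum number of samples in which the threshold must
#'   be exceeded (>= 1).
#' @return the filtered `expr_matrix`, feature order preserved.
#' @export
filter_features <- function(E, min_value = 1000, min_samples = 1L) {
  stopifnot(inherits(E, "expr_matrix"))
  if (em_scale(E) != "raw_count")
    stop("filter_features expects raw counts (scale 'raw_count')")
  if (min_samples < 1L) stop("'min_samples' must be >= 1")
  keep <- rowSums(unclass(E) > min_value) >= min_samples
  if (!any(keep)) stop("no features pass filter")
  em_like(unclass(E)[keep, , drop = FALSE], E)
}

#' Log2 transform of count data
#'
#' @param E `expr_matrix` of raw counts.
#' @param pseudocount positive offset added before taking log2 (default 1).
#' @return `expr_matrix` on the `log2` scale.
#' @export
log_transform <- function(E, pseudocount = 1) {
  stopifnot(inherits(E, "expr_matrix"))
  if (em_scale(E) != "raw_count")
    stop("log_transform expects raw counts (scale 'raw_count')")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("'pseudocount' must be > 0")
  if (any(unclass(E) < 0)) stop("negative values in count matrix")
  em_like(log2(unclass(E) + pseudocount), E, scale = "log2")
}

#' Invert qPCR Ct values to an expression-like scale
#'
#' Missing Ct values and Ct above `limit` are replaced by `limit`; expression
#' is then `limit - Ct`, so undetected miRNAs score 0 and strongly expressed
#' ones score high.
#'
#' @param Ct `expr_matrix` of Ct values (missing entries allowed).
#' @param limit detection limit in cycles (default 36).
#' @return `expr_matrix` on the `ct_inverted` scale, no missing values.
#' @export
invert_ct <- function(Ct, limit = 36) {
  stopifnot(inherits(Ct, "expr_matrix"))
  v <- unclass(Ct)
  if (any(v[is.finite(v)] < 0)) stop("Ct values must be positive")
  v[!is.finite(v) | v > limit] <- limit
  em_like(limit - v, Ct, scale = "ct_inverted")
}

#' Harmonise a matrix to a reference distribution
#'
#' Applies an affine map `a*x + b` to `E_new` (restricted to the features it
#' shares with `E_ref`) so that the pooled value distribution of the result
#' matches that of `E_ref` in location and spread. Used to bring microarray
#' log-intensities onto an RNA-seq log-count scale before joint decomposition.
#'
#' Robust moment matching (median and MAD of the pooled values) is the
#' default; `method = "sd"` uses mean and standard deviation instead.
#'
#' @param E_new `expr_matrix` to be transformed (log-like scale).
#' @param E_ref reference `expr_matrix` (log-like scale).
#' @param method `"mad"` (median/MAD, default) or `"sd"` (mean/sd).
#' @return `expr_matrix` restricted to shared features, scale `harmonised`;
#'   coefficients in attributes `a` and `b`.
#' @export
harmonize_to_reference <- function(E_new, E_ref, method = c("mad", "sd")) {
  stopifnot(inherits(E_new, "expr_matrix"), inherits(E_ref, "expr_matrix"))
  method <- match.arg(method)
  shared <- intersect(rownames(E_new), rownames(E_ref))
  if (length(shared) < 2L) stop("fewer than 2 shared features")
  x <- as.vector(unclass(E_new)[shared, , drop = FALSE])
  y <- as.vector(unclass(E_ref)[shared, , drop = FALSE])
  if (method == "mad") {
    loc_x <- stats::median(x); sc_x <- stats::mad(x)
    loc_y <- stats::median(y); sc_y <- stats::mad(y)
  } else {
    loc_x <- mean(x); sc_x <- stats::sd(x)
    loc_y <- mean(y); sc_y <- stats::sd(y)
  }
  if (sc_x == 0) stop("degenerate (constant) input matrix")
  a <- sc_y / sc_x
  b <- loc_y - a * loc_x
  out <- em_like(a * unclass(E_new)[shared, , drop = FALSE] + b, E_new,
                 scale = "harmonised")
  attr(out, "a") <- a
  attr(out, "b") <- b
  out
}

#' Concatenate two cohorts into one matrix with batch labels
#'
#' Column-binds the two matrices on the intersection of their feature ids and
#' records which input each sample came from, so that downstream components
#' capturing the cross-cohort technical offset can be recognised.
#'
#' @param E_a,E_b `expr_matrix` objects on log-like scales with disjoint
#'   sample ids.
#' @param batch_names length-2 character, batch tag for each input.
#' @return a list with `E` (the combined `expr_matrix`, scale of `E_a`) and
#'   `batch` (data.frame sample_id, batch).
#' @export
concat_datasets <- function(E_a, E_b,
                            batch_names = c("discovery", "investigation")) {
  stopifnot(inherits(E_a, "expr_matrix"), inherits(E_b, "expr_matrix"))
  ok <- c("log2", "ct_inverted", "harmonised")
  if (!(em_scale(E_a) %in% ok) || !(em_scale(E_b) %in% ok))
    stop("both matrices must be on a log-like scale")
  if (length(intersect(colnames(E_a), colnames(E_b))) > 0L)
    stop("duplicate sample ids across inputs: ",
         paste(intersect(colnames(E_a), colnames(E_b)), collapse = ", "))
  shared <- intersect(rownames(E_a), rownames(E_b))
  if (length(shared) == 0L) stop("empty feature intersection")
  E <- cbind(unclass(E_a)[shared, , drop = FALSE],
             unclass(E_b)[shared, , drop = FALSE])
  batch <- data.frame(
    sample_id = c(colnames(E_a), colnames(E_b)),
    batch = rep(batch_names, c(ncol(E_a), ncol(E_b))),
    stringsAsFactors = FALSE)
  list(E = em_like(E, E_a), batch = batch)
}
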