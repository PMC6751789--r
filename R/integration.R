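#' Link components across omics layers by weight correlation
#'
#' Computes Pearson correlation between component weight rows of two
#' decompositions over their shared samples, and keeps pairs with squared
#' correlation strictly above the threshold as edges. With
#' `fit_b` equal to `fit_a` the same operation yields within-layer links
#' (self-pairs excluded).
#'
#' @param fit_a,fit_b `consica` objects with >= 3 shared samples.
#' @param r2_threshold strict lower bound on r^2 (default 0.25, i.e.
#'   |r| > 0.5).
#' @param layers length-2 character tags for the two layers (e.g.
#'   `c("RIC", "MIC")`).
#' @return object of class `component_graph`: list with `edges`
#'   (data.frame node_a, node_b, r, r2), `nodes` (data.frame id, layer),
#'   `threshold`, `samples_used`.
#' @export
link_components <- function(fit_a, fit_b, r2_threshold = 0.25,
                            layers = c("a", "b")) {
  Ma <- if (inherits(fit_a, "consica")) fit_a$M else fit_a
  Mb <- if (inherits(fit_b, "consica")) fit_b$M else fit_b
  shared <- intersect(colnames(Ma), colnames(Mb))
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  same <- identical(Ma, Mb) && identical(layers[1], layers[2])
  R <- stats::cor(t(Ma[, shared, drop = FALSE]),
                  t(Mb[, shared, drop = FALSE]))
  ida <- paste0(layers[1], ":", rownames(Ma))
  idb <- paste0(layers[2], ":", rownames(Mb))
  idx <- which(R^2 > r2_threshold, arr.ind = TRUE)
  if (same) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  edges <- data.frame(node_a = ida[idx[, 1]], node_b = idb[idx[, 2]],
                      r = R[idx], r2 = R[idx]^2, stringsAsFactors = FALSE)
  nodes <- unique(data.frame(
    id = c(ida, idb),
    layer = rep(layers, c(length(ida), length(idb))),
    stringsAsFactors = FALSE))
  structure(list(edges = edges[order(-edges$r2), , drop = FALSE],
                 nodes = nodes, threshold = r2_threshold,
                 samples_used = shared),
            class = "component_graph")
}

#' @export
print.component_graph <- function(x, ...) {
  cat(sprintf("Component graph: %d nodes, %d edges (r^2 > %g, %d shared samples)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold,
              length(x$samples_used)))
  if (nrow(x$edges)) print(utils::head(x$edges, 10), row.names = FALSE,
                           digits = 3)
  invisible(x)
}

#' Clusters of mutually linked components
#'
#' Connected components of the link graph; singletons are nodes with no
#' edge above the threshold.
#'
#' @param graph a `component_graph`.
#' @return list of character vectors (cluster members), largest first;
#'   attribute `membership` maps every node to its cluster index.
#' @export
cluster_components <- function(graph) {
  stopifnot(inherits(graph, "component_graph"))
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("node_a", "node_b"), drop = FALSE],
    directed = FALSE, vertices = graph$nodes$id)
  comp <- igraph::components(g)
  memb <- comp$membership
  cl <- split(names(memb), memb)
  cl <- cl[order(-lengths(cl), vapply(cl, min, character(1)))]
  names(cl) <- NULL
  attr(cl, "membership") <- memb
  cl
}

#' Write a component graph
#'
#' Edge-list TSV (columns node_a, node_b, r, r2) or GraphML for
#' visualisation tools.
#'
#' @param graph a `component_graph`.
#' @param path output file.
#' @param format `"tsv"` (default) or `"graphml"`.
#' @export
write_component_graph <- function(graph, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                       vertices = graph$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
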