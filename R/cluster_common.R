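#' Cluster labelings
#'
#' Per-localization integer labels: 0 marks noise/background, 1..K mark
#' clusters. Ids are contiguous, each with at least one member, numbered
#' by descending member count (ties broken by first occurrence).
#'
#' @param labels integer vector aligned 1:1 with the table rows.
#' @param algorithm `"kde"`, `"dbscan"` or `"voronoi"`.
#' @param params named list of the parameters used (provenance).
#' @return An object of class `cluster_labeling`.
#' @export
cluster_labeling <- function(labels, algorithm, params = list()) {
  labels <- as.integer(labels)
  if (any(labels < 0L)) stop("cluster labels must be >= 0")
  k <- length(unique(labels[labels > 0L]))
  if (k > 0L && !setequal(unique(labels[labels > 0L]), seq_len(k)))
    stop("cluster ids must be contiguous 1..K")
  structure(list(labels = labels, algorithm = algorithm, params = params,
                 n_clusters = k),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("<cluster_labeling:%s> %d localizations, %d cluster(s), %d noise\n",
              x$algorithm, length(x$labels), x$n_clusters,
              sum(x$labels == 0L)))
  invisible(x)
}

## Drop clusters below min_size and renumber the rest contiguously by
## descending member count (ties: lower original id first).
.finalize_labels <- function(raw, min_size) {
  raw <- as.integer(raw)
  if (!any(raw > 0L)) return(raw)
  counts <- table(raw[raw > 0L])
  keep_ids <- as.integer(names(counts))[counts >= min_size]
  raw[!(raw %in% keep_ids)] <- 0L
  if (length(keep_ids) == 0L) return(raw)
  counts <- counts[as.character(keep_ids)]
  ord <- keep_ids[order(-as.integer(counts), keep_ids)]
  out <- integer(length(raw))
  out[raw > 0L] <- match(raw[raw > 0L], ord)
  out
}

## Connected components of an undirected edge list over n nodes.
## Returns an integer membership vector (1..K); isolated nodes get their
## own component.
.components <- function(n, edges) {
  if (n == 0L) return(integer(0))
  if (is.null(edges) || nrow(edges) == 0L) return(seq_len(n))
  g <- igraph::graph_from_edgelist(cbind(edges[, 1L], edges[, 2L]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership
}
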