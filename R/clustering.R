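#' Count triangles in a graph
#'
#' Total number of distinct triangles; equals one third of the sum of per-node
#' triangle counts.
#'
#' @param g A graph as a data frame of edges.
#' @return A single non-negative integer.
#' @examples
#' count_triangles(hierarchical_model(1)) # K5 has choose(5, 3) = 10
#' @export
count_triangles <- function(g) {
  ig <- as_igraph(g)
  as.integer(sum(igraph::count_triangles(ig)) / 3)
}

#' Per-node clustering coefficients
#'
#' For a node of degree k with N triangles through it, the clustering
#' coefficient is 2N / (k (k - 1)): the fraction of neighbour pairs that are
#' themselves connected. Nodes of degree < 2 have no defined value and are
#' excluded from all clustering statistics in this package.
#'
#' @param g A graph as a data frame of edges.
#' @param nodes Optional character vector restricting the result to specific
#'   nodes. Requesting a node of degree < 2 (or an unknown node) is an error.
#' @return A tibble with columns `node`, `degree`, `triangles`, `clustering`,
#'   sorted by node id; only nodes with degree >= 2 appear unless explicitly
#'   requested.
#' @export
node_clustering <- function(g, nodes = NULL) {
  ig <- as_igraph(g)
  ids <- igraph::V(ig)$name
  deg <- igraph::degree(ig)
  tri <- igraph::count_triangles(ig)
  out <- tibble(node = ids, degree = as.integer(deg),
                triangles = as.integer(tri)) %>%
    arrange(.data$node)
  if (!is.null(nodes)) {
    missing <- setdiff(nodes, out$node)
    if (length(missing) > 0) {
      abort(sprintf("Unknown node(s): %s", paste(missing, collapse = ", ")))
    }
    out <- out[match(nodes, out$node), ]
    if (any(out$degree < 2)) {
      abort(sprintf(
        "Clustering coefficient is undefined for degree < 2 node(s): %s",
        paste(out$node[out$degree < 2], collapse = ", ")))
    }
  } else {
    out <- filter(out, .data$degree >= 2)
    if (nrow(out) == 0) abort("No nodes of degree >= 2; clustering undefined.")
  }
  mutate(out, clustering = 2 * .data$triangles /
           (.data$degree * (.data$degree - 1)))
}

#' Mean clustering coefficient
#'
#' Average of [node_clustering()] over all nodes of degree >= 2.
#'
#' @param g A graph as a data frame of edges.
#' @return A single value in \[0, 1\].
#' @export
mean_clustering <- function(g) {
  mean(node_clustering(g)$clustering)
}

#' C(k): mean clustering coefficient per degree
#'
#' Groups nodes by exact degree and averages their clustering coefficients.
#' Only degrees >= 2 appear (lower degrees have no defined coefficient).
#' Logarithmic binning, where wanted, is applied downstream at presentation
#' time; the spectrum itself is always unbinned.
#'
#' @param g A graph as a data frame of edges.
#' @return A tibble with columns `degree`, `c_mean`, `n_nodes`.
#' @export
ck_spectrum <- function(g) {
  node_clustering(g) %>%
    group_by(.data$degree) %>%
    summarise(c_mean = mean(.data$clustering), n_nodes = n()) %>%
    arrange(.data$degree)
}

#' Degree assortativity coefficient
#'
#' Pearson correlation between the degrees found at the two ends of an edge,
#' counting each edge in both orientations (Newman's r). Negative values mean
#' hubs avoid each other (disassortative mixing); positive values mean hub
#' affinity.
#'
#' @param g A graph as a data frame of edges.
#' @return A single value in \[-1, 1\].
#' @examples
#' assortativity_coefficient(spoke_graph(1, 5, 0)) # a star is exactly -1
#' @export
assortativity_coefficient <- function(g) {
  e <- as_edge_table(g)
  if (nrow(e) < 2) abort("Assortativity needs at least 2 edges.")
  d <- node_degrees(e)
  ka <- d$degree[match(e$from, d$node)]
  kb <- d$degree[match(e$to, d$node)]
  x <- c(ka, kb)
  y <- c(kb, ka)
  if (sd(x) == 0) {
    abort("Assortativity undefined: all edge endpoints have equal degree.")
  }
  cor(x, y)
}
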