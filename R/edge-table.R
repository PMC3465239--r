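#' Coerce a data frame to a canonical undirected edge table
#'
#' Graphs in spokenet are plain tibbles whose first two columns hold the
#' endpoints of each undirected edge. `as_edge_table()` canonicalises such a
#' data frame: endpoints become character, self-loops are dropped, duplicate
#' edges (in either orientation) are collapsed, each endpoint pair is ordered
#' lexicographically, and rows are sorted. Every other function in the package
#' accepts anything this function accepts.
#'
#' @param x A data frame with at least two columns; the first two are taken as
#'   edge endpoints. Extra columns are dropped.
#' @param quiet If `FALSE`, warn about dropped self-loops and duplicates
#'   (one warning per offending row category with counts).
#' @return A tibble with columns `from` and `to` (character), one row per
#'   undirected edge, `from <= to` lexicographically, sorted.
#' @examples
#' as_edge_table(data.frame(a = c("b", "a"), b = c("a", "b")))
#' @export
as_edge_table <- function(x, quiet = TRUE) {
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort("`x` must be a data frame with at least two columns (edge endpoints).")
  }
  from <- as.character(x[[1]])
  to <- as.character(x[[2]])
  keep <- !is.na(from) & !is.na(to) & nzchar(from) & nzchar(to)
  from <- from[keep]; to <- to[keep]
  loops <- from == to
  if (any(loops) && !quiet) {
    warn(sprintf("Dropped %d self-loop(s).", sum(loops)))
  }
  from2 <- pmin(from[!loops], to[!loops])
  to2 <- pmax(from[!loops], to[!loops])
  key <- paste(from2, to2, sep = "\r")
  dup <- duplicated(key)
  if (any(dup) && !quiet) {
    warn(sprintf("Collapsed %d duplicate edge(s).", sum(dup)))
  }
  out <- tibble(from = from2[!dup], to = to2[!dup])
  arrange(out, .data$from, .data$to)
}

#' Read an undirected graph from an edge-list TSV or GraphML file
#'
#' The TSV dialect is two (or more) whitespace/tab-separated columns, one edge
#' per line, lines starting with `#` ignored. Self-loops and duplicate edges
#' are dropped with a warning, so the result is always a simple graph.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"graphml"`.
#' @return A canonical edge tibble (see [as_edge_table()]).
#' @export
read_edgelist <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "tsv") {
    raw <- tryCatch(
      utils::read.table(path, header = FALSE, comment.char = "#",
                        colClasses = "character",
                        stringsAsFactors = FALSE, fill = FALSE),
      error = function(e) abort(sprintf("Could not parse '%s': %s", path, conditionMessage(e)))
    )
    if (nrow(raw) == 0 || ncol(raw) < 2) abort(sprintf("No edges found in '%s'.", path))
    as_edge_table(raw, quiet = FALSE)
  } else {
    ig <- igraph::read_graph(path, format = "graphml")
    ig <- igraph::as_undirected(ig, mode = "collapse")
    el <- igraph::as_edgelist(ig, names = TRUE)
    if (nrow(el) == 0) abort(sprintf("No edges found in '%s'.", path))
    as_edge_table(as.data.frame(el), quiet = FALSE)
  }
}

#' Write an edge table to a two-column TSV file
#'
#' @param g A graph as a data frame of edges.
#' @param path Output path.
#' @return `g`, invisibly (so calls can sit inside a pipe).
#' @export
write_edgelist <- function(g, path) {
  e <- as_edge_table(g)
  utils::write.table(e, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(g)
}

#' Nodes of a graph
#'
#' @param g A graph as a data frame of edges.
#' @return Character vector of node ids, sorted.
#' @export
graph_nodes <- function(g) {
  e <- as_edge_table(g)
  sort(unique(c(e$from, e$to)))
}

#' Node degrees
#'
#' @param g A graph as a data frame of edges.
#' @return A tibble with columns `node` and `degree`, sorted by node id.
#' @export
node_degrees <- function(g) {
  e <- as_edge_table(g)
  ends <- c(e$from, e$to)
  tab <- table(ends)
  tibble(node = names(tab), degree = as.integer(tab)) %>%
    arrange(.data$node)
}

#' Degree histogram
#'
#' Tallies how many nodes have each degree. The result carries the node count
#' `n_nodes`, edge count `n_edges` and mean degree as attributes; the identity
#' `sum(degree * count) == 2 * n_edges` always holds.
#'
#' @param g A graph as a data frame of edges.
#' @return A tibble with columns `degree` and `count`.
#' @export
degree_histogram <- function(g) {
  d <- node_degrees(g)
  out <- d %>%
    count(.data$degree, name = "count") %>%
    arrange(.data$degree)
  attr(out, "n_nodes") <- nrow(d)
  attr(out, "n_edges") <- sum(d$degree) / 2
  attr(out, "mean_degree") <- mean(d$degree)
  out
}

# internal: edge tibble -> igraph with all nodes (optionally isolated ones too)
as_igraph <- function(g, nodes = NULL) {
  e <- as_edge_table(g)
  if (is.null(nodes)) nodes <- sort(unique(c(e$from, e$to)))
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = nodes)
}

# internal: edge tibble -> list(edges = 1-based integer matrix, nodes = ids)
edge_index <- function(g) {
  e <- as_edge_table(g)
  nodes <- sort(unique(c(e$from, e$to)))
  list(
    edges = cbind(match(e$from, nodes), match(e$to, nodes)),
    nodes = nodes
  )
}

# internal: integer edge matrix + node ids -> canonical edge tibble
edges_from_index <- function(mat, nodes) {
  as_edge_table(tibble(from = nodes[mat[, 1]], to = nodes[mat[, 2]]))
}
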