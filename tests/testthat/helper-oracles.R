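# Independent brute-force oracles used to validate the fast implementations.
# These deliberately take different routes: dense adjacency-matrix algebra and
# explicit pair enumeration instead of igraph or hashed edge sets.

oracle_adjacency <- function(g) {
  e <- as_edge_table(g)
  nodes <- sort(unique(c(e$from, e$to)))
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  A[cbind(e$from, e$to)] <- 1L
  A[cbind(e$to, e$from)] <- 1L
  A
}

# total triangles = trace(A^3) / 6
oracle_triangle_total <- function(g) {
  A <- oracle_adjacency(g)
  A3 <- A %*% A %*% A
  sum(diag(A3)) / 6
}

# per-node triangles = diag(A^3) / 2
oracle_node_triangles <- function(g) {
  A <- oracle_adjacency(g)
  A3 <- A %*% A %*% A
  setNames(diag(A3) / 2, rownames(A))
}

# clustering of one node by explicit neighbour-pair enumeration
oracle_node_clustering <- function(g, v) {
  A <- oracle_adjacency(g)
  nb <- which(A[v, ] == 1)
  k <- length(nb)
  stopifnot(k >= 2)
  pairs <- combn(nb, 2)
  n_linked <- sum(A[cbind(pairs[1, ], pairs[2, ])])
  2 * n_linked / (k * (k - 1))
}

# Newman's assortativity via explicit moment sums over edges
oracle_assortativity <- function(g) {
  e <- as_edge_table(g)
  A <- oracle_adjacency(g)
  deg <- rowSums(A)
  j <- deg[e$from]; k <- deg[e$to]
  M <- nrow(e)
  m1 <- sum((j + k) / 2) / M
  num <- sum(j * k) / M - m1^2
  den <- sum((j^2 + k^2) / 2) / M - m1^2
  num / den
}

# Erdos-Renyi graph as an edge tibble (for randomized oracle suites)
random_gnp <- function(n, p) {
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- t(combn(seq_len(n), 2))
  on <- runif(nrow(pairs)) < p
  as_edge_table(tibble::tibble(from = ids[pairs[on, 1]],
                               to = ids[pairs[on, 2]]))
}

# relabel nodes with fresh opaque ids (isomorphic copy)
relabel_graph <- function(g, prefix = "x") {
  e <- as_edge_table(g)
  nodes <- sort(unique(c(e$from, e$to)))
  new <- setNames(sprintf("%s%03d", prefix, sample(seq_along(nodes))), nodes)
  as_edge_table(tibble::tibble(from = new[e$from], to = new[e$to]))
}

# direct per-edge tally of the joint degree matrix
oracle_jdm <- function(g) {
  e <- as_edge_table(g)
  d <- node_degrees(e)
  ka <- d$degree[match(e$from, d$node)]
  kb <- d$degree[match(e$to, d$node)]
  tab <- table(paste(pmin(ka, kb), pmax(ka, kb)))
  sort(tab)
}

edge_key_set <- function(g) {
  e <- as_edge_table(g)
  sort(paste(e$from, e$to))
}
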