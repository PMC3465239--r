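#' Degree-preserving rewiring null
#'
#' Randomises a graph by double-edge swaps (a,b),(c,d) -> (a,d),(c,b).
#' Proposals that would create a self-loop or multi-edge are rejected and
#' retried, so every node keeps its exact degree. If the proposal budget is
#' exhausted before `n_swaps` succeed (e.g. a lone triangle admits no valid
#' swap) the partially rewired graph is returned with a warning.
#'
#' @param g A graph as a data frame of edges.
#' @param n_swaps Number of successful swaps to perform; default 10 per edge,
#'   enough to decorrelate edge placement.
#' @param seed Optional RNG seed.
#' @param max_prop_factor Proposal budget as a multiple of `n_swaps`.
#' @return A canonical edge tibble with the same degree sequence as `g`.
#' @export
rewire_degree_preserving <- function(g, n_swaps = NULL, seed = NULL,
                                     max_prop_factor = 100) {
  idx <- edge_index(g)
  m <- nrow(idx$edges)
  if (m < 2) abort("Rewiring needs at least 2 edges.")
  if (is.null(n_swaps)) n_swaps <- 10L * m
  with_seed_if(seed, {
    res <- rewire_swaps_cpp(idx$edges - 1L, length(idx$nodes),
                            as.integer(n_swaps),
                            rep(FALSE, m), max_prop_factor)
    if (res$n_done < n_swaps) {
      warn(sprintf(
        "Only %d of %d swaps possible within the proposal budget.",
        as.integer(res$n_done), as.integer(n_swaps)))
    }
    edges_from_index(res$edges + 1L, idx$nodes)
  })
}

#' Partially rewired null with a guaranteed edge overlap
#'
#' Freezes a uniform random subset of `ceiling(overlap_fraction * M)` edges
#' and applies degree-preserving double swaps only to the remainder. The
#' result shares at least `overlap_fraction` of its edges with the input, a
#' stringent null that keeps local structure while randomising the rest.
#'
#' @param g A graph as a data frame of edges.
#' @param overlap_fraction Fraction of edges to freeze, in (0, 1\];
#'   `1` returns the input unchanged.
#' @param n_swaps Successful swaps among the free edges (default 10 per free
#'   edge).
#' @param seed Optional RNG seed.
#' @return A canonical edge tibble with attribute `"realized_overlap"`, the
#'   fraction of original edges present in the output.
#' @export
overlapping_null <- function(g, overlap_fraction = 0.3, n_swaps = NULL,
                             seed = NULL) {
  if (overlap_fraction <= 0 || overlap_fraction > 1) {
    abort("`overlap_fraction` must be in (0, 1].")
  }
  e <- as_edge_table(g)
  if (overlap_fraction == 1) {
    attr(e, "realized_overlap") <- 1
    return(e)
  }
  idx <- edge_index(e)
  m <- nrow(idx$edges)
  with_seed_if(seed, {
    n_freeze <- ceiling(overlap_fraction * m)
    frozen <- rep(FALSE, m)
    frozen[sample.int(m, n_freeze)] <- TRUE
    n_free <- m - n_freeze
    if (is.null(n_swaps)) n_swaps <- 10L * n_free
    res <- rewire_swaps_cpp(idx$edges - 1L, length(idx$nodes),
                            as.integer(n_swaps), frozen, 100)
    out <- edges_from_index(res$edges + 1L, idx$nodes)
    key0 <- paste(e$from, e$to)
    key1 <- paste(out$from, out$to)
    attr(out, "realized_overlap") <- mean(key0 %in% key1)
    out
  })
}

#' Random graph preserving the full joint degree matrix
#'
#' Builds a random simple graph whose edge counts between every pair of
#' degree classes equal those of the input exactly. For each degree pair
#' (k1, k2) with target count c, stubs of class k1 are matched at random to
#' stubs of class k2, rejecting self-loops and duplicate edges; a stalled
#' attempt restarts from scratch. Because the joint degree matrix determines
#' the degree-mixing statistics, the seed network has (up to noise-free
#' exactness) the same assortativity as the input.
#'
#' @param g A graph as a data frame of edges.
#' @param seed Optional RNG seed.
#' @param max_restarts Full restarts before giving up.
#' @return A canonical edge tibble with the same joint degree matrix as `g`.
#' @export
joint_degree_seed <- function(g, seed = NULL, max_restarts = 50) {
  idx <- edge_index(g)
  nodes <- idx$nodes
  n <- length(nodes)
  deg <- tabulate(c(idx$edges), nbins = n)
  k1 <- pmin(deg[idx$edges[, 1]], deg[idx$edges[, 2]])
  k2 <- pmax(deg[idx$edges[, 1]], deg[idx$edges[, 2]])
  # target counts per degree pair, hardest (largest degrees) first
  tgt <- tibble(k1 = k1, k2 = k2) %>%
    count(.data$k1, .data$k2, name = "target") %>%
    arrange(-pmax(.data$k1, .data$k2), -pmin(.data$k1, .data$k2))
  with_seed_if(seed, {
    for (attempt in seq_len(max_restarts)) {
      res <- try_seed_once(tgt, deg, n)
      if (!is.null(res)) {
        return(edges_from_index(res, nodes))
      }
    }
    abort(sprintf(
      "joint_degree_seed stalled after %d restarts (%d nodes, %d edges).",
      max_restarts, n, nrow(idx$edges)))
  })
}

# one full attempt at the joint-degree-preserving seed; NULL on stall
try_seed_once <- function(tgt, deg, n) {
  pools <- split(rep.int(seq_len(n), deg), rep.int(deg, deg))
  acc <- new.env(hash = TRUE, parent = emptyenv())
  E <- matrix(0L, sum(tgt$target), 2)
  row <- 0L
  for (t in seq_len(nrow(tgt))) {
    ka <- tgt$k1[t]; kb <- tgt$k2[t]; need <- tgt$target[t]
    pa <- as.character(ka); pb <- as.character(kb)
    placed <- 0L
    stall <- 0L
    budget <- 200L * need + 200L
    while (placed < need) {
      pool_a <- pools[[pa]]
      pool_b <- pools[[pb]]
      if (ka == kb) {
        if (length(pool_a) < 2) return(NULL)
        pick <- sample.int(length(pool_a), 2)
        u <- pool_a[pick[1]]; v <- pool_a[pick[2]]
      } else {
        if (length(pool_a) < 1 || length(pool_b) < 1) return(NULL)
        u <- pool_a[sample.int(length(pool_a), 1)]
        v <- pool_b[sample.int(length(pool_b), 1)]
      }
      key <- paste(min(u, v), max(u, v))
      if (u == v || !is.null(acc[[key]])) {
        stall <- stall + 1L
        if (stall > budget) return(NULL)
        next
      }
      acc[[key]] <- TRUE
      row <- row + 1L
      E[row, ] <- c(u, v)
      placed <- placed + 1L
      if (ka == kb) {
        pools[[pa]] <- pool_a[-pick]
      } else {
        pools[[pa]] <- pool_a[-match(u, pool_a)]
        pools[[pb]] <- pool_b[-match(v, pool_b)]
      }
    }
  }
  E
}
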