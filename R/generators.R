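#' Deterministic hierarchical network model
#'
#' Recursive construction that reconciles a scale-free degree distribution
#' with declining C(k). Level 1 is a five-clique (one centre, four peripheral
#' nodes). At each later level the current module is replicated four times and
#' every bottom-level peripheral node of the replicas gains an edge to the
#' root centre, giving 5^levels nodes and edge counts satisfying
#' E(L) = 5 E(L-1) + 4^L with E(1) = 10.
#'
#' @param levels Number of construction levels (1 gives K5; at most 7, a size
#'   guard: level 7 already has 78,125 nodes).
#' @return A canonical edge tibble. Node ids are zero-padded integers prefixed
#'   with `"h"`; the root centre is always the lexicographically first node.
#' @examples
#' nrow(hierarchical_model(2)) # 66 edges on 25 nodes
#' @export
hierarchical_model <- function(levels) {
  if (!is.numeric(levels) || length(levels) != 1 || levels < 1 ||
      levels != round(levels)) {
    abort("`levels` must be a positive integer.")
  }
  if (levels > 7) abort("`levels` > 7 rejected (size guard: 5^8 nodes).")
  edges <- t(combn(0:4, 2))
  periph <- 1:4
  if (levels >= 2) {
    for (L in 2:levels) {
      size <- 5^(L - 1)
      copies <- do.call(rbind, lapply(0:4, function(i) edges + i * size))
      periph <- unlist(lapply(1:4, function(i) periph + i * size))
      edges <- rbind(copies, cbind(periph, 0L))
    }
  }
  width <- nchar(as.character(5^levels - 1))
  ids <- sprintf("h%0*d", width, 0:(5^levels - 1))
  edges_from_index(edges + 1L, ids)
}

#' Sample a power-law degree sequence
#'
#' Draws n degrees from the normalised discrete distribution P(k) proportional
#' to k^-gamma on \[kmin, kmax\]. The default upper cutoff is the structural
#' cutoff floor(sqrt(n * kmin)), below which a configuration-model graph is
#' uncorrelated; super-hubs injected later deliberately exceed it. The sum of
#' degrees is forced even by redrawing one entry.
#'
#' @param n Number of nodes.
#' @param gamma Power-law exponent (> 1).
#' @param kmin,kmax Degree support bounds; `kmax = NULL` uses the structural
#'   cutoff.
#' @param seed Optional RNG seed (`NULL` uses the current RNG stream).
#' @return An integer vector of length n with an even sum.
#' @export
sample_powerlaw_degrees <- function(n, gamma, kmin = 1, kmax = NULL,
                                    seed = NULL) {
  if (gamma <= 1) abort("`gamma` must exceed 1.")
  if (is.null(kmax)) kmax <- max(kmin, floor(sqrt(n * kmin)))
  if (kmin < 1 || kmax < kmin || kmax > n - 1) {
    abort("Need 1 <= kmin <= kmax <= n - 1.")
  }
  with_seed_if(seed, {
    ks <- kmin:kmax
    if (length(ks) == 1) {
      # degenerate support: every degree equals ks, so redrawing cannot fix an
      # odd total
      if ((ks * n) %% 2 != 0) abort("Odd degree sum with single-value support.")
      return(rep(as.integer(ks), n))
    }
    p <- ks^(-gamma)
    d <- sample(ks, n, replace = TRUE, prob = p)
    while (sum(d) %% 2 != 0) {
      d[sample.int(n, 1)] <- sample(ks, 1, prob = p)
    }
    as.integer(d)
  })
}

#' Realise a degree sequence as a random simple graph (configuration model)
#'
#' Stub matching with rejection of self-loops and multi-edges: all stubs are
#' shuffled and paired; violating pairs are re-pooled and re-shuffled for
#' another round. Stubs still unmatchable after `max_rounds` rounds are
#' dropped with a warning, so the realised degree of at least 99 percent of
#' nodes equals the requested degree in practice.
#'
#' @param degrees Integer degree sequence with an even sum; must be graphical
#'   (Erdos-Gallai).
#' @param seed Optional RNG seed.
#' @param max_rounds Re-shuffling rounds before giving up on leftovers.
#' @return A canonical edge tibble on nodes `"n<index>"` (zero-padded).
#' @examples
#' configuration_graph(c(2, 2, 2), seed = 1) # the only simple realisation: K3
#' @export
configuration_graph <- function(degrees, seed = NULL, max_rounds = 80) {
  degrees <- as.integer(degrees)
  n <- length(degrees)
  if (sum(degrees) %% 2 != 0) abort("Degree sum must be even.")
  if (!is_graphical(degrees)) abort("Degree sequence is not graphical.")
  with_seed_if(seed, {
    stubs <- rep.int(seq_len(n), degrees)
    acc <- new.env(hash = TRUE, parent = emptyenv())
    E <- vector("list", max_rounds)
    pool <- sample(stubs)
    for (round in seq_len(max_rounds)) {
      m <- length(pool) %/% 2
      if (m == 0) break
      a <- pool[seq_len(m) * 2 - 1]
      b <- pool[seq_len(m) * 2]
      lo <- pmin(a, b); hi <- pmax(a, b)
      key <- paste(lo, hi)
      seen <- vapply(key, function(k) !is.null(acc[[k]]), logical(1))
      bad <- (lo == hi) | duplicated(key) | seen
      ok <- which(!bad)
      for (k in key[ok]) acc[[k]] <- TRUE
      E[[round]] <- cbind(lo[ok], hi[ok])
      leftover <- if (length(pool) %% 2 == 1) pool[length(pool)] else integer(0)
      pool <- c(a[bad], b[bad], leftover)
      if (length(pool) >= 2) pool <- sample(pool)
    }
    if (length(pool) > 0) {
      warn(sprintf("Dropped %d unmatchable stub(s) on %d node(s).",
                   length(pool), length(unique(pool))))
    }
    mat <- do.call(rbind, E[!vapply(E, is.null, logical(1))])
    width <- nchar(as.character(n))
    edges_from_index(mat, sprintf("n%0*d", width, seq_len(n)))
  })
}

# Erdos-Gallai graphicality test
is_graphical <- function(degrees) {
  d <- sort(as.integer(degrees), decreasing = TRUE)
  n <- length(d)
  if (any(d < 0) || (n > 0 && d[1] > n - 1)) return(FALSE)
  if (sum(d) %% 2 != 0) return(FALSE)
  csum <- cumsum(d)
  for (r in seq_len(n)) {
    rhs <- r * (r - 1) + sum(pmin(d[seq_len(n - r) + r], r))
    if (csum[r] > rhs) return(FALSE)
  }
  TRUE
}

#' Inject super-hubs by preferential attachment
#'
#' Adds one new node per requested degree d, wired to d distinct existing
#' nodes sampled without replacement with probability proportional to degree.
#' Attachment weights are frozen at the degrees seen when that hub's placement
#' starts (they are not updated edge by edge), and hubs injected earlier are
#' candidates for later hubs. Existing edges are never touched, so the edge
#' count grows by exactly `sum(hub_degrees)`.
#'
#' @param g A graph as a data frame of edges.
#' @param hub_degrees Integer vector; one hub is created per entry.
#' @param seed Optional RNG seed.
#' @param hub_prefix Prefix for the new node ids.
#' @return A canonical edge tibble with attribute `"injected"` holding the ids
#'   of the new nodes (also retrievable with [injected_nodes()]).
#' @export
inject_superhubs <- function(g, hub_degrees, seed = NULL,
                             hub_prefix = "superhub") {
  e <- as_edge_table(g)
  hub_degrees <- as.integer(hub_degrees)
  if (length(hub_degrees) == 0) {
    attr(e, "injected") <- character(0)
    return(e)
  }
  with_seed_if(seed, {
    from <- e$from; to <- e$to
    hubs <- character(length(hub_degrees))
    for (i in seq_along(hub_degrees)) {
      d <- hub_degrees[i]
      ends <- c(from, to)
      tab <- table(ends)
      cand <- names(tab)
      if (d > length(cand)) {
        abort(sprintf("Requested hub degree %d exceeds node count %d.",
                      d, length(cand)))
      }
      hub <- sprintf("%s_%d", hub_prefix, i)
      while (hub %in% cand) hub <- paste0(hub, "x")
      targets <- sample(cand, d, prob = as.numeric(tab), replace = FALSE)
      from <- c(from, pmin(hub, targets))
      to <- c(to, pmax(hub, targets))
      hubs[i] <- hub
    }
    out <- as_edge_table(tibble(from = from, to = to))
    attr(out, "injected") <- hubs
    out
  })
}

#' Ids of nodes added by [inject_superhubs()]
#'
#' @param g An edge tibble returned by [inject_superhubs()].
#' @return Character vector of injected node ids (empty if none recorded).
#' @export
injected_nodes <- function(g) {
  ids <- attr(g, "injected")
  if (is.null(ids)) character(0) else ids
}

#' Spoke-model graph
#'
#' A heuristic topology in which hubs connect only to their own low-degree
#' leaves and are joined indirectly through shared bridge nodes: no edge ever
#' joins two hubs, which makes the graph disassortative by construction.
#'
#' @param n_hubs Number of hubs.
#' @param leaves_per_hub Leaves attached to each hub.
#' @param n_bridges Number of degree-2 bridge nodes, each connected to two
#'   distinct random hubs (or to the single hub if `n_hubs == 1`).
#' @param seed Optional RNG seed.
#' @return A canonical edge tibble. Hubs are named `hub_*`, leaves `leaf_*`,
#'   bridges `bridge_*`.
#' @export
spoke_graph <- function(n_hubs, leaves_per_hub, n_bridges = 0, seed = NULL) {
  if (n_hubs < 1 || leaves_per_hub < 1 || n_bridges < 0) {
    abort("`n_hubs` and `leaves_per_hub` must be positive; `n_bridges` >= 0.")
  }
  with_seed_if(seed, {
    hubs <- sprintf("hub_%03d", seq_len(n_hubs))
    from <- character(0); to <- character(0)
    for (h in seq_len(n_hubs)) {
      leaves <- sprintf("leaf_%03d_%03d", h, seq_len(leaves_per_hub))
      from <- c(from, rep(hubs[h], leaves_per_hub))
      to <- c(to, leaves)
    }
    if (n_bridges > 0) {
      for (b in seq_len(n_bridges)) {
        bid <- sprintf("bridge_%03d", b)
        tgt <- if (n_hubs == 1) hubs else sample(hubs, 2)
        from <- c(from, rep(bid, length(tgt)))
        to <- c(to, tgt)
      }
    }
    as_edge_table(tibble(from = from, to = to))
  })
}

# run expr under a temporary seed when one is given
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
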