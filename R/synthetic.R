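#' Synthetic metabolic-like graph: power-law bulk plus super-hubs
#'
#' A configuration-model graph with degrees drawn from P(k) ~ k^-gamma up to
#' the structural cutoff, plus a few preferential-attachment super-hubs far
#' above the cutoff - the degree structure that makes C(k) of metabolic
#' networks decline as 1/k. With `superhub_degrees = integer(0)` this is a
#' plain configuration graph.
#'
#' @param n Number of bulk nodes.
#' @param gamma Power-law exponent.
#' @param superhub_degrees Degrees of injected hubs (possibly empty).
#' @param seed Optional RNG seed (drives degree sampling, matching, and
#'   injection).
#' @param kmin,kmax Degree support (see [sample_powerlaw_degrees()]).
#' @return A canonical edge tibble; injected hub ids in attribute
#'   `"injected"`.
#' @export
synth_metabolic_like <- function(n, gamma = 2.6, superhub_degrees = integer(0),
                                 seed = NULL, kmin = 1, kmax = NULL) {
  with_seed_if(seed, {
    degs <- sample_powerlaw_degrees(n, gamma, kmin = kmin, kmax = kmax)
    g <- suppressWarnings(configuration_graph(degs))
    inject_superhubs(g, superhub_degrees)
  })
}

#' Synthetic graph with a target degree assortativity
#'
#' Starts from an uncorrelated configuration-model graph and applies greedy
#' double-edge swaps accepted only when they move the assortativity
#' coefficient toward `target_r`, stopping within `tol` of the target or when
#' the proposal budget runs out. Degree-preserving swaps leave every node's
#' degree untouched, so only the mixing changes. Negative targets emulate the
#' hub repulsion of protein and genetic networks; positive targets emulate the
#' hub affinity of co-expression networks.
#'
#' @param n Number of nodes.
#' @param gamma Power-law exponent of the degree distribution.
#' @param target_r Target assortativity in (-1, 1).
#' @param seed Optional RNG seed.
#' @param tol Stop once `|r - target_r| <= tol`.
#' @param max_proposals Proposal budget (default 200 per edge).
#' @param kmin Minimum degree (default 2 keeps r estimable and the graph
#'   connected enough for profile work).
#' @return A canonical edge tibble; attribute `"assortativity"` holds the
#'   achieved r.
#' @export
synth_correlated_graph <- function(n, gamma = 2.6, target_r = -0.15,
                                   seed = NULL, tol = 0.02,
                                   max_proposals = NULL, kmin = 2) {
  with_seed_if(seed, {
    degs <- sample_powerlaw_degrees(n, gamma, kmin = kmin)
    g <- suppressWarnings(configuration_graph(degs))
    idx <- edge_index(g)
    E <- idx$edges
    m <- nrow(E)
    if (is.null(max_proposals)) max_proposals <- 200L * m
    deg <- tabulate(c(E), nbins = length(idx$nodes))
    # r depends on edge data only through sum(ka * kb); track it incrementally
    ka <- deg[E[, 1]]; kb <- deg[E[, 2]]
    mx <- mean(c(ka, kb)); vx <- stats::var(c(ka, kb)) * (2 * m - 1) / (2 * m)
    s_prod <- sum(ka * kb)
    r_of <- function(s) (s / m - mx^2) / vx
    acc <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(m)) acc[[paste(E[i, 1], E[i, 2])]] <- TRUE
    r_cur <- r_of(s_prod)
    p <- 0L
    while (abs(r_cur - target_r) > tol && p < max_proposals) {
      p <- p + 1L
      ij <- sample.int(m, 2)
      a <- E[ij[1], 1]; b <- E[ij[1], 2]
      c_ <- E[ij[2], 1]; d <- E[ij[2], 2]
      if (runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      if (a == d || c_ == b) next
      k1 <- paste(min(a, d), max(a, d)); k2 <- paste(min(c_, b), max(c_, b))
      if (k1 == k2 || !is.null(acc[[k1]]) || !is.null(acc[[k2]])) next
      ds <- deg[a] * deg[d] + deg[c_] * deg[b] -
        deg[a] * deg[b] - deg[c_] * deg[d]
      r_new <- r_of(s_prod + ds)
      if (abs(r_new - target_r) < abs(r_cur - target_r)) {
        rm(list = c(paste(E[ij[1], 1], E[ij[1], 2]),
                    paste(E[ij[2], 1], E[ij[2], 2])), envir = acc)
        E[ij[1], ] <- c(min(a, d), max(a, d))
        E[ij[2], ] <- c(min(c_, b), max(c_, b))
        acc[[k1]] <- TRUE; acc[[k2]] <- TRUE
        s_prod <- s_prod + ds
        r_cur <- r_new
      }
    }
    out <- edges_from_index(E, idx$nodes)
    attr(out, "assortativity") <- r_cur
    out
  })
}

#' Synthetic modular (planted-partition) graph
#'
#' Equal-sized modules with independent within-module edge probability `p_in`
#' and between-module probability `p_out`. With `p_in >> p_out` the triangle
#' count far exceeds any degree-matched random counterpart, emulating the
#' elevated modularity of biological networks.
#'
#' @param n_modules Number of modules.
#' @param module_size Nodes per module.
#' @param p_in,p_out Edge probabilities within/between modules.
#' @param seed Optional RNG seed.
#' @return A canonical edge tibble; attribute `"module"` is a named vector
#'   mapping node id to module index.
#' @export
synth_modular <- function(n_modules, module_size, p_in, p_out, seed = NULL) {
  if (n_modules < 1 || module_size < 2) abort("Need modules of >= 2 nodes.")
  with_seed_if(seed, {
    n <- n_modules * module_size
    module <- rep(seq_len(n_modules), each = module_size)
    width <- nchar(as.character(n))
    ids <- sprintf("m%0*d", width, seq_len(n))
    pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- module[pair[, 1]] == module[pair[, 2]]
    p <- ifelse(same, p_in, p_out)
    on <- runif(nrow(pair)) < p
    out <- as_edge_table(tibble(from = ids[pair[on, 1]],
                                to = ids[pair[on, 2]]))
    attr(out, "module") <- setNames(module, ids)
    out
  })
}

#' Synthetic block-correlated expression matrix with missing entries
#'
#' Genes are split round-robin into modules; each module shares a latent
#' per-array factor and each value is
#' `sqrt(rho_in) * factor + sqrt(1 - rho_in) * noise`, the simplest mechanism
#' giving a target pairwise within-module correlation of `rho_in` and zero
#' between modules. Entries are then masked missing independently.
#'
#' @param n_genes,n_arrays Matrix dimensions.
#' @param n_modules Number of co-expression modules.
#' @param rho_in Target within-module pairwise correlation in \[0, 1).
#' @param missing_rate Independent missingness probability per entry.
#' @param seed Optional RNG seed.
#' @return An expression tibble (`gene` + array columns); attribute
#'   `"module"` maps gene id to module index.
#' @export
synth_expression <- function(n_genes, n_arrays, n_modules = 3, rho_in = 0.7,
                             missing_rate = 0.02, seed = NULL) {
  if (rho_in < 0 || rho_in >= 1) abort("`rho_in` must be in [0, 1).")
  with_seed_if(seed, {
    module <- rep_len(seq_len(n_modules), n_genes)
    f <- matrix(rnorm(n_modules * n_arrays), n_modules, n_arrays)
    noise <- matrix(rnorm(n_genes * n_arrays), n_genes, n_arrays)
    x <- sqrt(rho_in) * f[module, , drop = FALSE] +
      sqrt(1 - rho_in) * noise
    mask <- matrix(runif(n_genes * n_arrays) < missing_rate,
                   n_genes, n_arrays)
    x[mask] <- NA
    genes <- sprintf("g%0*d", nchar(as.character(n_genes)), seq_len(n_genes))
    arrays <- sprintf("A%0*d", nchar(as.character(n_arrays)),
                      seq_len(n_arrays))
    out <- as_tibble(as.data.frame(x))
    names(out) <- arrays
    out <- dplyr::bind_cols(tibble(gene = genes), out)
    attr(out, "module") <- setNames(module, genes)
    out
  })
}
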