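#' Joint degree matrix of a graph
#'
#' Tallies, for every unordered pair of endpoint degrees (k1, k2), how many
#' edges join a degree-k1 node to a degree-k2 node. The normalised column
#' `prob` is the joint probability P(k1, k2) of finding a link between nodes
#' of those degrees; counts sum to the edge count M and probabilities to 1.
#' Raw degree pairs are sparse in graphs of 10^3-10^4 nodes, so an optional
#' base-2 logarithmic binning is available for presentation and profiles; the
#' exact-degree matrix is what the null models preserve.
#'
#' @param g A graph as a data frame of edges.
#' @param bins `NULL` for exact degrees or `"log2"` for base-2 logarithmic
#'   degree bins.
#' @return A tibble with columns `k1`, `k2` (`k1 <= k2`; bin lower edges when
#'   binned, plus `k_hi1`, `k_hi2` upper edges), `count` and `prob`.
#' @export
joint_degree_matrix <- function(g, bins = NULL) {
  e <- as_edge_table(g)
  if (nrow(e) == 0) abort("Graph has no edges.")
  d <- node_degrees(e)
  ka <- d$degree[match(e$from, d$node)]
  kb <- d$degree[match(e$to, d$node)]
  if (is.null(bins)) {
    out <- tibble(k1 = pmin(ka, kb), k2 = pmax(ka, kb)) %>%
      count(.data$k1, .data$k2, name = "count")
  } else {
    if (!identical(bins, "log2")) abort('`bins` must be NULL or "log2".')
    ba <- log2_bin(ka); bb <- log2_bin(kb)
    out <- tibble(b1 = pmin(ba, bb), b2 = pmax(ba, bb)) %>%
      count(.data$b1, .data$b2, name = "count") %>%
      mutate(k1 = 2^.data$b1, k_hi1 = 2^(.data$b1 + 1) - 1,
             k2 = 2^.data$b2, k_hi2 = 2^(.data$b2 + 1) - 1) %>%
      dplyr::select("k1", "k_hi1", "k2", "k_hi2", "count")
  }
  out <- mutate(out, prob = .data$count / sum(.data$count)) %>%
    arrange(.data$k1, .data$k2)
  attr(out, "n_edges") <- nrow(e)
  out
}

log2_bin <- function(k) floor(log2(k))

# binned joint-degree counts as a named vector over given pair keys
jdm_bin_counts <- function(deg_a, deg_b, keys) {
  ba <- log2_bin(deg_a); bb <- log2_bin(deg_b)
  key <- paste(pmin(ba, bb), pmax(ba, bb), sep = "|")
  tab <- table(factor(key, levels = keys))
  as.numeric(tab)
}

#' Correlation profile against a degree-preserving ensemble
#'
#' Compares the binned joint degree statistics of a graph with those of an
#' ensemble of degree-preserving rewired nulls: `ratio` is the observed count
#' over the ensemble mean (hub-hub repulsion shows as ratio < 1 in the
#' high-degree corner, hub affinity as ratio > 1) and `z` is the deviation in
#' ensemble standard deviations. Bins whose ensemble mean is zero are masked
#' (`NA` ratio).
#'
#' @param g A graph as a data frame of edges.
#' @param n_random Ensemble size (>= 2); 100 gives stable profiles.
#' @param seed Optional RNG seed.
#' @param swaps_per_edge Double-edge swaps per edge for each null.
#' @return A tibble of class `"correlation_profile"` with one row per base-2
#'   degree-bin pair: bin edges, `obs`, `null_mean`, `null_sd`, `ratio`, `z`.
#' @export
correlation_profile <- function(g, n_random = 100, seed = NULL,
                                swaps_per_edge = 10) {
  if (n_random < 2) abort("`n_random` must be at least 2.")
  e <- as_edge_table(g)
  idx <- edge_index(e)
  n <- length(idx$nodes)
  deg <- tabulate(c(idx$edges), nbins = n)
  m <- nrow(idx$edges)
  bins <- sort(unique(log2_bin(deg)))
  pairs <- expand.grid(b1 = bins, b2 = bins)
  pairs <- pairs[pairs$b1 <= pairs$b2, , drop = FALSE]
  keys <- paste(pairs$b1, pairs$b2, sep = "|")
  obs <- jdm_bin_counts(deg[idx$edges[, 1]], deg[idx$edges[, 2]], keys)
  with_seed_if(seed, {
    ens <- matrix(0, n_random, length(keys))
    for (r in seq_len(n_random)) {
      res <- rewire_swaps_cpp(idx$edges - 1L, n,
                              as.integer(swaps_per_edge * m),
                              rep(FALSE, m), 100)
      em <- res$edges + 1L
      ens[r, ] <- jdm_bin_counts(deg[em[, 1]], deg[em[, 2]], keys)
    }
    mu <- colMeans(ens)
    sdev <- apply(ens, 2, sd)
    out <- tibble(
      b1 = pairs$b1, b2 = pairs$b2,
      k_lo1 = 2^pairs$b1, k_hi1 = 2^(pairs$b1 + 1) - 1,
      k_lo2 = 2^pairs$b2, k_hi2 = 2^(pairs$b2 + 1) - 1,
      obs = obs, null_mean = mu, null_sd = sdev,
      ratio = ifelse(mu > 0, obs / mu, NA_real_),
      z = ifelse(sdev > 0, (obs - mu) / sdev, NA_real_)
    )
    out <- out[obs > 0 | mu > 0, ]
    attr(out, "n_random") <- n_random
    class(out) <- c("correlation_profile", class(out))
    out
  })
}

#' @rdname correlation_profile
#' @param object A `correlation_profile`.
#' @param ... Unused.
#' @export
autoplot.correlation_profile <- function(object, ...) {
  df <- as_tibble(object)
  df2 <- df[df$b1 != df$b2, ]
  df2 <- tibble(b1 = df2$b2, b2 = df2$b1, ratio = df2$ratio)
  full <- bind_rows(df[, c("b1", "b2", "ratio")], df2)
  ggplot2::ggplot(full, ggplot2::aes(x = factor(2^.data$b1),
                                     y = factor(2^.data$b2),
                                     fill = log2(.data$ratio))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkblue", mid = "white",
                                  high = "darkred", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::labs(x = "degree bin (lower edge)", y = "degree bin (lower edge)",
                  fill = "log2 P/Pr", title = "Correlation profile") +
    ggplot2::theme_minimal()
}

#' C(k) with a degree-preserving null envelope
#'
#' Computes the C(k) spectrum of a graph together with the per-degree mean and
#' quantile band of an ensemble of degree-preserving rewired nulls, and flags
#' degrees where the real curve exits the band. Because rewiring preserves the
#' degree sequence exactly, every ensemble member has the same set of degrees.
#'
#' @param g A graph as a data frame of edges.
#' @param n_random Ensemble size (>= 2).
#' @param seed Optional RNG seed.
#' @param probs Lower/upper band quantiles (default 5-95 percent).
#' @param swaps_per_edge Double-edge swaps per edge for each null.
#' @return A tibble of class `"ck_envelope"`: `degree`, `n_nodes`, `c_real`,
#'   `c_null_mean`, `band_lo`, `band_hi`, `outside`.
#' @export
ck_envelope <- function(g, n_random = 20, seed = NULL,
                        probs = c(0.05, 0.95), swaps_per_edge = 10) {
  if (n_random < 2) abort("`n_random` must be at least 2.")
  e <- as_edge_table(g)
  idx <- edge_index(e)
  n <- length(idx$nodes)
  m <- nrow(idx$edges)
  real <- ck_spectrum(e)
  with_seed_if(seed, {
    mats <- matrix(NA_real_, n_random, nrow(real))
    for (r in seq_len(n_random)) {
      res <- rewire_swaps_cpp(idx$edges - 1L, n,
                              as.integer(swaps_per_edge * m),
                              rep(FALSE, m), 100)
      sp <- ck_spectrum(edges_from_index(res$edges + 1L, idx$nodes))
      mats[r, ] <- sp$c_mean[match(real$degree, sp$degree)]
    }
    out <- mutate(
      real,
      c_real = .data$c_mean,
      c_null_mean = colMeans(mats),
      band_lo = apply(mats, 2, quantile, probs = probs[1], names = FALSE),
      band_hi = apply(mats, 2, quantile, probs = probs[2], names = FALSE),
      outside = .data$c_real < .data$band_lo | .data$c_real > .data$band_hi
    ) %>%
      dplyr::select("degree", "n_nodes", "c_real", "c_null_mean",
                    "band_lo", "band_hi", "outside")
    attr(out, "n_random") <- n_random
    class(out) <- c("ck_envelope", class(out))
    out
  })
}

#' @rdname ck_envelope
#' @param object A `ck_envelope`.
#' @param ... Unused.
#' @export
autoplot.ck_envelope <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$band_lo, 1e-6),
                                      ymax = pmax(.data$band_hi, 1e-6)),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = pmax(.data$c_null_mean, 1e-6)),
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = pmax(.data$c_real, 1e-6)),
                        colour = "forestgreen") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "C(k)",
                  title = "C(k) against degree-preserving null envelope") +
    ggplot2::theme_minimal()
}

#' Flag super-hubs against a fitted power-law degree distribution
#'
#' Fits the power-law exponent of the bulk of a degree histogram (degrees
#' within `fit_range`, by default from the minimum degree up to the structural
#' cutoff `sqrt(n * kmin)`) by ordinary least squares on the log-log
#' complementary cumulative distribution, whose slope is `1 - gamma`. The
#' CCDF is monotone and far less sensitive to empty or single-count degrees
#' than the raw histogram. The fitted law is then normalised and observed
#' degrees above the cutoff are flagged when the expected number of nodes at
#' or beyond that degree, `n * P(K >= k)`, falls below `alpha` - degrees one
#' should essentially never see in a sample of this size if the bulk law
#' extended to the tail, the signature of super-hubs such as currency
#' metabolites.
#'
#' The test is a tail-probability heuristic intended to make a visual judgment
#' reproducible; `alpha` and the fit range are deliberately exposed.
#'
#' @param hist A degree histogram as returned by [degree_histogram()] (columns
#'   `degree`, `count`), with at least 10 distinct degrees.
#' @param fit_range Length-2 numeric range of degrees used for the slope fit;
#'   `NULL` for `c(kmin, k_cutoff)`.
#' @param alpha Expected-count threshold below which a degree is flagged.
#' @param k_cutoff Structural cutoff separating bulk from tail; `NULL` for
#'   `floor(sqrt(n * kmin))`.
#' @return A tibble of tail degrees (`degree > k_cutoff`) with columns
#'   `degree`, `count`, `expected_n_ge` and `flagged`; attributes `gamma_hat`
#'   and `k_cutoff`. Zero rows means no candidate super-hubs.
#' @export
detect_superhubs <- function(hist, fit_range = NULL, alpha = 0.05,
                             k_cutoff = NULL) {
  if (!all(c("degree", "count") %in% names(hist))) {
    abort("`hist` needs columns `degree` and `count`.")
  }
  if (nrow(hist) < 10) {
    abort("Too few distinct degrees (< 10) to fit a power law.")
  }
  n <- sum(hist$count)
  kmin <- min(hist$degree)
  if (is.null(k_cutoff)) k_cutoff <- max(kmin + 1, floor(sqrt(n * kmin)))
  if (is.null(fit_range)) fit_range <- c(kmin, k_cutoff)
  hist <- arrange(as_tibble(hist), .data$degree)
  ccdf <- rev(cumsum(rev(hist$count))) / n
  in_range <- hist$degree >= fit_range[1] & hist$degree <= fit_range[2] &
    ccdf > 0
  if (sum(in_range) < 3) abort("Fewer than 3 usable degrees in the fit range.")
  fit <- lm(ly ~ lk, data = data.frame(lk = log10(hist$degree[in_range]),
                                       ly = log10(ccdf[in_range])))
  gamma_hat <- 1 - unname(coef(fit)[2])
  tail_deg <- hist[hist$degree > k_cutoff, ]
  expected <- vapply(tail_deg$degree, function(k) {
    n * powerlaw_tail_prob(k, gamma_hat, kmin)
  }, numeric(1))
  out <- tibble(degree = tail_deg$degree, count = tail_deg$count,
                expected_n_ge = expected,
                flagged = expected < alpha)
  attr(out, "gamma_hat") <- gamma_hat
  attr(out, "k_cutoff") <- k_cutoff
  out
}

# P(K >= k) under a discrete power law k^-gamma normalised on [kmin, Inf):
# finite sums plus an integral remainder for the far tail.
powerlaw_tail_prob <- function(k, gamma, kmin) {
  if (gamma <= 1) return(1)
  Jk <- ceiling(max(k, kmin)) + 2000
  tail_from <- function(a) {
    js <- seq(from = a, to = Jk)
    sum(js^(-gamma)) + (Jk + 0.5)^(1 - gamma) / (gamma - 1)
  }
  tail_from(k) / tail_from(kmin)
}
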