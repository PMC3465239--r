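#' Summary context for triangle-expectation theory
#'
#' Collects the network summaries the closed-form theory needs: node count S,
#' edge count M, mean degree and mean clustering coefficient. Either derive it
#' from a graph or supply the numbers directly (e.g. values printed for a
#' network you do not hold).
#'
#' @param g Optional graph as a data frame of edges.
#' @param S,M,k_mean,c_bar Manual values; `k_mean` defaults to `2 * M / S`.
#' @return An object of class `"theory_context"`.
#' @examples
#' theory_context(S = 778, M = 2409, c_bar = 0.21)
#' @export
theory_context <- function(g = NULL, S = NULL, M = NULL, k_mean = NULL,
                           c_bar = NULL) {
  if (!is.null(g)) {
    d <- node_degrees(g)
    S <- nrow(d)
    M <- sum(d$degree) / 2
    k_mean <- 2 * M / S
    c_bar <- mean_clustering(g)
  } else {
    if (is.null(S) || is.null(M)) abort("Supply a graph or both S and M.")
    if (is.null(k_mean)) k_mean <- 2 * M / S
    if (is.null(c_bar)) c_bar <- 0
  }
  if (M <= 0) abort("M must be positive.")
  structure(list(S = S, M = M, k_mean = k_mean, c_bar = c_bar),
            class = "theory_context")
}

#' @export
print.theory_context <- function(x, ...) {
  cat(sprintf("<theory_context> S = %g, M = %g, <k> = %.3f, C-bar = %.4f\n",
              x$S, x$M, x$k_mean, x$c_bar))
  invisible(x)
}

#' Probability that a new node attaches to a given node
#'
#' Under degree-proportional (preferential) attachment, a single new edge
#' lands on a node of degree k_i with probability k_i / 2M.
#'
#' @param k_i Degree (vectorised).
#' @param ctx A [theory_context()].
#' @return Probabilities in \[0, 1\].
#' @export
attach_probability <- function(k_i, ctx) {
  stopifnot(inherits(ctx, "theory_context"))
  if (any(k_i < 0)) abort("Degrees must be non-negative.")
  k_i / (2 * ctx$M)
}

#' Expected edge multiplicity between two nodes in a simple graph
#'
#' A new node of degree k_j places on a node of degree k_i an expected
#' `min(k_j * k_i / 2M, 1)` edges: the cap encodes that a simple graph allows
#' at most one edge per node pair, which is precisely what suppresses hub-hub
#' connections.
#'
#' @param k_i,k_j Degrees (vectorised).
#' @inheritParams attach_probability
#' @return Values in \[0, 1\].
#' @export
edge_multiplicity <- function(k_i, k_j, ctx) {
  stopifnot(inherits(ctx, "theory_context"))
  pmin(k_i * k_j / (2 * ctx$M), 1)
}

#' Expected triangles a newly attached node adds through an existing node
#'
#' For an uncorrelated network the neighbours of node i have average degree
#' <k>, so a new node j creates about
#' `k_i * m_ij * m_j<k>` triangles through i, where `m_ij` and `m_j<k>` are
#' capped edge multiplicities. Two regimes follow: while `m_ij` is below its
#' cap the count grows like k_i^2 with a degree-independent clustering
#' contribution; once `m_ij` saturates at 1 (k_i >= 2M / k_j) the count grows
#' like k_i and the clustering contribution decays as 1/k.
#'
#' @param k_i Degree of the existing node (vectorised).
#' @param k_j Degree of the newly added node.
#' @inheritParams attach_probability
#' @return Expected newly added triangle counts.
#' @export
expected_new_triangles <- function(k_i, k_j, ctx) {
  stopifnot(inherits(ctx, "theory_context"))
  m_ij <- edge_multiplicity(k_i, k_j, ctx)
  m_jk <- edge_multiplicity(k_j, ctx$k_mean, ctx)
  k_i * m_ij * m_jk
}

#' Predicted clustering coefficient after new attachments
#'
#' `C'(k_i) = c_bar + 2 * delta_n / (k_i * (k_i + 1))`: the baseline mean
#' clustering plus the contribution of `delta_n` newly added triangles, with
#' the node's degree grown by one through the new attachment.
#'
#' @param k_i Degree (vectorised, >= 1).
#' @param delta_n Newly added triangles through the node.
#' @param cbar Baseline mean clustering coefficient.
#' @return Predicted clustering values.
#' @export
predicted_ck <- function(k_i, delta_n, cbar) {
  if (any(k_i < 1)) abort("`k_i` must be at least 1.")
  cbar + 2 * delta_n / (k_i * (k_i + 1))
}

#' Neighbour edges required to sustain a clustering coefficient
#'
#' For a node of degree k to have clustering coefficient `cbar`, its
#' neighbours must share `round(k * (k - 1) * cbar / 2)` edges. For the
#' largest hubs of real networks this quickly exceeds the total edge count,
#' which is why super-hubs necessarily have small clustering.
#'
#' @param k Degree (vectorised, >= 2).
#' @param cbar Clustering coefficient in \[0, 1\].
#' @return Integer edge counts (rounded to nearest).
#' @examples
#' required_neighbor_edges(253, 0.21) # 6694
#' @export
required_neighbor_edges <- function(k, cbar) {
  if (any(k < 2)) abort("`k` must be at least 2.")
  if (any(cbar < 0 | cbar > 1)) abort("`cbar` must be in [0, 1].")
  as.integer(round(k * (k - 1) * cbar / 2))
}

#' Newly added triangles per original node between two nested graphs
#'
#' Counts, for every node of `g_before`, how many more triangles pass through
#' it in `g_after` - the empirical counterpart of
#' [expected_new_triangles()] after super-hub injection. `g_before` must be an
#' edge subset of `g_after`.
#'
#' @param g_before,g_after Graphs as data frames of edges.
#' @return A tibble with one row per node of `g_before`: `node`,
#'   `degree_before`, `delta_n`.
#' @export
measure_delta_triangles <- function(g_before, g_after) {
  eb <- as_edge_table(g_before)
  ea <- as_edge_table(g_after)
  kb <- paste(eb$from, eb$to)
  if (!all(kb %in% paste(ea$from, ea$to))) {
    abort("`g_before` is not an edge subset of `g_after`.")
  }
  nodes_b <- graph_nodes(eb)
  igb <- as_igraph(eb, nodes = nodes_b)
  iga <- as_igraph(ea)
  tb <- setNames(igraph::count_triangles(igb), igraph::V(igb)$name)
  ta <- setNames(igraph::count_triangles(iga), igraph::V(iga)$name)
  degb <- setNames(igraph::degree(igb), igraph::V(igb)$name)
  tibble(node = nodes_b,
         degree_before = as.integer(degb[nodes_b]),
         delta_n = as.integer(ta[nodes_b] - tb[nodes_b])) %>%
    arrange(.data$node)
}

#' Mean newly added triangles per pre-injection degree
#'
#' @param delta A tibble from [measure_delta_triangles()].
#' @return A tibble with `degree`, `dn_mean`, `n_nodes`.
#' @export
delta_triangles_by_degree <- function(delta) {
  delta %>%
    group_by(degree = .data$degree_before) %>%
    summarise(dn_mean = mean(.data$delta_n), n_nodes = n()) %>%
    arrange(.data$degree)
}

#' Ordinary least-squares slope on log-log axes
#'
#' Fits `log10(y) ~ log10(k)` by OLS over points with positive `k` and `y`
#' (zeros cannot be log-transformed and are dropped) and, optionally, a
#' minimum per-point sample size.
#'
#' @param data A data frame whose first two columns are `k` and `y`; an
#'   optional `n_nodes`/`n` column gives per-point sample sizes.
#' @param min_count Keep only points backed by at least this many samples.
#' @return An object of class `"loglog_fit"` with [tidy()] and [glance()]
#'   methods; `glance()` reports `slope`, `std_error`, `r_squared`,
#'   `n_points`.
#' @export
fit_loglog_slope <- function(data, min_count = 1) {
  k <- data[[1]]
  y <- data[[2]]
  w <- if ("n_nodes" %in% names(data)) data$n_nodes else
    if ("n" %in% names(data)) data$n else rep(1, length(k))
  keep <- k > 0 & y > 0 & w >= min_count & is.finite(k) & is.finite(y)
  if (sum(keep) < 3) abort("Need at least 3 positive points to fit a slope.")
  df <- data.frame(lk = log10(k[keep]), ly = log10(y[keep]))
  fit <- lm(ly ~ lk, data = df)
  sm <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    std_error = sm$coefficients[2, 2],
    r_squared = sm$r.squared,
    n_points = nrow(df),
    model = fit
  ), class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("<loglog_fit> slope = %.3f (se %.3f), R^2 = %.3f, %d points\n",
              x$slope, x$std_error, x$r_squared, x$n_points))
  invisible(x)
}

#' @rdname fit_loglog_slope
#' @param x A `loglog_fit`.
#' @param ... Unused.
#' @export
tidy.loglog_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = c(summary(x$model)$coefficients[1, 2], x$std_error))
}

#' @rdname fit_loglog_slope
#' @export
glance.loglog_fit <- function(x, ...) {
  tibble(slope = x$slope, std_error = x$std_error,
         r_squared = x$r_squared, n_points = x$n_points)
}
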