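test_that("theory context derives summaries from a graph or takes them raw", {
  ctx <- theory_context(S = 778, M = 2409, c_bar = 0.21)
  expect_equal(ctx$k_mean, 2 * 2409 / 778)
  expect_equal(ctx$c_bar, 0.21)
  g <- hierarchical_model(2)
  ctx_g <- theory_context(g)
  expect_identical(ctx_g$S, 25L)
  expect_equal(ctx_g$M, 66)
  expect_equal(ctx_g$c_bar, mean_clustering(g))
  expect_error(theory_context(S = 10), "both S and M")
  expect_error(theory_context(S = 10, M = 0), "positive")
})

test_that("attachment probability and edge multiplicity follow k/2M with a cap", {
  ctx <- theory_context(S = 1000, M = 2500)
  expect_equal(attach_probability(c(1, 10, 100), ctx),
               c(1, 10, 100) / 5000)
  expect_error(attach_probability(-1, ctx), "non-negative")
  # cap at one edge per pair: exact at and beyond the boundary
  expect_equal(edge_multiplicity(50, 100, ctx), 1)
  expect_equal(edge_multiplicity(49, 100, ctx), 4900 / 5000)
  expect_equal(edge_multiplicity(1000, 1000, ctx), 1)
  # continuity at the cap boundary
  k_star <- 2 * ctx$M / 100
  eps <- 1e-9
  expect_equal(edge_multiplicity(k_star - eps, 100, ctx),
               edge_multiplicity(k_star + eps, 100, ctx),
               tolerance = 1e-6)
})

test_that("expected new triangles switch from quadratic to linear at k*", {
  ctx <- theory_context(S = 10000, M = 15000, k_mean = 3)
  k_hub <- 2000
  k_star <- 2 * ctx$M / k_hub   # 15
  m_jk <- min(k_hub * 3 / (2 * ctx$M), 1)
  below <- 2:10
  dn_below <- expected_new_triangles(below, k_hub, ctx)
  # quadratic regime: dn / k^2 is constant
  expect_equal(dn_below / below^2,
               rep(k_hub * m_jk / (2 * ctx$M), length(below)))
  above <- seq(20, 200, by = 20)
  dn_above <- expected_new_triangles(above, k_hub, ctx)
  # capped regime: dn / k is constant
  expect_equal(dn_above / above, rep(m_jk, length(above)))
  # a low-degree added node never reaches the cap: quadratic everywhere
  dn_small <- expected_new_triangles(c(5, 50, 500), 20, ctx)
  expect_equal(dn_small / c(5, 50, 500)^2,
               rep(20 * min(20 * 3 / (2 * ctx$M), 1) / (2 * ctx$M), 3))
})

test_that("predicted C(k) adds 2 dn / (k (k+1)) to the baseline", {
  expect_equal(predicted_ck(10, 0, 0.2), 0.2)
  expect_equal(predicted_ck(10, 55, 0), 1)
  expect_equal(predicted_ck(c(2, 4), c(3, 10), 0.1),
               0.1 + 2 * c(3, 10) / (c(2, 4) * c(3, 5)))
  expect_error(predicted_ck(0, 1, 0.1), "at least 1")
})

test_that("required neighbour edges reproduce hand-computed values", {
  expect_identical(required_neighbor_edges(253, 0.21), 6694L)
  expect_identical(required_neighbor_edges(2, 1), 1L)
  expect_identical(required_neighbor_edges(10, 0), 0L)
  expect_identical(required_neighbor_edges(c(3, 4), 0.5),
                   as.integer(round(c(3, 6) * 0.5)))
  expect_error(required_neighbor_edges(1, 0.5), "at least 2")
  expect_error(required_neighbor_edges(5, 1.5), "0, 1")
})

test_that("measured triangle deltas match brute-force recounts", {
  withr::with_seed(111, {
    g <- random_gnp(40, 0.12)
    gi <- inject_superhubs(g, c(8, 5), seed = 112)
    delta <- measure_delta_triangles(g, gi)
    expect_setequal(delta$node, graph_nodes(g))
    tb <- oracle_node_triangles(g)
    ta <- oracle_node_triangles(gi)
    expect_equal(delta$delta_n * 1.0,
                 unname(ta[delta$node] - tb[delta$node]))
    # unchanged graph: all deltas zero
    d0 <- measure_delta_triangles(g, g)
    expect_true(all(d0$delta_n == 0L))
    expect_error(measure_delta_triangles(gi, g), "subset")
  })
})

test_that("delta-by-degree aggregation averages within degree classes", {
  delta <- tibble::tibble(node = c("a", "b", "c", "d"),
                          degree_before = c(2L, 2L, 3L, 3L),
                          delta_n = c(1L, 3L, 10L, 20L))
  agg <- delta_triangles_by_degree(delta)
  expect_identical(agg$degree, c(2L, 3L))
  expect_equal(agg$dn_mean, c(2, 15))
  expect_identical(agg$n_nodes, c(2L, 2L))
})

test_that("log-log slope fit recovers exact and noisy power laws", {
  k <- 1:50
  # suppressWarnings: lm flags exact power-law fixtures as "perfect fit"
  f <- suppressWarnings(fit_loglog_slope(data.frame(k = k, y = 3 * k^-1)))
  expect_equal(f$slope, -1, tolerance = 1e-10)
  expect_equal(f$intercept, log10(3), tolerance = 1e-10)
  expect_equal(f$r_squared, 1)
  f2 <- suppressWarnings(fit_loglog_slope(data.frame(k = k, y = 0.5 * k^2)))
  expect_equal(f2$slope, 2, tolerance = 1e-10)
  withr::with_seed(5, {
    noisy <- 2 * k^-1.5 * exp(rnorm(50, sd = 0.1))
    f3 <- fit_loglog_slope(data.frame(k = k, y = noisy))
    expect_equal(f3$slope, -1.5, tolerance = 0.1 / 1.5)
  })
  # zeros are dropped, min_count filters by support
  dat <- data.frame(k = 1:10, y = c(0, (2:10)^2), n_nodes = c(rep(10, 9), 1))
  f4 <- suppressWarnings(fit_loglog_slope(dat, min_count = 5))
  expect_identical(f4$n_points, 8L)
  expect_error(fit_loglog_slope(data.frame(k = 1:2, y = 1:2)), "at least 3")
})

test_that("tidy and glance on a slope fit are broom-shaped", {
  f <- suppressWarnings(fit_loglog_slope(data.frame(k = 1:20, y = (1:20)^-1.2)))
  td <- suppressWarnings(tidy(f))
  expect_identical(td$term, c("intercept", "slope"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  gl <- glance(f)
  expect_identical(names(gl), c("slope", "std_error", "r_squared", "n_points"))
  expect_equal(gl$slope, -1.2, tolerance = 1e-10)
})

test_that("predicted C(k) from theory tracks measured C(k) after injection", {
  # moderate-size end-to-end consistency check of the closed-form theory
  n <- 5000
  exp1 <- experiment_superhub(n = n, gamma = 2.6, hub_degrees = c(1000, 1000),
                              seed = 301)
  m <- exp1$params$m_edges
  cbar <- mean(exp1$ck_before$c_mean)
  ctx <- theory_context(S = n, M = m, c_bar = cbar)
  kstar <- exp1$params$kstar
  dnk <- exp1$delta_by_degree
  capped <- dnk[dnk$degree >= kstar & dnk$dn_mean > 0, ]
  pred <- expected_new_triangles(capped$degree, 1000, ctx) * 2
  meas_fit <- fit_loglog_slope(capped[, c("degree", "dn_mean")])
  pred_fit <- suppressWarnings(
    fit_loglog_slope(data.frame(k = capped$degree, y = pred)))
  expect_equal(meas_fit$slope, pred_fit$slope, tolerance = 0.2)
})
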