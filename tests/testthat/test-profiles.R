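test_that("joint degree matrix matches direct tallies and sums to M", {
  star <- spoke_graph(1, 5)
  jd <- joint_degree_matrix(star)
  expect_identical(nrow(jd), 1L)
  expect_identical(jd$k1, 1L)
  expect_identical(jd$k2, 5L)
  expect_identical(jd$count, 5L)
  expect_identical(jd$prob, 1)

  withr::with_seed(4, {
    g <- random_gnp(30, 0.2)
    jd2 <- joint_degree_matrix(g)
    expect_identical(sum(jd2$count), nrow(g))
    expect_equal(sum(jd2$prob), 1)
    # cross-check each pair count against the per-edge oracle tally
    o <- oracle_jdm(g)
    keys <- paste(jd2$k1, jd2$k2)
    expect_setequal(keys, names(o))
    expect_identical(as.integer(jd2$count), as.integer(o[keys]))
  })
  expect_error(joint_degree_matrix(data.frame(from = character(0),
                                              to = character(0))),
               "no edges")
})

test_that("log2-binned joint degree matrix pools degrees into octaves", {
  g <- spoke_graph(2, 6, n_bridges = 1, seed = 1)
  jd <- joint_degree_matrix(g, bins = "log2")
  expect_true(all(c("k1", "k_hi1", "k2", "k_hi2") %in% names(jd)))
  expect_identical(sum(jd$count), nrow(g))
  expect_true(all(jd$k1 <= jd$k2))
  expect_true(all(2^floor(log2(jd$k1)) == jd$k1))
  expect_error(joint_degree_matrix(g, bins = "log3"), "log2")
})

test_that("a member of the rewired ensemble has a flat correlation profile", {
  g0 <- suppressWarnings(configuration_graph(
    sample_powerlaw_degrees(1500, 2.6, kmin = 2, seed = 61), seed = 61))
  member <- rewire_degree_preserving(g0, seed = 62)
  prof <- correlation_profile(member, n_random = 40, seed = 63)
  ok <- !is.na(prof$ratio) & prof$null_mean >= 5
  expect_gt(sum(ok), 4)
  expect_lt(median(abs(log(prof$ratio[ok]))), 0.1)
})

test_that("profiles separate hub-hub repulsion from hub-hub affinity", {
  spoke <- spoke_graph(8, 40, n_bridges = 20, seed = 71)
  prof_s <- correlation_profile(spoke, n_random = 50, seed = 72)
  # the hub-hub corner is empty by construction but populated in the nulls
  top <- max(c(prof_s$b1, prof_s$b2))
  corner <- prof_s[prof_s$b1 == top & prof_s$b2 == top, ]
  expect_identical(corner$obs, 0)
  expect_gt(corner$null_mean, 0)
  expect_lt(hub_hub_ratio(prof_s), 1)

  assort <- synth_correlated_graph(800, target_r = 0.2, seed = 73)
  prof_a <- correlation_profile(assort, n_random = 50, seed = 74)
  expect_gt(hub_hub_ratio(prof_a), 1)
})

test_that("C(k) envelope is calibrated and flags a modular graph", {
  g0 <- suppressWarnings(configuration_graph(
    sample_powerlaw_degrees(1200, 2.6, kmin = 2, seed = 81), seed = 81))
  member <- rewire_degree_preserving(g0, seed = 82)
  env <- ck_envelope(member, n_random = 40, seed = 83)
  # the 5-95 percent band should hold the member at most degrees
  expect_gte(mean(!env$outside), 0.8)
  expect_identical(env$c_real,
                   ck_spectrum(member)$c_mean)

  gm <- synth_modular(8, 40, p_in = 0.3, p_out = 0.01, seed = 84)
  envm <- ck_envelope(gm, n_random = 25, seed = 85)
  # a strongly modular graph sits far above its degree-preserving nulls
  above <- envm$c_real > envm$band_hi
  expect_gt(mean(above), 0.5)
})

test_that("superhub detection flags injected hubs and nothing in a pure bulk", {
  pure <- synth_metabolic_like(10000, gamma = 2.6, seed = 91)
  det0 <- detect_superhubs(degree_histogram(pure))
  expect_identical(sum(det0$flagged), 0L)
  gamma_hat <- attr(det0, "gamma_hat")
  expect_gt(gamma_hat, 2.2)
  expect_lt(gamma_hat, 3.0)

  spiked <- synth_metabolic_like(10000, gamma = 2.6,
                                 superhub_degrees = c(2000, 2000), seed = 91)
  det1 <- detect_superhubs(degree_histogram(spiked))
  d <- node_degrees(spiked)
  hub_degrees <- sort(unique(d$degree[d$node %in% injected_nodes(spiked)]))
  expect_identical(sort(det1$degree[det1$flagged]), hub_degrees)
})

test_that("superhub detection input guards", {
  expect_error(detect_superhubs(data.frame(degree = 1:5)), "columns")
  expect_error(detect_superhubs(data.frame(degree = 1:5, count = 1:5)),
               "Too few")
})

test_that("power-law tail probability is a proper decreasing tail", {
  p <- vapply(c(1, 2, 5, 10, 50), powerlaw_tail_prob, numeric(1),
              gamma = 2.6, kmin = 1)
  expect_equal(p[1], 1)
  expect_true(all(diff(p) < 0))
  expect_gt(p[5], 0)
})

test_that("profile and envelope autoplot methods return ggplot objects", {
  g <- spoke_graph(4, 10, n_bridges = 4, seed = 3)
  prof <- correlation_profile(g, n_random = 10, seed = 4)
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
  env <- ck_envelope(hierarchical_model(2), n_random = 5, seed = 5)
  expect_s3_class(ggplot2::autoplot(env), "ggplot")
})
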