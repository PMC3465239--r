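#' Simulated-annealing null matched to a real triangle count
#'
#' Random graphs constrained only by the degree sequence have far fewer
#' triangles than biological networks. This null starts from a
#' [joint_degree_seed()] of the real graph and runs a Metropolis Monte-Carlo
#' walk whose moves exchange endpoint pairs of equal degree between two random
#' edges - the minimal move that preserves the full joint degree matrix. The
#' energy is `E = |N_random - N_real| / N_real`, the relative mismatch of
#' triangle counts, so a perfectly modularity-matched random network scores 0.
#' Each proposal is accepted with probability `min(exp(-dE / T), 1)`.
#'
#' The walk stops when `E <= tol`, when `max_steps` proposals have been made,
#' or when the windowed mean energy is stationary (relative change below
#' `stationarity_tol` between consecutive windows of `window` steps; set
#' `stationarity_tol = 0` to disable).
#'
#' @param g_real A graph as a data frame of edges; must contain at least one
#'   triangle (otherwise the energy is undefined).
#' @param t0 Initial effective temperature (> 0). Useful values are of the
#'   order of a few energy quanta `1 / N_real`.
#' @param cooling Geometric cooling factor in (0, 1\] applied every
#'   `cooling_interval` steps; `1` keeps the temperature fixed.
#' @param cooling_interval Steps between cooling applications.
#' @param max_steps Proposal budget.
#' @param tol Stop once energy falls to this value or below.
#' @param window,stationarity_tol Stationarity stopping rule (see above).
#' @param seed Optional RNG seed (also seeds the joint-degree seed network).
#' @param log_every Trajectory logging interval in steps.
#' @param log_proposals If `TRUE`, record (dE, accepted) for up to 2e5
#'   proposals that survived validity checks - used to audit the Metropolis
#'   rule.
#' @param start Optional pre-built seed graph (must have the same joint degree
#'   matrix as `g_real`); default builds one with [joint_degree_seed()].
#' @return An object of class `"triangle_anneal"`: a list with elements
#'   `graph` (edge tibble), `energy`, `triangles`, `n_real`, `steps`,
#'   `accepted`, `final_temp`, `stationary`, `trajectory` (tibble of step,
#'   energy) and optionally `proposals`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
anneal_to_triangle_count <- function(g_real, t0 = 0.05, cooling = 1,
                                     cooling_interval = 1000,
                                     max_steps = 2e5, tol = 0.1,
                                     window = 1e4, stationarity_tol = 1e-3,
                                     seed = NULL, log_every = 1000,
                                     log_proposals = FALSE, start = NULL) {
  e_real <- as_edge_table(g_real)
  if (nrow(e_real) < 2) abort("Annealing needs at least 2 edges.")
  n_real <- count_triangles(e_real)
  if (n_real == 0) {
    abort("Target graph has no triangles; energy |N_random - N|/N undefined.")
  }
  with_seed_if(seed, {
    seed_graph <- if (is.null(start)) joint_degree_seed(e_real) else
      as_edge_table(start)
    idx <- edge_index(seed_graph)
    deg <- tabulate(c(idx$edges), nbins = length(idx$nodes))
    res <- anneal_cpp(idx$edges - 1L, length(idx$nodes), as.integer(deg),
                      as.double(n_real), t0, cooling,
                      as.integer(cooling_interval), as.double(max_steps),
                      tol, as.integer(window), stationarity_tol,
                      as.integer(log_every), log_proposals)
    out <- list(
      graph = edges_from_index(res$edges + 1L, idx$nodes),
      energy = res$energy,
      triangles = res$triangles,
      n_real = n_real,
      steps = res$steps,
      accepted = res$accepted,
      final_temp = res$final_temp,
      stationary = res$stationary,
      trajectory = tibble(step = res$traj_step, energy = res$traj_E)
    )
    if (log_proposals) {
      out$proposals <- tibble(delta_e = res$prop_dE,
                              accepted = res$prop_acc == 1)
    }
    structure(out, class = "triangle_anneal")
  })
}

#' @export
print.triangle_anneal <- function(x, ...) {
  cat(sprintf(
    "<triangle_anneal> %d steps, %d accepted; triangles %d (target %d), E = %.4f\n",
    as.integer(x$steps), as.integer(x$accepted), as.integer(x$triangles),
    as.integer(x$n_real), x$energy))
  invisible(x)
}

#' @rdname anneal_to_triangle_count
#' @param x A `triangle_anneal` object.
#' @param ... Unused.
#' @export
tidy.triangle_anneal <- function(x, ...) x$trajectory

#' @rdname anneal_to_triangle_count
#' @export
glance.triangle_anneal <- function(x, ...) {
  tibble(energy = x$energy, triangles = x$triangles, n_real = x$n_real,
         steps = x$steps, accepted = x$accepted,
         acceptance_rate = x$accepted / max(x$steps, 1),
         final_temp = x$final_temp, stationary = x$stationary)
}

#' @rdname anneal_to_triangle_count
#' @param object A `triangle_anneal` object.
#' @export
autoplot.triangle_anneal <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$step, y = .data$energy)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "Monte-Carlo step",
                  y = "E = |N_random - N_real| / N_real",
                  title = "Annealing trajectory") +
    ggplot2::theme_minimal()
}
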