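#' Compare slanted and conventional forests on replicated synthetic studies
#'
#' The package's end-to-end experiment: for each replicate, simulate a study
#' from a preset, run the random walk with restart over the simulated
#' network with the simulated seed genes, convert the stationary
#' probabilities to selection weights, and measure LOOCV accuracy of the
#' slanted forest against the conventional (uniform-weight) forest on the
#' same data with matched fold seeds.
#'
#' The default \code{mtry} is \code{ceiling(n_genes / 30)}, the candidate
#' fraction of the case study's headline configuration (500 candidate genes
#' out of 15,191) carried over to the simulated dimension.
#'
#' @param preset name of a [scenario_presets()] entry, or a [sim_config()].
#' @param n_reps number of simulation replicates, default 20.
#' @param ntree trees per forest, default 100.
#' @param mtry candidate genes per node; default \code{ceiling(n_genes/30)}.
#' @param theta,tol restart probability and convergence threshold for
#'   [run_rwr()].
#' @param seed integer master seed; replicate r uses a seed derived from
#'   \code{(seed, r)}.
#' @return An object of class \code{ksrf_comparison}: data frame with one
#'   row per replicate (\code{rep}, \code{slanted}, \code{uniform}
#'   accuracies), plus attributes \code{mean_slanted}, \code{mean_uniform},
#'   \code{mean_gap_pp} (mean accuracy gap in percentage points).
#' @export
compare_modes <- function(preset = "hard_three_class", n_reps = 20,
                          ntree = 100, mtry = NULL, theta = 0.3, tol = 1e-6,
                          seed = 1) {
  res <- lapply(seq_len(n_reps), function(r) {
    rep_seed <- derive_seed(seed, 100 + r)
    sim <- simulate_scenario(preset, seed = rep_seed)
    mt <- mtry %||% ceiling(length(sim$graph$nodes) / 30)
    w <- rwr_weights(sim, theta = theta, tol = tol)
    acc_s <- loocv(sim$x, sim$y, weights = w, ntree = ntree, mtry = mt,
                   seed = rep_seed)$accuracy
    acc_u <- loocv(sim$x, sim$y, weights = NULL, ntree = ntree, mtry = mt,
                   seed = rep_seed)$accuracy
    c(slanted = acc_s, uniform = acc_u)
  })
  res <- as.data.frame(do.call(rbind, res))
  res$rep <- seq_len(n_reps)
  res <- res[c("rep", "slanted", "uniform")]
  structure(res, class = c("ksrf_comparison", "data.frame"),
            mean_slanted = mean(res$slanted),
            mean_uniform = mean(res$uniform),
            mean_gap_pp = 100 * (mean(res$slanted) - mean(res$uniform)))
}

#' @export
print.ksrf_comparison <- function(x, ...) {
  cat(sprintf("slanted vs uniform over %d replicate(s): %.1f%% vs %.1f%% (gap %+.1f pp)\n",
              nrow(x), 100 * attr(x, "mean_slanted"),
              100 * attr(x, "mean_uniform"), attr(x, "mean_gap_pp")))
  invisible(x)
}

#' Selection weights of a simulated study via the random walk
#'
#' Convenience wrapper: transition matrix of the simulated network, RWR from
#' the simulated seed genes, aligned to the expression gene order.
#'
#' @param sim a [simulate_scenario()] object.
#' @param theta,tol passed to [run_rwr()].
#' @return a [selection_weights()] vector.
#' @export
rwr_weights <- function(sim, theta = 0.3, tol = 1e-6) {
  stopifnot(inherits(sim, "ksrf_sim"))
  A <- transition_matrix(sim$graph)
  pr <- run_rwr(A, sim$seed_genes, theta = theta, tol = tol)
  selection_weights(pr, colnames(sim$x))
}
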