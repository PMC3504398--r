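#' Benchmark grid of completion experiments
#'
#' Runs the standard synthetic benchmark: for every combination of edit
#' budgets `(h, k)` and observation error level `o`, generates
#' `n_trials` independent trials (fresh coefficients and perturbations
#' each), completes each perturbed network with [complete_network()],
#' and aggregates mean edit accuracy and success rate per cell.
#'
#' Each trial is reseeded deterministically from `seed` and the trial
#' index, so any single cell or trial can be reproduced in isolation.
#'
#' @param cells Data frame with integer columns `h` and `k`, one row per
#'   budget pair. Defaults to the standard eight pairs
#'   `(0,1), (0,2), (1,0), (1,1), (1,2), (2,0), (2,1), (2,2)`.
#' @param o Numeric vector of observation error levels.
#' @param n_trials Trials per cell.
#' @param H,K Per-node caps for completion.
#' @param benchmark,copies Topology passed to [trial_config()].
#' @param b Process-noise amplitude.
#' @param seed Root seed; every trial derives its own sub-seed from it.
#' @param keep_trials Also return the per-trial scores as a list-column
#'   `trials` (for dispersion estimates).
#' @return Tibble: one row per `(h, k, o)` cell with `n_trials`,
#'   `mean_accuracy`, `success_rate`.
#' @export
run_benchmark_grid <- function(cells = NULL, o = c(0.1, 0.3, 0.5, 0.7),
                               n_trials = 100, H = 3, K = 3,
                               benchmark = "wnt5a", copies = 1,
                               b = 0.2, seed = 1, keep_trials = FALSE) {
  if (is.null(cells)) {
    cells <- tibble::tibble(h = c(0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L),
                            k = c(1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L))
  }
  cells <- tibble::as_tibble(cells)
  grid <- tidyr::crossing(cells, o = o)
  purrr::pmap_dfr(grid, function(h, k, o) {
    res <- purrr::map_dfr(seq_len(n_trials), function(i) {
      cfg <- trial_config(benchmark = benchmark, copies = copies,
                          o = o, b = b, h_del = h, k_add = k,
                          seed = derive_seed(seed, h * 1e6 + k * 1e5 +
                                               round(o * 1000), i))
      trial <- run_trial(cfg)
      out <- complete_network(trial$data, trial$network_init,
                              h = h, k = k, H = H, K = K)
      evaluate_trial(trial, out)
    })
    out <- tibble::tibble(h = h, k = k, o = o, n_trials = n_trials,
                          mean_accuracy = mean(res$accuracy),
                          success_rate = success_rate(res$success))
    if (keep_trials) out$trials <- list(res)
    out
  })
}

#' Benchmark grid of inference experiments
#'
#' Network inference benchmark: per trial, data are simulated from the
#' (optionally replicated) benchmark network, and [infer_network()] is
#' run from the empty network with an addition budget equal to the true
#' edge count. Accuracy is the fraction of true directed edges
#' recovered.
#'
#' @inheritParams run_benchmark_grid
#' @param K Per-node addition cap.
#' @return Tibble: one row per `(copies, o)` with `n_genes`, `k`,
#'   `n_trials`, `mean_accuracy`.
#' @export
run_inference_grid <- function(o = c(0.1, 0.3, 0.5, 0.7), copies = 1,
                               n_trials = 10, K = 3,
                               benchmark = "wnt5a", b = 0.2, seed = 1) {
  grid <- tidyr::crossing(copies = copies, o = o)
  purrr::pmap_dfr(grid, function(copies, o) {
    accs <- purrr::map_dbl(seq_len(n_trials), function(i) {
      cfg <- trial_config(benchmark = benchmark, copies = copies,
                          o = o, b = b,
                          seed = derive_seed(seed, copies * 1e7 +
                                               round(o * 1000), i))
      trial <- run_trial(cfg)
      k_true <- nrow(trial$network_true$edges)
      res <- infer_network(trial$data, k = k_true, K = K)
      inference_accuracy(trial$network_true, res$completed)
    })
    tibble::tibble(copies = copies,
                   n_genes = 10L * copies, k = 30L * copies, o = o,
                   n_trials = n_trials, mean_accuracy = mean(accs))
  })
}

# deterministic sub-seed below 2^31 from a root seed and indices
derive_seed <- function(seed, block, i) {
  as.integer((as.numeric(seed) * 7919 + block * 104729 + i * 15485863)
             %% 2147483629) + 1L
}
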