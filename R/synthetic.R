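#' Configuration for a synthetic completion/inference trial
#'
#' Bundles the simulation protocol used throughout the benchmark
#' experiments: coefficients drawn uniformly (linear terms on
#' `[-1, 1]`, pairwise-product terms on `[-0.5, 0.5]`, weaker because
#' cooperative effects are taken as weaker than direct ones), process
#' noise of amplitude `b = 0.2` inside the dynamics, 20 series of 10
#' time points each at `dt = 0.2` started from uniform `[-1, 1]` initial
#' values, and uniform observation noise of half-width `o`.
#'
#' @param benchmark Benchmark topology name (see [benchmark_network()]).
#' @param copies Number of disjoint copies of the benchmark (network
#'   size scaling; coefficients are resampled per copy).
#' @param network Optional explicit [grn()] overriding `benchmark`.
#' @param n_series Number of independent series per trial.
#' @param n_timepoints Observed rows per series (transitions per series
#'   is one less).
#' @param dt Time step between consecutive rows.
#' @param b Process-noise amplitude.
#' @param o Observation error level (uniform half-width), `>= 0`.
#' @param lin_range,pair_range Coefficient ranges (length-2 numeric).
#' @param x0_range Initial-value range.
#' @param h_del,k_add Completion budgets for the trial: the initial
#'   network is built by adding `h_del` spurious edges to the true
#'   network and deleting `k_add` true edges, so that a completion run
#'   with budgets `(h_del, k_add)` can restore it exactly.
#' @param seed Optional integer seed making the whole trial reproducible.
#' @return A `trial_config` list.
#' @export
trial_config <- function(benchmark = "wnt5a", copies = 1, network = NULL,
                         n_series = 20, n_timepoints = 10, dt = 0.2,
                         b = 0.2, o = 0.1,
                         lin_range = c(-1, 1), pair_range = c(-0.5, 0.5),
                         x0_range = c(-1, 1),
                         h_del = 0, k_add = 0, seed = NULL) {
  stopifnot(o >= 0, b >= 0, n_series >= 1, n_timepoints >= 2,
            dt > 0, copies >= 1, h_del >= 0, k_add >= 0,
            length(lin_range) == 2, length(pair_range) == 2,
            diff(lin_range) >= 0, diff(pair_range) >= 0)
  structure(list(benchmark = benchmark, copies = copies,
                 network = network, n_series = n_series,
                 n_timepoints = n_timepoints, dt = dt, b = b, o = o,
                 lin_range = lin_range, pair_range = pair_range,
                 x0_range = x0_range, h_del = h_del, k_add = k_add,
                 seed = seed),
            class = "trial_config")
}

#' Benchmark network topologies
#'
#' `"wnt5a"` returns a 10-gene directed benchmark with uniform
#' in-degree 3 (30 edges, no self-loops) using the gene names of the
#' WNT5A melanoma study. The edge set shipped here
#' (`extdata/wnt5a_synthetic.tsv`) is a synthetic surrogate with the
#' published topology's size and degree structure — each gene is
#' regulated by the genes 1, 2 and 4 positions after it in a fixed
#' circular order — not a transcription of the original wiring diagram.
#' Benchmark results on it depend on size and in-degree, not on the
#' identity of particular edges.
#'
#' @param name Benchmark name; only `"wnt5a"` is recognized.
#' @return A [grn()].
#' @examples
#' indegree(benchmark_network("wnt5a"))
#' @export
benchmark_network <- function(name = "wnt5a") {
  if (!identical(tolower(name), "wnt5a")) {
    stop("unknown benchmark '", name, "'", call. = FALSE)
  }
  path <- system.file("extdata", "wnt5a_synthetic.tsv",
                      package = "dplsq", mustWork = TRUE)
  read_network(path, format = "tsv")
}

#' Disjoint replicated network
#'
#' Scales a benchmark up by taking `copies` disjoint copies (no
#' cross-copy edges), with node names suffixed `_1`, `_2`, ... per copy.
#' With one copy the input is returned unchanged. Coefficients are meant
#' to be resampled per copy downstream, so copies share topology but not
#' dynamics.
#'
#' @param base A [grn()].
#' @param copies Number of copies, `>= 1`.
#' @return A [grn()] with `copies * n` nodes.
#' @export
replicate_network <- function(base, copies) {
  base <- as_grn(base)
  stopifnot(copies >= 1)
  if (copies == 1) return(base)
  parts <- lapply(seq_len(copies), function(c) {
    list(nodes = paste0(base$nodes, "_", c),
         edges = tibble::tibble(from = paste0(base$edges$from, "_", c),
                                to = paste0(base$edges$to, "_", c)))
  })
  grn(dplyr::bind_rows(lapply(parts, `[[`, "edges")),
      nodes = unlist(lapply(parts, `[[`, "nodes")))
}

#' Draw random dynamics coefficients for a network
#'
#' One [node_model()] per gene over its regulator set: intercept and
#' linear coefficients uniform on `lin_range`, pairwise-product
#' coefficients uniform on `pair_range`.
#'
#' @param network A [grn()].
#' @param lin_range,pair_range Length-2 numeric ranges.
#' @param seed Optional integer seed.
#' @return Named list of [node_model()]s in node order.
#' @export
sample_parameters <- function(network, lin_range = c(-1, 1),
                              pair_range = c(-0.5, 0.5), seed = NULL) {
  network <- as_grn(network)
  run <- function() {
    models <- lapply(network$nodes, function(v) {
      regs <- regulators(network, v)
      h <- length(regs)
      node_model(
        v, regs,
        a0 = stats::runif(1, lin_range[1], lin_range[2]),
        a_lin = stats::setNames(
          stats::runif(h, lin_range[1], lin_range[2]), regs),
        a_pair = stats::setNames(
          stats::runif(choose(h, 2), pair_range[1], pair_range[2]),
          pair_labels(regs)))
    })
    stats::setNames(models, network$nodes)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Randomly perturb a network, keeping the ground-truth edits
#'
#' Adds `add` edges drawn uniformly among absent ordered non-self pairs
#' and deletes `delete` edges drawn uniformly among existing edges, so
#' that a completion run knows exactly which edits would restore the
#' original. Added and deleted sets are disjoint by construction.
#'
#' @param network A [grn()].
#' @param add,delete Numbers of edges to add / delete.
#' @param seed Optional integer seed.
#' @return List: `network` (perturbed [grn()]), `added` and `deleted`
#'   (tibbles of the ground-truth edits).
#' @export
perturb_network <- function(network, add = 0, delete = 0, seed = NULL) {
  network <- as_grn(network)
  nodes <- network$nodes
  n <- length(nodes)
  present <- edge_key(network$edges$from, network$edges$to)
  all_from <- rep(nodes, each = n)
  all_to <- rep(nodes, n)
  keep <- all_from != all_to & !(edge_key(all_from, all_to) %in% present)
  absent <- tibble::tibble(from = all_from[keep], to = all_to[keep])
  if (add > nrow(absent)) {
    stop("cannot add ", add, " edges: only ", nrow(absent),
         " absent non-self pairs", call. = FALSE)
  }
  if (delete > nrow(network$edges)) {
    stop("cannot delete ", delete, " edges from a network with ",
         nrow(network$edges), call. = FALSE)
  }
  run <- function() {
    added <- absent[sample.int(nrow(absent), add), ]
    deleted <- network$edges[sample.int(nrow(network$edges), delete), ]
    list(network = apply_edits(network, deleted, added),
         added = added, deleted = deleted)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate one complete synthetic trial
#'
#' Composes the benchmark topology (optionally replicated), random
#' coefficient draws, noisy trajectory simulation from `n_series`
#' independent initial conditions, observation noise, and the
#' ground-truth perturbation into one reproducible bundle. A completion
#' run on `network_init` with budgets `(h_del, k_add)` is scored against
#' `network_true`.
#'
#' @param config A [trial_config()].
#' @return List: `network_true`, `network_init`, `data` ([ts_set()]),
#'   `models`, `edits` (list of `added`/`deleted` ground-truth tibbles;
#'   `added` are the spurious edges completion should delete), `config`.
#' @export
run_trial <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  run <- function() {
    net <- if (!is.null(config$network)) as_grn(config$network) else
      replicate_network(benchmark_network(config$benchmark),
                        config$copies)
    models <- sample_parameters(net, config$lin_range, config$pair_range)
    series <- lapply(seq_len(config$n_series), function(s) {
      x0 <- stats::setNames(
        stats::runif(length(net$nodes), config$x0_range[1],
                     config$x0_range[2]), net$nodes)
      x <- generate_trajectory(models, x0,
                               n_steps = config$n_timepoints - 1,
                               dt = config$dt, b = config$b)
      observe(x, config$o)
    })
    pert <- perturb_network(net, add = config$h_del,
                            delete = config$k_add)
    list(network_true = net, network_init = pert$network,
         data = ts_set(series, dt = config$dt), models = models,
         edits = list(added = pert$added, deleted = pert$deleted),
         config = config)
  }
  if (is.null(config$seed)) run() else
    withr::with_seed(config$seed, run())
}
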