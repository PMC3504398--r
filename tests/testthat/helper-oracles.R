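# Fixtures and independent oracles used across the suite.

# random directed network on n nodes with per-node indegree <= max_deg
random_network <- function(n, max_deg = 2) {
  nodes <- LETTERS[seq_len(n)]
  edges <- purrr::map_dfr(nodes, function(v) {
    deg <- sample(0:max_deg, 1)
    if (deg == 0) return(NULL)
    tibble::tibble(from = sample(setdiff(nodes, v), deg), to = v)
  })
  if (!nrow(edges)) edges <- NULL
  grn(edges, nodes = nodes)
}

# noise-free ts_set simulated from given models
noise_free_data <- function(models, genes, n_series = 3, n_steps = 7,
                            dt = 0.2) {
  series <- lapply(seq_len(n_series), function(s) {
    x0 <- stats::setNames(runif(length(genes), -1, 1), genes)
    generate_trajectory(models, x0, n_steps = n_steps, dt = dt, b = 0)
  })
  ts_set(series, dt = dt)
}

# small noisy benchmark instance for oracle comparisons
small_instance <- function(seed, n = 5, o = 0.1) {
  withr::with_seed(seed, {
    net <- random_network(n, max_deg = 2)
    models <- sample_parameters(net)
    data <- noise_free_data(models, net$nodes, n_series = 2,
                            n_steps = 7)
    data <- ts_set(lapply(data$series, observe, o = o), dt = data$dt)
    list(net = net, data = data)
  })
}

# term-by-term evaluation of the one-step update, written independently
# of node_rate()/simulate_step()
oracle_step <- function(x, model, dt, noise = 0) {
  regs <- model$regulators
  acc <- model$a0
  for (j in seq_along(regs)) acc <- acc + model$a_lin[[j]] * x[[regs[j]]]
  if (length(regs) >= 2) {
    q <- 0
    for (j in seq_len(length(regs) - 1)) {
      for (k in (j + 1):length(regs)) {
        q <- q + 1
        acc <- acc + model$a_pair[[q]] * x[[regs[j]]] * x[[regs[k]]]
      }
    }
  }
  x[[model$node]] + dt * (acc + noise)
}

# independent SSE of the best least-squares fit for (node, regulators),
# via lm.fit on an explicitly assembled design; returns the minimized
# squared one-step prediction error
oracle_sse <- function(data, node, regs) {
  Xs <- list(); ys <- c()
  for (s in data$series) {
    m <- nrow(s) - 1
    for (t in seq_len(m)) {
      row <- 1
      for (r in regs) row <- c(row, s[t, r])
      if (length(regs) >= 2) {
        for (j in seq_len(length(regs) - 1)) {
          for (k in (j + 1):length(regs)) {
            row <- c(row, s[t, regs[j]] * s[t, regs[k]])
          }
        }
      }
      Xs[[length(Xs) + 1]] <- row
      ys <- c(ys, (s[t + 1, node] - s[t, node]) / data$dt)
    }
  }
  X <- do.call(rbind, Xs)
  fit <- lm.fit(X, ys)
  sum(fit$residuals^2) * data$dt^2
}

# Exhaustive completion oracle: enumerates every joint assignment of
# h_j deletions and k_j additions over all nodes with the given totals
# and per-node caps, scoring each by summed oracle_sse. Independent of
# the package's sigma tables and dynamic program.
oracle_complete <- function(data, network, h, k, H, K) {
  nodes <- network$nodes
  n <- length(nodes)
  cache <- new.env(parent = emptyenv())
  sse_of <- function(node, regs) {
    key <- paste(node, paste(sort(regs), collapse = ","), sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <- oracle_sse(data, node, sort(regs))
    }
    cache[[key]]
  }
  # per-node options: (h_j, k_j, resulting regulator set)
  options_for <- function(v) {
    regs <- regulators(network, v)
    cand <- sort(setdiff(nodes, c(v, regs)))
    opts <- list()
    for (hj in 0:min(H, length(regs), h)) {
      dels <- if (hj == 0) list(character()) else
        utils::combn(regs, hj, simplify = FALSE)
      for (kj in 0:min(K, length(cand), k)) {
        if (length(regs) - hj + kj >= n) next
        adds <- if (kj == 0) list(character()) else
          utils::combn(cand, kj, simplify = FALSE)
        for (d in dels) for (a in adds) {
          opts[[length(opts) + 1]] <- list(
            hj = hj, kj = kj,
            sse = sse_of(v, c(setdiff(regs, d), a)))
        }
      }
    }
    opts
  }
  all_opts <- lapply(nodes, options_for)
  best <- Inf
  recurse <- function(i, hr, kr, acc) {
    if (acc >= best) return()
    if (i > n) {
      if (hr == 0 && kr == 0 && acc < best) best <<- acc
      return()
    }
    for (op in all_opts[[i]]) {
      if (op$hj > hr || op$kj > kr) next
      recurse(i + 1, hr - op$hj, kr - op$kj, acc + op$sse)
    }
  }
  recurse(1, h, k, 0)
  best
}
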