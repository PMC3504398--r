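#' Per-gene dynamics model
#'
#' Each gene i evolves by a discretized differential equation
#' \deqn{x_i(t+1) = x_i(t) + \Delta t\,\big(a_0 + \sum_j a_j x_{i_j}(t)
#'   + \sum_{j<k} a_{j,k} x_{i_j}(t) x_{i_k}(t) + b_i \omega\big),}
#' where the \eqn{x_{i_j}} are the gene's regulators, linear coefficients
#' carry activation/inhibition signs, pairwise-product terms capture
#' cooperative effects, and \eqn{b_i\omega} is optional process noise
#' (uniform \eqn{\omega \in [-1, 1]}).
#'
#' @param node Gene name.
#' @param regulators Character vector of regulator gene names (excluding
#'   `node` itself).
#' @param a0 Intercept (expression change per unit time).
#' @param a_lin Named numeric vector of linear coefficients, one per
#'   regulator (names must match `regulators`).
#' @param a_pair Named numeric vector of pairwise-product coefficients,
#'   one per unordered regulator pair, named `"u:v"` with `u < v` in the
#'   order of `regulators`; length must be `choose(h, 2)`.
#' @return A `node_model`.
#' @export
node_model <- function(node, regulators = character(), a0 = 0,
                       a_lin = NULL, a_pair = NULL) {
  regulators <- as.character(regulators)
  if (node %in% regulators) {
    stop("node '", node, "' cannot regulate itself", call. = FALSE)
  }
  h <- length(regulators)
  if (is.null(a_lin)) a_lin <- stats::setNames(numeric(h), regulators)
  if (h && !setequal(names(a_lin), regulators)) {
    stop("`a_lin` names must match `regulators`", call. = FALSE)
  }
  a_lin <- a_lin[regulators]
  pair_names <- pair_labels(regulators)
  if (is.null(a_pair)) {
    a_pair <- stats::setNames(numeric(length(pair_names)), pair_names)
  }
  if (length(a_pair) != length(pair_names) ||
      (length(a_pair) && !setequal(names(a_pair), pair_names))) {
    stop("`a_pair` must have one entry per regulator pair (",
         length(pair_names), ")", call. = FALSE)
  }
  if (length(pair_names)) a_pair <- a_pair[pair_names]
  structure(list(node = node, regulators = regulators,
                 a0 = unname(a0), a_lin = a_lin, a_pair = a_pair),
            class = "node_model")
}

# "u:v" labels for unordered pairs, j < k in regulator order
pair_labels <- function(regulators) {
  h <- length(regulators)
  if (h < 2) return(character())
  idx <- utils::combn(h, 2)
  paste(regulators[idx[1, ]], regulators[idx[2, ]], sep = ":")
}

#' @export
print.node_model <- function(x, ...) {
  cat("<node_model> ", x$node, " <- {",
      paste(x$regulators, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# evaluate dx/dt for one node at a state vector (named)
node_rate <- function(model, state) {
  miss <- setdiff(model$regulators, names(state))
  if (length(miss)) {
    stop("unknown regulator(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  v <- model$a0
  h <- length(model$regulators)
  if (h) {
    xr <- state[model$regulators]
    v <- v + sum(model$a_lin * xr)
    if (h >= 2) {
      idx <- utils::combn(h, 2)
      v <- v + sum(model$a_pair * xr[idx[1, ]] * xr[idx[2, ]])
    }
  }
  unname(v)
}

#' One step of the discretized dynamics
#'
#' Advances every gene one time step under its `node_model`, optionally
#' with a supplied per-gene process-noise term (zero for deterministic
#' prediction). The noise enters inside the `dt`-scaled parenthesis, so
#' the effective perturbation per step is `dt * noise`.
#'
#' @param state Named numeric vector of current expression values.
#' @param models List of [node_model()]s, one per gene in `state`.
#' @param dt Time step.
#' @param noise Named numeric vector (same genes as `state`) giving the
#'   realized process-noise term \eqn{b_i\omega} per gene, or `NULL`.
#' @return Named numeric vector of next-step values.
#' @examples
#' m <- node_model("A", a0 = 1)
#' simulate_step(c(A = 0), list(m), dt = 0.2) # 0.2
#' @export
simulate_step <- function(state, models, dt, noise = NULL) {
  genes <- names(state)
  if (is.null(genes)) stop("`state` must be named by gene", call. = FALSE)
  models <- name_models(models)
  if (!all(genes %in% names(models))) {
    stop("missing model for gene(s): ",
         paste(setdiff(genes, names(models)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(noise)) noise <- stats::setNames(numeric(length(genes)), genes)
  rates <- vapply(genes, function(g) node_rate(models[[g]], state), 0)
  state + dt * (rates + noise[genes])
}

name_models <- function(models) {
  if (inherits(models, "node_model")) models <- list(models)
  stats::setNames(models, vapply(models, function(m) m$node, ""))
}

#' Simulate a noisy trajectory
#'
#' Iterates [simulate_step()] from an initial state, drawing the process
#' noise \eqn{\omega} independently per gene per step, uniform on
#' \eqn{[-1, 1]}, scaled by the per-gene amplitude `b`.
#'
#' @param models List of [node_model()]s covering all genes in `x0`.
#' @param x0 Named numeric vector of initial values.
#' @param n_steps Number of transitions to simulate (the result has
#'   `n_steps + 1` rows).
#' @param dt Time step.
#' @param b Process-noise amplitude: a single number or a named per-gene
#'   vector. `0` gives the deterministic map.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric matrix, rows `t = 0..n_steps`, gene columns.
#' @export
generate_trajectory <- function(models, x0, n_steps, dt, b = 0,
                                seed = NULL) {
  stopifnot(n_steps >= 1)
  genes <- names(x0)
  if (length(b) == 1) b <- stats::setNames(rep(b, length(genes)), genes)
  run <- function() {
    out <- matrix(NA_real_, n_steps + 1, length(genes),
                  dimnames = list(NULL, genes))
    out[1, ] <- x0
    state <- x0
    for (t in seq_len(n_steps)) {
      omega <- stats::runif(length(genes), -1, 1)
      state <- simulate_step(state, models, dt,
                             noise = b[genes] * omega)
      out[t + 1, ] <- state
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Add uniform observation noise to a trajectory
#'
#' Observations are `y = x + o * eps` with `eps` uniform on \eqn{[-1, 1]},
#' drawn independently per gene and time point (including `t = 0`). `o` is
#' the observation error level: the half-width of the uniform error.
#'
#' @param x Numeric matrix of true values (time points by genes).
#' @param o Observation error level, `>= 0`.
#' @param seed Optional integer seed.
#' @return Matrix of observed values, same shape as `x`.
#' @export
observe <- function(x, o, seed = NULL) {
  if (!is.numeric(o) || length(o) != 1 || is.na(o) || o < 0) {
    stop("`o` must be a single nonnegative number", call. = FALSE)
  }
  run <- function() x + o * matrix(stats::runif(length(x), -1, 1),
                                   nrow(x), ncol(x))
  y <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  dimnames(y) <- dimnames(x)
  y
}
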