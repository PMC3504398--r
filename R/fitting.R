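#' Build the linear regression system for one gene
#'
#' The dynamics are linear in the coefficients, so fitting reduces to
#' ordinary least squares. One row is produced per consecutive pair of
#' time points within each series (never spanning series boundaries); the
#' response is the per-step difference quotient
#' `(y_node(t+1) - y_node(t)) / dt`, and the predictors are an intercept,
#' each regulator's value at `t`, and each pairwise product of regulator
#' values at `t`.
#'
#' @param data A [ts_set()].
#' @param node Gene whose dynamics are fitted.
#' @param regulators Character vector of candidate regulators (must not
#'   contain `node`).
#' @return List with `X` (design matrix, named columns `(Intercept)`,
#'   regulators, `"u:v"` products) and `y` (response vector).
#' @export
build_regression_system <- function(data, node, regulators = character()) {
  stopifnot(inherits(data, "ts_set"))
  regulators <- as.character(regulators)
  if (node %in% regulators) {
    stop("`regulators` must not contain the target node", call. = FALSE)
  }
  miss <- setdiff(c(node, regulators), data$genes)
  if (length(miss)) {
    stop("gene(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(data$series, function(s) {
    m <- nrow(s) - 1L
    cur <- s[seq_len(m), , drop = FALSE]
    nxt <- s[seq_len(m) + 1L, , drop = FALSE]
    y <- (nxt[, node] - cur[, node]) / data$dt
    h <- length(regulators)
    X <- matrix(1, m, 1, dimnames = list(NULL, "(Intercept)"))
    if (h) {
      X <- cbind(X, cur[, regulators, drop = FALSE])
      if (h >= 2) {
        idx <- utils::combn(h, 2)
        P <- cur[, regulators[idx[1, ]], drop = FALSE] *
          cur[, regulators[idx[2, ]], drop = FALSE]
        colnames(P) <- pair_labels(regulators)
        X <- cbind(X, P)
      }
    }
    list(X = X, y = y)
  })
  list(X = do.call(rbind, lapply(rows, `[[`, "X")),
       y = unlist(lapply(rows, `[[`, "y"), use.names = FALSE))
}

# Precomputed cross-products for fast SSE over many candidate regulator
# sets. Zfull stacks intercept, all linear and all pairwise-product
# columns once; any candidate set's normal equations are then a submatrix
# lookup instead of a fresh design-matrix build.
regression_context <- function(data) {
  stopifnot(inherits(data, "ts_set"))
  genes <- data$genes
  n <- length(genes)
  cur <- do.call(rbind, lapply(data$series, function(s)
    s[seq_len(nrow(s) - 1L), , drop = FALSE]))
  nxt <- do.call(rbind, lapply(data$series, function(s)
    s[seq_len(nrow(s) - 1L) + 1L, , drop = FALSE]))
  R <- (nxt - cur) / data$dt
  N <- nrow(cur)
  p_lin <- n
  pair_idx <- if (n >= 2) utils::combn(n, 2) else
    matrix(integer(), 2, 0)
  Z <- cbind(1, cur,
             cur[, pair_idx[1, ], drop = FALSE] *
               cur[, pair_idx[2, ], drop = FALSE])
  lin_col <- stats::setNames(1L + seq_len(n), genes)
  pair_col <- matrix(0L, n, n, dimnames = list(genes, genes))
  if (ncol(pair_idx)) {
    for (q in seq_len(ncol(pair_idx))) {
      j <- pair_idx[1, q]; k <- pair_idx[2, q]
      pair_col[j, k] <- pair_col[k, j] <- 1L + n + q
    }
  }
  list(G = crossprod(Z), B = crossprod(Z, R), yty = colSums(R^2),
       n_obs = N, dt = data$dt, genes = genes,
       lin_col = lin_col, pair_col = pair_col)
}

ctx_cols <- function(ctx, regulators) {
  h <- length(regulators)
  cols <- 1L
  if (h) {
    cols <- c(cols, ctx$lin_col[regulators])
    if (h >= 2) {
      idx <- utils::combn(h, 2)
      cols <- c(cols, ctx$pair_col[cbind(regulators[idx[1, ]],
                                         regulators[idx[2, ]])])
    }
  }
  unname(cols)
}

# Solve the (small) normal equations; pseudo-inverse fallback yields the
# minimum-norm solution when the design is rank deficient.
solve_normal <- function(Gss, bs) {
  coef <- tryCatch(drop(solve(Gss, bs)), error = function(e) NULL)
  deficient <- is.null(coef)
  if (deficient) coef <- drop(MASS::ginv(Gss) %*% bs)
  list(coef = coef, deficient = deficient)
}

# Minimized SSE on the original scale (squared one-step prediction
# error), i.e. difference-quotient RSS times dt^2.
ctx_sse <- function(ctx, node, regulators) {
  cols <- ctx_cols(ctx, regulators)
  bs <- ctx$B[cols, node]
  fit <- solve_normal(ctx$G[cols, cols, drop = FALSE], bs)
  rss <- max(0, ctx$yty[node] - sum(bs * fit$coef))
  rss * ctx$dt^2
}

#' Fit one gene's dynamics for a given regulator set
#'
#' Estimates the intercept, linear, and pairwise-product coefficients
#' minimizing the sum of squared one-step prediction errors
#' \deqn{S = \sum_t |y_i(t+1) - [y_i(t) + \Delta t \cdot \hat{f}(y(t))]|^2}
#' over all consecutive time-point pairs in all series. The objective is
#' a convex quadratic; the global minimum is returned. Rank-deficient
#' systems (constant trajectories, duplicated regressors) get the
#' minimum-norm solution with a warning; overparameterized fits
#' (`n_params > n_obs`) are permitted with a warning since the caller
#' controls data volume.
#'
#' @inheritParams build_regression_system
#' @return A `dplsq_fit`: fields `node`, `regulators`, `model`
#'   ([node_model()]), `sse` (minimized objective, on the squared
#'   prediction-error scale), `n_obs`, `n_params`.
#' @examples
#' net <- benchmark_network("wnt5a")
#' trial <- run_trial(trial_config(o = 0.1, seed = 1))
#' fit <- fit_node(trial$data, "WNT5A", regulators(net, "WNT5A"))
#' glance(fit)
#' @export
fit_node <- function(data, node, regulators = character()) {
  sys <- build_regression_system(data, node, regulators)
  n_obs <- length(sys$y)
  if (n_obs < 1) stop("no transitions to fit", call. = FALSE)
  h <- length(regulators)
  n_params <- 1L + h + choose(h, 2)
  if (n_params > n_obs) {
    warning("overparameterized fit: ", n_params, " parameters for ",
            n_obs, " observations", call. = FALSE)
  }
  G <- crossprod(sys$X)
  b <- crossprod(sys$X, sys$y)
  sol <- solve_normal(G, b)
  if (sol$deficient) {
    warning("rank-deficient system for node '", node,
            "'; minimum-norm solution returned", call. = FALSE)
  }
  coef <- stats::setNames(sol$coef, colnames(sys$X))
  rss <- max(0, sum(sys$y^2) - sum(b * sol$coef))
  model <- node_model(
    node, regulators, a0 = coef[["(Intercept)"]],
    a_lin = if (h) coef[regulators],
    a_pair = if (h >= 2) coef[pair_labels(regulators)]
  )
  structure(list(node = node, regulators = regulators, model = model,
                 coefficients = coef, sse = rss * data$dt^2,
                 n_obs = n_obs, n_params = n_params),
            class = "dplsq_fit")
}

#' @export
print.dplsq_fit <- function(x, ...) {
  cat("<dplsq_fit> ", x$node, " <- {",
      paste(x$regulators, collapse = ", "), "}, sse = ",
      signif(x$sse, 5), "\n", sep = "")
  invisible(x)
}

#' Tidy a per-gene fit
#'
#' @param x A `dplsq_fit` from [fit_node()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `type`
#'   (intercept/linear/pairwise), `estimate`.
#' @export
tidy.dplsq_fit <- function(x, ...) {
  type <- c("intercept",
            rep("linear", length(x$regulators)),
            rep("pairwise", choose(length(x$regulators), 2)))
  tibble::tibble(term = names(x$coefficients), type = type,
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.dplsq_fit
#' @return `glance()`: a one-row tibble with `sse`, `n_obs`, `n_params`.
#' @export
glance.dplsq_fit <- function(x, ...) {
  tibble::tibble(node = x$node, sse = x$sse, n_obs = x$n_obs,
                 n_params = x$n_params)
}
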