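#' Per-node minimum-SSE edit table
#'
#' For one gene, enumerates every way of deleting `h_j` of its incoming
#' edges and adding `k_j` new incoming edges (from genes that are not the
#' node itself and not already regulators), fits each resulting regulator
#' set by least squares, and records the minimum SSE together with the
#' minimizing edit sets. Infeasible cells — `h_j` over the per-node
#' deletion cap `H`, `k_j` over the addition cap `K`, a resulting
#' in-degree of `n` or more, or no valid combination — carry an `Inf`
#' sentinel so that sums through them stay infinite.
#'
#' Ties within `1e-12` are broken toward the first edit sets in
#' lexicographic order (deletions and additions enumerated over sorted
#' gene names), making results deterministic.
#'
#' @param data A [ts_set()] covering all network genes.
#' @param network A [grn()].
#' @param node Gene name.
#' @param H,K Per-node caps on deletions and additions.
#' @return A `sigma_table`: `sse` is an `(H+1) x (K+1)` matrix indexed by
#'   `[h_j + 1, k_j + 1]`, `deleted` and `added` are parallel list
#'   matrices holding the minimizing regulator names.
#' @export
sigma_table <- function(data, network, node, H = 3, K = 3) {
  ctx <- if (inherits(data, "ts_set")) regression_context(data) else data
  network <- as_grn(network)
  sigma_node(ctx, network, node, H, K)
}

sigma_node <- function(ctx, network, node, H, K) {
  n <- length(network$nodes)
  regs <- regulators(network, node)             # sorted
  cand <- sort(setdiff(network$nodes, c(node, regs)))
  deg <- length(regs)
  sse <- matrix(Inf, H + 1, K + 1)
  deleted <- added <- matrix(vector("list", (H + 1) * (K + 1)),
                             H + 1, K + 1)
  for (hj in 0:H) {
    if (hj > deg) next
    del_sets <- subset_list(regs, hj)
    for (kj in 0:K) {
      new_deg <- deg - hj + kj
      if (new_deg >= n || new_deg < 0 || kj > length(cand)) next
      add_sets <- subset_list(cand, kj)
      best <- Inf
      for (ds in del_sets) {
        kept <- setdiff(regs, ds)
        for (as_ in add_sets) {
          s <- ctx_sse(ctx, node, c(kept, as_))
          if (s < best - 1e-12) {
            best <- s
            deleted[[hj + 1, kj + 1]] <- ds
            added[[hj + 1, kj + 1]] <- as_
          }
        }
      }
      sse[hj + 1, kj + 1] <- best
    }
  }
  structure(list(node = node, sse = sse, deleted = deleted,
                 added = added, H = H, K = K, indegree = deg),
            class = "sigma_table")
}

# all size-r subsets of a sorted vector, in lexicographic order
subset_list <- function(x, r) {
  if (r == 0) return(list(character()))
  if (r > length(x)) return(list())
  utils::combn(x, r, simplify = FALSE)
}

#' Minimum SSE for a single edit count at one node
#'
#' Convenience accessors into [sigma_table()]: `sigma_entry()` for a
#' combined (deletions, additions) pair, `sigma_add()`/`sigma_del()` for
#' addition-only and deletion-only completion.
#'
#' @inheritParams sigma_table
#' @param h_j,k_j Number of incoming edges deleted / added at `node`.
#' @return List with `sse` (scalar, `Inf` when infeasible), `deleted`,
#'   `added` (character vectors of regulator names).
#' @export
sigma_entry <- function(data, network, node, h_j = 0, k_j = 0,
                        H = 3, K = 3) {
  if (h_j > H || k_j > K) {
    return(list(sse = Inf, deleted = NULL, added = NULL))
  }
  tab <- sigma_table(data, network, node, H = H, K = K)
  list(sse = tab$sse[h_j + 1, k_j + 1],
       deleted = tab$deleted[[h_j + 1, k_j + 1]],
       added = tab$added[[h_j + 1, k_j + 1]])
}

#' @rdname sigma_entry
#' @export
sigma_add <- function(data, network, node, k_j, K = 3) {
  sigma_entry(data, network, node, h_j = 0, k_j = k_j, H = 0, K = K)
}

#' @rdname sigma_entry
#' @export
sigma_del <- function(data, network, node, h_j, H = 3) {
  sigma_entry(data, network, node, h_j = h_j, k_j = 0, H = H, K = 0)
}

#' Complete a network under fixed edit budgets
#'
#' Distributes a global budget of `h` edge deletions and `k` edge
#' additions over the genes so that the total sum of squared one-step
#' prediction errors is minimized, by dynamic programming over the
#' per-node edit tables: with `D[h', k', i]` the optimal total SSE using
#' budgets `(h', k')` on the first `i` nodes,
#' \deqn{D[h, k, j+1] = \min_{h'+h''=h,\ k'+k''=k}
#'   \{D[h', k', j] + \sigma_{h'', k'', j+1}\}.}
#' The inner scan only visits `h'' <= H`, `k'' <= K`. The optimum is
#' exact and invariant to node order; traceback reconstructs one optimal
#' edit assignment (lexicographic tie-breaks) and applies it.
#'
#' @param data A [ts_set()] covering all network genes.
#' @param network Initial [grn()] (or edge-list data frame).
#' @param h,k Total number of edge deletions / additions to perform.
#' @param H,K Per-node caps. Defaults 3, enough for moderately regulated
#'   genes while keeping the per-node enumeration polynomial.
#' @return A `dplsq_completion` with fields `completed` ([grn()] or
#'   `NULL` when infeasible), `total_sse`, `feasible`, `edits` (tibble of
#'   per-edge `action`/`from`/`to`), `per_node` (tibble of per-gene edit
#'   counts and SSE), `D` (the DP value array), and the call settings.
#' @examples
#' net <- benchmark_network("wnt5a")
#' trial <- run_trial(trial_config(o = 0.1, k_add = 1, seed = 42))
#' res <- complete_network(trial$data, trial$network_init, h = 0, k = 1)
#' tidy(res)
#' @export
complete_network <- function(data, network, h, k, H = 3, K = 3) {
  stopifnot(h >= 0, k >= 0, H >= 0, K >= 0)
  network <- as_grn(network)
  stopifnot(inherits(data, "ts_set"))
  miss <- setdiff(network$nodes, data$genes)
  if (length(miss)) {
    stop("network gene(s) missing from data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ctx <- regression_context(data)
  nodes <- network$nodes
  n <- length(nodes)
  sig <- lapply(nodes, function(v)
    sigma_node(ctx, network, v, min(H, h), min(K, k)))
  names(sig) <- nodes

  # D[h'+1, k'+1, i]; split arrays record the argmin (h'', k'') per cell
  D <- array(Inf, c(h + 1, k + 1, n))
  Ah <- Ak <- array(NA_integer_, c(h + 1, k + 1, n))
  pad <- function(tab, hmax, kmax) {
    out <- matrix(Inf, hmax + 1, kmax + 1)
    hh <- seq_len(min(nrow(tab$sse), hmax + 1))
    kk <- seq_len(min(ncol(tab$sse), kmax + 1))
    out[hh, kk] <- tab$sse[hh, kk]
    out
  }
  M <- pad(sig[[1]], h, k)
  D[, , 1] <- M
  fh <- row(M) - 1L; fk <- col(M) - 1L
  fh[!is.finite(M)] <- NA_integer_
  fk[!is.finite(M)] <- NA_integer_
  Ah[, , 1] <- fh
  Ak[, , 1] <- fk
  if (n >= 2) {
    for (j in 2:n) {
      sj <- sig[[j]]$sse
      for (hp in 0:h) for (kp in 0:k) {
        best <- Inf; bh <- NA_integer_; bk <- NA_integer_
        for (h2 in 0:min(hp, min(H, h))) for (k2 in 0:min(kp, min(K, k))) {
          s <- sj[h2 + 1, k2 + 1]
          if (!is.finite(s)) next
          prev <- D[hp - h2 + 1, kp - k2 + 1, j - 1]
          if (!is.finite(prev)) next
          val <- prev + s
          if (val < best - 1e-12) {
            best <- val; bh <- h2; bk <- k2
          }
        }
        D[hp + 1, kp + 1, j] <- best
        Ah[hp + 1, kp + 1, j] <- bh
        Ak[hp + 1, kp + 1, j] <- bk
      }
    }
  }

  total <- D[h + 1, k + 1, n]
  settings <- list(h = h, k = k, H = H, K = K)
  if (!is.finite(total)) {
    return(new_completion(network, NULL, Inf, FALSE,
                          empty_edits(), empty_per_node(), D, settings))
  }

  # traceback
  hp <- h; kp <- k
  per_node <- vector("list", n)
  edit_rows <- list()
  for (j in n:1) {
    hj <- Ah[hp + 1, kp + 1, j]; kj <- Ak[hp + 1, kp + 1, j]
    tab <- sig[[j]]
    ds <- tab$deleted[[hj + 1, kj + 1]]
    as_ <- tab$added[[hj + 1, kj + 1]]
    per_node[[j]] <- tibble::tibble(
      node = nodes[j], n_del = hj, n_add = kj,
      sse = tab$sse[hj + 1, kj + 1])
    if (length(ds)) {
      edit_rows[[length(edit_rows) + 1]] <- tibble::tibble(
        node = nodes[j], action = "delete", from = ds, to = nodes[j])
    }
    if (length(as_)) {
      edit_rows[[length(edit_rows) + 1]] <- tibble::tibble(
        node = nodes[j], action = "add", from = as_, to = nodes[j])
    }
    hp <- hp - hj; kp <- kp - kj
  }
  edits <- if (length(edit_rows)) dplyr::bind_rows(edit_rows) else
    empty_edits()
  completed <- apply_edits(network,
                           edits[edits$action == "delete", ],
                           edits[edits$action == "add", ])
  new_completion(network, completed, total, TRUE, edits,
                 dplyr::bind_rows(per_node), D, settings)
}

empty_edits <- function() {
  tibble::tibble(node = character(), action = character(),
                 from = character(), to = character())
}
empty_per_node <- function() {
  tibble::tibble(node = character(), n_del = integer(),
                 n_add = integer(), sse = numeric())
}

new_completion <- function(initial, completed, total_sse, feasible,
                           edits, per_node, D, settings) {
  structure(list(initial = initial, completed = completed,
                 total_sse = total_sse, feasible = feasible,
                 edits = edits, per_node = per_node, D = D,
                 settings = settings),
            class = "dplsq_completion")
}

#' @export
print.dplsq_completion <- function(x, ...) {
  s <- x$settings
  cat("<dplsq_completion> h = ", s$h, ", k = ", s$k,
      " (caps H = ", s$H, ", K = ", s$K, ")\n", sep = "")
  if (x$feasible) {
    cat("  total SSE: ", signif(x$total_sse, 6), "; ",
        nrow(x$edits), " edit(s)\n", sep = "")
  } else {
    cat("  infeasible under the given budgets\n")
  }
  invisible(x)
}

#' Addition-only and deletion-only completion
#'
#' Specializations of [complete_network()]: `complete_by_addition()`
#' spends a budget of `k` edge additions (no deletions) and
#' `complete_by_deletion()` a budget of `h` deletions. Both agree exactly
#' with [complete_network()] under the corresponding zero budget.
#'
#' @inheritParams complete_network
#' @return A `dplsq_completion`.
#' @export
complete_by_addition <- function(data, network, k, K = 3) {
  complete_network(data, network, h = 0, k = k, H = 0, K = K)
}

#' @rdname complete_by_addition
#' @export
complete_by_deletion <- function(data, network, h, H = 3) {
  complete_network(data, network, h = h, k = 0, H = H, K = 0)
}

#' Infer a network from time series alone
#'
#' Runs addition-only completion starting from the edgeless network over
#' the data's genes: with no prior edges, distributing `k` additions is
#' network inference. Choosing `k` equal to the expected edge count and
#' `K` at the expected maximum in-degree recovers networks exactly on
#' clean data.
#'
#' @inheritParams complete_network
#' @param genes Genes to include; defaults to all genes in `data`.
#' @return A `dplsq_completion` whose `completed` network is the
#'   inferred one.
#' @export
infer_network <- function(data, k, K = 3, genes = NULL) {
  stopifnot(inherits(data, "ts_set"))
  if (is.null(genes)) genes <- data$genes
  empty <- grn(NULL, nodes = genes)
  complete_by_addition(data, empty, k = k, K = K)
}

#' Tidy a completion result
#'
#' @param x A `dplsq_completion`.
#' @param ... Unused.
#' @return `tidy()`: the per-edge edit tibble (`node`, `action`, `from`,
#'   `to`). `glance()`: one row with `total_sse`, `n_del`, `n_add`,
#'   `feasible`.
#' @export
tidy.dplsq_completion <- function(x, ...) x$edits

#' @rdname tidy.dplsq_completion
#' @export
glance.dplsq_completion <- function(x, ...) {
  tibble::tibble(total_sse = x$total_sse,
                 n_del = sum(x$edits$action == "delete"),
                 n_add = sum(x$edits$action == "add"),
                 feasible = x$feasible)
}

#' Adjacency view of a completion result
#'
#' Tile plot of the initial vs completed adjacency: kept, added, and
#' deleted edges.
#'
#' @param object A `dplsq_completion`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dplsq_completion <- function(object, ...) {
  if (!object$feasible) stop("nothing to plot: infeasible result",
                             call. = FALSE)
  init <- object$initial$edges
  init$status <- "kept"
  ed <- object$edits
  add <- ed[ed$action == "add", c("from", "to")]
  add$status <- "added"
  del_key <- edge_key(ed$from[ed$action == "delete"],
                      ed$to[ed$action == "delete"])
  init$status[edge_key(init$from, init$to) %in% del_key] <- "deleted"
  df <- dplyr::bind_rows(init, add)
  nodes <- object$initial$nodes
  df$from <- factor(df$from, levels = nodes)
  df$to <- factor(df$to, levels = nodes)
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to,
                                   fill = .data$status)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::scale_y_discrete(drop = FALSE, limits = rev) +
    ggplot2::labs(x = "regulator", y = "target", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
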