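#' Edit accuracy of a completed network
#'
#' Fraction of the `h + k` performed edits that are correct:
#' `(h + k - |E_orig| + |E_orig intersect E_cmpl|) / (h + k)`, clamped to
#' `[0, 1]`. Because the edit budget fixes `|E_cmpl| = |E_orig|`, every
#' missing original edge corresponds to one wrong edit, so the score is 1
#' exactly when all deleted and added edges are correct and 0 when none
#' is.
#'
#' @param e_orig,e_cmpl Original and completed networks ([grn()] or
#'   edge-list data frames).
#' @param h,k Numbers of deleted / added edges; `h + k >= 1`.
#' @return Scalar in `[0, 1]`.
#' @examples
#' net <- benchmark_network("wnt5a")
#' completion_accuracy(net, net, h = 1, k = 1) # 1
#' @export
completion_accuracy <- function(e_orig, e_cmpl, h, k) {
  if (h + k < 1) stop("h + k must be at least 1; use the success flag ",
                      "for zero-budget runs", call. = FALSE)
  a <- as_grn(e_orig)$edges
  b <- as_grn(e_cmpl)$edges
  inter <- sum(edge_key(a$from, a$to) %in% edge_key(b$from, b$to))
  min(1, max(0, (h + k - nrow(a) + inter) / (h + k)))
}

#' Inference accuracy
#'
#' Fraction of the true network's directed edges recovered by an
#' inferred network: `|E_true intersect E_inferred| / |E_true|`.
#'
#' @param e_true,e_inferred True and inferred networks.
#' @return Scalar in `[0, 1]`.
#' @export
inference_accuracy <- function(e_true, e_inferred) {
  a <- as_grn(e_true)$edges
  b <- as_grn(e_inferred)$edges
  if (nrow(a) < 1) stop("true network has no edges", call. = FALSE)
  sum(edge_key(a$from, a$to) %in% edge_key(b$from, b$to)) / nrow(a)
}

#' Success rate over a batch of trials
#'
#' Fraction of trials in which completion restored the original network
#' exactly.
#'
#' @param success Logical vector (or data frame with a `success`
#'   column), one entry per trial.
#' @return Scalar in `[0, 1]`.
#' @export
success_rate <- function(success) {
  if (is.data.frame(success)) success <- success$success
  success <- as.logical(success)
  if (!length(success)) stop("no trials supplied", call. = FALSE)
  mean(success)
}

#' Expected overlap of randomly selected edges
#'
#' Baseline for inference accuracy: when `n_select` edges are picked
#' uniformly without replacement from `n_possible` candidate edges of
#' which `n_true` are real, the expected number of real edges picked is
#' `n_true / n_possible * n_select`.
#'
#' @param n_select Number of edges selected.
#' @param n_possible Number of candidate edges.
#' @param n_true Number of true edges among the candidates.
#' @return Expected count of correctly selected edges.
#' @examples
#' random_baseline(25, 90, 25) # 6.944...
#' @export
random_baseline <- function(n_select, n_possible, n_true) {
  stopifnot(n_possible >= n_select, n_select >= 0, n_possible >= n_true)
  n_true / n_possible * n_select
}

#' Score one completion trial
#'
#' @param trial A trial bundle from [run_trial()].
#' @param result A `dplsq_completion` from [complete_network()] on the
#'   trial's initial network.
#' @return One-row tibble: `accuracy`, `success`, `total_sse`,
#'   `feasible`.
#' @export
evaluate_trial <- function(trial, result) {
  h <- trial$config$h_del; k <- trial$config$k_add
  if (!result$feasible) {
    return(tibble::tibble(accuracy = 0, success = FALSE,
                          total_sse = Inf, feasible = FALSE))
  }
  acc <- if (h + k >= 1) {
    completion_accuracy(trial$network_true, result$completed, h, k)
  } else {
    as.numeric(same_edges(trial$network_true, result$completed))
  }
  tibble::tibble(
    accuracy = acc,
    success = same_edges(trial$network_true, result$completed),
    total_sse = result$total_sse, feasible = TRUE)
}
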