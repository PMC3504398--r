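#' Set of expression time series sharing one time step
#'
#' Observed expression trajectories are held as a list of numeric matrices
#' (rows = time points, columns = genes), all with identical gene columns
#' and one shared uniform time step `dt`. Short series from many initial
#' conditions are the typical shape: a single long series is prone to
#' overfitting the per-gene regression.
#'
#' @param series A numeric matrix with gene column names, a data frame, or
#'   a list of such; a column named `t` is dropped (it is the 0-based time
#'   index, implied by row order).
#' @param dt Uniform time step between consecutive rows (time units).
#' @return A `ts_set` with elements `series` (list of matrices), `dt`, and
#'   `genes`.
#' @examples
#' m <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("A", "B")))
#' ts_set(m, dt = 0.2)
#' @export
ts_set <- function(series, dt) {
  if (!is.list(series) || is.data.frame(series)) series <- list(series)
  if (!length(series)) stop("`series` is empty", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  series <- lapply(series, function(s) {
    if (is.data.frame(s)) {
      s <- s[, setdiff(names(s), "t"), drop = FALSE]
      s <- as.matrix(s)
    }
    if (!is.matrix(s) || !is.numeric(s)) {
      stop("each series must be a numeric matrix or data frame",
           call. = FALSE)
    }
    if (is.null(colnames(s))) {
      stop("series columns must be named by gene", call. = FALSE)
    }
    if (nrow(s) < 2) stop("each series needs at least 2 time points",
                          call. = FALSE)
    s
  })
  genes <- colnames(series[[1]])
  for (s in series[-1]) {
    if (!identical(colnames(s), genes)) {
      stop("all series must share identical gene columns", call. = FALSE)
    }
  }
  structure(list(series = series, dt = dt, genes = genes),
            class = "ts_set")
}

#' @export
print.ts_set <- function(x, ...) {
  cat("<ts_set> ", length(x$series), " series, ",
      paste(vapply(x$series, nrow, 0L), collapse = "/"),
      " time points, ", length(x$genes), " genes, dt = ", x$dt, "\n",
      sep = "")
  invisible(x)
}

#' @describeIn ts_set Number of transitions (consecutive time-point pairs)
#'   summed over series.
#' @param x A `ts_set`.
#' @export
n_transitions <- function(x) {
  stopifnot(inherits(x, "ts_set"))
  sum(vapply(x$series, nrow, 0L) - 1L)
}

#' @export
as_tibble.ts_set <- function(x, ...) {
  purrr::imap_dfr(x$series, function(s, i) {
    out <- tibble::as_tibble(s)
    out$series <- i
    out$t <- seq_len(nrow(s)) - 1L
    tidyr::pivot_longer(out, cols = -c("series", "t"),
                        names_to = "gene", values_to = "value")
  })
}

#' Plot expression trajectories
#'
#' One facet per gene, one line per series.
#'
#' @param object A [ts_set()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ts_set <- function(object, ...) {
  df <- as_tibble(object)
  df$time <- df$t * object$dt
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   group = .data$series)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene)) +
    ggplot2::labs(x = "time", y = "expression")
}
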