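#' Directed gene regulatory network
#'
#' A `grn` is a lightweight container for a directed network over named
#' genes: an ordered character vector of node names plus a tibble of
#' directed edges (`from`, `to`). Self-loops are disallowed; regulation of
#' a gene by itself is outside the model class.
#'
#' @param edges A data frame with character columns `from` and `to`, one
#'   row per directed edge, or `NULL` for an edgeless network.
#' @param nodes Character vector of node names. Defaults to the sorted
#'   union of edge endpoints. Must cover every endpoint; extra names give
#'   isolated nodes. Order is kept as given and is stable thereafter
#'   (completion results do not depend on it).
#' @return A `grn` object.
#' @examples
#' net <- grn(tibble::tibble(from = c("A", "B"), to = c("B", "C")))
#' indegree(net)
#' @export
grn <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character())
  }
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    stop("`edges` must have columns `from` and `to`", call. = FALSE)
  }
  edges <- dplyr::distinct(edges[, c("from", "to")])
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) {
    bad <- edges$from[edges$from == edges$to][1]
    stop("self-loop on node '", bad, "' is not allowed", call. = FALSE)
  }
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edges$from, edges$to)))
  }
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  missing <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(missing)) {
    stop("edge endpoints not in `nodes`: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("<grn> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' @rdname grn
#' @param x An object to convert or query.
#' @export
as_grn <- function(x, ...) UseMethod("as_grn")

#' @export
as_grn.grn <- function(x, ...) x

#' @export
as_grn.data.frame <- function(x, nodes = NULL, ...) grn(x, nodes = nodes)

#' @export
as_tibble.grn <- function(x, ...) x$edges

#' Regulators (incoming neighbours) of a gene
#'
#' @param network A [grn()].
#' @param node A node name.
#' @return Character vector of genes with an edge into `node`, in sorted
#'   order.
#' @export
regulators <- function(network, node) {
  network <- as_grn(network)
  if (!node %in% network$nodes) {
    stop("unknown node '", node, "'", call. = FALSE)
  }
  sort(network$edges$from[network$edges$to == node])
}

#' In-degree of every node
#'
#' @param network A [grn()].
#' @return Named integer vector in node order.
#' @export
indegree <- function(network) {
  network <- as_grn(network)
  counts <- table(factor(network$edges$to, levels = network$nodes))
  stats::setNames(as.integer(counts), network$nodes)
}

edge_key <- function(from, to) paste(from, to, sep = "\r")

#' Set equality of two networks' edge sets
#'
#' @param a,b Networks ([grn()] or edge-list data frames).
#' @return `TRUE` when the directed edge sets are identical.
#' @export
same_edges <- function(a, b) {
  a <- as_grn(a); b <- as_grn(b)
  setequal(edge_key(a$edges$from, a$edges$to),
           edge_key(b$edges$from, b$edges$to))
}

# apply a per-node edit record (deleted/added edge tibbles) to a network
apply_edits <- function(network, deleted, added) {
  edges <- network$edges
  if (nrow(deleted)) {
    keep <- !(edge_key(edges$from, edges$to) %in%
                edge_key(deleted$from, deleted$to))
    edges <- edges[keep, ]
  }
  if (nrow(added)) {
    edges <- dplyr::bind_rows(edges, added[, c("from", "to")])
  }
  grn(edges, nodes = network$nodes)
}
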