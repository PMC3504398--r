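#' Read and write directed networks
#'
#' Networks are exchanged as 2-column TSV (`source TAB target`, no
#' header) or SIF (`source  relation  target`). Rows encoding self-loops
#' are rejected. Isolated nodes can be declared with `nodes`.
#'
#' @param path File path.
#' @param format `"tsv"` or `"sif"`; default guessed from the file
#'   extension (`.sif` means SIF, anything else TSV).
#' @param nodes Optional character vector of node names to include even
#'   when isolated (must cover all endpoints found in the file).
#' @return A [grn()].
#' @export
read_network <- function(path, format = NULL, nodes = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif"
      else "tsv"
  }
  format <- match.arg(format, c("tsv", "sif"))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(grn(NULL, nodes = nodes))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  want <- if (format == "tsv") 2L else 3L
  bad <- which(vapply(parts, length, 0L) != want)
  if (length(bad)) {
    stop("malformed ", format, " row at line ", bad[1], ": '",
         lines[bad[1]], "'", call. = FALSE)
  }
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", want)
  loops <- which(from == to)
  if (length(loops)) {
    stop("self-loop at line ", loops[1], " ('", from[loops[1]],
         "'): self-loops are not allowed", call. = FALSE)
  }
  grn(tibble::tibble(from = from, to = to), nodes = nodes)
}

#' @rdname read_network
#' @param network A [grn()] (or edge-list data frame) to write.
#' @param relation Relation label used in SIF output.
#' @export
write_network <- function(network, path, format = NULL,
                          relation = "regulates") {
  network <- as_grn(network)
  if (is.null(format)) {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif"
      else "tsv"
  }
  format <- match.arg(format, c("tsv", "sif"))
  e <- network$edges
  lines <- if (format == "tsv") paste(e$from, e$to, sep = "\t") else
    paste(e$from, relation, e$to, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read expression time series from TSV files
#'
#' Each file is one series: a header row of gene names (an optional
#' leading `t` column holds the 0-based time index and is dropped), then
#' one row per time point. A comment line `# dt=<value>` may declare the
#' time step; otherwise `dt` must be given (it is never inferred from
#' row counts). Missing cells (empty or `NA`) are linearly interpolated
#' within their column when `interpolate_missing = TRUE`; rows that are
#' missing at the boundary of any column are dropped (with a message)
#' since they cannot be interpolated.
#'
#' @param paths Character vector of file paths, one per series.
#' @param dt Time step; required unless every file declares it.
#' @param interpolate_missing Fill interior missing values by linear
#'   interpolation on the uniform time grid.
#' @return A [ts_set()].
#' @export
read_timeseries <- function(paths, dt = NULL,
                            interpolate_missing = FALSE) {
  stopifnot(length(paths) >= 1)
  series <- lapply(paths, function(p) {
    lines <- readLines(p)
    m <- regmatches(lines, regexpr("^#\\s*dt\\s*=\\s*([0-9.eE+-]+)",
                                   lines))
    file_dt <- if (length(m)) {
      as.numeric(sub("^#\\s*dt\\s*=\\s*", "", m[1]))
    } else NULL
    df <- readr::read_tsv(I(lines[!grepl("^#", lines)]),
                          col_types = readr::cols(
                            .default = readr::col_double()),
                          progress = FALSE)
    if (any(vapply(df, function(x) all(is.na(x)), TRUE))) {
      stop("non-numeric column in ", p, call. = FALSE)
    }
    df <- df[, setdiff(names(df), "t"), drop = FALSE]
    mat <- as.matrix(df)
    if (anyNA(mat)) {
      if (!interpolate_missing) {
        stop("missing values in ", p,
             " (set interpolate_missing = TRUE)", call. = FALSE)
      }
      mat <- fill_missing(mat, p)
    }
    list(mat = mat, dt = file_dt)
  })
  dts <- unique(unlist(lapply(series, `[[`, "dt")))
  if (length(dts) > 1) stop("conflicting dt declarations across files",
                            call. = FALSE)
  if (is.null(dt)) {
    if (!length(dts)) stop("`dt` not given and not declared in files",
                           call. = FALSE)
    dt <- dts
  }
  ts_set(lapply(series, `[[`, "mat"), dt = dt)
}

# interpolate interior NAs per column; drop leading/trailing rows that
# any column leaves NA
fill_missing <- function(mat, label) {
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    if (anyNA(x) && sum(!is.na(x)) >= 2) {
      idx <- seq_along(x)
      mat[, j] <- stats::approx(idx[!is.na(x)], x[!is.na(x)],
                                xout = idx, rule = 1)$y
    }
  }
  bad <- apply(mat, 1, anyNA)
  drop_head <- cumprod(bad)
  drop_tail <- rev(cumprod(rev(bad)))
  keep <- !(drop_head | drop_tail)
  if (any(bad & keep)) {
    stop("column with fewer than 2 observed values in ", label,
         call. = FALSE)
  }
  if (any(!keep)) {
    message("dropped ", sum(!keep),
            " boundary row(s) with missing values in ", label)
  }
  mat[keep, , drop = FALSE]
}

#' @rdname read_timeseries
#' @param data A [ts_set()] to write, one TSV per series.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are `<prefix><i>.tsv`.
#' @return `write_timeseries()`: the written paths, invisibly.
#' @export
write_timeseries <- function(data, dir, prefix = "series") {
  stopifnot(inherits(data, "ts_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(data$series), function(i) {
    p <- file.path(dir, sprintf("%s%d.tsv", prefix, i))
    s <- data$series[[i]]
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(sprintf("# dt=%g", data$dt), con)
    writeLines(paste(c("t", colnames(s)), collapse = "\t"), con)
    utils::write.table(cbind(t = seq_len(nrow(s)) - 1L, s), con,
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    p
  }, "")
  invisible(paths)
}
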