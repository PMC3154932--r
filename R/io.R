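# Readers and writers: plain-text series, TSV weighted edge lists, adjacency
# matrix dumps and JSON partition sidecars.  All writes are atomic
# (temp file + rename).

#' Read a time series from a text file
#'
#' Accepts one value per line or a single-column CSV; a single non-numeric
#' first row is treated as a header.  `#` comments are stripped; blank lines
#' ignored; order preserved.
#'
#' @param path file path.
#' @return Numeric vector.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", raw)
  tok <- vapply(strsplit(stripped, ","), function(f) {
    f <- trimws(f)
    f <- f[nzchar(f)]
    if (length(f) == 0L) "" else if (length(f) == 1L) f else NA_character_
  }, character(1))
  if (anyNA(tok))
    stop(sprintf("line %d: expected a single value per line",
                 which(is.na(tok))[1L]))
  keep <- which(nzchar(tok))
  if (length(keep) == 0L) stop("empty series file")
  vals <- suppressWarnings(as.numeric(tok[keep]))
  if (is.na(vals[1L]) && length(keep) > 1L) {  # header row
    keep <- keep[-1L]
    vals <- vals[-1L]
  }
  bad <- which(is.na(vals))
  if (length(bad))
    stop(sprintf("line %d: non-numeric value '%s'", keep[bad[1L]],
                 tok[keep[bad[1L]]]))
  if (length(vals) == 0L) stop("empty series file")
  vals
}

#' Write a time series to a text file
#'
#' One value per line, 17 significant digits (lossless for doubles), written
#' atomically.
#'
#' @param series numeric vector.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_series <- function(series, path) {
  atomic_write_lines(fmt_num(series), path)
  invisible(path)
}

#' Read a network from a TSV edge list
#'
#' Lines are `source<TAB>target[<TAB>weight]`; a missing weight column means
#' weight 1 (allowed only with `undirected = TRUE`, the unweighted pair-list
#' form, which is symmetrized).  Node ids may be arbitrary labels; they are
#' remapped to dense 1-based indices (numeric labels in numeric order, others
#' lexicographic) and the mapping is kept in the dimnames.
#'
#' @param path file path.
#' @param undirected symmetrize the input (each listed edge becomes two arcs).
#' @return A square numeric adjacency matrix with the original labels as
#'   dimnames.
#' @export
read_network <- function(path, undirected = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   colClasses = "character", blank.lines.skip = TRUE)
  if (ncol(df) == 2L) {
    if (!undirected)
      stop("two-column (unweighted) edge lists require undirected = TRUE")
    df$V3 <- "1"
  }
  if (ncol(df) < 3L) stop("edge list needs 2 or 3 tab-separated columns")
  w <- suppressWarnings(as.numeric(df[[3L]]))
  if (anyNA(w)) stop(sprintf("non-numeric weight on row %d", which(is.na(w))[1L]))
  if (any(w < 0)) stop(sprintf("negative weight on row %d", which(w < 0)[1L]))
  ids <- unique(c(df[[1L]], df[[2L]]))
  num <- suppressWarnings(as.numeric(ids))
  labels <- if (!anyNA(num)) ids[order(num)] else sort(ids)
  i <- match(df[[1L]], labels)
  j <- match(df[[2L]], labels)
  key <- if (undirected) paste(pmin(i, j), pmax(i, j)) else paste(i, j)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("duplicate arc %s -> %s", df[d, 1L], df[d, 2L]))
  }
  N <- length(labels)
  A <- matrix(0, N, N, dimnames = list(labels, labels))
  A[cbind(i, j)] <- w
  if (undirected) A[cbind(j, i)] <- w
  A
}

#' Write a network as a TSV weighted edge list
#'
#' One line `source<TAB>target<TAB>weight` per nonzero arc, weights at 17
#' significant digits, rows in row-major node order, written atomically.
#' Labels default to the matrix dimnames, else 0-based integer ids (matching
#' the on-disk convention of networks the package generates).
#'
#' @param W a [markov_network] or square matrix.
#' @param path output path.
#' @param labels optional node labels.
#' @return The path, invisibly.
#' @export
write_network <- function(W, path, labels = NULL) {
  W <- as_weight_matrix(W)
  if (is.null(labels))
    labels <- if (!is.null(rownames(W))) rownames(W)
              else as.character(seq_len(nrow(W)) - 1L)
  nz <- which(t(W) != 0, arr.ind = TRUE)    # transpose: row-major order
  lines <- sprintf("%s\t%s\t%s", labels[nz[, 2L]], labels[nz[, 1L]],
                   fmt_num(t(W)[nz]))
  atomic_write_lines(lines, path)
  invisible(path)
}

#' Write / read a quantile partition sidecar (JSON)
#'
#' Persists the bin boundaries and occupancy of a [quantile_partition] so an
#' inverse map run in another process can emit values on the original scale.
#'
#' @param partition a [quantile_partition].
#' @param path file path.
#' @return `write_partition` returns the path invisibly; `read_partition`
#'   returns a [quantile_partition].
#' @export
write_partition <- function(partition, path) {
  if (!inherits(partition, "quantile_partition"))
    stop("expected a quantile_partition")
  json <- jsonlite::toJSON(list(Q = partition$Q,
                                boundaries = partition$boundaries,
                                occupancy = partition$occupancy),
                           digits = NA, auto_unbox = TRUE)
  atomic_write_lines(json, path)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  obj <- jsonlite::fromJSON(path)
  quantile_partition(obj$Q, obj$boundaries, obj$occupancy)
}
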