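#' Read an omic matrix from a delimited text file
#'
#' Reads a TSV or CSV file with a header row and a first column of
#' identifiers. The delimiter is taken from the file extension (`.csv` is
#' comma, anything else tab) unless given explicitly. Matrices stored with
#' features as rows are transposed so that the returned matrix always has
#' samples as rows.
#'
#' @param path file path.
#' @param orientation `"samples_as_rows"` (default) or `"features_as_rows"`.
#' @param sep field delimiter; `NULL` (default) auto-detects.
#' @param missing_token string treated as missing (kept as `NA`; see
#'   [impute_mode()]); any other non-numeric cell is an error.
#' @return A validated omic matrix (samples as rows).
#' @seealso [omic_matrix()], [read_sample_labels()]
#' @export
read_omic_matrix <- function(path,
                             orientation = c("samples_as_rows",
                                             "features_as_rows"),
                             sep = NULL, missing_token = "NA") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          na.strings = missing_token, comment.char = "",
                          quote = "\"", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("parse error: fewer than 2 columns in ", path)
  ids <- df[[1L]]
  feat <- names(df)[-1L]   # before subsetting: [.data.frame deduplicates
  body <- df[-1L]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(df))))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(df))
  bad <- which(is.na(vals) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("parse error: non-numeric cell at row ", ids[bad[1L, 1L]],
         ", column ", feat[bad[1L, 2L]])
  rownames(vals) <- ids
  colnames(vals) <- feat
  if (orientation == "features_as_rows") vals <- t(vals)
  validate_omic_matrix(vals, check_finite = !anyNA(vals))
  vals
}

#' Read sample labels from a two-column table
#'
#' @param path path to a delimited file with columns sample id and group
#'   (header optional; detected from whether the second field of the first
#'   line repeats later as a group).
#' @param sep delimiter; `NULL` auto-detects from the extension.
#' @param header logical; does the file have a header line?
#' @return Labels as produced by [sample_labels()].
#' @export
read_sample_labels <- function(path, sep = NULL, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs two columns (sample, group)")
  sample_labels(df[[2L]], sample_ids = df[[1L]])
}

#' Write network tables for Cytoscape
#'
#' Writes the two tables needed to draw the network in a graph visualizer:
#' an edge table (`source`, `target`, `weight`, `sign`) and a node table
#' (`feature`, `loading`, `group`, `color`, `degree`). Edges are sorted by
#' decreasing absolute weight (ties broken by the lexicographic endpoint
#' pair) so output is deterministic and diffable.
#'
#' @param net a network as returned by [threshold_network()] and friends.
#' @param out_dir output directory (created if needed).
#' @param prefix optional file-name prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_network_tables <- function(net, out_dir, prefix = "") {
  stopifnot(inherits(net, "pccorr_network"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  edge_path <- file.path(out_dir, paste0(prefix, "edges.tsv"))
  node_path <- file.path(out_dir, paste0(prefix, "nodes.tsv"))
  edges <- net$edges
  nodes <- net$nodes
  if (nrow(edges) == 0L)
    warning("network is empty; writing header-only tables")
  if (nrow(edges) > 0L) {
    ord <- order(-abs(edges$weight), edges$source, edges$target)
    edges <- edges[ord, , drop = FALSE]
    edges$weight <- formatC(edges$weight, digits = 8, format = "g")
  }
  if (nrow(nodes) > 0L) {
    nodes <- nodes[order(nodes$feature), , drop = FALSE]
    nodes$loading <- formatC(nodes$loading, digits = 8, format = "g")
  }
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges = edge_path, nodes = node_path))
}

#' Read back network tables written by [write_network_tables()]
#'
#' @param out_dir directory holding the tables.
#' @param prefix file-name prefix used when writing.
#' @return A `pccorr_network` object (metadata not restored).
#' @export
read_network_tables <- function(out_dir, prefix = "") {
  edges <- utils::read.table(file.path(out_dir, paste0(prefix, "edges.tsv")),
                             header = TRUE, sep = "\t", comment.char = "",
                             stringsAsFactors = FALSE)
  nodes <- utils::read.table(file.path(out_dir, paste0(prefix, "nodes.tsv")),
                             header = TRUE, sep = "\t", comment.char = "",
                             colClasses = c(feature = "character"),
                             stringsAsFactors = FALSE)
  new_network(edges, nodes, metadata = list(source = "file"))
}

new_network <- function(edges, nodes, metadata = list(), exists = TRUE,
                        reason = NULL) {
  structure(list(edges = edges, nodes = nodes, metadata = metadata,
                 exists = exists, reason = reason),
            class = "pccorr_network")
}

empty_edges <- function() {
  data.frame(source = character(), target = character(),
             weight = numeric(), sign = character(),
             stringsAsFactors = FALSE)
}

empty_nodes <- function() {
  data.frame(feature = character(), loading = numeric(),
             group = character(), color = character(), degree = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.pccorr_network <- function(x, ...) {
  if (!isTRUE(x$exists)) {
    cat("<no network>", if (!is.null(x$reason)) paste0(" (", x$reason, ")"),
        "\n", sep = "")
    return(invisible(x))
  }
  meta <- x$metadata
  cat(sprintf("pccorr network: %d nodes, %d edges", nrow(x$nodes),
              nrow(x$edges)))
  if (!is.null(meta$cutoff)) cat(sprintf(" (cut-off %.3g)", meta$cutoff))
  if (!is.null(meta$method)) cat(sprintf(" [%s]", meta$method))
  cat("\n")
  invisible(x)
}

#' Canonical unordered edge keys
#'
#' Collapses an edge table to `"a|b"` strings with the endpoints in
#' lexicographic order, the form used for all set comparisons of edges.
#'
#' @param edges an edge data frame with `source` and `target` columns
#'   (e.g. `net$edges`).
#' @return Character vector of keys, one per edge row.
#' @export
edge_keys <- function(edges) {
  if (nrow(edges) == 0L) return(character())
  paste(pmin(edges$source, edges$target),
        pmax(edges$source, edges$target), sep = "|")
}
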