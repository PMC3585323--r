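# Readers for the common interchange formats. Node identifiers are opaque
# strings throughout; any weights found are only used for presence/absence.

#' Read a directed edge list from CSV or TSV
#'
#' Expects a header row with columns `source,target` or `from,to` (an
#' optional third `weight` column is kept and binarized downstream).
#'
#' @param path File path; the delimiter is taken from the extension
#'   (`.tsv`/`.tab` means tab) unless `delim` is given.
#' @param delim Optional field delimiter override.
#' @return A tibble with columns `from`, `to` (and `weight` if present).
#' @export
read_edgelist <- function(path, delim = NULL) {
  delim <- delim %||%
    (if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ",")
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  nm <- tolower(names(df))
  from_col <- match(TRUE, nm %in% c("from", "source"))
  to_col <- match(TRUE, nm %in% c("to", "target"))
  if (is.na(from_col) || is.na(to_col)) {
    stop("edge list needs source/target (or from/to) columns: ", path)
  }
  out <- tibble(from = as.character(df[[from_col]]),
                to = as.character(df[[to_col]]))
  w <- match("weight", nm)
  if (!is.na(w)) out$weight <- as.numeric(df[[w]])
  out
}

#' Read a directed adjacency matrix from CSV
#'
#' Square CSV with node identifiers in the first row and first column;
#' any nonzero entry is an edge.
#'
#' @param path File path.
#' @return A list with `edges` (tibble `from`, `to`) and `nodes` (character
#'   vector, in file order).
#' @export
read_adjacency <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  nodes <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(M) != ncol(M) || !identical(nodes, colnames(M))) {
    stop("adjacency CSV must be square with matching row/column node ids: ",
         path)
  }
  hit <- which(M != 0, arr.ind = TRUE)
  list(edges = tibble(from = nodes[hit[, 1]], to = nodes[hit[, 2]]),
       nodes = nodes)
}

#' Read a directed graph from GraphML
#'
#' Edge weights and other attributes are ignored (with a warning when
#' weights are present): only presence and direction of edges are used.
#'
#' @param path File path.
#' @return A list with `edges` (tibble `from`, `to`) and `nodes`.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (!igraph::is_directed(g)) stop("GraphML graph must be directed: ", path)
  if ("weight" %in% igraph::edge_attr_names(g)) {
    warning("GraphML edge weights ignored; only presence/direction used")
  }
  nodes <- igraph::vertex_attr(g, "name") %||%
    as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  list(edges = tibble(from = nodes[el[, 1]], to = nodes[el[, 2]]),
       nodes = nodes)
}

#' Read a network in any supported format
#'
#' @param path File path.
#' @param format `"edgelist"`, `"adjacency"` or `"graphml"`; the default
#'   guesses from the extension.
#' @return A list with `edges` and `nodes` (`nodes` is `NULL` for edge lists
#'   without a companion node file).
#' @export
read_network <- function(path, format = c("auto", "edgelist", "adjacency",
                                          "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
              else "edgelist"
  }
  switch(format,
    edgelist = list(edges = read_edgelist(path), nodes = NULL),
    adjacency = read_adjacency(path),
    graphml = read_graphml(path)
  )
}

#' Read a node list (one identifier per line)
#'
#' @param path File path.
#' @return Character vector of node identifiers.
#' @export
read_nodes <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}
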