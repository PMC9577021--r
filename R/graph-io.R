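#' Clean a protein-protein interaction edge list
#'
#' Normalizes a two-column edge table into the canonical undirected form used
#' throughout the package: self-interactions are dropped, duplicate and
#' reversed-duplicate records collapse to a single undirected edge, and each
#' edge is stored with its endpoints in lexicographic order. Protein IDs are
#' opaque case-sensitive strings; no normalization is applied.
#'
#' @param edges A data frame whose first two columns are protein IDs (any
#'   further columns are ignored, as in DIP-style multi-column exports).
#' @return A tibble with columns `protein_a`, `protein_b` (one row per
#'   undirected edge, `protein_a < protein_b`, sorted), carrying attributes
#'   `n_self_loops` and `n_duplicates` with the counts of dropped records.
#' @examples
#' ppi_edges(data.frame(a = c("A", "B", "C", "A"), b = c("B", "A", "C", "B")))
#' @export
ppi_edges <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) {
    stop("edge table needs at least two ID columns", call. = FALSE)
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (length(a) == 0) stop("empty edge list", call. = FALSE)
  bad <- is.na(a) | is.na(b) | a == "" | b == ""
  if (any(bad)) {
    stop("malformed edge record at line ", which(bad)[1], call. = FALSE)
  }
  self <- a == b
  lo <- pmin(a[!self], b[!self])
  hi <- pmax(a[!self], b[!self])
  key <- paste0(lo, "\r", hi)
  dup <- duplicated(key)
  out <- tibble::tibble(protein_a = lo[!dup], protein_b = hi[!dup])
  out <- dplyr::arrange(out, .data$protein_a, .data$protein_b)
  attr(out, "n_self_loops") <- sum(self)
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Read a PPI edge list from a DIP-style TSV file
#'
#' Lines starting with `#` are comments; the first two fields of each
#' remaining line are taken as the interacting protein IDs. The result is
#' cleaned with [ppi_edges()].
#'
#' @param path Path to the edge-list file.
#' @param delim Field delimiter (default tab).
#' @return A tibble as returned by [ppi_edges()].
#' @export
read_ppi_edges <- function(path, delim = "\t") {
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty edge-list file: ", path, call. = FALSE)
  parts <- strsplit(lines, delim, fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2)) {
    stop("malformed edge-list line ", which(keep)[which(nfield < 2)[1]],
         " in ", path, call. = FALSE)
  }
  ppi_edges(data.frame(
    protein_a = vapply(parts, `[[`, "", 1L),
    protein_b = vapply(parts, `[[`, "", 2L)
  ))
}

#' Write a PPI edge list to a TSV file
#'
#' @param edges Edge table (cleaned with [ppi_edges()] if necessary).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi_edges <- function(edges, path) {
  edges <- ppi_edges(edges)
  readr::write_tsv(edges, path, col_names = FALSE)
  invisible(path)
}

#' Build the undirected PPI graph object
#'
#' Wraps the cleaned edge list in an igraph graph plus a neighbor index with a
#' deterministic lexicographic node order, so every downstream ranking is
#' reproducible. Isolated proteins can be kept by passing them in `nodes`.
#'
#' @param edges Edge table (data frame, first two columns are protein IDs).
#' @param nodes Optional character vector of node IDs to include even if they
#'   appear in no edge.
#' @return An object of class `ppi_graph` with elements `graph` (igraph),
#'   `nodes` (sorted IDs), `edges` (tibble), `adj` (named list of sorted
#'   neighbor vectors) and `degree` (named integer).
#' @export
ppi_graph <- function(edges, nodes = NULL) {
  edges <- ppi_edges(edges)
  ids <- sort(unique(c(edges$protein_a, edges$protein_b, as.character(nodes))))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = ids)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, function(v) sort(names(v)))
  names(adj) <- ids
  structure(
    list(
      graph = g,
      nodes = ids,
      edges = edges,
      adj = adj,
      degree = vapply(adj, length, 0L)
    ),
    class = "ppi_graph"
  )
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("<ppi_graph> ", length(x$nodes), " proteins, ",
      nrow(x$edges), " interactions\n", sep = "")
  invisible(x)
}

#' Coerce to a `ppi_graph`
#'
#' @param x A `ppi_graph`, or an edge-list data frame.
#' @param ... Passed to [ppi_graph()].
#' @return A `ppi_graph`.
#' @export
as_ppi_graph <- function(x, ...) {
  if (inherits(x, "ppi_graph")) x else ppi_graph(x, ...)
}

check_node <- function(graph, i) {
  if (!i %in% graph$nodes) stop("unknown protein: ", i, call. = FALSE)
}

check_edge <- function(graph, i, j) {
  check_node(graph, i)
  check_node(graph, j)
  if (!j %in% graph$adj[[i]]) {
    stop("(", i, ", ", j, ") is not an edge of the network", call. = FALSE)
  }
}

#' Number of triangles through an edge
#'
#' Counts the triangles containing both endpoints of an interaction, i.e. the
#' size of the common neighborhood |N(i) \eqn{\cap} N(j)|. Symmetric in (i, j).
#'
#' @param graph A `ppi_graph` or edge-list data frame.
#' @param i,j Endpoint protein IDs; `{i, j}` must be an edge.
#' @return Integer triangle count.
#' @export
triangle_count <- function(graph, i, j) {
  graph <- as_ppi_graph(graph)
  check_edge(graph, i, j)
  length(intersect(graph$adj[[i]], graph$adj[[j]]))
}

#' Local clustering coefficient of a protein
#'
#' C(j) = 2 E_j / (d(j) (d(j) - 1)) where E_j is the number of distinct edges
#' among the neighbors of j. Defined as 0 for proteins of degree 0 or 1.
#'
#' @param graph A `ppi_graph` or edge-list data frame.
#' @param j Protein ID.
#' @return Real in \[0, 1\].
#' @export
clustering_coefficient <- function(graph, j) {
  graph <- as_ppi_graph(graph)
  check_node(graph, j)
  d <- graph$degree[[j]]
  if (d <= 1) return(0)
  nb <- graph$adj[[j]]
  e_j <- sum(vapply(nb, function(u) {
    sum(graph$adj[[u]] %in% nb)
  }, 0)) / 2
  2 * e_j / (d * (d - 1))
}

#' Edge clustering coefficient
#'
#' ECC(i, j) = T(i, j) / min(d(i) - 1, d(j) - 1), the triangle count through
#' the edge normalized by the smaller endpoint degree minus one. When either
#' endpoint has degree 1 the edge can be in no triangle and ECC is defined as
#' 0. Symmetric in (i, j).
#'
#' @inheritParams triangle_count
#' @return Real \eqn{\ge} 0.
#' @export
edge_clustering_coefficient <- function(graph, i, j) {
  graph <- as_ppi_graph(graph)
  check_edge(graph, i, j)
  denom <- min(graph$degree[[i]], graph$degree[[j]]) - 1L
  if (denom <= 0) return(0)
  triangle_count(graph, i, j) / denom
}

# Per-edge table of triangle counts and ECC values, computed once; used by the
# feature functions that sum over incident edges.
ecc_table <- function(graph) {
  graph <- as_ppi_graph(graph)
  e <- graph$edges
  tri <- mapply(function(a, b) {
    length(intersect(graph$adj[[a]], graph$adj[[b]]))
  }, e$protein_a, e$protein_b, USE.NAMES = FALSE)
  denom <- pmin(graph$degree[e$protein_a], graph$degree[e$protein_b]) - 1L
  ecc <- ifelse(denom > 0, tri / denom, 0)
  tibble::tibble(
    protein_a = e$protein_a, protein_b = e$protein_b,
    triangles = as.integer(tri), ecc = ecc
  )
}
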