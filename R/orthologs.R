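#' Read a human-yeast ortholog table
#'
#' TSV of `human_gene<TAB>yeast_gene` pairs (Homologene-style export), `#`
#' comments allowed. Duplicate pairs collapse; many-to-many orthology is
#' preserved.
#'
#' @param path Path to the table file.
#' @return A tibble of class `ortholog_table` with columns `human` and
#'   `yeast`.
#' @export
read_ortholog_table <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty ortholog table: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) {
    stop("malformed ortholog line ", which(keep)[which(bad)[1]], " in ", path,
         call. = FALSE)
  }
  ortholog_table(tibble::tibble(
    human = vapply(parts, `[[`, "", 1L),
    yeast = vapply(parts, `[[`, "", 2L)
  ))
}

#' Build an ortholog table from a data frame
#'
#' @param pairs Data frame whose first two columns are human and yeast gene
#'   IDs.
#' @return A deduplicated tibble of class `ortholog_table` with columns
#'   `human` and `yeast`, sorted.
#' @export
ortholog_table <- function(pairs) {
  out <- tibble::tibble(
    human = as.character(pairs[[1]]),
    yeast = as.character(pairs[[2]])
  )
  out <- dplyr::arrange(dplyr::distinct(out), .data$human, .data$yeast)
  class(out) <- c("ortholog_table", class(out))
  out
}

#' Write an ortholog table to TSV
#'
#' @param table An `ortholog_table` (or two-column data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(table, path) {
  readr::write_tsv(tibble::tibble(human = table[[1]], yeast = table[[2]]),
                   path, col_names = FALSE)
  invisible(path)
}

#' Derive yeast seed genes from human disease genes
#'
#' Maps the disease genes through the ortholog table and keeps the yeast
#' orthologs present in the PPI network; the result is the positive label set
#' for the classifier.
#'
#' @param disease_genes Character vector of human gene IDs.
#' @param table An `ortholog_table`.
#' @param graph A `ppi_graph`, edge-list data frame, or character vector of
#'   network protein IDs.
#' @return Sorted character vector of seed (yeast) protein IDs.
#' @export
seed_genes <- function(disease_genes, table, graph) {
  nodes <- if (is.character(graph)) graph else as_ppi_graph(graph)$nodes
  hits <- table$yeast[table$human %in% disease_genes]
  seeds <- sort(intersect(unique(hits), nodes))
  if (length(seeds) == 0) {
    stop("no disease gene has a yeast ortholog in the network", call. = FALSE)
  }
  seeds
}

#' Map candidate yeast genes back to human
#'
#' @param candidates Character vector of yeast protein IDs.
#' @param table An `ortholog_table`.
#' @return A list with `human` (sorted union of human orthologs of the
#'   candidates) and `unmapped` (candidates with no ortholog in the table).
#' @export
map_back <- function(candidates, table) {
  candidates <- unique(as.character(candidates))
  mapped <- candidates[candidates %in% table$yeast]
  list(
    human = sort(unique(table$human[table$yeast %in% mapped])),
    unmapped = sort(setdiff(candidates, mapped))
  )
}
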