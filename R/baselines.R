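#' Classical centrality baselines
#'
#' Ranks every protein with one of the comparison methods used alongside the
#' PSGN score: degree (DC), betweenness (BC), closeness (CC), eigenvector
#' (EC), PageRank, local average connectivity (LAC), network centrality (NC),
#' co-expression-weighted edge clustering (PeC), and weighted degree
#' centrality (WDC). NC and PeC reuse the feature-module implementations so
#' there is a single source of truth for those scores.
#'
#' Definitions follow the standard literature: CC is computed per connected
#' component as (n_c - 1) / sum of distances within the component; BC is
#' normalized shortest-path betweenness over existing paths; EC is the
#' principal eigenvector of the adjacency matrix; LAC(i) averages, over the
#' neighbors of i, their degree within the subgraph induced by N(i);
#' WDC(i) = sum over neighbors of (ECC(i, j) + lambda * PCC(i, j)).
#'
#' @param edges Edge-list data frame or `ppi_graph`.
#' @param method One of `"DC"`, `"BC"`, `"CC"`, `"EC"`, `"PageRank"`,
#'   `"LAC"`, `"NC"`, `"PeC"`, `"WDC"`.
#' @param expression Expression matrix; required for PeC and WDC.
#' @param damping PageRank damping factor (default 0.85).
#' @param lambda WDC mixing weight between ECC and PCC (default 0.5).
#' @return A tibble `rank`, `protein`, `score` sorted descending by score,
#'   ties broken lexicographically.
#' @export
compute_centrality <- function(edges, method, expression = NULL,
                               damping = 0.85, lambda = 0.5) {
  graph <- as_ppi_graph(edges)
  if (length(graph$nodes) == 0) stop("empty network", call. = FALSE)
  methods <- c("DC", "BC", "CC", "EC", "PageRank", "LAC", "NC", "PeC", "WDC")
  if (!method %in% methods) {
    stop("unknown method '", method, "'; choose one of ",
         paste(methods, collapse = ", "), call. = FALSE)
  }
  if (method %in% c("PeC", "WDC") && is.null(expression)) {
    stop(method, " requires an expression matrix", call. = FALSE)
  }
  g <- graph$graph
  score <- switch(method,
    DC = igraph::degree(g),
    BC = igraph::betweenness(g, normalized = TRUE),
    CC = closeness_by_component(graph),
    EC = igraph::eigen_centrality(g)$vector,
    PageRank = igraph::page_rank(g, damping = damping)$vector,
    LAC = lac_scores(graph),
    NC = stats::setNames(network_centrality_scores(graph)$nc, graph$nodes),
    PeC = stats::setNames(pec_scores(graph, expression)$pec, graph$nodes),
    WDC = wdc_scores(graph, expression, lambda)
  )
  score <- score[graph$nodes]
  out <- tibble::tibble(protein = graph$nodes, score = unname(score))
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$protein)
  dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
}

# Closeness per connected component: (n_c - 1) / sum of distances to the
# other members of the node's component; isolated nodes score 0.
closeness_by_component <- function(graph) {
  g <- graph$graph
  comp <- igraph::components(g)$membership
  d <- igraph::distances(g)
  score <- vapply(graph$nodes, function(v) {
    same <- names(comp)[comp == comp[[v]]]
    if (length(same) <= 1) return(0)
    (length(same) - 1) / sum(d[v, setdiff(same, v)])
  }, 0)
  score
}

# Local average connectivity: mean degree of N(i) within the induced
# subgraph on N(i).
lac_scores <- function(graph) {
  vapply(graph$nodes, function(v) {
    nb <- graph$adj[[v]]
    if (length(nb) == 0) return(0)
    within <- vapply(nb, function(u) sum(graph$adj[[u]] %in% nb), 0)
    mean(within)
  }, 0)
}

wdc_scores <- function(graph, expression, lambda) {
  et <- ecc_table(graph)
  pcc <- edge_pcc(expression, et$protein_a, et$protein_b)
  w <- et$ecc + lambda * pcc
  score <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  add <- tapply(c(w, w), c(et$protein_a, et$protein_b), sum)
  score[names(add)] <- add
  score
}

#' Rankings for several centrality methods at once
#'
#' @inheritParams compute_centrality
#' @param methods Character vector of method names (see
#'   [compute_centrality()]).
#' @return A tibble with columns `method`, `rank`, `protein`, `score`.
#' @export
baseline_rankings <- function(edges, methods, expression = NULL,
                              damping = 0.85, lambda = 0.5) {
  graph <- as_ppi_graph(edges)
  purrr::map_dfr(methods, function(m) {
    dplyr::mutate(
      compute_centrality(graph, m, expression, damping, lambda),
      method = m, .before = 1
    )
  })
}
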