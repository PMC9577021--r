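#' Read a protein complex catalog
#'
#' One complex per line, tab-separated member IDs (CYC2008-style). Lines
#' starting with `#` are skipped. Duplicate members within a complex collapse.
#'
#' @param path Path to the catalog file.
#' @return A list of character vectors, one per complex.
#' @export
read_complex_catalog <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty complex catalog: ", path, call. = FALSE)
  lapply(strsplit(lines, "\t", fixed = TRUE), function(x) unique(x[nzchar(x)]))
}

#' Write a protein complex catalog
#'
#' @param complexes List of character vectors of member IDs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complex_catalog <- function(complexes, path) {
  readr::write_lines(vapply(complexes, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' Protein complex (PC) score
#'
#' The number of curated complexes containing each protein; proteins absent
#' from the catalog score 0. More complex memberships indicate a protein
#' embedded in more functional modules, a strong correlate of essentiality.
#'
#' @param complexes List of character vectors (one complex each), as returned
#'   by [read_complex_catalog()].
#' @param proteins Character vector of protein IDs to score.
#' @return A tibble with columns `protein` and `pc`.
#' @export
complex_membership_scores <- function(complexes, proteins) {
  members <- unlist(lapply(complexes, unique), use.names = FALSE)
  tab <- table(members)
  pc <- as.integer(tab[proteins])
  pc[is.na(pc)] <- 0L
  tibble::tibble(protein = proteins, pc = pc)
}

#' Network centrality (NC) and its normalized form (NNC)
#'
#' NC(i) is the sum of edge clustering coefficients over the edges incident to
#' protein i; NNC(i) = NC(i) / max NC, so NNC lies in \[0, 1\] with maximum
#' exactly 1 whenever any protein closes a triangle. In a triangle-free
#' network all NC values are 0 and NNC is defined as 0 everywhere.
#'
#' @param graph A `ppi_graph` or edge-list data frame.
#' @return A tibble with columns `protein`, `nc`, `nnc`, one row per node in
#'   lexicographic order.
#' @export
network_centrality_scores <- function(graph) {
  graph <- as_ppi_graph(graph)
  if (length(graph$nodes) == 0) stop("empty network", call. = FALSE)
  et <- ecc_table(graph)
  nc <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  add <- tapply(c(et$ecc, et$ecc), c(et$protein_a, et$protein_b), sum)
  nc[names(add)] <- add
  mx <- max(nc)
  tibble::tibble(
    protein = graph$nodes,
    nc = unname(nc),
    nnc = if (mx > 0) unname(nc) / mx else unname(nc) * 0
  )
}

#' Neighbor-clustering edge coefficient NECC
#'
#' NECC(i, j) = T(i, j)^e C(j) / ((d(i) - 1)(d(j) - 1)), a directed edge
#' weight combining the (cubed, by default) triangle count through the edge
#' with the clustering coefficient of the target endpoint. Not symmetric: it
#' depends on C(j). Defined as 0 when either endpoint has degree 1.
#'
#' @param graph A `ppi_graph` or edge-list data frame.
#' @param i,j Endpoint protein IDs; `{i, j}` must be an edge.
#' @param exponent Power applied to the triangle count (default 3).
#' @return Real \eqn{\ge} 0.
#' @export
necc <- function(graph, i, j, exponent = 3) {
  graph <- as_ppi_graph(graph)
  check_edge(graph, i, j)
  di <- graph$degree[[i]]
  dj <- graph$degree[[j]]
  if (di <= 1 || dj <= 1) return(0)
  triangle_count(graph, i, j)^exponent * clustering_coefficient(graph, j) /
    ((di - 1) * (dj - 1))
}

#' Node sum of NECC over incident edges (NNEC)
#'
#' NNEC(i) = sum over neighbors j of NECC(i, j).
#'
#' @inheritParams network_centrality_scores
#' @param exponent Power applied to the triangle count (default 3).
#' @return A tibble with columns `protein` and `nnec`.
#' @export
nnec_scores <- function(graph, exponent = 3) {
  graph <- as_ppi_graph(graph)
  et <- ecc_table(graph)
  deg <- graph$degree
  cc <- vapply(graph$nodes, function(j) clustering_coefficient(graph, j), 0)
  da <- deg[et$protein_a]
  db <- deg[et$protein_b]
  ok <- da > 1 & db > 1
  base <- ifelse(ok, et$triangles^exponent / ((da - 1) * (db - 1)), 0)
  # contribution of edge (a, b) to NNEC(a) uses C(b), and vice versa
  contrib <- c(base * cc[et$protein_b], base * cc[et$protein_a])
  node <- c(et$protein_a, et$protein_b)
  nnec <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  add <- tapply(contrib, node, sum)
  nnec[names(add)] <- add
  tibble::tibble(protein = graph$nodes, nnec = unname(nnec))
}

#' Read a subcellular localization table
#'
#' TSV of `protein<TAB>location` records; extra columns are ignored and
#' duplicate (protein, location) pairs collapse to one.
#'
#' @param path Path to the localization file.
#' @return A tibble with columns `protein` and `location`.
#' @export
read_localization <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty localization table: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop("malformed localization line ", which(lengths(parts) < 2)[1],
         call. = FALSE)
  }
  dplyr::distinct(tibble::tibble(
    protein = vapply(parts, `[[`, "", 1L),
    location = vapply(parts, `[[`, "", 2L)
  ))
}

#' Subcellular localization correlation coefficients (SLCC)
#'
#' Contrasts, for each location, how often the top k% proteins of a ranking
#' appear there against how often the bottom k% do. With T and B the top and
#' bottom tallies: SLCC = 1 - B/T when T < B (negative association with
#' essentiality), and T/B - 1 otherwise. When T = 0 the coefficient is
#' substituted by the maximum of 1 - B/T over locations with T != 0; when
#' B = 0, by the maximum of T/B - 1 over locations with B != 0. Locations seen
#' in neither slice score 0.
#'
#' @param localization Tibble of `protein`, `location` records.
#' @param ranking Character vector of protein IDs sorted descending by NNC
#'   (ties broken lexicographically).
#' @param k_percent Slice size in percent (default 5); the slice holds
#'   `max(1, floor(k_percent * length(ranking) / 100))` proteins.
#' @return A tibble with columns `location`, `t_count`, `b_count`, `slcc`.
#' @export
localization_correlation <- function(localization, ranking, k_percent = 5) {
  if (length(ranking) == 0) stop("empty ranking", call. = FALSE)
  if (k_percent <= 0 || k_percent >= 50) {
    stop("k_percent must be in (0, 50)", call. = FALSE)
  }
  localization <- dplyr::distinct(
    tibble::as_tibble(localization[, c("protein", "location")])
  )
  k <- max(1L, floor(k_percent * length(ranking) / 100))
  top <- ranking[seq_len(k)]
  bottom <- ranking[seq.int(length(ranking) - k + 1L, length(ranking))]
  locs <- sort(unique(localization$location))
  t_count <- vapply(locs, function(l) {
    sum(localization$protein[localization$location == l] %in% top)
  }, 0L)
  b_count <- vapply(locs, function(l) {
    sum(localization$protein[localization$location == l] %in% bottom)
  }, 0L)
  slcc <- numeric(length(locs))
  both <- t_count > 0 & b_count > 0
  slcc[both] <- ifelse(
    t_count[both] < b_count[both],
    1 - b_count[both] / t_count[both],
    t_count[both] / b_count[both] - 1
  )
  neg_pool <- 1 - b_count[t_count > 0] / t_count[t_count > 0]
  pos_pool <- t_count[b_count > 0] / b_count[b_count > 0] - 1
  zero_t <- t_count == 0 & b_count > 0
  zero_b <- b_count == 0 & t_count > 0
  slcc[zero_t] <- if (length(neg_pool)) max(neg_pool) else 0
  slcc[zero_b] <- if (length(pos_pool)) max(pos_pool) else 0
  # locations in neither slice keep slcc = 0
  tibble::tibble(location = locs, t_count = t_count, b_count = b_count,
                 slcc = slcc)
}

#' Per-protein subcellular localization scores SL and NSL
#'
#' SL(i) sums the SLCC values of the distinct locations where protein i
#' appears (0 for unannotated proteins). NSL shifts and rescales:
#' NSL(i) = (SL(i) + max_SL) / max_j(SL(j) + max_SL), so the best-localized
#' protein gets exactly 1. If every shifted score is 0 all NSL are 0.
#'
#' @param localization Tibble of `protein`, `location` records.
#' @param slcc Tibble from [localization_correlation()].
#' @param proteins Character vector of network protein IDs to score.
#' @return A tibble with columns `protein`, `sl`, `nsl`.
#' @export
subcellular_scores <- function(localization, slcc, proteins) {
  localization <- dplyr::distinct(
    tibble::as_tibble(localization[, c("protein", "location")])
  )
  lookup <- stats::setNames(slcc$slcc, slcc$location)
  per <- tapply(
    lookup[localization$location], localization$protein,
    function(v) sum(v, na.rm = TRUE)
  )
  sl <- stats::setNames(numeric(length(proteins)), proteins)
  hit <- intersect(names(per), proteins)
  sl[hit] <- per[hit]
  shifted <- sl + max(sl)
  denom <- max(shifted)
  tibble::tibble(
    protein = proteins,
    sl = unname(sl),
    nsl = if (denom > 0) unname(shifted) / denom else unname(shifted) * 0
  )
}

#' Read a gene expression matrix
#'
#' TSV with a header row of sample names and one row per gene:
#' `gene<TAB>v1<TAB>...<TAB>vs` (GEO series-matrix-like).
#'
#' @param path Path to the expression file.
#' @return A numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (nrow(df) == 0 || ncol(df) < 3) {
    stop("expression table needs a gene column and >= 2 samples", call. = FALSE)
  }
  m <- as.matrix(df[, -1])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a gene expression matrix
#'
#' @param expr Numeric matrix with gene rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- tibble::as_tibble(expr, .name_repair = "minimal")
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(gene = rownames(expr)), df),
                   path)
  invisible(path)
}

#' Pearson correlation of two expression profiles
#'
#' The sample correlation over the s time points, with the 1/(s - 1)
#' convention. Missing genes or zero-variance profiles yield 0 so that absent
#' expression data degrades a neighbor's contribution to nothing rather than
#' propagating NA.
#'
#' @param expr Expression matrix (genes in rows, see [read_expression()]).
#' @param i,j Gene IDs.
#' @return Real in \[-1, 1\].
#' @export
expression_correlation <- function(expr, i, j) {
  if (!i %in% rownames(expr) || !j %in% rownames(expr)) return(0)
  x <- expr[i, ]
  y <- expr[j, ]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Co-expression-weighted edge clustering score PeC
#'
#' PeC(i) = sum over neighbors j of ECC(i, j) * PCC(i, j): the topological
#' weight of each incident edge damped by how strongly the two partners are
#' co-expressed, which suppresses false-positive interactions.
#'
#' @param graph A `ppi_graph` or edge-list data frame.
#' @param expr Expression matrix (genes in rows).
#' @return A tibble with columns `protein` and `pec`.
#' @export
pec_scores <- function(graph, expr) {
  graph <- as_ppi_graph(graph)
  et <- ecc_table(graph)
  pcc <- edge_pcc(expr, et$protein_a, et$protein_b)
  w <- et$ecc * pcc
  pec <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  add <- tapply(c(w, w), c(et$protein_a, et$protein_b), sum)
  pec[names(add)] <- add
  tibble::tibble(protein = graph$nodes, pec = unname(pec))
}

# Vectorized per-edge Pearson correlation; rows missing from expr or with zero
# variance give 0.
edge_pcc <- function(expr, a, b) {
  if (is.null(expr)) return(numeric(length(a)))
  s <- ncol(expr)
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1, stats::sd)
  z <- (expr - mu) / ifelse(sdv > 0, sdv, 1)
  ok <- a %in% rownames(expr) & b %in% rownames(expr)
  pcc <- numeric(length(a))
  if (any(ok)) {
    za <- z[a[ok], , drop = FALSE]
    zb <- z[b[ok], , drop = FALSE]
    val <- rowSums(za * zb) / (s - 1)
    val[sdv[a[ok]] == 0 | sdv[b[ok]] == 0] <- 0
    pcc[ok] <- val
  }
  pcc
}

#' Assemble the full heterogeneous feature table
#'
#' Computes, in dependency order, the four per-protein features and the
#' integrated PSGN score: NNC (pure topology) first, then the NNC-ranked
#' SLCC/NSL localization scores and their topology-weighted combination NNSL,
#' the complex-membership count PC, the co-expression score PeC, and finally
#' PSGN with adaptive weights for `input_count` requested candidates.
#'
#' @param edges Edge-list data frame (or `ppi_graph`).
#' @param complexes Complex catalog (list of ID vectors), or `NULL`.
#' @param localization Localization tibble, or `NULL`.
#' @param expression Expression matrix, or `NULL`.
#' @param input_count Expected number of essential proteins to identify
#'   (drives the adaptive weights; default 100).
#' @param k_percent Top/bottom slice size for SLCC (default 5).
#' @param necc_exponent Triangle-count exponent in NECC (default 3).
#' @param form Parenthesization of the integration formula, see
#'   [psgn_score()].
#' @return A tibble with one row per protein: `protein`, `pc`, `nnsl`, `pec`,
#'   `nnc`, `psgn`, plus annotation-coverage flags `in_complexes`,
#'   `in_localization`, `in_expression`.
#' @export
ppi_features <- function(edges, complexes = NULL, localization = NULL,
                         expression = NULL, input_count = 100,
                         k_percent = 5, necc_exponent = 3,
                         form = c("printed", "grouped")) {
  graph <- as_ppi_graph(edges)
  nodes <- graph$nodes
  cent <- network_centrality_scores(graph)

  pc <- if (is.null(complexes)) {
    tibble::tibble(protein = nodes, pc = 0L)
  } else {
    complex_membership_scores(complexes, nodes)
  }

  if (is.null(localization)) {
    sub <- tibble::tibble(protein = nodes, sl = 0, nsl = 0)
  } else {
    ranking <- cent$protein[order(-cent$nnc, cent$protein)]
    slcc <- localization_correlation(localization, ranking, k_percent)
    sub <- subcellular_scores(localization, slcc, nodes)
  }
  nnec <- nnec_scores(graph, exponent = necc_exponent)
  nnsl <- sub$nsl * nnec$nnec

  pec <- if (is.null(expression)) {
    tibble::tibble(protein = nodes, pec = 0)
  } else {
    pec_scores(graph, expression)
  }

  w <- adaptive_weights(input_count)
  pc_vals <- as.numeric(pc$pc)
  psgn_vals <- psgn_score(pc_vals, nnsl, pec$pec, cent$nnc,
                          w$a, w$b, form = form)
  feats <- tibble::tibble(
    protein = nodes,
    pc = pc_vals,
    nnsl = nnsl,
    pec = pec$pec,
    nnc = cent$nnc,
    psgn = psgn_vals,
    in_complexes = nodes %in% unlist(complexes, use.names = FALSE),
    in_localization = if (is.null(localization)) FALSE
                      else nodes %in% localization$protein,
    in_expression = if (is.null(expression)) FALSE
                    else nodes %in% rownames(expression)
  )
  attr(feats, "weights") <- w
  feats
}
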