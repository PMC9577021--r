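#' Configuration for the synthetic data generator
#'
#' The defaults emulate the study conditions of the yeast analysis at desk
#' scale: a scale-free-like interaction network, an essential fraction of
#' 0.23 (1,167 of 5,093 yeast proteins), 36 expression samples (a cell-cycle
#' time course), and planted essentiality signal controlled by three effect
#' sizes: planted positives attract `degree_boost`-fold more attachment,
#' join complexes with `complex_boost`-fold higher probability, and share a
#' latent expression factor whose strength grows with `coexpression_boost`.
#'
#' @param n_proteins Number of proteins (default 200).
#' @param positive_fraction Fraction of planted essential proteins (default
#'   0.23); the count is `floor(positive_fraction * n_proteins)`.
#' @param degree_boost,complex_boost,coexpression_boost Effect sizes, all
#'   \eqn{\ge} 1 (defaults 3).
#' @param n_complexes Number of protein complexes (default 40).
#' @param n_locations Number of subcellular locations (default 8).
#' @param n_samples Number of expression samples (default 36).
#' @param seed Integer seed; the bundle is fully reproducible from it.
#' @return A list of class `psgn_sim_config`.
#' @export
simulation_config <- function(n_proteins = 200, positive_fraction = 0.23,
                              degree_boost = 3, complex_boost = 3,
                              coexpression_boost = 3, n_complexes = 40,
                              n_locations = 8, n_samples = 36, seed = 1) {
  stopifnot(n_proteins >= 10, positive_fraction > 0, positive_fraction < 1,
            degree_boost >= 1, complex_boost >= 1, coexpression_boost >= 1,
            n_complexes >= 1, n_locations >= 2, n_samples >= 2)
  if (n_proteins < 10) stop("network too small", call. = FALSE)
  structure(
    list(n_proteins = as.integer(n_proteins),
         positive_fraction = positive_fraction,
         degree_boost = degree_boost, complex_boost = complex_boost,
         coexpression_boost = coexpression_boost,
         n_complexes = as.integer(n_complexes),
         n_locations = as.integer(n_locations),
         n_samples = as.integer(n_samples), seed = as.integer(seed)),
    class = "psgn_sim_config"
  )
}

#' Generate a complete synthetic input bundle
#'
#' Produces all seven pipeline inputs with planted essentiality signal:
#' a preferential-attachment network with triadic closure in which positives
#' receive boosted attachment; a complex catalog with boosted positive
#' membership; localization records in which a subset of locations is
#' enriched for positives; a latent-factor expression matrix giving
#' interacting positives high pairwise correlation; the positive (essential)
#' list; a human-yeast ortholog table; and the human disease gene list whose
#' seed genes recover the positives.
#'
#' @param config A [simulation_config()] (or arguments passed to it via
#'   `...`).
#' @param ... If `config` is missing, arguments for [simulation_config()].
#' @return A list of class `psgn_bundle` with elements `edges`, `complexes`,
#'   `localization`, `expression`, `positives`, `orthologs`,
#'   `disease_genes`, `config`.
#' @export
generate_bundle <- function(config = simulation_config(...), ...) {
  cfg <- config
  n <- cfg$n_proteins
  max_cplx <- 8L
  if (max_cplx > n) stop("complexes larger than the network", call. = FALSE)
  local_seed(cfg$seed, {
    ids <- sprintf("Y%04d", seq_len(n))
    n_pos <- floor(cfg$positive_fraction * n)
    positives <- sort(sample(ids, n_pos))
    is_pos <- stats::setNames(ids %in% positives, ids)

    ## --- network: preferential attachment + triadic closure -------------
    ord <- sample(ids)
    m0 <- 4L
    m_new <- 3L
    ea <- character(0)
    eb <- character(0)
    deg <- stats::setNames(integer(n), ids)
    seed_nodes <- ord[seq_len(m0)]
    for (i in seq_len(m0 - 1L)) {
      for (j in seq.int(i + 1L, m0)) {
        ea <- c(ea, seed_nodes[i]); eb <- c(eb, seed_nodes[j])
      }
    }
    deg[seed_nodes] <- m0 - 1L
    adj <- lapply(stats::setNames(vector("list", n), ids), function(x) character(0))
    for (i in seq_along(ea)) {
      adj[[ea[i]]] <- c(adj[[ea[i]]], eb[i])
      adj[[eb[i]]] <- c(adj[[eb[i]]], ea[i])
    }
    for (i in seq.int(m0 + 1L, n)) {
      v <- ord[i]
      prev <- ord[seq_len(i - 1L)]
      w <- (deg[prev] + 1) * ifelse(is_pos[prev], cfg$degree_boost, 1)
      targets <- sample(prev, min(m_new, length(prev)), prob = w)
      # triadic closure: sometimes also link to a neighbor of a target
      extra <- character(0)
      for (tg in targets) {
        nb <- setdiff(adj[[tg]], c(v, targets, extra))
        if (length(nb) > 0 && stats::runif(1) < 0.4) {
          extra <- c(extra, sample(nb, 1))
        }
      }
      for (tg in unique(c(targets, extra))) {
        ea <- c(ea, v); eb <- c(eb, tg)
        deg[v] <- deg[v] + 1L
        deg[tg] <- deg[tg] + 1L
        adj[[v]] <- c(adj[[v]], tg)
        adj[[tg]] <- c(adj[[tg]], v)
      }
    }
    edges <- ppi_edges(tibble::tibble(protein_a = ea, protein_b = eb))

    ## --- complexes -------------------------------------------------------
    wts <- ifelse(is_pos, cfg$complex_boost, 1)
    complexes <- lapply(seq_len(cfg$n_complexes), function(k) {
      size <- sample(3:max_cplx, 1)
      sort(sample(ids, size, prob = wts))
    })

    ## --- localization ----------------------------------------------------
    locs <- sprintf("L%02d", seq_len(cfg$n_locations))
    enriched <- locs[seq_len(max(1L, ceiling(cfg$n_locations / 3)))]
    other <- setdiff(locs, enriched)
    loc_rows <- lapply(ids, function(p) {
      k <- sample(1:3, 1)
      p_enriched <- if (is_pos[[p]]) 0.7 else 0.2
      chosen <- unique(vapply(seq_len(k), function(z) {
        if (stats::runif(1) < p_enriched || length(other) == 0) {
          sample(enriched, 1)
        } else {
          sample(other, 1)
        }
      }, ""))
      tibble::tibble(protein = p, location = chosen)
    })
    localization <- dplyr::bind_rows(loc_rows)

    ## --- expression: latent factor shared by positives -------------------
    rho <- 1 - 1 / cfg$coexpression_boost
    f <- stats::rnorm(cfg$n_samples)
    expr <- t(vapply(ids, function(p) {
      noise <- stats::rnorm(cfg$n_samples)
      sig <- if (is_pos[[p]]) sqrt(rho) * f + sqrt(1 - rho) * noise else noise
      5 + sig
    }, numeric(cfg$n_samples)))
    rownames(expr) <- ids
    colnames(expr) <- sprintf("S%02d", seq_len(cfg$n_samples))

    ## --- orthologs and disease genes -------------------------------------
    human_of <- stats::setNames(sprintf("HSA%04d", seq_len(n)), ids)
    keep <- is_pos | stats::runif(n) < 0.85
    pairs <- tibble::tibble(human = unname(human_of[keep]),
                            yeast = ids[keep])
    # a little many-to-many noise plus decoy yeast genes outside the network
    extra_h <- sample(pairs$human, max(1L, round(0.05 * nrow(pairs))))
    extra_y <- sample(ids, length(extra_h))
    decoy_h <- sprintf("HSA9%03d", seq_len(5))
    decoy_y <- sprintf("YX%03d", seq_len(5))
    orthologs <- ortholog_table(dplyr::bind_rows(
      pairs,
      tibble::tibble(human = extra_h, yeast = extra_y),
      tibble::tibble(human = decoy_h, yeast = decoy_y)
    ))
    disease_genes <- sort(unique(c(unname(human_of[positives]), decoy_h)))

    structure(
      list(edges = edges, complexes = complexes, localization = localization,
           expression = expr, positives = positives, orthologs = orthologs,
           disease_genes = disease_genes, config = cfg),
      class = "psgn_bundle"
    )
  })
}

#' @export
print.psgn_bundle <- function(x, ...) {
  cat("<psgn_bundle> ", x$config$n_proteins, " proteins, ",
      nrow(x$edges), " interactions, ", length(x$positives),
      " planted essentials\n", sep = "")
  invisible(x)
}

bundle_files <- c(
  edges = "network.tsv", complexes = "complexes.txt",
  localization = "localization.tsv", expression = "expression.tsv",
  positives = "essential.txt", orthologs = "orthologs.tsv",
  disease_genes = "disease_genes.txt"
)

#' Write a synthetic bundle to a directory
#'
#' Emits the seven input files in exactly the formats the readers consume:
#' `network.tsv`, `complexes.txt`, `localization.tsv`, `expression.tsv`,
#' `essential.txt`, `orthologs.tsv`, `disease_genes.txt`.
#'
#' @param bundle A `psgn_bundle` from [generate_bundle()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the seven file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, bundle_files)
  names(paths) <- names(bundle_files)
  write_ppi_edges(bundle$edges, paths[["edges"]])
  write_complex_catalog(bundle$complexes, paths[["complexes"]])
  readr::write_tsv(bundle$localization, paths[["localization"]],
                   col_names = FALSE)
  write_expression(bundle$expression, paths[["expression"]])
  readr::write_lines(bundle$positives, paths[["positives"]])
  write_ortholog_table(bundle$orthologs, paths[["orthologs"]])
  readr::write_lines(bundle$disease_genes, paths[["disease_genes"]])
  invisible(paths)
}

#' Read a bundle back from a directory
#'
#' @param dir Directory written by [write_bundle()].
#' @return A list with the same elements as [generate_bundle()] (minus the
#'   generating `config`).
#' @export
read_bundle <- function(dir) {
  paths <- file.path(dir, bundle_files)
  names(paths) <- names(bundle_files)
  list(
    edges = read_ppi_edges(paths[["edges"]]),
    complexes = read_complex_catalog(paths[["complexes"]]),
    localization = read_localization(paths[["localization"]]),
    expression = read_expression(paths[["expression"]]),
    positives = readr::read_lines(paths[["positives"]]),
    orthologs = read_ortholog_table(paths[["orthologs"]]),
    disease_genes = readr::read_lines(paths[["disease_genes"]])
  )
}
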