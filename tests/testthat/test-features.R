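k3_edges <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"))

test_that("complex membership counts match a brute-force scan", {
  catalog <- list(c("A", "B"), c("A", "C", "D"), c("A", "E"), c("B", "E"))
  sc <- complex_membership_scores(catalog, c("A", "B", "Z"))
  expect_equal(sc$pc, c(3L, 2L, 0L))

  set.seed(3)
  ids <- sprintf("p%02d", 1:25)
  catalog <- lapply(1:20, function(k) sample(ids, sample(2:8, 1)))
  sc <- complex_membership_scores(catalog, ids)
  brute <- vapply(ids, function(p) {
    sum(vapply(catalog, function(cx) p %in% cx, TRUE))
  }, 0L)
  expect_equal(sc$pc, unname(brute))
})

test_that("NC and NNC match oracle sums and normalization law", {
  g <- ppi_graph(k3_edges)
  cent <- network_centrality_scores(g)
  expect_equal(cent$nc, c(2, 2, 2))
  expect_equal(cent$nnc, c(1, 1, 1))

  path <- ppi_graph(data.frame(a = paste0("p", 1:4), b = paste0("p", 2:5)))
  cent <- network_centrality_scores(path)
  expect_true(all(cent$nnc == 0))

  edges <- oracle_random_graph(15, 0.3, seed = 2)
  cent <- network_centrality_scores(ppi_graph(edges))
  for (r in seq_len(nrow(cent))) {
    expect_equal(cent$nc[r], oracle_nc(edges, cent$protein[r]))
  }
  expect_equal(max(cent$nnc), 1)
  expect_equal(cent$nnc, unname(oracle_nnc(edges)[cent$protein]))
})

test_that("NECC and NNEC match direct evaluation with oracle T and C", {
  g <- ppi_graph(k3_edges)
  expect_equal(necc(g, "A", "B"), 1)
  pend <- ppi_graph(data.frame(a = c("A", "A", "B", "C"),
                               b = c("B", "C", "C", "D")))
  expect_equal(necc(pend, "C", "D"), 0)

  edges <- oracle_random_graph(12, 0.4, seed = 1)
  g <- ppi_graph(edges)
  nn <- nnec_scores(g)
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges$protein_a[r]; j <- g$edges$protein_b[r]
    expect_equal(necc(g, i, j), oracle_necc(edges, i, j), tolerance = 1e-12)
    expect_equal(necc(g, j, i), oracle_necc(edges, j, i), tolerance = 1e-12)
  }
  for (r in seq_len(nrow(nn))) {
    expect_equal(nn$nnec[r], oracle_nnec(edges, nn$protein[r]),
                 tolerance = 1e-12)
  }
  # configurable exponent
  i <- g$edges$protein_a[1]; j <- g$edges$protein_b[1]
  expect_equal(necc(g, i, j, exponent = 1),
               oracle_necc(edges, i, j, exponent = 1))
})

test_that("SLCC branches, substitutions, and sign law hold", {
  # ranking of 40 proteins, k = 5% -> top/bottom slices of 2
  ranking <- sprintf("r%02d", 1:40)
  loc <- rbind(
    data.frame(protein = c("r01", "r02", "r39", "r40", "r20"), location = "top_heavy"),
    data.frame(protein = c("r01", "r39", "r40"), location = "bottom_heavy"),
    data.frame(protein = c("r39", "r40"), location = "only_bottom"),
    data.frame(protein = c("r01", "r02"), location = "only_top"),
    data.frame(protein = "r21", location = "neither")
  )
  sl <- localization_correlation(loc, ranking, k_percent = 5)
  row <- function(l) sl[sl$location == l, ]
  expect_equal(row("top_heavy")$slcc, 2 / 2 - 1)       # T=2, B=2 -> 0
  expect_equal(row("bottom_heavy")$slcc, 1 - 2 / 1)    # T=1, B=2 -> -1
  # B=0 rule: max of T/B - 1 over locations with B != 0
  expect_equal(row("only_top")$slcc, max(2 / 2 - 1, 1 / 2 - 1, 0 / 2 - 1))
  # T=0 rule: max of 1 - B/T over locations with T != 0 (only_top included)
  expect_equal(row("only_bottom")$slcc, max(1 - 2 / 2, 1 - 2 / 1, 1 - 0 / 2))
  expect_equal(row("neither")$slcc, 0)
  # sign law: negative iff T < B among locations with both counts
  both <- sl[sl$t_count > 0 & sl$b_count > 0, ]
  expect_equal(both$slcc < 0, unname(both$t_count < both$b_count))

  expect_error(localization_correlation(loc, character(0)), "empty")
  expect_error(localization_correlation(loc, ranking, k_percent = 60),
               "k_percent")
})

test_that("random localization tallies match the stand-alone SLCC oracle", {
  for (seed in 4:6) {
    set.seed(seed)
    ranking <- sprintf("q%02d", 1:30)
    loc <- data.frame(
      protein = sample(ranking, 60, replace = TRUE),
      location = sample(sprintf("L%d", 1:6), 60, replace = TRUE)
    )
    sl <- localization_correlation(loc, ranking, k_percent = 10)
    expect_equal(sl$slcc, oracle_slcc(sl$t_count, sl$b_count))
  }
})

test_that("SL sums distinct locations and NSL normalizes to max 1", {
  slcc <- tibble::tibble(location = c("La", "Lb", "Lc"),
                         slcc = c(1, -0.5, 2))
  loc <- data.frame(protein = c("P1", "P1", "P1", "P2", "P3"),
                    location = c("La", "Lb", "La", "Lc", "Lb"))
  sc <- subcellular_scores(loc, slcc, c("P1", "P2", "P3", "P4"))
  expect_equal(sc$sl, c(0.5, 2, -0.5, 0))
  # NSL = (SL + max_SL) / max(SL + max_SL) = (SL + 2) / 4
  expect_equal(sc$nsl, (sc$sl + 2) / 4)
  expect_equal(max(sc$nsl), 1)
  expect_equal(sc$nsl[which.max(sc$sl)], 1)
})

test_that("NNSL is the product of NSL and NNEC", {
  b <- generate_bundle(simulation_config(n_proteins = 60, seed = 4))
  feats <- ppi_features(b$edges, b$complexes, b$localization, b$expression)
  g <- ppi_graph(b$edges)
  cent <- network_centrality_scores(g)
  ranking <- cent$protein[order(-cent$nnc, cent$protein)]
  slcc <- localization_correlation(b$localization, ranking, 5)
  nsl <- subcellular_scores(b$localization, slcc, g$nodes)$nsl
  nnec <- nnec_scores(g)$nnec
  expect_equal(feats$nnsl, nsl * nnec, tolerance = 1e-12)
})

test_that("expression correlation follows the two-pass formula and 0-rules", {
  expr <- rbind(x = c(1, 2, 3), y = c(2, 4, 6), z = c(5, 5, 5))
  expect_equal(expression_correlation(expr, "x", "y"), 1)
  expect_equal(expression_correlation(expr, "x", "z"), 0)
  expect_equal(expression_correlation(expr, "x", "missing"), 0)

  ids <- sprintf("g%02d", 1:20)
  expr <- oracle_random_expression(ids, 36, seed = 5)
  set.seed(5)
  for (k in 1:30) {
    pair <- sample(ids, 2)
    expect_equal(expression_correlation(expr, pair[1], pair[2]),
                 oracle_pcc(expr[pair[1], ], expr[pair[2], ]),
                 tolerance = 1e-9)
  }
})

test_that("PeC matches the oracle sum over incident edges", {
  expr3 <- rbind(A = c(1, 2, 3), B = c(2, 4, 6), C = c(0, 1, 2))
  g <- ppi_graph(k3_edges)
  pec <- pec_scores(g, expr3)
  expect_equal(pec$pec[pec$protein == "A"], 2)  # all pairwise PCC = 1

  edges <- oracle_random_graph(15, 0.3, seed = 2)
  expr <- oracle_random_expression(oracle_nodes(edges), 36, seed = 5)
  pec <- pec_scores(ppi_graph(edges), expr)
  for (r in seq_len(nrow(pec))) {
    expect_equal(pec$pec[r], oracle_pec(edges, expr, pec$protein[r]),
                 tolerance = 1e-9)
  }
  # PeC = NC when every neighbor correlation is exactly 1
  nodes <- oracle_nodes(edges)
  perfect <- outer(seq_along(nodes), 1:10, function(i, t) i + t)
  rownames(perfect) <- nodes
  pec1 <- pec_scores(ppi_graph(edges), perfect)
  cent <- network_centrality_scores(ppi_graph(edges))
  expect_equal(pec1$pec, cent$nc, tolerance = 1e-9)
})

test_that("feature table flags annotation coverage and respects order", {
  b <- generate_bundle(simulation_config(n_proteins = 50, seed = 4))
  feats <- ppi_features(b$edges, b$complexes, b$localization, b$expression)
  expect_true(all(feats$nnc >= 0 & feats$nnc <= 1))
  expect_equal(max(feats$nnc), 1)
  expect_true(all(feats$in_expression))
  # dropping annotations zeroes the dependent features
  bare <- ppi_features(b$edges)
  expect_true(all(bare$pc == 0))
  expect_true(all(bare$pec == 0))
  expect_true(all(bare$nnsl == 0))
  expect_false(any(bare$in_complexes))
})
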