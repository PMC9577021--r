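test_that("precision at k matches brute-force set intersection", {
  ranking <- c("A", "B", "C", "D")
  expect_equal(precision_at_k(ranking, c("A", "C", "D"), 3), 2 / 3)
  expect_equal(precision_at_k(ranking, c("A", "B", "C", "D"), 2), 1)
  expect_error(precision_at_k(ranking, "A", 5), "k must lie")

  set.seed(17)
  ids <- sprintf("n%03d", 1:100)
  ranking <- sample(ids)
  truth <- sample(ids, 30)
  for (k in c(10, 20, 50)) {
    expect_equal(precision_at_k(ranking, truth, k),
                 length(intersect(ranking[1:k], truth)) / k)
  }
  # full-length precision equals the base rate
  expect_equal(precision_at_k(ranking, truth, 100), 0.3)
})

test_that("PR curve points and area match hand enumeration", {
  # ranking [E, N, E, N] with 2 truths
  curve <- pr_curve(c("E1", "N1", "E2", "N2"), c("E1", "E2"))
  expect_equal(curve$precision, c(1, 1 / 2, 2 / 3, 1 / 2))
  expect_equal(curve$recall, c(1 / 2, 1 / 2, 1, 1))
  # anchored trapezoid: 0.5*1 + 0 + 0.5*(2/3+1/2)/2 + 0
  expect_equal(attr(curve, "area"), 0.5 + 0.5 * (2 / 3 + 1 / 2) / 2)

  # perfect ranking scores exactly 1
  perfect <- pr_curve(c("E1", "E2", "N1", "N2"), c("E1", "E2"))
  expect_equal(attr(perfect, "area"), 1)

  # reversed perfect ranking equals brute-force trapezoid summation
  rev_rank <- c("N1", "N2", "E1", "E2")
  curve <- pr_curve(rev_rank, c("E1", "E2"))
  hits <- cumsum(rev_rank %in% c("E1", "E2"))
  p <- hits / seq_along(rev_rank)
  r <- hits / 2
  brute <- r[1] * p[1] + sum(diff(r) * (p[-1] + p[-4]) / 2)
  expect_equal(attr(curve, "area"), brute)

  expect_error(pr_curve(rev_rank, character(0)), "empty truth")
  expect_equal(glance(perfect)$pr_area, 1)
})

test_that("PR area of random rankings converges to the truth base rate", {
  set.seed(33)
  ids <- sprintf("n%03d", 1:100)
  truth <- ids[1:25]
  areas <- replicate(200, attr(pr_curve(sample(ids), truth), "area"))
  expect_lt(abs(mean(areas) - 0.25), 0.05)
})

test_that("jackknife curve is the cumulative truth count", {
  jk <- jackknife_curve(c("E1", "N1", "E2"), c("E1", "E2"))
  expect_equal(jk$true_positives, c(1, 1, 2))
  jk0 <- jackknife_curve(c("N1", "N2"), c("E1"))
  expect_equal(jk0$true_positives, c(0, 0))

  set.seed(17)
  ids <- sprintf("n%03d", 1:80)
  ranking <- sample(ids)
  truth <- sample(ids, 20)
  jk <- jackknife_curve(ranking, truth)
  expect_equal(jk$true_positives, cumsum(ranking %in% truth))
  expect_true(all(diff(jk$true_positives) %in% 0:1))
  expect_equal(jk$true_positives[80], length(intersect(ranking, truth)))
})

test_that("confusion metrics reproduce the hand-built table", {
  # 10 proteins, top 2 predicted, truth {A, C}: TP=1 FP=1 FN=1 TN=7
  ranking <- c("A", "B", paste0("x", 1:8))
  truth <- c("A", "C")
  ranking[5] <- "C"
  cm <- confusion_metrics(ranking, truth, top_fraction = 0.2)
  expect_equal(cm$tp, 1)
  expect_equal(cm$fp, 1)
  expect_equal(cm$fn, 1)
  expect_equal(cm$tn, 7)
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$specificity, 0.875)
  expect_equal(cm$precision, 0.5)
  expect_equal(cm$f_measure, 0.5)
  expect_equal(cm$accuracy, 0.8)
})

test_that("confusion metrics handle perfect, disjoint, and direct predictions", {
  ranking <- c("E1", "E2", "N1", "N2", "N3", "N4", "N5", "N6", "N7", "N8")
  perfect <- confusion_metrics(ranking, c("E1", "E2"), top_fraction = 0.2)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "precision",
                                "f_measure", "accuracy")]),
               c(sensitivity = 1, specificity = 1, precision = 1,
                 f_measure = 1, accuracy = 1))
  disjoint <- confusion_metrics(ranking, c("N7", "N8"), top_fraction = 0.2)
  expect_equal(disjoint$sensitivity, 0)
  expect_equal(disjoint$precision, 0)
  expect_equal(disjoint$f_measure, 0)

  preds <- tibble::tibble(protein = ranking,
                          predicted = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0))
  direct <- confusion_metrics(preds, c("E1", "E2"))
  expect_equal(direct$accuracy, 1)
})

test_that("metrics are invariant to protein relabeling", {
  set.seed(12)
  ids <- sprintf("n%02d", 1:40)
  ranking <- sample(ids)
  truth <- sample(ids, 10)
  perm <- stats::setNames(sprintf("m%02d", 1:40), ids)
  cm1 <- confusion_metrics(ranking, truth)
  cm2 <- confusion_metrics(unname(perm[ranking]), unname(perm[truth]))
  expect_equal(cm1, cm2)
  expect_equal(attr(pr_curve(ranking, truth), "area"),
               attr(pr_curve(unname(perm[ranking]), unname(perm[truth])),
                    "area"))
})

test_that("evaluation report bundles all protocol components", {
  b <- generate_bundle(simulation_config(n_proteins = 80, seed = 3))
  rk <- psgn_ranking(b$edges, b$complexes, b$localization, b$expression)
  rep <- evaluate_ranking(rk, b$positives)
  expect_s3_class(rep, "psgn_report")
  expect_equal(rep$jackknife$true_positives[nrow(rep$jackknife)],
               length(intersect(b$positives, rk$protein)))
  expect_true(all(rep$precision_at_k$precision >= 0 &
                    rep$precision_at_k$precision <= 1))
  expect_equal(rep$precision_at_k$k, default_cutoffs(80))
})

test_that("ablation produces paired rows and detects a planted PC-only signal", {
  # plant signal exclusively in the pc column; other features are noise
  directions <- 0
  for (seed in 1:3) {
    set.seed(seed)
    n <- 120
    label <- rbinom(n, 1, 0.3)
    data <- tibble::tibble(
      protein = sprintf("p%03d", 1:n),
      nnc = stats::runif(n), nnsl = stats::runif(n),
      pc = pmin(1, pmax(0, 0.3 * stats::rnorm(n) + 0.55 * label + 0.2)),
      pec = stats::runif(n), psgn = stats::runif(n),
      label = label
    )
    cfg <- classifier_config(engine = "logistic", frequency_threshold = 5,
                             seed = seed)
    tab <- ablation_harness(data, cfg)
    expect_equal(nrow(tab), 6)
    expect_equal(tab$removed,
                 c("none", "nnc", "nnsl", "pc", "pec", "psgn"))
    full_f <- tab$f_measure[tab$removed == "none"]
    drop_pc <- tab$f_measure[tab$removed == "pc"]
    if (drop_pc < full_f) directions <- directions + 1
  }
  expect_gte(directions, 2)
})

test_that("ablation full row equals a direct pipeline run with the same seed", {
  b <- generate_bundle(simulation_config(n_proteins = 60, seed = 2))
  data <- build_labeled_features(b$edges, b$complexes, b$localization,
                                 b$expression, positives = b$positives)
  cfg <- classifier_config(engine = "logistic", seed = 31)
  tab <- ablation_harness(data, cfg, subsets = list(none = c(
    "nnc", "nnsl", "pc", "pec", "psgn"
  )))
  freq <- frequency_pipeline(data, cfg)
  pred <- tibble::tibble(
    protein = freq$protein,
    predicted = as.integer(freq$positive_count > cfg$frequency_threshold)
  )
  cm <- confusion_metrics(pred, freq$protein[freq$label == 1])
  expect_equal(tab$f_measure, cm$f_measure)
  expect_equal(tab$accuracy, cm$accuracy)
  expect_error(ablation_harness(data, cfg, subsets = list(a = character(0))),
               "non-empty")
})
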