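ranking_ids <- function(ranking) {
  if (is.data.frame(ranking)) {
    if (!"protein" %in% names(ranking)) {
      stop("ranking data frame needs a 'protein' column", call. = FALSE)
    }
    as.character(ranking$protein)
  } else {
    as.character(ranking)
  }
}

#' Precision among the top-k ranked proteins
#'
#' @param ranking A ranked tibble (e.g. from [rank_by_psgn()]) or an ordered
#'   character vector of protein IDs, best first.
#' @param truth Character vector of true essential proteins.
#' @param k Positive integer cutoff(s), each at most the ranking length.
#' @return Numeric vector of |top-k intersect truth| / k, one per `k`.
#' @export
precision_at_k <- function(ranking, truth, k) {
  ids <- ranking_ids(ranking)
  if (any(k < 1) || any(k > length(ids))) {
    stop("k must lie in [1, ", length(ids), "]", call. = FALSE)
  }
  hits <- cumsum(ids %in% truth)
  hits[k] / k
}

#' Precision-recall curve over every rank cutoff
#'
#' Walks the ranking from the top, computing precision and recall at every
#' cutoff 1..n (ties are processed in ranking order). The area is the
#' trapezoidal integral over recall, anchored at the first ranked point
#' (recall 0 is assigned the first point's precision), so a perfect ranking
#' scores exactly 1.
#'
#' @inheritParams precision_at_k
#' @return A tibble of class `psgn_pr` with columns `rank`, `precision`,
#'   `recall`; the area is in the `"area"` attribute (see also
#'   [glance.psgn_pr()]).
#' @export
pr_curve <- function(ranking, truth) {
  ids <- ranking_ids(ranking)
  truth <- intersect(unique(truth), truth)
  if (length(truth) == 0) stop("empty truth set", call. = FALSE)
  hits <- cumsum(ids %in% truth)
  r <- seq_along(ids)
  prec <- hits / r
  rec <- hits / length(truth)
  area <- rec[1] * prec[1]
  if (length(r) > 1) {
    area <- area + sum(diff(rec) * (prec[-1] + prec[-length(prec)]) / 2)
  }
  out <- tibble::tibble(rank = r, precision = prec, recall = rec)
  attr(out, "area") <- area
  attr(out, "n_truth") <- length(truth)
  class(out) <- c("psgn_pr", class(out))
  out
}

#' One-row summary of a precision-recall curve
#'
#' @param x A `psgn_pr` tibble from [pr_curve()].
#' @param ... Unused.
#' @return A one-row tibble: `n_ranked`, `n_truth`, `pr_area`,
#'   `final_recall`.
#' @export
glance.psgn_pr <- function(x, ...) {
  tibble::tibble(
    n_ranked = nrow(x),
    n_truth = attr(x, "n_truth"),
    pr_area = attr(x, "area"),
    final_recall = x$recall[nrow(x)]
  )
}

#' Jackknife curve of cumulative true positives
#'
#' Element r is the number of true essential proteins among the top-r ranked
#' proteins; the curve is non-decreasing with steps of 0 or 1 and ends at the
#' number of truths present in the ranking.
#'
#' @inheritParams precision_at_k
#' @return A tibble of class `psgn_jackknife` with columns `rank` and
#'   `true_positives`.
#' @export
jackknife_curve <- function(ranking, truth) {
  ids <- ranking_ids(ranking)
  out <- tibble::tibble(
    rank = seq_along(ids),
    true_positives = cumsum(ids %in% truth)
  )
  class(out) <- c("psgn_jackknife", class(out))
  out
}

#' Confusion-matrix metrics at a top-fraction binarization
#'
#' For a ranking, the top `top_fraction` of proteins (at least one) are
#' declared essential and the rest non-essential; for classifier output a
#' data frame with `protein` and `predicted` columns is used as-is. The five
#' metrics are sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision
#' TP/(TP+FP), F-measure 2PR/(P+R), and accuracy (TP+TN)/total; any 0/0
#' ratio is reported as 0.
#'
#' @param x A ranking (tibble or ordered ID vector), or a data frame with
#'   columns `protein` and `predicted` (0/1).
#' @param truth Character vector of true essential proteins.
#' @param top_fraction Fraction of top-ranked proteins labeled essential
#'   (default 0.2); ignored when predictions are supplied.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `precision`, `f_measure`, `accuracy`.
#' @export
confusion_metrics <- function(x, truth, top_fraction = 0.2) {
  if (is.data.frame(x) && "predicted" %in% names(x)) {
    universe <- as.character(x$protein)
    predicted <- universe[x$predicted == 1]
  } else {
    universe <- ranking_ids(x)
    if (top_fraction <= 0 || top_fraction >= 1) {
      stop("top_fraction must be in (0, 1)", call. = FALSE)
    }
    predicted <- universe[seq_len(max(1L, floor(top_fraction * length(universe))))]
  }
  truth <- intersect(truth, universe)
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tn <- length(universe) - tp - fp - fn
  ratio <- function(num, den) if (den == 0) 0 else num / den
  prec <- ratio(tp, tp + fp)
  sens <- ratio(tp, tp + fn)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = sens,
    specificity = ratio(tn, tn + fp),
    precision = prec,
    f_measure = ratio(2 * prec * sens, prec + sens),
    accuracy = ratio(tp + tn, length(universe))
  )
}

# Rank-statistic ROC AUC (equivalent to the Mann-Whitney U normalization).
roc_auc <- function(score, label) {
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Default top-k cutoff list scaled to the network size
#'
#' Mirrors the published top-100..top-600 cutoffs (chosen for a 5,093-protein
#' network) proportionally for networks of other sizes.
#'
#' @param n_proteins Number of ranked proteins.
#' @return Integer vector of cutoffs.
#' @export
default_cutoffs <- function(n_proteins) {
  k <- unique(pmax(1L, round(seq(100, 600, by = 100) * n_proteins / 5093)))
  k[k <= n_proteins]
}

#' Full evaluation report for a ranking
#'
#' Bundles precision at the standard cutoffs, the precision-recall curve and
#' area, the jackknife curve, and the confusion metrics at the top-20%
#' binarization.
#'
#' @inheritParams precision_at_k
#' @param cutoffs Integer cutoffs for precision@k (default
#'   [default_cutoffs()]).
#' @param top_fraction Binarization fraction for the confusion metrics
#'   (default 0.2).
#' @return A list of class `psgn_report` with elements `precision_at_k`
#'   (tibble `k`, `precision`), `pr` (`psgn_pr`), `jackknife`
#'   (`psgn_jackknife`), and `confusion` (one-row tibble).
#' @export
evaluate_ranking <- function(ranking, truth, cutoffs = NULL,
                             top_fraction = 0.2) {
  ids <- ranking_ids(ranking)
  if (is.null(cutoffs)) cutoffs <- default_cutoffs(length(ids))
  structure(
    list(
      precision_at_k = tibble::tibble(
        k = cutoffs, precision = precision_at_k(ids, truth, cutoffs)
      ),
      pr = pr_curve(ids, truth),
      jackknife = jackknife_curve(ids, truth),
      confusion = confusion_metrics(ids, truth, top_fraction)
    ),
    class = "psgn_report"
  )
}

#' @export
print.psgn_report <- function(x, ...) {
  cat("<psgn_report>\n")
  cat("  PR area:", signif(attr(x$pr, "area"), 4), "\n")
  cat("  precision@k:\n")
  print(x$precision_at_k, n = Inf)
  cat("  confusion (top fraction):\n")
  print(x$confusion)
  invisible(x)
}

#' Leave-one-feature-out ablation of the classifier pipeline
#'
#' Reruns the frequency-voting pipeline once per feature subset (the full
#' five-feature sequence plus each leave-one-out subset by default), with the
#' same seed in every row so comparisons are paired, and tabulates the five
#' confusion metrics plus ROC AUC of the vote fraction against the labels.
#'
#' @param data Labeled feature tibble from [build_labeled_features()].
#' @param config A [classifier_config()].
#' @param subsets Named list of feature-name vectors; default is the full
#'   set and all leave-one-out subsets of
#'   `c("nnc", "nnsl", "pc", "pec", "psgn")`.
#' @return A tibble with one row per subset: `removed`, `n_features`, the
#'   five metrics, and `auc`.
#' @export
ablation_harness <- function(data, config = classifier_config(),
                             subsets = NULL) {
  all_f <- feature_sequence_order
  if (is.null(subsets)) {
    subsets <- c(list(none = all_f),
                 stats::setNames(lapply(all_f, function(f) setdiff(all_f, f)),
                                 all_f))
  }
  if (any(lengths(subsets) == 0)) {
    stop("feature subsets must be non-empty", call. = FALSE)
  }
  purrr::imap_dfr(subsets, function(feats, name) {
    sub <- data[, c("protein", feats, "label")]
    attr(sub, "scaling") <- attr(data, "scaling")
    freq <- frequency_pipeline(sub, config)
    pred <- tibble::tibble(
      protein = freq$protein,
      predicted = as.integer(freq$positive_count > config$frequency_threshold)
    )
    cm <- confusion_metrics(pred, freq$protein[freq$label == 1])
    vote <- freq$positive_count / pmax(freq$test_appearances, 1L)
    dplyr::bind_cols(
      tibble::tibble(removed = if (identical(name, "none")) "none" else name,
                     n_features = length(feats)),
      cm[, c("sensitivity", "specificity", "precision", "f_measure",
             "accuracy")],
      tibble::tibble(auc = roc_auc(vote, freq$label))
    )
  })
}
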