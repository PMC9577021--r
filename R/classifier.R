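#' Configuration for the repeated-split classifier pipeline
#'
#' Controls the frequency-voting procedure: in each of `n_repetitions` rounds
#' a stratified random `train_fraction` of the proteins trains the classifier
#' and every held-out protein receives a hard label; the per-protein count of
#' positive predictions over its test appearances is the voting score, and
#' proteins whose count exceeds `frequency_threshold` become candidates.
#'
#' @param n_repetitions Number of random splits (default 10).
#' @param train_fraction Fraction of proteins used for training each round
#'   (default `1 / n_repetitions`, so each protein is held out about
#'   `n_repetitions - 1` times).
#' @param frequency_threshold Candidate proteins must be predicted positive
#'   strictly more than this many times (default 8).
#' @param engine Classifier backend: `"bilstm"` (default), `"logistic"`,
#'   `"svm"`, `"rf"`, `"dt"`, or `"oracle"` (predicts the true label; for
#'   pipeline testing only).
#' @param hidden,layers,epochs,learning_rate,class_weighting Bidirectional
#'   LSTM settings, see [bilstm_fit()].
#' @param seed Master seed; fully determines splits and initialization.
#' @return A list of class `psgn_classifier_config`.
#' @export
classifier_config <- function(n_repetitions = 10,
                              train_fraction = 1 / n_repetitions,
                              frequency_threshold = 8,
                              engine = c("bilstm", "logistic", "svm", "rf",
                                         "dt", "oracle"),
                              hidden = 32, layers = 1, epochs = 150,
                              learning_rate = 0.05, class_weighting = TRUE,
                              seed = 1) {
  engine <- match.arg(engine)
  stopifnot(n_repetitions >= 1, train_fraction > 0, train_fraction < 1,
            frequency_threshold >= 0, hidden >= 1, layers >= 1, epochs >= 1,
            learning_rate > 0)
  if (frequency_threshold > n_repetitions) {
    stop("frequency_threshold cannot exceed n_repetitions", call. = FALSE)
  }
  structure(
    list(n_repetitions = as.integer(n_repetitions),
         train_fraction = train_fraction,
         frequency_threshold = as.integer(frequency_threshold),
         engine = engine, hidden = as.integer(hidden),
         layers = as.integer(layers), epochs = as.integer(epochs),
         learning_rate = learning_rate, class_weighting = class_weighting,
         seed = as.integer(seed)),
    class = "psgn_classifier_config"
  )
}

feature_sequence_order <- c("nnc", "nnsl", "pc", "pec", "psgn")

#' Build the labeled feature sequences for classification
#'
#' Computes the five-feature representation (NNC, NNSL, PC, PeC, PSGN, in
#' that fixed sequence order), min-max scales each feature column to
#' \[0, 1\] (a constant column scales to all zeros), and attaches 0/1 labels:
#' 1 for the seed/essential proteins, 0 for every other network protein.
#'
#' @inheritParams ppi_features
#' @param positives Character vector of essential/seed protein IDs (must
#'   intersect the network).
#' @return A tibble with columns `protein`, `nnc`, `nnsl`, `pc`, `pec`,
#'   `psgn`, `label`; the applied per-column minima and maxima are stored in
#'   the `"scaling"` attribute.
#' @export
build_labeled_features <- function(edges, complexes = NULL,
                                   localization = NULL, expression = NULL,
                                   positives, input_count = 100,
                                   k_percent = 5, necc_exponent = 3) {
  feats <- ppi_features(edges, complexes, localization, expression,
                        input_count = input_count, k_percent = k_percent,
                        necc_exponent = necc_exponent)
  positives <- intersect(as.character(positives), feats$protein)
  if (length(positives) == 0) {
    stop("no positive (seed) proteins present in the network", call. = FALSE)
  }
  out <- tibble::tibble(protein = feats$protein)
  scaling <- tibble::tibble(feature = feature_sequence_order,
                            min = NA_real_, max = NA_real_)
  for (f in feature_sequence_order) {
    v <- feats[[f]]
    rng <- range(v)
    scaling$min[scaling$feature == f] <- rng[1]
    scaling$max[scaling$feature == f] <- rng[2]
    out[[f]] <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  }
  out$label <- as.integer(out$protein %in% positives)
  attr(out, "scaling") <- scaling
  out
}

as_sequence_matrix <- function(data) {
  cols <- intersect(feature_sequence_order, names(data))
  m <- as.matrix(data[, cols, drop = FALSE])
  rownames(m) <- data$protein
  m
}

combine_seeds <- function(a, b) {
  ((a %% 46337) * 46337 + (b %% 46337)) %% 2147483646 + 1
}

# Stratified split indices: train gets max(1, round(fraction * class size))
# members of each class so both labels are always represented.
stratified_split <- function(labels, fraction, seed) {
  local_seed(seed, {
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_take <- max(1L, round(fraction * length(idx)))
      n_take <- min(n_take, length(idx) - 1L)  # keep every class testable
      n_take <- max(n_take, 1L)
      train <- c(train, sample(idx, n_take))
    }
    sort(train)
  })
}

fit_and_predict <- function(train_x, train_y, test_x, test_y, config, seed) {
  switch(config$engine,
    bilstm = {
      fit <- bilstm_fit(train_x, train_y, hidden = config$hidden,
                        layers = config$layers, epochs = config$epochs,
                        learning_rate = config$learning_rate,
                        class_weighting = config$class_weighting, seed = seed)
      predict(fit, test_x, type = "class")
    },
    logistic = {
      df <- data.frame(y = train_y, train_x)
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = df, family = stats::binomial())
      )
      p <- suppressWarnings(
        stats::predict(fit, data.frame(test_x), type = "response")
      )
      as.numeric(p >= 0.5)
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop("engine 'svm' needs the e1071 package", call. = FALSE)
      }
      fit <- local_seed(seed, e1071::svm(train_x, factor(train_y)))
      as.numeric(as.character(predict(fit, test_x)))
    },
    rf = {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("engine 'rf' needs the randomForest package", call. = FALSE)
      }
      fit <- local_seed(seed,
        randomForest::randomForest(train_x, factor(train_y)))
      as.numeric(as.character(predict(fit, test_x)))
    },
    dt = {
      if (!requireNamespace("rpart", quietly = TRUE)) {
        stop("engine 'dt' needs the rpart package", call. = FALSE)
      }
      df <- data.frame(y = factor(train_y), train_x)
      fit <- rpart::rpart(y ~ ., data = df, method = "class")
      as.numeric(as.character(
        predict(fit, data.frame(test_x), type = "class")
      ))
    },
    oracle = as.numeric(test_y)
  )
}

#' One train/predict round of the voting pipeline
#'
#' Draws one stratified split, trains the configured classifier on the
#' training proteins, and returns hard labels for every held-out protein.
#' Deterministic given (`config$seed`, `split_seed`).
#'
#' @param data Labeled feature tibble from [build_labeled_features()].
#' @param config A [classifier_config()].
#' @param split_seed Integer seed for this round's split.
#' @return A tibble with columns `protein`, `label`, `predicted` for the test
#'   proteins.
#' @export
train_predict_once <- function(data, config, split_seed = 1) {
  # canonical protein order makes the split invariant to input row order
  data <- data[order(data$protein), ]
  labels <- data$label
  if (length(unique(labels)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  x <- as_sequence_matrix(data)
  seed <- combine_seeds(config$seed, split_seed)
  train <- stratified_split(labels, config$train_fraction, seed)
  test <- setdiff(seq_len(nrow(data)), train)
  pred <- fit_and_predict(x[train, , drop = FALSE], labels[train],
                          x[test, , drop = FALSE], labels[test],
                          config, seed)
  tibble::tibble(protein = data$protein[test], label = labels[test],
                 predicted = as.integer(pred))
}

#' Frequency-voting pipeline over repeated random splits
#'
#' Runs `config$n_repetitions` independent stratified train/test rounds and
#' counts, per protein, how many times it was predicted essential while held
#' out. Everything is reproducible from `config$seed`.
#'
#' @inheritParams train_predict_once
#' @return A tibble of class `psgn_freq` with columns `protein`, `label`,
#'   `positive_count`, `test_appearances`.
#' @export
frequency_pipeline <- function(data, config = classifier_config()) {
  rep_seeds <- local_seed(config$seed,
                          sample.int(1000000L, config$n_repetitions))
  counts <- stats::setNames(integer(nrow(data)), data$protein)
  appear <- counts
  for (i in seq_len(config$n_repetitions)) {
    pred <- train_predict_once(data, config, split_seed = rep_seeds[i])
    appear[pred$protein] <- appear[pred$protein] + 1L
    pos <- pred$protein[pred$predicted == 1L]
    counts[pos] <- counts[pos] + 1L
  }
  out <- tibble::tibble(
    protein = data$protein, label = data$label,
    positive_count = unname(counts[data$protein]),
    test_appearances = unname(appear[data$protein])
  )
  attr(out, "config") <- config
  class(out) <- c("psgn_freq", class(out))
  out
}

#' Select candidate essential proteins by vote count
#'
#' Returns the proteins whose positive-prediction count is strictly greater
#' than the threshold (the published screen keeps scores greater than 8 out
#' of 10 repetitions).
#'
#' @param freq A `psgn_freq` tibble from [frequency_pipeline()].
#' @param threshold Non-negative integer cutoff; defaults to the threshold in
#'   the configuration that produced `freq`, or 8.
#' @return Character vector of candidate protein IDs (sorted).
#' @export
select_candidates <- function(freq, threshold = NULL) {
  if (is.null(threshold)) {
    cfg <- attr(freq, "config")
    threshold <- if (!is.null(cfg)) cfg$frequency_threshold else 8L
  }
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  sort(freq$protein[freq$positive_count > threshold])
}

#' Full classification pipeline from raw inputs
#'
#' Builds labeled feature sequences and runs the frequency-voting pipeline.
#'
#' @inheritParams build_labeled_features
#' @param config A [classifier_config()].
#' @return A `psgn_freq` tibble, see [frequency_pipeline()].
#' @export
psgn_classify <- function(edges, complexes = NULL, localization = NULL,
                          expression = NULL, positives,
                          input_count = 100,
                          config = classifier_config()) {
  data <- build_labeled_features(edges, complexes, localization, expression,
                                 positives, input_count = input_count)
  frequency_pipeline(data, config)
}
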