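# Compact bidirectional LSTM binary classifier, implemented directly in R.
# Sequences here are short (the five-feature protein representation) and
# training sets small, so plain matrix arithmetic with full backpropagation
# through time is fast and keeps the package dependency-free.

sigm <- function(x) 1 / (1 + exp(-x))

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One LSTM direction: parameters for input dim d, hidden size h.
# Gate row blocks in W/U/b order: input, forget, output, cell candidate.
lstm_cell_init <- function(d, h) {
  r <- 1 / sqrt(h)
  W <- matrix(stats::runif(4 * h * d, -r, r), 4 * h, d)
  U <- matrix(stats::runif(4 * h * h, -r, r), 4 * h, h)
  b <- rep(0, 4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias starts open
  list(W = W, U = U, b = b)
}

# xs: list over time of d x n input matrices. Returns per-step gate/state
# caches needed for backpropagation plus the hidden sequence.
lstm_forward <- function(p, xs) {
  h <- length(p$b) / 4
  n <- ncol(xs[[1]])
  idx <- split(seq_len(4 * h), rep(1:4, each = h))
  hs <- cs <- gates <- vector("list", length(xs))
  h_prev <- c_prev <- matrix(0, h, n)
  for (t in seq_along(xs)) {
    z <- p$W %*% xs[[t]] + p$U %*% h_prev + p$b
    gi <- sigm(z[idx[[1]], , drop = FALSE])
    gf <- sigm(z[idx[[2]], , drop = FALSE])
    go <- sigm(z[idx[[3]], , drop = FALSE])
    gg <- tanh(z[idx[[4]], , drop = FALSE])
    c_t <- gf * c_prev + gi * gg
    tc <- tanh(c_t)
    h_t <- go * tc
    gates[[t]] <- list(i = gi, f = gf, o = go, g = gg, tc = tc,
                       h_prev = h_prev, c_prev = c_prev)
    hs[[t]] <- h_t
    cs[[t]] <- c_t
    h_prev <- h_t
    c_prev <- c_t
  }
  list(hs = hs, cs = cs, gates = gates)
}

# dh_ext: list over time of h x n gradients flowing into each hidden state.
# Returns parameter gradients and the gradient w.r.t. each input step.
lstm_backward <- function(p, xs, cache, dh_ext) {
  h <- length(p$b) / 4
  n <- ncol(xs[[1]])
  dW <- p$W * 0
  dU <- p$U * 0
  db <- p$b * 0
  dxs <- vector("list", length(xs))
  dh_carry <- dc <- matrix(0, h, n)
  for (t in rev(seq_along(xs))) {
    g <- cache$gates[[t]]
    dh <- dh_ext[[t]] + dh_carry
    do_ <- dh * g$tc
    dct <- dc + dh * g$o * (1 - g$tc^2)
    di <- dct * g$g
    df <- dct * g$c_prev
    dg <- dct * g$i
    dz <- rbind(di * g$i * (1 - g$i),
                df * g$f * (1 - g$f),
                do_ * g$o * (1 - g$o),
                dg * (1 - g$g^2))
    dW <- dW + dz %*% t(xs[[t]])
    dU <- dU + dz %*% t(g$h_prev)
    db <- db + rowSums(dz)
    dxs[[t]] <- t(p$W) %*% dz
    dh_carry <- t(p$U) %*% dz
    dc <- dct * g$f
  }
  list(dW = dW, dU = dU, db = db, dxs = dxs)
}

bilstm_init <- function(input_dim, hidden, layers) {
  lapply(seq_len(layers), function(l) {
    d <- if (l == 1) input_dim else 2 * hidden
    list(fwd = lstm_cell_init(d, hidden), bwd = lstm_cell_init(d, hidden))
  })
}

# x: n x T matrix of scalar-token sequences. Returns probabilities plus the
# full cache for the backward pass.
bilstm_forward <- function(params, x) {
  Tn <- ncol(x)
  n <- nrow(x)
  xs <- lapply(seq_len(Tn), function(t) matrix(x[, t], 1, n))
  caches <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    cf <- lstm_forward(params$layers[[l]]$fwd, xs)
    cb <- lstm_forward(params$layers[[l]]$bwd, rev(xs))
    caches[[l]] <- list(fwd = cf, bwd = cb, xs = xs)
    xs <- lapply(seq_len(Tn), function(t) {
      rbind(cf$hs[[t]], cb$hs[[Tn + 1 - t]])
    })
  }
  last <- caches[[length(caches)]]
  hcat <- rbind(last$fwd$hs[[Tn]], last$bwd$hs[[Tn]])
  logit <- as.vector(params$w %*% hcat) + params$b0
  list(prob = sigm(logit), logit = logit, hcat = hcat, caches = caches)
}

# Weighted binary cross-entropy loss and full-parameter gradient.
bilstm_loss_grad <- function(params, x, y, wt) {
  fw <- bilstm_forward(params, x)
  n <- nrow(x)
  Tn <- ncol(x)
  h <- nrow(params$layers[[1]]$fwd$U) / 4
  eps <- 1e-12
  loss <- mean(wt * (-y * log(fw$prob + eps) - (1 - y) * log(1 - fw$prob + eps)))
  dlogit <- matrix(wt * (fw$prob - y) / n, 1, n)
  grads <- list(
    w = dlogit %*% t(fw$hcat),
    b0 = sum(dlogit),
    layers = vector("list", length(params$layers))
  )
  dhcat <- t(params$w) %*% dlogit
  zero <- function(nr, nc) matrix(0, nr, nc)
  dh_fwd <- replicate(Tn, zero(h, n), simplify = FALSE)
  dh_bwd <- replicate(Tn, zero(h, n), simplify = FALSE)
  dh_fwd[[Tn]] <- dhcat[seq_len(h), , drop = FALSE]
  dh_bwd[[Tn]] <- dhcat[h + seq_len(h), , drop = FALSE]
  for (l in rev(seq_along(params$layers))) {
    cache <- fw$caches[[l]]
    bf <- lstm_backward(params$layers[[l]]$fwd, cache$xs, cache$fwd, dh_fwd)
    bb <- lstm_backward(params$layers[[l]]$bwd, rev(cache$xs), cache$bwd,
                        dh_bwd)
    grads$layers[[l]] <- list(
      fwd = list(W = bf$dW, U = bf$dU, b = bf$db),
      bwd = list(W = bb$dW, U = bb$dU, b = bb$db)
    )
    if (l > 1) {
      dh_fwd <- vector("list", Tn)
      dh_bwd <- vector("list", Tn)
      for (t in seq_len(Tn)) {
        dx <- bf$dxs[[t]] + bb$dxs[[Tn + 1 - t]]
        dh_fwd[[t]] <- dx[seq_len(h), , drop = FALSE]
        dh_bwd[[Tn + 1 - t]] <- dx[h + seq_len(h), , drop = FALSE]
      }
    }
  }
  list(loss = loss, grads = grads, prob = fw$prob)
}

# Flatten/unflatten for the Adam update.
flatten_params <- function(p) {
  out <- list(w = p$w, b0 = p$b0)
  for (l in seq_along(p$layers)) {
    for (d in c("fwd", "bwd")) {
      for (m in c("W", "U", "b")) {
        out[[paste(l, d, m, sep = ".")]] <- p$layers[[l]][[d]][[m]]
      }
    }
  }
  out
}

unflatten_params <- function(flat, template) {
  template$w <- flat$w
  template$b0 <- flat$b0
  for (l in seq_along(template$layers)) {
    for (d in c("fwd", "bwd")) {
      for (m in c("W", "U", "b")) {
        template$layers[[l]][[d]][[m]] <- flat[[paste(l, d, m, sep = ".")]]
      }
    }
  }
  template
}

#' Fit the bidirectional LSTM classifier
#'
#' Trains a small bidirectional LSTM on scalar-token feature sequences (one
#' row per protein, one column per sequence step) with a sigmoid head and
#' weighted binary cross-entropy, full-batch Adam optimization, and a fixed
#' epoch budget. All randomness (initialization) is controlled by `seed`.
#'
#' @param x Numeric matrix, proteins in rows, sequence steps in columns.
#' @param y Binary labels (0/1), length `nrow(x)`.
#' @param hidden Hidden units per direction (default 32).
#' @param layers Stacked bidirectional layers (default 1).
#' @param epochs Training epochs (default 150).
#' @param learning_rate Adam step size (default 0.05).
#' @param class_weighting Weight samples inversely to class frequency
#'   (default `TRUE`), so the rare essential class is not ignored.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `psgn_bilstm` with the learned parameters and
#'   the training loss trace.
#' @export
bilstm_fit <- function(x, y, hidden = 32, layers = 1, epochs = 150,
                       learning_rate = 0.05, class_weighting = TRUE,
                       seed = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)),
            hidden >= 1, layers >= 1, epochs >= 1, learning_rate > 0)
  wt <- rep(1, length(y))
  if (class_weighting && length(unique(y)) == 2) {
    wt <- ifelse(y == 1, 0.5 / mean(y == 1), 0.5 / mean(y == 0))
    wt <- wt / mean(wt)
  }
  params <- local_seed(seed, {
    p <- list(layers = bilstm_init(1, hidden, layers))
    r <- 1 / sqrt(2 * hidden)
    p$w <- matrix(stats::runif(2 * hidden, -r, r), 1, 2 * hidden)
    p$b0 <- 0
    p
  })
  m <- v <- lapply(flatten_params(params), function(z) z * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lg <- bilstm_loss_grad(params, x, y, wt)
    loss_trace[ep] <- lg$loss
    gflat <- flatten_params(list(w = lg$grads$w, b0 = lg$grads$b0,
                                 layers = lg$grads$layers))
    pflat <- flatten_params(params)
    for (k in names(pflat)) {
      m[[k]] <- beta1 * m[[k]] + (1 - beta1) * gflat[[k]]
      v[[k]] <- beta2 * v[[k]] + (1 - beta2) * gflat[[k]]^2
      mhat <- m[[k]] / (1 - beta1^ep)
      vhat <- v[[k]] / (1 - beta2^ep)
      pflat[[k]] <- pflat[[k]] - learning_rate * mhat / (sqrt(vhat) + eps)
    }
    params <- unflatten_params(pflat, params)
  }
  structure(
    list(params = params, hidden = hidden, layers = layers, epochs = epochs,
         learning_rate = learning_rate, class_weighting = class_weighting,
         seed = seed, loss_trace = loss_trace,
         n_train = nrow(x), positive_rate = mean(y)),
    class = "psgn_bilstm"
  )
}

#' Predict from a fitted bidirectional LSTM
#'
#' @param object A `psgn_bilstm` fit.
#' @param newdata Numeric matrix of feature sequences (rows are proteins).
#' @param type `"class"` for hard 0/1 labels at the 0.5 threshold, `"prob"`
#'   for positive-class probabilities.
#' @param ... Unused.
#' @return Numeric vector of labels or probabilities.
#' @export
predict.psgn_bilstm <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  p <- bilstm_forward(object$params, as.matrix(newdata))$prob
  if (type == "prob") p else as.numeric(p >= 0.5)
}

#' @export
print.psgn_bilstm <- function(x, ...) {
  cat("<psgn_bilstm> ", x$layers, " layer(s) x ", x$hidden,
      " hidden units/direction; trained ", x$epochs, " epochs on ",
      x$n_train, " sequences (final loss ",
      signif(x$loss_trace[x$epochs], 4), ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameters of a fitted bidirectional LSTM
#'
#' @param x A `psgn_bilstm` fit.
#' @param ... Unused.
#' @return A tibble with one row per parameter block: `layer`, `direction`,
#'   `parameter`, `n`, `mean`, `sd`, `l2_norm`.
#' @export
tidy.psgn_bilstm <- function(x, ...) {
  rows <- list()
  for (l in seq_along(x$params$layers)) {
    for (d in c("fwd", "bwd")) {
      for (m in c("W", "U", "b")) {
        val <- as.numeric(x$params$layers[[l]][[d]][[m]])
        rows[[length(rows) + 1]] <- tibble::tibble(
          layer = l, direction = d, parameter = m, n = length(val),
          mean = mean(val), sd = stats::sd(val),
          l2_norm = sqrt(sum(val^2))
        )
      }
    }
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    layer = NA_integer_, direction = "head", parameter = "w",
    n = length(x$params$w), mean = mean(x$params$w),
    sd = stats::sd(as.numeric(x$params$w)),
    l2_norm = sqrt(sum(x$params$w^2))
  )
  dplyr::bind_rows(rows)
}

#' One-row summary of a fitted bidirectional LSTM
#'
#' @param x A `psgn_bilstm` fit.
#' @param ... Unused.
#' @return A one-row tibble: `hidden`, `layers`, `epochs`, `learning_rate`,
#'   `n_train`, `positive_rate`, `initial_loss`, `final_loss`.
#' @export
glance.psgn_bilstm <- function(x, ...) {
  tibble::tibble(
    hidden = x$hidden, layers = x$layers, epochs = x$epochs,
    learning_rate = x$learning_rate, n_train = x$n_train,
    positive_rate = x$positive_rate,
    initial_loss = x$loss_trace[1],
    final_loss = x$loss_trace[x$epochs]
  )
}
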