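#' Adaptive integration weights
#'
#' The two mixing weights of the PSGN score follow a linear model in the
#' expected number of essential proteins to identify:
#' a = alpha1 + beta1 * input and b = alpha2 + beta2 * input, clamped to
#' \[0, 1\]. With the default coefficients (alpha1 = 0.49, beta1 = -0.0005,
#' alpha2 = 1, beta2 = -0.0003) both weights decrease as more candidates are
#' requested, shifting emphasis from node-level biological evidence (complex
#' membership, localization) toward edge-level co-expression and finally pure
#' network topology.
#'
#' @param input_count Expected number of essential proteins to identify
#'   (positive integer).
#' @param alpha1,beta1 Linear coefficients for the node-vs-edge weight a.
#' @param alpha2,beta2 Linear coefficients for the biology-vs-topology
#'   weight b.
#' @return A list with elements `a` and `b`, each in \[0, 1\].
#' @examples
#' adaptive_weights(100) # a = 0.44, b = 0.97
#' @export
adaptive_weights <- function(input_count, alpha1 = 0.49, beta1 = -0.0005,
                             alpha2 = 1, beta2 = -0.0003) {
  if (!is.numeric(input_count) || length(input_count) != 1 ||
      is.na(input_count) || input_count < 1) {
    stop("input_count must be a single number >= 1", call. = FALSE)
  }
  clamp <- function(x) min(max(x, 0), 1)
  list(
    a = clamp(alpha1 + beta1 * input_count),
    b = clamp(alpha2 + beta2 * input_count)
  )
}

#' Integrated PSGN score
#'
#' Combines the four heterogeneous features linearly:
#' `(PC + a * NNSL + (1 - a) * PeC) * b + (1 - b) * NNC`, where a balances
#' node-level against edge-level biological evidence and b balances
#' biological against topological evidence. The alternative grouping
#' `form = "grouped"`, `(a * (PC + NNSL) + (1 - a) * PeC) * b + (1 - b) * NNC`,
#' applies a to both node-level features.
#'
#' @param pc,nnsl,pec,nnc Numeric feature vectors (recycled to a common
#'   length).
#' @param a,b Mixing weights in \[0, 1\], typically from
#'   [adaptive_weights()].
#' @param form Which parenthesization to use: `"printed"` (default) or
#'   `"grouped"`.
#' @return Numeric vector of PSGN scores.
#' @export
psgn_score <- function(pc, nnsl, pec, nnc, a, b,
                       form = c("printed", "grouped")) {
  form <- match.arg(form)
  stopifnot(a >= 0, a <= 1, b >= 0, b <= 1)
  bio <- switch(form,
    printed = pc + a * nnsl + (1 - a) * pec,
    grouped = a * (pc + nnsl) + (1 - a) * pec
  )
  bio * b + (1 - b) * nnc
}

#' Rank proteins by PSGN score
#'
#' Scores every protein in a feature table with the adaptive weights for
#' `input_count` candidates and sorts descending; ties break lexicographically
#' by protein ID, so the ranking is fully deterministic.
#'
#' @param features Feature tibble with columns `protein`, `pc`, `nnsl`,
#'   `pec`, `nnc` (e.g. from [ppi_features()]).
#' @param input_count Expected number of candidates (default 100).
#' @param normalize_pc If `TRUE`, min-max normalize the raw complex counts
#'   before integration (default `FALSE`: PC enters as a raw count).
#' @param form Parenthesization, see [psgn_score()].
#' @return A tibble `rank`, `protein`, `psgn`, `pc`, `nnsl`, `pec`, `nnc`,
#'   sorted by descending score, of class `psgn_ranking`.
#' @export
rank_by_psgn <- function(features, input_count = 100, normalize_pc = FALSE,
                         form = c("printed", "grouped")) {
  if (nrow(features) == 0) stop("empty feature table", call. = FALSE)
  w <- adaptive_weights(input_count)
  pc <- features$pc
  if (normalize_pc) {
    rng <- range(pc)
    pc <- if (diff(rng) > 0) (pc - rng[1]) / diff(rng) else pc * 0
  }
  out <- tibble::tibble(
    protein = features$protein,
    psgn = psgn_score(pc, features$nnsl, features$pec, features$nnc,
                      w$a, w$b, form = form),
    pc = features$pc,
    nnsl = features$nnsl,
    pec = features$pec,
    nnc = features$nnc
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$psgn), .data$protein)
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  attr(out, "weights") <- w
  attr(out, "input_count") <- input_count
  class(out) <- c("psgn_ranking", class(out))
  out
}

#' Score and rank a network in one call
#'
#' Convenience wrapper: builds the feature table with [ppi_features()] and
#' ranks it with [rank_by_psgn()].
#'
#' @inheritParams ppi_features
#' @inheritParams rank_by_psgn
#' @return A `psgn_ranking` tibble.
#' @export
psgn_ranking <- function(edges, complexes = NULL, localization = NULL,
                         expression = NULL, input_count = 100,
                         k_percent = 5, necc_exponent = 3,
                         normalize_pc = FALSE,
                         form = c("printed", "grouped")) {
  feats <- ppi_features(edges, complexes, localization, expression,
                        input_count = input_count, k_percent = k_percent,
                        necc_exponent = necc_exponent, form = form)
  rank_by_psgn(feats, input_count = input_count, normalize_pc = normalize_pc,
               form = form)
}
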