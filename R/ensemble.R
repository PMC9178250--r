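edge_key <- function(regulator, target) paste(regulator, target, sep = "\r")

#' Construct a prior edge set
#'
#' The prior is an incomplete list of trusted directed edges. It is used
#' only to weight candidate networks by overlap — prior edges are never
#' injected into the inferred network directly.
#'
#' @param edges Edge data frame with `regulator`, `target` columns (as from
#'   [load_edge_list()]).
#' @return A list of class `prior_edge_set` with the de-duplicated edge
#'   keys and `preNumber`, the prior cardinality.
#' @export
prior_edge_set <- function(edges) {
  keys <- unique(edge_key(edges$regulator, edges$target))
  if (length(keys) == 0L) stop("prior edge set is empty")
  structure(list(keys = keys, preNumber = length(keys)),
            class = "prior_edge_set")
}

#' Prior-overlap vote weight of one candidate network
#'
#' A candidate whose top-m edge set shares more edges with the prior is
#' considered closer to the true network and gets a proportionally larger
#' say in the vote: its weight is the number of its top edges found in the
#' prior, divided by the prior size. The weight therefore lies in
#' \[0, min(1, m / preNumber)\].
#'
#' @param candidate A candidate from [extract_candidates()].
#' @param prior A [prior_edge_set()].
#' @return The scalar vote weight.
#' @export
vote_weight <- function(candidate, prior) {
  stopifnot(inherits(prior, "prior_edge_set"))
  te <- candidate$top_edges
  sum(edge_key(te$regulator, te$target) %in% prior$keys) / prior$preNumber
}

#' Integrate candidate networks by weighted voting
#'
#' Sums the full normalised candidate matrices, each scaled by its vote
#' weight: score(i, j) = sum_k w_k * W_k\[i, j\]. With `weights = NULL`
#' (no-prior mode) every candidate votes with weight 1. If every supplied
#' weight is zero — no candidate overlaps the prior at all — the vote would
#' be degenerate, so the function falls back to uniform weights with a
#' warning.
#'
#' @param candidates List of candidates from [extract_candidates()].
#' @param weights Numeric vector of vote weights, one per candidate, or
#'   `NULL` for uniform weights.
#' @return The combined G x G score matrix.
#' @export
weighted_vote <- function(candidates, weights = NULL) {
  stopifnot(length(candidates) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(candidates))
  stopifnot(length(weights) == length(candidates))
  if (all(weights == 0)) {
    warning("no candidate network overlaps the prior; ",
            "falling back to uniform vote weights")
    weights <- rep(1, length(candidates))
  }
  out <- candidates[[1L]]$W * weights[1L]
  for (k in seq_along(candidates)[-1L]) {
    if (!identical(dim(candidates[[k]]$W), dim(out))) {
      stop("candidate ", k, " has mismatched dimensions")
    }
    out <- out + candidates[[k]]$W * weights[k]
  }
  out
}

#' Re-orient a reverse-time weight matrix
#'
#' In the reverse model the predictors are later-time genes predicting an
#' earlier-time target, so a raw weight from predictor a to predicted b is
#' evidence that b (earlier) regulates a (later), under the assumption
#' that genes expressed earlier regulate genes expressed later. The
#' re-orientation is therefore the matrix transpose.
#'
#' @param reverse_raw G x G weight matrix from a reverse-trained model.
#' @return The transposed matrix, where entry (i, j) means i regulates j in
#'   real time.
#' @export
reverse_edge_orientation <- function(reverse_raw) {
  t(reverse_raw)
}

# rank all off-diagonal entries by descending score, lexicographic tie-break
rank_grn <- function(scores, m) {
  all_edges <- top_edges(scores, nrow(scores) * (nrow(scores) - 1L))
  m <- min(m, nrow(all_edges))
  structure(list(scores = scores, ranked_edges = all_edges,
                 selected = all_edges[seq_len(m), , drop = FALSE], m = m),
            class = "ranked_grn")
}

#' Combine forward and reverse score matrices into the final ranked network
#'
#' Adds the two direction-wise score matrices elementwise (each min-max
#' normalised first, by default, so neither direction dominates by scale),
#' then ranks all off-diagonal pairs by descending combined score with a
#' deterministic lexicographic tie-break, and selects the top m edges.
#'
#' @param forward G x G forward-inference score matrix.
#' @param reverse G x G reverse-inference score matrix, already re-oriented
#'   with [reverse_edge_orientation()].
#' @param m Number of edges in the selected network.
#' @param direction_norm Min-max normalise each matrix before adding
#'   (default `TRUE`); set `FALSE` to add the raw matrices.
#' @return A `ranked_grn`: `scores` (combined matrix), `ranked_edges` (all
#'   pairs, rank order), `selected` (top-m prefix).
#' @export
combine_bidirectional <- function(forward, reverse, m = NULL,
                                  direction_norm = TRUE) {
  if (!identical(dim(forward), dim(reverse))) {
    stop("forward and reverse score matrices have different shapes")
  }
  if (direction_norm) {
    forward <- normalize_weight_matrix(forward)
    reverse <- normalize_weight_matrix(reverse)
  }
  scores <- forward + reverse
  if (is.null(m)) m <- default_top_m(nrow(scores))
  rank_grn(scores, m)
}

# default size of the selected network: 1.2 x the reference edge count when
# a reference is available, else 20% of all possible directed edges
default_top_m <- function(G, n_reference = NULL) {
  if (!is.null(n_reference) && n_reference > 0) {
    as.integer(ceiling(1.2 * n_reference))
  } else {
    as.integer(ceiling(0.2 * G * (G - 1L)))
  }
}
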