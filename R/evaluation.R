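# shared bookkeeping: scores and 0/1 labels over all ordered off-diagonal
# gene pairs; reference self-loops are dropped with a warning because the
# model never scores the diagonal
edge_universe <- function(scores, reference) {
  G <- nrow(scores)
  genes <- rownames(scores)
  if (is.null(genes)) genes <- paste0("G", seq_len(G))
  unknown <- setdiff(unique(c(reference$regulator, reference$target)), genes)
  if (length(unknown) > 0L) {
    stop("reference genes absent from the scored gene set: ",
         paste(unknown, collapse = ", "))
  }
  loops <- reference$regulator == reference$target
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop reference edge(s)")
    reference <- reference[!loops, , drop = FALSE]
  }
  i <- rep(seq_len(G), times = G)
  j <- rep(seq_len(G), each = G)
  off <- i != j
  i <- i[off]; j <- j[off]
  keys <- edge_key(genes[i], genes[j])
  truth <- keys %in% unique(edge_key(reference$regulator, reference$target))
  n_pos <- sum(truth)
  if (n_pos == 0L) stop("reference network has no usable edges")
  if (n_pos == length(truth)) {
    stop("reference network contains every possible edge; metrics undefined")
  }
  list(s = scores[cbind(i, j)], y = truth)
}

#' Area under the ROC curve for a scored network
#'
#' Sweeps the score threshold over all distinct values of the off-diagonal
#' score matrix and integrates true-positive rate against false-positive
#' rate. Ties are handled by the rank-sum (trapezoidal) convention, so the
#' result equals P(score of a true edge > score of a false edge) + 1/2
#' P(equal). A constant scoring therefore gives 0.5.
#'
#' @param scores G x G score matrix with gene dimnames (diagonal ignored).
#' @param reference Reference edge data frame (`regulator`, `target`);
#'   regulation signs, if any, are ignored.
#' @return AUROC in \[0, 1\].
#' @export
grn_auroc <- function(scores, reference) {
  u <- edge_universe(scores, reference)
  n1 <- sum(u$y); n0 <- sum(!u$y)
  r <- rank(u$s)  # average ranks on ties = trapezoidal ROC
  (sum(r[u$y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve for a scored network
#'
#' Non-interpolated step summation: descending over distinct score values,
#' the area is the sum of (recall increment) x (precision at that
#' threshold). Edges sharing a score enter as one block, so tied scores are
#' treated symmetrically.
#'
#' @inheritParams grn_auroc
#' @return AUPRC in \[0, 1\].
#' @export
grn_auprc <- function(scores, reference) {
  u <- edge_universe(scores, reference)
  n1 <- sum(u$y)
  thr <- sort(unique(u$s), decreasing = TRUE)
  grp <- match(u$s, thr)
  tp_g <- vapply(seq_along(thr), function(g) sum(u$y[grp == g]), numeric(1L))
  n_g <- vapply(seq_along(thr), function(g) sum(grp == g), numeric(1L))
  tp <- cumsum(tp_g)
  pos <- cumsum(n_g)
  precision <- tp / pos
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate a scored network against a reference
#'
#' @inheritParams grn_auroc
#' @return List with `auroc`, `auprc`, `n_true_edges`,
#'   `n_possible_edges`.
#' @export
evaluate_grn <- function(scores, reference) {
  u <- edge_universe(scores, reference)
  list(auroc = grn_auroc(scores, reference),
       auprc = grn_auprc(scores, reference),
       n_true_edges = sum(u$y),
       n_possible_edges = length(u$y))
}

#' Overall scores across benchmark subsets
#'
#' Each benchmark dataset consists of several simulated subsets; the
#' overall score of a method on the dataset is the arithmetic mean of its
#' per-subset AUROC (and likewise AUPRC).
#'
#' @param per_subset Data frame with columns `auroc` and `auprc`, one row
#'   per subset.
#' @return List with `auroc_score` and `auprc_score`.
#' @export
overall_score <- function(per_subset) {
  stopifnot(nrow(per_subset) >= 1L)
  list(auroc_score = mean(per_subset$auroc),
       auprc_score = mean(per_subset$auprc))
}
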