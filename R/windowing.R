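#' Order cells along pseudotime, per trajectory
#'
#' Splits the cells of an expression matrix by trajectory and, within each
#' trajectory, sorts them by ascending pseudotime. The sort is stable: cells
#' with tied times keep their input order. The resulting series are the
#' time axes on which lagged regression windows are built.
#'
#' @param expr Numeric matrix, genes x cells, with dimnames.
#' @param pt Pseudotime data frame (`cell`, `t`, `trajectory`), as returned
#'   by [load_pseudotime()]. Cells on several trajectories are duplicated
#'   into each, so windows never jump across branches.
#' @return A list with one genes x ordered-cells matrix per trajectory.
#' @export
order_cells <- function(expr, pt) {
  missing_cells <- setdiff(pt$cell, colnames(expr))
  if (length(missing_cells) > 0L) {
    stop("pseudotime cells absent from expression matrix: ",
         paste(missing_cells, collapse = ", "))
  }
  series <- list()
  for (k in sort(unique(pt$trajectory))) {
    sub <- pt[pt$trajectory == k, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("dropping empty trajectory ", k)
      next
    }
    ord <- order(sub$t)  # radix sort: stable on ties
    series[[paste0("trajectory", k)]] <- expr[, sub$cell[ord], drop = FALSE]
  }
  if (length(series) == 0L) stop("no non-empty trajectories")
  series
}

#' Build supervised lagged regression windows
#'
#' Slices each ordered series into maximally overlapping (stride 1) windows
#' of `p` consecutive samples plus a one-sample target. In the forward
#' direction the inputs are samples t..t+p-1 in ascending time and the
#' target is sample t+p; in the reverse direction the inputs are samples
#' t+p..t+1 in descending time and the target is sample t, so the model is
#' asked to predict earlier expression from later expression.
#'
#' @param series A single genes x samples matrix or a list of them (one per
#'   trajectory, as from [order_cells()]).
#' @param p Positive integer time lag: how many preceding (or following)
#'   samples predict the target.
#' @param direction `"forward"` or `"reverse"`.
#' @return A list of class `window_batch` with `inputs` (array
#'   T x p x G), `targets` (matrix T x G), `p`, `direction`, `genes`.
#'   Each trajectory of length L contributes max(0, L - p) windows.
#' @export
build_windows <- function(series, p, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(p), length(p) == 1L, p >= 1)
  p <- as.integer(p)
  if (is.matrix(series)) series <- list(series)
  genes <- rownames(series[[1L]])
  G <- nrow(series[[1L]])
  lens <- vapply(series, ncol, integer(1L))
  n_win <- pmax(0L, lens - p)
  if (sum(n_win) == 0L) {
    stop("every trajectory is too short: need at least ", p + 1L,
         " ordered samples to build one window with lag p = ", p)
  }
  total <- sum(n_win)
  inputs <- array(0, dim = c(total, p, G))
  targets <- matrix(0, nrow = total, ncol = G, dimnames = list(NULL, genes))
  row <- 0L
  for (s in seq_along(series)) {
    X <- series[[s]]
    if (n_win[s] == 0L) next
    for (t in seq_len(n_win[s])) {
      row <- row + 1L
      if (direction == "forward") {
        inputs[row, , ] <- t(X[, t:(t + p - 1L), drop = FALSE])
        targets[row, ] <- X[, t + p]
      } else {
        inputs[row, , ] <- t(X[, (t + p):(t + 1L), drop = FALSE])
        targets[row, ] <- X[, t]
      }
    }
  }
  structure(list(inputs = inputs, targets = targets, p = p,
                 direction = direction, genes = genes),
            class = "window_batch")
}
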