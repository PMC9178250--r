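#' Configuration for the synthetic benchmark generator
#'
#' The generator plants a sparse directed network and simulates noisy
#' expression dynamics from it, emulating the structure of Boolean-model
#' benchmark datasets: a handful of genes, thousands of ordered cells, and
#' a known ground-truth network. It is an explicit stand-in for mechanistic
#' Boolean/ODE simulators, not a reimplementation of one.
#'
#' @param G Gene count.
#' @param density Expected fraction of ordered off-diagonal gene pairs that
#'   carry an edge.
#' @param n_cells Ordered samples per trajectory.
#' @param n_trajectories Number of independent trajectories (fresh initial
#'   states).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   applied at every simulation step.
#' @param dropout_rate Probability of zeroing each entry independently,
#'   mimicking single-cell dropout.
#' @param dynamics `"sigmoid"` (logistic update) or `"linear"` (identity
#'   update with clipping to \[0, 10\]; the planted matrix is rescaled to
#'   spectral radius 0.9 so the system cannot diverge).
#' @param seed Integer seed; all outputs are bit-reproducible given
#'   (config, seed).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(G, density = 0.2, n_cells = 2000L,
                             n_trajectories = 1L, noise_sd = 0.05,
                             dropout_rate = 0,
                             dynamics = c("sigmoid", "linear"), seed = 1L) {
  dynamics <- match.arg(dynamics)
  stopifnot(density > 0, density < 1, noise_sd >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(G = as.integer(G), density = density,
                 n_cells = as.integer(n_cells),
                 n_trajectories = as.integer(n_trajectories),
                 noise_sd = noise_sd, dropout_rate = dropout_rate,
                 dynamics = dynamics, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Plant a sparse ground-truth regulatory network
#'
#' Samples floor(density * G * (G - 1)) edge positions uniformly without
#' replacement among the ordered off-diagonal pairs, with interaction
#' strengths uniform on +/-\[0.5, 1.5\]. Entry A\[i, j\] is the influence of
#' gene i on gene j; the diagonal is zero.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `ground_truth` with `A` (G x G signed strength
#'   matrix) and `support` (edge data frame of the nonzero entries).
#' @export
sample_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  G <- cfg$G
  n_pairs <- G * (G - 1L)
  n_edges <- floor(cfg$density * n_pairs)
  if (n_edges < 1L) {
    stop("density ", cfg$density, " yields no edges for G = ", G)
  }
  genes <- paste0("G", seq_len(G))
  with_seed(cfg$seed, {
    i <- rep(seq_len(G), times = G); j <- rep(seq_len(G), each = G)
    off <- which(i != j)
    pick <- sort(sample(off, n_edges))
    A <- matrix(0, G, G, dimnames = list(genes, genes))
    strengths <- stats::runif(n_edges, 0.5, 1.5) *
      sample(c(-1, 1), n_edges, replace = TRUE)
    A[cbind(i[pick], j[pick])] <- strengths
    support <- data.frame(regulator = genes[i[pick]], target = genes[j[pick]],
                          score = strengths, stringsAsFactors = FALSE)
    structure(list(A = A, support = support), class = "ground_truth")
  })
}

#' Simulate ordered noisy expression from a planted network
#'
#' Each trajectory starts from x(0) ~ Uniform(0, 1)^G and iterates
#' x(t+1)\[j\] = sigma(sum_i A\[i, j\] x(t)\[i\]) + eps, with eps ~
#' N(0, noise_sd), where sigma is the logistic function for `sigmoid`
#' dynamics or the identity clipped to \[0, 10\] for `linear` dynamics
#' (with A rescaled to spectral radius 0.9). After simulation, entries are
#' zeroed independently with probability `dropout_rate`. Pseudotime is the
#' step index.
#'
#' @param gt A `ground_truth` from [sample_network()].
#' @param cfg The matching [synthetic_config()].
#' @return List with `expr` (genes x cells matrix) and `pseudotime` (data
#'   frame `cell`, `t`, `trajectory`).
#' @export
simulate_expression <- function(gt, cfg) {
  stopifnot(inherits(gt, "ground_truth"), inherits(cfg, "synthetic_config"))
  G <- cfg$G
  A <- gt$A
  if (cfg$dynamics == "linear") {
    rho <- max(abs(eigen(A, only.values = TRUE)$values))
    if (rho > 0) A <- A * (0.9 / rho)
  }
  step_fun <- if (cfg$dynamics == "sigmoid") {
    function(v) 1 / (1 + exp(-v))
  } else {
    function(v) pmin(pmax(v, 0), 10)
  }
  with_seed(cfg$seed + 1L, {
    mats <- vector("list", cfg$n_trajectories)
    pts <- vector("list", cfg$n_trajectories)
    for (r in seq_len(cfg$n_trajectories)) {
      X <- matrix(0, G, cfg$n_cells)
      x <- stats::runif(G)
      X[, 1L] <- x
      for (s in seq_len(cfg$n_cells - 1L)) {
        x <- step_fun(as.numeric(x %*% A))
        if (cfg$noise_sd > 0) x <- x + stats::rnorm(G, 0, cfg$noise_sd)
        if (any(abs(x) > 1e6)) {
          stop("dynamics diverged (|x| > 1e6); rescale A to a smaller ",
               "spectral radius")
        }
        X[, s + 1L] <- x
      }
      if (cfg$dropout_rate > 0) {
        X[stats::runif(length(X)) < cfg$dropout_rate] <- 0
      }
      cells <- sprintf("T%d_C%d", r, seq_len(cfg$n_cells))
      dimnames(X) <- list(rownames(A), cells)
      mats[[r]] <- X
      pts[[r]] <- data.frame(cell = cells, t = seq_len(cfg$n_cells) - 1,
                             trajectory = r, stringsAsFactors = FALSE)
    }
    list(expr = do.call(cbind, mats), pseudotime = do.call(rbind, pts))
  })
}

#' Subsample an incomplete prior from the ground truth
#'
#' Draws ceiling(fraction * |support|) true edges uniformly without
#' replacement, emulating the situation where only a fraction (for example
#' 15%) of the real regulatory edges are known in advance.
#'
#' @param gt A `ground_truth`.
#' @param fraction Fraction of true edges to reveal, in (0, 1].
#' @param seed Integer seed.
#' @return An edge data frame (`regulator`, `target`), a subset of the
#'   ground-truth support.
#' @export
subsample_prior <- function(gt, fraction, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"), fraction > 0, fraction <= 1)
  n <- nrow(gt$support)
  k <- ceiling(fraction * n)
  with_seed(seed, {
    pick <- sort(sample.int(n, k))
    gt$support[pick, c("regulator", "target"), drop = FALSE]
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Writes `ExpressionData.csv`, `PseudoTime.csv`, `refNetwork.csv` and
#' (when `prior_fraction` is given) `prior.csv` into a directory, in the
#' same dialects the loaders read.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [synthetic_config()].
#' @param prior_fraction Optional fraction of true edges to write as the
#'   incomplete prior.
#' @return Invisibly, the list of file paths written.
#' @export
write_synthetic_dataset <- function(dir, cfg, prior_fraction = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- sample_network(cfg)
  sim <- simulate_expression(gt, cfg)
  paths <- list(
    expression = file.path(dir, "ExpressionData.csv"),
    pseudotime = file.path(dir, "PseudoTime.csv"),
    reference = file.path(dir, "refNetwork.csv")
  )
  write_expression(sim$expr, paths$expression)
  write_pseudotime(sim$pseudotime, paths$pseudotime)
  ref <- gt$support
  ref$sign <- ifelse(ref$score >= 0, "+", "-")
  ref$score <- NULL
  write_edge_list(ref, paths$reference)
  if (!is.null(prior_fraction)) {
    paths$prior <- file.path(dir, "prior.csv")
    write_edge_list(subsample_prior(gt, prior_fraction, seed = cfg$seed + 2L),
                    paths$prior)
  }
  invisible(paths)
}
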