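#' Configuration for the recurrent regression network
#'
#' The network maps each gene to one unit, so every layer is G units wide
#' and every layer-to-layer weight matrix is gene x gene. It consists of a
#' vanilla tanh recurrent layer unrolled over the `p` lagged inputs, `n_fc`
#' fully connected layers with an identity residual connection added after
#' every `residual_period` layers, and a linear output layer. Training
#' minimises mean squared prediction error plus `alpha` times the L1 norm
#' of all gene x gene weight matrices, which pushes the learned matrices
#' towards the sparsity expected of regulatory networks.
#'
#' @param G Number of genes (network width); must be at least 2.
#' @param p Time lag: number of preceding samples used to predict the next
#'   one. Default 10.
#' @param n_fc Number of fully connected layers; default 50. Must be a
#'   multiple of `residual_period`.
#' @param residual_period Layers per residual skip; default 5.
#' @param alpha L1 penalty coefficient; default 1e-4.
#' @param epochs Training epochs; default 200.
#' @param learning_rate Adam learning rate; default 1e-3.
#' @param batch_size Minibatch size; default 64.
#' @param seed Integer seed driving parameter initialisation (under
#'   `"glorot"`) and batch shuffling.
#' @param init Initialisation scheme. `"identity"` (default) anchors the
#'   network to the gene coordinate system: input projection and output
#'   layer start at the identity, every other weight at zero, so each
#'   residual block starts as the identity map and the whole network
#'   starts as a persistence predictor. Weight extraction identifies
#'   hidden unit j with gene j, and this anchoring keeps that
#'   identification valid during training (random initialisation lets the
#'   optimiser settle into unit permutations, which scrambles extracted
#'   edges). `"glorot"` gives standard uniform random initialisation.
#' @return A list of class `model_config`.
#' @export
model_config <- function(G, p = 10L, n_fc = 50L, residual_period = 5L,
                         alpha = 1e-4, epochs = 200L, learning_rate = 1e-3,
                         batch_size = 64L, seed = 1L,
                         init = c("identity", "glorot")) {
  init <- match.arg(init)
  G <- as.integer(G); p <- as.integer(p); n_fc <- as.integer(n_fc)
  residual_period <- as.integer(residual_period)
  if (p < 1L) stop("time lag p must be >= 1")
  if (n_fc %% residual_period != 0L) {
    stop("n_fc (", n_fc, ") must be divisible by residual_period (",
         residual_period, ")")
  }
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(G = G, p = p, n_fc = n_fc,
                 residual_period = residual_period, alpha = alpha,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 init = init),
            class = "model_config")
}

# run expr with the global RNG seeded, then restore the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained recurrent regression network
#'
#' Allocates all parameters at their initial values (uniform Glorot draws,
#' zero biases), deterministically from `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @return A list of class `rrn_model` holding the parameter list and the
#'   configuration. Parameters: `Win` (input projection, G x G), `Whh`
#'   (hidden-to-hidden, G x G), one G x G matrix per fully connected layer,
#'   `Wout` (output, G x G), and the corresponding bias vectors.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  G <- cfg$G
  if (G < 2L) stop("need at least 2 genes to infer a network (G = ", G, ")")
  params <- with_seed(cfg$seed, {
    ident <- cfg$init == "identity"
    p <- list(Win = if (ident) diag(G) else glorot(G, G),
              Whh = if (ident) matrix(0, G, G) else glorot(G, G),
              br = numeric(G))
    for (l in seq_len(cfg$n_fc)) {
      p[[paste0("Wfc", l)]] <- if (ident) matrix(0, G, G) else glorot(G, G)
      p[[paste0("bfc", l)]] <- numeric(G)
    }
    p$Wout <- if (ident) diag(G) else glorot(G, G)
    p$bout <- numeric(G)
    p
  })
  structure(list(params = params, cfg = cfg, trained = FALSE,
                 loss_history = numeric(0)),
            class = "rrn_model")
}

# names of the gene x gene weight matrices (L1-penalised; biases are not)
weight_names <- function(cfg) {
  c("Win", "Whh", paste0("Wfc", seq_len(cfg$n_fc)), "Wout")
}

#' Total L1 norm of a model's gene x gene weight matrices
#'
#' @param model An `rrn_model`.
#' @return Sum of absolute values over all weight matrices (biases excluded).
#' @export
l1_norm <- function(model) {
  sum(vapply(weight_names(model$cfg),
             function(nm) sum(abs(model$params[[nm]])), numeric(1L)))
}

# forward pass for a minibatch; returns prediction plus caches for backprop
rrn_forward <- function(params, X, cfg) {
  B <- dim(X)[1L]; p <- cfg$p; G <- cfg$G; P <- cfg$residual_period
  br <- matrix(params$br, B, G, byrow = TRUE)
  Hs <- vector("list", p + 1L)
  Hs[[1L]] <- matrix(0, B, G)
  Xs <- vector("list", p)
  for (t in seq_len(p)) {
    Xt <- matrix(X[, t, ], nrow = B, ncol = G)
    Xs[[t]] <- Xt
    Hs[[t + 1L]] <- tanh(Xt %*% params$Win + Hs[[t]] %*% params$Whh + br)
  }
  zs <- vector("list", cfg$n_fc + 1L)   # zs[[l+1]] = activation after layer l
  hs <- vector("list", cfg$n_fc)        # tanh outputs before the skip add
  zs[[1L]] <- Hs[[p + 1L]]
  for (l in seq_len(cfg$n_fc)) {
    b <- matrix(params[[paste0("bfc", l)]], B, G, byrow = TRUE)
    hs[[l]] <- tanh(zs[[l]] %*% params[[paste0("Wfc", l)]] + b)
    zs[[l + 1L]] <- if (l %% P == 0L) hs[[l]] + zs[[l + 1L - P]] else hs[[l]]
  }
  yhat <- zs[[cfg$n_fc + 1L]] %*% params$Wout +
    matrix(params$bout, B, G, byrow = TRUE)
  list(yhat = yhat, Hs = Hs, Xs = Xs, zs = zs, hs = hs)
}

# gradient of (mean squared error + alpha * L1) for one minibatch
rrn_backward <- function(params, cache, Y, cfg) {
  B <- nrow(Y); G <- cfg$G; P <- cfg$residual_period; n_fc <- cfg$n_fc
  grads <- list()
  dy <- 2 * (cache$yhat - Y) / B
  grads$Wout <- crossprod(cache$zs[[n_fc + 1L]], dy)
  grads$bout <- colSums(dy)
  dz <- dy %*% t(params$Wout)
  pending <- vector("list", n_fc + 1L)  # skip-connection gradients, by z index
  for (l in n_fc:1L) {
    if (!is.null(pending[[l + 1L]])) {
      dz <- dz + pending[[l + 1L]]
      pending[[l + 1L]] <- NULL
    }
    if (l %% P == 0L) {
      j <- l - P + 1L  # z index (l - P) maps to list slot l - P + 1
      pending[[j]] <- if (is.null(pending[[j]])) dz else pending[[j]] + dz
    }
    dpre <- dz * (1 - cache$hs[[l]]^2)
    grads[[paste0("Wfc", l)]] <- crossprod(cache$zs[[l]], dpre)
    grads[[paste0("bfc", l)]] <- colSums(dpre)
    dz <- dpre %*% t(params[[paste0("Wfc", l)]])
  }
  if (!is.null(pending[[1L]])) dz <- dz + pending[[1L]]
  dH <- dz
  gWin <- matrix(0, G, G); gWhh <- matrix(0, G, G); gbr <- numeric(G)
  for (t in cfg$p:1L) {
    dpre <- dH * (1 - cache$Hs[[t + 1L]]^2)
    gWin <- gWin + crossprod(cache$Xs[[t]], dpre)
    gWhh <- gWhh + crossprod(cache$Hs[[t]], dpre)
    gbr <- gbr + colSums(dpre)
    dH <- dpre %*% t(params$Whh)
  }
  grads$Win <- gWin; grads$Whh <- gWhh; grads$br <- gbr
  if (cfg$alpha > 0) {
    for (nm in weight_names(cfg)) {
      grads[[nm]] <- grads[[nm]] + cfg$alpha * sign(params[[nm]])
    }
  }
  grads
}

#' Train a recurrent regression network on a window batch
#'
#' Minimises the mean squared one-step prediction error over all window
#' samples plus `alpha` times the L1 norm of the gene x gene weight
#' matrices, using minibatch Adam. Training is deterministic given
#' `cfg$seed` (which drives both initialisation and epoch shuffling).
#'
#' @param model An untrained `rrn_model` from [build_model()], or `NULL` to
#'   build one from `cfg`.
#' @param batch A `window_batch` from [build_windows()]; its lag must equal
#'   `cfg$p`.
#' @param cfg The [model_config()] used to build the model.
#' @return The trained `rrn_model`, with `loss_history` holding the mean
#'   per-epoch loss (MSE + L1 term) and `genes` recording gene names.
#' @export
train <- function(model, batch, cfg) {
  if (is.null(model)) model <- build_model(cfg)
  stopifnot(inherits(batch, "window_batch"))
  if (batch$p != cfg$p) {
    stop("window lag (", batch$p, ") does not match cfg$p (", cfg$p, ")")
  }
  n <- dim(batch$inputs)[1L]
  if (n == 0L) stop("empty window batch")
  params <- model$params
  adam_m <- lapply(params, function(x) x * 0)
  adam_v <- lapply(params, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  loss_history <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      epoch_sse <- 0
      for (s in starts) {
        take <- idx[s:min(s + cfg$batch_size - 1L, n)]
        X <- batch$inputs[take, , , drop = FALSE]
        Y <- batch$targets[take, , drop = FALSE]
        cache <- rrn_forward(params, X, cfg)
        epoch_sse <- epoch_sse + sum((cache$yhat - Y)^2)
        grads <- rrn_backward(params, cache, Y, cfg)
        step <- step + 1L
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        for (nm in names(params)) {
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * grads[[nm]]
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * grads[[nm]]^2
          params[[nm]] <- params[[nm]] - cfg$learning_rate * corr *
            adam_m[[nm]] / (sqrt(adam_v[[nm]]) + eps)
        }
      }
      l1 <- sum(vapply(weight_names(cfg),
                       function(nm) sum(abs(params[[nm]])), numeric(1L)))
      loss_history[epoch] <- epoch_sse / n + cfg$alpha * l1
      if (!is.finite(loss_history[epoch])) {
        stop("training loss became non-finite at epoch ", epoch,
             "; try a lower learning_rate")
      }
    }
  })
  model$params <- params
  model$loss_history <- loss_history
  model$trained <- TRUE
  model$genes <- batch$genes
  model$direction <- batch$direction
  model
}

#' Predict one-step-ahead expression with a trained model
#'
#' @param object A trained `rrn_model`.
#' @param inputs Array T x p x G of lagged inputs (as in a `window_batch`).
#' @param ... Unused.
#' @return Matrix T x G of predicted expression.
#' @export
predict.rrn_model <- function(object, inputs, ...) {
  rrn_forward(object$params, inputs, object$cfg)$yhat
}

#' Normalise a raw weight matrix into edge evidence
#'
#' Takes elementwise absolute values (so inhibitory weights count as
#' evidence, matching unsigned evaluation), zeroes the diagonal, and
#' min-max scales the matrix to \[0, 1\]. A constant matrix maps to all
#' zeros.
#'
#' @param W A square numeric matrix.
#' @return The normalised matrix.
#' @export
normalize_weight_matrix <- function(W) {
  W <- abs(W)
  diag(W) <- 0
  rng <- range(W)
  if (rng[2L] > rng[1L]) (W - rng[1L]) / (rng[2L] - rng[1L]) else W * 0
}

#' Top m directed edges of a score matrix
#'
#' Ranks all off-diagonal entries by descending score; ties are broken
#' lexicographically on (regulator index, target index) so the selection is
#' deterministic.
#'
#' @param W Square score matrix with gene dimnames.
#' @param m Number of edges to keep; clamped to G*(G-1) with a warning.
#' @return Data frame `regulator`, `target`, `score`, the m top edges in
#'   rank order.
#' @export
top_edges <- function(W, m) {
  G <- nrow(W)
  if (m > G * (G - 1L)) {
    warning("m = ", m, " exceeds the ", G * (G - 1L),
            " possible directed edges; clamping")
    m <- G * (G - 1L)
  }
  genes <- rownames(W)
  if (is.null(genes)) genes <- paste0("G", seq_len(G))
  i <- rep(seq_len(G), times = G)
  j <- rep(seq_len(G), each = G)
  off <- i != j
  i <- i[off]; j <- j[off]; w <- W[cbind(i, j)]
  ord <- order(-w, i, j)[seq_len(m)]
  data.frame(regulator = genes[i[ord]], target = genes[j[ord]],
             score = w[ord], stringsAsFactors = FALSE)
}

#' Extract candidate networks from a trained model
#'
#' Every gene x gene weight matrix sitting between the recurrent layer and
#' the output — the input projection plus each fully connected layer — is
#' read out as one candidate network: normalised with
#' [normalize_weight_matrix()] and summarised by its top-m edge set. With
#' the defaults this yields `n_fc + 1` candidates, each later treated as
#' one voter in the ensemble.
#'
#' @param tm A trained `rrn_model`.
#' @param m Edges kept per candidate (used for prior-overlap vote weights).
#' @param include_recurrent Also extract the hidden-to-hidden and output
#'   matrices as candidates (off by default).
#' @return A list of candidates, each a list with `name`, `W` (normalised
#'   G x G matrix) and `top_edges`.
#' @export
extract_candidates <- function(tm, m, include_recurrent = FALSE) {
  stopifnot(inherits(tm, "rrn_model"), isTRUE(tm$trained), m >= 1)
  nms <- c("Win", paste0("Wfc", seq_len(tm$cfg$n_fc)))
  if (include_recurrent) nms <- c(nms, "Whh", "Wout")
  genes <- tm$genes
  if (is.null(genes)) genes <- paste0("G", seq_len(tm$cfg$G))
  G <- tm$cfg$G
  if (m > G * (G - 1L)) {
    warning("m = ", m, " exceeds the ", G * (G - 1L),
            " possible directed edges; clamping")
    m <- G * (G - 1L)
  }
  lapply(nms, function(nm) {
    W <- normalize_weight_matrix(tm$params[[nm]])
    dimnames(W) <- list(genes, genes)
    list(name = nm, W = W, top_edges = top_edges(W, m))
  })
}
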