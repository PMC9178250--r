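# small in-code fixtures shared across test files

toy_expr <- function(G = 3, n = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(round(runif(G * n), 3), G, n,
              dimnames = list(paste0("G", 1:G), paste0("C", 1:n)))
  m
}

toy_pt <- function(expr, t = NULL) {
  if (is.null(t)) t <- seq_len(ncol(expr)) - 1
  data.frame(cell = colnames(expr), t = t, trajectory = 1L,
             stringsAsFactors = FALSE)
}

write_expr_csv <- function(expr, path = tempfile(fileext = ".csv")) {
  bigrn::write_expression(expr, path)
  path
}

# an ordered series with distinguishable columns: entry [g, t] = 10*g + t
ladder_series <- function(G = 2, n = 6) {
  matrix(10 * seq_len(G) + rep(seq_len(n), each = G), G, n,
         dimnames = list(paste0("G", 1:G), paste0("C", 1:n)))
}

# a fake trained model whose weight matrices are supplied directly, for
# exercising extraction/voting without a training run
fake_trained <- function(mats, G = nrow(mats[[1]]), p = 2, genes = NULL) {
  n_fc <- length(mats) - 1L
  cfg <- model_config(G = G, p = p, n_fc = max(n_fc, 5L), residual_period = 1L)
  cfg$n_fc <- n_fc
  m <- list(params = list(), cfg = cfg, trained = TRUE,
            genes = genes %||% paste0("G", seq_len(G)))
  m$params$Win <- mats[[1]]
  for (l in seq_len(n_fc)) m$params[[paste0("Wfc", l)]] <- mats[[l + 1L]]
  m$params$Whh <- diag(G) * 0
  m$params$Wout <- diag(G) * 0
  class(m) <- "rrn_model"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force AUROC oracle: explicit concordant-pair counting
auroc_bruteforce <- function(s, y) {
  pos <- s[y]; neg <- s[!y]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# brute-force AUPRC oracle: explicit precision-recall stepping over
# descending distinct thresholds
auprc_bruteforce <- function(s, y) {
  thr <- sort(unique(s), decreasing = TRUE)
  area <- 0; prev_recall <- 0
  for (th in thr) {
    sel <- s >= th
    precision <- sum(y & sel) / sum(sel)
    recall <- sum(y & sel) / sum(y)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# turn a score vector + label vector over off-diagonal pairs of a G-gene
# universe into (scores matrix, reference edge df) for the metric functions
vec_to_grn <- function(s, y, G) {
  genes <- paste0("G", seq_len(G))
  i <- rep(seq_len(G), times = G); j <- rep(seq_len(G), each = G)
  off <- i != j
  i <- i[off]; j <- j[off]
  scores <- matrix(0, G, G, dimnames = list(genes, genes))
  scores[cbind(i, j)] <- s
  ref <- data.frame(regulator = genes[i[y]], target = genes[j[y]],
                    stringsAsFactors = FALSE)
  list(scores = scores, reference = ref)
}
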