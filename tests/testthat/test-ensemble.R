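mk_cand <- function(W, m = nrow(W) * (nrow(W) - 1L)) {
  genes <- rownames(W) %||% paste0("G", seq_len(nrow(W)))
  dimnames(W) <- list(genes, genes)
  list(name = "test", W = W, top_edges = top_edges(W, m))
}

test_that("vote weights are overlap counts over prior size", {
  genes <- paste0("G", 1:6)
  W <- matrix(0, 6, 6, dimnames = list(genes, genes))
  # top 5 edges by construction: G1->G2..G6
  W[1, 2:6] <- seq(0.9, 0.5, by = -0.1)
  cand <- mk_cand(W, m = 5)

  prior10 <- data.frame(
    regulator = c(paste0("G", 1:4), rep("G1", 4), "G5", "G6"),
    target = c(paste0("G", c(2, 3, 4, 5)), paste0("G", 3:6), "G6", "G2"))
  # overlap = G1->2,3,4,5,6 vs prior: G1->2, G1->3,4,5,6 -> count pairs
  pr <- prior_edge_set(prior10)
  expect_equal(pr$preNumber, 10L)
  expect_equal(vote_weight(cand, pr), 5 / 10)

  none <- prior_edge_set(data.frame(regulator = "G6", target = "G5"))
  expect_equal(vote_weight(cand, none), 0)

  sub <- prior_edge_set(data.frame(regulator = "G1",
                                   target = paste0("G", c(2, 4, 6))))
  expect_equal(vote_weight(cand, sub), 1)  # top edges contain whole prior

  # bound: 0 <= w <= min(1, m / preNumber)
  expect_lte(vote_weight(cand, pr), min(1, 5 / pr$preNumber))
})

test_that("weighted voting sums full matrices by vote weight", {
  set.seed(3)
  W1 <- matrix(runif(4), 2, 2); diag(W1) <- 0
  W2 <- matrix(runif(4), 2, 2); diag(W2) <- 0
  c1 <- mk_cand(W1); c2 <- mk_cand(W2)
  expect_equal(weighted_vote(list(c1, c2), c(1, 1)), c1$W + c2$W,
               ignore_attr = TRUE)
  expect_equal(weighted_vote(list(c1, c2), c(0.5, 0)), 0.5 * c1$W,
               ignore_attr = TRUE)

  # three 3x3 candidates against an independent loop-based summation
  cands <- lapply(1:3, function(k) {
    W <- matrix(runif(9), 3, 3); diag(W) <- 0
    mk_cand(W)
  })
  w <- c(0.2, 0.3, 0.5)
  got <- weighted_vote(cands, w)
  manual <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    manual[i, j] <- manual[i, j] + w[k] * cands[[k]]$W[i, j]
  }
  expect_equal(got, manual, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("all-zero vote weights fall back to a uniform vote", {
  c1 <- mk_cand(matrix(c(0, 1, 2, 0), 2, 2))
  expect_warning(got <- weighted_vote(list(c1, c1), c(0, 0)), "uniform")
  expect_equal(got, 2 * c1$W, ignore_attr = TRUE)
})

test_that("voting is linear: scaling candidates scales scores, not ranks", {
  set.seed(8)
  cands <- lapply(1:4, function(k) {
    W <- matrix(runif(16), 4, 4); diag(W) <- 0
    mk_cand(W)
  })
  w <- runif(4)
  base <- weighted_vote(cands, w)
  scaled <- weighted_vote(lapply(cands, function(cc) {
    cc$W <- 3 * cc$W; cc
  }), w)
  expect_equal(scaled, 3 * base, tolerance = 1e-12)
  expect_identical(rank_order <- top_edges(scaled, 12)[, 1:2],
                   top_edges(base, 12)[, 1:2])
})

test_that("reverse weights are re-oriented by transposition", {
  W <- matrix(runif(9), 3, 3)
  expect_equal(reverse_edge_orientation(reverse_edge_orientation(W)), W)
  R <- matrix(0, 3, 3, dimnames = list(paste0("G", 1:3), paste0("G", 1:3)))
  R["G1", "G2"] <- 0.7  # raw: later G1 predicts earlier G2 => edge G2 -> G1
  expect_equal(reverse_edge_orientation(R)["G2", "G1"], 0.7)
})

test_that("bidirectional combination adds scores and ranks deterministically", {
  genes <- paste0("G", 1:3)
  F_ <- matrix(runif(9, 0.1, 1), 3, 3, dimnames = list(genes, genes))
  diag(F_) <- 0
  zero <- F_ * 0
  # additive identity: all-zero reverse leaves the forward ranking intact
  both <- combine_bidirectional(F_, zero, m = 6, direction_norm = FALSE)
  solo <- combine_bidirectional(F_, zero, m = 6, direction_norm = FALSE)
  expect_identical(both$ranked_edges[, 1:2], solo$ranked_edges[, 1:2])
  # forward = reverse doubles scores without changing the ranking
  dbl <- combine_bidirectional(F_, F_, m = 6, direction_norm = FALSE)
  expect_equal(dbl$scores, 2 * F_)
  expect_identical(dbl$ranked_edges[, 1:2], both$ranked_edges[, 1:2])

  # symmetric tie between (G1,G2) and (G2,G1): lexicographic order wins
  Fw <- matrix(0, 3, 3, dimnames = list(genes, genes)); Fw["G1", "G2"] <- 1
  Rv <- matrix(0, 3, 3, dimnames = list(genes, genes)); Rv["G2", "G1"] <- 1
  tie <- combine_bidirectional(Fw, Rv, m = 2, direction_norm = FALSE)
  expect_equal(paste(tie$selected$regulator, tie$selected$target),
               c("G1 G2", "G2 G1"))

  expect_error(combine_bidirectional(Fw, matrix(0, 2, 2)), "shape")
})

test_that("reverse inference ranks true chain edges above their transposes", {
  hits <- sapply(1:3, function(s) {
    genes <- paste0("G", 1:3)
    A <- matrix(0, 3, 3, dimnames = list(genes, genes))
    A["G1", "G2"] <- 1.2; A["G2", "G3"] <- 1.2
    gt <- structure(list(A = A, support = data.frame(
      regulator = c("G1", "G2"), target = c("G2", "G3"))),
      class = "ground_truth")
    scfg <- synthetic_config(G = 3, density = 0.3, n_cells = 400,
                             noise_sd = 0.05, seed = 70 + s)
    sim <- simulate_expression(gt, scfg)
    wb <- build_windows(order_cells(sim$expr, sim$pseudotime), 5, "reverse")
    cfg <- model_config(G = 3, p = 5, n_fc = 10, epochs = 60, seed = s)
    tm <- train(NULL, wb, cfg)
    raw <- weighted_vote(extract_candidates(tm, m = 2))
    oriented <- reverse_edge_orientation(raw)
    mean(c(oriented["G1", "G2"] > oriented["G2", "G1"],
           oriented["G2", "G3"] > oriented["G3", "G2"]))
  })
  expect_gt(mean(hits), 0.5)
})
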