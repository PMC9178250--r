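test_that("model layout follows the configuration", {
  cfg <- model_config(G = 5, p = 10, n_fc = 50)
  m <- build_model(cfg)
  fc <- m$params[grep("^Wfc", names(m$params))]
  expect_length(fc, 50L)
  expect_true(all(vapply(fc, function(w) identical(dim(w), c(5L, 5L)),
                         logical(1))))
  expect_identical(dim(m$params$Win), c(5L, 5L))
  expect_identical(dim(m$params$Whh), c(5L, 5L))
  # the recurrent layer is unrolled once per lagged input
  X <- array(0.3, dim = c(4, 10, 5))
  expect_identical(dim(predict(m, X)), c(4L, 5L))

  expect_error(model_config(G = 5, n_fc = 7, residual_period = 5),
               "divisible")
  expect_error(build_model(model_config(G = 1)), "at least 2 genes")
})

test_that("a constant series is learned to near-zero error", {
  c0 <- 0.4
  s <- matrix(c0, 2, 40, dimnames = list(c("G1", "G2"), paste0("C", 1:40)))
  cfg <- model_config(G = 2, p = 3, n_fc = 10, alpha = 0, epochs = 300,
                      seed = 4)
  wb <- build_windows(s, p = 3, direction = "forward")
  tm <- train(NULL, wb, cfg)
  expect_lt(tail(tm$loss_history, 1), 1e-4)
  expect_lte(tail(tm$loss_history, 1), tm$loss_history[1])
  pred <- predict(tm, wb$inputs)
  expect_true(all(abs(pred - c0) < 0.02))
})

test_that("the L1 penalty shrinks the weight matrices", {
  norms <- sapply(1:3, function(s) {
    scfg <- synthetic_config(G = 4, density = 0.25, n_cells = 60,
                             noise_sd = 0.02, seed = 20 + s)
    sim <- simulate_expression(sample_network(scfg), scfg)
    wb <- build_windows(order_cells(sim$expr, sim$pseudotime), 3, "forward")
    fit <- function(a) {
      cfg <- model_config(G = 4, p = 3, n_fc = 10, alpha = a, epochs = 60,
                          seed = s)
      l1_norm(train(NULL, wb, cfg))
    }
    c(none = fit(0), strong = fit(0.1))
  })
  expect_lt(mean(norms["strong", ]), mean(norms["none", ]))
  expect_true(all(norms["strong", ] <= norms["none", ]))
})

test_that("a noiseless linear system is fit to small error", {
  scfg <- synthetic_config(G = 5, density = 0.25, n_cells = 30,
                           n_trajectories = 10, noise_sd = 0,
                           dynamics = "linear", seed = 9)
  sim <- simulate_expression(sample_network(scfg), scfg)
  wb <- build_windows(order_cells(sim$expr, sim$pseudotime), 3, "forward")
  cfg <- model_config(G = 5, p = 3, n_fc = 10, alpha = 0, epochs = 150,
                      seed = 2)
  tm <- train(NULL, wb, cfg)
  expect_lt(tail(tm$loss_history, 1), 1e-2)
})

test_that("training is deterministic given the seed", {
  s <- ladder_series(3, 30) / 40
  wb <- build_windows(s, p = 2, direction = "forward")
  cfg <- model_config(G = 3, p = 2, n_fc = 5, epochs = 30, seed = 77)
  tm1 <- train(NULL, wb, cfg)
  tm2 <- train(NULL, wb, cfg)
  expect_identical(tm1$loss_history, tm2$loss_history)
  c1 <- extract_candidates(tm1, m = 3)
  c2 <- extract_candidates(tm2, m = 3)
  expect_identical(lapply(c1, `[[`, "top_edges"),
                   lapply(c2, `[[`, "top_edges"))
})

test_that("weight-matrix normalisation and top-edge selection", {
  W <- matrix(c(0, 2, -4, 0), 2, 2, dimnames = list(c("g1", "g2"),
                                                    c("g1", "g2")))
  # |.| then min-max: [[0,1],[0.5,0]] with (g1,g2) the strongest edge
  N <- normalize_weight_matrix(W)
  expect_equal(N, matrix(c(0, 0.5, 1, 0), 2, 2), ignore_attr = TRUE)
  te <- top_edges(N, 1)
  expect_equal(te$regulator, "g1")
  expect_equal(te$target, "g2")

  # diagonal is forced to zero even when dominant
  W2 <- diag(c(9, 9)); W2[1, 2] <- 1
  expect_equal(diag(normalize_weight_matrix(W2)), c(0, 0))

  # ties break lexicographically on (regulator, target)
  Wt <- matrix(1, 3, 3); diag(Wt) <- 0
  te3 <- top_edges(Wt, 3)
  expect_equal(paste(te3$regulator, te3$target),
               c("G1 G2", "G1 G3", "G2 G1"))

  expect_warning(tem <- top_edges(Wt, 99), "clamping")
  expect_equal(nrow(tem), 6L)
})

test_that("every matrix between recurrence and output becomes a candidate", {
  mats <- replicate(51, matrix(runif(9), 3, 3), simplify = FALSE)
  tm <- fake_trained(mats, p = 2)
  cands <- extract_candidates(tm, m = 4)
  expect_length(cands, 51L)
  expect_equal(cands[[1]]$name, "Win")
  expect_true(all(vapply(cands, function(cc) {
    all(cc$W >= 0 & cc$W <= 1) && all(diag(cc$W) == 0)
  }, logical(1))))
  expect_length(extract_candidates(tm, m = 4, include_recurrent = TRUE), 53L)
})

test_that("planted linear networks are recovered by the input projection", {
  # many short trajectories keep every transition informative (decaying
  # clipped-linear dynamics carry signal only in early steps), and a
  # moderate density lets inhibitory edges show through multi-parent
  # targets despite the clip at zero
  aucs <- sapply(1:3, function(s) {
    scfg <- synthetic_config(G = 8, density = 0.3, n_cells = 2,
                             n_trajectories = 200, noise_sd = 0,
                             dynamics = "linear", seed = 40 + s)
    gt <- sample_network(scfg)
    sim <- simulate_expression(gt, scfg)
    wb <- build_windows(order_cells(sim$expr, sim$pseudotime), 1, "forward")
    cfg <- model_config(G = 8, p = 1, n_fc = 50, epochs = 200, seed = s)
    tm <- train(NULL, wb, cfg)
    cand <- extract_candidates(tm, m = 2 * nrow(gt$support))[[1]]
    grn_auroc(cand$W, gt$support)  # input projection vs planted support
  })
  expect_gte(mean(aucs), 0.8)
})

test_that("a divergent learning rate is reported, not propagated", {
  s <- ladder_series(2, 20)  # unscaled, values up to ~26
  wb <- build_windows(s, p = 2, direction = "forward")
  cfg <- model_config(G = 2, p = 2, n_fc = 5, epochs = 30,
                      learning_rate = 1e200, seed = 1)
  expect_error(train(NULL, wb, cfg), "learning_rate|non-finite")
})
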