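toy_setup <- function() {
  tt <- tiny_dataset()
  cfg <- model_config(k1 = 2, k2 = 2, kg = 2, kl = 2, nn_layers = c(3, 2),
                      seed = 11)
  list(enc = tt$enc, cfg = cfg,
       params = init_parameters(cfg, tt$enc))
}

test_that("initialization is deterministic and Xavier-scaled", {
  ts <- toy_setup()
  again <- init_parameters(ts$cfg, ts$enc)
  expect_identical(ts$params, again)

  # empirical variance of a large Xavier layer matches 2 / (fan_in + fan_out)
  big_tab <- as_observation_table(data.frame(
    inbred_id = sprintf("I%03d", 1:400), tester_id = "T1",
    location_id = "L1", genetic_group_id = "G1", yield = rep(1, 400)))
  enc <- build_encoding(big_tab)
  cfg <- model_config(k1 = 250, k2 = 2, kg = 2, kl = 2, nn_layers = 2,
                      seed = 5)
  W <- init_parameters(cfg, enc)$W1b  # 400 x 250 = 1e5 draws
  expect_equal(stats::var(as.numeric(W)), 2 / (400 + 250), tolerance = 0.2)

  expect_error(model_config(k1 = 0), "k1")
})

test_that("embedding lookup equals the one-hot matrix product", {
  M <- matrix(c(1, 3, 5, 2, 4, 6), nrow = 3)  # [[1,2],[3,4],[5,6]]
  expect_equal(embed_lookup(M, 1L), c(3, 4))
  expect_error(embed_lookup(M, 3L), "out of range")
  expect_error(embed_lookup(M, -1L), "out of range")

  set.seed(42)
  R <- matrix(rnorm(35), 7, 5)
  for (i in 0:6) {
    onehot <- as.numeric(seq_len(7) == i + 1)
    expect_equal(embed_lookup(R, i), as.numeric(onehot %*% R))
  }
})

test_that("GMF branch computes the h-weighted product and reduces to MF", {
  ts <- toy_setup()
  p <- ts$params
  p$W1b[1, ] <- c(1, 2)
  p$W1t[1, ] <- c(3, 4)

  p$h <- c(1, 1)
  expect_equal(gmf_forward(p, 0, 0), 11)  # plain dot product when h = 1
  p$h <- c(1, 0)
  expect_equal(gmf_forward(p, 0, 0), 3)
  p$h <- c(0, 0)
  expect_equal(gmf_forward(p, 0:1, c(0L, 0L)), c(0, 0))

  # GMF == MF identity on random parameters when h is all-ones
  set.seed(9)
  p$W1b <- matrix(rnorm(4), 2, 2)
  p$W1t <- matrix(rnorm(4), 2, 2)
  p$h <- c(1, 1)
  for (b in 0:1) for (t in 0:1) {
    expect_equal(gmf_forward(p, b, t),
                 sum(p$W1b[b + 1, ] * p$W1t[t + 1, ]))
  }
})

test_that("NN branch follows the tower equations", {
  ts <- toy_setup()
  p <- ts$params
  # all-zero weights: rectifier of zero is zero, head bias zero
  p$W2b[] <- 0; p$W2t[] <- 0; p$Wg[] <- 0; p$Wl[] <- 0
  for (j in seq_along(p$nn_W)) p$nn_W[[j]][] <- 0
  p$nn_head_w[] <- 0
  expect_equal(nn_forward(p, ts$cfg, 0, 0, 0, 0), 0)

  # single-layer hand computation
  cfg1 <- model_config(k1 = 2, k2 = 1, kg = 1, kl = 1, nn_layers = 2,
                       seed = 3)
  p1 <- init_parameters(cfg1, ts$enc)
  p1$W2b[1, ] <- 0.5
  p1$W2t[1, ] <- -0.25
  p1$Wg[1, ] <- 1.0
  p1$Wl[1, ] <- 2.0
  W1 <- matrix(c(1, 0, 0, 1, 1, -1, 0.5, 0.5), nrow = 2)
  p1$nn_W[[1]] <- W1
  p1$nn_b[[1]] <- c(0.1, -0.2)
  p1$nn_head_w <- c(1, 1)
  p1$nn_head_b <- 0.05
  x <- c(0.5, -0.25, 1.0, 2.0)
  a1 <- pmax(as.numeric(W1 %*% x) + c(0.1, -0.2), 0)
  expect_equal(nn_forward(p1, cfg1, 0, 0, 0, 0), sum(a1) + 0.05)

  # evaluation mode is deterministic
  ts2 <- toy_setup()
  o1 <- nn_forward(ts2$params, ts2$cfg, 0, 0, 0, 0)
  o2 <- nn_forward(ts2$params, ts2$cfg, 0, 0, 0, 0)
  expect_identical(o1, o2)
})

test_that("training-mode dropout perturbs the forward pass", {
  ts <- toy_setup()
  eval_out <- nn_forward(ts$params, ts$cfg, 0, 0, 0, 0)
  set.seed(1)
  outs <- replicate(20, nn_forward(ts$params, ts$cfg, 0, 0, 0, 0,
                                   train_mode = TRUE))
  expect_gt(length(unique(outs)), 1)
  expect_false(all(outs == eval_out))
})

test_that("fusion layer selector identities hold", {
  ts <- toy_setup()
  p <- ts$params
  qg <- gmf_forward(p, 0, 1)
  qn <- nn_forward(p, ts$cfg, 0, 1, 0, 1)

  p$fusion_W <- c(1, 0); p$fusion_b <- 0
  expect_equal(fused_forward(p, ts$cfg, 0, 1, 0, 1), qg)
  p$fusion_W <- c(0, 1)
  expect_equal(fused_forward(p, ts$cfg, 0, 1, 0, 1), qn)

  # forced branch scalars: q_GMF = 2, q_NN = 4, fusion [0.5, 0.5] + 0.1
  p2 <- ts$params
  p2$W1b[1, ] <- c(2, 0)
  p2$W1t[1, ] <- c(1, 0)
  p2$h <- c(1, 1)
  p2$W2b[] <- 0; p2$W2t[] <- 0; p2$Wg[] <- 0; p2$Wl[] <- 0
  for (j in seq_along(p2$nn_W)) p2$nn_W[[j]][] <- 0
  p2$nn_head_w[] <- 0
  p2$nn_head_b <- 4
  p2$fusion_W <- c(0.5, 0.5)
  p2$fusion_b <- 0.1
  expect_equal(fused_forward(p2, ts$cfg, 0, 0, 0, 0), 3.1)

  cfg_g <- fast_config(branch = "gmf_only")
  expect_equal(fused_forward(p2, cfg_g, 0, 0, 0, 0), 2)
})

test_that("Huber loss matches both branches and is smooth at the knot", {
  expect_equal(huber_loss(1, 1, 0.1), 0)
  expect_equal(huber_loss(1.0, 1.05, 0.1), 0.5 * 0.05^2)      # quadratic
  expect_equal(huber_loss(1.0, 1.3, 0.1), 0.1 * 0.3 - 0.005)  # linear
  expect_equal(huber_loss(1.0, 1.1, 0.1), 0.5 * 0.01)         # knot

  r <- seq(-0.5, 0.5, by = 0.01)
  L <- huber_loss(r, 0, 0.1)
  expect_true(all(L >= 0))
  expect_equal(L, rev(L))                                  # sign-symmetric
  expect_true(all(L <= 0.5 * r^2 + 1e-12))                 # below L2/2

  # once-differentiable at |r| = delta: central differences converge to delta
  eps <- 1e-6
  d_left <- (huber_loss(0.1, 0, 0.1) - huber_loss(0.1 - eps, 0, 0.1)) / eps
  d_right <- (huber_loss(0.1 + eps, 0, 0.1) - huber_loss(0.1, 0, 0.1)) / eps
  expect_equal(d_left, 0.1, tolerance = 1e-4)
  expect_equal(d_right, 0.1, tolerance = 1e-4)

  expect_error(huber_loss(1, 1, 0), "positive")
  expect_error(huber_loss(1:3, 1:2), "length")
})

test_that("coarse configuration requires the nn_only branch", {
  expect_error(model_config(use_parent_ids = FALSE, branch = "fused"),
               "nn_only")
  cfg <- model_config(use_parent_ids = FALSE, branch = "nn_only")
  expect_false(cfg$use_parent_ids)
})
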