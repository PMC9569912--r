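# Instance generators: dilated convolution, gate blocks, cross-attention,
# pooling, and the assembled bag.

test_that("dilated convolution follows its defining sum", {
  expect_equal(dilated_conv_1d(c(3, 1, 4, 1, 5), f = 1, d = 1), c(3, 1, 4, 1, 5))
  # x = 1..5, f = (1,1,1), d = 2: position 5 sees x5 + x3 + x1 = 9
  out <- dilated_conv_1d(1:5, f = c(1, 1, 1), d = 2)
  expect_equal(out[5], 9)
  expect_equal(out, c(1, 2, 4, 6, 9))             # full causal response
  expect_equal(dilated_conv_1d(rep(0, 7), f = c(2, -1, 3), d = 3), rep(0, 7))
})

test_that("multichannel convolution matches the scalar oracle", {
  withr::local_seed(21)
  for (d in c(1L, 2L, 3L)) {
    X <- matrix(stats::rnorm(6 * 2), 6, 2)
    W <- lapply(1:3, function(i) matrix(stats::rnorm(2 * 4), 2, 4))
    b <- stats::rnorm(4)
    got <- mildta:::conv1d_forward(X, W, b, d)$out
    expect_equal(got, oracle_conv1d(X, W, b, d), tolerance = 1e-12)
  }
})

test_that("gate behaviour: zero gate halves output, saturated gate passes it", {
  cfg <- tiny_model_config()
  p <- init_params(cfg, 5, 5, seed = 4)
  blk <- p$cnn_d[[1]]
  X <- matrix(stats::rnorm(4 * 8), 4, 8)
  C <- 8
  # bias-only convolution: content half fixed at 2, gate half at 0
  blk$W <- lapply(blk$W, function(w) w * 0)
  blk$b <- c(rep(2, C), rep(0, C))
  H <- mildta:::conv1d_forward(X, blk$W, blk$b, 1L)$out
  Ho <- H[, 1:C] * mildta:::sigmoid(H[, (C + 1):(2 * C)])
  expect_equal(unique(as.numeric(Ho)), 1)          # 2 * sigmoid(0) = 1
  # saturated gate: output approaches the content half
  blk$b <- c(rep(2, C), rep(50, C))
  H <- mildta:::conv1d_forward(X, blk$W, blk$b, 1L)$out
  Ho <- H[, 1:C] * mildta:::sigmoid(H[, (C + 1):(2 * C)])
  expect_equal(unique(round(as.numeric(Ho), 10)), 2)
})

test_that("gate block matches the scalar oracle on a tiny input", {
  withr::local_seed(22)
  cfg <- tiny_model_config()
  p <- init_params(cfg, 5, 5, seed = 22)
  blk <- p$cnn_d[[2]]
  X <- matrix(stats::rnorm(4 * 8), 4, 8)
  mask <- c(TRUE, TRUE, TRUE, FALSE)
  got <- gate_block(X, blk, mask, dilation = 2L)
  want <- oracle_gate_block(X, blk, mask, dilation = 2L)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("global max pooling is a masked per-channel maximum", {
  X <- matrix(c(1, 5, 3,
                2, 0, 9,
                7, 1, 1), 3, 3, byrow = TRUE)
  expect_equal(global_max_pool(X), c(7, 5, 9))
  # masked final row cannot win even with the largest values
  X2 <- rbind(X, c(100, 100, 100))
  expect_equal(global_max_pool(X2, mask = c(TRUE, TRUE, TRUE, FALSE)), c(7, 5, 9))
  # brute-force enumeration over a random map
  withr::local_seed(23)
  Y <- matrix(stats::rnorm(15), 3, 5)
  expect_equal(global_max_pool(Y), apply(Y, 2, max))
  expect_error(global_max_pool(Y, mask = rep(FALSE, 3)),
               class = "mildta_input_error")
  # constant-over-positions map pools to that constant
  expect_equal(global_max_pool(matrix(4.5, 6, 2)), c(4.5, 4.5))
})

test_that("private instances have width d_model and respect masking", {
  cfg <- tiny_model_config()
  p <- init_params(cfg, 5, 5, seed = 6)
  ctx_d <- random_ctx(6, 8, n_real = 4, seed = 1)
  ctx_p <- random_ctx(10, 8, n_real = 7, seed = 2)
  pr <- private_instances(ctx_d, ctx_p, p, cfg)
  expect_length(pr$private_d, 8)
  expect_length(pr$private_p, 8)
  # pad rows of the input must not matter
  ctx_d2 <- ctx_d
  ctx_d2$values[5:6, ] <- 99
  pr2 <- private_instances(ctx_d2, ctx_p, p, cfg)
  expect_equal(pr2$private_d, pr$private_d, tolerance = 1e-12)
  bad <- ctx_d; bad$mask[] <- FALSE
  expect_error(private_instances(bad, ctx_p, p, cfg),
               class = "mildta_input_error")
})

test_that("receptive field of the dilated stack is bounded", {
  # With dilations (1, 2) and kernel 3, the pre-pooling feature at position s
  # can reach back at most (3-1)*1 + (3-1)*2 = 6 positions; a perturbation
  # further back must leave it unchanged.
  cfg <- tiny_model_config()
  p <- init_params(cfg, 5, 5, seed = 14)
  T <- 16
  ctx <- random_ctx(T, 8, n_real = T, seed = 3)
  base <- ctx$values
  run <- function(vals) {
    c2 <- ctx; c2$values <- vals
    X <- vals
    for (i in seq_along(p$cnn_d))
      X <- gate_block(X, p$cnn_d[[i]], ctx$mask, cfg$dilation_rates[i])
    X
  }
  out0 <- run(base)
  pert <- base; pert[1, ] <- pert[1, ] + 100   # position 1
  out1 <- run(pert)
  s <- 12                                      # distance 11 > 6
  expect_equal(out1[s, ], out0[s, ], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(out1[4, ], out0[4, ])))  # within reach
})

test_that("cross-attention matches the scalar oracle and its singleton limit", {
  withr::local_seed(25)
  cfg <- tiny_model_config()
  p <- init_params(cfg, 5, 5, seed = 25)
  X1 <- random_ctx(2, 8, seed = 4)
  X2 <- random_ctx(3, 8, n_real = 2, seed = 5)
  got <- mhca(X1, X2, p$att_dp, n_heads = 2)
  want <- oracle_mhca(X1$values, X2$values, p$att_dp, X2$mask, 2)
  expect_equal(got$values, want, tolerance = 1e-5)
  expect_equal(got$mask, X1$mask)
  expect_equal(nrow(got$values), 2)

  # single unmasked key: every query attends to it with weight 1
  X2one <- random_ctx(1, 8, seed = 6)
  fw <- mildta:::attention_forward(X1$values, X2one$values, p$att_dp,
                                   X2one$mask, 2)
  for (A in fw$cache$A) expect_equal(as.numeric(A), c(1, 1))
  # Z = X1 + broadcast transform of the single value row
  z <- mhca(X1, X2one, p$att_dp, 2)
  delta <- z$values - X1$values
  expect_equal(delta[1, ], delta[2, ], tolerance = 1e-12)
  expect_error(mhca(X1, list(values = X2$values, mask = rep(FALSE, 3)),
                    p$att_dp, 2),
               class = "mildta_input_error")
})

test_that("the assembled bag has four instances with the right structure", {
  cfg <- tiny_model_config()
  p <- init_params(cfg, 5, 5, seed = 16)
  ctx_d <- random_ctx(6, 8, n_real = 5, seed = 7)
  ctx_p <- random_ctx(10, 8, n_real = 8, seed = 8)
  pr <- private_instances(ctx_d, ctx_p, p, cfg)
  inst <- build_instance_set(ctx_d, ctx_p, pr, p, cfg)
  expect_named(inst, c("public_dp", "public_pd", "public_concat", "private_d"))
  expect_length(inst, 4)                             # bag cardinality
  expect_length(inst$public_concat, 16)              # 2 * d_model
  expect_equal(inst$public_concat[1:8], pr$private_d)
  expect_equal(inst$public_concat[9:16], pr$private_p)
  expect_equal(inst$private_d, pr$private_d)
  expect_true(all(is.finite(unlist(inst))))
})

test_that("instance subsets drop exactly the disabled roles", {
  cfg <- tiny_model_config(instance_subset = c("private", "public_late"))
  p <- init_params(cfg, 5, 5, seed = 17)
  expect_null(p$att_dp)
  ctx_d <- random_ctx(6, 8, seed = 9)
  ctx_p <- random_ctx(10, 8, seed = 10)
  pr <- private_instances(ctx_d, ctx_p, p, cfg)
  inst <- build_instance_set(ctx_d, ctx_p, pr, p, cfg)
  expect_named(inst, c("public_concat", "private_d"))

  cfg2 <- tiny_model_config(instance_subset = "public_early")
  p2 <- init_params(cfg2, 5, 5, seed = 18)
  expect_null(p2$cnn_d)
  inst2 <- build_instance_set(ctx_d, ctx_p, NULL, p2, cfg2)
  expect_named(inst2, c("public_dp", "public_pd"))
})

test_that("mutating pad positions never changes any instance vector", {
  cfg <- tiny_model_config()
  p <- init_params(cfg, 6, 6, seed = 19)
  tok_d <- make_tokens(c(2L, 3L, 4L, 5L), 6)
  tok_p <- make_tokens(c(3L, 2L, 6L, 7L, 4L), 10)
  fw1 <- mildta:::forward_pair(p, cfg, tok_d, tok_p)
  tok_d2 <- tok_d; tok_d2$ids[5:6] <- c(7L, 2L)
  tok_p2 <- tok_p; tok_p2$ids[6:10] <- 5L
  fw2 <- mildta:::forward_pair(p, cfg, tok_d2, tok_p2)
  expect_equal(fw2$instances, fw1$instances, tolerance = 1e-12)
  expect_equal(fw2$yhat, fw1$yhat, tolerance = 1e-12)
})
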