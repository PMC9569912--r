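# MIL regression head: scoring, fusion, loss, gradients, weight recovery.

test_that("scorers map instances to scalars and zero inputs give zero scores", {
  cfg <- tiny_model_config()
  p <- init_params(cfg, 5, 5, seed = 41)
  inst <- structure(list(public_dp = rep(0, 8), public_pd = rep(0, 8),
                         public_concat = rep(0, 16), private_d = rep(0, 8)),
                    class = "mildta_instances")
  s <- score_instances(inst, p$scorers)
  expect_length(s, 4)
  expect_equal(unname(s), rep(0, 4))   # zero biases at init, zero input
  bad <- inst; bad$private_d <- rep(0, 5)
  expect_error(score_instances(bad, p$scorers), class = "mildta_config_error")
})

test_that("a two-layer toy scorer matches hand matrix arithmetic", {
  W1 <- matrix(c(1, 0, -1, 2, 1, 1), 3, 2)   # 3 -> 2
  b1 <- c(0.5, -0.5)
  W2 <- matrix(c(2, -1), 2, 1)               # 2 -> 1
  b2 <- 0.25
  scorer <- list(list(W = W1, b = b1), list(W = W2, b = b2))
  x <- c(0.3, -0.2, 0.7)
  h <- pmax(as.numeric(x %*% W1) + b1, 0)
  want <- as.numeric(h %*% W2) + b2
  got <- score_instances(structure(list(private_d = x), class = "mildta_instances"),
                         list(private_d = scorer))
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("score fusion is the stated weighted sum", {
  expect_equal(fuse_scores(c(3, 7, 1, 9), c(1, 0, 0, 0)), 3)
  expect_equal(fuse_scores(c(3, 7, 1, 9), rep(0.25, 4)), 5)
  expect_equal(fuse_scores(c(1, 2, -1, 0.5), c(0.1, 0.2, 0.3, 0.4)), 0.4)
  expect_error(fuse_scores(1:3, 1:4), class = "mildta_input_error")
})

test_that("mse_loss uses the mean convention", {
  expect_equal(mse_loss(c(2, 5), c(1, 3)), 2.5)
  expect_equal(mse_loss(1:4, 1:4), 0)
  expect_error(mse_loss(numeric(0), numeric(0)), class = "mildta_input_error")
})

test_that("analytic gradients match finite differences through the whole model", {
  cfg <- tiny_model_config()
  p <- init_params(cfg, 8, 8, seed = 42)
  tok_d <- make_tokens(c(2L, 5L, 7L, 3L), 6)
  tok_p <- make_tokens(c(4L, 2L, 9L, 6L, 2L, 3L), 10)
  fw <- mildta:::forward_pair(p, cfg, tok_d, tok_p, want_cache = TRUE)
  g <- mildta:::backward_pair(1, p, cfg, fw$cache)

  fd_at <- function(mutate) {
    eps <- 1e-6
    f <- function(v) mildta:::forward_pair(mutate(p, v), cfg, tok_d, tok_p)$yhat
    (f(eps) - f(-eps)) / (2 * eps)
  }
  # fusion weights: tolerance 1e-4 per the gradient-sanity contract
  for (k in 1:4) {
    fd <- fd_at(function(q, v) { q$fusion$w[k] <- q$fusion$w[k] + v; q })
    expect_equal(g$fusion$w[k], fd, tolerance = 1e-4)
  }
  # a cross-section of deeper parameters
  checks <- list(
    list(get = function(q) q$att_dp$Wv[3, 2],
         set = function(q, v) { q$att_dp$Wv[3, 2] <- q$att_dp$Wv[3, 2] + v; q },
         grad = function(G) G$att_dp$Wv[3, 2]),
    list(get = function(q) q$cnn_p[[2]]$W[[1]][2, 5],
         set = function(q, v) { q$cnn_p[[2]]$W[[1]][2, 5] <- q$cnn_p[[2]]$W[[1]][2, 5] + v; q },
         grad = function(G) G$cnn_p[[2]]$W[[1]][2, 5]),
    list(get = function(q) q$enc_d[[1]]$ffn$b1[3],
         set = function(q, v) { q$enc_d[[1]]$ffn$b1[3] <- q$enc_d[[1]]$ffn$b1[3] + v; q },
         grad = function(G) G$enc_d[[1]]$ffn$b1[3]),
    list(get = function(q) q$emb_p[5, 4],
         set = function(q, v) { q$emb_p[5, 4] <- q$emb_p[5, 4] + v; q },
         grad = function(G) G$emb_p[5, 4]))
  for (ch in checks) {
    fd <- fd_at(ch$set)
    expect_equal(ch$grad(g), fd, tolerance = 1e-5)
  }
})

test_that("prediction is recomputable from instance scores and weights", {
  cfg <- tiny_model_config()
  p <- init_params(cfg, 8, 8, seed = 43)
  tok_d <- make_tokens(c(3L, 2L), 6)
  tok_p <- make_tokens(c(2L, 4L, 5L), 10)
  fw <- mildta:::forward_pair(p, cfg, tok_d, tok_p)
  expect_equal(fw$yhat, fuse_scores(fw$scores, p$fusion$w), tolerance = 1e-12)
})

test_that("fusion weights are recovered from planted linear labels", {
  # Freeze every parameter below the fusion layer; generate labels
  # y = w* . s from the frozen scores and check gradient training recovers
  # w* against the closed-form least-squares solution.
  withr::local_seed(44)
  sim <- generate_dt_dataset(synth_config(n_drugs = 10, n_targets = 6,
                                          density = 1, noise_sd = 0, seed = 45))
  ds <- sim$dataset
  n <- nrow(ds$pairs)
  split <- manual_split(ds, train = 1:n, val = 1:n)
  mcfg <- tiny_model_config()
  mcfg$max_len_drug <- 24L; mcfg$max_len_protein <- 48L
  cfg <- train_config(model = mcfg, learning_rate = 0.02, batch_size = 16,
                      max_epochs = 2500, early_stopping_patience = 2500,
                      vocab_drug = 20, vocab_protein = 25,
                      trainable = "fusion_only", seed = 46)
  tks <- build_tokenizers(ds, cfg, split)
  # plant labels from the frozen scores
  toks <- mildta:::tokenize_entities(ds, tks, cfg)
  p0 <- init_params(cfg$model, length(tks$drug$tokens),
                    length(tks$protein$tokens), seed = cfg$seed)
  S <- t(vapply(seq_len(n), function(i)
    mildta:::forward_pair(p0, cfg$model, toks$drug[[ds$pairs$drug_id[i]]],
                          toks$protein[[ds$pairs$target_id[i]]])$scores,
    numeric(4)))
  w_star <- c(0.9, -0.4, 0.3, 1.2)
  ds$pairs$affinity <- as.numeric(S %*% w_star)
  fit <- train(cfg, split, ds, tokenizers = tks)
  w_hat <- fit$checkpoint$params$fusion$w
  # closed-form oracle on the same design matrix
  w_ls <- as.numeric(stats::lm.fit(S, ds$pairs$affinity)$coefficients)
  expect_equal(w_ls, w_star, tolerance = 1e-8)
  expect_lt(max(abs(w_hat - w_star)), 1e-2)
})
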