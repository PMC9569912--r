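# Training loop, evaluation determinism, checkpoints, configs, CLI.

small_training_setup <- function(n_drugs = 8, n_targets = 6, seed = 50) {
  sim <- generate_dt_dataset(synth_config(n_drugs = n_drugs, n_targets = n_targets,
                                          density = 1, noise_sd = 0,
                                          drug_len_range = c(12L, 18L),
                                          target_len_range = c(20L, 30L),
                                          seed = seed))
  ds <- sim$dataset
  n <- nrow(ds$pairs)
  split <- manual_split(ds, train = seq_len(n), val = seq_len(min(n, 16)),
                        test = seq_len(min(n, 16)))
  mcfg <- model_config(d_model = 8, n_heads = 2, n_layers = 1, ffn_dim = 16,
                       n_gate_blocks = 1, kernel_size = 3, dilation_rates = 1L,
                       max_len_drug = 12, max_len_protein = 20,
                       scorer_widths = c(16L, 8L))
  cfg <- train_config(model = mcfg, batch_size = 16, max_epochs = 4,
                      early_stopping_patience = 10, vocab_drug = 20,
                      vocab_protein = 25, seed = 51)
  list(ds = ds, split = split, cfg = cfg)
}

test_that("training reduces the loss and records a history", {
  su <- small_training_setup()
  fit <- train(su$cfg, su$split, su$ds)
  h <- fit$history
  expect_true(all(c("epoch", "train_loss", "val_loss", "val_ci") %in% names(h)))
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(attr(h, "stopping_reason") %in% c("max_epochs", "patience_exhausted"))
  expect_equal(attr(h, "best_epoch"), which.min(h$val_loss))
})

test_that("training is deterministic given seed, config and data", {
  su <- small_training_setup()
  f1 <- train(su$cfg, su$split, su$ds)
  f2 <- train(su$cfg, su$split, su$ds)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$checkpoint$params$fusion$w, f2$checkpoint$params$fusion$w)
})

test_that("early stopping triggers after a validation plateau", {
  su <- small_training_setup()
  cfg <- su$cfg
  cfg$max_epochs <- 60L
  cfg$early_stopping_patience <- 3L
  cfg$learning_rate <- 0.3         # oscillates; validation loss plateaus fast
  fit <- train(cfg, su$split, su$ds)
  h <- fit$history
  expect_identical(attr(h, "stopping_reason"), "patience_exhausted")
  expect_lt(nrow(h), 60)
})

test_that("evaluation is deterministic and checkpoints round-trip", {
  su <- small_training_setup()
  fit <- train(su$cfg, su$split, su$ds)
  r1 <- evaluate(fit$checkpoint, su$split, su$ds, "test")
  r2 <- evaluate(fit$checkpoint, su$split, su$ds, "test")
  expect_identical(r1, r2)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$checkpoint, f)
  ck <- load_checkpoint(f)
  r3 <- evaluate(ck, su$split, su$ds, "test")
  expect_identical(r3, r1)
  expect_error(evaluate(fit$checkpoint,
                        manual_split(su$ds, train = 1, val = 1), su$ds, "test"),
               class = "mildta_input_error")
})

test_that("training aborts with diagnostics when the loss diverges", {
  su <- small_training_setup()
  cfg <- su$cfg
  cfg$learning_rate <- 1e30
  cfg$max_epochs <- 30L
  expect_error(train(cfg, su$split, su$ds), regexp = "divergence",
               class = "mildta_input_error")
})

test_that("every ablation subset configuration trains end-to-end", {
  su <- small_training_setup(n_drugs = 6, n_targets = 4)
  cfg <- su$cfg
  cfg$max_epochs <- 2L
  tab <- ablate(cfg, su$ds, su$split)
  expect_equal(nrow(tab), 7)
  expect_setequal(tab$subset, names(mildta:::ABLATION_SUBSETS))
  expect_equal(tab$n_instances[tab$subset == "private"], 1)
  expect_equal(tab$n_instances[tab$subset == "private+public_late+public_early"], 4)
  expect_true(all(is.finite(tab$mse)))
})

test_that("config files round-trip through the YAML reader", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("model:",
               "  d_model: 16", "  n_heads: 2", "  n_layers: 1",
               "  n_gate_blocks: 1", "  dilation_rates: 2",
               "  max_len_drug: 10", "  max_len_protein: 20",
               "  scorer_widths: [8, 4]",
               "training:",
               "  learning_rate: 0.005", "  batch_size: 8",
               "  max_epochs: 3", "  vocab_drug: 25", "  vocab_protein: 30",
               "  seed: 99"), f)
  cfg <- read_train_config(f)
  expect_s3_class(cfg, "mildta_train_config")
  expect_equal(cfg$model$d_model, 16L)
  expect_equal(cfg$learning_rate, 0.005)
  expect_equal(cfg$betas, c(0.9, 0.999))     # defaults retained
  expect_equal(cfg$eps, 1e-8)
  expect_equal(cfg$seed, 99L)
})

test_that("the CLI dispatcher runs simulate, tokenize and split end-to-end", {
  dir <- withr::local_tempdir()
  data_f <- file.path(dir, "synth.tsv")
  suppressMessages(dmil_cli(c("simulate", "--n-drugs", "8", "--n-targets", "6",
                              "--density", "1", "--seed", "3", "--out", data_f)))
  expect_true(file.exists(data_f))
  ds <- load_dataset(data_f, "pairs-table")
  expect_equal(nrow(ds$pairs), 48)

  corp_f <- file.path(dir, "corpus.txt")
  writeLines(generate_corpus(20, c("A", "B", "C"), c(5, 12), seed = 1), corp_f)
  tok_f <- file.path(dir, "tok.vocab")
  suppressMessages(dmil_cli(c("tokenize", "train", "--corpus", corp_f,
                              "--vocab-size", "8", "--out", tok_f)))
  expect_true(file.exists(tok_f))
  tk <- load_tokenizer(tok_f)
  expect_length(tk$tokens, 8)

  split_f <- file.path(dir, "split.json")
  out <- suppressMessages(dmil_cli(c("split", "--data", data_f, "--strategy",
                                     "blind", "--seed", "4", "--out", split_f)))
  expect_true(file.exists(split_f))
  js <- jsonlite::read_json(split_f, simplifyVector = TRUE)
  expect_identical(js$strategy, "blind")
  expect_error(suppressMessages(dmil_cli(c("nonsense"))),
               class = "mildta_input_error")
})
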