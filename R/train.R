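# Training loop, evaluation, and the instance-subset ablation harness.

#' Training configuration
#'
#' Optimizer defaults follow the published settings: AdamW with learning
#' rate 1e-3, betas (0.9, 0.999) and eps 1e-8, minimizing the mean squared
#' error, with early stopping on the validation loss. The architecture
#' defaults come from [model_config()].
#'
#' @param model a `mildta_config` (architecture).
#' @param learning_rate AdamW step size.
#' @param betas length-2 vector of AdamW moment decays.
#' @param eps AdamW denominator offset.
#' @param weight_decay decoupled weight-decay coefficient (default 0;
#'   unstated in the reference settings).
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping (>= 1).
#' @param vocab_drug,vocab_protein tokenizer vocabulary sizes used when the
#'   tokenizers are trained from the dataset.
#' @param trainable `"all"` or `"fusion_only"` (freeze everything below the
#'   fusion weights; used for fusion-weight recovery analyses).
#' @param seed integer seed controlling initialization and batch shuffling.
#' @return a `mildta_train_config` list.
#' @export
train_config <- function(model = model_config(),
                         learning_rate = 1e-3, betas = c(0.9, 0.999),
                         eps = 1e-8, weight_decay = 0,
                         batch_size = 64L, max_epochs = 100L,
                         early_stopping_patience = 20L,
                         vocab_drug = 900L, vocab_protein = 10000L,
                         trainable = c("all", "fusion_only"),
                         seed = 1L) {
  if (learning_rate <= 0) config_error("train_config: learning_rate must be > 0")
  if (early_stopping_patience < 1) config_error("train_config: patience must be >= 1")
  if (length(model$instance_subset) == 0)
    config_error("train_config: instance_subset must be non-empty")
  out <- list(model = model, learning_rate = learning_rate, betas = betas,
              eps = eps, weight_decay = weight_decay,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              early_stopping_patience = as.integer(early_stopping_patience),
              vocab_drug = as.integer(vocab_drug),
              vocab_protein = as.integer(vocab_protein),
              trainable = match.arg(trainable), seed = as.integer(seed))
  class(out) <- "mildta_train_config"
  out
}

# One decoupled-weight-decay Adam step over a parameter tree. Returns
# updated (params, m, v) trees; gradients are matched to parameters by name.
adamw_step <- function(params, grads, m, v, lr, b1, b2, eps, wd, t) {
  bc1 <- 1 - b1^t; bc2 <- 1 - b2^t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      nm <- names(p)
      for (i in seq_along(p)) {
        if (is.null(p[[i]])) next
        gi <- if (!is.null(nm) && nzchar(nm[i]) && !is.null(g[[nm[i]]])) g[[nm[i]]] else g[[i]]
        r <- rec(p[[i]], gi, m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + wd * p)
      list(p = p, m = m, v = v)
    }
  }
  rec(params, grads, m, v)
}

#' Train the tokenizers a model needs from a dataset
#'
#' Trains one unigram tokenizer on the drug SMILES strings and one on the
#' target sequences (by default from the training partition only, so the
#' vocabulary never sees test sequences).
#'
#' @param ds a `mildta_dataset`.
#' @param cfg a `mildta_train_config`.
#' @param split optional `mildta_split`; when given, only entities that
#'   occur in training pairs contribute to the corpora.
#' @return list with `drug` and `protein` tokenizers.
#' @export
build_tokenizers <- function(ds, cfg, split = NULL) {
  if (is.null(split)) {
    d_corp <- unname(ds$drugs); t_corp <- unname(ds$targets)
  } else {
    d_corp <- unname(ds$drugs[unique(ds$pairs$drug_id[split$train])])
    t_corp <- unname(ds$targets[unique(ds$pairs$target_id[split$train])])
  }
  n_dchar <- length(unique(unlist(strsplit(d_corp, ""))))
  n_tchar <- length(unique(unlist(strsplit(t_corp, ""))))
  list(drug = train_unigram_tokenizer(d_corp, max(cfg$vocab_drug, n_dchar),
                                      seed = cfg$seed),
       protein = train_unigram_tokenizer(t_corp, max(cfg$vocab_protein, n_tchar),
                                         seed = cfg$seed))
}

# Pre-tokenize every unique entity once; returns lookup lists by id.
tokenize_entities <- function(ds, tokenizers, cfg) {
  list(drug = lapply(ds$drugs, function(s)
         suppressMessages(encode(tokenizers$drug, s, cfg$model$max_len_drug))),
       protein = lapply(ds$targets, function(s)
         suppressMessages(encode(tokenizers$protein, s, cfg$model$max_len_protein))))
}

predict_idx <- function(params, cfg, toks, ds, idx) {
  vapply(idx, function(i) {
    forward_pair(params, cfg$model,
                 toks$drug[[ds$pairs$drug_id[i]]],
                 toks$protein[[ds$pairs$target_id[i]]])$yhat
  }, numeric(1))
}

#' Train the MIL affinity model
#'
#' Minimizes the mean-squared-error loss over the training pairs with AdamW,
#' evaluating the validation loss each epoch and stopping early when it has
#' not improved for `early_stopping_patience` epochs. The checkpoint holds
#' the parameters of the best validation epoch, the tokenizers, and the full
#' configuration; a run is a pure function of (seed, config, data).
#'
#' @param cfg a `mildta_train_config`.
#' @param split a `mildta_split`.
#' @param ds the `mildta_dataset` the split indexes.
#' @param tokenizers optional pre-trained tokenizers (list with `drug`,
#'   `protein`); trained from the training partition when omitted.
#' @param verbose print per-epoch losses.
#' @return list with `checkpoint` (class `mildta_checkpoint`) and `history`
#'   (data.frame of per-epoch losses and validation CI, plus `best_epoch`
#'   and `stopping_reason` attributes).
#' @export
train <- function(cfg, split, ds, tokenizers = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "mildta_train_config"), inherits(split, "mildta_split"),
            inherits(ds, "mildta_dataset"))
  if (is.null(tokenizers)) tokenizers <- build_tokenizers(ds, cfg, split)
  toks <- tokenize_entities(ds, tokenizers, cfg)
  params <- init_params(cfg$model, length(tokenizers$drug$tokens),
                        length(tokenizers$protein$tokens), seed = cfg$seed)

  if (cfg$trainable == "fusion_only")
    return(train_fusion_only(cfg, split, ds, tokenizers, toks, params, verbose))

  mstate <- tree_zeros_like(params)
  vstate <- tree_zeros_like(params)
  tr <- split$train; va <- split$val
  y <- ds$pairs$affinity
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_ci = numeric(0))
  step_t <- 0L
  stopping <- "max_epochs"

  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- tr[sample.int(length(tr))]
      ep_loss <- 0
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        bidx <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        grads <- NULL
        bloss <- 0
        for (i in bidx) {
          fw <- tryCatch(
            forward_pair(params, cfg$model,
                         toks$drug[[ds$pairs$drug_id[i]]],
                         toks$protein[[ds$pairs$target_id[i]]],
                         want_cache = TRUE),
            mildta_input_error = function(e) input_error(sprintf(
              "train: divergence at epoch %d (%s); lower the learning rate",
              epoch, conditionMessage(e))))
          if (!is.finite(fw$yhat))
            input_error(sprintf("train: non-finite prediction at epoch %d (divergence); lower the learning rate", epoch))
          resid <- fw$yhat - y[i]
          bloss <- bloss + resid^2
          gi <- backward_pair(2 * resid / length(bidx), params, cfg$model, fw$cache)
          grads <- if (is.null(grads)) gi else tree_add_named(grads, gi)
        }
        ep_loss <- ep_loss + bloss
        step_t <- step_t + 1L
        st <- adamw_step(params, grads, mstate, vstate, cfg$learning_rate,
                         cfg$betas[1], cfg$betas[2], cfg$eps,
                         cfg$weight_decay, step_t)
        params <- st$p; mstate <- st$m; vstate <- st$v
      }
      ep_loss <- ep_loss / length(tr)
      vp <- predict_idx(params, cfg, toks, ds, va)
      vloss <- mse_loss(vp, y[va])
      vci <- tryCatch(concordance_index(vp, y[va]), error = function(e) NA_real_)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                     val_loss = vloss, val_ci = vci))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f  val CI %.3f",
                        epoch, ep_loss, vloss, vci))
      if (vloss < best$loss - 1e-12) {
        best <- list(loss = vloss, params = params, epoch = epoch)
      } else if (epoch - best$epoch >= cfg$early_stopping_patience) {
        stopping <- "patience_exhausted"
        break
      }
    }
  })
  attr(hist, "best_epoch") <- best$epoch
  attr(hist, "stopping_reason") <- stopping
  ckpt <- list(params = best$params, config = cfg, tokenizers = tokenizers)
  class(ckpt) <- "mildta_checkpoint"
  list(checkpoint = ckpt, history = hist)
}

# Fusion-only training: everything below the fusion weights is frozen, so
# the per-pair instance scores are constants; compute them once and run the
# same AdamW/MSE machinery on the fusion parameters alone.
train_fusion_only <- function(cfg, split, ds, tokenizers, toks, params, verbose) {
  tr <- split$train; va <- split$val
  y <- ds$pairs$affinity
  score_of <- function(i)
    forward_pair(params, cfg$model, toks$drug[[ds$pairs$drug_id[i]]],
                 toks$protein[[ds$pairs$target_id[i]]])$scores
  S_tr <- do.call(rbind, lapply(tr, score_of))
  S_va <- if (length(va)) do.call(rbind, lapply(va, score_of)) else NULL
  fus <- params$fusion
  m <- tree_zeros_like(fus); v <- tree_zeros_like(fus)
  best <- list(loss = Inf, fusion = fus, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_ci = numeric(0))
  step_t <- 0L
  stopping <- "max_epochs"
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(length(tr))
      ep_loss <- 0
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        bidx <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        pred <- as.numeric(S_tr[bidx, , drop = FALSE] %*% fus$w) + (fus$b %||% 0)
        resid <- pred - y[tr][bidx]
        ep_loss <- ep_loss + sum(resid^2)
        g <- list(w = as.numeric(t(S_tr[bidx, , drop = FALSE]) %*% (2 * resid / length(bidx))))
        if (!is.null(fus$b)) g$b <- mean(2 * resid)
        step_t <- step_t + 1L
        st <- adamw_step(fus, g, m, v, cfg$learning_rate, cfg$betas[1],
                         cfg$betas[2], cfg$eps, cfg$weight_decay, step_t)
        fus <- st$p; m <- st$m; v <- st$v
      }
      ep_loss <- ep_loss / length(tr)
      if (!is.null(S_va)) {
        vp <- as.numeric(S_va %*% fus$w) + (fus$b %||% 0)
        vloss <- mse_loss(vp, y[va])
        vci <- tryCatch(concordance_index(vp, y[va]), error = function(e) NA_real_)
      } else { vloss <- ep_loss; vci <- NA_real_ }
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                     val_loss = vloss, val_ci = vci))
      if (verbose) message(sprintf("epoch %3d  train %.6f  val %.6f", epoch, ep_loss, vloss))
      if (vloss < best$loss - 1e-12) {
        best <- list(loss = vloss, fusion = fus, epoch = epoch)
      } else if (epoch - best$epoch >= cfg$early_stopping_patience) {
        stopping <- "patience_exhausted"
        break
      }
    }
  })
  params$fusion <- best$fusion
  attr(hist, "best_epoch") <- best$epoch
  attr(hist, "stopping_reason") <- stopping
  ckpt <- list(params = params, config = cfg, tokenizers = tokenizers)
  class(ckpt) <- "mildta_checkpoint"
  list(checkpoint = ckpt, history = hist)
}

# Name-aware gradient accumulation (gradient trees share ordering, but be
# safe and match by name like the optimizer does).
tree_add_named <- function(a, b) {
  if (is.list(a)) {
    nm <- names(a)
    for (i in seq_along(a)) {
      if (is.null(a[[i]])) next
      bi <- if (!is.null(nm) && nzchar(nm[i]) && !is.null(b[[nm[i]]])) b[[nm[i]]] else b[[i]]
      a[[i]] <- tree_add_named(a[[i]], bi)
    }
    a
  } else a + b
}

#' Predict affinities for a set of pairs
#'
#' @param checkpoint a `mildta_checkpoint`.
#' @param ds a `mildta_dataset`.
#' @param idx pair indices (default all).
#' @return numeric vector of predicted affinities.
#' @export
predict_affinity <- function(checkpoint, ds, idx = seq_len(nrow(ds$pairs))) {
  stopifnot(inherits(checkpoint, "mildta_checkpoint"))
  cfg <- checkpoint$config
  toks <- tokenize_entities(ds, checkpoint$tokenizers, cfg)
  predict_idx(checkpoint$params, cfg, toks, ds, idx)
}

#' Evaluate a checkpoint on a split partition
#'
#' Deterministic forward pass over the partition followed by the full
#' metrics report (CI, MSE, Pearson R, rm2, acceptability flag).
#'
#' @param checkpoint a `mildta_checkpoint`.
#' @param split a `mildta_split`.
#' @param ds the matching dataset.
#' @param partition `"test"`, `"val"` or `"train"`.
#' @return a `mildta_metrics` report.
#' @export
evaluate <- function(checkpoint, split, ds, partition = c("test", "val", "train")) {
  partition <- match.arg(partition)
  idx <- split[[partition]]
  if (length(idx) == 0) input_error("evaluate: empty partition")
  pred <- predict_affinity(checkpoint, ds, idx)
  metrics_report(pred, ds$pairs$affinity[idx])
}

#' Save / load a checkpoint
#'
#' @param checkpoint a `mildta_checkpoint`.
#' @param path file path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "mildta_checkpoint"))
  saveRDS(checkpoint, path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "mildta_checkpoint"))
    input_error("load_checkpoint: file does not contain a checkpoint")
  ck
}

ABLATION_SUBSETS <- list(
  "private"                          = c("private"),
  "private+public_late"              = c("private", "public_late"),
  "private+public_early"             = c("private", "public_early"),
  "public_early"                     = c("public_early"),
  "public_late"                      = c("public_late"),
  "public_late+public_early"         = c("public_late", "public_early"),
  "private+public_late+public_early" = c("private", "public_late", "public_early"))

#' Instance-subset ablation study
#'
#' Retrains the model from scratch for each of the seven non-empty subsets
#' of instance families (private, public-late = concatenation, public-early
#' = cross-attention) and evaluates each on the test partition, mirroring
#' the standard ablation design for this architecture.
#'
#' @param base_cfg a `mildta_train_config`; its `instance_subset` is
#'   overridden per row.
#' @param ds a `mildta_dataset`.
#' @param split a `mildta_split`.
#' @param tokenizers optional shared tokenizers.
#' @param verbose print progress.
#' @return data.frame with one row per configuration: subset label, active
#'   instance count, CI, MSE, R, rm2, acceptability.
#' @export
ablate <- function(base_cfg, ds, split, tokenizers = NULL, verbose = FALSE) {
  stopifnot(inherits(base_cfg, "mildta_train_config"))
  if (is.null(tokenizers)) tokenizers <- build_tokenizers(ds, base_cfg, split)
  rows <- lapply(names(ABLATION_SUBSETS), function(lbl) {
    cfg <- base_cfg
    cfg$model$instance_subset <- ABLATION_SUBSETS[[lbl]]
    if (verbose) message("ablate: ", lbl)
    fit <- train(cfg, split, ds, tokenizers = tokenizers)
    rep <- evaluate(fit$checkpoint, split, ds, "test")
    data.frame(subset = lbl,
               n_instances = length(enabled_roles(cfg$model$instance_subset)),
               ci = rep$ci, mse = rep$mse, pearson_r = rep$pearson_r,
               rm2 = rep$rm2, acceptable = rep$acceptable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
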