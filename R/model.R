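# Model configuration, parameter initialization, and the per-pair forward /
# backward pass that assembles the four bag instances and the fused
# affinity prediction.

INSTANCE_ROLES <- c("public_dp", "public_pd", "public_concat", "private_d")

role_of_subset <- list(private = "private_d",
                       public_early = c("public_dp", "public_pd"),
                       public_late = "public_concat")

enabled_roles <- function(instance_subset) {
  roles <- unlist(role_of_subset[instance_subset], use.names = FALSE)
  INSTANCE_ROLES[INSTANCE_ROLES %in% roles]
}

#' Model configuration
#'
#' Architecture hyperparameters with the published defaults: embedding and
#' model width 128, 2 encoder layers per stream, 4 attention heads, 3 gated
#' convolution blocks with kernel size 3 and 128 filters each, maximum token
#' lengths 128 (SMILES) / 512 (protein), and scorer MLPs with hidden widths
#' 1024, 1024, 512 before the scalar output.
#'
#' @param d_model embedding / model width (divisible by `n_heads`).
#' @param n_heads attention heads for self- and cross-attention.
#' @param n_layers transformer encoder layers per stream.
#' @param ffn_dim feed-forward hidden width (default `4 * d_model`).
#' @param n_gate_blocks gated convolution blocks per stream.
#' @param kernel_size convolution kernel size.
#' @param dilation_rates one dilation rate per gate block.
#' @param max_len_drug,max_len_protein padded token-sequence lengths.
#' @param scorer_widths hidden widths of each instance-scoring MLP.
#' @param instance_subset which instance families are active: any non-empty
#'   subset of `"private"`, `"public_early"`, `"public_late"`.
#' @param fusion_intercept add an intercept to the score fusion (default
#'   FALSE: the fusion is a pure weighted sum).
#' @return a `mildta_config` list.
#' @export
model_config <- function(d_model = 128L, n_heads = 4L, n_layers = 2L,
                         ffn_dim = 4L * d_model, n_gate_blocks = 3L,
                         kernel_size = 3L, dilation_rates = c(1L, 2L, 4L),
                         max_len_drug = 128L, max_len_protein = 512L,
                         scorer_widths = c(1024L, 1024L, 512L),
                         instance_subset = c("private", "public_early", "public_late"),
                         fusion_intercept = FALSE) {
  if (d_model %% n_heads != 0)
    config_error("model_config: d_model must be divisible by n_heads")
  if (length(dilation_rates) != n_gate_blocks)
    config_error("model_config: need one dilation rate per gate block")
  if (any(dilation_rates < 1)) config_error("model_config: dilation rates must be >= 1")
  instance_subset <- match.arg(instance_subset,
                               c("private", "public_early", "public_late"),
                               several.ok = TRUE)
  cfg <- list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
              n_layers = as.integer(n_layers), ffn_dim = as.integer(ffn_dim),
              n_gate_blocks = as.integer(n_gate_blocks),
              kernel_size = as.integer(kernel_size),
              dilation_rates = as.integer(dilation_rates),
              max_len_drug = as.integer(max_len_drug),
              max_len_protein = as.integer(max_len_protein),
              scorer_widths = as.integer(scorer_widths),
              instance_subset = instance_subset,
              fusion_intercept = isTRUE(fusion_intercept))
  class(cfg) <- "mildta_config"
  cfg
}

# Fan-in scaled uniform init; deterministic under with_seed at the caller.
init_mat <- function(nr, nc, fan_in = nr) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(1 / fan_in), nr, nc)
}

init_attention <- function(d_model) {
  list(Wq = init_mat(d_model, d_model), Wk = init_mat(d_model, d_model),
       Wv = init_mat(d_model, d_model), Wo = init_mat(d_model, d_model))
}

init_encoder_layer <- function(d_model, ffn_dim) {
  list(att = init_attention(d_model),
       ln1 = list(g = rep(1, d_model), b = rep(0, d_model)),
       ffn = list(W1 = init_mat(d_model, ffn_dim), b1 = rep(0, ffn_dim),
                  W2 = init_mat(ffn_dim, d_model), b2 = rep(0, d_model)),
       ln2 = list(g = rep(1, d_model), b = rep(0, d_model)))
}

init_gate_block <- function(d_model, kernel_size) {
  list(W = lapply(seq_len(kernel_size),
                  function(i) init_mat(d_model, 2L * d_model,
                                       fan_in = d_model * kernel_size)),
       b = rep(0, 2L * d_model),
       ln = list(g = rep(1, d_model), b = rep(0, d_model)))
}

init_mlp <- function(widths) {
  lapply(seq_len(length(widths) - 1), function(i)
    list(W = init_mat(widths[i], widths[i + 1]), b = rep(0, widths[i + 1])))
}

#' Initialize all model parameters
#'
#' @param cfg a `mildta_config`.
#' @param vocab_drug,vocab_protein tokenizer vocabulary sizes (number of real
#'   tokens; the embedding tables add two rows for the pad and unk ids).
#' @param seed integer seed for the fan-in-scaled uniform initialization.
#' @return nested parameter list (`mildta_params`). Components not required
#'   by `cfg$instance_subset` are absent.
#' @export
init_params <- function(cfg, vocab_drug, vocab_protein, seed = 1L) {
  m <- cfg$d_model
  need_private <- any(c("private", "public_late") %in% cfg$instance_subset)
  need_early <- "public_early" %in% cfg$instance_subset
  roles <- enabled_roles(cfg$instance_subset)
  with_seed(seed, {
    p <- list(
      emb_d = init_mat(vocab_drug + 2L, m, fan_in = m),
      emb_p = init_mat(vocab_protein + 2L, m, fan_in = m),
      enc_d = lapply(seq_len(cfg$n_layers), function(i) init_encoder_layer(m, cfg$ffn_dim)),
      enc_p = lapply(seq_len(cfg$n_layers), function(i) init_encoder_layer(m, cfg$ffn_dim))
    )
    if (need_private) {
      p$cnn_d <- lapply(seq_len(cfg$n_gate_blocks), function(i) init_gate_block(m, cfg$kernel_size))
      p$cnn_p <- lapply(seq_len(cfg$n_gate_blocks), function(i) init_gate_block(m, cfg$kernel_size))
    }
    if (need_early) {
      p$att_dp <- init_attention(m)
      p$att_pd <- init_attention(m)
    }
    p$scorers <- stats::setNames(lapply(roles, function(r) {
      width_in <- if (r == "public_concat") 2L * m else m
      init_mlp(c(width_in, cfg$scorer_widths, 1L))
    }), roles)
    p$fusion <- list(w = rep(0.25, length(roles)))
    if (cfg$fusion_intercept) p$fusion$b <- 0
    class(p) <- c("mildta_params", "list")
    p
  })
}

# ---- exported module surfaces ---------------------------------------------

#' Encode a drug/protein token-sequence pair into context matrices
#'
#' Token-id embedding plus sinusoidal positional encoding feeds a stack of
#' transformer encoder layers; the drug and protein streams use independent
#' parameter stacks. With zero layers the output is the embedding plus
#' positional encoding.
#'
#' @param drug,protein `mildta_tokens` objects.
#' @param params a `mildta_params` object.
#' @param cfg the matching `mildta_config`.
#' @return list with `drug` and `protein`, each a list holding `values`
#'   (`max_len x d_model` matrix) and `mask`.
#' @export
encode_pair <- function(drug, protein, params, cfg) {
  list(drug = encode_stream(drug, params$emb_d, params$enc_d, cfg)$ctx,
       protein = encode_stream(protein, params$emb_p, params$enc_p, cfg)$ctx)
}

encode_stream <- function(tok, emb, enc_layers, cfg, want_cache = FALSE) {
  ids <- tok$ids
  if (any(ids < 0) || any(ids + 1L > nrow(emb)))
    input_error("encode_pair: token id outside the embedding table")
  rows <- ids + 1L                 # pad id 0 -> row 1
  X <- emb[rows, , drop = FALSE] + positional_encoding(length(ids), ncol(emb))
  caches <- vector("list", length(enc_layers))
  H <- X
  for (l in seq_along(enc_layers)) {
    st <- encoder_layer_forward(H, enc_layers[[l]], tok$mask, cfg$n_heads)
    caches[[l]] <- st$cache
    H <- st$out
  }
  list(ctx = list(values = H, mask = tok$mask),
       cache = if (want_cache) list(rows = rows, layers = caches) else NULL)
}

encode_stream_backward <- function(dH, cache, enc_layers, emb_dim_rows) {
  dp_layers <- vector("list", length(enc_layers))
  for (l in rev(seq_along(enc_layers))) {
    bb <- encoder_layer_backward(dH, cache$layers[[l]])
    dp_layers[[l]] <- bb$dp
    dH <- bb$dX
  }
  demb <- matrix(0, emb_dim_rows[1], emb_dim_rows[2])
  # accumulate embedding-row gradients (repeated ids add up)
  agg <- rowsum(dH, group = cache$rows)
  demb[as.integer(rownames(agg)), ] <- agg
  list(demb = demb, dp_layers = dp_layers)
}

#' Private-feature branch: gated dilated convolutions plus max pooling
#'
#' Each context matrix passes through the stream's stack of gated dilated
#' convolution blocks and a masked global max pooling. The drug vector is
#' the bag's private instance; the protein vector only feeds the
#' concatenation instance.
#'
#' @param ctx_drug,ctx_protein context matrices (lists with `values`,
#'   `mask`) from [encode_pair()].
#' @param params a `mildta_params` with `cnn_d` / `cnn_p` components.
#' @param cfg the matching `mildta_config`.
#' @return list with `private_d` and `private_p`, numeric vectors of length
#'   `d_model`.
#' @export
private_instances <- function(ctx_drug, ctx_protein, params, cfg) {
  list(private_d = cnn_stream(ctx_drug, params$cnn_d, cfg)$out,
       private_p = cnn_stream(ctx_protein, params$cnn_p, cfg)$out)
}

cnn_stream <- function(ctx, blocks, cfg, want_cache = FALSE) {
  X <- ctx$values
  X[!ctx$mask, ] <- 0
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    st <- gate_block_forward(X, blocks[[i]], ctx$mask, cfg$dilation_rates[i])
    caches[[i]] <- st$cache
    X <- st$out
  }
  gm <- gmp_forward(X, ctx$mask)
  list(out = gm$out,
       cache = if (want_cache) list(blocks = caches, gmp = gm$cache, mask = ctx$mask) else NULL)
}

cnn_stream_backward <- function(dv, cache, blocks) {
  dX <- gmp_backward(dv, cache$gmp)
  dp_blocks <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    bb <- gate_block_backward(dX, cache$blocks[[i]])
    dp_blocks[[i]] <- bb$dp
    dX <- bb$dX
  }
  dX[!cache$mask, ] <- 0
  list(dX = dX, dp_blocks = dp_blocks)
}

#' Multi-head cross-attention between two context matrices
#'
#' Queries come from `query_src`, keys and values from `kv_src` (with its
#' padded positions excluded from every softmax); the head outputs are
#' concatenated, linearly mixed, and added residually to the query stream.
#'
#' @param query_src,kv_src context matrices (lists with `values`, `mask`).
#' @param params attention parameter list (`Wq`, `Wk`, `Wv`, `Wo`).
#' @param n_heads number of heads.
#' @return a context matrix with `query_src`'s length and mask.
#' @export
mhca <- function(query_src, kv_src, params, n_heads = 4L) {
  att <- attention_forward(query_src$values, kv_src$values, params,
                           kv_src$mask, n_heads)
  list(values = query_src$values + att$out, mask = query_src$mask)
}

#' Assemble the instance set of one drug-target bag
#'
#' Builds the (up to) four MIL instances: the two cross-attention public
#' instances (max-pooled), the concatenation of the two private vectors, and
#' the drug private vector, honouring `cfg$instance_subset`.
#'
#' @param ctx_drug,ctx_protein context matrices from [encode_pair()].
#' @param priv output of [private_instances()] (or NULL when neither the
#'   private nor the concatenation instance is active).
#' @param params a `mildta_params`.
#' @param cfg the matching `mildta_config`.
#' @return named list of instance vectors in the fixed role order
#'   `public_dp`, `public_pd`, `public_concat`, `private_d` (class
#'   `mildta_instances`).
#' @export
build_instance_set <- function(ctx_drug, ctx_protein, priv, params, cfg) {
  roles <- enabled_roles(cfg$instance_subset)
  inst <- list()
  if ("public_dp" %in% roles) {
    z <- mhca(ctx_drug, ctx_protein, params$att_dp, cfg$n_heads)
    inst$public_dp <- global_max_pool(z$values, z$mask)
  }
  if ("public_pd" %in% roles) {
    z <- mhca(ctx_protein, ctx_drug, params$att_pd, cfg$n_heads)
    inst$public_pd <- global_max_pool(z$values, z$mask)
  }
  if ("public_concat" %in% roles)
    inst$public_concat <- c(priv$private_d, priv$private_p)
  if ("private_d" %in% roles)
    inst$private_d <- priv$private_d
  structure(inst[roles[roles %in% names(inst)]], class = "mildta_instances")
}

# ---- full per-pair forward / backward -------------------------------------

forward_pair <- function(params, cfg, tok_d, tok_p, want_cache = FALSE) {
  need_private <- any(c("private", "public_late") %in% cfg$instance_subset)
  need_early <- "public_early" %in% cfg$instance_subset
  roles <- enabled_roles(cfg$instance_subset)

  sd <- encode_stream(tok_d, params$emb_d, params$enc_d, cfg, want_cache)
  sp <- encode_stream(tok_p, params$emb_p, params$enc_p, cfg, want_cache)

  cache <- list(sd = sd$cache, sp = sp$cache, roles = roles)
  inst <- list()

  if (need_early) {
    att_dp <- attention_forward(sd$ctx$values, sp$ctx$values, params$att_dp,
                                sp$ctx$mask, cfg$n_heads)
    z_dp <- sd$ctx$values + att_dp$out
    g_dp <- gmp_forward(z_dp, sd$ctx$mask)
    inst$public_dp <- g_dp$out
    att_pd <- attention_forward(sp$ctx$values, sd$ctx$values, params$att_pd,
                                sd$ctx$mask, cfg$n_heads)
    z_pd <- sp$ctx$values + att_pd$out
    g_pd <- gmp_forward(z_pd, sp$ctx$mask)
    inst$public_pd <- g_pd$out
    if (want_cache) cache[c("att_dp", "gmp_dp", "att_pd", "gmp_pd")] <-
      list(att_dp$cache, g_dp$cache, att_pd$cache, g_pd$cache)
  }
  if (need_private) {
    cd <- cnn_stream(sd$ctx, params$cnn_d, cfg, want_cache)
    cp <- cnn_stream(sp$ctx, params$cnn_p, cfg, want_cache)
    if ("public_concat" %in% roles) inst$public_concat <- c(cd$out, cp$out)
    if ("private_d" %in% roles) inst$private_d <- cd$out
    if (want_cache) cache[c("cnn_d", "cnn_p")] <- list(cd$cache, cp$cache)
  }
  inst <- inst[roles]

  scores <- numeric(length(roles))
  sc_caches <- vector("list", length(roles))
  for (i in seq_along(roles)) {
    mf <- mlp_forward(inst[[i]], params$scorers[[roles[i]]])
    scores[i] <- mf$out
    sc_caches[[i]] <- mf$cache
  }
  yhat <- sum(params$fusion$w * scores) + (params$fusion$b %||% 0)

  if (want_cache) {
    cache$scores <- scores
    cache$sc_caches <- sc_caches
  }
  list(yhat = yhat, scores = scores, instances = inst,
       cache = if (want_cache) cache else NULL)
}

backward_pair <- function(dyhat, params, cfg, cache) {
  roles <- cache$roles
  m <- cfg$d_model
  g <- list(fusion = list(w = dyhat * cache$scores))
  if (!is.null(params$fusion$b)) g$fusion$b <- dyhat
  dscores <- dyhat * params$fusion$w

  dinst <- stats::setNames(vector("list", length(roles)), roles)
  g$scorers <- stats::setNames(vector("list", length(roles)), roles)
  for (i in seq_along(roles)) {
    mb <- mlp_backward(dscores[i], cache$sc_caches[[i]])
    g$scorers[[roles[i]]] <- mb$dp
    dinst[[roles[i]]] <- mb$dX
  }

  # context-matrix gradients; sizes are the tokenized sequence lengths
  dHd <- matrix(0, length(cache$sd$rows), m)
  dHp <- matrix(0, length(cache$sp$rows), m)

  need_private <- any(c("private", "public_late") %in% cfg$instance_subset)
  if (need_private) {
    dpriv_d <- rep(0, m); dpriv_p <- rep(0, m)
    if ("public_concat" %in% roles) {
      dpriv_d <- dpriv_d + dinst$public_concat[1:m]
      dpriv_p <- dpriv_p + dinst$public_concat[(m + 1):(2 * m)]
    }
    if ("private_d" %in% roles) dpriv_d <- dpriv_d + dinst$private_d
    cdb <- cnn_stream_backward(dpriv_d, cache$cnn_d, params$cnn_d)
    cpb <- cnn_stream_backward(dpriv_p, cache$cnn_p, params$cnn_p)
    g$cnn_d <- cdb$dp_blocks
    g$cnn_p <- cpb$dp_blocks
    dHd <- dHd + cdb$dX
    dHp <- dHp + cpb$dX
  }
  if ("public_early" %in% cfg$instance_subset) {
    dz_dp <- gmp_backward(dinst$public_dp, cache$gmp_dp)
    ab_dp <- attention_backward(dz_dp, cache$att_dp)
    g$att_dp <- ab_dp$dp
    dHd <- dHd + dz_dp + ab_dp$dXq
    dHp <- dHp + ab_dp$dXkv
    dz_pd <- gmp_backward(dinst$public_pd, cache$gmp_pd)
    ab_pd <- attention_backward(dz_pd, cache$att_pd)
    g$att_pd <- ab_pd$dp
    dHp <- dHp + dz_pd + ab_pd$dXq
    dHd <- dHd + ab_pd$dXkv
  }

  sdb <- encode_stream_backward(dHd, cache$sd, params$enc_d, dim(params$emb_d))
  spb <- encode_stream_backward(dHp, cache$sp, params$enc_p, dim(params$emb_p))
  g$emb_d <- sdb$demb
  g$emb_p <- spb$demb
  g$enc_d <- sdb$dp_layers
  g$enc_p <- spb$dp_layers
  g
}
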