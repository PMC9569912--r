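# Independent straight-line reference implementations used as oracles.
# These deliberately share no code with the package internals: everything is
# written as explicit scalar loops.

# Brute-force concordance index: double loop over ordered pairs.
oracle_ci <- function(pred, true) {
  num <- 0; z <- 0
  n <- length(true)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (true[i] > true[j]) {
      z <- z + 1
      d <- pred[i] - pred[j]
      num <- num + if (d > 0) 1 else if (d < 0) 0 else 0.5
    }
  }
  num / z
}

# Pearson correlation from first principles.
oracle_pearson <- function(p, d) {
  n <- length(p)
  mp <- sum(p) / n; md <- sum(d) / n
  cv <- sum((p - mp) * (d - md)) / (n - 1)
  sp <- sqrt(sum((p - mp)^2) / (n - 1))
  sd_ <- sqrt(sum((d - md)^2) / (n - 1))
  cv / (sp * sd_)
}

# rm2 from first principles: squared correlation with and without intercept.
oracle_rm2 <- function(pred, true) {
  r2 <- oracle_pearson(pred, true)^2
  k <- sum(true * pred) / sum(pred^2)      # zero-intercept fit of true on pred
  r02 <- 1 - sum((true - k * pred)^2) / sum((true - mean(true))^2)
  r2 * (1 - sqrt(max(r2 - r02, 0)))
}

# All segmentations of a string into substrings (exponential; tiny inputs).
all_segmentations <- function(s) {
  n <- nchar(s)
  if (n == 0) return(list(character(0)))
  out <- list()
  for (l in seq_len(n)) {
    head_tok <- substr(s, 1, l)
    for (rest in all_segmentations(substr(s, l + 1, n)))
      out[[length(out) + 1]] <- c(head_tok, rest)
  }
  out
}

# Best log-likelihood over all segmentations representable in a vocabulary.
oracle_best_segmentation <- function(s, tokens, logp) {
  best <- -Inf; best_seg <- NULL
  for (seg in all_segmentations(s)) {
    if (all(seg %in% tokens)) {
      ll <- sum(logp[match(seg, tokens)])
      if (ll > best + 1e-12) { best <- ll; best_seg <- seg }
    }
  }
  list(loglik = best, seg = best_seg)
}

# Scalar softmax attention: one (query, key/value) pair of matrices, one
# head, explicit loops. mask_kv marks usable key positions.
oracle_attention <- function(Q, K, V, mask_kv) {
  Tq <- nrow(Q); Tk <- nrow(K); d <- ncol(Q)
  out <- matrix(0, Tq, ncol(V))
  for (t in seq_len(Tq)) {
    s <- rep(-Inf, Tk)
    for (u in seq_len(Tk)) if (mask_kv[u]) {
      acc <- 0
      for (c in seq_len(d)) acc <- acc + Q[t, c] * K[u, c]
      s[u] <- acc / sqrt(d)
    }
    w <- exp(s - max(s[is.finite(s)]))
    w[!is.finite(s)] <- 0
    w <- w / sum(w)
    for (c in seq_len(ncol(V)))
      out[t, c] <- sum(w * V[, c])
  }
  out
}

# Scalar multi-head attention with output mixing (columns blocked by head).
oracle_multihead <- function(Xq, Xkv, p, mask_kv, n_heads) {
  d_model <- ncol(Xq)
  dh <- d_model / n_heads
  Q <- Xq %*% p$Wq; K <- Xkv %*% p$Wk; V <- Xkv %*% p$Wv
  O <- matrix(0, nrow(Xq), d_model)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    O[, idx] <- oracle_attention(Q[, idx, drop = FALSE], K[, idx, drop = FALSE],
                                 V[, idx, drop = FALSE], mask_kv)
  }
  O %*% p$Wo
}

# Scalar layer normalization, row by row.
oracle_layernorm <- function(X, g, b, eps = 1e-5) {
  Y <- X
  for (t in seq_len(nrow(X))) {
    mu <- mean(X[t, ])
    v <- mean((X[t, ] - mu)^2)
    Y[t, ] <- (X[t, ] - mu) / sqrt(v + eps) * g + b
  }
  Y
}

# Scalar transformer encoder layer (post-norm).
oracle_encoder_layer <- function(X, p, mask, n_heads) {
  a <- oracle_multihead(X, X, p$att, mask, n_heads)
  r1 <- oracle_layernorm(X + a, p$ln1$g, p$ln1$b)
  f <- r1
  for (t in seq_len(nrow(r1))) {
    h <- pmax(as.numeric(r1[t, ] %*% p$ffn$W1) + p$ffn$b1, 0)
    f[t, ] <- as.numeric(h %*% p$ffn$W2) + p$ffn$b2
  }
  oracle_layernorm(r1 + f, p$ln2$g, p$ln2$b)
}

# Scalar dilated causal convolution of one channel stack.
oracle_conv1d <- function(X, W, b, d) {
  n <- nrow(X); k <- length(W); co <- length(b)
  out <- matrix(0, n, co)
  for (s in seq_len(n)) for (o in seq_len(co)) {
    acc <- b[o]
    for (i in 0:(k - 1)) {
      src <- s - d * i
      if (src >= 1)
        for (c in seq_len(ncol(X))) acc <- acc + W[[i + 1]][c, o] * X[src, c]
    }
    out[s, o] <- acc
  }
  out
}

# Scalar gate block: conv -> split -> gate -> layernorm -> residual -> mask.
oracle_gate_block <- function(X, p, mask, dilation) {
  C <- ncol(X)
  H <- oracle_conv1d(X, p$W, p$b, dilation)
  Hl <- H[, 1:C, drop = FALSE]
  Hr <- H[, (C + 1):(2 * C), drop = FALSE]
  Ho <- Hl * (1 / (1 + exp(-Hr)))
  out <- oracle_layernorm(Ho, p$ln$g, p$ln$b) + X
  out[!mask, ] <- 0
  out
}

# Scalar cross-attention block with residual (queries from X1, kv from X2).
oracle_mhca <- function(X1, X2, p, mask_kv, n_heads) {
  X1 + oracle_multihead(X1, X2, p, mask_kv, n_heads)
}
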