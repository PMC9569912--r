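# Low-level differentiable building blocks. Every forward returns
# list(out, cache); every backward consumes (d_out, cache) and returns the
# input gradient plus parameter gradients. All are verified against scalar
# straight-line oracles and finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- linear ---------------------------------------------------------------

linear_forward <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(Y))
  list(out = Y, cache = list(X = X, W = W, has_b = !is.null(b)))
}

linear_backward <- function(dY, cache) {
  list(dX = dY %*% t(cache$W),
       dW = t(cache$X) %*% dY,
       db = if (cache$has_b) colSums(dY) else NULL)
}

# ---- layer normalization --------------------------------------------------

LN_EPS <- 1e-5

layernorm_forward <- function(X, g, b, eps = LN_EPS) {
  n <- nrow(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xh <- xc * inv
  Y <- xh * rep(g, each = n) + rep(b, each = n)
  list(out = Y, cache = list(xh = xh, inv = inv, g = g))
}

layernorm_backward <- function(dY, cache) {
  xh <- cache$xh; inv <- cache$inv
  dxh <- dY * rep(cache$g, each = nrow(dY))
  dX <- inv * (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh))
  list(dX = dX, dg = colSums(dY * xh), db = colSums(dY))
}

# ---- masked softmax over rows ---------------------------------------------

row_softmax <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)          # -Inf (masked) entries become exactly 0
  E / rowSums(E)
}

#' Sinusoidal positional encoding
#'
#' Entry `(p, 2i)` is `sin(p / 10000^(2i/d_model))` and entry `(p, 2i+1)` is
#' `cos(p / 10000^(2i/d_model))`, with positions `p = 0 .. T-1` in rows.
#'
#' @param T sequence length (rows).
#' @param d_model embedding width (even).
#' @return a `T x d_model` matrix with entries in \[-1, 1\].
#' @export
positional_encoding <- function(T, d_model) {
  key <- paste0(T, "x", d_model)
  hit <- get0(key, envir = .pe_cache)
  if (!is.null(hit)) return(hit)
  stopifnot(T >= 1, d_model >= 2)
  if (d_model %% 2 != 0) input_error("positional_encoding: d_model must be even")
  p <- 0:(T - 1)
  i2 <- seq(0, d_model - 2, by = 2)             # the 2i values
  ang <- outer(p, 1 / 10000^(i2 / d_model))     # T x d_model/2
  PE <- matrix(0, T, d_model)
  PE[, i2 + 1] <- sin(ang)
  PE[, i2 + 2] <- cos(ang)
  assign(key, PE, envir = .pe_cache)
  PE
}

.pe_cache <- new.env(hash = TRUE, parent = emptyenv())

# ---- scaled dot-product attention (self or cross) -------------------------
# Params: Wq, Wk, Wv (d_model x d_model, columns blocked by head), Wo.
# Queries come from Xq; keys/values from Xkv; key positions with mask_kv
# FALSE are excluded from every softmax.

attention_forward <- function(Xq, Xkv, p, mask_kv, n_heads) {
  if (!any(mask_kv)) input_error("attention: all key positions masked")
  d_model <- ncol(Xq)
  dh <- d_model / n_heads
  Q <- Xq %*% p$Wq; K <- Xkv %*% p$Wk; V <- Xkv %*% p$Wv
  O <- matrix(0, nrow(Xq), d_model)
  A_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(dh)
    S[, !mask_kv] <- -Inf
    A <- row_softmax(S)
    A_list[[h]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  out <- O %*% p$Wo
  list(out = out,
       cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V, O = O,
                    A = A_list, p = p, n_heads = n_heads, dh = dh))
}

attention_backward <- function(dOut, cache) {
  p <- cache$p; nh <- cache$n_heads; dh <- cache$dh
  dO <- dOut %*% t(p$Wo)
  dWo <- t(cache$O) %*% dOut
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(nh)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, idx] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- (dS %*% cache$K[, idx, drop = FALSE]) / sqrt(dh)
    dK[, idx] <- (t(dS) %*% cache$Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  list(dXq = dQ %*% t(p$Wq),
       dXkv = dK %*% t(p$Wk) + dV %*% t(p$Wv),
       dp = list(Wq = t(cache$Xq) %*% dQ,
                 Wk = t(cache$Xkv) %*% dK,
                 Wv = t(cache$Xkv) %*% dV,
                 Wo = dWo))
}

#' Single self-attention head (reference entry point)
#'
#' Computes `softmax(Q K' / sqrt(d)) V` with `Q = x Wq`, `K = x Wk`,
#' `V = x Wv`, excluding masked key positions from the softmax.
#'
#' @param x `T x d` input matrix.
#' @param weights list with `Wq`, `Wk`, `Wv` (`d x d`).
#' @param mask logical vector of length `T`; FALSE marks padding.
#' @return `T x d` output matrix.
#' @export
self_attention_head <- function(x, weights, mask = rep(TRUE, nrow(x))) {
  if (!any(mask)) input_error("self_attention_head: all positions masked")
  Q <- x %*% weights$Wq; K <- x %*% weights$Wk; V <- x %*% weights$Wv
  S <- (Q %*% t(K)) / sqrt(ncol(Q))
  S[, !mask] <- -Inf
  row_softmax(S) %*% V
}

# ---- position-wise feed-forward -------------------------------------------

ffn_forward <- function(X, p) {
  n <- nrow(X)
  h_pre <- X %*% p$W1 + rep(p$b1, each = n)
  h <- pmax(h_pre, 0)
  out <- h %*% p$W2 + rep(p$b2, each = n)
  list(out = out, cache = list(X = X, h_pre = h_pre, h = h, p = p))
}

ffn_backward <- function(dOut, cache) {
  p <- cache$p
  dh <- dOut %*% t(p$W2)
  dh_pre <- dh * (cache$h_pre > 0)
  list(dX = dh_pre %*% t(p$W1),
       dp = list(W1 = t(cache$X) %*% dh_pre, b1 = colSums(dh_pre),
                 W2 = t(cache$h) %*% dOut, b2 = colSums(dOut)))
}

# ---- transformer encoder layer --------------------------------------------
# Post-norm ordering: LayerNorm(x + MultiHead(x)), then LayerNorm(r + FFN(r)).

encoder_layer_forward <- function(X, p, mask, n_heads) {
  if (any(!is.finite(X))) input_error("encoder_layer: non-finite input")
  att <- attention_forward(X, X, p$att, mask, n_heads)
  ln1 <- layernorm_forward(X + att$out, p$ln1$g, p$ln1$b)
  ff <- ffn_forward(ln1$out, p$ffn)
  ln2 <- layernorm_forward(ln1$out + ff$out, p$ln2$g, p$ln2$b)
  list(out = ln2$out,
       cache = list(att = att$cache, ln1 = ln1$cache, ff = ff$cache, ln2 = ln2$cache))
}

encoder_layer_backward <- function(dOut, cache) {
  l2 <- layernorm_backward(dOut, cache$ln2)
  fb <- ffn_backward(l2$dX, cache$ff)
  d_r1 <- l2$dX + fb$dX
  l1 <- layernorm_backward(d_r1, cache$ln1)
  ab <- attention_backward(l1$dX, cache$att)
  dX <- l1$dX + ab$dXq + ab$dXkv      # self-attention: Xq and Xkv are X
  list(dX = dX,
       dp = list(att = ab$dp,
                 ln1 = list(g = l1$dg, b = l1$db),
                 ffn = fb$dp,
                 ln2 = list(g = l2$dg, b = l2$db)))
}

#' Transformer encoder layer (reference entry point)
#'
#' Multi-head self-attention with padding-masked keys, residual connection
#' and layer normalization, then a position-wise feed-forward network with a
#' second residual + normalization (post-norm ordering).
#'
#' @param x `T x d_model` input matrix.
#' @param params layer parameter list (`att`, `ln1`, `ffn`, `ln2`), as
#'   produced by the model initializer.
#' @param mask logical length-`T` vector, FALSE at padding.
#' @param n_heads number of attention heads.
#' @return `T x d_model` matrix.
#' @export
encoder_layer <- function(x, params, mask = rep(TRUE, nrow(x)), n_heads = 4) {
  encoder_layer_forward(x, params, mask, n_heads)$out
}

# ---- dilated causal 1-D convolution ---------------------------------------

#' Dilated causal 1-D convolution of a scalar sequence
#'
#' Output position `s` is `sum_{i=0}^{k-1} f(i) * x[s - d*i]`, with
#' out-of-range indices contributing zero (left zero-padding), so output
#' length equals input length.
#'
#' @param x numeric input sequence.
#' @param f filter coefficients, length `k`.
#' @param d dilation rate (>= 1).
#' @return numeric sequence, same length as `x`.
#' @export
dilated_conv_1d <- function(x, f, d = 1L) {
  stopifnot(length(f) >= 1, d >= 1)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_along(f) - 1L) {
    shift <- d * i
    if (shift < n)
      out[(shift + 1):n] <- out[(shift + 1):n] + f[i + 1] * x[1:(n - shift)]
  }
  out
}

# Multichannel version: X is T x C_in, W a list of k matrices C_in x C_out.
conv1d_forward <- function(X, W, b, d) {
  n <- nrow(X)
  out <- matrix(rep(b, each = n), n, length(b))
  for (i in seq_along(W) - 1L) {
    shift <- d * i
    if (shift < n) {
      Xs <- if (shift == 0) X else
        rbind(matrix(0, shift, ncol(X)), X[1:(n - shift), , drop = FALSE])
      out <- out + Xs %*% W[[i + 1]]
    }
  }
  list(out = out, cache = list(X = X, W = W, d = d))
}

conv1d_backward <- function(dOut, cache) {
  X <- cache$X; W <- cache$W; d <- cache$d
  n <- nrow(X)
  dX <- matrix(0, n, ncol(X))
  dW <- vector("list", length(W))
  for (i in seq_along(W) - 1L) {
    shift <- d * i
    if (shift < n) {
      Xs <- if (shift == 0) X else
        rbind(matrix(0, shift, ncol(X)), X[1:(n - shift), , drop = FALSE])
      dW[[i + 1]] <- t(Xs) %*% dOut
      dcontrib <- dOut %*% t(W[[i + 1]])
      dX[1:(n - shift), ] <- dX[1:(n - shift), , drop = FALSE] +
        dcontrib[(shift + 1):n, , drop = FALSE]
    } else {
      dW[[i + 1]] <- matrix(0, ncol(X), ncol(dOut))
    }
  }
  list(dX = dX, dW = dW, db = colSums(dOut))
}

# ---- gated convolution block ----------------------------------------------
# Dilated conv to 2C channels, split into content/gate halves,
# H_o = H_l * sigmoid(H_r), LayerNorm, then residual add of the block input.
# Padded time-steps are zeroed on exit so they stay masked.

gate_block_forward <- function(X, p, mask, dilation) {
  C <- ncol(X)
  cv <- conv1d_forward(X, p$W, p$b, dilation)
  if (ncol(cv$out) != 2 * C)
    config_error("gate_block: convolution must produce 2x input channels")
  Hl <- cv$out[, 1:C, drop = FALSE]
  Hr <- cv$out[, (C + 1):(2 * C), drop = FALSE]
  G <- sigmoid(Hr)
  Ho <- Hl * G
  ln <- layernorm_forward(Ho, p$ln$g, p$ln$b)
  out <- ln$out + X
  out[!mask, ] <- 0
  list(out = out,
       cache = list(conv = cv$cache, Hl = Hl, G = G, ln = ln$cache, mask = mask))
}

gate_block_backward <- function(dOut, cache) {
  dOut[!cache$mask, ] <- 0
  lb <- layernorm_backward(dOut, cache$ln)
  dHl <- lb$dX * cache$G
  dHr <- lb$dX * cache$Hl * cache$G * (1 - cache$G)
  cb <- conv1d_backward(cbind(dHl, dHr), cache$conv)
  dX <- cb$dX + dOut                      # residual path
  dX[!cache$mask, ] <- 0
  list(dX = dX,
       dp = list(W = cb$dW, b = cb$db, ln = list(g = lb$dg, b = lb$db)))
}

#' Gated dilated convolution block (reference entry point)
#'
#' @param x `T x C` input matrix.
#' @param params block parameters (`W` list of `k` matrices `C x 2C`, `b`
#'   length `2C`, `ln` gain/bias).
#' @param mask logical length-`T` vector.
#' @param dilation dilation rate of this block.
#' @return `T x C` matrix.
#' @export
gate_block <- function(x, params, mask = rep(TRUE, nrow(x)), dilation = 1L) {
  gate_block_forward(x, params, mask, dilation)$out
}

# ---- masked global max pooling --------------------------------------------

gmp_forward <- function(X, mask) {
  rows <- which(mask)
  if (length(rows) == 0) input_error("global max pooling: all positions masked")
  sub <- X[rows, , drop = FALSE]
  arg <- max.col(t(sub), ties.method = "first")
  val <- sub[cbind(arg, seq_len(ncol(X)))]
  list(out = val, cache = list(rows = rows, arg = arg, dims = dim(X)))
}

gmp_backward <- function(dOut, cache) {
  dX <- matrix(0, cache$dims[1], cache$dims[2])
  dX[cbind(cache$rows[cache$arg], seq_len(cache$dims[2]))] <- dOut
  dX
}

#' Masked global max pooling
#'
#' Per-channel maximum over the unmasked sequence positions.
#'
#' @param x `T x C` matrix.
#' @param mask logical length-`T` vector; FALSE positions are excluded.
#' @return numeric vector of length `C`.
#' @export
global_max_pool <- function(x, mask = rep(TRUE, nrow(x))) {
  gmp_forward(x, mask)$out
}

# ---- MLP scorer ------------------------------------------------------------
# ReLU hidden layers, linear scalar output.

mlp_forward <- function(x, layers) {
  caches <- vector("list", length(layers))
  h <- matrix(x, 1)
  for (i in seq_along(layers)) {
    lf <- linear_forward(h, layers[[i]]$W, layers[[i]]$b)
    pre <- lf$out
    act <- if (i < length(layers)) pmax(pre, 0) else pre
    caches[[i]] <- list(lin = lf$cache, pre = pre, last = i == length(layers))
    h <- act
  }
  list(out = as.numeric(h), cache = caches)
}

mlp_backward <- function(dOut, cache) {
  dh <- matrix(dOut, 1)
  dp <- vector("list", length(cache))
  for (i in rev(seq_along(cache))) {
    if (!cache[[i]]$last) dh <- dh * (cache[[i]]$pre > 0)
    lb <- linear_backward(dh, cache[[i]]$lin)
    dp[[i]] <- list(W = lb$dW, b = lb$db)
    dh <- lb$dX
  }
  list(dX = as.numeric(dh), dp = dp)
}
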