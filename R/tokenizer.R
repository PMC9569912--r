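# Data-driven unigram subword tokenization.
#
# A vocabulary of substrings with log-probabilities is learned from a raw
# sequence corpus by the unigram language-model scheme: seed a candidate set
# with frequent substrings, run EM over segmentation lattices to estimate
# token probabilities, then prune low-utility multi-character tokens in
# batches until the requested vocabulary size is reached. Single characters
# are never pruned, so any string over the training alphabet remains
# segmentable. Encoding is the Viterbi (maximum-likelihood) segmentation.

PAD_ID <- 0L
UNK_ID <- 1L

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Hash environment token -> c(index, logp) for O(1) lattice lookups.
vocab_env <- function(tokens, logp) {
  e <- new.env(hash = TRUE, parent = emptyenv(), size = length(tokens))
  for (i in seq_along(tokens)) assign(tokens[i], c(i, logp[i]), envir = e)
  e
}

# One E-step over a single string: returns expected token counts
# (sparse, as a named numeric vector of vocab indices) and the string's
# log-likelihood under the current unigram model.
lattice_estep <- function(chars, env, max_tok_len, n_vocab) {
  n <- length(chars)
  # alpha[j+1]: log prob of prefix of length j; beta[j+1]: of suffix after j
  alpha <- c(0, rep(-Inf, n))
  arcs_start <- integer(0); arcs_end <- integer(0)
  arcs_idx <- integer(0); arcs_lp <- numeric(0)
  for (j in seq_len(n)) {
    lmax <- min(max_tok_len, j)
    cand <- rep(-Inf, lmax)
    for (l in seq_len(lmax)) {
      tok <- paste(chars[(j - l + 1):j], collapse = "")
      hit <- get0(tok, envir = env)
      if (!is.null(hit)) {
        cand[l] <- alpha[j - l + 1] + hit[2]
        arcs_start <- c(arcs_start, j - l + 1L)
        arcs_end <- c(arcs_end, j)
        arcs_idx <- c(arcs_idx, as.integer(hit[1]))
        arcs_lp <- c(arcs_lp, hit[2])
      }
    }
    alpha[j + 1] <- logsumexp(cand)
  }
  ll <- alpha[n + 1]
  beta <- c(rep(-Inf, n), 0)
  for (j in seq(n, 1)) {
    lmax <- min(max_tok_len, n - j + 1)
    cand <- rep(-Inf, lmax)
    for (l in seq_len(lmax)) {
      tok <- paste(chars[j:(j + l - 1)], collapse = "")
      hit <- get0(tok, envir = env)
      if (!is.null(hit)) cand[l] <- hit[2] + beta[j + l]
    }
    beta[j] <- logsumexp(cand)
  }
  counts <- numeric(n_vocab)
  if (is.finite(ll) && length(arcs_idx)) {
    post <- exp(alpha[arcs_start] + arcs_lp + beta[arcs_end + 1L] - ll)
    for (k in seq_along(arcs_idx)) counts[arcs_idx[k]] <- counts[arcs_idx[k]] + post[k]
  }
  list(counts = counts, ll = ll)
}

#' Train a unigram subword tokenizer
#'
#' Learns a vocabulary of `vocab_size` substrings with log-probabilities from
#' a corpus of raw sequences (one string each), by EM over segmentation
#' lattices followed by batched pruning of the lowest expected-count
#' multi-character tokens. All single characters observed in the corpus are
#' retained, so every string over the training alphabet can be segmented.
#'
#' @param corpus character vector of training sequences (non-empty).
#' @param vocab_size requested vocabulary size; must be at least the number
#'   of distinct characters in the corpus. If the corpus admits fewer
#'   distinct substrings than requested, the maximum achievable size is used.
#' @param seed integer seed (training is deterministic; the seed is kept for
#'   interface stability and future stochastic variants).
#' @param max_token_len maximum candidate substring length (default 6).
#' @param em_iters EM iterations between pruning rounds (default 3).
#' @param seed_multiplier candidate pool size as a multiple of `vocab_size`.
#' @return an object of class `mildta_tokenizer`: list with `tokens`
#'   (character), `logp` (<= 0), `ids` (integer ids, starting at 2),
#'   `alphabet`, `pad_id` (0), `unk_id` (1), `max_token_len`.
#' @export
train_unigram_tokenizer <- function(corpus, vocab_size, seed = 1L,
                                    max_token_len = 6L, em_iters = 3L,
                                    seed_multiplier = 8L) {
  corpus <- as.character(corpus)
  corpus <- corpus[nchar(corpus) > 0]
  if (length(corpus) == 0) input_error("train_unigram_tokenizer: empty corpus")

  # Collapse duplicate strings; weight their statistics by multiplicity.
  tab <- table(corpus)
  strings <- names(tab)
  weights <- as.numeric(tab)
  char_list <- strsplit(strings, "", fixed = TRUE)

  alphabet <- sort(unique(unlist(char_list)))
  n_char <- length(alphabet)
  if (vocab_size < n_char)
    input_error(sprintf(
      "train_unigram_tokenizer: vocab_size %d below the %d distinct characters in the corpus; minimum feasible size is %d",
      vocab_size, n_char, n_char))

  # Candidate seeding: all substrings up to max_token_len, weighted counts.
  cand_env <- new.env(hash = TRUE, parent = emptyenv())
  for (si in seq_along(char_list)) {
    ch <- char_list[[si]]
    n <- length(ch)
    w <- weights[si]
    for (j in seq_len(n)) {
      for (l in seq_len(min(max_token_len, n - j + 1))) {
        tok <- paste(ch[j:(j + l - 1)], collapse = "")
        prev <- get0(tok, envir = cand_env, ifnotfound = 0)
        assign(tok, prev + w, envir = cand_env)
      }
    }
  }
  cand_tok <- ls(cand_env, sorted = TRUE)
  cand_cnt <- vapply(cand_tok, function(t) get(t, envir = cand_env), numeric(1))
  is_single <- nchar(cand_tok) == 1L
  # keep every single char; cap multi-char pool at seed_multiplier * vocab_size
  multi_ord <- order(-cand_cnt[!is_single], cand_tok[!is_single])
  multi_tok <- cand_tok[!is_single][multi_ord]
  multi_cnt <- cand_cnt[!is_single][multi_ord]
  # drop multi-char candidates seen only once unless pool would be tiny
  keep_n <- min(length(multi_tok), max(0L, seed_multiplier * vocab_size - n_char))
  tokens <- c(alphabet, multi_tok[seq_len(keep_n)])
  counts <- c(cand_cnt[match(alphabet, cand_tok)], multi_cnt[seq_len(keep_n)])

  logp <- log(counts / sum(counts))

  run_em <- function(tokens, logp, iters) {
    for (it in seq_len(iters)) {
      env <- vocab_env(tokens, logp)
      exp_counts <- numeric(length(tokens))
      for (si in seq_along(char_list)) {
        es <- lattice_estep(char_list[[si]], env, max_token_len, length(tokens))
        exp_counts <- exp_counts + weights[si] * es$counts
      }
      # M-step with a tiny floor so retained single chars never hit -Inf
      exp_counts <- pmax(exp_counts, 1e-10)
      logp <- log(exp_counts / sum(exp_counts))
      attr(logp, "exp_counts") <- exp_counts
    }
    logp
  }

  logp <- run_em(tokens, logp, em_iters)
  target <- min(vocab_size, length(tokens))

  while (length(tokens) > target) {
    ec <- attr(logp, "exp_counts")
    multi <- which(nchar(tokens) > 1L)
    surplus <- length(tokens) - target
    if (length(multi) == 0) break
    n_drop <- min(length(multi), max(1L, min(surplus, ceiling(0.2 * length(multi)))))
    # prune lowest expected-count tokens (lowest contribution to the corpus
    # likelihood); lexicographic tie-break for determinism
    ord <- multi[order(ec[multi], tokens[multi])]
    drop <- ord[seq_len(n_drop)]
    keep <- setdiff(seq_along(tokens), drop)
    tokens <- tokens[keep]
    logp <- run_em(tokens, as.numeric(logp[keep]), em_iters)
  }

  model <- list(tokens = tokens,
                logp = as.numeric(logp),
                ids = seq_along(tokens) + 1L,   # 0 = pad, 1 = unk
                alphabet = alphabet,
                pad_id = PAD_ID, unk_id = UNK_ID,
                max_token_len = as.integer(max_token_len))
  class(model) <- "mildta_tokenizer"
  model
}

#' Character-level tokenizer
#'
#' Identity vocabulary over a fixed alphabet with uniform log-probabilities;
#' segments every string into its characters. Provided as the optional
#' atom-level input view.
#'
#' @param alphabet character vector of single characters.
#' @return a `mildta_tokenizer`.
#' @export
char_tokenizer <- function(alphabet) {
  alphabet <- sort(unique(as.character(alphabet)))
  if (any(nchar(alphabet) != 1L))
    input_error("char_tokenizer: alphabet entries must be single characters")
  model <- list(tokens = alphabet,
                logp = rep(log(1 / length(alphabet)), length(alphabet)),
                ids = seq_along(alphabet) + 1L,
                alphabet = alphabet,
                pad_id = PAD_ID, unk_id = UNK_ID,
                max_token_len = 1L)
  class(model) <- "mildta_tokenizer"
  model
}

#' @export
print.mildta_tokenizer <- function(x, ...) {
  cat(sprintf("Unigram tokenizer: %d tokens (%d single chars), max token length %d\n",
              length(x$tokens), length(x$alphabet), x$max_token_len))
  invisible(x)
}

# Viterbi segmentation of one string into vocabulary tokens; unknown
# characters become their own single-character tokens flagged unknown.
# Ties in log-likelihood are broken toward the longer final token.
viterbi_segment <- function(model, sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0) return(list(tokens = character(0), ids = integer(0)))
  env <- vocab_env(model$tokens, model$logp)
  unk_lp <- min(model$logp) - 10   # discourage but permit unknown chars
  best <- c(0, rep(-Inf, n))
  back_len <- integer(n)
  back_idx <- integer(n)           # vocab index, or NA for unk
  for (j in seq_len(n)) {
    for (l in seq(min(model$max_token_len, j), 1)) {  # longest first: tie-break
      tok <- paste(chars[(j - l + 1):j], collapse = "")
      hit <- get0(tok, envir = env)
      sc <- if (!is.null(hit)) best[j - l + 1] + hit[2]
            else if (l == 1L) best[j] + unk_lp else -Inf
      if (sc > best[j + 1] + 1e-12) {
        best[j + 1] <- sc
        back_len[j] <- l
        back_idx[j] <- if (!is.null(hit)) as.integer(hit[1]) else NA_integer_
      }
    }
  }
  toks <- character(0); ids <- integer(0)
  j <- n
  while (j > 0) {
    l <- back_len[j]
    toks <- c(paste(chars[(j - l + 1):j], collapse = ""), toks)
    ids <- c(if (is.na(back_idx[j])) model$unk_id else model$ids[back_idx[j]], ids)
    j <- j - l
  }
  list(tokens = toks, ids = ids, loglik = best[n + 1])
}

#' Encode a sequence into a fixed-length padded token-id vector
#'
#' Segments `sequence` by the Viterbi (maximum-likelihood) unigram
#' segmentation, maps tokens to ids, and truncates/pads to `max_len`.
#' Truncation keeps the head of the sequence. Characters outside the model
#' alphabet map to the unknown id (one token per character) and are noted
#' via a message.
#'
#' @param model a `mildta_tokenizer`.
#' @param sequence a single string (may be empty).
#' @param max_len output length.
#' @return an object of class `mildta_tokens`: list with `ids` (length
#'   `max_len`, pad id beyond the real tokens), `mask` (logical, TRUE at real
#'   tokens), `original_length` (token count before truncation), and `tokens`
#'   (untruncated surface strings, for round-tripping).
#' @export
encode <- function(model, sequence, max_len) {
  stopifnot(inherits(model, "mildta_tokenizer"), max_len >= 1)
  seg <- viterbi_segment(model, as.character(sequence))
  n_unk <- sum(seg$ids == model$unk_id)
  if (n_unk > 0)
    message(sprintf("encode: %d character(s) outside the tokenizer alphabet mapped to <unk>", n_unk))
  orig <- length(seg$ids)
  keep <- min(orig, max_len)
  ids <- rep(model$pad_id, max_len)
  if (keep > 0) ids[seq_len(keep)] <- seg$ids[seq_len(keep)]
  out <- list(ids = as.integer(ids),
              mask = seq_len(max_len) <= keep,
              original_length = orig,
              tokens = seg$tokens)
  class(out) <- "mildta_tokens"
  out
}

#' Reconstruct the surface string of an encoding
#'
#' Concatenates the untruncated surface tokens stored by [encode()];
#' round-trips the input string exactly for sequences over the model
#' alphabet.
#'
#' @param tokens a `mildta_tokens` object.
#' @return a string.
#' @export
decode <- function(tokens) {
  stopifnot(inherits(tokens, "mildta_tokens"))
  paste(tokens$tokens, collapse = "")
}

#' Serialize a tokenizer to a plain-text file
#'
#' Versioned header, special ids, alphabet, then one `token TAB logp` row per
#' vocabulary entry.
#'
#' @param model a `mildta_tokenizer`.
#' @param path output file path.
#' @export
save_tokenizer <- function(model, path) {
  stopifnot(inherits(model, "mildta_tokenizer"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("mildta-tokenizer\tv1",
               sprintf("pad\t%d", model$pad_id),
               sprintf("unk\t%d", model$unk_id),
               sprintf("max_token_len\t%d", model$max_token_len),
               sprintf("alphabet\t%s", paste(model$alphabet, collapse = ""))),
             con)
  writeLines(sprintf("%s\t%.17g", model$tokens, model$logp), con)
}

#' Load a tokenizer saved by [save_tokenizer()]
#'
#' @param path file path.
#' @return a `mildta_tokenizer`.
#' @export
load_tokenizer <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!startsWith(lines[1], "mildta-tokenizer"))
    input_error("load_tokenizer: not a tokenizer file (bad header)")
  hdr <- strsplit(lines[2:5], "\t", fixed = TRUE)
  vals <- stats::setNames(vapply(hdr, `[`, "", 2), vapply(hdr, `[`, "", 1))
  body <- strsplit(lines[-(1:5)], "\t", fixed = TRUE)
  model <- list(tokens = vapply(body, `[`, "", 1),
                logp = as.numeric(vapply(body, `[`, "", 2)),
                ids = seq_along(body) + 1L,
                alphabet = strsplit(vals[["alphabet"]], "", fixed = TRUE)[[1]],
                pad_id = as.integer(vals[["pad"]]),
                unk_id = as.integer(vals[["unk"]]),
                max_token_len = as.integer(vals[["max_token_len"]]))
  class(model) <- "mildta_tokenizer"
  model
}
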