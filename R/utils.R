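#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish bad input from bad config
# from a metric that is mathematically undefined on the given data.
input_error <- function(msg) {
  stop(structure(class = c("mildta_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

config_error <- function(msg) {
  stop(structure(class = c("mildta_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

undefined_metric_error <- function(msg) {
  stop(structure(class = c("mildta_undefined_metric", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the previous RNG state so
#' that seeded helpers never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Recursive helpers over parameter trees (nested named lists with numeric
# leaves). Used by gradient accumulation and the optimizer.
tree_unary <- function(x, f) {
  if (is.list(x)) {
    out <- lapply(x, function(e) if (is.null(e)) NULL else tree_unary(e, f))
    out
  } else f(x)
}

# Walks `a`'s structure; matches `b`'s branches by name where available so
# differently ordered trees (e.g. parameters vs gradients) still line up.
tree_binary <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    nm <- names(a)
    for (i in seq_along(a)) {
      bi <- if (!is.null(nm) && nzchar(nm[i]) && !is.null(b[[nm[i]]])) b[[nm[i]]] else b[[i]]
      out[[i]] <- if (is.null(a[[i]])) NULL else tree_binary(a[[i]], bi, f)
    }
    out
  } else f(a, b)
}

tree_add <- function(a, b) tree_binary(a, b, `+`)

tree_zeros_like <- function(x) tree_unary(x, function(v) v * 0)

# Flatten all numeric leaves into one vector (finite-difference checks).
tree_flatten <- function(x) {
  if (is.list(x)) unlist(lapply(x, function(e) if (is.null(e)) numeric(0) else tree_flatten(e)))
  else as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
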