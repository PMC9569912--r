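# MIL regression head: per-instance MLP scoring and learned linear fusion.

#' Score each bag instance with its own MLP
#'
#' Each instance vector is passed through its dedicated multi-layer
#' perceptron (ReLU hidden activations, linear scalar output). The scorers
#' are independent because the concatenation instance is twice as wide as
#' the others and each score keeps a per-instance interpretation.
#'
#' @param instances a `mildta_instances` list (named instance vectors).
#' @param scorers named list of MLP parameter stacks matching the instance
#'   roles, as in `mildta_params$scorers`.
#' @return numeric vector of one score per instance, in instance order.
#' @export
score_instances <- function(instances, scorers) {
  roles <- names(instances)
  if (!all(roles %in% names(scorers)))
    config_error("score_instances: missing scorer for some instance role")
  vapply(roles, function(r) {
    layer1 <- scorers[[r]][[1]]
    if (length(instances[[r]]) != nrow(layer1$W))
      config_error(sprintf(
        "score_instances: instance '%s' width %d does not match scorer input width %d",
        r, length(instances[[r]]), nrow(layer1$W)))
    mlp_forward(instances[[r]], scorers[[r]])$out
  }, numeric(1))
}

#' Fuse instance scores into the bag affinity
#'
#' The predicted affinity is the weighted sum of the per-instance scores;
#' the weights are learned during training and there is no intercept unless
#' one was configured.
#'
#' @param scores numeric vector of instance scores.
#' @param weights numeric vector of the same length.
#' @param intercept optional scalar added to the sum (default 0).
#' @return the predicted affinity (scalar).
#' @export
fuse_scores <- function(scores, weights, intercept = 0) {
  if (length(scores) != length(weights))
    input_error("fuse_scores: scores and weights must have equal length")
  sum(weights * scores) + intercept
}

#' Mean-squared-error training loss
#'
#' @param y_hat predicted affinities.
#' @param y observed affinities, same length.
#' @return mean of squared residuals.
#' @export
mse_loss <- function(y_hat, y) {
  if (length(y_hat) == 0) input_error("mse_loss: empty input")
  if (length(y_hat) != length(y))
    input_error("mse_loss: y_hat and y must have equal length")
  mean((y - y_hat)^2)
}
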