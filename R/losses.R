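#' Training loss functions
#'
#' The four losses used to train the network variants, applied to batches of
#' output maps. With residual r = predicted - target:
#' * `MSE`: mean(r^2)
#' * `MAE`: mean(|r|)
#' * `LCL`: mean(log cosh r) — the logarithmic hyperbolic cosine loss
#' * `DICE`: `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)`,
#'   `eps = 1e-6` (a soft dice loss; targets are binary masks)
#'
#' Multi-channel inputs (4th dimension = channel when `predicted` is an
#' (H, W, C, B) batch with `channel_dim = 3`) are reduced as the unweighted
#' mean of the per-channel losses.
#'
#' @param loss_name One of `"MSE"`, `"MAE"`, `"LCL"`, `"DICE"`.
#' @param predicted,target Numeric arrays of identical shape.
#' @param channel_dim Dimension indexing output channels (default 3 for
#'   (H, W, C, B) batches); ignored for vector input.
#' @return Scalar loss.
#' @export
#' @examples
#' compute_loss("LCL", 0.1, 0)  # log(cosh(0.1)) ~ 0.004992
compute_loss <- function(loss_name, predicted, target, channel_dim = 3L) {
  if (!identical(dim(predicted), dim(target)) ||
      length(predicted) != length(target)) {
    stop("predicted and target shapes differ")
  }
  per_channel <- split_channels(predicted, target, channel_dim)
  vals <- vapply(per_channel, function(ch) {
    loss_1(loss_name, ch$p, ch$t)
  }, numeric(1))
  mean(vals)
}

loss_1 <- function(loss_name, p, t) {
  r <- p - t
  switch(loss_name,
    MSE = mean(r^2),
    MAE = mean(abs(r)),
    LCL = mean(log_cosh(r)),
    DICE = {
      eps <- 1e-6
      1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
    },
    stop("unknown loss name: ", loss_name))
}

# d loss / d predicted, matching compute_loss()'s channel-mean reduction
loss_grad <- function(loss_name, predicted, target, channel_dim = 3L) {
  per_channel <- split_channels(predicted, target, channel_dim)
  nch <- length(per_channel)
  g <- lapply(per_channel, function(ch) {
    r <- ch$p - ch$t
    n <- length(r)
    switch(loss_name,
      MSE = 2 * r / (n * nch),
      MAE = sign(r) / (n * nch),
      LCL = tanh(r) / (n * nch),
      DICE = {
        eps <- 1e-6
        P <- sum(ch$p); T_ <- sum(ch$t); S <- sum(ch$p * ch$t)
        den <- (P + T_ + eps)
        -(2 * ch$t * den - (2 * S + eps)) / (den^2 * nch)
      },
      stop("unknown loss name: ", loss_name))
  })
  join_channels(g, dim(predicted), channel_dim)
}

# numerically stable log(cosh(x)) = |x| + log1p(exp(-2|x|)) - log(2)
log_cosh <- function(x) {
  a <- abs(x)
  a + log1p(exp(-2 * a)) - log(2)
}

split_channels <- function(p, t, channel_dim) {
  d <- dim(p)
  if (is.null(d) || length(d) < channel_dim) {
    return(list(list(p = p, t = t)))
  }
  if (length(d) == 4L && channel_dim == 3L) {
    lapply(seq_len(d[3]), function(c) {
      list(p = p[, , c, , drop = FALSE], t = t[, , c, , drop = FALSE])
    })
  } else {
    lapply(seq_len(d[channel_dim]), function(c) {
      idx <- slice.index(p, channel_dim) == c
      list(p = p[idx], t = t[idx])
    })
  }
}

join_channels <- function(gs, d, channel_dim) {
  if (is.null(d) || length(d) < channel_dim) return(gs[[1]])
  out <- array(0, d)
  if (length(d) == 4L && channel_dim == 3L) {
    for (c in seq_along(gs)) out[, , c, ] <- gs[[c]]
  } else {
    for (c in seq_along(gs)) {
      out[slice.index(out, channel_dim) == c] <- gs[[c]]
    }
  }
  out
}
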