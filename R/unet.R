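#' Build a 2-D U-net model
#'
#' Encoder-decoder with skip connections: `encoder_depth` resolution
#' halvings (2x2 max pooling), two 3x3 convolution + ReLU blocks per level,
#' nearest-neighbour upsampling followed by a 1x1 channel-halving
#' projection and skip concatenation on the way up, and a linear 1x1 output
#' convolution (regression head — no final nonlinearity). Channel width
#' doubles at each deeper level starting from `config$base_channels`.
#' Weights use He initialization, seeded from `config$seed`.
#'
#' @param variant A variant name or one-row data.frame from
#'   [network_variants()].
#' @param config A [training_config()].
#' @return An `mrf_unet` model object (parameters + architecture metadata).
#' @export
build_unet <- function(variant = "MSE-5", config = training_config()) {
  if (is.character(variant)) variant <- get_variant(variant)
  depth <- config$encoder_depth
  if (config$patch_size %% (2^depth) != 0) {
    stop("patch_size (", config$patch_size,
         ") must be divisible by 2^encoder_depth (", 2^depth, ")")
  }
  f <- config$base_channels
  cin <- variant$n_inputs
  layers <- list()
  ch <- cin
  for (l in seq_len(depth)) {
    w <- f * 2^(l - 1)
    layers[[paste0("enc", l, "a")]] <- c(k = 3, cin = ch, cout = w)
    layers[[paste0("enc", l, "b")]] <- c(k = 3, cin = w, cout = w)
    ch <- w
  }
  wb <- f * 2^depth
  layers[["bot_a"]] <- c(k = 3, cin = ch, cout = wb)
  layers[["bot_b"]] <- c(k = 3, cin = wb, cout = wb)
  ch <- wb
  for (l in rev(seq_len(depth))) {
    w <- f * 2^(l - 1)
    layers[[paste0("up", l)]] <- c(k = 1, cin = ch, cout = w)
    layers[[paste0("dec", l, "a")]] <- c(k = 3, cin = 2 * w, cout = w)
    layers[[paste0("dec", l, "b")]] <- c(k = 3, cin = w, cout = w)
    ch <- w
  }
  layers[["out"]] <- c(k = 1, cin = ch, cout = variant$n_outputs)

  params <- with_seed(config$seed, {
    lapply(layers, function(sp) {
      k <- sp[["k"]]; ci <- sp[["cin"]]; co <- sp[["cout"]]
      sd <- sqrt(2 / (k * k * ci))
      list(w = array(rnorm(k * k * ci * co, sd = sd), c(k, k, ci, co)),
           b = numeric(co))
    })
  })
  structure(list(variant = variant, config = config, layers = layers,
                 params = params),
            class = "mrf_unet")
}

#' @export
print.mrf_unet <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$w) + length(p$b),
                   numeric(1)))
  cat(sprintf("mrf_unet '%s': %d -> %d channels, depth %d, %s parameters\n",
              x$variant$name, x$variant$n_inputs, x$variant$n_outputs,
              x$config$encoder_depth, format(np, big.mark = ",")))
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

conv_block_fwd <- function(params, name, x, cache) {
  p <- params[[name]]
  z <- cpp_conv2d_fwd(x, p$w, p$b)
  a <- relu(z)
  if (!is.null(cache)) {
    cache[[paste0(name, ".x")]] <- x
    cache[[paste0(name, ".z")]] <- z
  }
  list(a = a, cache = cache)
}

# Forward pass over a batch x (H, W, Cin, B). When `cache` is TRUE the
# intermediate tensors needed by unet_backward() are retained.
unet_forward <- function(model, x, cache = FALSE) {
  depth <- model$config$encoder_depth
  cc <- if (cache) list() else NULL
  skips <- vector("list", depth)
  cur <- x
  for (l in seq_len(depth)) {
    r <- conv_block_fwd(model$params, paste0("enc", l, "a"), cur, cc)
    cc <- r$cache
    r <- conv_block_fwd(model$params, paste0("enc", l, "b"), r$a, cc)
    cc <- r$cache
    skips[[l]] <- r$a
    mp <- cpp_maxpool2_fwd(r$a)
    if (cache) cc[[paste0("pool", l, ".idx")]] <- mp$idx
    if (cache) cc[[paste0("pool", l, ".dim")]] <- dim(r$a)
    cur <- mp$y
  }
  r <- conv_block_fwd(model$params, "bot_a", cur, cc); cc <- r$cache
  r <- conv_block_fwd(model$params, "bot_b", r$a, cc); cc <- r$cache
  cur <- r$a
  for (l in rev(seq_len(depth))) {
    up <- cpp_upsample2_fwd(cur)
    pu <- model$params[[paste0("up", l)]]
    if (cache) cc[[paste0("up", l, ".x")]] <- up
    proj <- cpp_conv2d_fwd(up, pu$w, pu$b)  # linear 1x1 projection
    cat_in <- abind4(proj, skips[[l]])
    r <- conv_block_fwd(model$params, paste0("dec", l, "a"), cat_in, cc)
    cc <- r$cache
    r <- conv_block_fwd(model$params, paste0("dec", l, "b"), r$a, cc)
    cc <- r$cache
    cur <- r$a
  }
  po <- model$params[["out"]]
  if (cache) cc[["out.x"]] <- cur
  y <- cpp_conv2d_fwd(cur, po$w, po$b)
  list(y = y, cache = cc)
}

# Backward pass; `gy` is dLoss/dOutput for the same batch that produced
# `cache`. Returns gradients named like model$params.
unet_backward <- function(model, cache, gy) {
  depth <- model$config$encoder_depth
  grads <- list()
  conv_block_bwd <- function(name, ga) {
    # ga: gradient w.r.t. the block's ReLU output
    z <- cache[[paste0(name, ".z")]]
    gz <- ga * (z > 0)
    g <- cpp_conv2d_bwd(cache[[paste0(name, ".x")]],
                        model$params[[name]]$w, gz)
    grads[[name]] <<- list(w = g$gw, b = g$gb)
    g$gx
  }
  g <- cpp_conv2d_bwd(cache[["out.x"]], model$params[["out"]]$w, gy)
  grads[["out"]] <- list(w = g$gw, b = g$gb)
  cur <- g$gx
  gskip <- vector("list", depth)
  for (l in seq_len(depth)) {  # decoder levels, deepest processed last
    cur <- conv_block_bwd(paste0("dec", l, "b"), cur)
    cur <- conv_block_bwd(paste0("dec", l, "a"), cur)
    w <- model$layers[[paste0("up", l)]][["cout"]]
    gproj <- cur[, , seq_len(w), , drop = FALSE]
    gskip[[l]] <- cur[, , w + seq_len(dim(cur)[3] - w), , drop = FALSE]
    gu <- cpp_conv2d_bwd(cache[[paste0("up", l, ".x")]],
                         model$params[[paste0("up", l)]]$w, gproj)
    grads[[paste0("up", l)]] <- list(w = gu$gw, b = gu$gb)
    cur <- cpp_upsample2_bwd(gu$gx)
  }
  cur <- conv_block_bwd("bot_b", cur)
  cur <- conv_block_bwd("bot_a", cur)
  for (l in rev(seq_len(depth))) {  # encoder levels, deepest first
    dm <- cache[[paste0("pool", l, ".dim")]]
    gpool <- cpp_maxpool2_bwd(cache[[paste0("pool", l, ".idx")]], cur,
                              dm[1], dm[2])
    ga <- gpool + gskip[[l]]
    cur <- conv_block_bwd(paste0("enc", l, "b"), ga)
    cur <- conv_block_bwd(paste0("enc", l, "a"), cur)
  }
  grads
}

# concatenate two (H, W, C, B) arrays along the channel dimension
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) list(w = p$w * 0, b = p$b * 0)),
       v = lapply(params, function(p) list(w = p$w * 0, b = p$b * 0)),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (f in c("w", "b")) {
      g <- grads[[nm]][[f]]
      state$m[[nm]][[f]] <- beta1 * state$m[[nm]][[f]] + (1 - beta1) * g
      state$v[[nm]][[f]] <- beta2 * state$v[[nm]][[f]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[f]] / bc1
      vhat <- state$v[[nm]][[f]] / bc2
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}
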