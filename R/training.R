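#' Assemble one training case
#'
#' Converts a baseline stack plus its target maps into the normalized
#' tensors the network trains on. The input is scaled by the per-case mean
#' brain signal (mean of the strictly positive first-frame voxels); T1 and
#' T2* targets are divided by `config$t1_scale` / `config$t2s_scale` so all
#' five output channels are order one and an unweighted joint loss is
#' meaningful. Channel order of the targets is fixed: `t1_norm`,
#' `t2s_norm`, `prob_nawm`, `prob_gm`, `prob_lesion`.
#'
#' For the 2-channel reference variant (`MSE-2-1`) pass `input_maps`
#' (a list with `t1_ms` and `t2s_ms`, e.g. from [reconstruct_maps()])
#' instead of relying on the stack frames.
#'
#' @param stack A [baseline_stack()].
#' @param targets `NULL` (inference only) or a list with `t1_ms`, `t2s_ms`,
#'   `prob_nawm`, `prob_gm`, `lesion_mask`.
#' @param config A [training_config()].
#' @param input_maps Optional 2-channel quantitative-map input.
#' @return A `training_case`: `input` (H, W, Cin, nz), `target`
#'   (H, W, 5, nz) or `NULL`, `lesion_mask`, `input_scale`, `voxel_size`.
#' @export
make_training_case <- function(stack, targets = NULL,
                               config = training_config(),
                               input_maps = NULL) {
  d <- dim(stack$data)
  if (is.null(input_maps)) {
    f1 <- stack$data[, , , 1]
    sc <- mean(f1[f1 > 0])
    if (!is.finite(sc) || sc <= 0) sc <- 1
    input <- aperm(stack$data, c(1, 2, 4, 3)) / sc
  } else {
    sc <- 1
    input <- array(0, c(d[1], d[2], 2, d[3]))
    input[, , 1, ] <- input_maps$t1_ms / config$t1_scale
    input[, , 2, ] <- input_maps$t2s_ms / config$t2s_scale
  }
  target <- NULL
  lesion <- NULL
  if (!is.null(targets)) {
    target <- array(0, c(d[1], d[2], 5, d[3]))
    target[, , 1, ] <- targets$t1_ms / config$t1_scale
    target[, , 2, ] <- targets$t2s_ms / config$t2s_scale
    target[, , 3, ] <- targets$prob_nawm
    target[, , 4, ] <- targets$prob_gm
    target[, , 5, ] <- targets$lesion_mask * 1
    lesion <- targets$lesion_mask != 0
  }
  structure(list(input = input, target = target, lesion_mask = lesion,
                 input_scale = sc, voxel_size = stack$voxel_size),
            class = "training_case")
}

#' Build the epoch slice sampler
#'
#' Enumerates all 2-D slices of the training cases. Slices whose in-slice
#' lesion volume is at least `config$lesion_volume_min` microliters
#' (1 ul = 1 mm^3) are listed `config$augment_factor` times per epoch to
#' counter the small total lesion volume; every listed slice contributes
#' `config$patches_per_slice` random patches per epoch.
#'
#' @param cases List of [make_training_case()] objects with targets.
#' @param config A [training_config()].
#' @return A `slice_sampler`: `cases`, `slices` (data.frame `case`, `z`,
#'   `reps`), `config`.
#' @export
build_training_set <- function(cases, config = training_config()) {
  if (!length(cases)) stop("no training cases supplied")
  rows <- list()
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    if (is.null(cs$target)) stop("case ", ci, " has no target maps")
    d <- dim(cs$input)
    if (d[1] < config$patch_size || d[2] < config$patch_size) {
      stop("patch_size exceeds the slice matrix of case ", ci)
    }
    vox_ul <- prod(cs$voxel_size)
    for (z in seq_len(d[4])) {
      les_ul <- sum(cs$lesion_mask[, , z]) * vox_ul
      rows[[length(rows) + 1]] <- data.frame(
        case = ci, z = z,
        reps = if (les_ul >= config$lesion_volume_min) config$augment_factor
               else 1L)
    }
  }
  slices <- do.call(rbind, rows)
  if (is.null(slices) || !nrow(slices)) stop("training set contains no slices")
  structure(list(cases = cases, slices = slices, config = config),
            class = "slice_sampler")
}

# epoch-wise patch coordinate stream: one row per patch (case, z, i0, j0),
# fully determined by (config$seed, epoch)
epoch_patches <- function(sampler, epoch) {
  cfg <- sampler$config
  with_seed(derive_seed(cfg$seed, paste0("epoch", epoch)), {
    sl <- sampler$slices
    expanded <- sl[rep(seq_len(nrow(sl)), sl$reps), c("case", "z")]
    expanded <- expanded[sample.int(nrow(expanded)), , drop = FALSE]
    ps <- cfg$patch_size
    out <- lapply(seq_len(nrow(expanded)), function(r) {
      d <- dim(sampler$cases[[expanded$case[r]]]$input)
      data.frame(case = expanded$case[r], z = expanded$z[r],
                 i0 = sample.int(d[1] - ps + 1, cfg$patches_per_slice,
                                 replace = TRUE),
                 j0 = sample.int(d[2] - ps + 1, cfg$patches_per_slice,
                                 replace = TRUE))
    })
    out <- do.call(rbind, out)
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

target_channels <- function(n_outputs) {
  if (n_outputs == 5L) 1:5 else 5L
}

#' Train a network variant
#'
#' Mini-batch Adam on random patches from the slice sampler. Per epoch the
#' mean training loss is recorded; when validation cases are supplied the
#' lesion-channel dice at the 33 % binarization threshold is tracked and
#' the best-validation parameters are kept. The returned model averages the
#' end-of-epoch parameters over the last quarter of the schedule
#' (stochastic weight averaging): with a constant step size the optimizer
#' keeps bouncing inside a noise ball around the optimum, and averaging the
#' tail iterates removes that oscillation from the regression output
#' without damping late learning the way step-size decay would. The raw
#' final-iterate parameters are kept as `last_params`. After training, the
#' fit is checked for the known failure mode where a network converges to
#' a local minimum with all lesion probabilities equal to zero; such fits
#' carry `collapsed = TRUE` ("converged to empty prediction").
#'
#' @param variant Variant name or row (see [network_variants()]).
#' @param sampler A [build_training_set()] sampler.
#' @param config A [training_config()]; defaults to the sampler's.
#' @param validation Optional list of [make_training_case()] objects with
#'   targets.
#' @param verbose Print per-epoch progress.
#' @return An `mrf_unet_fit`: `model`, `history` (epoch, loss, val_dice),
#'   `collapsed`, `best_epoch`.
#' @export
train <- function(variant, sampler, config = sampler$config,
                  validation = NULL, verbose = FALSE) {
  if (is.character(variant)) variant <- get_variant(variant)
  model <- build_unet(variant, config)
  st <- adam_init(model$params)
  chans <- target_channels(variant$n_outputs)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_dice = numeric())
  best <- list(dice = -Inf, params = model$params, epoch = NA_integer_)

  lr_decay <- if (is.null(config$lr_decay)) 1 else config$lr_decay
  swa_from <- config$epochs - max(2L, ceiling(config$epochs / 4)) + 1L
  swa <- NULL
  swa_n <- 0L
  for (ep in seq_len(config$epochs)) {
    lr_ep <- config$learning_rate * lr_decay^(ep - 1)
    coords <- epoch_patches(sampler, ep)
    ps <- config$patch_size
    losses <- c()
    for (s in seq(1, nrow(coords), by = config$batch_size)) {
      e <- min(s + config$batch_size - 1, nrow(coords))
      nb <- e - s + 1
      cinn <- dim(sampler$cases[[1]]$input)[3]
      xb <- array(0, c(ps, ps, cinn, nb))
      tb <- array(0, c(ps, ps, length(chans), nb))
      for (b in seq_len(nb)) {
        rw <- coords[s + b - 1, ]
        cs <- sampler$cases[[rw$case]]
        ii <- rw$i0:(rw$i0 + ps - 1); jj <- rw$j0:(rw$j0 + ps - 1)
        xb[, , , b] <- cs$input[ii, jj, , rw$z]
        tb[, , , b] <- cs$target[ii, jj, chans, rw$z]
      }
      fw <- unet_forward(model, xb, cache = TRUE)
      lo <- compute_loss(variant$loss, fw$y, tb)
      if (!is.finite(lo)) {
        stop("training diverged: non-finite ", variant$loss,
             " loss at epoch ", ep)
      }
      losses <- c(losses, lo)
      gy <- loss_grad(variant$loss, fw$y, tb)
      grads <- unet_backward(model, fw$cache, gy)
      upd <- adam_step(model$params, grads, st, lr_ep)
      model$params <- upd$params
      st <- upd$state
    }
    if (ep >= swa_from) {
      swa_n <- swa_n + 1L
      if (is.null(swa)) {
        swa <- model$params
      } else {
        for (nm in names(swa)) {
          for (f in c("w", "b")) {
            swa[[nm]][[f]] <- swa[[nm]][[f]] +
              (model$params[[nm]][[f]] - swa[[nm]][[f]]) / swa_n
          }
        }
      }
    }
    vd <- NA_real_
    if (!is.null(validation)) {
      vd <- mean(vapply(validation, function(vc) {
        pr <- predict_case(model, vc)
        dice(binarize(pr$prob_lesion, 0.33), vc$target[, , 5, ] != 0)
      }, numeric(1)))
      if (vd > best$dice) {
        best <- list(dice = vd, params = model$params, epoch = ep)
      }
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = mean(losses),
                                val_dice = vd))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.6f  val_dice %s", ep, mean(losses),
                      ifelse(is.na(vd), "-", sprintf("%.3f", vd))))
    }
  }

  last_params <- model$params
  if (!is.null(swa)) model$params <- swa
  fit <- structure(list(model = model, history = history,
                        best_epoch = best$epoch,
                        best_params = if (is.finite(best$dice)) best$params,
                        last_params = last_params,
                        collapsed = FALSE),
                   class = "mrf_unet_fit")
  probe <- if (!is.null(validation)) validation else sampler$cases
  mx <- max(vapply(probe, function(vc) {
    max(predict_case(model, vc)$prob_lesion)
  }, numeric(1)))
  fit$collapsed <- mx < 0.33
  if (fit$collapsed) {
    warning("variant ", variant$name, " converged to empty prediction: ",
            "all lesion probabilities below the 33% threshold")
  }
  fit
}

#' @export
print.mrf_unet_fit <- function(x, ...) {
  cat(sprintf("mrf_unet_fit '%s': %d epochs, final loss %.5g%s%s\n",
              x$model$variant$name, nrow(x$history),
              x$history$loss[nrow(x$history)],
              if (!all(is.na(x$history$val_dice)))
                sprintf(", best val dice %.3f (epoch %d)",
                        max(x$history$val_dice, na.rm = TRUE), x$best_epoch)
              else "",
              if (x$collapsed) " [collapsed to empty lesion prediction]"
              else ""))
  invisible(x)
}

# full-slice inference for one case with a bare model
predict_case <- function(model, case, use_params = NULL) {
  if (!is.null(use_params)) model$params <- use_params
  d <- dim(case$input)
  if (d[3] != model$variant$n_inputs) {
    stop("case has ", d[3], " input channels but variant '",
         model$variant$name, "' expects ", model$variant$n_inputs)
  }
  mult <- 2^model$config$encoder_depth
  H <- ceiling(d[1] / mult) * mult
  W <- ceiling(d[2] / mult) * mult
  x <- array(0, c(H, W, d[3], d[4]))
  ri <- reflect_index(d[1], H)
  rj <- reflect_index(d[2], W)
  x[, , , ] <- case$input[ri, rj, , , drop = FALSE]
  y <- unet_forward(model, x)$y
  y <- y[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]
  cfg <- model$config
  chans <- target_channels(model$variant$n_outputs)
  out <- list()
  if (identical(chans, 1:5)) {
    out$t1_ms <- y[, , 1, ] * cfg$t1_scale
    out$t2s_ms <- y[, , 2, ] * cfg$t2s_scale
    out$prob_nawm <- y[, , 3, ]
    out$prob_gm <- y[, , 4, ]
    out$prob_lesion <- y[, , 5, ]
  } else {
    out$prob_lesion <- y[, , 1, ]
  }
  for (nm in names(out)) dim(out[[nm]]) <- d[c(1, 2, 4)]
  out$raw <- y
  out$channel_scales <- c(t1 = cfg$t1_scale, t2s = cfg$t2s_scale)
  structure(out, class = "output_maps")
}

# reflective (mirror) index extension from n to m >= n samples
reflect_index <- function(n, m) {
  if (m == n) return(seq_len(n))
  if (n == 1L) return(rep_len(1L, m))
  base <- c(seq_len(n), seq(n - 1, 2))  # one full mirror cycle
  rep_len(base, m)
}

#' Predict output maps for new data
#'
#' Full-slice (not patch-wise) inference with reflective padding of the
#' in-plane matrix to a multiple of `2^encoder_depth`. The quantitative
#' channels are denormalized back to ms via the stored channel scales;
#' probability channels are returned unclipped (their background is
#' non-zero by construction of the regression head) — clip at evaluation
#' time with [binarize()].
#'
#' @param object An `mrf_unet_fit` from [train()].
#' @param newdata A `training_case` (see [make_training_case()]) or
#'   [baseline_stack()].
#' @param use_best Use the best-validation checkpoint when available.
#' @param ... Unused.
#' @return An `output_maps` list: `t1_ms`, `t2s_ms`, `prob_nawm`,
#'   `prob_gm`, `prob_lesion` (subset per variant), plus `raw` normalized
#'   channels and `channel_scales`.
#' @export
predict.mrf_unet_fit <- function(object, newdata, use_best = FALSE, ...) {
  if (inherits(newdata, "baseline_stack")) {
    newdata <- make_training_case(newdata, config = object$model$config)
  }
  predict_case(object$model, newdata,
               use_params = if (use_best && !is.null(object$best_params))
                 object$best_params)
}
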