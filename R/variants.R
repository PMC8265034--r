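#' Network variant taxonomy
#'
#' The eight trained network configurations: every loss with either all five
#' output maps (T1, T2*, NAWM-, GM-, lesion-probability) or the lesion
#' probability map alone, plus the reference network `MSE-2-1` that takes
#' the two quantitative maps (T1, T2*) as input instead of the 35 baseline
#' images.
#'
#' @return A data.frame with columns `name`, `loss`, `n_inputs`, `n_outputs`.
#' @export
#' @examples
#' network_variants()
network_variants <- function() {
  data.frame(
    name = c("MSE-5", "MAE-5", "LCL-5", "MSE-1", "MAE-1", "LCL-1",
             "DICE-1", "MSE-2-1"),
    loss = c("MSE", "MAE", "LCL", "MSE", "MAE", "LCL", "DICE", "MSE"),
    n_inputs = c(35L, 35L, 35L, 35L, 35L, 35L, 35L, 2L),
    n_outputs = c(5L, 5L, 5L, 1L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
}

#' Look up one network variant by name
#'
#' @param name Variant name, e.g. `"MSE-5"`.
#' @return One-row data.frame (see [network_variants()]).
#' @export
get_variant <- function(name) {
  tab <- network_variants()
  row <- tab[tab$name == name, ]
  if (!nrow(row)) {
    stop("unknown network variant '", name, "'; expected one of: ",
         paste(tab$name, collapse = ", "))
  }
  row
}

#' Training configuration
#'
#' Defaults follow the study protocol: 64 random patches per slice of
#' 64 x 64 voxels, mini-batch size 64, 100 epochs, learning rate 1e-4
#' (Adam), and five-fold augmentation of slices whose in-slice lesion
#' volume is at least `lesion_volume_min` microliters. The encoder depth of
#' the U-net is three; the channel width at full resolution is
#' configurable.
#'
#' @param patches_per_slice Random patches drawn per listed slice per epoch.
#' @param patch_size Square patch edge in voxels; must be divisible by
#'   `2^encoder_depth`.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param lr_decay Multiplicative per-epoch learning-rate decay factor in
#'   (0, 1]; 1 (the default) keeps the rate constant. Short schedules
#'   benefit from annealing the step size so late-epoch gradient noise does
#'   not blur the regression output.
#' @param augment_factor Repetition factor for lesion-bearing slices.
#' @param lesion_volume_min Minimum in-slice lesion volume (microliters =
#'   mm^3) for a slice to be augmented.
#' @param seed Integer seed for initialization and patch sampling.
#' @param encoder_depth Number of resolution halvings.
#' @param base_channels Feature channels at full resolution (doubled at each
#'   deeper level).
#' @param t1_scale,t2s_scale Denormalization scales (ms) making the T1 and
#'   T2* channels order one.
#' @return A `training_config` list.
#' @export
training_config <- function(patches_per_slice = 64L, patch_size = 64L,
                            batch_size = 64L, epochs = 100L,
                            learning_rate = 1e-4, lr_decay = 1,
                            augment_factor = 5L,
                            lesion_volume_min = 100, seed = 1L,
                            encoder_depth = 3L, base_channels = 32L,
                            t1_scale = 3500, t2s_scale = 2500) {
  cfg <- list(patches_per_slice = as.integer(patches_per_slice),
              patch_size = as.integer(patch_size),
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              learning_rate = learning_rate,
              lr_decay = lr_decay,
              augment_factor = as.integer(augment_factor),
              lesion_volume_min = lesion_volume_min,
              seed = as.integer(seed),
              encoder_depth = as.integer(encoder_depth),
              base_channels = as.integer(base_channels),
              t1_scale = t1_scale, t2s_scale = t2s_scale)
  stopifnot(cfg$patches_per_slice > 0, cfg$patch_size > 0, cfg$batch_size > 0,
            cfg$epochs > 0, cfg$learning_rate > 0, cfg$augment_factor > 0,
            cfg$encoder_depth > 0, cfg$base_channels > 0,
            cfg$lr_decay > 0, cfg$lr_decay <= 1)
  structure(cfg, class = "training_config")
}
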