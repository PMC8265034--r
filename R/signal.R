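#' Simulate the magnitude fingerprint of one voxel
#'
#' Perfectly spoiled gradient-echo recursion with per-frame T2* echo decay
#' and an optional initial inversion preparation. Writing `Mz-` for the
#' normalized longitudinal magnetization just before excitation of frame i,
#'
#'   s_i   = |Mz-(i)| * sin(b1 * alpha_i) * exp(-TE_i / T2*) * M0
#'   Mz+   = Mz-(i) * cos(b1 * alpha_i)
#'   Mz-(i+1) = 1 + (Mz+ - 1) * exp(-TR_i / T1)
#'
#' with `Mz-(1) = -1` under inversion and `+1` otherwise. Magnitude data are
#' non-negative by construction.
#'
#' @param t1,t2s Relaxation times in ms (strictly positive).
#' @param m0 Proton-density scale, arbitrary units, `>= 0`.
#' @param b1_scale Dimensionless flip-angle scale (B1+ inhomogeneity).
#' @param schedule An [mrf_schedule()].
#' @return Numeric vector of `schedule$n_frames` non-negative magnitudes.
#' @export
#' @examples
#' s <- simulate_fingerprint(850, 50, 1, 1, default_schedule())
simulate_fingerprint <- function(t1, t2s, m0 = 1, b1_scale = 1,
                                 schedule = default_schedule()) {
  if (any(t1 <= 0) || any(t2s <= 0)) {
    stop("relaxation times t1 and t2s must be strictly positive")
  }
  if (any(b1_scale <= 0)) stop("b1_scale must be strictly positive")
  if (any(m0 < 0)) stop("m0 must be non-negative")
  n <- max(length(t1), length(t2s), length(m0), length(b1_scale))
  t1 <- rep_len(t1, n); t2s <- rep_len(t2s, n)
  m0 <- rep_len(m0, n); b1 <- rep_len(b1_scale, n)

  alpha <- schedule$flip_deg * pi / 180
  sig <- matrix(0, n, schedule$n_frames)
  mz <- rep(if (schedule$inversion) -1 else 1, n)
  for (i in seq_len(schedule$n_frames)) {
    a <- b1 * alpha[i]
    sig[, i] <- abs(mz) * sin(a) * exp(-schedule$te_ms[i] / t2s) * m0
    mzp <- mz * cos(a)
    mz <- 1 + (mzp - 1) * exp(-schedule$tr_ms[i] / t1)
  }
  if (n == 1L) drop(sig) else sig
}

#' Baseline image stack
#'
#' 4-D non-negative magnitude stack, one channel per MRF frame, together with
#' the voxel size and the schedule that produced it.
#'
#' @param data 4-D array `(nx, ny, nz, n_frames)`, non-negative.
#' @param schedule The [mrf_schedule()] of the acquisition.
#' @param voxel_size Numeric length-3, mm.
#' @return A `baseline_stack` object.
#' @export
baseline_stack <- function(data, schedule, voxel_size = c(1, 1, 2)) {
  d <- dim(data)
  if (length(d) != 4L) stop("data must be a 4-D array (nx, ny, nz, n_frames)")
  if (d[4] != schedule$n_frames) {
    stop("frame count of data (", d[4], ") does not match schedule (",
         schedule$n_frames, ")")
  }
  if (min(data) < 0) stop("magnitude data must be non-negative")
  structure(list(data = data, schedule = schedule,
                 voxel_size = as.double(voxel_size)),
            class = "baseline_stack")
}

#' @export
print.baseline_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("baseline_stack: %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Simulate a baseline stack from a phantom
#'
#' Voxel-wise application of [simulate_fingerprint()] using the phantom's
#' T1, T2*, M0 and B1+ maps. Background voxels (`m0 == 0`) are zero in every
#' frame.
#'
#' @param phantom A [phantom_volume] as returned by [generate_phantom()].
#' @param schedule An [mrf_schedule()].
#' @return A [baseline_stack()].
#' @export
simulate_baseline_stack <- function(phantom, schedule = default_schedule()) {
  dm <- dim(phantom$t1_map)
  for (nm in c("t2s_map", "m0_map", "b1_map")) {
    if (!identical(dim(phantom[[nm]]), dm)) {
      stop("phantom map ", nm, " does not match the shape of t1_map")
    }
  }
  data <- array(0, c(dm, schedule$n_frames))
  idx <- which(phantom$m0_map > 0)
  if (length(idx)) {
    sig <- simulate_fingerprint(phantom$t1_map[idx], phantom$t2s_map[idx],
                                phantom$m0_map[idx], phantom$b1_map[idx],
                                schedule)
    sig <- matrix(sig, nrow = length(idx))
    nvox <- prod(dm)
    for (i in seq_len(schedule$n_frames)) {
      data[idx + (i - 1) * nvox] <- sig[, i]
    }
  }
  baseline_stack(data, schedule, phantom$voxel_size)
}

#' Add Rician noise to a magnitude stack
#'
#' Each magnitude value v is replaced by `sqrt((v + g1)^2 + g2^2)` with g1,
#' g2 independent zero-mean Gaussians — the magnitude of a complex signal
#' with additive complex Gaussian noise. The noise standard deviation is
#' `mean(brain signal) / snr`, where the brain reference is the mean of the
#' strictly positive voxels of the first frame.
#'
#' @param stack A [baseline_stack()].
#' @param snr Signal-to-noise ratio (> 0) referencing sigma to the mean
#'   within-brain signal.
#' @param seed Integer seed; the draw is reproducible.
#' @return A noisy [baseline_stack()]; attribute `sigma` records the noise SD.
#' @export
add_rician_noise <- function(stack, snr = 40, seed = 1L) {
  if (snr <= 0) stop("snr must be strictly positive")
  v <- stack$data
  f1 <- v[, , , 1, drop = TRUE]
  pos <- f1 > 0
  sigma <- if (any(pos)) mean(f1[pos]) / snr else 1 / snr
  noisy <- with_seed(seed, {
    g1 <- array(rnorm(length(v), sd = sigma), dim(v))
    g2 <- array(rnorm(length(v), sd = sigma), dim(v))
    sqrt((v + g1)^2 + g2^2)
  })
  out <- baseline_stack(noisy, stack$schedule, stack$voxel_size)
  attr(out, "sigma") <- sigma
  out
}
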