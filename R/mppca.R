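#' Marchenko-Pastur PCA denoising of a baseline stack
#'
#' Sliding-window principal component analysis with automatic noise-level
#' and rank selection. For each 2-D in-plane window (slices are processed
#' independently because they are thick relative to the in-plane
#' resolution), the M x N Casorati matrix X (M window voxels, N frames) is
#' decomposed by SVD. With R = min(M, N), Q = max(M, N) and covariance
#' eigenvalues `lambda_i = s_i^2 / Q` in descending order, the smallest
#' number of signal components p is chosen such that the remaining
#' eigenvalues form a Marchenko-Pastur noise bulk:
#'
#'   lambda_(p+1) - lambda_R  <  4 * sqrt((R - p) / Q) * sigma2_hat,
#'   sigma2_hat = mean(lambda_(p+1), ..., lambda_R)
#'
#' i.e. the spread of the candidate bulk must not exceed the
#' Marchenko-Pastur support width for iid noise of variance sigma2_hat.
#' Components beyond p are suppressed and the window is reconstructed from
#' the leading p components. Voxels closer than half a window to the
#' in-plane edge are passed through unchanged.
#'
#' @param stack A [baseline_stack()].
#' @param window Odd in-plane window extent (default 5, i.e. 5 x 5).
#' @param mode `"average"` — overlapping window reconstructions are averaged
#'   with uniform weights (default); `"center"` — each window writes back
#'   only its center voxel.
#' @return A `denoise_result`: `denoised` ([baseline_stack()]), `sigma_map`
#'   (estimated noise SD per voxel), `rank_map` (retained components per
#'   voxel, rounded under averaging), `n_clipped` (count of negative
#'   reconstructed values clipped to zero to keep the magnitude contract).
#' @export
mppca_denoise <- function(stack, window = 5L, mode = c("average", "center")) {
  mode <- match.arg(mode)
  d <- dim(stack$data)
  if (d[4] < 2) stop("denoising requires at least 2 frames")
  w <- as.integer(window)
  if (w %% 2L == 0L || w < 1L) stop("window must be odd")
  if (w * w < 2L) stop("window must contain at least 2 voxels")
  if (w > d[1] || w > d[2]) stop("window larger than the in-plane matrix")
  half <- (w - 1L) %/% 2L
  n <- d[4]
  M <- w * w
  R <- min(M, n); Q <- max(M, n)
  npix <- d[1] * d[2]

  den <- stack$data
  sigma_map <- array(0, d[1:3])
  rank_map <- array(0, d[1:3])
  n_clipped <- 0L

  for (z in seq_len(d[3])) {
    sl <- matrix(stack$data[, , z, ], npix, n)
    acc <- matrix(0, npix, n)
    wt <- numeric(npix)
    sig <- numeric(npix)
    rk <- numeric(npix)
    for (ci in seq(half + 1L, d[1] - half)) {
      rows_i <- (ci - half):(ci + half)
      for (cj in seq(half + 1L, d[2] - half)) {
        vox <- as.vector(outer(rows_i, ((cj - half):(cj + half) - 1L) * d[1],
                               "+"))
        X <- sl[vox, , drop = FALSE]
        sv <- svd(X)
        lam <- sv$d^2 / Q
        p <- R - 1L
        sigma2 <- 0
        for (cand in 0:(R - 1L)) {
          bulk <- lam[(cand + 1L):R]
          s2 <- mean(bulk)
          # the 1e-12 * lam[1] slack accepts numerically-zero bulks on
          # noiseless (exactly low-rank) data
          if (lam[cand + 1L] - lam[R] <
              4 * sqrt((R - cand) / Q) * s2 + 1e-12 * lam[1L]) {
            p <- cand; sigma2 <- s2
            break
          }
        }
        Xr <- if (p == 0L) {
          matrix(0, M, n)
        } else {
          sv$u[, seq_len(p), drop = FALSE] %*%
            (sv$d[seq_len(p)] * t(sv$v[, seq_len(p), drop = FALSE]))
        }
        if (mode == "average") {
          acc[vox, ] <- acc[vox, ] + Xr
          wt[vox] <- wt[vox] + 1
          sig[vox] <- sig[vox] + sqrt(max(sigma2, 0))
          rk[vox] <- rk[vox] + p
        } else {
          ctr <- vox[half * w + half + 1L]
          acc[ctr, ] <- Xr[half * w + half + 1L, ]
          wt[ctr] <- 1
          sig[ctr] <- sqrt(max(sigma2, 0))
          rk[ctr] <- p
        }
      }
    }
    cov <- wt > 0
    out_sl <- sl
    out_sl[cov, ] <- acc[cov, , drop = FALSE] / wt[cov]
    n_clipped <- n_clipped + sum(out_sl < 0)
    out_sl[out_sl < 0] <- 0
    den[, , z, ] <- out_sl
    sg <- numeric(npix); sg[cov] <- sig[cov] / wt[cov]
    rr <- numeric(npix); rr[cov] <- rk[cov] / wt[cov]
    sigma_map[, , z] <- sg
    rank_map[, , z] <- round(rr)
  }

  structure(list(denoised = baseline_stack(den, stack$schedule,
                                           stack$voxel_size),
                 sigma_map = sigma_map, rank_map = rank_map,
                 n_clipped = n_clipped),
            class = "denoise_result")
}
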