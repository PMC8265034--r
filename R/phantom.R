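#' Digital brain phantom configuration
#'
#' Configuration for the seeded digital brain phantom that stands in for a
#' patient cohort. The geometry is a concentric-ellipsoid brain: a thin CSF
#' rim at the surface, a gray-matter ribbon beneath it, white matter in the
#' interior and CSF-filled ventricles near the center. Focal white-matter
#' lesions with elevated T1 and T2* are inserted as ellipsoidal blobs inside
#' normal-appearing white matter (NAWM).
#'
#' Default tissue values are typical 3 T literature values and must lie
#' inside the dictionary ranges (T1 300-3500 ms, T2* 10-2500 ms).
#'
#' @param shape Integer length-3 matrix size in voxels. The default 240 x 240
#'   in-plane matrix corresponds to a 240 x 240 mm field of view at 1 mm.
#' @param voxel_size Numeric length-3, mm (default 1 x 1 x 2).
#' @param t1_ms,t2s_ms Named numeric vectors with entries `nawm`, `gm`,
#'   `csf`: tissue relaxation times in ms.
#' @param m0 Named numeric vector, proton-density scale per tissue.
#' @param n_lesions Expected lesion count; the realized count is a Poisson
#'   draw with this mean. 0 gives a healthy phantom.
#' @param lesion_radius_vox Length-2 range of in-plane lesion semi-axes in
#'   voxels.
#' @param lesion_elevation Length-2 range of the fractional T1/T2* increase
#'   of lesions over NAWM (default 10-60 %).
#' @param prob_sigma Gaussian blur (voxels) applied to hard tissue labels to
#'   emulate soft segmentation probability maps.
#' @param b1_field `"polynomial"` for a smooth quadratic transmit-field
#'   profile, `"uniform"` for B1+ = 1 everywhere.
#' @param t1_range,t2s_range Admissible (dictionary) ranges in ms; configured
#'   tissue values outside these are rejected.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(240L, 240L, 24L),
                           voxel_size = c(1, 1, 2),
                           t1_ms = c(nawm = 850, gm = 1400, csf = 3300),
                           t2s_ms = c(nawm = 50, gm = 55, csf = 1500),
                           m0 = c(nawm = 0.8, gm = 0.85, csf = 1.0),
                           n_lesions = 8,
                           lesion_radius_vox = c(2, 10),
                           lesion_elevation = c(0.1, 0.6),
                           prob_sigma = 1,
                           b1_field = c("polynomial", "uniform"),
                           t1_range = c(300, 3500),
                           t2s_range = c(10, 2500)) {
  b1_field <- match.arg(b1_field)
  tiss <- c("nawm", "gm", "csf")
  for (nm in tiss) {
    if (t1_ms[[nm]] < t1_range[1] || t1_ms[[nm]] > t1_range[2]) {
      stop("configured ", nm, " T1 (", t1_ms[[nm]],
           " ms) is outside the dictionary range [", t1_range[1], ", ",
           t1_range[2], "] ms")
    }
    if (t2s_ms[[nm]] < t2s_range[1] || t2s_ms[[nm]] > t2s_range[2]) {
      stop("configured ", nm, " T2* (", t2s_ms[[nm]],
           " ms) is outside the dictionary range [", t2s_range[1], ", ",
           t2s_range[2], "] ms")
    }
  }
  if (n_lesions < 0) stop("n_lesions must be >= 0")
  structure(list(shape = as.integer(shape), voxel_size = as.double(voxel_size),
                 t1_ms = t1_ms, t2s_ms = t2s_ms, m0 = m0,
                 n_lesions = n_lesions,
                 lesion_radius_vox = lesion_radius_vox,
                 lesion_elevation = lesion_elevation,
                 prob_sigma = prob_sigma, b1_field = b1_field,
                 t1_range = t1_range, t2s_range = t2s_range),
            class = "phantom_config")
}

#' Generate a seeded digital brain phantom
#'
#' Builds the ground-truth maps the pipeline trains on and evaluates
#' against: T1, T2*, M0, B1+ scale, soft tissue probability maps (NAWM, GM,
#' CSF) and a binary lesion mask. Identical `config` and `seed` give a
#' bit-identical phantom.
#'
#' Probability maps are Gaussian-blurred hard labels renormalized to sum to
#' one inside the brain, emulating soft segmentation output; partial volume
#' is represented in these probability maps. Quantitative maps assign each
#' voxel its pure tissue value (discrete-tissue phantom convention);
#' lesions multiply T1 and T2* by `1 + elevation * L` with a smooth lesion
#' field `L`, so lesion insertion can only raise relaxation times. Lesions
#' are seeded in voxels with NAWM probability > 0.5 and never overlap CSF.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed.
#' @return A `phantom_volume`: list with `t1_map`, `t2s_map`, `m0_map`,
#'   `b1_map`, `prob_nawm`, `prob_gm`, `prob_csf`, `lesion_mask`,
#'   `brain_mask`, `voxel_size`, `seed`, `config`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_config(shape = c(64L, 64L, 4L),
#'                                       lesion_radius_vox = c(2, 5)), seed = 1)
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  with_seed(seed, generate_phantom_impl(config, seed))
}

generate_phantom_impl <- function(config, seed) {
  dm <- config$shape
  cx <- (dm + 1) / 2
  ax <- 0.45 * dm[1]; ay <- 0.45 * dm[2]; az <- 0.55 * dm[3]
  gi <- array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dm)
  gj <- array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dm)
  gk <- array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm)
  r2 <- ((gi - cx[1]) / ax)^2 + ((gj - cx[2]) / ay)^2 + ((gk - cx[3]) / az)^2
  r <- sqrt(r2)

  brain <- r < 1
  # concentric shells: CSF rim, GM ribbon, WM interior
  lab_csf <- brain & r >= 0.95
  lab_gm <- brain & r >= 0.78 & r < 0.95
  lab_wm <- brain & r < 0.78
  # ventricles: two ellipsoids flanking the midline
  for (s in c(-1, 1)) {
    vc <- c(cx[1] + s * 0.12 * dm[1], cx[2], cx[3])
    vr2 <- ((gi - vc[1]) / (0.07 * dm[1]))^2 +
           ((gj - vc[2]) / (0.22 * dm[2]))^2 +
           ((gk - vc[3]) / (0.45 * dm[3]))^2
    vent <- vr2 < 1 & brain
    lab_csf <- lab_csf | vent
    lab_wm <- lab_wm & !vent
    lab_gm <- lab_gm & !vent
  }

  sig <- config$prob_sigma
  p_nawm <- gauss_smooth3d(lab_wm * 1, sig)
  p_gm <- gauss_smooth3d(lab_gm * 1, sig)
  p_csf <- gauss_smooth3d(lab_csf * 1, sig)
  tot <- p_nawm + p_gm + p_csf
  inb <- brain & tot > 0
  for (p in c("p_nawm", "p_gm", "p_csf")) {
    v <- get(p)
    v[!inb] <- 0
    v[inb] <- v[inb] / tot[inb]
    assign(p, v)
  }

  # quantitative maps come from the hard labels (each voxel is one pure
  # tissue, the classic discrete-tissue digital-phantom convention); the
  # blurred probability maps alone represent partial volume, emulating soft
  # segmentation output
  t1 <- lab_wm * config$t1_ms[["nawm"]] + lab_gm * config$t1_ms[["gm"]] +
    lab_csf * config$t1_ms[["csf"]]
  t2s <- lab_wm * config$t2s_ms[["nawm"]] + lab_gm * config$t2s_ms[["gm"]] +
    lab_csf * config$t2s_ms[["csf"]]
  m0 <- lab_wm * config$m0[["nawm"]] + lab_gm * config$m0[["gm"]] +
    lab_csf * config$m0[["csf"]]

  # lesions: Poisson count of ellipsoidal blobs restricted to NAWM
  lesion_mask <- array(FALSE, dm)
  nawm_region <- p_nawm > 0.5
  n_les <- if (config$n_lesions > 0) rpois(1, config$n_lesions) else 0L
  cand <- which(nawm_region)
  zaspect <- config$voxel_size[3] / config$voxel_size[1]
  if (n_les > 0 && length(cand)) {
    for (l in seq_len(n_les)) {
      ctr <- arrayInd(cand[sample.int(length(cand), 1)], dm)
      rad <- runif(2, config$lesion_radius_vox[1], config$lesion_radius_vox[2])
      radz <- max(1, mean(rad) / zaspect)
      elev <- runif(1, config$lesion_elevation[1], config$lesion_elevation[2])
      lr2 <- ((gi - ctr[1]) / rad[1])^2 + ((gj - ctr[2]) / rad[2])^2 +
             ((gk - ctr[3]) / radz)^2
      blob <- lr2 < 1 & nawm_region
      if (!any(blob)) next
      L <- gauss_smooth3d(blob * 1, 0.8)
      L[p_csf >= 0.5] <- 0
      L <- L / max(L)
      t1 <- t1 * (1 + elev * L)
      t2s <- t2s * (1 + elev * L)
      lesion_mask <- lesion_mask | blob
    }
  }
  t1[brain] <- pmin(pmax(t1[brain], config$t1_range[1]), config$t1_range[2])
  t2s[brain] <- pmin(pmax(t2s[brain], config$t2s_range[1]), config$t2s_range[2])
  t1[!brain] <- 0; t2s[!brain] <- 0; m0[!brain] <- 0

  b1 <- if (config$b1_field == "uniform") {
    array(1, dm)
  } else {
    X <- 2 * (gi - cx[1]) / dm[1]
    Y <- 2 * (gj - cx[2]) / dm[2]
    pmin(pmax(1.15 - 0.5 * (X^2 + Y^2), 0.6), 1.4)
  }

  structure(list(t1_map = t1, t2s_map = t2s, m0_map = m0, b1_map = b1,
                 prob_nawm = p_nawm, prob_gm = p_gm, prob_csf = p_csf,
                 lesion_mask = lesion_mask, brain_mask = brain,
                 voxel_size = config$voxel_size, seed = seed,
                 config = config),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("phantom_volume: %s voxels, %d lesion voxels in %d component(s), seed %d\n",
              paste(dim(x$t1_map), collapse = " x "), sum(x$lesion_mask),
              max(label_components(x$lesion_mask)), x$seed))
  invisible(x)
}

#' Perturb a lesion mask to emulate a second annotation
#'
#' Emulates intra-observer variability in manual lesion segmentation: each
#' lesion component is shifted by a small random offset and its boundary
#' voxels are randomly toggled. The expected dice overlap with the input
#' decreases monotonically as `severity` grows; `severity = 0` returns the
#' input unchanged. The default severity is calibrated so that the mean dice
#' between original and perturbed masks on default phantoms is about 0.68,
#' the level of human intra-observer agreement.
#'
#' @param mask Binary 3-D array.
#' @param seed Integer seed.
#' @param severity Perturbation strength in \[0, 1\].
#' @return Binary array of the same shape.
#' @export
perturb_lesion_mask <- function(mask, seed = 1L, severity = 0.7) {
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  m <- mask != 0
  if (!any(m)) {
    warning("empty input mask returned unchanged")
    return(m)
  }
  if (severity == 0) return(m)
  with_seed(seed, {
    lab <- label_components(m)
    out <- array(FALSE, dim(m))
    for (k in seq_len(max(lab))) {
      comp <- lab == k
      sh <- c(round(rnorm(2, 0, 1.6 * severity)),
              round(rnorm(1, 0, 0.5 * severity)))
      out <- out | (shift_array(comp, sh) != 0)
    }
    # toggle voxels in the boundary band (dilation minus erosion)
    band <- dilate6(out) & !erode6(out)
    flip <- band & array(runif(length(out)) < 0.5 * severity, dim(out))
    xor(out, flip)
  })
}
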