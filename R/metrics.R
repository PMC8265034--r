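#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`. When both masks are empty the coefficient is
#' defined as 1: an empty prediction on a healthy subject is a perfect
#' score.
#'
#' @param a,b Binary arrays of identical shape.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    stop("dice: mask shapes differ")
  }
  a <- a != 0; b <- b != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Binarize a probability map
#'
#' Closed threshold: a voxel is set iff `value >= threshold`, so the
#' conventional 33 % (lesion) and 80 % (tissue) thresholds are inclusive.
#'
#' @param prob_map Numeric array.
#' @param threshold Fraction in (0, 1).
#' @return Logical array.
#' @export
binarize <- function(prob_map, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  prob_map >= threshold
}

#' Lesion detection rate
#'
#' Ground-truth lesions are 26-connected components of `gt_mask`; a lesion
#' counts as detected iff it shares at least one voxel with the predicted
#' mask. The rate is detected / total. With no ground-truth lesions the
#' rate is defined as 1 and the result carries attribute `no_gt = TRUE`.
#'
#' @param gt_mask,pred_mask Binary arrays of identical shape.
#' @return Scalar fraction in \[0, 1\].
#' @export
lesion_detection_rate <- function(gt_mask, pred_mask) {
  if (!identical(dim(gt_mask), dim(pred_mask))) {
    stop("lesion_detection_rate: mask shapes differ")
  }
  lab <- label_components(gt_mask)
  k <- max(lab)
  if (k == 0) {
    return(structure(1, no_gt = TRUE))
  }
  hit <- unique(lab[lab > 0 & pred_mask != 0])
  length(hit) / k
}

#' Dice and detection rate over a binarization threshold sweep
#'
#' Evaluates [dice()] and [lesion_detection_rate()] of the binarized
#' probability map against the ground truth at each threshold, and reports
#' the dice-maximizing threshold. The detection rate is non-increasing in
#' the threshold because the probability background is non-zero.
#'
#' @param prob_map Numeric array (lesion probability).
#' @param gt_mask Binary ground-truth lesion mask.
#' @param thresholds Strictly increasing fractions in (0, 1).
#' @return A `threshold_sweep` data.frame with columns `threshold`, `dice`,
#'   `detection_rate`; attribute `best_threshold` is the argmax-dice
#'   threshold.
#' @export
threshold_sweep <- function(prob_map, gt_mask,
                            thresholds = seq(0.05, 0.95, by = 0.05)) {
  if (any(thresholds <= 0) || any(thresholds >= 1) ||
      any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing within (0, 1)")
  }
  res <- lapply(thresholds, function(th) {
    pm <- binarize(prob_map, th)
    data.frame(threshold = th, dice = dice(pm, gt_mask),
               detection_rate = as.numeric(lesion_detection_rate(gt_mask, pm)))
  })
  out <- do.call(rbind, res)
  attr(out, "best_threshold") <- out$threshold[which.max(out$dice)]
  class(out) <- c("threshold_sweep", class(out))
  out
}

#' Mean relative deviation between two quantitative maps
#'
#' `mean(|test - ref| / ref)` over the mask — the agreement measure for the
#' T1 and T2* channels.
#'
#' @param test_map,ref_map Numeric arrays (ms).
#' @param mask Binary array; `ref_map` must be strictly positive inside it.
#' @return Scalar fraction.
#' @export
mean_relative_deviation <- function(test_map, ref_map, mask) {
  idx <- which(mask != 0)
  if (!length(idx)) stop("mean_relative_deviation: empty mask")
  r <- ref_map[idx]
  if (any(r <= 0)) stop("ref_map must be strictly positive inside the mask")
  mean(abs(test_map[idx] - r) / r)
}

#' Per-lesion statistics
#'
#' For each 26-connected ground-truth lesion: its volume in microliters
#' (voxel count times voxel volume; 1 ul = 1 mm^3), the dice coefficient
#' between the lesion and the predicted voxels inside its bounding box
#' dilated by 2 voxels (a documented convention restricting the comparison
#' to the lesion's neighbourhood), the total predicted volume of the
#' overlapping predicted components, and the detected flag (at least one
#' overlapping voxel).
#'
#' @param gt_mask,pred_mask Binary arrays of identical shape.
#' @param voxel_size Numeric length-3, mm.
#' @return A `lesion_table` data.frame: `lesion`, `volume_ul`, `dice`,
#'   `pred_volume_ul`, `detected`.
#' @export
per_lesion_stats <- function(gt_mask, pred_mask, voxel_size = c(1, 1, 2)) {
  if (!identical(dim(gt_mask), dim(pred_mask))) {
    stop("per_lesion_stats: mask shapes differ")
  }
  dm <- dim(gt_mask)
  vox_ul <- prod(voxel_size)
  lab <- label_components(gt_mask)
  plab <- label_components(pred_mask)
  k <- max(lab)
  rows <- lapply(seq_len(k), function(l) {
    comp <- lab == l
    idx <- which(comp)
    co <- arrayInd(idx, dm)
    lo <- pmax(apply(co, 2, min) - 2L, 1L)
    hi <- pmin(apply(co, 2, max) + 2L, dm)
    sub <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    d_loc <- dice(sub(comp), sub(pred_mask != 0))
    over <- unique(plab[idx][plab[idx] > 0 & pred_mask[idx] != 0])
    pv <- if (length(over)) sum(plab %in% over) * vox_ul else 0
    data.frame(lesion = l, volume_ul = length(idx) * vox_ul, dice = d_loc,
               pred_volume_ul = pv,
               detected = any(pred_mask[idx] != 0))
  })
  out <- if (k) do.call(rbind, rows) else
    data.frame(lesion = integer(), volume_ul = numeric(), dice = numeric(),
               pred_volume_ul = numeric(), detected = logical())
  class(out) <- c("lesion_table", class(out))
  out
}

#' Cross-section profiles through one lesion
#'
#' Percent increase of T1 and T2* relative to the mean over
#' normal-appearing white matter, `100 * (map - mean_NAWM) / mean_NAWM`,
#' evaluated along one horizontal and one vertical in-plane line through
#' the lesion centroid, together with the lesion probability along the same
#' cuts.
#'
#' @param t1_map,t2s_map Quantitative maps (ms).
#' @param prob_map Lesion probability map.
#' @param lesion_component Binary mask of a single connected lesion.
#' @param nawm_mask Non-empty binary NAWM mask.
#' @return A `lesion_profile` list: `delta_t1_pct` / `delta_t2s_pct` (full
#'   percent-increase maps), `centroid`, and data.frames `horizontal`,
#'   `vertical` with per-voxel `position`, `dt1_pct`, `dt2s_pct`, `prob`.
#' @export
lesion_profile <- function(t1_map, t2s_map, prob_map, lesion_component,
                           nawm_mask) {
  if (!any(nawm_mask != 0)) stop("nawm_mask is empty")
  ncomp <- max(label_components(lesion_component))
  if (ncomp != 1) {
    stop("lesion_component contains ", ncomp,
         " connected components; select a single lesion before profiling")
  }
  mt1 <- mean(t1_map[nawm_mask != 0])
  mt2 <- mean(t2s_map[nawm_mask != 0])
  d1 <- 100 * (t1_map - mt1) / mt1
  d2 <- 100 * (t2s_map - mt2) / mt2
  co <- arrayInd(which(lesion_component != 0), dim(lesion_component))
  ctr <- round(colMeans(co))
  horiz <- data.frame(position = seq_len(dim(t1_map)[1]),
                      dt1_pct = d1[, ctr[2], ctr[3]],
                      dt2s_pct = d2[, ctr[2], ctr[3]],
                      prob = prob_map[, ctr[2], ctr[3]])
  vert <- data.frame(position = seq_len(dim(t1_map)[2]),
                     dt1_pct = d1[ctr[1], , ctr[3]],
                     dt2s_pct = d2[ctr[1], , ctr[3]],
                     prob = prob_map[ctr[1], , ctr[3]])
  structure(list(delta_t1_pct = d1, delta_t2s_pct = d2, centroid = ctr,
                 horizontal = horiz, vertical = vert),
            class = "lesion_profile")
}
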