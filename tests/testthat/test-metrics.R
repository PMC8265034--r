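test_that("dice handles identity, disjoint, partial and empty cases", {
  a <- array(0, c(4, 4, 2)); a[1:2, 1:2, 1] <- 1
  b <- array(0, c(4, 4, 2)); b[3:4, 3:4, 2] <- 1
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0)
  p <- array(0, c(4, 4, 2)); p[1:2, 1, 1] <- 1; p[4, 4, 1:2] <- 1
  expect_equal(dice(a, p), 0.5)  # |a|=|p|=4, overlap 2 -> 2*2/8
  expect_equal(dice(a * 0, b * 0), 1)  # both empty: perfect by convention
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, array(0, c(4, 4, 3))), "differ")
})

test_that("binarization uses a closed threshold and is monotone", {
  m <- array(runif(6 * 6 * 2), c(6, 6, 2))
  expect_equal(sum(binarize(array(0.3, c(2, 2, 1)), 0.33)), 0)
  expect_true(all(binarize(array(0.8, c(2, 2, 1)), 0.8)))
  v1 <- sum(binarize(m, 0.3)); v2 <- sum(binarize(m, 0.6))
  expect_gte(v1, v2)
  expect_error(binarize(m, 0), "in \\(0, 1\\)")
})

test_that("lesion detection rate counts overlapped 26-components", {
  gt <- array(0, c(10, 10, 2))
  gt[1:2, 1:2, 1] <- 1
  gt[6:7, 6:7, 1] <- 1
  gt[9:10, 1:2, 2] <- 1
  pred <- array(0, c(10, 10, 2))
  pred[2, 2, 1] <- 1        # hits lesion 1 with a single voxel
  pred[6:7, 6, 1] <- 1      # hits lesion 2
  expect_equal(lesion_detection_rate(gt, pred), 2 / 3)
  expect_equal(lesion_detection_rate(gt, gt), 1)
  expect_equal(lesion_detection_rate(gt, gt * 0), 0)
  healthy <- lesion_detection_rate(gt * 0, pred)
  expect_equal(as.numeric(healthy), 1)
  expect_true(attr(healthy, "no_gt"))
})

test_that("threshold sweeps are monotone in detection and peak strictly
           inside (0,1) for blurred maps", {
  ph <- tiny_phantom(seed = 9)
  gt <- ph$lesion_mask
  prob <- mrfepi:::gauss_smooth3d(gt * 1, 1.5)
  prob <- prob / max(prob) * 0.9 + 0.1  # non-zero background
  sw <- threshold_sweep(prob, gt, thresholds = seq(0.02, 0.98,
                                                   length.out = 49))
  expect_true(all(diff(sw$detection_rate) <= 0))
  expect_true(all(sw$dice >= 0 & sw$dice <= 1))
  best <- attr(sw, "best_threshold")
  expect_gt(best, min(sw$threshold))
  expect_lt(best, max(sw$threshold))
  # a probability map equal to the mask scores dice 1 at every threshold
  sw2 <- threshold_sweep(gt * 1, gt, thresholds = c(0.25, 0.5, 0.75))
  expect_equal(sw2$dice, rep(1, 3))
})

test_that("mask volume and detection rate are non-increasing over sweeps of
           random probability maps", {
  set.seed(14)
  ths <- seq(0.02, 0.98, length.out = 50)
  for (i in 1:20) {
    prob <- mrfepi:::gauss_smooth3d(array(runif(16 * 16 * 2), c(16, 16, 2)),
                                    1)
    prob <- (prob - min(prob)) / (max(prob) - min(prob) + 1e-9)
    gt <- binarize(mrfepi:::gauss_smooth3d(
      array(runif(16 * 16 * 2), c(16, 16, 2)), 2), 0.55)
    vols <- vapply(ths, function(t) sum(binarize(prob, t)), numeric(1))
    sw <- threshold_sweep(prob, gt, ths)
    expect_true(all(diff(vols) <= 0))
    expect_true(all(diff(sw$detection_rate) <= 0))
  }
})

test_that("mean relative deviation matches a per-voxel loop oracle", {
  set.seed(3)
  ref <- array(runif(5 * 5 * 2, 500, 1500), c(5, 5, 2))
  test <- ref * array(runif(length(ref), 0.8, 1.2), dim(ref))
  mask <- array(runif(length(ref)) > 0.4, dim(ref))
  expect_equal(mean_relative_deviation(ref, ref, mask), 0)
  expect_equal(mean_relative_deviation(1.1 * ref, ref, mask), 0.1)
  acc <- c()
  for (k in which(mask)) acc <- c(acc, abs(test[k] - ref[k]) / ref[k])
  expect_equal(mean_relative_deviation(test, ref, mask), mean(acc))
  expect_error(mean_relative_deviation(test, ref, mask & FALSE), "empty")
})

test_that("per-lesion statistics report volumes, local dice and detection", {
  gt <- array(0, c(12, 12, 4))
  gt[2:6, 2:6, 2] <- 1      # 25 voxels = 50 ul at 1x1x2mm
  gt[9:10, 9:10, 3] <- 1    # 4 voxels = 8 ul
  tab <- per_lesion_stats(gt, gt, voxel_size = c(1, 1, 2))
  expect_equal(nrow(tab), 2L)
  expect_equal(sort(tab$volume_ul), c(8, 50))
  expect_equal(tab$dice, c(1, 1))
  expect_equal(tab$pred_volume_ul, tab$volume_ul)
  expect_true(all(tab$detected))
  expect_equal(sum(tab$volume_ul), sum(gt) * 2)  # volumes sum to total
  # miss the second lesion entirely
  pred <- gt; pred[9:10, 9:10, 3] <- 0
  tab2 <- per_lesion_stats(gt, pred, voxel_size = c(1, 1, 2))
  miss <- tab2[tab2$volume_ul == 8, ]
  expect_equal(miss$dice, 0)
  expect_false(miss$detected)
  # a 50-voxel lesion at 1x1x2 mm is 100 ul
  one <- array(0, c(12, 12, 4)); one[which(gt == 1)[1:4]] <- 1
  expect_equal(per_lesion_stats(one, one)$volume_ul, 4 * 2)
})

test_that("lesion profiles co-localize probability and relaxation increase", {
  dm <- c(21, 21, 3)
  t1 <- array(900, dm); t2s <- array(50, dm)
  nawm <- array(TRUE, dm)
  les <- array(0, dm); les[9:13, 9:13, 2] <- 1
  prob <- mrfepi:::gauss_smooth3d(les, 1.5); prob <- prob / max(prob)
  t1 <- t1 * (1 + 0.3 * prob)   # up to +30% at the lesion core
  t2s <- t2s * (1 + 0.3 * prob)
  lp <- lesion_profile(t1, t2s, prob, les, nawm & !les)
  expect_equal(lp$centroid, c(11, 11, 2))
  expect_equal(max(lp$horizontal$dt1_pct),
               lp$horizontal$dt1_pct[which.max(lp$horizontal$prob)])
  expect_lte(abs(which.max(lp$vertical$prob) -
                   which.max(lp$vertical$dt1_pct)), 2)
  # uniform map -> zero percent increase everywhere
  flat <- lesion_profile(array(900, dm), array(50, dm), prob, les, nawm)
  expect_equal(max(abs(flat$horizontal$dt1_pct)), 0)
  # explicit +30% lesion voxels
  t1b <- array(900, dm); t1b[les == 1] <- 900 * 1.3
  lp2 <- lesion_profile(t1b, t2s, prob, les, nawm & !les)
  expect_equal(lp2$delta_t1_pct[les == 1], rep(30, sum(les)))
  two <- les; two[1:2, 1:2, 1] <- 1
  expect_error(lesion_profile(t1, t2s, prob, two, nawm), "components")
})

test_that("metrics are invariant to a consistent axis permutation", {
  ph <- tiny_phantom(seed = 10)
  gt <- ph$lesion_mask
  pred <- perturb_lesion_mask(gt, seed = 2, severity = 0.4)
  perm <- function(a) aperm(a, c(2, 1, 3))
  expect_equal(dice(gt, pred), dice(perm(gt), perm(pred)))
  expect_equal(as.numeric(lesion_detection_rate(gt, pred)),
               as.numeric(lesion_detection_rate(perm(gt), perm(pred))))
})
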