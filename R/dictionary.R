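#' Geometric parameter grid with fixed relative spacing
#'
#' Dictionary entries are spaced by a constant relative step (default 5 %),
#' i.e. a geometric sequence `v_k = min * (1 + rel_step)^k`. The sequence is
#' truncated at the last value `<= max * (1 + rel_step)`, so the final entry
#' may overshoot `max` by less than one step — this guarantees the whole
#' range is covered and the nearest grid value is never more than half a
#' step away.
#'
#' @param min,max Range endpoints (ms), `0 < min < max`.
#' @param rel_step Relative spacing between consecutive entries (default 0.05).
#' @return Ascending numeric vector; consecutive ratios equal
#'   `1 + rel_step` exactly.
#' @export
#' @examples
#' g <- build_grid(300, 3500)
#' head(g)  # 300.0 315.0 330.75 ...
build_grid <- function(min, max, rel_step = 0.05) {
  if (min <= 0) stop("min must be strictly positive")
  if (min >= max) stop("min must be smaller than max")
  if (rel_step <= 0) stop("rel_step must be strictly positive")
  n <- floor(log(max * (1 + rel_step) / min) / log1p(rel_step)) + 1
  min * (1 + rel_step)^(seq_len(n) - 1)
}

#' Dictionary parameter grid over (T1, T2*, B1 scale)
#'
#' Default grids follow the matching protocol: T1 300-3500 ms and T2*
#' 10-2500 ms in geometric steps of 5 %, and a flip-angle scale factor
#' 0.6-1.4 in arithmetic steps of 0.1 (9 entries) to correct B1+
#' inhomogeneity.
#'
#' @param t1_range,t2s_range Range endpoints in ms.
#' @param rel_step Relative grid spacing for T1 and T2*.
#' @param b1_values Ascending vector of flip-angle scale factors.
#' @return A `parameter_grid` list with `t1_values`, `t2s_values`,
#'   `b1_values`.
#' @export
parameter_grid <- function(t1_range = c(300, 3500), t2s_range = c(10, 2500),
                           rel_step = 0.05,
                           b1_values = seq(0.6, 1.4, by = 0.1)) {
  if (any(diff(b1_values) <= 0)) stop("b1_values must be ascending")
  structure(list(t1_values = build_grid(t1_range[1], t1_range[2], rel_step),
                 t2s_values = build_grid(t2s_range[1], t2s_range[2], rel_step),
                 b1_values = as.double(b1_values),
                 rel_step = rel_step),
            class = "parameter_grid")
}

#' Build the fingerprint dictionary
#'
#' Simulates one fingerprint per (T1, T2*, B1) grid point with `m0 = 1` and
#' L2-normalizes each to a unit-norm atom. The atom order is
#' column-major over (T1 fastest, then T2*, then B1), and the per-atom
#' parameter index is stored alongside.
#'
#' @param schedule An [mrf_schedule()].
#' @param grid A [parameter_grid()].
#' @return An `mrf_dictionary` with fields `atoms` (n_atoms x n_frames,
#'   unit rows), `norms` (pre-normalization L2 norms), `t1`, `t2s`, `b1`
#'   (per-atom parameters), `schedule`, `grid`.
#' @export
build_dictionary <- function(schedule = default_schedule(),
                             grid = parameter_grid()) {
  if (!length(grid$t1_values) || !length(grid$t2s_values) ||
      !length(grid$b1_values)) {
    stop("parameter grid must be non-empty")
  }
  combos <- expand.grid(t1 = grid$t1_values, t2s = grid$t2s_values,
                        b1 = grid$b1_values, KEEP.OUT.ATTRS = FALSE)
  atoms <- simulate_fingerprint(combos$t1, combos$t2s, 1, combos$b1, schedule)
  atoms <- matrix(atoms, nrow = nrow(combos))
  norms <- sqrt(rowSums(atoms^2))
  bad <- which(norms == 0)
  if (length(bad)) {
    stop(sprintf("degenerate all-zero fingerprint at (t1=%g, t2s=%g, b1=%g)",
                 combos$t1[bad[1]], combos$t2s[bad[1]], combos$b1[bad[1]]))
  }
  structure(list(atoms = atoms / norms, norms = norms,
                 t1 = combos$t1, t2s = combos$t2s, b1 = combos$b1,
                 schedule = schedule, grid = grid),
            class = "mrf_dictionary")
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf("mrf_dictionary: %d atoms (%d T1 x %d T2* x %d B1), %d frames\n",
              nrow(x$atoms), length(x$grid$t1_values),
              length(x$grid$t2s_values), length(x$grid$b1_values),
              ncol(x$atoms)))
  invisible(x)
}

#' Match fingerprints against the dictionary
#'
#' Pattern matching by maximal normalized inner product: each fingerprint is
#' L2-normalized and compared with every unit-norm atom; the best-matching
#' atom's grid parameters are returned. `m0` is the projection of the raw
#' fingerprint on the best atom divided by the atom's pre-normalization
#' norm, recovering the proton-density scale. Matching is invariant to
#' positive scaling of the input. Ties break to the lowest atom index.
#' All-zero fingerprints are flagged as background (all outputs 0).
#'
#' @param fingerprint Numeric vector of length `n_frames`, or a matrix with
#'   one fingerprint per row.
#' @param dictionary An `mrf_dictionary`.
#' @return A data.frame with columns `t1`, `t2s`, `b1`, `m0`, `correlation`.
#' @export
match_voxel <- function(fingerprint, dictionary) {
  fp <- if (is.matrix(fingerprint)) fingerprint else matrix(fingerprint, 1)
  if (ncol(fp) != ncol(dictionary$atoms)) {
    stop("fingerprint length (", ncol(fp), ") does not match dictionary (",
         ncol(dictionary$atoms), " frames)")
  }
  nrm <- sqrt(rowSums(fp^2))
  live <- nrm > 0
  out <- data.frame(t1 = numeric(nrow(fp)), t2s = 0, b1 = 0, m0 = 0,
                    correlation = 0)
  if (any(live)) {
    fpn <- fp[live, , drop = FALSE] / nrm[live]
    # inner products in blocks to bound memory on large voxel batches
    best <- integer(nrow(fpn)); bestc <- numeric(nrow(fpn))
    At <- t(dictionary$atoms)
    step <- max(1L, floor(5e6 / nrow(dictionary$atoms)))
    for (s in seq(1, nrow(fpn), by = step)) {
      e <- min(s + step - 1, nrow(fpn))
      cc <- fpn[s:e, , drop = FALSE] %*% At
      b <- max.col(cc, ties.method = "first")
      best[s:e] <- b
      bestc[s:e] <- cc[cbind(seq_len(e - s + 1), b)]
    }
    out$t1[live] <- dictionary$t1[best]
    out$t2s[live] <- dictionary$t2s[best]
    out$b1[live] <- dictionary$b1[best]
    out$m0[live] <- nrm[live] * bestc / dictionary$norms[best]
    out$correlation[live] <- pmin(bestc, 1)
  }
  out
}

#' Reconstruct quantitative maps by voxel-wise pattern matching
#'
#' Applies [match_voxel()] to every voxel inside `brain_mask`; voxels
#' outside the mask are 0 in all outputs. The conventional reconstruction
#' branch — its T1/T2* maps serve as training targets for the network.
#'
#' @param stack A [baseline_stack()].
#' @param dictionary An `mrf_dictionary`.
#' @param brain_mask Binary 3-D array; defaults to voxels with any signal.
#' @return A `quantitative_maps` list: `t1_ms`, `t2s_ms`, `b1_scale`, `m0`,
#'   `correlation` (all arrays of the stack's spatial shape).
#' @export
reconstruct_maps <- function(stack, dictionary, brain_mask = NULL) {
  d <- dim(stack$data)
  if (d[4] != ncol(dictionary$atoms)) {
    stop("stack frame count (", d[4], ") does not match dictionary (",
         ncol(dictionary$atoms), ")")
  }
  if (is.null(brain_mask)) {
    brain_mask <- array(rowSums(matrix(stack$data, prod(d[1:3]), d[4])) > 0,
                        d[1:3])
  }
  if (!identical(dim(brain_mask), d[1:3])) {
    stop("brain_mask shape does not match the stack")
  }
  maps <- list(t1_ms = array(0, d[1:3]), t2s_ms = array(0, d[1:3]),
               b1_scale = array(0, d[1:3]), m0 = array(0, d[1:3]),
               correlation = array(0, d[1:3]))
  idx <- which(brain_mask != 0)
  if (length(idx)) {
    fp <- matrix(stack$data, prod(d[1:3]), d[4])[idx, , drop = FALSE]
    m <- match_voxel(fp, dictionary)
    maps$t1_ms[idx] <- m$t1
    maps$t2s_ms[idx] <- m$t2s
    maps$b1_scale[idx] <- m$b1
    maps$m0[idx] <- m$m0
    maps$correlation[idx] <- m$correlation
  }
  structure(maps, class = "quantitative_maps")
}
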