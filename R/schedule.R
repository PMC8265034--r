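#' MRF-EPI acquisition schedule
#'
#' A fingerprint schedule defines, for each of the acquired baseline frames,
#' the excitation flip angle, echo time and repetition time, plus whether the
#' train is preceded by a 180-degree inversion preparation. The magnitude
#' signal evolution of a voxel across these frames is its "fingerprint".
#'
#' @param n_frames Number of baseline frames.
#' @param flip_deg Per-frame flip angle in degrees.
#' @param te_ms Per-frame echo time in ms.
#' @param tr_ms Per-frame repetition time in ms.
#' @param inversion Logical; apply an initial inversion preparation.
#'
#' @return An object of class `mrf_schedule`.
#' @export
mrf_schedule <- function(flip_deg, te_ms, tr_ms, inversion = TRUE,
                         n_frames = length(flip_deg)) {
  if (length(flip_deg) != n_frames || length(te_ms) != n_frames ||
      length(tr_ms) != n_frames) {
    stop("flip_deg, te_ms and tr_ms must all have length n_frames")
  }
  if (any(flip_deg <= 0) || any(te_ms <= 0) || any(tr_ms <= 0)) {
    stop("schedule entries must be strictly positive")
  }
  if (any(te_ms >= tr_ms)) {
    stop("each te_ms must be smaller than the corresponding tr_ms")
  }
  structure(
    list(n_frames = as.integer(n_frames),
         flip_deg = as.double(flip_deg),
         te_ms = as.double(te_ms),
         tr_ms = as.double(tr_ms),
         inversion = isTRUE(inversion)),
    class = "mrf_schedule")
}

#' Default 35-frame MRF-EPI schedule
#'
#' The protocol acquires 35 baseline frames with flip angles varying between
#' 34 and 86 degrees, echo times between 16 and 76.5 ms, and repetition times
#' between 3530 and 6370 ms. Only the ranges are fixed by the protocol; the
#' default schedule varies the flip angle smoothly (two sinusoidal lobes,
#' endpoints attained exactly) and interpolates TE and TR linearly across
#' their ranges. An explicit per-frame table can be supplied instead via
#' [read_schedule()].
#'
#' @param n_frames Number of frames (default 35).
#' @param inversion Logical; inversion preparation (default `TRUE`).
#' @return An `mrf_schedule`.
#' @export
#' @examples
#' sched <- default_schedule()
#' range(sched$flip_deg)  # 34 86
default_schedule <- function(n_frames = 35L, inversion = TRUE) {
  t <- seq(0, 1, length.out = n_frames)
  # one raised-cosine lobe: 34 deg at both ends, 86 deg at mid-train; for odd
  # n_frames the extremes fall exactly on grid samples
  flip <- 34 + (86 - 34) * 0.5 * (1 - cos(2 * pi * t))
  te <- seq(16, 76.5, length.out = n_frames)
  tr <- seq(3530, 6370, length.out = n_frames)
  mrf_schedule(flip, te, tr, inversion = inversion)
}

#' Read / write a schedule table
#'
#' Plain-text whitespace- or comma-delimited table with header columns
#' `frame`, `flip_deg`, `te_ms`, `tr_ms`.
#'
#' @param path File path.
#' @param inversion Logical flag stored on the returned schedule.
#' @return `read_schedule()` returns an `mrf_schedule`; `write_schedule()`
#'   returns `path` invisibly.
#' @export
read_schedule <- function(path, inversion = TRUE) {
  tab <- utils::read.table(path, header = TRUE,
                           sep = if (grepl("\\.csv$", path)) "," else "")
  need <- c("frame", "flip_deg", "te_ms", "tr_ms")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("schedule table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tab <- tab[order(tab$frame), ]
  mrf_schedule(tab$flip_deg, tab$te_ms, tab$tr_ms, inversion = inversion)
}

#' @rdname read_schedule
#' @param schedule An `mrf_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  tab <- data.frame(frame = seq_len(schedule$n_frames),
                    flip_deg = schedule$flip_deg,
                    te_ms = schedule$te_ms,
                    tr_ms = schedule$tr_ms)
  utils::write.table(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.mrf_schedule <- function(x, ...) {
  cat(sprintf(paste0("MRF-EPI schedule: %d frames, flip %.1f-%.1f deg, ",
                     "TE %.1f-%.1f ms, TR %.0f-%.0f ms, inversion %s\n"),
              x$n_frames, min(x$flip_deg), max(x$flip_deg),
              min(x$te_ms), max(x$te_ms), min(x$tr_ms), max(x$tr_ms),
              if (x$inversion) "on" else "off"))
  invisible(x)
}
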