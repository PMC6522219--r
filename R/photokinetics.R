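#' Normalize a FRAP trace
#'
#' Double normalization: the bleach-spot signal is first divided by the
#' whole-nucleus reference at each frame (cancelling acquisition
#' photobleaching), then divided by the mean of the corrected signal
#' over the pre-bleach frames, so the pre-bleach level is 1 by
#' construction.
#'
#' @param trace an [intensity_trace()] with a reference channel.
#' @param pre_frames number of pre-bleach frames (default 15; the
#'   bleach is applied between frames `pre_frames - 1` and
#'   `pre_frames`, 0-based).
#' @return data.frame with `frame`, `time` (s), `normalized`.
#' @export
normalize_frap <- function(trace, pre_frames = 15L) {
  if (all(is.na(trace$reference_raw)))
    stop("FRAP normalization needs a reference channel", call. = FALSE)
  if (any(trace$reference_raw == 0, na.rm = TRUE))
    stop("reference channel contains zeros", call. = FALSE)
  bf <- attr(trace, "bleach_frame")
  if (!is.null(bf) && bf != pre_frames)
    warning("bleach_frame (", bf, ") != pre_frames (", pre_frames, ")",
            call. = FALSE)
  corrected <- trace$spot_raw / trace$reference_raw
  pre <- mean(corrected[seq_len(pre_frames)])
  if (pre == 0) stop("zero pre-bleach signal", call. = FALSE)
  data.frame(frame = trace$frame,
             time = trace$frame * attr(trace, "frame_interval"),
             normalized = corrected / pre)
}

#' Correct a FLIP trace for acquisition photobleaching
#'
#' The measurement spot is far from the bleach spot, so the only
#' correction needed is the global acquisition photobleaching, modelled
#' as an exponential decay with an empirically determined per-frame
#' rate (default 0.09): `corrected = spot / exp(-rate * frame)`, then
#' normalized to its initial value.
#'
#' @param trace an [intensity_trace()].
#' @param bleach_rate per-frame decay rate (default 0.09).
#' @return data.frame with `frame`, `time` (s), `normalized`.
#' @export
normalize_flip <- function(trace, bleach_rate = 0.09) {
  corrected <- trace$spot_raw / exp(-bleach_rate * trace$frame)
  if (corrected[1L] == 0) stop("zero initial signal", call. = FALSE)
  data.frame(frame = trace$frame,
             time = trace$frame * attr(trace, "frame_interval"),
             normalized = corrected / corrected[1L])
}

#' Aggregate normalized recovery traces
#'
#' Pointwise mean and standard error over cells.
#'
#' @param traces list of data.frames from [normalize_frap()] or
#'   [normalize_flip()], all the same length.
#' @param kind `"FRAP"` or `"FLIP"` (metadata only).
#' @return object of class `recovery_curve`: data.frame with `frame`,
#'   `time`, `mean`, `sem`, plus attributes `n_cells` and `kind`.
#' @export
aggregate_curves <- function(traces, kind = c("FRAP", "FLIP")) {
  kind <- match.arg(kind)
  lens <- vapply(traces, nrow, integer(1))
  if (length(unique(lens)) != 1L)
    stop("traces differ in length", call. = FALSE)
  m <- vapply(traces, function(tr) tr$normalized, numeric(lens[1L]))
  m <- matrix(m, nrow = lens[1L])
  out <- data.frame(frame = traces[[1L]]$frame,
                    time = traces[[1L]]$time,
                    mean = rowMeans(m),
                    sem = apply(m, 1L, stats::sd) / sqrt(length(traces)))
  attr(out, "n_cells") <- length(traces)
  attr(out, "kind") <- kind
  class(out) <- c("recovery_curve", "data.frame")
  out
}

#' @export
plot.recovery_curve <- function(x, ...) {
  graphics::plot(x$time, x$mean, type = "l", xlab = "time (s)",
                 ylab = "normalized intensity", ...)
  graphics::lines(x$time, x$mean + x$sem, lty = 3)
  graphics::lines(x$time, x$mean - x$sem, lty = 3)
  invisible(x)
}
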