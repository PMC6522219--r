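#' Smooth per-residue disorder scores
#'
#' Centred rolling mean of the disorder profile. Smoothing prevents
#' single low-scoring residues from splitting one large disordered
#' region into several apparent ones. For an even window the centre is
#' left-heavy (positions i-w/2 ... i+w/2-1); at the termini the window
#' shrinks to the available residues, so the output length equals the
#' input length.
#'
#' @param profile a [disorder_profile()].
#' @param window rolling-mean width in residues (default 8; 1 = no
#'   smoothing).
#' @return a [disorder_profile()] with smoothed scores.
#' @export
smooth_scores <- function(profile, window = 8L) {
  stopifnot(inherits(profile, "disorder_profile"), window >= 1L)
  s <- profile$scores
  n <- length(s)
  if (window >= n)
    return(disorder_profile(profile$sequence_id, rep(mean(s), n)))
  left <- floor(window / 2)
  right <- window - left - 1L
  cs <- cumsum(c(0, s))
  lo <- pmax(1L, seq_len(n) - left)
  hi <- pmin(n, seq_len(n) + right)
  disorder_profile(profile$sequence_id,
                   (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Segment disordered regions and compute fraction IDR
#'
#' Maximal runs of smoothed scores strictly greater than `threshold`
#' are annotated as disordered regions; runs longer than `min_len`
#' residues (strictly, i.e. length >= min_len + 1) qualify for the
#' fraction-IDR calculation. All runs are reported with a qualifying
#' flag.
#'
#' @param profile a (smoothed) [disorder_profile()].
#' @param threshold disorder-likelihood cutoff (default 0.55, strict
#'   inequality).
#' @param min_len length cutoff in residues; only runs with more than
#'   `min_len` residues count towards fraction IDR (default 10).
#' @return object of class `disorder_summary`: list with `segments`
#'   (data.frame: start, end, length, qualifies; 1-based inclusive),
#'   `fraction_idr`, `n_segments` (qualifying), and the settings.
#' @export
segment_idrs <- function(profile, threshold = 0.55, min_len = 10L) {
  stopifnot(inherits(profile, "disorder_profile"))
  above <- profile$scores > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  seg$length <- seg$end - seg$start + 1L
  seg$qualifies <- seg$length > min_len
  frac <- if (nrow(seg)) sum(seg$length[seg$qualifies]) / profile$length
          else 0
  structure(list(segments = seg, fraction_idr = frac,
                 n_segments = sum(seg$qualifies),
                 threshold = threshold, min_len = as.integer(min_len),
                 sequence_id = profile$sequence_id,
                 length = profile$length),
            class = "disorder_summary")
}

#' Disorder summary for one protein
#'
#' Convenience wrapper: smooth, segment, summarise.
#'
#' @param profile a raw [disorder_profile()].
#' @param window,threshold,min_len see [smooth_scores()] and
#'   [segment_idrs()].
#' @return a `disorder_summary`.
#' @export
fraction_idr <- function(profile, window = 8L, threshold = 0.55,
                         min_len = 10L) {
  segment_idrs(smooth_scores(profile, window), threshold, min_len)
}

#' @export
print.disorder_summary <- function(x, ...) {
  cat(sprintf("%s: %d residues, %d IDR(s), fraction IDR = %.3f\n",
              x$sequence_id, x$length, x$n_segments, x$fraction_idr))
  invisible(x)
}
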