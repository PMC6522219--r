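#' Extract mobile three-point segments
#'
#' Collects every consecutive three-localization set (frame increments
#' of exactly 1, no gaps) and keeps those whose two displacements are
#' both at least `min_jump`. The hard threshold is essential: the
#' apparent motion of bound molecules is pure localization error, which
#' would otherwise make the angular statistics spuriously anisotropic.
#' An optional two-state displacement HMM can additionally drop triples
#' whose segments are classified as bound.
#'
#' @param trajs a [trajectories()] table.
#' @param min_jump minimum displacement (µm; default 0.150).
#' @param classifier `"threshold"` (default) or `"hmm"` (threshold plus
#'   HMM-based removal of bound segments).
#' @return data.frame of class `angle_triples` with the vertex
#'   coordinates/frame and both displacement vectors.
#' @export
filter_mobile_segments <- function(trajs, min_jump = 0.150,
                                   classifier = c("threshold", "hmm")) {
  classifier <- match.arg(classifier)
  df <- as.data.frame(trajs)
  key <- paste(df$cell_id, df$traj_id)
  n <- nrow(df)
  if (n < 3L) return(empty_triples())
  i1 <- seq_len(n - 2L); i2 <- i1 + 1L; i3 <- i1 + 2L
  ok <- key[i1] == key[i2] & key[i2] == key[i3] &
    df$frame[i2] - df$frame[i1] == 1L & df$frame[i3] - df$frame[i2] == 1L
  v1x <- df$x[i2] - df$x[i1]; v1y <- df$y[i2] - df$y[i1]
  v2x <- df$x[i3] - df$x[i2]; v2y <- df$y[i3] - df$y[i2]
  l1 <- sqrt(v1x^2 + v1y^2); l2 <- sqrt(v2x^2 + v2y^2)
  keep <- ok & l1 >= min_jump & l2 >= min_jump
  if (classifier == "hmm" && any(ok)) {
    lab <- hmm_classify_segments(df, key)
    # drop triples either of whose segments is labelled bound
    keep <- keep & lab[i1] == "free" & lab[i2] == "free"
  }
  out <- data.frame(cell_id = df$cell_id[i1][keep],
                    traj_id = df$traj_id[i1][keep],
                    vx = df$x[i2][keep], vy = df$y[i2][keep],
                    vframe = df$frame[i2][keep],
                    v1x = v1x[keep], v1y = v1y[keep],
                    v2x = v2x[keep], v2y = v2y[keep],
                    l1 = l1[keep], l2 = l2[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("angle_triples", "data.frame")
  out
}

empty_triples <- function() {
  out <- data.frame(cell_id = character(0), traj_id = character(0),
                    vx = numeric(0), vy = numeric(0),
                    vframe = integer(0),
                    v1x = numeric(0), v1y = numeric(0),
                    v2x = numeric(0), v2y = numeric(0),
                    l1 = numeric(0), l2 = numeric(0))
  class(out) <- c("angle_triples", "data.frame")
  out
}

# Two-state maximum-likelihood HMM on per-segment displacements with
# Rayleigh emissions (scale = per-state mean squared displacement).
# Returns a per-row state label; the last row of each trajectory
# inherits the label of its final segment.
hmm_classify_segments <- function(df, key) {
  n <- nrow(df)
  nxt <- c(key[-1L] == key[-n], FALSE)
  d2 <- c((df$x[-1L] - df$x[-n])^2 + (df$y[-1L] - df$y[-n])^2, NA)
  d2[!nxt] <- NA
  obs <- d2[!is.na(d2)]
  if (length(obs) < 10L) return(rep("free", n))
  # EM for a two-component exponential mixture on squared displacements
  # (Rayleigh jump lengths), then per-trajectory Viterbi smoothing
  s <- c(stats::quantile(obs, 0.25), stats::quantile(obs, 0.75))
  w <- c(0.5, 0.5)
  for (it in seq_len(100L)) {
    den1 <- w[1L] / s[1L] * exp(-obs / s[1L])
    den2 <- w[2L] / s[2L] * exp(-obs / s[2L])
    g <- den1 / (den1 + den2)
    s_new <- c(sum(g * obs) / sum(g), sum((1 - g) * obs) / sum(1 - g))
    w_new <- c(mean(g), 1 - mean(g))
    if (max(abs(s_new - s)) < 1e-12) { s <- s_new; w <- w_new; break }
    s <- s_new; w <- w_new
  }
  bound_state <- which.min(s)
  # sticky transitions favour within-trajectory persistence
  trans <- matrix(c(0.9, 0.1, 0.1, 0.9), 2L)
  lab <- rep("free", n)
  for (idx in split(seq_len(n), key)) {
    seg <- d2[idx]
    seg <- seg[!is.na(seg)]
    if (!length(seg)) next
    m <- length(seg)
    logem <- rbind(-log(s[1L]) - seg / s[1L], -log(s[2L]) - seg / s[2L])
    v <- matrix(-Inf, 2L, m); ptr <- matrix(0L, 2L, m)
    v[, 1L] <- log(w) + logem[, 1L]
    if (m > 1L) for (t in 2:m) for (st in 1:2) {
      cand <- v[, t - 1L] + log(trans[, st])
      ptr[st, t] <- which.max(cand)
      v[st, t] <- max(cand) + logem[st, t]
    }
    path <- integer(m)
    path[m] <- which.max(v[, m])
    if (m > 1L) for (t in (m - 1L):1L) path[t] <- ptr[path[t + 1L], t + 1L]
    states <- ifelse(path == bound_state, "bound", "free")
    lab[idx[seq_len(m)]] <- states
    lab[idx[length(idx)]] <- states[m]
  }
  lab
}

#' Angles between consecutive displacements
#'
#' Computes the folded angle `theta = arccos(v1.v2 / (|v1||v2|))` in
#' degrees (0 = forward, 180 = direct reversal) for each retained
#' triple, and assigns each angle to a region by containment of its
#' vertex (the middle localization) in the drift-interpolated
#' compartments at the vertex's own frame.
#'
#' @param triples output of [filter_mobile_segments()].
#' @param anns optional annotations (as in [assign_compartments()]);
#'   when omitted every angle is labelled `"all"`.
#' @return data.frame of class `angle_samples` with `theta` (degrees),
#'   displacement lengths and `region` (`"inside"`/`"outside"`/`"all"`).
#' @export
compute_angles <- function(triples, anns = NULL) {
  dot <- triples$v1x * triples$v2x + triples$v1y * triples$v2y
  costh <- pmin(1, pmax(-1, dot / (triples$l1 * triples$l2)))
  theta <- acos(costh) * 180 / pi
  region <- rep("all", nrow(triples))
  if (!is.null(anns) && nrow(triples)) {
    if (inherits(anns, "cell_annotation")) {
      a <- anns
      anns <- stats::setNames(
        lapply(unique(triples$cell_id), function(id) a),
        unique(triples$cell_id))
    }
    for (cid in unique(triples$cell_id)) {
      i <- which(triples$cell_id == cid)
      ann <- anns[[cid]]
      if (is.null(ann))
        stop("no annotation for cell ", cid, call. = FALSE)
      fl <- containment_flags(triples$vframe[i], triples$vx[i],
                              triples$vy[i], ann)
      region[i] <- ifelse(fl$compartment, "inside", "outside")
    }
  }
  out <- data.frame(theta = theta, l1 = triples$l1, l2 = triples$l2,
                    region = region, stringsAsFactors = FALSE)
  class(out) <- c("angle_samples", "data.frame")
  out
}

#' Fold anisotropy: backward/forward wedge ratio
#'
#' The likelihood of a backward translocation (`180 +/- wedge`
#' degrees) relative to a forward translocation (`0 +/- wedge`):
#' `f = #{theta >= 180 - wedge} / #{theta <= wedge}`. Ideal Brownian
#' motion gives f = 1; f > 1 indicates revisiting/trapping behaviour.
#' Uncertainty is the bootstrap SD over triples.
#'
#' @param angles an `angle_samples` data.frame (optionally filtered to
#'   one region first).
#' @param wedge half-width of the wedges in degrees (default 30).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return object of class `anisotropy_fold`: list with `f_180_0`,
#'   `n_backward`, `n_forward`, `boot_sd`.
#' @export
fold_anisotropy <- function(angles, wedge = 30, n_boot = 1000L,
                            seed = NULL) {
  th <- angles$theta
  nb <- sum(th >= 180 - wedge)
  nf <- sum(th <= wedge)
  if (nf == 0L)
    stop("no forward-wedge angles: fold ratio undefined", call. = FALSE)
  f <- nb / nf
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      b <- th[sample.int(length(th), replace = TRUE)]
      nbf <- sum(b <= wedge)
      if (nbf == 0L) NA_real_ else sum(b >= 180 - wedge) / nbf
    }, numeric(1))
  })
  structure(list(f_180_0 = f, n_backward = nb, n_forward = nf,
                 wedge = wedge,
                 boot_sd = stats::sd(boot, na.rm = TRUE),
                 n_angles = length(th)),
            class = "anisotropy_fold")
}

#' @export
print.anisotropy_fold <- function(x, ...) {
  cat(sprintf("f(180/0) = %.3f +/- %.3f (boot SD); %d backward / %d forward of %d angles\n",
              x$f_180_0, x$boot_sd, x$n_backward, x$n_forward,
              x$n_angles))
  invisible(x)
}

#' Angular histogram
#'
#' Histogram of folded angles in fixed-width bins, for rose-plot style
#' summaries.
#'
#' @param angles an `angle_samples` data.frame.
#' @param bin_width degrees per bin (default 5).
#' @return data.frame with `bin_start`, `bin_end`, `count`, `density`.
#' @export
angle_histogram <- function(angles, bin_width = 5) {
  breaks <- seq(0, 180, by = bin_width)
  h <- graphics::hist(angles$theta, breaks = breaks, plot = FALSE)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1L],
             count = h$counts,
             density = h$counts / sum(h$counts) / bin_width)
}
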