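#' Trajectory-linking configuration
#'
#' Frame-to-frame linking parameters. The search radius for a link
#' spanning `k` frames derives from the diffusion ceiling as
#' `r_max(k) = sqrt(4 * d_max * k * dt)`.
#'
#' @param d_max diffusion ceiling (µm²/s; default 10).
#' @param gap_frames detection gaps bridged inside a trajectory
#'   (default 1).
#' @param max_competitors links are refused (trajectory terminated)
#'   when more than this many candidates fall inside the search radius
#'   (default 3).
#' @param frame_interval seconds per frame.
#' @return object of class `linking_config`.
#' @export
linking_config <- function(d_max = 10, gap_frames = 1L,
                           max_competitors = 3L,
                           frame_interval = 0.007447) {
  stopifnot(d_max > 0, gap_frames >= 0L, max_competitors >= 1L,
            frame_interval > 0)
  structure(list(d_max = d_max, gap_frames = as.integer(gap_frames),
                 max_competitors = as.integer(max_competitors),
                 frame_interval = frame_interval),
            class = "linking_config")
}

#' Link localizations into trajectories
#'
#' Greedy nearest-neighbour assignment frame to frame: within each
#' target frame, candidate links are granted shortest-distance first
#' (ties by input order), each localization joining at most one
#' trajectory; a trajectory end may bridge up to `gap_frames` missing
#' frames with the correspondingly enlarged search radius; ends seeing
#' more than `max_competitors` candidates are terminated rather than
#' linked. Deterministic given the input order.
#'
#' @param locs a [localizations()] table (one or more cells).
#' @param config a [linking_config()].
#' @return a [trajectories()] table.
#' @export
link_localizations <- function(locs, config = linking_config()) {
  df <- as.data.frame(locs)
  dup <- duplicated(df[c("cell_id", "frame", "x", "y")])
  if (any(dup))
    warning(sum(dup), " duplicate (frame, x, y) localizations kept",
            call. = FALSE)
  pieces <- lapply(split(df, df$cell_id), function(sub) {
    sub <- sub[order(sub$frame), , drop = FALSE]
    ids <- .link_cpp(sub$x, sub$y, as.integer(sub$frame),
                     config$d_max, config$frame_interval,
                     config$gap_frames, config$max_competitors)
    data.frame(traj_id = sprintf("%s_t%05d", sub$cell_id[1L], ids),
               cell_id = sub$cell_id, frame = sub$frame,
               x = sub$x, y = sub$y, stringsAsFactors = FALSE)
  })
  trajectories(do.call(rbind, pieces), max_gap = config$gap_frames)
}

#' Drift-interpolated annotation polygons at one frame
#'
#' Cell movement across the acquisition is assumed linear: each polygon
#' vertex is interpolated between its "before" and "after" positions at
#' fraction `frame / (n_frames - 1)`.
#'
#' @param ann a [cell_annotation()].
#' @param frame 0-based frame index in `[0, n_frames - 1]`.
#' @return list with `nucleus` and `compartments` at that frame.
#' @export
interpolate_annotation <- function(ann, frame) {
  stopifnot(inherits(ann, "cell_annotation"))
  if (frame < 0 || frame > ann$n_frames - 1L)
    stop("frame out of range", call. = FALSE)
  f <- if (ann$n_frames == 1L) 0 else frame / (ann$n_frames - 1)
  lerp <- function(b, a)
    polygon_region((1 - f) * unclass(b) + f * unclass(a))
  list(nucleus = lerp(ann$nucleus_before, ann$nucleus_after),
       compartments = mapply(lerp, ann$compartments_before,
                             ann$compartments_after, SIMPLIFY = FALSE))
}

# containment flags for a block of localizations against one annotation
containment_flags <- function(frame, x, y, ann) {
  in_nuc <- logical(length(x))
  in_comp <- logical(length(x))
  for (f in unique(frame)) {
    i <- which(frame == f)
    polys <- interpolate_annotation(ann, min(f, ann$n_frames - 1L))
    in_nuc[i] <- in_region(x[i], y[i], polys$nucleus)
    inc <- rep(FALSE, length(i))
    for (cp in polys$compartments)
      inc <- inc | in_region(x[i], y[i], cp)
    in_comp[i] <- inc
  }
  list(nucleus = in_nuc, compartment = in_comp)
}

#' Sort trajectories by compartment
#'
#' Localizations outside the drift-interpolated nucleus are discarded;
#' a trajectory is labelled `"inside"` if at least one of its remaining
#' localizations falls inside any drift-interpolated compartment at its
#' own frame (a deliberately permissive rule that minimises sorting
#' bias), otherwise `"outside"`.
#'
#' @param trajs a [trajectories()] table.
#' @param anns list of [cell_annotation()]s named by `cell_id` (or a
#'   single annotation applied to all cells).
#' @return the trajectories with added logical column `in_compartment`
#'   (per localization) and character column `label` (per trajectory).
#' @export
assign_compartments <- function(trajs, anns) {
  df <- as.data.frame(trajs)
  if (inherits(anns, "cell_annotation")) {
    a <- anns
    anns <- stats::setNames(lapply(unique(df$cell_id), function(id) a),
                            unique(df$cell_id))
  }
  pieces <- lapply(split(df, df$cell_id), function(sub) {
    ann <- anns[[sub$cell_id[1L]]]
    if (is.null(ann))
      stop("no annotation for cell ", sub$cell_id[1L], call. = FALSE)
    fl <- containment_flags(sub$frame, sub$x, sub$y, ann)
    sub <- sub[fl$nucleus, , drop = FALSE]
    flc <- fl$compartment[fl$nucleus]
    sub$in_compartment <- flc
    inside_traj <- tapply(flc, sub$traj_id, any)
    sub$label <- ifelse(inside_traj[sub$traj_id], "inside", "outside")
    sub
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(out$cell_id, out$traj_id, out$frame), , drop = FALSE]
  attr(out, "max_gap") <- attr(trajs, "max_gap")
  class(out) <- c("trajectories", "data.frame")
  out
}

#' Place mock compartments in a nucleus
#'
#' The sorting-bias null control: real compartment outlines are drawn
#' from a library and dropped at uniform-random positions inside a
#' target nucleus by trial and error until every chosen outline fits
#' without overlapping the nuclear boundary, a nucleolus, previously
#' annotated compartments, or another mock.
#'
#' @param ann_library list of compartment [polygon_region()]s.
#' @param count_distribution integer vector: the empirical distribution
#'   of compartments per cell to draw the mock count from.
#' @param target a [cell_annotation()] providing nucleus, nucleoli and
#'   any existing compartments to avoid.
#' @param seed integer seed.
#' @param max_attempts placement attempts per mock before giving up.
#' @param rotate if `TRUE`, each mock is also rotated by a uniform
#'   random angle (off by default: outlines are translated only).
#' @return a [cell_annotation()] whose compartments are the placed
#'   mocks (before = after; existing compartments are replaced).
#' @export
place_mock_compartments <- function(ann_library, count_distribution,
                                    target, seed = NULL,
                                    max_attempts = 1000L,
                                    rotate = FALSE) {
  if (!length(ann_library)) stop("empty annotation library", call. = FALSE)
  stopifnot(inherits(target, "cell_annotation"))
  with_seed(seed, {
    n_mock <- sample(rep(count_distribution, 2L), 1L)
    avoid <- c(target$nucleoli, target$compartments_before)
    nuc <- target$nucleus_before
    placed <- list()
    for (m in seq_len(n_mock)) {
      src <- ann_library[[sample.int(length(ann_library), 1L)]]
      ctr <- region_centroid(src)
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        pos <- runif_in_region(1L, nuc)
        cand <- unclass(src)
        cand[, 1L] <- cand[, 1L] - ctr[1L]
        cand[, 2L] <- cand[, 2L] - ctr[2L]
        if (rotate) {
          th <- stats::runif(1L, 0, 2 * pi)
          cand <- cbind(cand[, 1L] * cos(th) - cand[, 2L] * sin(th),
                        cand[, 1L] * sin(th) + cand[, 2L] * cos(th))
        }
        cand[, 1L] <- cand[, 1L] + pos[1L]
        cand[, 2L] <- cand[, 2L] + pos[2L]
        cand <- polygon_region(cand)
        # fully inside: every vertex inside and no edge crossing
        if (!all(in_region(cand[, 1L], cand[, 2L], nuc))) next
        if (.edges_cross_cpp(cand[, 1L], cand[, 2L],
                             nuc[, 1L], nuc[, 2L])) next
        crosses <- FALSE
        for (other in c(avoid, placed))
          if (regions_overlap(cand, other)) { crosses <- TRUE; break }
        if (crosses) next
        placed[[length(placed) + 1L]] <- cand
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not place mock compartment ", m, " in cell ",
             target$cell_id, " after ", max_attempts, " attempts",
             call. = FALSE)
    }
    cell_annotation(cell_id = target$cell_id,
                    nucleus_before = target$nucleus_before,
                    nucleus_after = target$nucleus_after,
                    compartments_before = placed,
                    compartments_after = placed,
                    nucleoli = target$nucleoli,
                    n_frames = target$n_frames)
  })
}

#' Jump lengths crossing compartment boundaries
#'
#' Classifies every consecutive-frame displacement as "entering" (start
#' outside, end inside a compartment), "exiting" (the reverse), or
#' neither, using the per-localization containment flags from
#' [assign_compartments()].
#'
#' @param trajs labelled trajectories (with `in_compartment` column).
#' @return list with `entering` and `exiting` (numeric jump lengths,
#'   µm), empirical CDF functions `cdf_entering`/`cdf_exiting` (or
#'   `NULL` when empty), and `per_cell` (data.frame of per-cell mean
#'   jump lengths with SEM).
#' @export
boundary_crossing_jumps <- function(trajs) {
  df <- as.data.frame(trajs)
  if (!"in_compartment" %in% names(df))
    stop("run assign_compartments() first", call. = FALSE)
  key <- paste(df$cell_id, df$traj_id)
  n <- nrow(df)
  a <- seq_len(n - 1L); b <- a + 1L
  ok <- key[a] == key[b] & df$frame[b] - df$frame[a] == 1L
  jl <- sqrt((df$x[b] - df$x[a])^2 + (df$y[b] - df$y[a])^2)
  entering <- ok & !df$in_compartment[a] & df$in_compartment[b]
  exiting <- ok & df$in_compartment[a] & !df$in_compartment[b]
  if (!any(entering) && !any(exiting))
    warning("no boundary-crossing jumps found", call. = FALSE)
  cell <- df$cell_id[a]
  per_cell_stats <- function(sel) {
    if (!any(sel)) return(NULL)
    sp <- split(jl[sel], cell[sel])
    data.frame(cell_id = names(sp),
               mean = vapply(sp, mean, numeric(1)),
               sem = vapply(sp, function(v)
                 stats::sd(v) / sqrt(length(v)), numeric(1)),
               n = vapply(sp, length, integer(1)), row.names = NULL)
  }
  list(entering = jl[entering], exiting = jl[exiting],
       cdf_entering = if (any(entering)) stats::ecdf(jl[entering]),
       cdf_exiting = if (any(exiting)) stats::ecdf(jl[exiting]),
       per_cell = list(entering = per_cell_stats(entering),
                       exiting = per_cell_stats(exiting)))
}
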