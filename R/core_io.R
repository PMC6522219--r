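#' Localization table constructor
#'
#' Validates a table of single-molecule detections. Internal coordinates
#' are always micrometres, 2-D, origin at the image top-left with y
#' increasing downward; frames are 0-based.
#'
#' @param x,y coordinates in µm.
#' @param frame non-negative integer frame index (0-based).
#' @param cell_id cell identifier (coerced to character).
#' @param channel optional channel identifier.
#' @return a `data.frame` of class `localizations` with columns
#'   `x`, `y`, `frame`, `cell_id` (and `channel` when given).
#' @export
localizations <- function(x, y, frame, cell_id, channel = NULL) {
  x <- as.double(x); y <- as.double(y)
  frame <- as.integer(frame)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("localization coordinates must be finite", call. = FALSE)
  bad <- which(is.na(frame) | frame < 0L)
  if (length(bad))
    stop("negative or missing frame index at row ", bad[1L], call. = FALSE)
  df <- data.frame(x = x, y = y, frame = frame,
                   cell_id = as.character(cell_id),
                   stringsAsFactors = FALSE)
  if (!is.null(channel)) df$channel <- as.character(channel)
  class(df) <- c("localizations", "data.frame")
  df
}

#' Read a localization table
#'
#' Reads a delimited text table of detections and converts pixel
#' coordinates to micrometres. The camera pixel size is deliberately a
#' required argument: it is instrument metadata that the coordinate
#' convention depends on, and no default could be safe.
#'
#' @param path CSV file path.
#' @param pixel_size pixel size in µm; coordinates in the file are
#'   multiplied by this factor. Use `1` if the file is already in µm.
#' @param columns named list mapping the required fields `x`, `y`,
#'   `frame`, `cell_id` (and optionally `channel`) to column names in
#'   the file.
#' @return a [localizations()] table, ordered as in the file.
#' @export
read_localizations <- function(path, pixel_size,
                               columns = list(x = "x", y = "y",
                                              frame = "frame",
                                              cell_id = "cell_id")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (missing(pixel_size) || !is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size (um) is required and must be > 0", call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "frame", "cell_id")
  for (f in need) {
    cn <- columns[[f]]
    if (is.null(cn) || !cn %in% names(raw))
      stop("missing mapped column for '", f, "'", call. = FALSE)
  }
  if (nrow(raw) == 0L)
    return(localizations(numeric(0), numeric(0), integer(0), character(0)))
  num <- function(field) {
    v <- raw[[columns[[field]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad))
      stop("non-numeric ", field, " at row ", bad[1L], call. = FALSE)
    out
  }
  fr <- num("frame")
  bad <- which(is.na(fr) | fr < 0)
  if (length(bad))
    stop("invalid frame index at row ", bad[1L], call. = FALSE)
  ch <- if (!is.null(columns$channel)) raw[[columns$channel]] else NULL
  localizations(num("x") * pixel_size, num("y") * pixel_size,
                fr, raw[[columns$cell_id]], channel = ch)
}

#' Trajectory table constructor
#'
#' A trajectory is an ordered run of localizations sharing `traj_id`
#' and `cell_id` with strictly increasing frames; frame increments of up
#' to `1 + max_gap` are allowed (a gap is a missed detection).
#'
#' @param df data.frame with columns `traj_id`, `cell_id`, `frame`,
#'   `x`, `y` (µm).
#' @param max_gap maximum number of missing frames inside a trajectory
#'   (`Inf` to skip the gap check, e.g. after nuclear masking has
#'   removed localizations).
#' @return a `data.frame` of class `trajectories`, sorted by
#'   `cell_id`, `traj_id`, `frame`, with `max_gap` kept as an attribute.
#' @export
trajectories <- function(df, max_gap = 1L) {
  need <- c("traj_id", "cell_id", "frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing trajectory columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  df$traj_id <- as.character(df$traj_id)
  df$cell_id <- as.character(df$cell_id)
  df$frame <- as.integer(df$frame)
  df$x <- as.double(df$x); df$y <- as.double(df$y)
  df <- df[order(df$cell_id, df$traj_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df)) {
    if (any(!is.finite(df$x)) || any(!is.finite(df$y)) || any(df$frame < 0L))
      stop("invalid trajectory coordinates or frames", call. = FALSE)
    key <- paste(df$cell_id, df$traj_id)
    d <- diff(df$frame)
    same <- key[-1L] == key[-length(key)]
    if (any(same & d < 1L))
      stop("frames must strictly increase within a trajectory",
           call. = FALSE)
    if (any(same & d > 1L + max_gap))
      stop("frame gap exceeds max_gap within a trajectory", call. = FALSE)
  }
  attr(df, "max_gap") <- as.numeric(max_gap)
  class(df) <- c("trajectories", "data.frame")
  df
}

#' Write trajectories to CSV
#'
#' One row per localization with columns `traj_id`, `cell_id`, `frame`,
#' `x_um`, `y_um`. Coordinates are written with enough digits that a
#' round trip reproduces them to well below 1e-9 µm.
#'
#' @param trajs a [trajectories()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  out <- data.frame(traj_id = trajs$traj_id, cell_id = trajs$cell_id,
                    frame = trajs$frame,
                    x_um = sprintf("%.12g", trajs$x),
                    y_um = sprintf("%.12g", trajs$y))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#' @param path file written by [write_trajectories()].
#' @param max_gap maximum in-trajectory frame gap to validate against.
#' @return a [trajectories()] table.
#' @export
read_trajectories <- function(path, max_gap = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(traj_id = "character",
                                        cell_id = "character"))
  if (nrow(raw) == 0L)
    return(trajectories(data.frame(traj_id = character(0),
                                   cell_id = character(0),
                                   frame = integer(0),
                                   x = numeric(0), y = numeric(0)),
                        max_gap = max_gap))
  trajectories(data.frame(traj_id = raw$traj_id, cell_id = raw$cell_id,
                          frame = raw$frame, x = raw$x_um, y = raw$y_um),
               max_gap = max_gap)
}

#' Cell annotation
#'
#' Nucleus, replication-compartment and nucleolus polygons for one cell,
#' each drawn on the "before" and "after" reference images of the
#' movie. Before/after partners must have the same vertex count so that
#' per-frame positions can be linearly interpolated (drift correction).
#'
#' @param cell_id cell identifier.
#' @param nucleus_before,nucleus_after nucleus [polygon_region()]s.
#' @param compartments_before,compartments_after equal-length lists of
#'   [polygon_region()]s (may be empty).
#' @param nucleoli list of [polygon_region()]s.
#' @param n_frames number of movie frames the annotation spans.
#' @return object of class `cell_annotation`.
#' @export
cell_annotation <- function(cell_id, nucleus_before, nucleus_after = NULL,
                            compartments_before = list(),
                            compartments_after = NULL,
                            nucleoli = list(), n_frames = 1L) {
  if (is.null(nucleus_after)) nucleus_after <- nucleus_before
  if (is.null(compartments_after)) compartments_after <- compartments_before
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (length(compartments_before) != length(compartments_after))
    stop("before/after compartment lists differ in length", call. = FALSE)
  if (nrow(nucleus_before) != nrow(nucleus_after))
    stop("nucleus before/after vertex counts differ", call. = FALSE)
  for (i in seq_along(compartments_before)) {
    if (nrow(compartments_before[[i]]) != nrow(compartments_after[[i]]))
      stop("compartment ", i, " before/after vertex counts differ",
           call. = FALSE)
  }
  structure(list(cell_id = as.character(cell_id),
                 nucleus_before = nucleus_before,
                 nucleus_after = nucleus_after,
                 compartments_before = compartments_before,
                 compartments_after = compartments_after,
                 nucleoli = nucleoli,
                 n_frames = n_frames),
            class = "cell_annotation")
}

#' Read cell annotations from polygon JSON
#'
#' The annotation file is a JSON array of cells; each cell has
#' `cell_id`, `n_frames`, a `nucleus` object with `before`/`after`
#' vertex arrays, a `compartments` array of objects with
#' `before`/`after`, and an optional `nucleoli` array of vertex arrays.
#' Vertex arrays are Nx2 (µm). See the bundled example under
#' `inst/extdata`.
#'
#' @param path JSON file path.
#' @return list of [cell_annotation()] objects, named by cell id.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(js, function(cell) {
    poly <- function(v) polygon_region(do.call(rbind, lapply(v, unlist)))
    comps <- cell$compartments
    if (is.null(comps)) comps <- list()
    nuc_b <- poly(cell$nucleus$before)
    nuc_a <- if (is.null(cell$nucleus$after)) nuc_b else
      poly(cell$nucleus$after)
    cell_annotation(
      cell_id = cell$cell_id,
      nucleus_before = nuc_b, nucleus_after = nuc_a,
      compartments_before = lapply(comps, function(cp) poly(cp$before)),
      compartments_after = lapply(comps, function(cp)
        if (is.null(cp$after)) poly(cp$before) else poly(cp$after)),
      nucleoli = lapply(cell$nucleoli, poly),
      n_frames = if (is.null(cell$n_frames)) 1L else cell$n_frames)
  })
  names(out) <- vapply(out, function(a) a$cell_id, character(1))
  out
}

#' Write cell annotations to polygon JSON
#' @param anns list of [cell_annotation()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(anns, path) {
  enc <- lapply(anns, function(a) {
    vj <- function(p) apply(unclass(p), 1L, as.list)
    list(cell_id = a$cell_id, n_frames = a$n_frames,
         nucleus = list(before = vj(a$nucleus_before),
                        after = vj(a$nucleus_after)),
         compartments = mapply(function(b, af)
           list(before = vj(b), after = vj(af)),
           a$compartments_before, a$compartments_after,
           SIMPLIFY = FALSE),
         nucleoli = lapply(a$nucleoli, vj))
  })
  jsonlite::write_json(unname(enc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a labelled mask TIFF as polygons
#'
#' Reads a labelled 16-bit mask image (0 = background, 1 = nucleus,
#' labels >= 2 = compartments) and traces each label's outline into a
#' polygon at pixel resolution, scaled by `pixel_size`. Requires the
#' `tiff` package.
#'
#' @param path TIFF path.
#' @param pixel_size µm per pixel.
#' @return list with `nucleus` ([polygon_region()]) and `compartments`
#'   (list of polygons), in image coordinates (µm, y downward).
#' @export
read_mask_tiff <- function(path, pixel_size) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for mask images", call. = FALSE)
  if (missing(pixel_size) || pixel_size <= 0)
    stop("pixel_size (um) is required and must be > 0", call. = FALSE)
  img <- tiff::readTIFF(path, as.is = TRUE)
  labs <- sort(setdiff(unique(as.vector(img)), 0L))
  polys <- lapply(labs, function(l) trace_mask_outline(img == l, pixel_size))
  names(polys) <- labs
  list(nucleus = polys[["1"]],
       compartments = unname(polys[setdiff(names(polys), "1")]))
}

# Marching-squares boundary walk around a logical mask (single connected
# component assumed); returns a polygon through pixel-edge midpoints.
trace_mask_outline <- function(mask, pixel_size) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  # corner lattice: value at (i, j) summarises the 2x2 pixel block
  idx <- which(pad, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask label", call. = FALSE)
  start <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE][1L, ]
  # walk clockwise keeping mask pixels on the right
  dirs <- list(c(-1L, 0L), c(0L, 1L), c(1L, 0L), c(0L, -1L))
  pos <- c(start[1L] - 1L, start[2L] - 1L)  # corner above-left of start
  d <- 2L  # heading right
  path <- list()
  repeat {
    path[[length(path) + 1L]] <- pos
    # pixels left/right of the heading at this corner
    probe <- function(di, dj) {
      i <- pos[1L] + di; j <- pos[2L] + dj
      i >= 1L && j >= 1L && i <= nr + 2L && j <= nc + 2L && pad[i, j]
    }
    fwd <- dirs[[d]]
    lf <- switch(d, probe(0L, 0L), probe(0L, 1L), probe(1L, 1L),
                 probe(1L, 0L))
    rt <- switch(d, probe(0L, 1L), probe(1L, 1L), probe(1L, 0L),
                 probe(0L, 0L))
    if (lf) d <- (d - 2L) %% 4L + 1L         # turn left
    else if (!rt) d <- d %% 4L + 1L          # turn right
    pos <- pos + dirs[[d]]
    if (all(pos == path[[1L]]) && length(path) > 2L) break
    if (length(path) > 4L * (nr + 2L) * (nc + 2L))
      stop("mask outline tracing failed", call. = FALSE)
  }
  pm <- do.call(rbind, path)
  # corners are between pixels: convert to image coordinates (x = col,
  # y = row), 0-based pixel centres, then to um
  polygon_region(cbind((pm[, 2L] - 1.5) * pixel_size,
                       (pm[, 1L] - 1.5) * pixel_size))
}

#' Intensity trace constructor (FRAP/FLIP)
#'
#' @param spot_raw per-frame raw intensity of the measurement spot.
#' @param reference_raw per-frame raw intensity of the reference
#'   (whole nucleus for FRAP; may be `NA` for FLIP).
#' @param bleach_frame 0-based index of the first post-bleach frame.
#' @param frame_interval seconds per frame.
#' @return a `data.frame` of class `intensity_trace` with a `frame`
#'   column contiguous from 0.
#' @export
intensity_trace <- function(spot_raw, reference_raw = NA_real_,
                            bleach_frame = 15L, frame_interval = 0.25) {
  n <- length(spot_raw)
  if (any(spot_raw < 0, na.rm = TRUE))
    stop("spot intensities must be >= 0", call. = FALSE)
  df <- data.frame(frame = seq_len(n) - 1L,
                   spot_raw = as.double(spot_raw),
                   reference_raw = rep_len(as.double(reference_raw), n))
  attr(df, "bleach_frame") <- as.integer(bleach_frame)
  attr(df, "frame_interval") <- as.double(frame_interval)
  class(df) <- c("intensity_trace", "data.frame")
  df
}

#' Read an intensity trace CSV
#'
#' Expects columns `frame`, `spot`, and optionally `reference`.
#' @param path CSV path.
#' @param bleach_frame,frame_interval see [intensity_trace()].
#' @return an [intensity_trace()].
#' @export
read_intensity_trace <- function(path, bleach_frame = 15L,
                                 frame_interval = 0.25) {
  raw <- utils::read.csv(path)
  if (!all(c("frame", "spot") %in% names(raw)))
    stop("trace file needs 'frame' and 'spot' columns", call. = FALSE)
  raw <- raw[order(raw$frame), ]
  if (!identical(as.integer(raw$frame), seq_len(nrow(raw)) - 1L))
    stop("trace frames must be contiguous from 0", call. = FALSE)
  intensity_trace(raw$spot,
                  if ("reference" %in% names(raw)) raw$reference else NA,
                  bleach_frame = bleach_frame,
                  frame_interval = frame_interval)
}

#' Disorder profile constructor
#' @param sequence_id identifier.
#' @param scores per-residue disorder likelihoods in \[0, 1\].
#' @return object of class `disorder_profile`.
#' @export
disorder_profile <- function(sequence_id, scores) {
  scores <- as.double(scores)
  if (any(is.na(scores)) || any(scores < 0) || any(scores > 1))
    stop("disorder scores must lie in [0, 1]", call. = FALSE)
  structure(list(sequence_id = as.character(sequence_id),
                 scores = scores, length = length(scores)),
            class = "disorder_profile")
}

#' Read per-residue disorder scores
#'
#' Two-column TSV (residue index, score), one file per protein, the
#' layout written by the IUPred predictor. Lines starting with `#` are
#' skipped.
#'
#' @param path TSV path.
#' @param sequence_id identifier; defaults to the file name.
#' @return a [disorder_profile()].
#' @export
read_disorder_scores <- function(path, sequence_id = NULL) {
  if (is.null(sequence_id))
    sequence_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#")
  raw <- raw[order(raw[[1L]]), ]
  if (!identical(as.integer(raw[[1L]]), seq_len(nrow(raw))))
    stop("residue indices must be contiguous from 1", call. = FALSE)
  disorder_profile(sequence_id, raw[[2L]])
}
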