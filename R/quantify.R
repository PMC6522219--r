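#' Estimate genome copy numbers from FISH intensities
#'
#' The replication-inhibited (PAA) condition pins the intensity of a
#' single viral genome: each compartment's copy number is its
#' background-subtracted integrated intensity divided by the median
#' PAA intensity. Scale-invariant by construction.
#'
#' @param measurements a data.frame with columns `rc_id`, `condition`,
#'   `integrated_intensity` (e.g. from [simulate_fish_intensities()]).
#' @param paa_condition name of the calibration condition.
#' @return list with `per_rc` (the table plus `copy_number`) and
#'   `medians` (per-condition median copy numbers; PAA is exactly 1).
#' @export
estimate_copy_number <- function(measurements, paa_condition = "PAA") {
  if (!paa_condition %in% measurements$condition)
    stop("calibration condition '", paa_condition, "' missing",
         call. = FALSE)
  ref <- stats::median(
    measurements$integrated_intensity[measurements$condition ==
                                        paa_condition])
  if (ref <= 0) stop("non-positive PAA median intensity", call. = FALSE)
  per_rc <- measurements
  per_rc$copy_number <- per_rc$integrated_intensity / ref
  med <- tapply(per_rc$copy_number, per_rc$condition, stats::median)
  list(per_rc = per_rc,
       medians = data.frame(condition = names(med),
                            median_copy_number = as.numeric(med),
                            row.names = NULL))
}

#' Genome budget of an infected nucleus
#'
#' The bookkeeping that compares viral and host DNA content: total
#' viral base pairs from the genome copy number, the viral share of
#' total nuclear DNA, host and viral DNA concentrations, and (when an
#' accessibility read percentage is supplied) the fold enrichment of
#' accessibility over DNA share. The host content is fixed at the
#' diploid value (2 x 3.2e9 bp) by convention, making the viral
#' fractions an upper bound for hyperploid lines.
#'
#' @param copy_number viral genome copies in the nucleus.
#' @param nucleus_volume nuclear volume (µm³).
#' @param rc_volume total replication-compartment volume (µm³).
#' @param atac_viral_read_pct percentage of ATAC-seq reads mapping to
#'   the virus (optional).
#' @param viral_genome_bp viral genome size (bp; default 1.5e5).
#' @param host_genome_bp haploid host genome size (bp; default 3.2e9).
#' @param ploidy host genome copies (default 2).
#' @return object of class `genome_budget` (a list of the quantities;
#'   full precision — round only for presentation).
#' @export
genome_budget <- function(copy_number, nucleus_volume, rc_volume,
                          atac_viral_read_pct = NULL,
                          viral_genome_bp = 1.5e5,
                          host_genome_bp = 3.2e9, ploidy = 2) {
  stopifnot(copy_number >= 0, nucleus_volume > 0, rc_volume > 0,
            viral_genome_bp > 0, host_genome_bp > 0)
  total_host <- host_genome_bp * ploidy
  total_viral <- copy_number * viral_genome_bp
  percent_viral <- 100 * total_viral / (total_host + total_viral)
  out <- list(
    host_genome_bp = host_genome_bp, ploidy = ploidy,
    viral_genome_bp = viral_genome_bp, copy_number = copy_number,
    genome_size_ratio = host_genome_bp / viral_genome_bp,
    total_host_bp = total_host, total_viral_bp = total_viral,
    percent_viral = percent_viral,
    percent_host = 100 - percent_viral,
    host_conc = total_host / nucleus_volume,
    viral_conc = total_viral / rc_volume,
    conc_ratio = (total_host / nucleus_volume) /
      (total_viral / rc_volume),
    atac_viral_read_pct = atac_viral_read_pct,
    fold_enrichment = if (!is.null(atac_viral_read_pct)) {
      if (percent_viral == 0) NA_real_
      else atac_viral_read_pct / percent_viral
    })
  if (copy_number == 0)
    out$fold_enrichment <- NA_real_
  class(out) <- "genome_budget"
  out
}

#' @export
print.genome_budget <- function(x, ...) {
  sig2 <- function(v) signif(v, 2)
  cat("Genome budget (2 significant figures for presentation)\n")
  cat(sprintf("  host total      %.2g bp; viral total %.2g bp (%g copies)\n",
              x$total_host_bp, x$total_viral_bp, x$copy_number))
  cat(sprintf("  viral %% of DNA  %.2g%%\n", sig2(x$percent_viral)))
  cat(sprintf("  conc host/viral %.2g / %.2g bp/um^3 (ratio %.2g)\n",
              sig2(x$host_conc), sig2(x$viral_conc), sig2(x$conc_ratio)))
  if (!is.null(x$atac_viral_read_pct))
    cat(sprintf("  ATAC %% viral    %.3g -> fold enrichment %.2g\n",
                x$atac_viral_read_pct, sig2(x$fold_enrichment)))
  invisible(x)
}

#' Accessibility fold enrichment
#'
#' Ratio of the viral ATAC-seq read percentage to the viral percentage
#' of total DNA — how much more accessible the viral genome is than
#' expected from its abundance.
#'
#' @param viral_read_pct percentage of reads mapping to the virus.
#' @param percent_viral viral percentage of total DNA (> 0).
#' @return the fold enrichment.
#' @export
atac_enrichment <- function(viral_read_pct, percent_viral) {
  if (percent_viral <= 0)
    stop("percent_viral must be > 0", call. = FALSE)
  viral_read_pct / percent_viral
}

#' Estimate multiplicity of infection
#'
#' Under a Poisson model of infection events per cell,
#' `P(k) = MOI^k e^(-MOI) / k!`, the fraction of uninfected cells
#' determines the MOI: `MOI = -ln(f_uninfected)`.
#'
#' @param n_uninfected number of uninfected cells (> 0; a zero count
#'   gives an unbounded estimate — score more cells).
#' @param n_total total cells scored.
#' @return object of class `moi_estimate`: list with `f_uninfected`,
#'   `moi`, and `pmf(k)` (the fitted Poisson pmf).
#' @export
estimate_moi <- function(n_uninfected, n_total) {
  if (n_uninfected <= 0)
    stop("no uninfected cells: MOI unbounded; score more cells or ",
         "dilute further", call. = FALSE)
  if (n_uninfected > n_total)
    stop("n_uninfected exceeds n_total", call. = FALSE)
  f <- n_uninfected / n_total
  moi <- -log(f)
  structure(list(f_uninfected = f, moi = moi,
                 pmf = function(k) stats::dpois(k, moi)),
            class = "moi_estimate")
}

#' Feret-diameter aspect ratio of a region
#'
#' Ratio of the maximal to the minimal Feret (caliper) diameter of the
#' polygon — 1 for a circle, larger for elongated shapes. Computed on
#' the convex hull: the maximum caliper is the largest vertex-pair
#' distance; the minimum is the smallest width across the hull over
#' the edge-normal directions (rotating calipers).
#'
#' @param region a [polygon_region()].
#' @return list with `aspect_ratio`, `max_feret`, `min_feret` (µm).
#' @export
shape_metrics <- function(region) {
  v <- unclass(region)
  h <- grDevices::chull(v)
  hv <- v[h, , drop = FALSE]
  m <- nrow(hv)
  if (m < 3L) stop("degenerate polygon", call. = FALSE)
  d <- as.matrix(stats::dist(hv))
  max_f <- max(d)
  # min width over hull edge directions
  min_f <- Inf
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- hv[j, ] - hv[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2L], e[1L]) / len
    proj <- hv %*% nrm
    min_f <- min(min_f, max(proj) - min(proj))
  }
  if (!is.finite(min_f) || min_f <= 0)
    stop("degenerate polygon", call. = FALSE)
  list(aspect_ratio = max_f / min_f, max_feret = max_f,
       min_feret = min_f)
}
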