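#' Parameters for super-enhancer calling
#'
#' Defaults follow the standard ROSE-style recipe: peaks fully inside a
#' TSS +/- 2 kb window are excluded, enhancers within 12.5 kb of each other
#' are stitched, and the cutoff is the slope-1 tangent of the min-max scaled
#' rank/signal curve.
#'
#' @param tss_exclusion_radius bases around each TSS (default 2000).
#' @param stitch_gap maximum gap (bases) joining two enhancers (default
#'   12500, inclusive: a gap of exactly `stitch_gap` stitches).
#' @param min_points_for_cutoff minimum number of stitched enhancers required
#'   to place a tangent (default 3).
#' @return A list of class `se_call_params`.
#' @export
se_call_params <- function(tss_exclusion_radius = 2000,
                           stitch_gap = 12500,
                           min_points_for_cutoff = 3) {
  stopifnot(tss_exclusion_radius > 0, stitch_gap > 0, min_points_for_cutoff > 0)
  structure(list(tss_exclusion_radius = tss_exclusion_radius,
                 stitch_gap = stitch_gap,
                 min_points_for_cutoff = min_points_for_cutoff),
            class = "se_call_params")
}

#' Remove TSS-proximal peaks
#'
#' Drops every peak whose entire span lies within some window
#' `[tss - radius, tss + radius + 1)`; all other peaks are kept in their
#' input order. Peaks on chromosomes without genes are always kept.
#'
#' @param peaks peak data.frame (see [validate_peaks()]).
#' @param annotation a [genome_annotation()].
#' @param radius window half-width in bases (default 2000).
#' @return The filtered peak data.frame.
#' @export
filter_tss_proximal <- function(peaks, annotation, radius = 2000) {
  stopifnot(radius > 0)
  validate_peaks(peaks)
  tss <- gene_tss(annotation)
  if (nrow(tss) == 0L) {
    warning("empty annotation: no TSS-proximal filtering applied")
    return(peaks)
  }
  drop <- logical(nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    t <- sort(tss$tss[tss$chrom == chr])
    if (length(t) == 0L) next
    i <- which(peaks$chrom == chr)
    # peak [s,e) is inside [tss-r, tss+r+1) iff some tss in [e-r-1, s+r]
    lo <- peaks$end[i] - radius - 1
    hi <- peaks$start[i] + radius
    n_le_hi <- findInterval(hi, t)
    n_lt_lo <- findInterval(lo - 0.5, t)
    drop[i] <- hi >= lo & (n_le_hi - n_lt_lo) > 0
  }
  peaks[!drop, , drop = FALSE]
}

#' Stitch peaks into candidate enhancers
#'
#' Per chromosome, peaks are merged into maximal chains in which each
#' adjacent pair (ordered by start) is separated by at most `stitch_gap`
#' bases; this equals the connected components of the graph joining any two
#' peaks with gap <= `stitch_gap`. The stitch is inclusive: a gap of exactly
#' `stitch_gap` joins.
#'
#' @param peaks peak data.frame.
#' @param stitch_gap maximum joining gap in bases (default 12500).
#' @return data.frame of stitched enhancers: `se_id`, `chrom`, `start`,
#'   `end`, `n_peaks`, `total_signal`, `members` (comma-joined member peak
#'   names, in start order), sorted by `(chrom, start)`.
#' @export
stitch_peaks <- function(peaks, stitch_gap = 12500) {
  stopifnot(stitch_gap > 0)
  validate_peaks(peaks)
  if (nrow(peaks) == 0L)
    return(data.frame(se_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), n_peaks = integer(),
                      total_signal = numeric(), members = character(),
                      stringsAsFactors = FALSE))
  o <- order(peaks$chrom, peaks$start, peaks$end)
  p <- peaks[o, , drop = FALSE]
  run_end <- cummax_by_chrom(p$chrom, p$end)
  new_chain <- c(TRUE,
                 p$chrom[-1] != p$chrom[-nrow(p)] |
                   p$start[-1] - run_end[-nrow(p)] > stitch_gap)
  grp <- cumsum(new_chain)
  out <- do.call(rbind, lapply(split(seq_len(nrow(p)), grp), function(i) {
    data.frame(chrom = p$chrom[i[1]],
               start = min(p$start[i]), end = max(p$end[i]),
               n_peaks = length(i), total_signal = sum(p$signal[i]),
               members = paste(p$name[i], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(se_id = sprintf("SE_%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# running max of val within runs of identical chrom (chrom-sorted input)
cummax_by_chrom <- function(chrom, val) {
  unlist(lapply(split(val, factor(chrom, levels = unique(chrom))), cummax),
         use.names = FALSE)
}

#' Rank stitched enhancers and min-max scale the curve
#'
#' Enhancers are sorted by ascending total signal (ties broken by
#' `(chrom, start)` for determinism); rank 1 is the lowest signal.
#' `scaled_x = (rank - 1)/(n - 1)` and
#' `scaled_y = (signal - min)/(max - min)`. When all signals are equal (or
#' `n = 1`) the curve is degenerate: `scaled_y` is all 0 and the
#' `degenerate` attribute is set.
#'
#' @param enhancers data.frame from [stitch_peaks()] (any data.frame with
#'   `chrom`, `start` and `total_signal` works).
#' @return The enhancers sorted by rank with columns `rank`, `scaled_x`,
#'   `scaled_y` added and a logical attribute `degenerate`.
#' @export
rank_and_scale <- function(enhancers) {
  n <- nrow(enhancers)
  if (n == 0L) stop("cannot rank an empty enhancer set")
  e <- enhancers[order(enhancers$total_signal, enhancers$chrom, enhancers$start), ,
                 drop = FALSE]
  rownames(e) <- NULL
  e$rank <- seq_len(n)
  e$scaled_x <- if (n == 1L) 0 else (e$rank - 1) / (n - 1)
  rng <- e$total_signal[n] - e$total_signal[1]
  degenerate <- n == 1L || rng == 0
  e$scaled_y <- if (degenerate) rep(0, n) else
    (e$total_signal - e$total_signal[1]) / rng
  attr(e, "degenerate") <- degenerate
  e
}

#' Slope-1 tangent cutoff of the ranked enhancer curve
#'
#' On the min-max scaled curve the tangency point is the point minimizing
#' `scaled_y - scaled_x`; for a convex non-decreasing curve this is where the
#' slope-1 line supports the curve from below. Ties are resolved toward the
#' point with the greatest `scaled_y` (fewer super-enhancers). The cutoff
#' signal is the tangency point's unscaled total signal; super-enhancers are
#' the enhancers strictly above it.
#'
#' @param curve output of [rank_and_scale()].
#' @param min_points_for_cutoff minimum curve size (default 3).
#' @return list with `cutoff_signal`, `tangency_rank` and `no_ses` (TRUE when
#'   the curve was degenerate or too small, in which case `cutoff_signal` is
#'   `Inf` and a warning is raised).
#' @export
tangent_cutoff <- function(curve, min_points_for_cutoff = 3) {
  n <- nrow(curve)
  if (isTRUE(attr(curve, "degenerate")) || n < min_points_for_cutoff) {
    warning("degenerate or too-small curve: no super-enhancers called")
    return(list(cutoff_signal = Inf, tangency_rank = NA_integer_,
                no_ses = TRUE))
  }
  d <- curve$scaled_y - curve$scaled_x
  ties <- which(d <= min(d) + 1e-12)
  idx <- ties[which.max(curve$scaled_y[ties])]
  list(cutoff_signal = curve$total_signal[idx],
       tangency_rank = curve$rank[idx], no_ses = FALSE)
}

#' Call super-enhancers from H3K27ac peaks
#'
#' The full recipe: TSS-proximal exclusion, stitching within `stitch_gap`,
#' rank ordering by total signal, min-max scaling, slope-1 tangent cutoff.
#' An enhancer is a super-enhancer iff its total signal is strictly greater
#' than the cutoff signal (the tangency enhancer itself is typical).
#'
#' @param peaks peak data.frame.
#' @param annotation a [genome_annotation()].
#' @param params a [se_call_params()].
#' @return An object of class `se_call`: list with `enhancers` (ranked
#'   data.frame carrying `rank`, `scaled_x`, `scaled_y`, `is_super`),
#'   `cutoff_signal`, `tangency_rank`, `degenerate`, `n_input_peaks`,
#'   `n_filtered_peaks` and `params`.
#' @examples
#' ann <- genome_annotation(data.frame(gene_id = "g1", chrom = "chr1",
#'                                     strand = "+", start = 0, end = 1000))
#' peaks <- data.frame(chrom = "chr1", start = (1:20) * 50000,
#'                     end = (1:20) * 50000 + 1000,
#'                     name = paste0("p", 1:20), signal = c(rep(10, 19), 500))
#' res <- call_superenhancers(peaks, ann)
#' sum(res$enhancers$is_super)
#' @export
call_superenhancers <- function(peaks, annotation, params = se_call_params()) {
  stopifnot(inherits(params, "se_call_params"))
  kept <- filter_tss_proximal(peaks, annotation, params$tss_exclusion_radius)
  if (nrow(kept) == 0L) {
    warning("no peaks left after TSS-proximal filtering")
    enhancers <- stitch_peaks(kept, params$stitch_gap)
    enhancers$rank <- integer(0); enhancers$scaled_x <- numeric(0)
    enhancers$scaled_y <- numeric(0); enhancers$is_super <- logical(0)
    return(structure(list(enhancers = enhancers, cutoff_signal = Inf,
                          tangency_rank = NA_integer_, degenerate = TRUE,
                          n_input_peaks = nrow(peaks), n_filtered_peaks = nrow(peaks),
                          params = params),
                     class = "se_call"))
  }
  stitched <- stitch_peaks(kept, params$stitch_gap)
  curve <- rank_and_scale(stitched)
  cut <- tangent_cutoff(curve, params$min_points_for_cutoff)
  curve$is_super <- curve$total_signal > cut$cutoff_signal
  structure(list(enhancers = curve,
                 cutoff_signal = cut$cutoff_signal,
                 tangency_rank = cut$tangency_rank,
                 degenerate = isTRUE(attr(curve, "degenerate")),
                 n_input_peaks = nrow(peaks),
                 n_filtered_peaks = nrow(peaks) - nrow(kept),
                 params = params),
            class = "se_call")
}

#' @export
print.se_call <- function(x, ...) {
  n <- nrow(x$enhancers)
  cat("se_call:", n, "stitched enhancers (",
      sum(x$enhancers$is_super), "super,", sum(!x$enhancers$is_super),
      "typical )\n")
  cat("  input peaks:", x$n_input_peaks,
      "| TSS-proximal removed:", x$n_filtered_peaks, "\n")
  cat("  cutoff signal:", format(x$cutoff_signal),
      "at rank", x$tangency_rank, "\n")
  invisible(x)
}

#' Write the outputs of a super-enhancer call
#'
#' Emits a BED-like table of stitched enhancers
#' (`chrom, start, end, se_id, total_signal, is_super`) and a TSV of the
#' ranked curve (`rank, scaled_x, scaled_y, signal`).
#'
#' @param result an `se_call` object.
#' @param bed_path,curve_path output paths (either may be `NULL` to skip).
#' @return `result`, invisibly.
#' @export
write_se_call <- function(result, bed_path = NULL, curve_path = NULL) {
  stopifnot(inherits(result, "se_call"))
  e <- result$enhancers
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = e$chrom, start = e$start, end = e$end,
                      name = e$se_id, signal = e$total_signal,
                      is_super = as.integer(e$is_super))
    write_bed(bed, bed_path)
  }
  if (!is.null(curve_path))
    write_table(data.frame(rank = e$rank, scaled_x = e$scaled_x,
                           scaled_y = e$scaled_y, signal = e$total_signal,
                           is_super = e$is_super), curve_path)
  invisible(result)
}
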