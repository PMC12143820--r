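feature_classes <- c("promoter", "exon", "intron", "distal_intergenic")

#' Classify peaks into genomic feature classes
#'
#' Each peak is represented by a single point — its summit when present,
#' otherwise its midpoint — so the classes are exhaustive and mutually
#' exclusive. Precedence: promoter (point within some
#' `[tss - radius, tss + radius + 1)` window) > exon > intron (inside a gene
#' span but not in an exon or promoter window) > distal intergenic.
#'
#' @param peaks peak data.frame.
#' @param annotation a [genome_annotation()].
#' @param promoter_radius promoter window half-width in bases (default 2000,
#'   matching the TSS exclusion radius used in SE calling).
#' @return Factor with levels `promoter`, `exon`, `intron`,
#'   `distal_intergenic`, one per peak.
#' @export
classify_peaks <- function(peaks, annotation, promoter_radius = 2000) {
  stopifnot(inherits(annotation, "genome_annotation"), promoter_radius > 0)
  validate_peaks(peaks)
  point <- peak_midpoint(peaks)
  cls <- rep("distal_intergenic", nrow(peaks))
  genes <- annotation$genes
  exons <- annotation$exons
  for (chr in unique(peaks$chrom)) {
    i <- which(peaks$chrom == chr)
    p <- point[i]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0L) next
    in_span <- point_in_any(p, g$start, g$end)
    ex <- exons[exons$chrom == chr, , drop = FALSE]
    in_exon <- if (nrow(ex)) point_in_any(p, ex$start, ex$end) else
      rep(FALSE, length(p))
    in_prom <- point_in_any(p, g$tss - promoter_radius,
                            g$tss + promoter_radius + 1)
    cls[i] <- ifelse(in_prom, "promoter",
              ifelse(in_exon, "exon",
              ifelse(in_span, "intron", "distal_intergenic")))
  }
  factor(cls, levels = feature_classes)
}

# is each point contained in any of the (possibly overlapping) [start,end)?
point_in_any <- function(points, starts, ends) {
  red <- IRanges::reduce(IRanges::IRanges(start = starts + 1, end = ends))
  s <- IRanges::start(red) - 1
  e <- IRanges::end(red)
  idx <- findInterval(points, s)
  idx > 0 & points < e[pmax(idx, 1L)]
}

#' Genomic distribution of peak feature classes
#'
#' @inheritParams classify_peaks
#' @return list with `counts` (named integer vector over the four classes)
#'   and `fractions` (summing to 1).
#' @export
annotation_distribution <- function(peaks, annotation, promoter_radius = 2000) {
  if (nrow(peaks) == 0L) stop("cannot summarize an empty peak set")
  cls <- classify_peaks(peaks, annotation, promoter_radius)
  counts <- table(cls)
  list(counts = c(counts), fractions = c(counts) / sum(counts))
}

#' Nearest gene to a genomic region
#'
#' The gene whose TSS minimizes the distance to the region midpoint; the
#' signed distance is `tss - midpoint` (negative when the TSS lies upstream,
#' i.e. to the left, of the midpoint). Ties are broken by lexicographic
#' `gene_id`.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (a `summit` column,
#'   if present, is used as the reference point as in [classify_peaks()]).
#' @param annotation a [genome_annotation()].
#' @return data.frame with one row per region: `gene_id`, `distance`.
#' @export
nearest_gene <- function(regions, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  validate_intervals(regions, "region")
  mids <- peak_midpoint(regions)
  genes <- annotation$genes
  gene_id <- character(nrow(regions))
  distance <- numeric(nrow(regions))
  for (k in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[k], , drop = FALSE]
    if (nrow(g) == 0L)
      stop("no genes on chromosome ", regions$chrom[k],
           ": region cannot be assigned")
    d <- abs(g$tss - mids[k])
    cand <- which(d == min(d))
    best <- cand[order(g$gene_id[cand])][1]
    gene_id[k] <- g$gene_id[best]
    distance[k] <- g$tss[best] - mids[k]
  }
  data.frame(gene_id = gene_id, distance = distance, stringsAsFactors = FALSE)
}

#' Highest-signal peak near a gene
#'
#' Among peaks whose reference point (summit, else midpoint) lies within
#' `[tss - window, tss + window]`, returns the one with the highest signal;
#' ties are broken toward the leftmost start. `NULL` when no peak qualifies.
#'
#' @param annotation a [genome_annotation()].
#' @param gene_id a gene present in `annotation`.
#' @param peaks peak data.frame.
#' @param window half-width in bases around the TSS (default 100000).
#' @return A one-row data.frame (the peak) or `NULL`.
#' @export
best_peak_for_gene <- function(annotation, gene_id, peaks, window = 100000) {
  stopifnot(inherits(annotation, "genome_annotation"), window > 0)
  g <- annotation$genes[annotation$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("unknown gene_id: ", gene_id)
  mids <- peak_midpoint(peaks)
  cand <- which(peaks$chrom == g$chrom &
                  mids >= g$tss - window & mids <= g$tss + window)
  if (length(cand) == 0L) return(NULL)
  best <- cand[order(-peaks$signal[cand], peaks$start[cand])][1]
  peaks[best, , drop = FALSE]
}

#' Annotate peaks: class, nearest gene, distance
#'
#' Convenience wrapper joining [classify_peaks()] and [nearest_gene()] into
#' one table (peaks on gene-free chromosomes get `NA` gene assignments).
#'
#' @inheritParams classify_peaks
#' @return data.frame: `name`, `chrom`, `start`, `end`, `class`,
#'   `nearest_gene`, `distance`.
#' @export
annotate_peaks <- function(peaks, annotation, promoter_radius = 2000) {
  cls <- classify_peaks(peaks, annotation, promoter_radius)
  ng <- data.frame(gene_id = rep(NA_character_, nrow(peaks)),
                   distance = rep(NA_real_, nrow(peaks)))
  has_genes <- peaks$chrom %in% annotation$genes$chrom
  if (any(has_genes))
    ng[has_genes, ] <- nearest_gene(peaks[has_genes, , drop = FALSE], annotation)
  data.frame(name = peaks$name, chrom = peaks$chrom, start = peaks$start,
             end = peaks$end, class = as.character(cls),
             nearest_gene = ng$gene_id, distance = ng$distance,
             stringsAsFactors = FALSE)
}
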