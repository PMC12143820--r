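#' Genomic intervals
#'
#' All coordinates in sercall are 0-based half-open `[start, end)`, the native
#' BED/narrowPeak convention. GTF input (1-based closed) is converted at the
#' reader boundary, see [read_gtf_genes()].
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-valued vectors, `0 <= start < end`.
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_interval("chr1", 0, 100)
#' @export
genomic_interval <- function(chrom, start, end) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end   = as.numeric(end),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop(what, ": chrom must be non-empty")
  if (any(df$start < 0))
    stop(what, ": start must be >= 0")
  if (any(df$start >= df$end))
    stop(what, ": start must be < end")
  if (any(df$start != floor(df$start)) || any(df$end != floor(df$end)))
    stop(what, ": coordinates must be integers")
  invisible(df)
}

#' Do two intervals overlap?
#'
#' Half-open semantics: `[0,100)` and `[100,200)` are adjacent, not
#' overlapping. Vectorized over rows; intervals on different chromosomes never
#' overlap.
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end` (recycled to a
#'   common length).
#' @return Logical vector.
#' @examples
#' interval_overlaps(genomic_interval("chr1", 0, 100), genomic_interval("chr1", 99, 200))
#' @export
interval_overlaps <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Gap between two intervals on the same chromosome
#'
#' Number of bases strictly between the intervals; 0 when they overlap or are
#' adjacent.
#'
#' @inheritParams interval_overlaps
#' @return Numeric vector of gap widths.
#' @examples
#' interval_gap(genomic_interval("chr1", 0, 1000), genomic_interval("chr1", 5000, 6000))
#' @export
interval_gap <- function(a, b) {
  if (any(a$chrom != b$chrom))
    stop("intervals on different chromosomes are incomparable")
  pmax(0, pmax(a$start, b$start) - pmin(a$end, b$end))
}

#' Construct a gene-model annotation
#'
#' Holds one representative span (and TSS) per gene plus merged exon
#' intervals. The TSS is `start` for `+` genes and `end - 1` (the last covered
#' base) for `-` genes; strand affects nothing else, H3K27ac peaks being
#' unstranded.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` and optionally `symbol`.
#' @param exons optional data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end`; overlapping exons of a gene are merged.
#' @return An object of class `genome_annotation`: a list with elements
#'   `genes` (with a derived `tss` column) and `exons`.
#' @examples
#' ann <- genome_annotation(data.frame(gene_id = "g1", chrom = "chr1",
#'                                     strand = "+", start = 1000, end = 5000))
#' ann$genes$tss
#' @export
genome_annotation <- function(genes, exons = NULL) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  validate_intervals(genes, "gene")
  if (anyDuplicated(genes$gene_id))
    stop("gene_id values must be unique")
  if (!all(genes$strand %in% c("+", "-")))
    stop("unknown strand character (must be '+' or '-')")
  if (is.null(genes$symbol)) genes$symbol <- rep(NA_character_, nrow(genes))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  if (is.null(exons) || nrow(exons) == 0L) {
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    exons <- as.data.frame(exons, stringsAsFactors = FALSE)
    validate_intervals(exons, "exon")
    if (!all(exons$gene_id %in% genes$gene_id))
      stop("exon gene_id not present in genes")
    exons <- merge_exons_by_gene(exons)
    span <- genes[match(exons$gene_id, genes$gene_id), ]
    if (any(exons$start < span$start | exons$end > span$end))
      stop("exons must lie within the gene span")
  }
  structure(list(genes = genes, exons = exons), class = "genome_annotation")
}

merge_exons_by_gene <- function(exons) {
  pieces <- lapply(split(exons, exons$gene_id), function(e) {
    e <- e[order(e$start, e$end), , drop = FALSE]
    red <- IRanges::reduce(IRanges::IRanges(start = e$start + 1, end = e$end))
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               start = IRanges::start(red) - 1, end = IRanges::end(red),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,",
      nrow(x$exons), "merged exons on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Transcription start sites of an annotation
#'
#' @param annotation a [genome_annotation()].
#' @return data.frame with `gene_id`, `chrom`, `tss`.
#' @export
gene_tss <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  annotation$genes[, c("gene_id", "chrom", "tss")]
}

#' Validate a peak table
#'
#' Peaks are scored genomic intervals: columns `chrom`, `start`, `end`,
#' `name`, `signal` (>= 0) and optional `summit` (offset from `start`, in
#' `[0, width)`, `NA` when unknown).
#'
#' @param peaks data.frame of peaks.
#' @return The validated data.frame (invisibly usable in a pipe).
#' @export
validate_peaks <- function(peaks) {
  validate_intervals(peaks, "peak")
  stopifnot(all(c("name", "signal") %in% names(peaks)))
  if (any(is.na(peaks$signal)) || any(peaks$signal < 0))
    stop("peak signal must be non-negative")
  if (!is.null(peaks$summit)) {
    bad <- !is.na(peaks$summit) &
      (peaks$summit < 0 | peaks$summit >= peaks$end - peaks$start)
    if (any(bad)) stop("summit offset outside [0, width)")
  }
  peaks
}

peak_midpoint <- function(peaks) {
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2
  if (!is.null(peaks$summit)) {
    has <- !is.na(peaks$summit)
    mid[has] <- peaks$start[has] + peaks$summit[has]
  }
  mid
}
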