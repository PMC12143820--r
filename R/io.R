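#' Read peaks from an ENCODE narrowPeak or 5-column BED file
#'
#' Lines must carry at least 5 tab-separated fields. For full 10-field
#' narrowPeak records the signal is taken from the `signalValue` column
#' (column 7; the BED `score` column is display-clamped to 1000 and is not
#' used) and the summit offset from column 10 (`-1` meaning unknown). For
#' 5-9 field records the signal falls back to column 5 and no summit is set.
#' Malformed lines raise an error naming the line number; nothing is skipped
#' silently.
#'
#' @param path path to a narrowPeak/BED file.
#' @return data.frame of peaks (`chrom`, `start`, `end`, `name`, `signal`,
#'   `summit`), see [validate_peaks()].
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), signal = numeric(), summit = numeric(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L))
    stop("malformed record (fewer than 5 fields) at line ",
         which(nf < 5L)[1], " of ", path)
  get <- function(i) vapply(fields, `[`, character(1), i)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-numeric coordinates at line ",
         which(is.na(start) | is.na(end))[1], " of ", path)
  if (any(start >= end))
    stop("start >= end at line ", which(start >= end)[1], " of ", path)
  signal <- suppressWarnings(as.numeric(ifelse(nf >= 10L, get(7), get(5))))
  if (any(is.na(signal)))
    stop("non-numeric signal at line ", which(is.na(signal))[1], " of ", path)
  if (any(signal < 0))
    stop("negative signal at line ", which(signal < 0)[1], " of ", path)
  summit <- rep(NA_real_, length(lines))
  full <- nf >= 10L
  if (any(full)) {
    sm <- suppressWarnings(as.numeric(vapply(fields[full], `[`, character(1), 10)))
    sm[!is.na(sm) & sm < 0] <- NA_real_
    summit[full] <- sm
  }
  peaks <- data.frame(chrom = get(1), start = start, end = end,
                      name = get(4), signal = signal, summit = summit,
                      stringsAsFactors = FALSE)
  validate_peaks(peaks)
}

#' Read gene models from a GTF file
#'
#' Imports `gene` and `exon` features (via rtracklayer), converts 1-based
#' closed GTF coordinates to the package's 0-based half-open convention, takes
#' the gene span as the union extent of the gene's features, and merges
#' overlapping exons. When a GTF carries no `gene` rows, spans are derived
#' from the union of that gene's other features.
#'
#' @param path path to a GTF file with `gene_id` attributes.
#' @return A [genome_annotation()].
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (is.null(meta$gene_id) || any(is.na(meta$gene_id)))
    stop("GTF record without gene_id attribute in ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("unknown strand character in ", path, " (must be '+' or '-')")
  df <- data.frame(gene_id = as.character(meta$gene_id),
                   type = as.character(meta$type),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = strand,
                   start = GenomicRanges::start(gr) - 1,   # 1-based -> 0-based
                   end = as.numeric(GenomicRanges::end(gr)),
                   symbol = if (is.null(meta$gene_name)) NA_character_
                            else as.character(meta$gene_name),
                   stringsAsFactors = FALSE)
  spans <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
    if (length(unique(g$chrom)) > 1L || length(unique(g$strand)) > 1L)
      stop("gene ", g$gene_id[1], " spans multiple chromosomes or strands")
    sym <- g$symbol[!is.na(g$symbol)]
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end),
               symbol = if (length(sym)) sym[1] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  exons <- df[df$type == "exon", c("gene_id", "chrom", "start", "end")]
  genome_annotation(spans, if (nrow(exons)) exons else NULL)
}

#' Read a bedGraph signal track
#'
#' @param path path to a 4-column bedGraph file.
#' @return data.frame (`chrom`, `start`, `end`, `value`) sorted by
#'   `(chrom, start)`; overlapping records are an error (ambiguous track).
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed bedGraph record at line ", which(nf < 4L)[1], " of ", path)
  get <- function(i) vapply(fields, `[`, character(1), i)
  track <- data.frame(chrom = get(1),
                      start = as.numeric(get(2)), end = as.numeric(get(3)),
                      value = as.numeric(get(4)), stringsAsFactors = FALSE)
  if (any(is.na(track$start) | is.na(track$end) | is.na(track$value)))
    stop("non-numeric bedGraph fields in ", path)
  if (any(track$value < 0)) stop("negative bedGraph value in ", path)
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  rownames(track) <- NULL
  same <- track$chrom[-1] == track$chrom[-nrow(track)]
  if (nrow(track) > 1L && any(same & track$start[-1] < track$end[-nrow(track)]))
    stop("overlapping bedGraph records in ", path, " (ambiguous track)")
  track
}

#' Area under a signal track within a region
#'
#' Sum over overlapping track records of `value * overlap_width`; 0 when the
#' region touches no record.
#'
#' @param track a track from [read_bedgraph()].
#' @param chrom,start,end the query region (0-based half-open).
#' @return A single number.
#' @export
signal_over <- function(track, chrom, start, end) {
  t <- track[track$chrom == chrom & track$start < end & track$end > start, ,
             drop = FALSE]
  if (nrow(t) == 0L) return(0)
  sum(t$value * (pmin(t$end, end) - pmax(t$start, start)))
}

#' Write peaks/regions as BED
#'
#' Tab-separated, 0-based half-open, sorted by `(chrom, start)`. With `name`
#' and `signal` columns present a 5-column BED is written that round-trips
#' through [read_narrowpeak()]; any further columns are appended after
#' column 5.
#'
#' @param records data.frame with at least `chrom`, `start`, `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  cols <- c("chrom", "start", "end",
            intersect(c("name", "signal"), names(records)),
            setdiff(names(records), c("chrom", "start", "end", "name",
                                      "signal", "summit")))
  out <- records[order(records$chrom, records$start), cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, na = ".",
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Write a TSV table with a header line
#'
#' Missing values are written as `"."` (BED-family convention).
#'
#' @param rows data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  tryCatch(
    utils::write.table(rows, path, sep = "\t", quote = FALSE, na = ".",
                       row.names = FALSE, col.names = TRUE),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a TSV table written by [write_table()]
#'
#' @param path input path.
#' @return data.frame; `"."` entries become `NA`.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
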