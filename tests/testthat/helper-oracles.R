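# Independent brute-force oracles used across the suite.

# O(n^2) supporting-line oracle for the slope-1 tangency: for each point i,
# check whether the line y = x + (y_i - x_i) leaves no point strictly below
# it; among supporting points pick the one with the greatest scaled_y.
oracle_tangency_index <- function(scaled_x, scaled_y, eps = 1e-12) {
  n <- length(scaled_x)
  d <- scaled_y - scaled_x
  supporting <- vapply(seq_len(n), function(i)
    all(scaled_y >= scaled_x + d[i] - eps), logical(1))
  cand <- which(supporting)
  cand[which.max(scaled_y[cand])]
}

# O(n^2) connected components of the gap-<=-threshold interval graph,
# breadth-first, independent of the chain-based stitcher.
oracle_components <- function(peaks, gap) {
  n <- nrow(peaks)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (peaks$chrom[i] != peaks$chrom[j]) next
    g <- max(0, max(peaks$start[i], peaks$start[j]) -
                min(peaks$end[i], peaks$end[j]))
    adj[i, j] <- g <= gap
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# partition of peak names implied by a component labelling
partition_from_labels <- function(names, labels) {
  sets <- unname(lapply(split(names, labels), sort))
  sets[order(vapply(sets, `[`, character(1), 1))]
}

# partition of peak names from stitch_peaks() output
partition_from_stitched <- function(stitched) {
  sets <- lapply(strsplit(stitched$members, ",", fixed = TRUE), sort)
  sets[order(vapply(sets, `[`, character(1), 1))]
}

random_peaks <- function(n, n_chrom = 2, span = 2e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- round(runif(n, 0, span))
  data.frame(chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
             start = start, end = start + round(runif(n, 100, 2000)),
             name = sprintf("p%03d", seq_len(n)),
             signal = rlnorm(n, 1, 1), stringsAsFactors = FALSE)
}

# small deterministic annotation used by several suites
toy_annotation <- function() {
  genome_annotation(
    genes = data.frame(
      gene_id = c("gA", "gB", "gC"),
      chrom = c("chr1", "chr1", "chr2"),
      strand = c("+", "-", "+"),
      start = c(100000, 300000, 50000),
      end = c(130000, 320000, 80000),
      stringsAsFactors = FALSE),
    exons = data.frame(
      gene_id = c("gA", "gA", "gB", "gC"),
      chrom = c("chr1", "chr1", "chr1", "chr2"),
      start = c(100000, 110000, 318000, 50000),
      end = c(103000, 113000, 320000, 52000),
      stringsAsFactors = FALSE))
}

make_peaks <- function(chrom, start, end, signal = 1,
                       name = sprintf("p%d", seq_along(start)), summit = NA) {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             signal = signal, summit = summit, stringsAsFactors = FALSE)
}
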