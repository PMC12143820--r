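#' Consensus regions across two peak sets
#'
#' Union of both sets with overlapping intervals merged (strict overlap —
#' merely adjacent intervals stay separate). Each output region records the
#' names of the contributing peaks.
#'
#' @param peaks_a,peaks_b peak data.frames.
#' @return data.frame: `region_id`, `chrom`, `start`, `end`, `members`
#'   (comma-joined contributing peak names), sorted by `(chrom, start)`.
#' @export
build_consensus_regions <- function(peaks_a, peaks_b) {
  all <- rbind(peaks_a[, c("chrom", "start", "end", "name")],
               peaks_b[, c("chrom", "start", "end", "name")])
  if (nrow(all) == 0L)
    return(data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), members = character(),
                      stringsAsFactors = FALSE))
  validate_intervals(all, "peak")
  all <- all[order(all$chrom, all$start, all$end), , drop = FALSE]
  run_end <- cummax_by_chrom(all$chrom, all$end)
  new_region <- c(TRUE,
                  all$chrom[-1] != all$chrom[-nrow(all)] |
                    all$start[-1] >= run_end[-nrow(all)])
  grp <- cumsum(new_region)
  out <- do.call(rbind, lapply(split(seq_len(nrow(all)), grp), function(i) {
    data.frame(chrom = all$chrom[i[1]],
               start = min(all$start[i]), end = max(all$end[i]),
               members = paste(unique(all$name[i]), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(region_id = sprintf("R_%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Two-condition differential signal test for a region
#'
#' Library-normalized log2 fold change with a pseudocount on both sides,
#'
#' `log2fc = log2((count_b + pc)/lib_b) - log2((count_a + pc)/lib_a)`,
#'
#' and an exact two-sided conditional binomial test: conditional on the
#' pooled total `n = count_a + count_b` (counts rounded to integers), the
#' b-side count is Binomial(`n`, `lib_b/(lib_a + lib_b)`) under the null of
#' equal normalized rates. Swapping the two conditions negates `log2fc`
#' exactly and preserves the p-value. Vectorized over regions.
#'
#' @param count_a,count_b non-negative signal/read counts per condition.
#' @param lib_a,lib_b positive normalization totals (library sizes).
#' @param pseudocount added to both counts for the fold change (default 1).
#' @return data.frame with columns `log2fc`, `p_value`.
#' @export
differential_signal_test <- function(count_a, count_b, lib_a, lib_b,
                                     pseudocount = 1) {
  if (any(count_a < 0) || any(count_b < 0))
    stop("counts must be non-negative")
  stopifnot(all(lib_a > 0), all(lib_b > 0))
  k <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, k); count_b <- rep_len(count_b, k)
  lib_a <- rep_len(lib_a, k); lib_b <- rep_len(lib_b, k)
  log2fc <- (log2(count_b + pseudocount) - log2(lib_b)) -
            (log2(count_a + pseudocount) - log2(lib_a))
  xa <- round(count_a); xb <- round(count_b)
  n <- xa + xb
  p0 <- lib_b / (lib_a + lib_b)
  p_value <- vapply(seq_len(k), function(i) {
    if (n[i] == 0) return(1)
    stats::binom.test(xb[i], n[i], p = p0[i])$p.value
  }, numeric(1))
  data.frame(log2fc = log2fc, p_value = p_value)
}

#' Classify differential regions as up/down/ns
#'
#' Strict inequalities: `up` iff `log2fc > fc_threshold` and
#' `p < p_threshold`; `down` symmetric; otherwise `ns`. A `log2fc` of exactly
#' the threshold is never called.
#'
#' @param log2fc,p_value numeric vectors.
#' @param fc_threshold threshold on `|log2fc|`, in log2 units (default 1).
#' @param p_threshold raw p-value gate (default 0.05).
#' @return Factor with levels `up`, `down`, `ns`.
#' @export
classify_regions <- function(log2fc, p_value, fc_threshold = 1,
                             p_threshold = 0.05) {
  stopifnot(fc_threshold > 0, p_threshold > 0)
  call <- ifelse(p_value < p_threshold & log2fc > fc_threshold, "up",
          ifelse(p_value < p_threshold & log2fc < -fc_threshold, "down", "ns"))
  factor(call, levels = c("up", "down", "ns"))
}

#' Reads/fragments per kilobase of gene per million mapped reads
#'
#' `count * 1e9 / (library_size * gene_length_bp)`.
#'
#' @param count read count(s), >= 0.
#' @param gene_length_bp gene length(s) in bases, > 0.
#' @param library_size total mapped reads, > 0.
#' @return FPKM value(s).
#' @export
fpkm <- function(count, gene_length_bp, library_size) {
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  count * 1e9 / (library_size * gene_length_bp)
}

#' Differential expression screen for one gene
#'
#' Fold change of group means with a pseudocount,
#' `fc = (mean_b + pc)/(mean_a + pc)`, and a two-sided Welch t-test on
#' `log2(FPKM + pc)` when both groups have at least two replicates (else
#' `p = 1` with a warning). Direction: `up` if `fc > fc_threshold`, `down` if
#' `fc < 1/fc_threshold`, gated by `p < p_threshold`; otherwise `ns`.
#'
#' @param fpkm_a,fpkm_b numeric vectors of replicate FPKM values (at least
#'   one replicate each).
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param p_threshold raw p-value gate (default 0.05).
#' @param pseudocount added before ratios and logs (default 1).
#' @return list with `mean_a`, `mean_b`, `fold_change`, `p_value`,
#'   `direction`.
#' @export
expression_differential <- function(fpkm_a, fpkm_b, fc_threshold = 2,
                                    p_threshold = 0.05, pseudocount = 1) {
  if (length(fpkm_a) == 0L || length(fpkm_b) == 0L)
    stop("each group needs at least one replicate")
  stopifnot(all(fpkm_a >= 0), all(fpkm_b >= 0), fc_threshold > 0)
  mean_a <- mean(fpkm_a); mean_b <- mean(fpkm_b)
  fold_change <- (mean_b + pseudocount) / (mean_a + pseudocount)
  if (length(fpkm_a) >= 2L && length(fpkm_b) >= 2L) {
    p_value <- tryCatch(
      stats::t.test(log2(fpkm_b + pseudocount), log2(fpkm_a + pseudocount),
                    var.equal = FALSE)$p.value,
      error = function(e) 1)   # constant data: no evidence of change
  } else {
    warning("fewer than 2 replicates in a group: p set to 1")
    p_value <- 1
  }
  direction <-
    if (p_value < p_threshold && fold_change > fc_threshold) "up"
    else if (p_value < p_threshold && fold_change < 1 / fc_threshold) "down"
    else "ns"
  list(mean_a = mean_a, mean_b = mean_b, fold_change = fold_change,
       p_value = p_value, direction = direction)
}

#' Differential expression screen over a gene table
#'
#' Applies [expression_differential()] row-wise to replicate FPKM matrices
#' and appends a Benjamini-Hochberg adjusted p-value column (reported for
#' reference; the up/down calls use the raw p-value gate).
#'
#' @param fpkm_a,fpkm_b numeric matrices (genes x replicates), same row
#'   order.
#' @param gene_ids character vector of gene identifiers.
#' @inheritParams expression_differential
#' @return data.frame: `gene_id`, `mean_a`, `mean_b`, `fold_change`,
#'   `p_value`, `padj`, `direction`.
#' @export
de_analysis <- function(fpkm_a, fpkm_b, gene_ids, fc_threshold = 2,
                        p_threshold = 0.05, pseudocount = 1) {
  fpkm_a <- as.matrix(fpkm_a); fpkm_b <- as.matrix(fpkm_b)
  stopifnot(nrow(fpkm_a) == length(gene_ids), nrow(fpkm_b) == length(gene_ids))
  rows <- lapply(seq_along(gene_ids), function(i)
    expression_differential(fpkm_a[i, ], fpkm_b[i, ], fc_threshold,
                            p_threshold, pseudocount))
  out <- data.frame(gene_id = gene_ids,
                    mean_a = vapply(rows, `[[`, numeric(1), "mean_a"),
                    mean_b = vapply(rows, `[[`, numeric(1), "mean_b"),
                    fold_change = vapply(rows, `[[`, numeric(1), "fold_change"),
                    p_value = vapply(rows, `[[`, numeric(1), "p_value"),
                    direction = vapply(rows, `[[`, character(1), "direction"),
                    stringsAsFactors = FALSE)
  out$padj <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("gene_id", "mean_a", "mean_b", "fold_change", "p_value", "padj",
          "direction")]
}
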