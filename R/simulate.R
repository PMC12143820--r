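#' Configuration for the synthetic two-condition landscape generator
#'
#' The generator emulates the structure of a two-condition H3K27ac ChIP-seq /
#' RNA-seq study: a gene annotation, scattered single background peaks
#' (the typical-enhancer population), planted multi-peak super-enhancer
#' clusters with boosted signal, a fraction of TSS-proximal peaks, a second
#' condition in which a subset of clusters changes signal (half up, half
#' down), and replicate expression tables in which the genes nearest to
#' differential clusters change concordantly.
#'
#' Background peaks are placed with more than `stitch_gap` separation so each
#' forms its own stitched enhancer; only planted clusters stitch. Background
#' signals are log-normal with a deliberately tight spread
#' (`background_sdlog = 0.06`): the benchmark is designed so planted clusters
#' are separable by the slope-1 tangent, which a heavy background tail
#' prevents (see the package vignette for what this does and does not show
#' about real data).
#'
#' @param seed integer RNG seed; identical configs and seeds give
#'   byte-identical outputs.
#' @param n_chrom,chrom_length genome shape (default 4 x 25 Mb).
#' @param n_genes genes placed uniformly without overlap (default 400).
#' @param n_background_peaks scattered peaks (default 2000).
#' @param n_typical_enhancers optional unboosted 2-3 peak clusters (default
#'   0; raising this degrades planted-SE recovery, by design of the tangent).
#' @param n_super_clusters planted SE clusters (default 30).
#' @param peaks_per_cluster inclusive integer range (default `c(3, 8)`).
#' @param intra_cluster_gap gap range in bases between cluster peaks
#'   (default `c(500, 11000)`; must stay below the 12.5 kb stitch gap).
#' @param background_meanlog,background_sdlog log-normal signal parameters
#'   (defaults 2.5 and 0.06).
#' @param se_signal_multiplier per-peak signal boost in clusters (default 5).
#' @param n_differential_ses clusters changed in condition B (default 8).
#' @param differential_effect linear fold applied to differential clusters
#'   and their planted genes (default 4).
#' @param tss_proximal_fraction fraction of background peaks planted fully
#'   inside a TSS +/- 2 kb window (default 0.2).
#' @param condition_noise_sdlog multiplicative log-normal noise between
#'   conditions for unchanged peaks (default 0.05).
#' @param expr_meanlog,expr_sdlog log-normal distribution of baseline gene
#'   mean counts (defaults `log(200)` and 1).
#' @param dispersion negative-binomial dispersion of counts (default 0.05).
#' @param n_replicates replicates per condition (default 3).
#' @param concordant_fraction fraction of differential clusters whose
#'   nearest gene receives the matched expression effect (default 1).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chrom = 4, chrom_length = 25e6,
                              n_genes = 400,
                              n_background_peaks = 2000,
                              n_typical_enhancers = 0,
                              n_super_clusters = 30,
                              peaks_per_cluster = c(3, 8),
                              intra_cluster_gap = c(500, 11000),
                              background_meanlog = 2.5,
                              background_sdlog = 0.06,
                              se_signal_multiplier = 5,
                              n_differential_ses = 8,
                              differential_effect = 4,
                              tss_proximal_fraction = 0.2,
                              condition_noise_sdlog = 0.05,
                              expr_meanlog = log(200), expr_sdlog = 1,
                              dispersion = 0.05,
                              n_replicates = 3,
                              concordant_fraction = 1) {
  stopifnot(n_chrom >= 1, chrom_length > 0, n_genes >= 0,
            n_background_peaks >= 0, n_typical_enhancers >= 0,
            n_super_clusters >= 0,
            length(peaks_per_cluster) == 2, peaks_per_cluster[1] >= 1,
            peaks_per_cluster[1] <= peaks_per_cluster[2],
            length(intra_cluster_gap) == 2, intra_cluster_gap[1] >= 1,
            intra_cluster_gap[1] <= intra_cluster_gap[2],
            intra_cluster_gap[2] <= 12500,
            se_signal_multiplier > 1, differential_effect > 1,
            n_differential_ses <= n_super_clusters,
            tss_proximal_fraction >= 0, tss_proximal_fraction <= 1,
            dispersion > 0, n_replicates >= 0,
            concordant_fraction >= 0, concordant_fraction <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a two-condition enhancer landscape with ground truth
#'
#' @param config a [simulation_config()].
#' @return list of class `se_simulation`: `annotation`
#'   (a [genome_annotation()]), `peaks_a`, `peaks_b` (peak data.frames with
#'   identical intervals and condition-specific signals), `truth` (list with
#'   `clusters` — planted cluster spans, direction and nearest gene — and
#'   `genes` — planted expression direction and fold per gene), and `config`.
#' @export
simulate_landscape <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  L <- config$chrom_length
  stitch_guard <- 12500 + 200   # keep non-cluster peaks from stitching in

  ## genes: uniform non-overlapping placement per chromosome
  n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
  genes <- NULL
  for (ci in seq_len(config$n_chrom)) {
    n <- n_per[ci]
    if (n == 0) next
    len <- round(stats::runif(n, 5000, 30000))
    margin <- 50000
    free <- L - 2 * margin - sum(len) - (n - 1) * 5000
    if (free <= 0)
      stop("infeasible placement: too many genes for chrom_length")
    u <- sort(round(stats::runif(n, 0, free)))
    start <- margin + u + cumsum(c(0, len[-n] + 5000))
    genes <- rbind(genes, data.frame(
      gene_id = sprintf("g%s_%03d", ci, seq_len(n)),
      chrom = chroms[ci], strand = sample(c("+", "-"), n, replace = TRUE),
      start = start, end = start + len, stringsAsFactors = FALSE))
  }
  genes$symbol <- toupper(genes$gene_id)
  ## three exons per gene at fixed relative positions
  exons <- NULL
  if (!is.null(genes)) {
    len <- genes$end - genes$start
    exons <- do.call(rbind, lapply(c(0, 0.45, 0.9), function(f)
      data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                 start = round(genes$start + f * len),
                 end = round(genes$start + f * len) + pmax(200, round(0.08 * len)),
                 stringsAsFactors = FALSE)))
    exons$end <- pmin(exons$end, genes$end[match(exons$gene_id, genes$gene_id)])
  }
  annotation <- genome_annotation(genes, exons)
  tss <- gene_tss(annotation)

  ## planted clusters (super + optional typical), rejection-placed away from
  ## TSS windows and from each other
  zones <- data.frame(chrom = tss$chrom, start = tss$tss - 3600,
                      end = tss$tss + 3600, stringsAsFactors = FALSE)
  ## clusters are anchored near gene TSSs (15-80 kb away: outside the TSS
  ## exclusion window, inside the default integration gene window) so that
  ## planted super-enhancers have a recoverable nearest gene
  place_cluster <- function(k, gaps, widths) {
    clen <- sum(widths) + sum(gaps)
    for (try in 1:2000) {
      g <- tss[sample.int(nrow(tss), 1), ]
      side <- sample(c(-1, 1), 1)
      d <- round(stats::runif(1, 15000, 80000))
      pos <- if (side > 0) g$tss + d else g$tss - d - clen
      if (pos < stitch_guard || pos + clen > L - stitch_guard) next
      hit <- zones$chrom == g$chrom & zones$start < pos + clen + stitch_guard &
        zones$end > pos - stitch_guard
      if (!any(hit)) {
        zones <<- rbind(zones, data.frame(chrom = g$chrom,
                                          start = pos - stitch_guard,
                                          end = pos + clen + stitch_guard))
        return(list(chrom = g$chrom, pos = pos))
      }
    }
    stop("infeasible placement: could not place cluster (genome too crowded)")
  }
  build_cluster <- function(id_prefix, idx, kmin, kmax, boost) {
    k <- if (kmin == kmax) kmin else sample(seq(kmin, kmax), 1)
    widths <- round(stats::runif(k, 500, 1500))
    gaps <- if (k > 1)
      round(stats::runif(k - 1, config$intra_cluster_gap[1],
                         config$intra_cluster_gap[2])) else numeric(0)
    at <- place_cluster(k, gaps, widths)
    start <- at$pos + cumsum(c(0, widths[-k] + gaps))
    data.frame(chrom = at$chrom, start = start, end = start + widths,
               name = sprintf("%s%02d_p%d", id_prefix, idx, seq_len(k)),
               signal = boost * stats::rlnorm(k, config$background_meanlog,
                                              config$background_sdlog),
               summit = NA_real_, cluster = sprintf("%s%02d", id_prefix, idx),
               stringsAsFactors = FALSE)
  }
  cl_peaks <- NULL
  for (i in seq_len(config$n_super_clusters))
    cl_peaks <- rbind(cl_peaks, build_cluster(
      "SEC", i, config$peaks_per_cluster[1], config$peaks_per_cluster[2],
      config$se_signal_multiplier))
  for (i in seq_len(config$n_typical_enhancers))
    cl_peaks <- rbind(cl_peaks, build_cluster("TEC", i, 2, 3, 1))

  ## scattered background peaks: slot construction guarantees that any two
  ## are separated by more than the stitch gap
  n_bg <- config$n_background_peaks
  n_prox <- round(config$tss_proximal_fraction * n_bg)
  n_scatter <- n_bg - n_prox
  slot_w <- 28000
  slots <- do.call(rbind, lapply(chroms, function(chr) {
    s <- seq(0, L - slot_w, by = slot_w)
    data.frame(chrom = chr, start = s, stringsAsFactors = FALSE)
  }))
  bad <- vapply(seq_len(nrow(slots)), function(i) {
    z <- zones[zones$chrom == slots$chrom[i], , drop = FALSE]
    any(z$start < slots$start[i] + slot_w & z$end > slots$start[i])
  }, logical(1))
  slots <- slots[!bad, , drop = FALSE]
  if (nrow(slots) < n_scatter)
    stop("infeasible placement: not enough room for background peaks")
  pick <- slots[sort(sample.int(nrow(slots), n_scatter)), , drop = FALSE]
  w <- round(stats::runif(n_scatter, 300, 1200))
  off <- round(stats::runif(n_scatter, 0, slot_w / 2 - w))
  scatter <- data.frame(chrom = pick$chrom, start = pick$start + off,
                        end = pick$start + off + w,
                        name = sprintf("bg_%04d", seq_len(n_scatter)),
                        signal = stats::rlnorm(n_scatter,
                                               config$background_meanlog,
                                               config$background_sdlog),
                        summit = NA_real_, cluster = NA_character_,
                        stringsAsFactors = FALSE)

  ## TSS-proximal background peaks, fully inside [tss - 2000, tss + 2001)
  prox <- NULL
  if (n_prox > 0) {
    if (nrow(tss) == 0) stop("tss_proximal_fraction > 0 needs genes")
    if (n_prox > nrow(tss))
      stop("infeasible placement: more TSS-proximal peaks than genes ",
           "(at most one per TSS)")
    gi <- sample.int(nrow(tss), n_prox)
    pw <- round(stats::runif(n_prox, 200, 800))
    ps <- tss$tss[gi] - 2000 + round(stats::runif(n_prox, 0, 4001 - pw))
    prox <- data.frame(chrom = tss$chrom[gi], start = ps, end = ps + pw,
                       name = sprintf("tssprox_%04d", seq_len(n_prox)),
                       signal = stats::rlnorm(n_prox, config$background_meanlog,
                                              config$background_sdlog),
                       summit = NA_real_, cluster = NA_character_,
                       stringsAsFactors = FALSE)
  }

  peaks_a <- rbind(cl_peaks, scatter, prox)
  peaks_a <- peaks_a[order(peaks_a$chrom, peaks_a$start), , drop = FALSE]
  rownames(peaks_a) <- NULL

  ## condition B: same intervals, jittered signals, planted effects
  n_diff <- config$n_differential_ses
  diff_ids <- if (n_diff > 0)
    sprintf("SEC%02d", sort(sample.int(config$n_super_clusters, n_diff))) else
    character(0)
  direction <- rep(c("up", "down"), length.out = n_diff)
  names(direction) <- diff_ids
  effect <- rep(1, nrow(peaks_a))
  pd <- direction[match(peaks_a$cluster, diff_ids)]
  effect[!is.na(pd) & pd == "up"] <- config$differential_effect
  effect[!is.na(pd) & pd == "down"] <- 1 / config$differential_effect
  peaks_b <- peaks_a
  peaks_b$signal <- peaks_a$signal * effect *
    stats::rlnorm(nrow(peaks_a), 0, config$condition_noise_sdlog)

  ## ground truth
  super <- peaks_a[!is.na(peaks_a$cluster) & startsWith(peaks_a$cluster, "SEC"), ]
  spans <- do.call(rbind, lapply(split(super, super$cluster), function(p)
    data.frame(truth_id = p$cluster[1], chrom = p$chrom[1],
               start = min(p$start), end = max(p$end), n_peaks = nrow(p),
               base_total_signal = sum(p$signal), stringsAsFactors = FALSE)))
  rownames(spans) <- NULL
  spans$direction <- ifelse(spans$truth_id %in% diff_ids,
                            direction[spans$truth_id], "none")
  spans$effect <- ifelse(spans$direction == "none", 1, config$differential_effect)
  ngg <- nearest_gene(spans[, c("chrom", "start", "end")], annotation)
  spans$nearest_gene <- ngg$gene_id
  spans$distance <- ngg$distance

  n_conc <- round(config$concordant_fraction * n_diff)
  conc_ids <- diff_ids[seq_len(n_conc)]
  tg <- spans[spans$truth_id %in% conc_ids, , drop = FALSE]
  truth_genes <- data.frame(gene_id = tg$nearest_gene, truth_id = tg$truth_id,
                            direction = tg$direction,
                            fold = config$differential_effect,
                            stringsAsFactors = FALSE)

  keep <- c("chrom", "start", "end", "name", "signal", "summit")
  structure(list(annotation = annotation,
                 peaks_a = peaks_a[, keep], peaks_b = peaks_b[, keep],
                 truth = list(clusters = spans, genes = truth_genes),
                 config = config),
            class = "se_simulation")
}

#' @export
print.se_simulation <- function(x, ...) {
  cat("se_simulation:", nrow(x$peaks_a), "peaks per condition,",
      nrow(x$annotation$genes), "genes,",
      nrow(x$truth$clusters), "planted SE clusters (",
      sum(x$truth$clusters$direction != "none"), "differential )\n")
  invisible(x)
}

#' Simulate replicate expression tables linked to the landscape
#'
#' Per-gene negative-binomial counts; genes recorded in the ground truth as
#' concordant targets of differential clusters have their condition-B mean
#' multiplied (up) or divided (down) by the planted fold. FPKM is computed
#' with [fpkm()] from the annotated gene lengths and per-replicate library
#' sizes.
#'
#' @param annotation a [genome_annotation()].
#' @param truth the `truth` element of an `se_simulation`.
#' @param config the [simulation_config()] used for the landscape.
#' @return list: `counts_a`, `counts_b`, `fpkm_a`, `fpkm_b` (genes x
#'   replicates matrices with gene_id rownames), `gene_length`, `lib_a`,
#'   `lib_b`.
#' @export
simulate_expression <- function(annotation, truth, config) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(annotation, "genome_annotation"))
  if (config$n_replicates < 1)
    stop("n_replicates must be at least 1")
  set.seed(config$seed + 1L)
  genes <- annotation$genes
  ng <- nrow(genes)
  nr <- config$n_replicates
  mu_a <- stats::rlnorm(ng, config$expr_meanlog, config$expr_sdlog)
  mu_b <- mu_a
  hit <- match(truth$genes$gene_id, genes$gene_id)
  fold <- ifelse(truth$genes$direction == "up",
                 truth$genes$fold, 1 / truth$genes$fold)
  mu_b[hit] <- mu_a[hit] * fold
  size <- 1 / config$dispersion
  draw <- function(mu) matrix(stats::rnbinom(ng * nr, mu = rep(mu, nr),
                                             size = size),
                              nrow = ng, ncol = nr,
                              dimnames = list(genes$gene_id, NULL))
  counts_a <- draw(mu_a); counts_b <- draw(mu_b)
  gene_length <- genes$end - genes$start
  lib_a <- pmax(colSums(counts_a), 1)
  lib_b <- pmax(colSums(counts_b), 1)
  fpkm_a <- fpkm(counts_a, gene_length, rep(lib_a, each = ng))
  fpkm_b <- fpkm(counts_b, gene_length, rep(lib_b, each = ng))
  list(counts_a = counts_a, counts_b = counts_b,
       fpkm_a = fpkm_a, fpkm_b = fpkm_b,
       gene_length = gene_length, lib_a = lib_a, lib_b = lib_b)
}

#' Write a simulated study to disk as standard-format files
#'
#' Emits a GTF of the gene models, a narrowPeak file and a bedGraph track
#' per condition (track value = signal / width, so the area over a peak
#' equals its signal), expression count and FPKM TSVs, ground-truth TSVs,
#' and a `manifest.tsv` listing every emitted file with its MD5 checksum.
#'
#' @param sim an `se_simulation` from [simulate_landscape()].
#' @param expr output of [simulate_expression()] (omitted when `NULL`).
#' @param outdir output directory (created if needed).
#' @param overwrite allow overwriting an existing manifest (default FALSE).
#' @return data.frame manifest (file, md5), invisibly.
#' @export
write_fixture <- function(sim, expr = NULL, outdir, overwrite = FALSE) {
  stopifnot(inherits(sim, "se_simulation"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(outdir, "manifest.tsv")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists in ", outdir, " (use overwrite = TRUE)")

  files <- character()
  put <- function(name) { files <<- c(files, name); file.path(outdir, name) }

  genes <- sim$annotation$genes
  exons <- sim$annotation$exons
  gtf <- c(sprintf('%s\tsercall_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
                   genes$chrom, genes$start + 1, genes$end, genes$strand,
                   genes$gene_id, genes$symbol),
           sprintf('%s\tsercall_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   exons$chrom, exons$start + 1, exons$end,
                   genes$strand[match(exons$gene_id, genes$gene_id)],
                   exons$gene_id))
  writeLines(gtf, put("genes.gtf"))

  write_np <- function(peaks, name) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t-1\t-1\t%d",
                       peaks$chrom, peaks$start, peaks$end, peaks$name,
                       pmin(1000L, as.integer(round(peaks$signal))),
                       formatC(peaks$signal, digits = 6, format = "f"),
                       ifelse(is.na(peaks$summit), -1L, as.integer(peaks$summit))),
               put(name))
  }
  o <- order(sim$peaks_a$chrom, sim$peaks_a$start)
  write_np(sim$peaks_a[o, ], "peaks_a.narrowPeak")
  write_np(sim$peaks_b[o, ], "peaks_b.narrowPeak")

  write_bg <- function(peaks, name) {
    p <- peaks[order(peaks$chrom, peaks$start), ]
    writeLines(sprintf("%s\t%d\t%d\t%s", p$chrom, p$start, p$end,
                       formatC(p$signal / (p$end - p$start),
                               digits = 8, format = "f")),
               put(name))
  }
  write_bg(sim$peaks_a, "signal_a.bedGraph")
  write_bg(sim$peaks_b, "signal_b.bedGraph")

  write_table(sim$truth$clusters, put("truth_clusters.tsv"))
  write_table(sim$truth$genes, put("truth_genes.tsv"))

  if (!is.null(expr)) {
    mat_tsv <- function(m, name) {
      df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
      names(df)[-1] <- paste0("rep", seq_len(ncol(m)))
      write_table(df, put(name))
    }
    mat_tsv(expr$counts_a, "counts_a.tsv")
    mat_tsv(expr$counts_b, "counts_b.tsv")
    mat_tsv(expr$fpkm_a, "fpkm_a.tsv")
    mat_tsv(expr$fpkm_b, "fpkm_b.tsv")
  }

  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE)
  write_table(manifest, manifest_path)
  invisible(manifest)
}

#' Verify a fixture directory against its manifest
#'
#' @param outdir directory written by [write_fixture()].
#' @return TRUE invisibly; error naming the first mismatching file
#'   otherwise.
#' @export
verify_fixture <- function(outdir) {
  manifest <- read_table(file.path(outdir, "manifest.tsv"))
  now <- unname(tools::md5sum(file.path(outdir, manifest$file)))
  bad <- which(is.na(now) | now != manifest$md5)
  if (length(bad))
    stop("checksum mismatch for ", manifest$file[bad[1]], " in ", outdir)
  invisible(TRUE)
}
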