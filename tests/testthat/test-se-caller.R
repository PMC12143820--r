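test_that("TSS-proximal filtering removes only fully contained peaks", {
  ann <- genome_annotation(data.frame(gene_id = "g1", chrom = "chr1",
                                      strand = "+", start = 10000, end = 13000))
  peaks <- make_peaks("chr1",
                      start = c(9500, 7000, 8000),
                      end   = c(10500, 9000, 12001),
                      name = c("contained", "outside", "exact"))
  kept <- filter_tss_proximal(peaks, ann, radius = 2000)
  expect_equal(kept$name, "outside")  # window [8000, 12001): exact fill filtered

  far <- make_peaks("chr9", 100, 600, name = "lonely")
  expect_equal(filter_tss_proximal(far, ann, 2000)$name, "lonely")
  expect_warning(
    out <- filter_tss_proximal(peaks, genome_annotation(
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), start = numeric(), end = numeric())),
      2000),
    "empty annotation")
  expect_equal(out, peaks)
})

test_that("stitching joins chains within the gap, inclusively at 12500", {
  peaks <- make_peaks("chr1", start = c(0, 5000, 30000),
                      end = c(1000, 6000, 31000), signal = c(1, 2, 4))
  st <- stitch_peaks(peaks, 12500)
  expect_equal(nrow(st), 2)
  expect_equal(st$n_peaks, c(2, 1))
  expect_equal(st$total_signal, c(3, 4))
  expect_equal(st$start, c(0, 30000))
  expect_equal(st$end, c(6000, 31000))

  boundary <- make_peaks("chr1", start = c(0, 13500), end = c(1000, 14000))
  expect_equal(nrow(stitch_peaks(boundary, 12500)), 1)  # gap exactly 12500
  over <- make_peaks("chr1", start = c(0, 13501), end = c(1000, 14000))
  expect_equal(nrow(stitch_peaks(over, 12500)), 2)      # one base more splits

  single <- make_peaks("chr1", 100, 900, signal = 5)
  st1 <- stitch_peaks(single, 12500)
  expect_equal(st1$start, 100)
  expect_equal(st1$end, 900)
  expect_equal(st1$total_signal, 5)
})

test_that("stitching equals connected components of the gap graph", {
  set.seed(101)
  for (i in 1:100) {
    peaks <- random_peaks(n = sample(3:40, 1))
    gap <- sample(c(500, 2000, 12500), 1)
    st <- stitch_peaks(peaks, gap)
    expect_identical(partition_from_stitched(st),
                     partition_from_labels(peaks$name,
                                           oracle_components(peaks, gap)))
    # every peak lands in exactly one stitched enhancer
    members <- unlist(strsplit(st$members, ",", fixed = TRUE))
    expect_setequal(members, peaks$name)
    expect_equal(length(members), nrow(peaks))
    expect_equal(sum(st$total_signal), sum(peaks$signal))
  }
})

test_that("ranking and min-max scaling order the curve", {
  e <- data.frame(chrom = "chr1", start = c(10, 20, 30),
                  total_signal = c(5, 1, 3))
  r <- rank_and_scale(e)
  expect_equal(r$total_signal, c(1, 3, 5))
  expect_equal(r$scaled_x, c(0, 0.5, 1))
  expect_equal(r$scaled_y, c(0, 0.5, 1))
  expect_false(attr(r, "degenerate"))

  flat <- rank_and_scale(data.frame(chrom = "chr1", start = 1:4,
                                    total_signal = rep(2, 4)))
  expect_true(attr(flat, "degenerate"))
  expect_equal(flat$scaled_y, rep(0, 4))

  one <- rank_and_scale(data.frame(chrom = "chr1", start = 1, total_signal = 9))
  expect_true(attr(one, "degenerate"))
  expect_equal(one$scaled_x, 0)
  expect_error(rank_and_scale(data.frame(chrom = character(), start = numeric(),
                                         total_signal = numeric())), "empty")
})

test_that("tangent cutoff matches the closed form on the y = x^2 grid", {
  x <- seq(0, 1, length.out = 101)
  curve <- rank_and_scale(data.frame(chrom = "chr1", start = seq_along(x),
                                     total_signal = x^2))
  cut <- tangent_cutoff(curve)
  expect_equal(curve$scaled_x[cut$tangency_rank], 0.5)  # argmin of x^2 - x
  expect_equal(cut$cutoff_signal, 0.25)
  expect_equal(sum(curve$total_signal > cut$cutoff_signal), 50)
})

test_that("a diagonal curve ties everywhere and yields zero SEs", {
  x <- seq(0, 1, length.out = 11)
  curve <- rank_and_scale(data.frame(chrom = "chr1", start = seq_along(x),
                                     total_signal = x))
  cut <- tangent_cutoff(curve)
  expect_equal(cut$tangency_rank, 11)  # highest point among ties
  expect_equal(sum(curve$total_signal > cut$cutoff_signal), 0)
})

test_that("tangent cutoff equals the supporting-line oracle on random curves", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(10:200, 1)
    curve <- rank_and_scale(data.frame(chrom = "chr1", start = seq_len(n),
                                       total_signal = sort(rlnorm(n, 0, 1))))
    cut <- tangent_cutoff(curve)
    idx <- oracle_tangency_index(curve$scaled_x, curve$scaled_y)
    expect_equal(cut$tangency_rank, idx)
    expect_equal(cut$cutoff_signal, curve$total_signal[idx])
  }
})

test_that("degenerate or tiny curves warn and call no SEs", {
  flat <- rank_and_scale(data.frame(chrom = "chr1", start = 1:5,
                                    total_signal = rep(3, 5)))
  expect_warning(cut <- tangent_cutoff(flat), "degenerate")
  expect_true(cut$no_ses)
  expect_equal(cut$cutoff_signal, Inf)
  two <- rank_and_scale(data.frame(chrom = "chr1", start = 1:2,
                                   total_signal = c(1, 2)))
  expect_warning(tangent_cutoff(two, min_points_for_cutoff = 3), "too-small")
})

test_that("SE calls are invariant to signal scaling and input order", {
  sim <- simulate_landscape(simulation_config(seed = 5, n_chrom = 2,
                                              n_genes = 100,
                                              n_background_peaks = 300,
                                              n_super_clusters = 10,
                                              n_differential_ses = 2))
  base <- call_superenhancers(sim$peaks_a, sim$annotation)
  key <- function(r) {
    e <- r$enhancers[r$enhancers$is_super, ]
    sort(paste(e$chrom, e$start, e$end))
  }
  scaled_peaks <- sim$peaks_a
  scaled_peaks$signal <- scaled_peaks$signal * 10
  expect_identical(key(call_superenhancers(scaled_peaks, sim$annotation)),
                   key(base))
  set.seed(1)
  shuffled <- sim$peaks_a[sample.int(nrow(sim$peaks_a)), ]
  expect_identical(key(call_superenhancers(shuffled, sim$annotation)),
                   key(base))
  # super + typical = all stitched enhancers
  expect_equal(sum(base$enhancers$is_super) + sum(!base$enhancers$is_super),
               nrow(base$enhancers))
})

test_that("raising an enhancer's signal never demotes it from super", {
  sim <- simulate_landscape(simulation_config(seed = 6, n_chrom = 2,
                                              n_genes = 100,
                                              n_background_peaks = 300,
                                              n_super_clusters = 8,
                                              n_differential_ses = 2))
  base <- call_superenhancers(sim$peaks_a, sim$annotation)
  e <- base$enhancers
  pick <- e[e$is_super, ][1, ]  # boost one super-enhancer further
  peaks <- sim$peaks_a
  hit <- peaks$chrom == pick$chrom & peaks$start >= pick$start &
    peaks$end <= pick$end
  peaks$signal[hit] <- peaks$signal[hit] * 3
  again <- call_superenhancers(peaks, sim$annotation)
  e2 <- again$enhancers
  expect_true(e2$is_super[e2$chrom == pick$chrom & e2$start == pick$start])
})

test_that("an all-TSS-proximal input yields zero enhancers with a warning", {
  ann <- genome_annotation(data.frame(gene_id = "g1", chrom = "chr1",
                                      strand = "+", start = 10000, end = 13000))
  peaks <- make_peaks("chr1", start = c(9000, 9500), end = c(9400, 10200))
  expect_warning(res <- call_superenhancers(peaks, ann), "no peaks left")
  expect_equal(nrow(res$enhancers), 0)
  expect_true(res$degenerate)
})

test_that("the seed-42 fixture recovers planted clusters accurately", {
  sim <- simulate_landscape(simulation_config(seed = 42))
  res <- call_superenhancers(sim$peaks_a, sim$annotation)
  called <- res$enhancers[res$enhancers$is_super, ]
  tr <- sim$truth$clusters
  hits_truth <- vapply(seq_len(nrow(called)), function(i)
    any(tr$chrom == called$chrom[i] & tr$start < called$end[i] &
          tr$end > called$start[i]), logical(1))
  recovered <- vapply(seq_len(nrow(tr)), function(i)
    any(called$chrom == tr$chrom[i] & called$start < tr$end[i] &
          called$end > tr$start[i]), logical(1))
  expect_gte(mean(hits_truth), 0.9)   # precision
  expect_gte(mean(recovered), 0.9)    # recall
})
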