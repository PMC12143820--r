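small_config <- function(seed = 3, ...) {
  simulation_config(seed = seed, n_chrom = 2, n_genes = 80,
                    n_background_peaks = 300, n_super_clusters = 6,
                    n_differential_ses = 2, ...)
}

test_that("identical seed gives identical landscapes", {
  s1 <- simulate_landscape(small_config())
  s2 <- simulate_landscape(small_config())
  expect_identical(s1$peaks_a, s2$peaks_a)
  expect_identical(s1$peaks_b, s2$peaks_b)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_landscape(small_config(seed = 4))
  expect_false(identical(s1$peaks_a, s3$peaks_a))
})

test_that("ground truth bookkeeping matches the configuration", {
  cfg <- simulation_config(seed = 10, n_chrom = 2, n_genes = 80,
                           n_background_peaks = 200, n_super_clusters = 5,
                           n_differential_ses = 4)
  sim <- simulate_landscape(cfg)
  tr <- sim$truth$clusters
  expect_equal(nrow(tr), 5)
  expect_equal(sum(tr$direction != "none"), 4)
  expect_equal(sum(tr$direction == "up"), 2)      # split evenly up/down
  expect_equal(sum(tr$direction == "down"), 2)
  expect_true(all(nzchar(tr$nearest_gene)))       # every diff SE has a gene
  expect_equal(nrow(sim$peaks_a), 200 + sum(tr$n_peaks))
  expect_identical(sim$peaks_a[, c("chrom", "start", "end")],
                   sim$peaks_b[, c("chrom", "start", "end")])
})

test_that("planted cluster gaps respect the stitching precondition", {
  sim <- simulate_landscape(small_config(seed = 12))
  for (id in sim$truth$clusters$truth_id) {
    members <- sim$peaks_a[grepl(paste0("^", id, "_"), sim$peaks_a$name), ]
    members <- members[order(members$start), ]
    if (nrow(members) > 1)
      expect_true(all(members$start[-1] - members$end[-nrow(members)] <= 12500))
  }
  # and planted clusters each stitch into a single enhancer
  st <- stitch_peaks(sim$peaks_a, 12500)
  for (id in sim$truth$clusters$truth_id) {
    tr <- sim$truth$clusters[sim$truth$clusters$truth_id == id, ]
    hit <- st[st$chrom == tr$chrom & st$start <= tr$start & st$end >= tr$end, ]
    expect_equal(nrow(hit), 1)
  }
})

test_that("differential clusters change signal in condition B as planted", {
  sim <- simulate_landscape(small_config(seed = 13))
  tr <- sim$truth$clusters
  for (i in seq_len(nrow(tr))) {
    m <- grepl(paste0("^", tr$truth_id[i], "_"), sim$peaks_a$name)
    ratio <- sum(sim$peaks_b$signal[m]) / sum(sim$peaks_a$signal[m])
    expected <- switch(tr$direction[i], up = 4, down = 0.25, none = 1)
    expect_equal(ratio, expected, tolerance = 0.25)  # condition noise is small
  }
})

test_that("expression simulation plants concordant fold changes", {
  cfg <- small_config(seed = 21)
  sim <- simulate_landscape(cfg)
  expr <- simulate_expression(sim$annotation, sim$truth, cfg)
  expect_equal(dim(expr$fpkm_a), c(80, 3))
  de <- de_analysis(expr$fpkm_a, expr$fpkm_b, rownames(expr$fpkm_a))
  planted <- merge(sim$truth$genes, de, by = "gene_id")
  expect_true(all(planted$direction.x == planted$direction.y))
  expect_error(simulate_expression(sim$annotation, sim$truth,
                                   small_config(n_replicates = 0)),
               "n_replicates")
})

test_that("planted expression effects are recovered across seeds", {
  hits_planted <- 0; hits_null <- 0
  for (s in 1:10) {
    cfg <- small_config(seed = s)
    sim <- simulate_landscape(cfg)
    expr <- simulate_expression(sim$annotation, sim$truth, cfg)
    g <- sim$truth$genes$gene_id[1]
    i <- match(g, rownames(expr$fpkm_a))
    r <- expression_differential(expr$fpkm_a[i, ], expr$fpkm_b[i, ])
    want <- sim$truth$genes$direction[1]
    ok <- if (want == "up") r$direction == "up" && r$fold_change > 2 else
      r$direction == "down" && r$fold_change < 0.5
    hits_planted <- hits_planted + ok
    null_gene <- setdiff(rownames(expr$fpkm_a), sim$truth$genes$gene_id)[1]
    j <- match(null_gene, rownames(expr$fpkm_a))
    fc <- expression_differential(expr$fpkm_a[j, ], expr$fpkm_b[j, ])$fold_change
    hits_null <- hits_null + (fc >= 0.5 && fc <= 2)
  }
  expect_gte(hits_planted, 9)
  expect_gte(hits_null, 9)
})

test_that("fixtures round-trip through standard formats with checksums", {
  cfg <- small_config(seed = 30)
  sim <- simulate_landscape(cfg)
  expr <- simulate_expression(sim$annotation, sim$truth, cfg)
  dir <- withr::local_tempdir()
  man <- write_fixture(sim, expr, dir)
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_true(all(c("genes.gtf", "peaks_a.narrowPeak", "signal_b.bedGraph",
                    "fpkm_a.tsv", "truth_clusters.tsv") %in% man$file))
  expect_silent(verify_fixture(dir))

  # the emitted files reproduce the in-memory objects
  back <- read_narrowpeak(file.path(dir, "peaks_a.narrowPeak"))
  expect_equal(back$start, sim$peaks_a$start)
  expect_equal(back$signal, sim$peaks_a$signal, tolerance = 1e-5)
  ann <- read_gtf_genes(file.path(dir, "genes.gtf"))
  expect_identical(ann$genes$gene_id, sim$annotation$genes$gene_id)
  expect_equal(ann$genes$tss, sim$annotation$genes$tss)
  # bedGraph area over a peak equals its signal
  track <- read_bedgraph(file.path(dir, "signal_a.bedGraph"))
  expect_equal(signal_over(track, sim$peaks_a$chrom[1], sim$peaks_a$start[1],
                           sim$peaks_a$end[1]),
               sim$peaks_a$signal[1], tolerance = 1e-4)

  # overwrite protection, determinism, and tamper detection
  expect_error(write_fixture(sim, expr, dir), "manifest already exists")
  man2 <- write_fixture(sim, expr, dir, overwrite = TRUE)
  expect_identical(man$md5, man2$md5)
  cat("tamper\n", file = file.path(dir, "fpkm_a.tsv"), append = TRUE)
  expect_error(verify_fixture(dir), "checksum mismatch")
})
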