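test_that("point classification follows the precedence rule", {
  ann <- toy_annotation()   # gA: chr1 [100000,130000) +, exons at 100k and 110k
  at <- function(chrom, pos, summit = NA)
    classify_peaks(make_peaks(chrom, pos - 50, pos + 50, summit = summit), ann)
  expect_equal(as.character(at("chr1", 100000)), "promoter")  # point at TSS
  expect_equal(as.character(at("chr1", 105000)), "intron")    # between exons, >2kb from TSS
  expect_equal(as.character(at("chr1", 111000)), "exon")
  expect_equal(as.character(at("chr1", 2000000)), "distal_intergenic")
  expect_equal(as.character(at("chr2", 75000)), "intron")     # gC body, no exon there
  # promoter window beats the exon it overlaps
  expect_equal(as.character(at("chr1", 101000)), "promoter")
})

test_that("summit, when present, is the classified point", {
  ann <- toy_annotation()
  # peak spans promoter and intron; summit decides
  p <- make_peaks("chr1", 99000, 109000, summit = 7000)  # point 106000: intron
  expect_equal(as.character(classify_peaks(p, ann)), "intron")
  p$summit <- 1500                                       # point 100500: promoter
  expect_equal(as.character(classify_peaks(p, ann)), "promoter")
})

test_that("class distribution counts and sums to one", {
  ann <- toy_annotation()
  peaks <- make_peaks("chr1",
                      start = c(99990, 99990, 104000, 104500, 105000,
                                5e5, 6e5, 7e5, 8e5, 9e5),
                      end   = c(100010, 100010, 104020, 104520, 105020,
                                5e5 + 20, 6e5 + 20, 7e5 + 20, 8e5 + 20, 9e5 + 20))
  d <- annotation_distribution(peaks, ann)
  expect_equal(sum(d$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(d$counts[c("promoter", "intron", "distal_intergenic")]),
               c(2L, 3L, 5L))
  expect_equal(unname(d$fractions[["promoter"]]), 0.2)
  expect_error(annotation_distribution(peaks[0, ], ann), "empty")
})

test_that("planted class proportions are recovered within binomial error", {
  ann <- toy_annotation()
  set.seed(33)
  n <- 2000
  labels <- sample(c("promoter", "exon", "intron", "distal_intergenic"), n,
                   replace = TRUE, prob = c(0.2, 0.1, 0.35, 0.35))
  pos <- vapply(labels, function(cl) switch(cl,
    promoter = round(runif(1, 98100, 101900)),
    exon = round(runif(1, 110100, 112900)),           # gA exon 2, >2kb from TSS
    intron = round(runif(1, 115000, 127000)),
    distal_intergenic = round(runif(1, 5e5, 5e6))), numeric(1))
  peaks <- make_peaks("chr1", pos - 10, pos + 10)
  d <- annotation_distribution(peaks, ann)
  expected <- c(promoter = 0.2, exon = 0.1, intron = 0.35,
                distal_intergenic = 0.35)
  expect_true(all(abs(d$fractions[names(expected)] - expected) <= 0.05))
})

test_that("nearest gene minimizes TSS distance with signed output", {
  ann <- genome_annotation(data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = "+",
    start = c(4000, 9000), end = c(6000, 9500)))
  r <- nearest_gene(data.frame(chrom = "chr1", start = 4900, end = 5100), ann)
  expect_equal(r$gene_id, "gA")
  expect_equal(r$distance, -1000)   # TSS upstream of the midpoint
  # equidistant TSSs resolve lexicographically
  mid <- (4000 + 9000) / 2
  tie <- nearest_gene(data.frame(chrom = "chr1", start = mid - 10,
                                 end = mid + 10), ann)
  expect_equal(tie$gene_id, "gA")
  # distance is 0 iff midpoint hits a TSS
  hit <- nearest_gene(data.frame(chrom = "chr1", start = 3990, end = 4010), ann)
  expect_equal(hit$distance, 0)
  expect_error(nearest_gene(data.frame(chrom = "chrX", start = 0, end = 10), ann),
               "no genes on chromosome")
})

test_that("best peak for a gene takes the highest signal in the window", {
  ann <- toy_annotation()   # gA TSS at 100000
  peaks <- make_peaks("chr1",
                      start = c(90000, 150000, 400000),
                      end = c(90400, 150400, 400400),
                      signal = c(5, 9, 100), name = c("near5", "near9", "far"))
  best <- best_peak_for_gene(ann, "gA", peaks, window = 100000)
  expect_equal(best$name, "near9")
  expect_null(best_peak_for_gene(ann, "gA", peaks[3, ], window = 100000))
  ties <- make_peaks("chr1", start = c(100, 900), end = c(300, 1100),
                     signal = 7, name = c("left", "right"))
  expect_equal(best_peak_for_gene(ann, "gA", ties, window = 100000)$name,
               "left")
  expect_error(best_peak_for_gene(ann, "nope", peaks), "unknown gene_id")
})

test_that("classification is invariant to gene order in the annotation", {
  g <- toy_annotation()$genes
  ex <- toy_annotation()$exons
  a1 <- toy_annotation()
  a2 <- genome_annotation(g[rev(seq_len(nrow(g))), ], ex)
  peaks <- make_peaks("chr1", seq(95000, 135000, by = 1000),
                      seq(95000, 135000, by = 1000) + 100)
  expect_identical(classify_peaks(peaks, a1), classify_peaks(peaks, a2))
})
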