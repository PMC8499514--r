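single_motif_genome <- function() {
  s <- paste(rep("ACGGA", 2000), collapse = "")  # motif-free 10 kb
  substr(s, 5000, 5003) <- "GTAC"
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "chr1"
  g
}

test_that("random integration sites respect the motif constraint", {
  g <- single_motif_genome()
  ris <- generate_random_is(g, n = 10, max_dist = 1500, seed = 3)
  expect_equal(nrow(ris), 10)
  expect_true(all(ris$pos >= 3500 & ris$pos <= 6503))
  expect_true(all(ris$motif_distance <= 1500))
  # determinism under a seed
  ris2 <- generate_random_is(g, n = 10, max_dist = 1500, seed = 3)
  expect_identical(ris, ris2)
  # motif-free genome is unsatisfiable
  g0 <- Biostrings::DNAStringSet(paste(rep("ACGGA", 2000), collapse = ""))
  names(g0) <- "chr1"
  expect_error(generate_random_is(g0, n = 5), "unsatisfiable")
})

genes3 <- data.frame(
  gene_id = c("G1", "G2", "G3"),
  chrom = "chr1",
  start = c(10000, 30000, 50000),
  end = c(15000, 35000, 55000),
  strand = c("+", "-", "+"),
  biotype = c("protein_coding", "lncRNA", "processed_pseudogene"),
  stringsAsFactors = FALSE)

test_that("nearest-gene annotation uses body distance with tie priority", {
  sites <- data.frame(chrom = "chr1",
                      pos = c(12000, 16200, 15800, 9000))
  ann <- annotate_nearest_gene(sites, genes3)
  expect_equal(ann$gene_distance, c(0, 1200, 800, 1000))
  expect_equal(ann$biotype_class,
               c("protein_coding", "distal", "protein_coding",
                 "protein_coding"))
  # nearest wins regardless of biotype
  sites2 <- data.frame(chrom = "chr1", pos = 29200)  # 800 from G2 lncRNA
  expect_equal(annotate_nearest_gene(sites2, genes3)$biotype_class, "lncRNA")
  # exact tie: protein_coding outranks lncRNA
  gtie <- data.frame(gene_id = c("A", "B"), chrom = "chr1",
                     start = c(100, 1100), end = c(400, 1400),
                     strand = "+", biotype = c("lncRNA", "protein_coding"))
  tie_site <- data.frame(chrom = "chr1", pos = 750)  # 350 from both
  expect_equal(annotate_nearest_gene(tie_site, gtie)$nearest_gene, "B")
  # pseudogene biotype collapses to "other"
  s3 <- data.frame(chrom = "chr1", pos = 52000)
  expect_equal(annotate_nearest_gene(s3, genes3)$biotype_class, "other")
})

test_that("activity classification is strict at the FPKM threshold", {
  sites <- data.frame(chrom = "chr1", pos = c(12000, 32000, 16200))
  ann <- annotate_nearest_gene(sites, genes3)
  fpkm <- data.frame(gene_id = c("G1", "G2", "G3"), fpkm = c(1.0, 7.3, 0))
  ann <- classify_activity(ann, fpkm)
  expect_equal(ann$active, c(FALSE, TRUE, NA))  # FPKM 1.0 is NOT active
})

test_that("peak distances are zero inside and edge-measured outside", {
  peaks <- data.frame(chrom = "chr1", start = c(2000, 8000),
                      end = c(2500, 8400))
  sites <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      pos = c(2200, 1500, 5000, 100))
  d <- peak_distance(sites, peaks)
  expect_equal(d, c(0, 500, 2500, NA))
  dl <- peak_distance(sites, list(F1 = peaks, F2 = peaks[1, ]))
  expect_equal(dim(dl), c(4L, 2L))
  expect_equal(unname(dl[, "F1"]), d)
  # center mode measures to the midpoint
  dc <- peak_distance(sites[1, , drop = FALSE], peaks, mode = "center")
  expect_equal(dc, 50)  # midpoint 2250
})

test_that("distance histograms bin within the window and conserve counts", {
  h <- bin_by_distance(c(0, 0, 950), bin_width = 100, max_dist = 1000)
  expect_equal(unname(h[1]), 2L)
  expect_equal(unname(h[10]), 1L)
  expect_equal(sum(h), 3L)
  expect_equal(sum(bin_by_distance(c(1500, 2000))), 0L)
  d <- c(0, 50, 120, 999, 1000, 1001, NA)
  expect_equal(sum(bin_by_distance(d)), sum(!is.na(d) & d <= 1000))
})

test_that("Yates chi-squared matches the printed formula and stats oracle", {
  expect_equal(chisq_yates(50, 50, 50, 50)$statistic, 0)
  expect_equal(chisq_yates(50, 50, 50, 50)$p_value, 1)
  # VIS vs random proximity tables reject decisively
  expect_lt(chisq_yates(486, 411, 116, 884)$p_value, 0.001)
  expect_lt(chisq_yates(694, 203, 270, 730)$p_value, 0.001)
  # hand evaluation of the formula
  a <- 694; b <- 203; c <- 270; d <- 730; N <- a + b + c + d
  stat <- N * (abs(a * d - b * c) - N / 2)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(chisq_yates(a, b, c, d)$statistic, stat)
  expect_error(chisq_yates(0, 0, 3, 4), "degenerate")
})

test_that("coverage matrices bin tracks around anchors", {
  track <- data.frame(chrom = "chr1", start = 1, end = 20000, score = 3.5)
  anchors <- data.frame(chrom = "chr1", pos = c(10000, 300))
  m <- coverage_matrix(anchors, track, flank = 1000, n_bins = 20)
  expect_equal(dim(m), c(2L, 20L))
  expect_true(all(abs(m[1, ] - 3.5) < 1e-9))
  expect_equal(attr(m, "clipped"), c(FALSE, TRUE))
  expect_true(all(m[2, 1:5] == 0))  # off-chromosome bins are zero

  # delta peak at the anchor: center bins maximal, symmetric decay
  delta <- data.frame(chrom = "chr1", start = 9990, end = 10010, score = 10)
  md <- coverage_matrix(anchors[1, , drop = FALSE], delta, flank = 1000,
                        n_bins = 20)
  expect_equal(which.max(colMeans(md)), 10, tolerance = 1)
  expect_true(md[1, 1] == 0 && md[1, 20] == 0)
})

test_that("scale-regions matrices run 5' to 3' on the gene strand", {
  # signal only over the first half of a plus-strand gene body
  track <- data.frame(chrom = "chr1", start = 5000, end = 7500, score = 2)
  plus <- data.frame(chrom = "chr1", start = 5000, end = 10000,
                     strand = "+")
  minus <- data.frame(chrom = "chr1", start = 5000, end = 10000,
                      strand = "-")
  mp <- coverage_matrix(plus, track, mode = "scale_regions",
                        body_bins = 10, flank_bins = 2)
  mm <- coverage_matrix(minus, track, mode = "scale_regions",
                        body_bins = 10, flank_bins = 2)
  body_p <- mp[1, 3:12]; body_m <- mm[1, 3:12]
  expect_gt(mean(body_p[1:5]), mean(body_p[6:10]))  # 5' half hot for +
  expect_gt(mean(body_m[6:10]), mean(body_m[1:5]))  # mirrored for -
})

test_that("feature projection separates a planted coverage signal", {
  set.seed(9)
  base <- matrix(runif(200, 0, 0.2), 20, 10)
  feats <- list(A = base + matrix(runif(200, 0, 0.1), 20),
                B = base + matrix(runif(200, 0, 0.1), 20),
                C = base + matrix(runif(200, 0, 0.1), 20),
                planted = base + 5)
  pc <- coverage_pca(feats)
  d <- as.matrix(dist(pc$scores[, 1:2]))
  expect_gt(min(d["planted", c("A", "B", "C")]),
            3 * max(d[c("A", "B", "C"), c("A", "B", "C")]))
  expect_equal(sum(pc$var_explained), 1)
})
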