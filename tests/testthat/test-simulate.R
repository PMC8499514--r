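test_that("motif density in the synthetic genome follows its Poisson rate", {
  cfg <- sim_config(seed = 5, genome_length = 1e6, n_chromosomes = 1L,
                    motif_rate = 1, n_genes = 0L)
  ref <- make_reference(cfg)
  n_motif <- sum(vapply(ref$motifs, nrow, integer(1)))
  expect_lt(abs(n_motif - 1000), 5 * sqrt(1000))
})

test_that("a gene-free reference yields only distal context calls", {
  cfg <- sim_config(seed = 5, genome_length = 2e5, n_chromosomes = 1L,
                    n_genes = 0L,
                    bias_weights = c(h3k36me3 = 0, gene_body = 0, tss = 0,
                                     intergenic = 1))
  ref <- make_reference(cfg)
  expect_equal(nrow(ref$genes), 0)
  sites <- data.frame(chrom = "chr1", pos = c(1000, 50000))
  ann <- annotate_nearest_gene(sites, ref$genes)
  expect_true(all(ann$biotype_class == "distal"))
})

test_that("identical seeds reproduce the fixture byte-for-byte", {
  cfg <- sim_config(seed = 8, genome_length = 1e5, n_chromosomes = 1L,
                    n_genes = 20L, n_clones = 10L, depth = 200L)
  f1 <- list(config = cfg, reference = make_reference(cfg))
  f1$truth <- simulate_clones(f1$reference, cfg)
  f1$reads <- simulate_reads(f1$truth, f1$reference, cfg)
  f2 <- list(config = cfg, reference = make_reference(cfg))
  f2$truth <- simulate_clones(f2$reference, cfg)
  f2$reads <- simulate_reads(f2$truth, f2$reference, cfg)
  expect_identical(as.character(f1$reference$genome),
                   as.character(f2$reference$genome))
  expect_identical(f1$truth$clones, f2$truth$clones)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  write_fixture(f1, d1); write_fixture(f2, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, files))),
                   unname(tools::md5sum(file.path(d2, files))))
})

test_that("emitted files round-trip through standard-format readers", {
  cfg <- sim_config(seed = 8, genome_length = 1e5, n_chromosomes = 1L,
                    n_genes = 20L, n_clones = 10L, depth = 200L)
  fx <- list(config = cfg, reference = make_reference(cfg))
  fx$truth <- simulate_clones(fx$reference, cfg)
  fx$reads <- simulate_reads(fx$truth, fx$reference, cfg)
  dir <- file.path(tempdir(), "fx_rt")
  write_fixture(fx, dir)

  g <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(g[[1]]),
                   as.character(fx$reference$genome[[1]]))
  genes <- read_gene_models(file.path(dir, "genes.gtf"))
  expect_setequal(genes$gene_id, fx$reference$genes$gene_id)
  expect_equal(genes$start[order(genes$gene_id)],
               fx$reference$genes$start[order(fx$reference$genes$gene_id)])
  peaks <- read_peak_sets(file.path(dir, "peaks"))
  expect_setequal(names(peaks), names(fx$reference$peaks))
  expect_equal(peaks$H3K36me3$start, fx$reference$peaks$H3K36me3$start)
  cov <- rtracklayer::import(file.path(dir, "coverage", "ATAC.bedGraph"),
                             format = "bedGraph")
  expect_gt(length(cov), 0)
  sid <- fx$truth$samples$sample_id[1]
  fq <- Biostrings::readDNAStringSet(
    file.path(dir, "reads", paste0(sid, ".fastq")), format = "fastq")
  expect_equal(length(fq), length(fx$reads$reads[[sid]]))
})

test_that("integration bias weights control site placement", {
  cfg <- sim_config(seed = 13, genome_length = 5e5, n_chromosomes = 1L,
                    n_genes = 60L, n_clones = 40L,
                    bias_weights = c(h3k36me3 = 1, gene_body = 0, tss = 0,
                                     intergenic = 0))
  ref <- make_reference(cfg)
  truth <- simulate_clones(ref, cfg)
  d <- peak_distance(truth$clones, ref$peaks$H3K36me3)
  expect_true(all(d == 0))
  # every clone respects the assay recoverability constraint
  md <- with(truth$clones,
             vistrackr:::motif_distance(chrom, pos, ref$motifs))
  expect_true(all(md <= 1500))
})

test_that("degenerate clonal configurations behave analytically", {
  cfg <- sim_config(seed = 13, genome_length = 1e5, n_chromosomes = 1L,
                    n_genes = 10L, n_clones = 1L, collision_clones = 0L,
                    depth = 100L)
  ref <- make_reference(cfg)
  truth <- simulate_clones(ref, cfg)
  expect_true(all(truth$freq == 1))
  dp <- diversity_profile(matrix(100L, 1, 1))
  expect_true(all(dp$H == 0))
  # depth 0 gives empty read sets
  cfg0 <- sim_config(seed = 13, genome_length = 1e5, n_chromosomes = 1L,
                     n_genes = 10L, n_clones = 5L, collision_clones = 0L,
                     depth = 0L)
  ref0 <- make_reference(cfg0)
  truth0 <- simulate_clones(ref0, cfg0)
  rd0 <- simulate_reads(truth0, ref0, cfg0)
  expect_true(all(vapply(rd0$reads, length, integer(1)) == 0))
})

test_that("true frequencies are proper distributions per sample", {
  fx <- small_fixture()
  expect_true(all(abs(colSums(fx$truth$freq) - 1) < 1e-9))
  expect_true(all(fx$truth$freq >= 0))
  # every read name traces to a clone
  rn <- names(fx$reads$reads[[1]])
  cid <- sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", rn)
  expect_true(all(cid %in% fx$truth$clones$clone_id))
})

test_that("index hopping is absorbed by crossover correction", {
  cfg <- small_config(hop_rate = 0.05, collision_clones = 0L)
  ref <- make_reference(cfg)
  truth <- simulate_clones(ref, cfg)
  rd <- simulate_reads(truth, ref, cfg)
  res <- run_vis_pipeline(rd$reads, ref$genome, truth$samples)
  cols <- truth$samples$animal == cfg$animal
  tot <- rowSums(rd$realized[, cols, drop = FALSE])
  tk <- paste(truth$clones$chrom, truth$clones$pos, truth$clones$strand,
              truth$clones$index_label, sep = ":")
  expect_setequal(site_key(res$matrix), tk[tot >= sum(cols)])
  # raw matrix does contain hopped minor labels before correction
  expect_gt(nrow(res$raw$sites), nrow(res$matrix$sites))
})

test_that("endpoint tissue samples support cross-tissue sharing analysis", {
  cfg <- small_config(tissues_at_endpoint = TRUE, collision_clones = 0L)
  ref <- make_reference(cfg)
  truth <- simulate_clones(ref, cfg)
  expect_setequal(unique(truth$samples$tissue), c("blood", "BM", "spleen"))
  keys <- paste(truth$clones$chrom, truth$clones$pos, sep = ":")
  last <- max(truth$samples$timepoint)
  sets <- lapply(c("blood", "spleen", "BM"), function(tis) {
    j <- which(truth$samples$tissue == tis &
                 truth$samples$timepoint == last)[1]
    keys[truth$freq[, j] > 0]
  })
  names(sets) <- c("blood", "spleen", "BM")
  sh <- sharing_matrix(sets)
  expect_true(all(diag(sh$percent) == 100))
  expect_equal(sh$shared["blood", "spleen"], sh$shared["spleen", "blood"])
  # clones present everywhere in truth: full sharing
  expect_gt(sh$percent["blood", "BM"], 99)
})
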