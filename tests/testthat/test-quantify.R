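samples2 <- data.frame(sample_id = c("s1", "s2"), animal = "m1",
                       timepoint = c(13, 13), tissue = "blood",
                       replicate = c(1, 2), population = "mixed",
                       stringsAsFactors = FALSE)

mk_calls <- function(pos, sample_id = "s1", chrom = "chr1", strand = "+",
                     label = "H5") {
  if (length(pos) == 0)
    return(data.frame(read_id = character(), sample_id = character(),
                      status = character(), index_label = character(),
                      chrom = character(), pos = integer(),
                      strand = character(), identity = numeric(),
                      matched_len = integer(), stringsAsFactors = FALSE))
  data.frame(read_id = paste0("r", seq_along(pos)), sample_id = sample_id,
             status = "accepted", index_label = label, chrom = chrom,
             pos = pos, strand = strand, identity = 1,
             matched_len = 40, stringsAsFactors = FALSE)
}

mk_matrix <- function(counts, labels = NULL, pos = NULL, strand = "+",
                      samples = samples2) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  sites <- data.frame(
    chrom = "chr1",
    pos = if (is.null(pos)) seq(1000, by = 1000, length.out = n) else pos,
    strand = strand,
    index_label = if (is.null(labels)) rep("H5", n) else labels,
    stringsAsFactors = FALSE)
  clonal_matrix(sites, samples, counts)
}

test_that("nearby read positions merge to the modal site", {
  cm <- aggregate_sites(mk_calls(c(1000, 1002, 1000)), samples2,
                        merge_window = 5)
  expect_equal(nrow(cm$sites), 1)
  expect_equal(cm$sites$pos, 1000)
  expect_equal(sum(cm$counts), 3)

  cm2 <- aggregate_sites(mk_calls(c(1000, 1010)), samples2, merge_window = 5)
  expect_equal(cm2$sites$pos, c(1000, 1010))

  # opposite strands never merge
  calls <- rbind(mk_calls(1000, strand = "+"), mk_calls(1000, strand = "-"))
  expect_equal(nrow(aggregate_sites(calls, samples2)$sites), 2)

  # modal tie breaks toward the smallest position
  cm3 <- aggregate_sites(mk_calls(c(1000, 1000, 1003, 1003)), samples2)
  expect_equal(cm3$sites$pos, 1000)

  expect_equal(nrow(aggregate_sites(mk_calls(integer(0)), samples2)$sites), 0)
})

test_that("signal crossover folds dominated minor labels into the major", {
  m <- mk_matrix(rbind(c(300, 200), c(2, 1)), labels = c("H5", "WT"),
                 pos = c(5000, 5000))
  out <- correct_signal_crossover(m, ratio = 0.1)
  expect_equal(nrow(out$sites), 1)
  expect_equal(out$sites$index_label, "H5")
  expect_equal(unname(out$counts[1, ]), c(302, 201))

  # comparable counts: both kept
  m2 <- mk_matrix(rbind(c(150, 150), c(100, 100)), labels = c("H5", "WT"),
                  pos = c(5000, 5000))
  expect_equal(nrow(correct_signal_crossover(m2)$sites), 2)

  # single label untouched
  m3 <- mk_matrix(rbind(c(10, 10)))
  expect_identical(correct_signal_crossover(m3)$counts, m3$counts)
})

test_that("collision correction keeps dominant-animal sites only", {
  s <- data.frame(sample_id = c("a1", "b1"), animal = c("A", "B"),
                  timepoint = 13, tissue = "blood", replicate = 1,
                  population = "mixed", stringsAsFactors = FALSE)
  m <- mk_matrix(rbind(c(400, 5), c(100, 90), c(50, 0)), samples = s)
  out <- correct_collisions(m, ratio = 0.1)
  k <- site_key(out)
  # dominant site kept in A only
  expect_equal(unname(out$counts[k == site_key(m)[1], ]), c(400, 0))
  # no dominance: removed from both
  expect_false(site_key(m)[2] %in% k)
  # single-animal site untouched
  expect_equal(unname(out$counts[k == site_key(m)[3], ]), c(50, 0))
})

test_that("minimum-count filter is strict and idempotent", {
  m <- mk_matrix(rbind(c(1, 2), c(2, 2), c(0, 1)))
  out <- filter_min_count(m, n_samples = 4)
  expect_equal(nrow(out$sites), 1)        # total 3 < 4 removed, 4 >= 4 kept
  expect_equal(sum(out$counts), 4)
  out1 <- filter_min_count(m, n_samples = 1)
  expect_equal(nrow(out1$sites), 3)       # only zero-total sites removed
  expect_error(filter_min_count(m, n_samples = 0), "invalid sample count")
  twice <- filter_min_count(filter_min_count(m))
  expect_identical(twice$counts, filter_min_count(m)$counts)
})

test_that("corrections never increase the total read count", {
  res <- small_pipeline()
  expect_lte(sum(res$matrix$counts), sum(res$raw$counts))
})

test_that("frequencies are proportional abundances summing to one", {
  m <- mk_matrix(cbind(c(10, 30, 60), c(1, 1, 2)))
  fp <- compute_frequencies(m)
  expect_equal(unname(fp$p[, 1]), c(0.1, 0.3, 0.6))
  expect_equal(colSums(fp$p), c(s1 = 1, s2 = 1), tolerance = 1e-9)
  m1 <- mk_matrix(cbind(c(5, 0, 0), c(1, 1, 2)))
  expect_equal(unname(compute_frequencies(m1)$p[1, 1]), 1.0)
  m0 <- mk_matrix(cbind(c(0, 0, 0), c(1, 1, 2)))
  fp0 <- compute_frequencies(m0)
  expect_equal(unname(fp0$p[, 1]), c(0, 0, 0))
  expect_equal(fp0$empty_samples, "s1")
})

test_that("replicate merging sums counts or averages frequencies", {
  m <- mk_matrix(cbind(c(10, 0), c(0, 10)))
  mc <- merge_replicates(m, "sum_counts")
  expect_equal(ncol(mc$counts), 1)
  expect_equal(unname(mc$counts[, 1]), c(10, 10))

  m2 <- mk_matrix(cbind(c(20, 80), c(10, 40)))
  fp <- merge_replicates(m2, "mean_frequency")
  expect_equal(unname(fp$p[, 1]), c(0.2, 0.8))  # identical profiles

  # one empty replicate: sum equals the other replicate
  m3 <- mk_matrix(cbind(c(3, 7), c(0, 0)))
  expect_equal(unname(merge_replicates(m3, "sum_counts")$counts[, 1]),
               c(3, 7))
  s_bad <- samples2; s_bad$replicate[2] <- NA
  m_bad <- mk_matrix(cbind(c(1, 1), c(1, 1)), samples = s_bad)
  expect_error(merge_replicates(m_bad, "sum_counts"), "s2")
})

test_that("estimated frequencies track simulated truth (r >= 0.9)", {
  fx <- small_fixture()
  res <- small_pipeline()
  tk <- truth_site_keys(fx)
  rec <- site_key(res$matrix)
  mm <- match(rec, tk)
  expect_true(all(!is.na(mm)))
  fp <- res$frequencies
  m1 <- which(fp$samples$animal == fx$config$animal)
  rs <- vapply(m1, function(j)
    cor(fp$p[, j], fx$truth$freq[mm, fp$samples$sample_id[j]]), 0)
  expect_true(all(rs >= 0.9))
})

test_that("injected crossover and collisions are removed on fixtures", {
  fx <- small_fixture()  # hop_rate 0.01 < ratio 0.1; 3 collision clones
  res <- small_pipeline()
  expect_setequal(site_key(res$matrix), expected_recovered_keys(fx))
  # collision clones survive only in the dominant animal
  coll <- fx$truth$clones[fx$truth$clones$collision, ]
  ck <- paste(coll$chrom, coll$pos, coll$strand, coll$index_label, sep = ":")
  other <- res$matrix$samples$animal != fx$config$animal
  expect_true(all(res$matrix$counts[match(ck, site_key(res$matrix)),
                                    other] == 0))
})
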