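# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small, fast fixture: 0.4 Mb genome, 60 clones, 50 reads/clone on average
small_config <- function(...) {
  args <- list(seed = 42L, genome_length = 4e5, n_chromosomes = 2L,
               n_genes = 40L, n_clones = 60L, depth = 3000L)
  over <- list(...)
  do.call(sim_config, c(over, args[setdiff(names(args), names(over))]))
}

small_fixture <- function() memo("small", {
  cfg <- small_config()
  ref <- make_reference(cfg)
  truth <- simulate_clones(ref, cfg)
  reads <- simulate_reads(truth, ref, cfg)
  list(config = cfg, reference = ref, truth = truth, reads = reads)
})

small_pipeline <- function() memo("small_pipe", {
  fx <- small_fixture()
  run_vis_pipeline(fx$reads$reads, fx$reference$genome, fx$truth$samples)
})

# the canonical full-scale fixture (2 Mb, 300 clones, ~152k reads)
full_fixture <- function() memo("full", default_fixture(seed = 1L))

full_pipeline <- function() memo("full_pipe", {
  fx <- full_fixture()
  run_vis_pipeline(fx$reads$reads, fx$reference$genome, fx$truth$samples)
})

truth_site_keys <- function(fx) {
  cl <- fx$truth$clones
  paste(cl$chrom, cl$pos, cl$strand, cl$index_label, sep = ":")
}

# truth site set after applying the published per-animal count filter to the
# true emitted read counts (sampling dropout is not pipeline error)
expected_recovered_keys <- function(fx) {
  cols <- fx$truth$samples$animal == fx$config$animal
  tot <- rowSums(fx$reads$realized[, cols, drop = FALSE])
  truth_site_keys(fx)[tot >= sum(cols)]
}

# a tiny deterministic genome with a single planted locus layout
toy_genome <- function(len = 10000L, seed = 7L) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
  names(g) <- "chr1"
  g
}

# assemble a perfect junction read for a clone at (chrom, pos, strand)
toy_read <- function(genome, chrom, pos, strand = "+", label = "H1",
                     host_len = 30L) {
  idx <- default_ltr_indexes()
  chr <- genome[[chrom]]
  host <- if (strand == "+") {
    as.character(Biostrings::subseq(chr, pos, pos + host_len - 1L))
  } else {
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(chr, pos - host_len + 1L, pos)))
  }
  paste0(default_ltr_anchor(), idx[[label]], host)
}

flip_base <- function(b) unname(c(A = "C", C = "G", G = "T", T = "A")[b])

# sort-based quartile oracle: linear interpolation between order statistics
quartile_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# two-way ANOVA mean squares via stats::aov (independent of the package's
# explicit sum-of-squares computation)
aov_mean_squares <- function(m) {
  df <- data.frame(y = as.vector(m),
                   row = factor(as.vector(row(m))),
                   col = factor(as.vector(col(m))))
  a <- anova(stats::aov(y ~ row + col, data = df))
  list(ms_r = a["row", "Mean Sq"], ms_c = a["col", "Mean Sq"],
       ms_e = a["Residuals", "Mean Sq"])
}
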