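#' Simulation configuration
#'
#' Bundles every knob of the synthetic assay: a random genome with a
#' controlled density of CviQI/RsaI (GTAC) motifs, non-overlapping genes
#' with biotypes and log-normal expression, chromatin-feature peaks placed
#' relative to gene bodies and TSSs, a clonal population with configurable
#' integration bias, longitudinal abundance drift, and junction-read
#' sequencing with substitution error, LTR-index hopping, cross-animal
#' collisions and negative-binomial amplification overdispersion (the
#' whole-genome-amplification noise model).
#'
#' Defaults describe the canonical fixture: a 2 Mb two-chromosome genome,
#' 300 clones in one animal, blood sampled at weeks 13/15/17/19 in MDA
#' duplicates (8 samples), 19,000 reads per sample (~152k reads).
#'
#' @param seed integer seed; every downstream draw is reproducible from it.
#' @param genome_length total genome length in bp.
#' @param n_chromosomes number of chromosomes (equal sizes).
#' @param motif_rate motif density per kb (Poisson-planted; the background
#'   is scrubbed of incidental occurrences so the density is controlled).
#' @param n_genes number of non-overlapping genes.
#' @param biotype_mix named probabilities for protein_coding / lncRNA /
#'   other.
#' @param fpkm_meanlog,fpkm_sdlog log-normal expression parameters (FPKM;
#'   meanlog 0 puts ~50% of genes above the FPKM > 1 activity cutoff).
#' @param gene_len_meanlog,gene_len_sdlog log-normal gene length (bp).
#' @param n_clones number of integrated clones.
#' @param bias_weights named probabilities for integration placement:
#'   `h3k36me3` (inside an H3K36me3 peak), `gene_body`, `tss`
#'   (within 500 bp of a TSS), `intergenic`.
#' @param p_wt probability a clone carries the WT (anti-HIV vector) index;
#'   the rest carry H5 (control vector).
#' @param abundance_sdlog log-normal spread of initial clone abundances.
#' @param drift_sdlog per-timepoint multiplicative log-normal drift of
#'   clone abundances (what makes bands/persistence structure).
#' @param timepoints tracked weeks post-transplant.
#' @param n_replicates MDA replicates per timepoint.
#' @param tissues_at_endpoint also emit spleen and BM samples at the final
#'   timepoint (single replicate each).
#' @param depth reads per sample.
#' @param nb_dispersion negative-binomial size parameter for per-clone read
#'   counts (amplification overdispersion; larger = closer to Poisson).
#' @param host_len host bases carried by each junction read.
#' @param error_rate per-base substitution sequencing error rate.
#' @param hop_rate LTR-index hopping rate per read.
#' @param collision_clones number of top clones copied into a second animal
#'   at low count (0 disables the collision channel).
#' @param collision_depth reads per collision-animal sample.
#' @param animal primary animal id.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6, n_chromosomes = 2L,
                       motif_rate = 2,
                       n_genes = 150L,
                       biotype_mix = c(protein_coding = 0.7, lncRNA = 0.15,
                                       other = 0.15),
                       fpkm_meanlog = 0, fpkm_sdlog = 1.5,
                       gene_len_meanlog = log(5000), gene_len_sdlog = 0.5,
                       n_clones = 300L,
                       bias_weights = c(h3k36me3 = 0.5, gene_body = 0.3,
                                        tss = 0.05, intergenic = 0.15),
                       p_wt = 0.12,
                       abundance_sdlog = 1.2, drift_sdlog = 0.35,
                       timepoints = c(13, 15, 17, 19), n_replicates = 2L,
                       tissues_at_endpoint = FALSE,
                       depth = 19000L, nb_dispersion = 30,
                       host_len = 40L, error_rate = 0.002,
                       hop_rate = 0.01,
                       collision_clones = 3L, collision_depth = 60L,
                       animal = "m1") {
  cfg <- as.list(environment())
  stopifnot(cfg$error_rate >= 0, cfg$error_rate <= 1,
            cfg$hop_rate >= 0, cfg$hop_rate <= 1,
            abs(sum(bias_weights) - 1) < 1e-8,
            abs(sum(biotype_mix) - 1) < 1e-8)
  structure(cfg, class = "sim_config")
}

#' Generate the synthetic reference: genome, genes, expression, peaks,
#' coverage
#'
#' The genome is uniform-random DNA scrubbed of incidental GTAC occurrences
#' and re-seeded with Poisson-planted GTAC motifs at `motif_rate`/kb, so the
#' restriction-motif density is a controlled quantity. Genes are
#' non-overlapping with biotypes and log-normal FPKM. Peaks mimic the
#' canonical epigenomic layout: H3K36me3/H3K79me2 inside active gene bodies,
#' H3K4me3/H3K9ac/H3K9cr/H3K27ac/RNApolII/ATAC at active TSSs, H3K4me1 at
#' enhancer-like offsets, H3K27me3 over inactive gene bodies. Coverage
#' tracks are peak-consistent (elevated inside peaks, baseline elsewhere).
#'
#' @param config a [sim_config].
#' @return list of class `sim_reference`: `genome` (DNAStringSet), `genes`
#'   (data.frame gene_id/chrom/start/end/strand/biotype/fpkm), `peaks`
#'   (named list of interval data.frames), `coverage` (named list of
#'   bedGraph-style data.frames), `motifs` (per-chromosome motif intervals).
#' @export
make_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  chr_len <- rep(floor(config$genome_length / config$n_chromosomes),
                 config$n_chromosomes)
  chr_names <- paste0("chr", seq_len(config$n_chromosomes))

  seqs <- lapply(chr_len, function(len) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    s <- scrub_motif(s, "GTAC")
    n_plant <- rpois(1, config$motif_rate * len / 1000)
    if (n_plant > 0) {
      at <- sort(sample.int(len - 4L, n_plant))
      for (p in at) s[p:(p + 3L)] <- c("G", "T", "A", "C")
    }
    paste(s, collapse = "")
  })
  genome <- DNAStringSet(unlist(seqs))
  names(genome) <- chr_names

  genes <- place_genes(chr_names, chr_len, config)
  peaks <- place_peaks(genes, chr_len, chr_names)
  coverage <- lapply(peaks, function(p)
    peak_coverage_track(p, chr_names, chr_len))

  structure(list(genome = genome, genes = genes, peaks = peaks,
                 coverage = coverage,
                 motifs = motif_positions(genome, "GTAC"),
                 chr_len = setNames(chr_len, chr_names)),
            class = "sim_reference")
}

# destroy every occurrence of the motif in a character-vector sequence by
# mutating its third base (A -> C cannot recreate GTAC across the edit)
scrub_motif <- function(s, motif) {
  seq_str <- paste(s, collapse = "")
  hits <- start(matchPattern(DNAString(motif), DNAString(seq_str)))
  if (length(hits)) s[hits + 2L] <- "C"
  s
}

place_genes <- function(chr_names, chr_len, config) {
  n <- config$n_genes
  if (n == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), biotype = character(),
                      fpkm = numeric()))
  per_chr <- diff(floor(seq(0, n, length.out = length(chr_names) + 1)))
  rows <- list()
  gid <- 0L
  for (k in seq_along(chr_names)) {
    nk <- per_chr[k]
    if (nk == 0) next
    slot <- floor(chr_len[k] / nk)
    for (j in seq_len(nk)) {
      gid <- gid + 1L
      len <- min(round(rlnorm(1, config$gene_len_meanlog,
                              config$gene_len_sdlog)),
                 slot - 200L)
      len <- max(len, 300L)
      lo <- (j - 1L) * slot + 1L
      start <- lo + sample.int(max(slot - len - 100L, 1L), 1L)
      rows[[gid]] <- data.frame(
        gene_id = sprintf("G%04d", gid), chrom = chr_names[k],
        start = start, end = start + len - 1L,
        strand = sample(c("+", "-"), 1L),
        biotype = sample(names(config$biotype_mix), 1L,
                         prob = config$biotype_mix),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  genes$fpkm <- rlnorm(nrow(genes), config$fpkm_meanlog, config$fpkm_sdlog)
  genes
}

place_peaks <- function(genes, chr_len, chr_names) {
  feats <- c("ATAC", "H3K4me3", "H3K9ac", "H3K9cr", "H3K27ac", "H3K4me1",
             "H3K79me2", "H3K36me3", "H3K27me3", "RNApolII")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  peaks <- setNames(rep(list(empty), length(feats)), feats)
  if (nrow(genes) == 0) return(peaks)
  active <- genes$fpkm > 1
  tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  lim <- setNames(chr_len, chr_names)

  body_peaks <- function(g, width) {
    if (nrow(g) == 0) return(empty)
    s <- mapply(function(a, b) a + sample.int(max(b - a - width, 1L), 1L),
                g$start, g$end)
    clip_intervals(data.frame(chrom = g$chrom, start = s,
                              end = pmin(s + width - 1L, g$end)), lim)
  }
  tss_peaks <- function(which_genes, width, offset_sd = 100) {
    if (!any(which_genes)) return(empty)
    ctr <- round(tss[which_genes] + rnorm(sum(which_genes), 0, offset_sd))
    clip_intervals(data.frame(chrom = genes$chrom[which_genes],
                              start = ctr - floor(width / 2),
                              end = ctr + floor(width / 2)), lim)
  }

  peaks$H3K36me3 <- body_peaks(genes[active, ], 800L)
  peaks$H3K79me2 <- body_peaks(genes[active, ], 600L)
  peaks$H3K27me3 <- body_peaks(genes[!active, ], 1000L)
  peaks$H3K4me3 <- tss_peaks(active, 500L)
  peaks$ATAC <- tss_peaks(active, 300L)
  peaks$H3K9ac <- tss_peaks(active, 400L)
  peaks$H3K9cr <- tss_peaks(active, 400L)
  peaks$H3K27ac <- tss_peaks(active, 400L)
  peaks$RNApolII <- tss_peaks(active, 300L)
  # enhancer-like: offset a few kb from active TSSs
  enh_ctr <- round(tss[active] + sample(c(-1, 1), sum(active), TRUE) *
                     runif(sum(active), 2000, 8000))
  peaks$H3K4me1 <- clip_intervals(
    data.frame(chrom = genes$chrom[active], start = enh_ctr - 250L,
               end = enh_ctr + 250L), lim)
  lapply(peaks, merge_intervals)
}

clip_intervals <- function(df, lim) {
  df$start <- pmax(as.integer(df$start), 1L)
  df$end <- pmin(as.integer(df$end), lim[df$chrom])
  df <- df[df$start <= df$end, , drop = FALSE]
  rownames(df) <- NULL
  df
}

merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  gr <- reduce(GRanges(df$chrom, IRanges(df$start, df$end)))
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr), stringsAsFactors = FALSE)
}

# bedGraph-style track consistent with a peak set: baseline 0.5 outside
# peaks, 5.0 inside
peak_coverage_track <- function(peaks, chr_names, chr_len) {
  rows <- list()
  for (k in seq_along(chr_names)) {
    cn <- chr_names[k]
    p <- peaks[peaks$chrom == cn, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    bounds <- c(1L, as.vector(rbind(p$start, p$end + 1L)), chr_len[k] + 1L)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1] - 1L
    score <- rep(c(0.5, 5.0), length.out = length(starts))
    ok <- starts <= ends
    rows[[k]] <- data.frame(chrom = cn, start = starts[ok], end = ends[ok],
                            score = score[ok], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the clonal population with known truth
#'
#' Draws `n_clones` integration sites per the configured bias weights (every
#' site respects the GTAC recoverability constraint: within 1500 bp of a
#' motif, as the assay requires), assigns each clone an LTR index, draws
#' initial abundances log-normally and evolves them across timepoints by a
#' multiplicative log-normal random walk so a minority of clones expand --
#' creating the band/persistence structure a real repopulation shows.
#'
#' @param reference a `sim_reference` from [make_reference].
#' @param config the same [sim_config].
#' @return list of class `sim_truth`: `clones` (clone_id, chrom, pos,
#'   strand, index_label, animal, category), `samples` (sample sheet),
#'   `freq` (clone x sample true frequency matrix, columns sum to 1).
#' @export
simulate_clones <- function(reference, config = sim_config()) {
  set.seed(config$seed + 1L)
  genes <- reference$genes
  sites <- draw_clone_sites(reference, config)
  n <- nrow(sites)
  sites$clone_id <- sprintf("C%04d", seq_len(n))
  sites$index_label <- ifelse(runif(n) < config$p_wt, "WT", "H5")
  sites$animal <- config$animal

  base <- rlnorm(n, 0, config$abundance_sdlog)
  tp <- config$timepoints
  w <- matrix(NA_real_, n, length(tp))
  w[, 1] <- base
  for (j in seq_along(tp)[-1])
    w[, j] <- w[, j - 1] * rlnorm(n, 0, config$drift_sdlog)
  freq_tp <- sweep(w, 2L, colSums(w), "/")

  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         timepoint = tp, KEEP.OUT.ATTRS = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_blood_wk%d_r%d", config$animal,
                        samples$timepoint, samples$replicate),
    animal = config$animal, timepoint = samples$timepoint,
    tissue = "blood", replicate = samples$replicate, population = "mixed",
    stringsAsFactors = FALSE)
  freq <- freq_tp[, match(samples$timepoint, tp), drop = FALSE]

  if (isTRUE(config$tissues_at_endpoint)) {
    last <- length(tp)
    for (tis in c("spleen", "BM")) {
      wt <- w[, last] * rlnorm(n, 0, if (tis == "spleen") 0.15 else 0.6)
      samples <- rbind(samples, data.frame(
        sample_id = sprintf("%s_%s_wk%d_r1", config$animal, tis, tp[last]),
        animal = config$animal, timepoint = tp[last], tissue = tis,
        replicate = 1L, population = "mixed", stringsAsFactors = FALSE))
      freq <- cbind(freq, wt / sum(wt))
    }
  }

  if (config$collision_clones > 0) {
    k <- min(config$collision_clones, n)
    coll <- order(-base)[seq_len(k)]  # most abundant clones collide
    m2 <- paste0(config$animal, "_x")
    m2_samples <- data.frame(
      sample_id = sprintf("%s_blood_wk%d_r%d", m2, tp[1], 1:2),
      animal = m2, timepoint = tp[1], tissue = "blood", replicate = 1:2,
      population = "mixed", stringsAsFactors = FALSE)
    m2_freq <- matrix(0, n, 2)
    m2_freq[coll, ] <- 1 / k
    samples <- rbind(samples, m2_samples)
    freq <- cbind(freq, m2_freq)
    sites$collision <- seq_len(n) %in% coll
  } else {
    sites$collision <- FALSE
  }

  colnames(freq) <- samples$sample_id
  rownames(freq) <- sites$clone_id
  structure(list(clones = sites, samples = samples, freq = freq),
            class = "sim_truth")
}

draw_clone_sites <- function(reference, config) {
  genes <- reference$genes
  k36 <- reference$peaks$H3K36me3
  lim <- reference$chr_len
  chr_names <- names(lim)
  cats <- sample(names(config$bias_weights), config$n_clones * 4L,
                 replace = TRUE, prob = config$bias_weights)
  out <- list()
  seen <- character()
  i <- 0L
  for (cat in cats) {
    if (length(out) >= config$n_clones) break
    pos <- switch(
      cat,
      h3k36me3 = {
        if (nrow(k36) == 0) next
        r <- k36[sample.int(nrow(k36), 1L), ]
        c(r$chrom, sample(r$start:r$end, 1L))
      },
      gene_body = {
        if (nrow(genes) == 0) next
        g <- genes[sample.int(nrow(genes), 1L), ]
        c(g$chrom, sample(g$start:g$end, 1L))
      },
      tss = {
        if (nrow(genes) == 0) next
        g <- genes[sample.int(nrow(genes), 1L), ]
        t0 <- if (g$strand == "-") g$end else g$start
        c(g$chrom, max(1L, min(lim[[g$chrom]],
                               t0 + sample(-500:500, 1L))))
      },
      intergenic = {
        cn <- sample(chr_names, 1L, prob = lim)
        p <- sample.int(lim[[cn]], 1L)
        gd <- if (nrow(genes)) min(interval_gap(
          p, genes$start[genes$chrom == cn], genes$end[genes$chrom == cn]),
          Inf) else Inf
        if (is.finite(gd) && gd <= 1000) next
        c(cn, p)
      })
    if (is.null(pos)) next
    cn <- pos[1]; p <- as.integer(pos[2])
    # assay recoverability: a GTAC motif within 1500 bp
    if (is.na(motif_distance(cn, p, reference$motifs)) ||
        motif_distance(cn, p, reference$motifs) > 1500) next
    # keep host windows inside the chromosome for both strands
    if (p < 60L || p > lim[[cn]] - 60L) next
    # distinct clones get distinct, well-separated junctions (within a few
    # bp two integrations would be indistinguishable from read jitter)
    key_near <- paste(cn, (p %/% 10L) + -1:1)
    if (any(key_near %in% seen)) next
    seen <- c(seen, paste(cn, p %/% 10L))
    i <- i + 1L
    out[[i]] <- data.frame(chrom = cn, pos = p,
                           strand = sample(c("+", "-"), 1L),
                           category = cat, stringsAsFactors = FALSE)
  }
  if (length(out) < config$n_clones)
    stop("could not place the requested number of clones; ",
         "check bias weights against the reference")
  do.call(rbind, out)
}

#' Simulate junction reads for every sample
#'
#' Per sample, per-clone read counts are drawn negative-binomially around
#' `depth * frequency` (amplification overdispersion); each read is the LTR
#' anchor, the clone's 16-nt LTR index, and `host_len` host bases downstream
#' of the integration junction on the clone's strand. Per-base substitution
#' errors and LTR-index hopping are applied at the configured rates. Read
#' names encode the source clone (`sample|clone|serial`), so every read
#' traces to its clone.
#'
#' @param truth a `sim_truth` from [simulate_clones].
#' @param reference the `sim_reference`.
#' @param config the [sim_config].
#' @return list of class `sim_reads`: `reads` (named list of DNAStringSet
#'   per sample), `realized` (clone x sample matrix of true emitted read
#'   counts), `truth`, `config`.
#' @export
simulate_reads <- function(truth, reference, config = sim_config()) {
  set.seed(config$seed + 2L)
  anchor <- default_ltr_anchor()
  indexes <- default_ltr_indexes()
  genome <- reference$genome
  n <- nrow(truth$clones)
  host <- clone_host_sequences(truth$clones, genome, config$host_len)

  reads <- list()
  realized <- matrix(0L, n, nrow(truth$samples),
                     dimnames = list(truth$clones$clone_id,
                                     truth$samples$sample_id))
  for (j in seq_len(nrow(truth$samples))) {
    sid <- truth$samples$sample_id[j]
    depth <- if (truth$samples$animal[j] == config$animal)
      config$depth else config$collision_depth
    mu <- depth * truth$freq[, j]
    cnt <- ifelse(mu > 0, rnbinom(n, mu = mu, size = config$nb_dispersion),
                  0L)
    realized[, j] <- as.integer(cnt)
    if (sum(cnt) == 0) {
      reads[[sid]] <- DNAStringSet()
      next
    }
    clone_i <- rep.int(seq_len(n), cnt)
    labels <- truth$clones$index_label[clone_i]
    hop <- runif(length(clone_i)) < config$hop_rate
    if (any(hop)) {
      labels[hop] <- vapply(labels[hop], function(l)
        sample(setdiff(names(indexes), l), 1L), "")
    }
    seqs <- paste0(anchor, unname(indexes[labels]), host[clone_i])
    seqs <- inject_errors(seqs, config$error_rate)
    names(seqs) <- sprintf("%s|%s|%d", sid,
                           truth$clones$clone_id[clone_i],
                           seq_along(clone_i))
    reads[[sid]] <- DNAStringSet(seqs)
  }
  structure(list(reads = reads, realized = realized, truth = truth,
                 config = config),
            class = "sim_reads")
}

# host sequence downstream of the junction on the clone's strand
clone_host_sequences <- function(clones, genome, host_len) {
  vapply(seq_len(nrow(clones)), function(i) {
    chr <- genome[[clones$chrom[i]]]
    p <- clones$pos[i]
    if (clones$strand[i] == "+") {
      as.character(subseq(chr, p, min(p + host_len - 1L, length(chr))))
    } else {
      as.character(reverseComplement(
        subseq(chr, max(p - host_len + 1L, 1L), p)))
    }
  }, "")
}

# vectorized substitution errors: only reads that drew >= 1 error are touched
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  L <- nchar(seqs)
  n_err <- rbinom(length(seqs), L, rate)
  for (i in which(n_err > 0)) {
    at <- sample.int(L[i], n_err[i])
    for (p in at) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  seqs
}

#' Generate the canonical default fixture
#'
#' Reference + truth + reads in one call, reproducible from the seed.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config].
#' @return list: `config`, `reference`, `truth`, `reads` (a `sim_reads`).
#' @export
default_fixture <- function(seed = 1L, ...) {
  config <- sim_config(seed = seed, ...)
  reference <- make_reference(config)
  truth <- simulate_clones(reference, config)
  reads <- simulate_reads(truth, reference, config)
  list(config = config, reference = reference, truth = truth, reads = reads)
}

#' Write the synthetic reference and reads to standard file formats
#'
#' FASTA genome, GTF gene annotation (with `gene_biotype`), FPKM TSV, one
#' BED per peak feature, one bedGraph per coverage track, one FASTQ per
#' sample, plus the sample sheet and truth tables as TSV.
#'
#' @param fixture output of [default_fixture] (or a compatible list).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- fixture$reference
  writeXStringSet(ref$genome, file.path(dir, "genome.fa"))

  genes <- ref$genes
  if (nrow(genes)) {
    gr <- GRanges(genes$chrom, IRanges(genes$start, genes$end),
                  strand = genes$strand, source = "vistrackr",
                  type = "gene", gene_id = genes$gene_id,
                  gene_biotype = genes$biotype)
    rtracklayer::export(gr, file.path(dir, "genes.gtf"), format = "gtf")
  } else {
    writeLines(character(), file.path(dir, "genes.gtf"))
  }
  write.table(genes[, c("gene_id", "fpkm")], file.path(dir, "fpkm.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  peak_dir <- file.path(dir, "peaks")
  dir.create(peak_dir, showWarnings = FALSE)
  for (f in names(ref$peaks)) {
    p <- ref$peaks[[f]]
    gr <- GRanges(p$chrom, IRanges(p$start, p$end))
    rtracklayer::export(gr, file.path(peak_dir, paste0(f, ".bed")),
                        format = "bed")
  }
  cov_dir <- file.path(dir, "coverage")
  dir.create(cov_dir, showWarnings = FALSE)
  for (f in names(ref$coverage)) {
    cv <- ref$coverage[[f]]
    gr <- GRanges(cv$chrom, IRanges(cv$start, cv$end), score = cv$score)
    rtracklayer::export(gr, file.path(cov_dir, paste0(f, ".bedGraph")),
                        format = "bedGraph")
  }

  if (!is.null(fixture$reads)) {
    fq_dir <- file.path(dir, "reads")
    dir.create(fq_dir, showWarnings = FALSE)
    for (sid in names(fixture$reads$reads)) {
      rs <- fixture$reads$reads[[sid]]
      writeXStringSet(rs, file.path(fq_dir, paste0(sid, ".fastq")),
                      format = "fastq")
    }
    write.table(fixture$truth$samples, file.path(dir, "samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(fixture$truth$clones, file.path(dir, "truth_clones.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
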