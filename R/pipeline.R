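#' Run the full junction-to-frequencies pipeline
#'
#' Calls junctions per sample ([call_junctions]), aggregates accepted reads
#' into a VIS-by-sample matrix ([aggregate_sites]), applies signal-crossover
#' and cross-animal collision correction, removes low-count sites, and
#' computes clone frequencies.
#'
#' @param reads_by_sample named list (by sample_id) of reads: DNAStringSet,
#'   character vectors, or FASTQ paths.
#' @param genome named [Biostrings::DNAStringSet] or FASTA path.
#' @param samples sample sheet data.frame (or TSV path) with `sample_id`,
#'   `animal`, `timepoint`, `tissue`, `replicate`, `population`.
#' @param index_set an [ltr_index_set].
#' @param anchor LTR terminal anchor sequence.
#' @param merge_window site merge radius in bp.
#' @param crossover_ratio,collision_ratio dominance ratios for the two
#'   corrections.
#' @param min_host_len,min_identity junction acceptance thresholds.
#' @param min_count_filter apply the per-animal minimum-count filter.
#' @return list: `calls` (per-read table over all samples), `raw`
#'   (uncorrected [clonal_matrix]), `matrix` (corrected and filtered
#'   [clonal_matrix]), `frequencies` (frequency_profile).
#' @export
run_vis_pipeline <- function(reads_by_sample, genome, samples,
                             index_set = default_ltr_indexes(),
                             anchor = default_ltr_anchor(),
                             merge_window = 5L, crossover_ratio = 0.1,
                             collision_ratio = 0.1, min_host_len = 25L,
                             min_identity = 0.95, min_count_filter = TRUE) {
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  genome <- as_genome(genome)
  stopifnot(!is.null(names(reads_by_sample)),
            all(names(reads_by_sample) %in% samples$sample_id))
  calls <- do.call(rbind, lapply(names(reads_by_sample), function(sid)
    call_junctions(reads_by_sample[[sid]], genome, index_set = index_set,
                   anchor = anchor, min_host_len = min_host_len,
                   min_identity = min_identity, sample_id = sid)))
  raw <- aggregate_sites(calls, samples, merge_window = merge_window)
  m <- correct_signal_crossover(raw, ratio = crossover_ratio)
  if ("animal" %in% names(samples))
    m <- correct_collisions(m, ratio = collision_ratio)
  if (min_count_filter) m <- filter_min_count(m)
  list(calls = calls, raw = raw, matrix = m,
       frequencies = compute_frequencies(m))
}

#' Write per-read calls as TSV
#' @param calls calls data.frame from [call_junctions].
#' @param file output path.
#' @export
write_calls <- function(calls, file) {
  write.table(calls, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read gene models from a GTF file
#'
#' Keeps `gene`-type records (or derives gene extents from all records of
#' each `gene_id` when no gene rows exist) and collapses annotation biotypes
#' onto protein_coding / lncRNA / other.
#'
#' @param file GTF/GFF path.
#' @return gene model data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`).
#' @export
read_gene_models <- function(file) {
  gr <- rtracklayer::import(file)
  md <- mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene"))
    gr <- gr[md$type == "gene"]
  md <- mcols(gr)
  biotype_col <- intersect(c("gene_biotype", "gene_type", "biotype"),
                           names(md))
  biotype <- if (length(biotype_col)) as.character(md[[biotype_col[1]]])
             else "other"
  genes <- data.frame(
    gene_id = as.character(md$gene_id),
    chrom = as.character(seqnames(gr)),
    start = start(gr), end = end(gr),
    strand = as.character(strand(gr)),
    biotype = biotype, stringsAsFactors = FALSE)
  normalize_biotypes(genes[!duplicated(genes$gene_id), , drop = FALSE])
}

#' Read peak BED files from a directory
#'
#' One BED/narrowPeak per chromatin feature; file base names become feature
#' names.
#'
#' @param dir directory of `.bed` / `.narrowPeak` files.
#' @return named list of interval data.frames.
#' @export
read_peak_sets <- function(dir) {
  files <- list.files(dir, pattern = "\\.(bed|narrowPeak)$",
                      full.names = TRUE)
  out <- lapply(files, function(f) as_interval_df(rtracklayer::import(f)))
  names(out) <- sub("\\.(bed|narrowPeak)$", "", basename(files))
  out
}
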