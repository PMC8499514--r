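#' Aggregate per-read calls into a VIS-by-sample count matrix
#'
#' Accepted reads sharing (chrom, strand, index_label) whose positions lie
#' within `merge_window` bp of each other (chain clustering on sorted
#' positions) are merged into one site at the modal read position (ties
#' broken toward the smallest position); this absorbs the 1-2 bp jitter that
#' end-trimming and sequencing error put on junction coordinates.
#'
#' @param calls per-read calls data.frame from [call_junctions], with a
#'   `sample_id` column.
#' @param samples sample sheet data.frame (one row per `sample_id`).
#' @param merge_window merge radius in bp (default 5).
#' @param drop_unclassified drop reads whose LTR index could not be
#'   classified (default TRUE).
#' @return A [clonal_matrix].
#' @export
aggregate_sites <- function(calls, samples, merge_window = 5L,
                            drop_unclassified = TRUE) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  acc <- calls[calls$status == "accepted", , drop = FALSE]
  if (drop_unclassified)
    acc <- acc[acc$index_label != "unclassified", , drop = FALSE]
  if (nrow(acc) == 0) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), index_label = character())
    return(clonal_matrix(empty, samples,
                         matrix(0L, 0L, nrow(samples))))
  }
  if (!all(acc$sample_id %in% samples$sample_id))
    stop("calls contain sample_ids absent from the sample sheet")

  grp <- paste(acc$chrom, acc$strand, acc$index_label, sep = "\r")
  acc$site_pos <- NA_integer_
  for (g in unique(grp)) {
    rows <- which(grp == g)
    pos <- acc$pos[rows]
    o <- order(pos)
    sp <- pos[o]
    new_cluster <- c(TRUE, diff(sp) > merge_window)
    cl <- cumsum(new_cluster)
    rep_pos <- vapply(split(sp, cl), modal_position, numeric(1))
    acc$site_pos[rows[o]] <- as.integer(rep_pos[cl])
  }

  key <- paste(acc$chrom, acc$site_pos, acc$strand, acc$index_label,
               sep = "\r")
  ukey <- unique(key)
  ki <- match(key, ukey)
  si <- match(acc$sample_id, samples$sample_id)
  counts <- matrix(0L, length(ukey), nrow(samples))
  tab <- table(factor(ki, levels = seq_along(ukey)),
               factor(si, levels = seq_len(nrow(samples))))
  counts[] <- as.integer(tab)
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  sites <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                      strand = parts[, 3], index_label = parts[, 4],
                      stringsAsFactors = FALSE)
  o <- order(sites$chrom, sites$pos, sites$strand, sites$index_label)
  clonal_matrix(sites[o, ], samples, counts[o, , drop = FALSE])
}

# modal value; ties broken toward the smallest
modal_position <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Correct LTR-index signal crossover (index hopping)
#'
#' Index hopping makes a fraction of reads from one vector population appear
#' under another index label at the same genomic coordinate. When one
#' genomic site (chrom, pos, strand) carries two or more labels and a minor
#' label's total count is below `ratio` times the major label's total, the
#' minor counts are reassigned to the major label; labels with comparable
#' counts are kept distinct (two genuinely co-integrated clones at the same
#' base are vanishingly unlikely but not impossible).
#'
#' @param m a [clonal_matrix].
#' @param ratio dominance ratio (default 0.1).
#' @return A corrected [clonal_matrix].
#' @export
correct_signal_crossover <- function(m, ratio = 0.1) {
  gkey <- paste(m$sites$chrom, m$sites$pos, m$sites$strand, sep = "\r")
  counts <- m$counts
  keep <- rep(TRUE, nrow(counts))
  for (g in unique(gkey[duplicated(gkey)])) {
    rows <- which(gkey == g)
    tot <- rowSums(counts[rows, , drop = FALSE])
    major <- rows[which.max(tot)]
    if (sum(tot == max(tot)) > 1L) next  # tied majors: keep all distinct
    minors <- rows[tot < ratio * max(tot)]
    for (r in minors) {
      counts[major, ] <- counts[major, ] + counts[r, ]
      keep[r] <- FALSE
    }
  }
  cm_subset(clonal_matrix(m$sites, m$samples, counts), which(keep))
}

#' Correct cross-animal VIS collisions
#'
#' A collision is the same site key observed in more than one animal --
#' physically impossible for independent integrations at base resolution, so
#' one animal's signal is an artifact (index hopping across libraries or
#' carry-over). If one animal dominates (every other animal's total is below
#' `ratio` times the dominant total) the site is kept only there; with no
#' dominant animal the site is removed everywhere.
#'
#' @param m a [clonal_matrix] whose sample sheet has an `animal` column.
#' @param ratio dominance ratio (default 0.1).
#' @return A corrected [clonal_matrix].
#' @export
correct_collisions <- function(m, ratio = 0.1) {
  if (!"animal" %in% names(m$samples))
    stop("sample sheet lacks an 'animal' column")
  animals <- unique(m$samples$animal)
  if (length(animals) < 2) return(m)
  cols <- lapply(animals, function(a) which(m$samples$animal == a))
  per_animal <- vapply(cols, function(cc)
    rowSums(m$counts[, cc, drop = FALSE]), numeric(nrow(m$counts)))
  per_animal <- matrix(per_animal, nrow = nrow(m$counts))
  counts <- m$counts
  for (r in which(rowSums(per_animal > 0) > 1L)) {
    tot <- per_animal[r, ]
    mx <- max(tot)
    dominant <- which(tot == mx)
    others <- setdiff(which(tot > 0), dominant)
    if (length(dominant) == 1L && all(tot[others] < ratio * mx)) {
      for (a in others) counts[r, cols[[a]]] <- 0L
    } else {
      counts[r, ] <- 0L
    }
  }
  m2 <- clonal_matrix(m$sites, m$samples, counts)
  cm_subset(m2, which(rowSums(counts) > 0))
}

#' Remove low-count sites
#'
#' Drops each site whose total sequence count across an animal's samples is
#' strictly below the number of samples analysed for that animal (or the
#' explicit `n_samples` override). Low-count junctions at this level are
#' indistinguishable from PCR/sequencing artifacts.
#'
#' @param m a [clonal_matrix].
#' @param n_samples optional explicit threshold; default is the per-animal
#'   sample count from the sample sheet.
#' @return A filtered [clonal_matrix].
#' @export
filter_min_count <- function(m, n_samples = NULL) {
  if (!is.null(n_samples) && n_samples <= 0)
    stop("invalid sample count")
  groups <- if (!is.null(n_samples) || !"animal" %in% names(m$samples)) {
    list(seq_len(nrow(m$samples)))
  } else {
    lapply(unique(m$samples$animal),
           function(a) which(m$samples$animal == a))
  }
  counts <- m$counts
  for (cc in groups) {
    thr <- if (is.null(n_samples)) length(cc) else n_samples
    tot <- rowSums(counts[, cc, drop = FALSE])
    low <- tot > 0 & tot < thr
    counts[low, cc] <- 0L
  }
  m2 <- clonal_matrix(m$sites, m$samples, counts)
  cm_subset(m2, which(rowSums(counts) > 0))
}

#' Clone frequencies (proportional abundances)
#'
#' Per sample, the proportional abundance of clone i is p_i = s_i / S with
#' s_i its sequence count and S the sample's total count. Samples with S = 0
#' yield all-zero columns and are flagged in the `empty_samples` attribute.
#'
#' @param m a [clonal_matrix].
#' @return A `frequency_profile`: list with `sites`, `samples` and the
#'   proportions matrix `p` (columns of non-empty samples sum to 1).
#' @export
compute_frequencies <- function(m) {
  S <- colSums(m$counts)
  p <- sweep(m$counts, 2L, pmax(S, 1L), "/")
  p[, S == 0] <- 0
  structure(list(sites = m$sites, samples = m$samples, p = p,
                 empty_samples = m$samples$sample_id[S == 0]),
            class = "frequency_profile")
}

#' @export
print.frequency_profile <- function(x, ...) {
  cat("frequency_profile:", nrow(x$p), "clones x", ncol(x$p), "samples\n")
  invisible(x)
}

#' Merge replicate samples
#'
#' Replicates (same animal/timepoint/tissue/population, distinct `replicate`
#' ids) are merged either by summing raw counts (`sum_counts`, the
#' convention used for diversity on pooled replicate counts) or by averaging
#' replicate frequency vectors and renormalising (`mean_frequency`, the
#' convention for clone-level frequency tracking).
#'
#' @param m a [clonal_matrix].
#' @param mode `"sum_counts"` or `"mean_frequency"`.
#' @return A [clonal_matrix] (`sum_counts`) or `frequency_profile`
#'   (`mean_frequency`) with one column per replicate group.
#' @export
merge_replicates <- function(m, mode = c("sum_counts", "mean_frequency")) {
  mode <- match.arg(mode)
  s <- m$samples
  if (!"replicate" %in% names(s)) stop("sample sheet lacks 'replicate'")
  if (any(is.na(s$replicate)))
    stop("unmatched replicate for sample ",
         s$sample_id[which(is.na(s$replicate))[1]])
  meta_cols <- setdiff(names(s), c("sample_id", "replicate"))
  gkey <- do.call(paste, c(s[meta_cols], sep = "\r"))
  ug <- unique(gkey)
  gi <- match(gkey, ug)
  merged_samples <- s[match(ug, gkey), meta_cols, drop = FALSE]
  merged_samples <- cbind(
    sample_id = vapply(seq_along(ug), function(k)
      paste(unlist(merged_samples[k, intersect(c("animal", "tissue",
        "timepoint", "population"), meta_cols)]), collapse = "_"), ""),
    merged_samples)
  if (anyDuplicated(merged_samples$sample_id))
    merged_samples$sample_id <- make.unique(merged_samples$sample_id)
  rownames(merged_samples) <- NULL

  if (mode == "sum_counts") {
    counts <- vapply(seq_along(ug), function(k)
      as.integer(rowSums(m$counts[, gi == k, drop = FALSE])),
      integer(nrow(m$counts)))
    counts <- matrix(counts, nrow = nrow(m$counts))
    return(clonal_matrix(m$sites, merged_samples, counts))
  }
  fp <- compute_frequencies(m)
  p <- vapply(seq_along(ug), function(k)
    rowMeans(fp$p[, gi == k, drop = FALSE]), numeric(nrow(fp$p)))
  p <- matrix(p, nrow = nrow(fp$p))
  cs <- colSums(p)
  p <- sweep(p, 2L, pmax(cs, .Machine$double.eps), "/")
  colnames(p) <- merged_samples$sample_id
  rownames(p) <- rownames(fp$p)
  structure(list(sites = m$sites, samples = merged_samples, p = p,
                 empty_samples = merged_samples$sample_id[cs == 0]),
            class = "frequency_profile")
}
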