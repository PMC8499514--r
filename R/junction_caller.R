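#' Default LTR terminal anchor
#'
#' The constant 3'-end U5 LTR sequence immediately upstream of the 16-nt LTR
#' index. A true junction read runs anchor, index, then host DNA; the anchor
#' is how the caller finds the vector-host boundary inside a read.
#'
#' @return A character scalar.
#' @export
default_ltr_anchor <- function() "CCCTTTTAGTCAGTG"

#' Locate the LTR anchor and extract the host segment of junction reads
#'
#' Scans each read for the LTR terminal anchor (ungapped, at most
#' `max_anchor_mismatch` mismatches; the leftmost best match wins). The
#' `index_len` bases after the anchor are the LTR-index window; everything
#' after the index window is the candidate host segment. Reads without an
#' in-budget anchor match are flagged `no_ltr`; reads whose host segment is
#' shorter than `min_host_len` are flagged `short_host`.
#'
#' @param reads a [Biostrings::DNAStringSet], named character vector, or path
#'   to a FASTQ file (optionally gzipped).
#' @param anchor the constant LTR terminal sequence (default
#'   [default_ltr_anchor()]).
#' @param index_len length of the LTR-index window that follows the anchor.
#' @param max_anchor_mismatch mismatch budget for the anchor scan (no
#'   indels; default 2).
#' @param min_host_len minimum host segment length for a usable junction
#'   (default 25).
#' @return A data.frame with one row per read: `read_id`, `status`
#'   (`"ok"`, `"no_ltr"` or `"short_host"`), `ltr_end_offset` (1-based
#'   position of the first host base, NA if no anchor), `index_window`, and
#'   `host_segment`.
#' @export
extract_host_junction <- function(reads, anchor = default_ltr_anchor(),
                                  index_len = 16L, max_anchor_mismatch = 2L,
                                  min_host_len = 25L) {
  reads <- as_read_set(reads)
  seqs <- as.character(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  n <- length(seqs)
  la <- nchar(anchor)
  anchor <- toupper(anchor)

  best_off <- rep(NA_integer_, n)
  best_mm <- rep(la + 1L, n)
  if (n > 0) {
    max_off <- max(nchar(seqs)) - la + 1L
    for (o in seq_len(max(max_off, 0L))) {
      todo <- which(best_mm > 0L)  # a perfect hit cannot be improved
      if (length(todo) == 0) break
      win <- substr(seqs[todo], o, o + la - 1L)
      cand <- nchar(win) == la
      if (!any(cand)) next
      mm <- integer(length(todo))
      for (j in seq_len(la)) {
        mm <- mm + (substr(win, j, j) != substr(anchor, j, j))
      }
      upd <- cand & mm <= max_anchor_mismatch & mm < best_mm[todo]
      best_off[todo[upd]] <- o
      best_mm[todo[upd]] <- mm[upd]
    }
  }

  found <- !is.na(best_off)
  idx_start <- best_off + la
  ltr_end <- idx_start + index_len # first host base
  index_window <- ifelse(found, substr(seqs, idx_start, ltr_end - 1L), NA)
  index_window[found & nchar(index_window) < index_len] <- NA
  host <- ifelse(found, substr(seqs, ltr_end, nchar(seqs)), "")
  status <- ifelse(!found, "no_ltr",
                   ifelse(nchar(host) < min_host_len, "short_host", "ok"))
  data.frame(
    read_id = ids, status = status,
    ltr_end_offset = ifelse(found, ltr_end, NA_integer_),
    index_window = as.character(index_window),
    host_segment = host,
    stringsAsFactors = FALSE
  )
}

#' Map host junction segments onto a reference genome
#'
#' Two-pass placement of host segments. Pass 1 finds candidate loci by exact
#' seeding: the first and last `seed_width` bases of the segment (and of its
#' reverse complement) are matched exactly against the genome, so any
#' segment with at most one substitution error in each terminal seed region
#' is seeded; segments that evade seeding fall back to a genome-wide
#' mismatch-tolerant scan. Pass 2 rescores the full segment ungapped at
#' every offset of the `window_flank` window around each candidate locus and
#' keeps the best placement. A segment is accepted iff its identity
#' (matching columns / segment length) is at least `min_identity` over at
#' least `min_match_len` bases AND the best placement is unique; equal-best
#' placements at distinct loci are rejected as `multimapped`.
#'
#' Reported `pos` is the 1-based reference coordinate of the first host base
#' at the junction: the leftmost aligned base for a `+` placement and the
#' rightmost for a `-` placement (where the read ran into the host on the
#' minus strand).
#'
#' @param segments character vector of host segments.
#' @param genome a named [Biostrings::DNAStringSet] (or path to a FASTA
#'   file).
#' @param min_identity minimum aligned identity (default 0.95).
#' @param min_match_len minimum segment length (default 25).
#' @param window_flank half-width of the pass-2 rescoring window (default
#'   500).
#' @param seed_width exact-seed width for pass 1 (default 20).
#' @return A data.frame with one row per segment: `status` (`"accepted"`,
#'   `"unmapped"`, `"multimapped"`, `"low_identity"`, `"short_host"`),
#'   `chrom`, `pos`, `strand`, `identity`, `matched_len`.
#' @export
validate_and_map <- function(segments, genome, min_identity = 0.95,
                             min_match_len = 25L, window_flank = 500L,
                             seed_width = 20L) {
  genome <- as_genome(genome)
  segments <- toupper(as.character(segments))
  n <- length(segments)
  res <- data.frame(
    status = rep("unmapped", n), chrom = NA_character_,
    pos = NA_integer_, strand = NA_character_,
    identity = NA_real_, matched_len = nchar(segments),
    stringsAsFactors = FALSE
  )
  if (n == 0) return(res)
  res$status[nchar(segments) < min_match_len] <- "short_host"

  uniq <- unique(segments[res$status == "unmapped"])
  uniq <- uniq[nchar(uniq) >= seed_width & !grepl("[^ACGT]", uniq)]
  if (length(uniq) == 0) return(res)

  cand <- seed_candidates(uniq, genome, seed_width)
  placed <- lapply(seq_along(uniq), function(i) {
    ci <- cand[[i]]
    if (nrow(ci) == 0) {
      ci <- fallback_candidates(uniq[i], genome)
      if (nrow(ci) == 0) return(NULL)
    }
    rescore_candidates(uniq[i], ci, genome, window_flank)
  })

  seg_idx <- match(segments, uniq)
  seg_idx[res$status != "unmapped"] <- NA
  row_groups <- split(seq_len(n), seg_idx)
  for (i in seq_along(uniq)) {
    rows <- row_groups[[as.character(i)]]
    if (is.null(rows)) next
    p <- placed[[i]]
    if (is.null(p)) next
    len <- nchar(uniq[i])
    identity <- (len - p$best_edits) / len
    if (p$n_best > 1L) {
      res$status[rows] <- "multimapped"
    } else if (identity < min_identity) {
      res$status[rows] <- "low_identity"
    } else {
      res$status[rows] <- "accepted"
      res$chrom[rows] <- p$chrom
      res$strand[rows] <- p$strand
      res$pos[rows] <- if (p$strand == "+") p$offset else p$offset + len - 1L
    }
    res$identity[rows] <- identity
  }
  res
}

# Pass 1: exact seed hits -> candidate (chrom, strand, segment start offset)
# tables, one per unique segment.
seed_candidates <- function(uniq, genome, seed_width) {
  lens <- nchar(uniq)
  rc <- as.character(reverseComplement(DNAStringSet(uniq)))
  seed_seq <- c(
    substr(uniq, 1L, seed_width),
    substr(uniq, lens - seed_width + 1L, lens),
    substr(rc, 1L, seed_width),
    substr(rc, nchar(rc) - seed_width + 1L, nchar(rc))
  )
  seed_seg <- rep(seq_along(uniq), 4L)
  # role 1/2: prefix/suffix of forward segment; 3/4: of reverse complement
  seed_role <- rep(1:4, each = length(uniq))
  keep <- !duplicated(paste(seed_seq, seed_seg, seed_role))
  pd <- PDict(DNAStringSet(seed_seq[keep]))
  seed_seg <- seed_seg[keep]; seed_role <- seed_role[keep]

  cand <- vector("list", length(uniq))
  for (i in seq_along(cand)) cand[[i]] <- list()
  for (chrom in names(genome)) {
    m <- matchPDict(pd, genome[[chrom]])
    nh <- elementNROWS(m)
    for (k in which(nh > 0)) {
      i <- seed_seg[k]; role <- seed_role[k]; len <- lens[i]
      starts <- start(m[[k]])
      # infer the start of the full (plus-strand) match of the segment (role
      # 1,2) or its reverse complement (role 3,4)
      seg_start <- switch(role, starts, starts - (len - seed_width),
                          starts, starts - (len - seed_width))
      strand <- if (role <= 2) "+" else "-"
      cand[[i]][[length(cand[[i]]) + 1L]] <-
        data.frame(chrom = chrom, strand = strand, offset = seg_start,
                   stringsAsFactors = FALSE)
    }
  }
  lapply(cand, function(x) {
    if (length(x) == 0)
      return(data.frame(chrom = character(), strand = character(),
                        offset = integer()))
    unique(do.call(rbind, x))
  })
}

# Genome-wide mismatch-tolerant fallback for segments whose seeds all carry
# errors; bounded mismatch budget keeps this a rare, cheap path.
fallback_candidates <- function(segment, genome) {
  len <- nchar(segment)
  budget <- max(2L, ceiling(0.1 * len))
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") DNAString(segment) else
      reverseComplement(DNAString(segment))
    for (chrom in names(genome)) {
      m <- matchPattern(pat, genome[[chrom]], max.mismatch = budget)
      if (length(m) > 0)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, strand = strand, offset = start(m),
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), strand = character(),
                      offset = integer()))
  unique(do.call(rbind, out))
}

# Pass 2: ungapped rescore of the full segment over the +/- window_flank
# neighbourhood of each candidate; returns the best placement and whether it
# is unique.
rescore_candidates <- function(segment, cand, genome, window_flank) {
  len <- nchar(segment)
  pat_fwd <- DNAString(segment)
  pat_rev <- reverseComplement(pat_fwd)
  best <- NULL
  for (j in seq_len(nrow(cand))) {
    chrom <- cand$chrom[j]
    chr <- genome[[chrom]]
    from <- max(1L, cand$offset[j] - window_flank)
    to <- min(length(chr) - len + 1L, cand$offset[j] + window_flank)
    if (to < from) next
    at <- from:to
    pat <- if (cand$strand[j] == "+") pat_fwd else pat_rev
    ed <- neditStartingAt(pat, chr, starting.at = at, with.indels = FALSE)
    k <- min(ed)
    offs <- at[ed == k]
    hits <- data.frame(chrom = chrom, strand = cand$strand[j], offset = offs,
                       edits = k, stringsAsFactors = FALSE)
    best <- if (is.null(best)) hits else rbind(best, hits)
  }
  if (is.null(best) || nrow(best) == 0) return(NULL)
  best <- unique(best)
  k <- min(best$edits)
  top <- best[best$edits == k, , drop = FALSE]
  list(best_edits = k, n_best = nrow(top),
       chrom = top$chrom[1], strand = top$strand[1], offset = top$offset[1])
}

#' Call integration sites from junction reads
#'
#' End-to-end per-read driver: anchor location and host-segment extraction
#' ([extract_host_junction]), LTR-index classification
#' ([classify_ltr_index]), and two-pass host mapping ([validate_and_map]).
#'
#' @inheritParams extract_host_junction
#' @inheritParams validate_and_map
#' @param index_set an [ltr_index_set] (default [default_ltr_indexes()]).
#' @param max_index_mismatch mismatch budget for index classification.
#' @param sample_id optional sample label recycled into the output.
#' @return A per-read calls data.frame: `read_id`, `sample_id` (if given),
#'   `status`, `index_label`, `chrom`, `pos`, `strand`, `identity`,
#'   `matched_len`. `status == "accepted"` rows satisfy the identity and
#'   length thresholds.
#' @export
call_junctions <- function(reads, genome, index_set = default_ltr_indexes(),
                           anchor = default_ltr_anchor(),
                           max_anchor_mismatch = 2L, max_index_mismatch = 1L,
                           min_host_len = 25L, min_identity = 0.95,
                           window_flank = 500L, sample_id = NULL) {
  idx_len <- nchar(index_set[[1]])
  ext <- extract_host_junction(reads, anchor = anchor, index_len = idx_len,
                               max_anchor_mismatch = max_anchor_mismatch,
                               min_host_len = min_host_len)
  ext$index_label <- "unclassified"
  ok <- ext$status == "ok" & !is.na(ext$index_window)
  ext$index_label[ok] <- classify_ltr_index(ext$index_window[ok], index_set,
                                            max_index_mismatch)
  map <- data.frame(status = ext$status, chrom = NA_character_,
                    pos = NA_integer_, strand = NA_character_,
                    identity = NA_real_, matched_len = nchar(ext$host_segment),
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    map[ok, ] <- validate_and_map(ext$host_segment[ok], genome,
                                  min_identity = min_identity,
                                  min_match_len = min_host_len,
                                  window_flank = window_flank)
  }
  out <- data.frame(read_id = ext$read_id, status = map$status,
                    index_label = ext$index_label, chrom = map$chrom,
                    pos = map$pos, strand = map$strand,
                    identity = map$identity, matched_len = map$matched_len,
                    stringsAsFactors = FALSE)
  if (!is.null(sample_id)) out <- cbind(sample_id = sample_id, out)
  out
}

# ---- input coercion helpers -------------------------------------------------

as_read_set <- function(reads) {
  if (is(reads, "DNAStringSet")) return(reads)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    return(readDNAStringSet(reads, format = "fastq"))
  DNAStringSet(toupper(reads))
}

as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    return(genome)
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    g <- readDNAStringSet(genome)
    names(g) <- sub("\\s.*$", "", names(g))
    return(g)
  }
  stop("genome must be a named DNAStringSet or a FASTA path")
}
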