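#' Motif-constrained random integration sites
#'
#' The junction assay recovers an integration site only if a restriction
#' motif (CviQI/RsaI, GTAC) lies close enough downstream to release a
#' sequenceable fragment, so a fair "random integration" null must carry the
#' same constraint. Positions are rejection-sampled uniformly over the
#' genome (chromosomes weighted by length, strand uniform) and kept iff they
#' lie within `max_dist` bp of a motif occurrence (distance 0 inside the
#' motif, else bp to the nearer motif edge).
#'
#' @param genome named [Biostrings::DNAStringSet] or FASTA path.
#' @param n number of sites (default 1000).
#' @param max_dist maximum distance to the nearest motif (default 1500).
#' @param motif restriction motif (default `"GTAC"`, its own reverse
#'   complement).
#' @param seed optional integer seed; the same seed yields identical sites.
#' @param max_rounds bounded attempt budget (default 1000 sampling rounds).
#' @return data.frame `chrom`, `pos`, `strand`, `motif_distance`.
#' @export
generate_random_is <- function(genome, n = 1000L, max_dist = 1500L,
                               motif = "GTAC", seed = NULL,
                               max_rounds = 1000L) {
  genome <- as_genome(genome)
  motifs <- motif_positions(genome, motif)
  if (all(vapply(motifs, nrow, integer(1)) == 0))
    stop("unsatisfiable constraint: genome contains no '", motif, "' site")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  lens <- width(genome)
  out <- NULL
  rounds <- 0L
  while (is.null(out) || nrow(out) < n) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("unsatisfiable constraint: attempt budget exhausted")
    m <- max(n, 1000L)
    ci <- sample.int(length(genome), m, replace = TRUE, prob = lens)
    pos <- floor(runif(m, 1, lens[ci] + 1))
    strand <- sample(c("+", "-"), m, replace = TRUE)
    d <- motif_distance(names(genome)[ci], pos, motifs)
    keep <- !is.na(d) & d <= max_dist
    batch <- data.frame(chrom = names(genome)[ci][keep], pos = pos[keep],
                        strand = strand[keep], motif_distance = d[keep],
                        stringsAsFactors = FALSE)
    out <- if (is.null(out)) batch else rbind(out, batch)
  }
  out <- out[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-chromosome motif occurrence intervals (start, end), forward and
# reverse-complement orientations merged
motif_positions <- function(genome, motif) {
  pats <- unique(c(motif, as.character(reverseComplement(DNAString(motif)))))
  out <- lapply(names(genome), function(chrom) {
    st <- sort(unique(unlist(lapply(pats, function(p)
      start(matchPattern(DNAString(p), genome[[chrom]]))))))
    data.frame(start = st, end = st + nchar(motif) - 1L)
  })
  names(out) <- names(genome)
  out
}

# distance from positions to the nearest motif interval on their chromosome
motif_distance <- function(chrom, pos, motifs) {
  d <- rep(NA_real_, length(pos))
  for (cn in unique(chrom)) {
    mt <- motifs[[cn]]
    rows <- which(chrom == cn)
    if (is.null(mt) || nrow(mt) == 0) next
    i <- findInterval(pos[rows], mt$start)
    cand_lo <- pmax(i, 1L)
    cand_hi <- pmin(i + 1L, nrow(mt))
    d_lo <- interval_gap(pos[rows], mt$start[cand_lo], mt$end[cand_lo])
    d_hi <- interval_gap(pos[rows], mt$start[cand_hi], mt$end[cand_hi])
    d[rows] <- pmin(d_lo, d_hi)
  }
  d
}

# coordinate distance from a point to an interval: 0 inside, else bp to the
# nearer edge
interval_gap <- function(pos, start, end) {
  ifelse(pos < start, start - pos, ifelse(pos > end, pos - end, 0))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Annotate sites with their nearest gene
#'
#' Distance is 0 for a site inside a gene body, else bp to the nearest gene
#' boundary (gene-body convention; TSS-relative distance available via
#' `mode = "tss"`). The biotype call is that of the nearest gene when the
#' distance is at most `window`, otherwise `distal`. Exact distance ties are
#' broken by biotype priority protein_coding > lncRNA > other, then by
#' gene_id order.
#'
#' @param sites data.frame with `chrom`, `pos` (and optionally `strand`).
#' @param genes gene model data.frame: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype` (values collapsed to protein_coding / lncRNA /
#'   other).
#' @param window proximity window in bp (default 1000).
#' @param mode `"body"` (default) or `"tss"` (distance to the
#'   strand-correct transcription start).
#' @return data.frame: sites plus `nearest_gene`, `gene_distance`,
#'   `biotype_class` in \{protein_coding, lncRNA, other, distal\}.
#' @export
annotate_nearest_gene <- function(sites, genes, window = 1000L,
                                  mode = c("body", "tss")) {
  mode <- match.arg(mode)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  genes <- normalize_biotypes(genes)
  out <- cbind(sites,
               nearest_gene = NA_character_,
               gene_distance = NA_real_,
               biotype_class = "distal",
               stringsAsFactors = FALSE)
  if (nrow(genes) == 0 || nrow(sites) == 0) return(out)
  gstart <- if (mode == "body") genes$start else
    ifelse(genes$strand == "-", genes$end, genes$start)
  gend <- if (mode == "body") genes$end else gstart
  prio <- match(genes$biotype, c("protein_coding", "lncRNA", "other"))
  for (i in seq_len(nrow(sites))) {
    same <- which(genes$chrom == sites$chrom[i])
    if (length(same) == 0) next
    d <- interval_gap(sites$pos[i], gstart[same], gend[same])
    dmin <- min(d)
    tied <- same[d == dmin]
    best <- tied[order(prio[tied], genes$gene_id[tied])][1]
    out$nearest_gene[i] <- genes$gene_id[best]
    out$gene_distance[i] <- dmin
    out$biotype_class[i] <- if (dmin <= window) genes$biotype[best] else
      "distal"
  }
  out
}

# collapse annotation biotypes onto the three-way split used throughout:
# protein_coding, lncRNA, other (pseudogenes and remaining non-coding)
normalize_biotypes <- function(genes) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes) == 0) return(genes)
  b <- tolower(genes$biotype)
  genes$biotype <- ifelse(b == "protein_coding", "protein_coding",
                          ifelse(b %in% c("lncrna", "lincrna"), "lncRNA",
                                 "other"))
  genes
}

#' Flag sites near transcriptionally active genes
#'
#' A genic site is `active` iff its nearest gene's expression is strictly
#' above `threshold` (FPKM > 1 by default); distal sites get NA.
#'
#' @param annotation output of [annotate_nearest_gene].
#' @param fpkm named numeric vector (names = gene_id) or data.frame with
#'   `gene_id` and `fpkm`.
#' @param threshold activity cutoff (default 1.0, strict).
#' @return `annotation` with an added logical column `active`.
#' @export
classify_activity <- function(annotation, fpkm, threshold = 1.0) {
  if (is.data.frame(fpkm)) fpkm <- setNames(fpkm$fpkm, fpkm$gene_id)
  genic <- annotation$biotype_class != "distal"
  annotation$active <- NA
  annotation$active[genic] <-
    unname(fpkm[annotation$nearest_gene[genic]]) > threshold
  annotation
}

#' Distance from sites to the nearest chromatin-feature peak
#'
#' Distance is 0 for a site inside a peak interval, else bp to the nearest
#' interval edge on the same chromosome (`edge` convention; `center` mode
#' measures to peak midpoints). Chromosomes without any peak yield NA.
#'
#' @param sites data.frame with `chrom`, `pos`.
#' @param peaks a single peak table (`chrom`, `start`, `end` data.frame or
#'   `GRanges`) or a named list of them, one per chromatin feature.
#' @param mode `"edge"` (default) or `"center"`.
#' @return numeric vector (single peak set) or site x feature matrix.
#' @export
peak_distance <- function(sites, peaks, mode = c("edge", "center")) {
  mode <- match.arg(mode)
  if (is.list(peaks) && !is.data.frame(peaks) && !is(peaks, "GRanges")) {
    out <- vapply(peaks, function(p)
      peak_distance(sites, p, mode), numeric(nrow(sites)))
    return(matrix(out, nrow = nrow(sites),
                  dimnames = list(NULL, names(peaks))))
  }
  pk <- as_interval_df(peaks)
  d <- rep(NA_real_, nrow(sites))
  for (cn in unique(sites$chrom)) {
    rows <- which(sites$chrom == cn)
    p <- pk[pk$chrom == cn, , drop = FALSE]
    if (nrow(p) == 0) next
    if (mode == "center") {
      mid <- floor((p$start + p$end) / 2)
      p$start <- mid; p$end <- mid
    }
    p <- p[order(p$start), , drop = FALSE]
    i <- findInterval(sites$pos[rows], p$start)
    lo <- pmax(i, 1L); hi <- pmin(i + 1L, nrow(p))
    d[rows] <- pmin(
      interval_gap(sites$pos[rows], p$start[lo], p$end[lo]),
      interval_gap(sites$pos[rows], p$start[hi], p$end[hi]))
  }
  d
}

as_interval_df <- function(x) {
  if (is(x, "GRanges"))
    return(data.frame(chrom = as.character(seqnames(x)), start = start(x),
                      end = end(x), stringsAsFactors = FALSE))
  as.data.frame(x, stringsAsFactors = FALSE)
}

#' Histogram of site-to-peak distances
#'
#' Bins absolute distances into `bin_width`-bp bins over \[0, `max_dist`\];
#' sites farther than `max_dist` (or NA) are excluded. The first bin starts
#' at 0 (sites inside peaks), the last bin includes `max_dist`.
#'
#' @param distances numeric vector of distances (bp).
#' @param bin_width bin width in bp (default 100).
#' @param max_dist histogram range (default 1000).
#' @return named integer vector of bin counts (`[0,100)`, `[100,200)`, ...).
#' @export
bin_by_distance <- function(distances, bin_width = 100L, max_dist = 1000L) {
  breaks <- seq(0, max_dist, by = bin_width)
  if (breaks[length(breaks)] < max_dist) breaks <- c(breaks, max_dist)
  d <- distances[!is.na(distances) & distances <= max_dist]
  d[d == max_dist] <- max_dist - 1e-9  # closed last bin
  bins <- cut(d, breaks = breaks, right = FALSE, include.lowest = TRUE)
  tab <- table(bins)
  setNames(as.integer(tab), levels(bins))
}

#' Pearson chi-squared test with Yates continuity correction (2x2)
#'
#' For a 2x2 table (a, b / c, d) with N = a+b+c+d:
#' \deqn{\chi^2 = \frac{N (\max(|ad - bc| - N/2, 0))^2}
#'   {(a+b)(c+d)(a+c)(b+d)}}
#' with the p-value from the chi-squared distribution on 1 df. Used to test
#' whether VIS proximity to a genomic/epigenomic feature differs from the
#' motif-matched random null.
#'
#' @param a,b,c,d the four cell counts (e.g. a = VIS near feature, b = VIS
#'   not near, c = random IS near, d = random IS not near).
#' @return list with `statistic` and `p_value`.
#' @export
chisq_yates <- function(a, b, c, d) {
  cells <- as.numeric(c(a, b, c, d))
  if (any(is.na(cells)) || any(cells < 0)) stop("invalid table")
  N <- sum(cells)
  if (N <= 0) stop("degenerate table")
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("degenerate table")
  stat <- N * max(abs(a * d - b * c) - N / 2, 0)^2 / prod(margins)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Binned coverage matrix around anchors
#'
#' `reference_point` mode bins the +/-`flank` window around each anchor
#' point into `n_bins` bins of mean track coverage (for profile plots over
#' integration sites). `scale_regions` mode rescales each anchor interval
#' (gene body) to `body_bins` bins with unscaled `flank`-bp flanks of
#' `flank_bins` bins each, columns running 5' to 3' on the anchor strand
#' (for TSS-to-TES metagene profiles). Column means of the returned matrix
#' are the profile curve.
#'
#' @param anchors data.frame with `chrom`, `pos` (reference_point) or
#'   `chrom`, `start`, `end`, `strand` (scale_regions).
#' @param track coverage as a `GRanges` with a `score` column, a bedGraph
#'   file path, or a data.frame (`chrom`, `start`, `end`, `score`).
#' @param flank flank size in bp (default 1000 for reference_point, 2000
#'   for scale_regions).
#' @param n_bins number of bins across the reference_point window (default
#'   50).
#' @param mode `"reference_point"` or `"scale_regions"`.
#' @param body_bins,flank_bins bin counts for scale_regions mode.
#' @return numeric matrix anchors x bins with attribute `clipped` flagging
#'   anchors whose window ran off a chromosome end (out-of-range bins are 0).
#' @export
coverage_matrix <- function(anchors, track, flank = NULL, n_bins = 50L,
                            mode = c("reference_point", "scale_regions"),
                            body_bins = 50L, flank_bins = 20L) {
  mode <- match.arg(mode)
  if (is.null(flank)) flank <- if (mode == "reference_point") 1000L else 2000L
  cov <- as_coverage_rle(track)
  n <- nrow(anchors)
  clipped <- logical(n)
  if (mode == "reference_point") {
    mat <- matrix(0, n, n_bins)
    bnd <- seq(-flank, flank, length.out = n_bins + 1)
    for (i in seq_len(n)) {
      starts <- floor(anchors$pos[i] + bnd[-(n_bins + 1)])
      ends <- floor(anchors$pos[i] + bnd[-1]) - 1
      res <- binned_means(cov, anchors$chrom[i], starts, ends)
      mat[i, ] <- res$means
      clipped[i] <- res$clipped
    }
  } else {
    total_bins <- body_bins + 2L * flank_bins
    mat <- matrix(0, n, total_bins)
    for (i in seq_len(n)) {
      s <- anchors$start[i]; e <- anchors$end[i]
      up <- seq(s - flank, s, length.out = flank_bins + 1)
      body <- seq(s, e + 1, length.out = body_bins + 1)
      down <- seq(e + 1, e + 1 + flank, length.out = flank_bins + 1)
      bnd <- c(up[-(flank_bins + 1)], body[-(body_bins + 1)],
               down)
      starts <- floor(bnd[-length(bnd)])
      ends <- pmax(ceiling(bnd[-1]) - 1, starts)
      res <- binned_means(cov, anchors$chrom[i], starts, ends)
      v <- res$means
      if (!is.null(anchors$strand) && anchors$strand[i] == "-")
        v <- rev(v)
      mat[i, ] <- v
      clipped[i] <- res$clipped
    }
  }
  attr(mat, "clipped") <- clipped
  mat
}

# mean coverage over [starts, ends] on one chromosome, clipping to bounds;
# fully out-of-range bins are 0
binned_means <- function(cov, chrom, starts, ends) {
  means <- numeric(length(starts))
  if (!chrom %in% names(cov))
    return(list(means = means, clipped = TRUE))
  rle <- cov[[chrom]]
  len <- length(rle)
  cs <- pmax(starts, 1L); ce <- pmin(ends, len)
  ok <- cs <= ce
  if (any(ok)) {
    v <- Views(rle, start = cs[ok], end = ce[ok])
    means[ok] <- viewMeans(v)
  }
  list(means = means, clipped = any(starts < 1 | ends > len))
}

as_coverage_rle <- function(track) {
  if (is(track, "GRanges")) {
    return(coverage(track, weight = "score"))
  }
  if (is.character(track) && length(track) == 1 && file.exists(track)) {
    return(coverage(rtracklayer::import(track, format = "bedGraph"),
                    weight = "score"))
  }
  if (is.data.frame(track)) {
    gr <- GRanges(track$chrom, IRanges(track$start, track$end),
                  score = track$score)
    return(coverage(gr, weight = "score"))
  }
  stop("track must be a GRanges with score, bedGraph path, or data.frame")
}

#' Variance-maximising projection of per-feature coverage at sites
#'
#' Summarises each chromatin feature by its mean coverage over the window
#' around every site (one value per site), then projects the feature x site
#' matrix onto its principal axes. Features whose coverage pattern at
#' integration sites differs from the rest (e.g. gene-body marks under an
#' integration bias) separate on the leading component.
#'
#' @param feature_matrices named list of site x bin matrices from
#'   [coverage_matrix], one per feature.
#' @return list: `scores` (feature x PC matrix), `sdev`, `var_explained`.
#' @export
coverage_pca <- function(feature_matrices) {
  stopifnot(length(feature_matrices) >= 2)
  m <- t(vapply(feature_matrices, rowMeans,
                numeric(nrow(feature_matrices[[1]]))))
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  list(scores = pc$x, sdev = pc$sdev,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}
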