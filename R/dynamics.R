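#' Classify clones into frequency bands
#'
#' Clones are banded by their maximum frequency across tracked timepoints:
#' strictly below the first quartile of the max-frequency distribution is
#' `low`, strictly above the third quartile is `high`, everything else
#' (including values equal to either quartile) is `medium`. Quartiles use
#' linear interpolation between order statistics ([stats::quantile] type 7).
#'
#' @param max_freqs numeric vector of per-clone maximum frequencies.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
classify_frequency_bands <- function(max_freqs) {
  n <- length(max_freqs)
  if (n < 4) {
    warning("fewer than 4 clones; all classified as medium")
    return(factor(rep("medium", n), levels = c("low", "medium", "high")))
  }
  q <- quantile(max_freqs, c(0.25, 0.75), names = FALSE, type = 7)
  band <- ifelse(max_freqs < q[1], "low",
                 ifelse(max_freqs > q[2], "high", "medium"))
  factor(band, levels = c("low", "medium", "high"))
}

#' Persistent clones
#'
#' A clone is persistent iff its frequency is strictly positive at every
#' tracked timepoint.
#'
#' @param freqs numeric matrix, clones x timepoints.
#' @return logical vector, one entry per clone.
#' @export
find_persistent <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) < 2) stop("need at least 2 timepoints")
  apply(freqs > 0, 1L, all)
}

#' Top clones at one timepoint
#'
#' The `k` highest-frequency clones, descending; exact frequency ties are
#' broken by site-key lexicographic order so results are deterministic.
#'
#' @param freqs named numeric vector of clone frequencies (names are site
#'   keys).
#' @param k number of clones to return (default 10).
#' @return character vector of site keys (length `min(k, #clones with
#'   names)`).
#' @export
top_clones <- function(freqs, k = 10L) {
  if (is.null(names(freqs))) names(freqs) <- seq_along(freqs)
  o <- order(-freqs, names(freqs), method = "radix")
  names(freqs)[o][seq_len(min(k, length(freqs)))]
}

#' Clone sharing between units (timepoints or tissues)
#'
#' `shared[i, j]` is the number of site keys detected in both unit i and
#' unit j (the diagonal is each unit's own size); `percent[i, j]` is
#' row-relative: 100 * |V_i intersect V_j| / |V_i|.
#'
#' @param site_sets named list of character vectors of site keys.
#' @return list with integer matrix `shared` and numeric matrix `percent`.
#' @export
sharing_matrix <- function(site_sets) {
  site_sets <- lapply(site_sets, unique)
  n <- length(site_sets)
  shared <- matrix(0L, n, n, dimnames = list(names(site_sets),
                                             names(site_sets)))
  for (i in seq_len(n)) for (j in seq_len(n))
    shared[i, j] <- length(intersect(site_sets[[i]], site_sets[[j]]))
  sizes <- vapply(site_sets, length, integer(1))
  percent <- 100 * sweep(shared, 1L, pmax(sizes, 1L), "/")
  percent[sizes == 0, ] <- NA_real_
  list(shared = shared, percent = percent)
}

#' Pearson correlation between two clone profiles
#'
#' Standard product-moment correlation, with explicit guards for the
#' degenerate inputs that silently produce NA in plain [stats::cor].
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  cor(x, y, method = "pearson")
}

#' Intraclass correlation, single-rater absolute agreement
#'
#' Replicate concordance of clonal profiles from the two-way ANOVA
#' decomposition of an n-clone x k-replicate matrix into row (clone), column
#' (replicate) and error mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' Unlike Pearson's r, absolute agreement penalises systematic shifts
#' between replicates, so it is the stricter reproducibility statistic. The
#' consistency form ((MS_R - MS_E) / (MS_R + (k-1) MS_E)), which ignores
#' column offsets, is available via `type = "consistency"`.
#'
#' @param data numeric matrix, n clones x k replicates, no missing cells.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return ICC estimate (at most 1; may be negative).
#' @export
icc_a1 <- function(data, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop("need at least 2 rows and 2 columns")
  if (any(is.na(data))) stop("no missing cells allowed")
  grand <- mean(data)
  if (all(data == grand)) stop("degenerate data")
  row_m <- rowMeans(data); col_m <- colMeans(data)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_t <- sum((data - grand)^2)
  ss_e <- ss_t - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  if (type == "agreement") {
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
  } else {
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  }
}

#' Longitudinal clone classification table
#'
#' Convenience driver over a replicate-merged frequency profile: per-clone
#' maximum frequency across an animal's timepoints, frequency band,
#' persistence, and membership in the union of per-timepoint top-`k` sets.
#'
#' @param fp a `frequency_profile` whose samples are one column per
#'   timepoint (e.g. from [merge_replicates] with `mean_frequency`).
#' @param animal optional animal id to subset the samples.
#' @param k top-clone set size per timepoint (default 10).
#' @return data.frame: site key columns plus `max_frequency`, `band`,
#'   `persistent`, `top_k`.
#' @export
classify_clones <- function(fp, animal = NULL, k = 10L) {
  cols <- seq_len(ncol(fp$p))
  if (!is.null(animal)) cols <- which(fp$samples$animal == animal)
  p <- fp$p[, cols, drop = FALSE]
  keys <- site_key(fp$sites)
  rownames(p) <- keys
  detected <- rowSums(p) > 0
  p <- p[detected, , drop = FALSE]
  max_f <- apply(p, 1L, max)
  top <- unique(unlist(lapply(seq_len(ncol(p)), function(j)
    top_clones(p[, j], k))))
  data.frame(
    fp$sites[detected, , drop = FALSE],
    max_frequency = max_f,
    band = classify_frequency_bands(max_f),
    # persistence is only defined across >= 2 tracked timepoints
    persistent = if (ncol(p) >= 2) find_persistent(p) else
      rep(NA, nrow(p)),
    top_k = rownames(p) %in% top,
    stringsAsFactors = FALSE
  )
}
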