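#' Renyi entropy of a clone frequency vector
#'
#' \deqn{H_\alpha = \frac{1}{1-\alpha} \log \sum_i p_i^\alpha}
#' in natural log units (nats), with the analytic limits at the special
#' orders: \eqn{H_0 = \log(richness)}, \eqn{H_1 = -\sum p_i \log p_i}
#' (Shannon), \eqn{H_2 = \log(1/\sum p_i^2)} (log inverse Simpson) and
#' \eqn{H_\infty = -\log \max p_i}. Zero-frequency clones are excluded from
#' the power sum (and do not count toward richness). `alpha` weights large
#' clones more as it grows, so the profile over a grid of orders summarises
#' both richness and evenness of a clonal population.
#'
#' @param p numeric vector of proportional abundances (non-negative, summing
#'   to 1 over the detected clones).
#' @param alpha a single non-negative order; `Inf` allowed.
#' @param base logarithm base (default `exp(1)` for nats).
#' @return The entropy \eqn{H_\alpha}.
#' @export
renyi_entropy <- function(p, alpha, base = exp(1)) {
  p <- p[p > 0]
  if (length(p) == 0) stop("no clones")
  stopifnot(length(alpha) == 1, alpha >= 0)
  if (abs(sum(p) - 1) > 1e-6)
    stop("frequencies must sum to 1")
  h <- if (is.infinite(alpha)) {
    -log(max(p))
  } else if (alpha == 1) {
    -sum(p * log(p))
  } else {
    log(sum(p^alpha)) / (1 - alpha)
  }
  h / log(base)
}

#' Default Renyi order grid
#'
#' Includes the interpretable orders 0 (log richness), 1 (Shannon), 2 (log
#' inverse Simpson) and Inf (top-clone share), with intermediate orders for
#' profile shape.
#' @return numeric vector of orders.
#' @export
default_alpha_grid <- function() c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, Inf)

#' Replicate-averaged Renyi diversity profiles
#'
#' Computes per-replicate frequency vectors from raw counts (vector
#' populations are pooled: the index label plays no role here), evaluates
#' \eqn{H_\alpha} on the order grid for every sample, and averages the
#' entropies over the replicates of each group. Averaging happens at the
#' statistic level, never at the count level.
#'
#' @param counts integer matrix, clones x samples (raw counts), or a
#'   [clonal_matrix].
#' @param replicate_groups factor/vector assigning each sample column to a
#'   replicate group (e.g. animal-timepoint); default: every column its own
#'   group. For a [clonal_matrix], defaults to all sample-sheet metadata
#'   except `sample_id`/`replicate`.
#' @param alpha_grid orders at which to evaluate (default
#'   [default_alpha_grid()]).
#' @param base logarithm base (default natural).
#' @return list of class `diversity_profile`: `alpha`, per-sample entropy
#'   matrix `H` (alpha x sample), and replicate-averaged `averaged_H`
#'   (alpha x group).
#' @export
diversity_profile <- function(counts, replicate_groups = NULL,
                              alpha_grid = default_alpha_grid(),
                              base = exp(1)) {
  if (inherits(counts, "clonal_matrix")) {
    if (is.null(replicate_groups)) {
      meta <- setdiff(names(counts$samples), c("sample_id", "replicate"))
      replicate_groups <- if (length(meta))
        do.call(paste, c(counts$samples[meta], sep = "_")) else NULL
    }
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (is.null(replicate_groups)) replicate_groups <- seq_len(ncol(counts))
  stopifnot(length(replicate_groups) == ncol(counts))
  H <- vapply(seq_len(ncol(counts)), function(j) {
    s <- counts[, j]
    if (sum(s) == 0) return(rep(NA_real_, length(alpha_grid)))
    p <- s / sum(s)
    vapply(alpha_grid, function(a) renyi_entropy(p, a, base), numeric(1))
  }, numeric(length(alpha_grid)))
  H <- matrix(H, nrow = length(alpha_grid),
              dimnames = list(as.character(alpha_grid), colnames(counts)))
  groups <- as.character(replicate_groups)
  ug <- unique(groups)
  avg <- vapply(ug, function(g)
    rowMeans(H[, groups == g, drop = FALSE], na.rm = TRUE),
    numeric(length(alpha_grid)))
  avg <- matrix(avg, nrow = length(alpha_grid),
                dimnames = list(as.character(alpha_grid), ug))
  structure(list(alpha = alpha_grid, H = H, averaged_H = avg),
            class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat("diversity_profile over", length(x$alpha), "orders x",
      ncol(x$H), "samples\n")
  print(round(x$averaged_H, 4))
  invisible(x)
}

#' Contribution of the highest-contributing clone
#'
#' Returns \eqn{p_{max} = \exp(-H_\infty)}, the frequency share of the top
#' clone, together with its reciprocal \eqn{\exp(H_\infty) = 1/p_{max}}
#' (the inverse Berger-Parker dominance, i.e. the Hill number of order
#' infinity) as attribute `inverse` for cross-checking.
#'
#' @param p numeric frequency vector.
#' @return `p_max` with attribute `inverse`.
#' @export
top_clone_contribution <- function(p) {
  h_inf <- renyi_entropy(p, Inf)
  structure(exp(-h_inf), inverse = exp(h_inf))
}
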