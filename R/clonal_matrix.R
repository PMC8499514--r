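#' VIS-by-sample count matrices
#'
#' A `clonal_matrix` holds deduplicated integration sites (rows), sample
#' metadata (columns) and a non-negative integer count matrix. The site key
#' is (chrom, pos, strand, index_label); `pos` is the 1-based coordinate of
#' the first host base at the junction.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `strand`,
#'   `index_label`.
#' @param samples data.frame with at least `sample_id`; typically also
#'   `animal`, `timepoint` (weeks), `tissue`, `replicate`, `population`.
#' @param counts integer matrix, `nrow(sites)` x `nrow(samples)`.
#' @return An object of class `clonal_matrix`.
#' @export
clonal_matrix <- function(sites, samples, counts) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  stopifnot(
    all(c("chrom", "pos", "strand", "index_label") %in% names(sites)),
    "sample_id" %in% names(samples),
    nrow(counts) == nrow(sites), ncol(counts) == nrow(samples)
  )
  if (anyDuplicated(site_key(sites))) stop("duplicate site keys")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_ids")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative integers")
  rownames(counts) <- site_key(sites)
  colnames(counts) <- samples$sample_id
  structure(list(sites = sites, samples = samples, counts = counts),
            class = "clonal_matrix")
}

#' @export
print.clonal_matrix <- function(x, ...) {
  cat("clonal_matrix:", nrow(x$sites), "sites x", nrow(x$samples),
      "samples;", sum(x$counts), "total reads\n")
  invisible(x)
}

#' @export
dim.clonal_matrix <- function(x) dim(x$counts)

#' Canonical site key strings
#' @param sites a site data.frame or `clonal_matrix`.
#' @return character vector `chrom:pos:strand:index_label`.
#' @export
site_key <- function(sites) {
  if (inherits(sites, "clonal_matrix")) sites <- sites$sites
  paste(sites$chrom, sites$pos, sites$strand, sites$index_label, sep = ":")
}

# subset a clonal_matrix by row index, dropping nothing else
cm_subset <- function(m, rows) {
  clonal_matrix(m$sites[rows, , drop = FALSE], m$samples,
                m$counts[rows, , drop = FALSE])
}

#' Write / read a clonal matrix as TSV
#'
#' One row per site (`chrom`, `pos`, `strand`, `index_label`) followed by
#' one count column per sample. The sample sheet is written alongside when
#' `samples_file` is given.
#'
#' @param m a [clonal_matrix].
#' @param file output TSV path.
#' @param samples_file optional path for the sample sheet TSV.
#' @export
write_clonal_matrix <- function(m, file, samples_file = NULL) {
  tab <- cbind(m$sites, as.data.frame(m$counts, check.names = FALSE))
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_file))
    write.table(m$samples, samples_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(file)
}

#' @rdname write_clonal_matrix
#' @param samples sample sheet data.frame or TSV path (columns matching the
#'   count columns of `file`).
#' @export
read_clonal_matrix <- function(file, samples) {
  tab <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  key_cols <- c("chrom", "pos", "strand", "index_label")
  counts <- as.matrix(tab[, samples$sample_id, drop = FALSE])
  clonal_matrix(tab[, key_cols], samples, counts)
}

#' Read a sample sheet TSV
#'
#' Expected columns: `sample_id`, `animal`, `timepoint`, `tissue`,
#' `replicate`, `population` (extra columns are preserved).
#'
#' @param file TSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(file) {
  read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
}
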