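#' LTR index sets
#'
#' An LTR index is a short barcode carried in the terminal bases of the
#' vector 3' U5 LTR; it distinguishes vector populations (e.g. a therapeutic
#' and a control vector) co-repopulating the same animal. An index set maps
#' labels to equal-length uppercase DNA barcodes.
#'
#' @param labels character vector of unique labels.
#' @param sequences character vector of index sequences (same length each,
#'   uppercase ACGT).
#' @return A named character vector of class `ltr_index_set`.
#' @examples
#' default_ltr_indexes()
#' @export
ltr_index_set <- function(labels, sequences) {
  stopifnot(length(labels) == length(sequences), length(labels) >= 1)
  if (anyDuplicated(labels)) stop("index labels must be unique")
  sequences <- toupper(sequences)
  if (length(unique(nchar(sequences))) != 1L)
    stop("all index sequences must have the same length")
  if (any(grepl("[^ACGT]", sequences)))
    stop("index sequences must be uppercase ACGT")
  structure(setNames(sequences, labels), class = "ltr_index_set")
}

#' @describeIn ltr_index_set The default three-vector index set: H1 and H5
#'   (control vector variants) and WT (the unmodified U5 terminus carried by
#'   the anti-HIV vector).
#' @export
default_ltr_indexes <- function() {
  ltr_index_set(
    labels    = c("H1", "H5", "WT"),
    sequences = c("TGGAAAATCTCCAACA", "TGGAAAATATCCAACA", "TGGAAAATCTCTAGCA")
  )
}

#' Classify the LTR index of a junction read
#'
#' Given the candidate index window of a read (the bases at the index
#' position inside the LTR, located via the LTR anchor), returns the label
#' whose barcode has the uniquely smallest Hamming distance to the window,
#' provided that distance is at most `max_mismatch`. Ties (two labels at the
#' same minimal distance) and windows shorter than the index length return
#' `"unclassified"` -- with barcodes differing at a single position, guessing
#' on a tie would systematically contaminate one population with the other.
#'
#' @param window character vector of candidate index windows (one per read).
#' @param index_set an [ltr_index_set].
#' @param max_mismatch maximum Hamming distance accepted (default 1).
#' @return character vector of labels, `"unclassified"` where no unique
#'   in-budget match exists.
#' @examples
#' classify_ltr_index("TGGAAAATCTCCAACA", default_ltr_indexes())
#' @export
classify_ltr_index <- function(window, index_set = default_ltr_indexes(),
                               max_mismatch = 1L) {
  stopifnot(inherits(index_set, "ltr_index_set") || is.character(index_set))
  idx_len <- nchar(index_set[[1]])
  window <- toupper(as.character(window))
  n <- length(window)
  out <- rep("unclassified", n)
  ok <- !is.na(window) & nchar(window) == idx_len
  if (!any(ok)) return(out)
  d <- hamming_to_each(window[ok], unname(index_set))
  best <- apply(d, 1L, min)
  n_best <- rowSums(d == best)
  hit <- best <= max_mismatch & n_best == 1L
  lab <- names(index_set)[apply(d, 1L, which.min)]
  out[ok][hit] <- lab[hit]
  out
}

# Hamming distance of each string in x (all same width) to each reference
# string; returns length(x) x length(refs) integer matrix. Vectorized over
# positions, not strings.
hamming_to_each <- function(x, refs) {
  w <- nchar(refs[1])
  d <- matrix(0L, nrow = length(x), ncol = length(refs))
  for (j in seq_len(w)) {
    cj <- substr(x, j, j)
    for (r in seq_along(refs)) {
      d[, r] <- d[, r] + (cj != substr(refs[r], j, j))
    }
  }
  d
}
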