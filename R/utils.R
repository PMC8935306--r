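## small shared helpers

.chr <- function(x) {
  if (is.character(x)) return(x)
  stats::setNames(as.character(x), names(x))
}

#' Banded edit distance between two sequences
#'
#' Unit-cost global alignment distance. The band is widened automatically to
#' cover any length difference; `band = 0` runs the full dynamic program.
#'
#' @param a,b character scalars or `DNAString`-like objects.
#' @param band band half-width around the main diagonal (0 = unbanded).
#' @return integer edit distance.
#' @export
editDist <- function(a, b, band = 0L) {
  .edit_distance_cpp(as.character(a), as.character(b), as.integer(band))
}

#' Pairwise identity of two sequences
#'
#' Identity is `1 - d / L` where `d` is the unit-cost global alignment
#' distance and `L` the alignment length.
#'
#' @inheritParams editDist
#' @return numeric in \[0, 1\].
#' @export
seqIdentity <- function(a, b) {
  pr <- .align_pair_cpp(as.character(a), as.character(b))
  1 - pr$dist / pr$length
}

#' Rand index between two partitions
#'
#' Agreement between two labelings of the same items: the fraction of item
#' pairs on which the partitions agree (placed together in both or apart in
#' both). Used to compare inferred homeolog groups with truth subgenome
#' labels.
#'
#' @param a,b vectors of group labels over the same items.
#' @return numeric in \[0, 1\]; 1 for identical partitions. `NA` for fewer
#'   than 2 items.
#' @export
randIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(NA_real_)
  idx <- utils::combn(n, 2)
  same_a <- a[idx[1, ]] == a[idx[2, ]]
  same_b <- b[idx[1, ]] == b[idx[2, ]]
  mean(same_a == same_b)
}

# deterministic ordering by one or more character keys
.ord <- function(...) do.call(order, list(..., method = "radix"))

.stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
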