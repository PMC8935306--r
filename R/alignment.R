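## Multiple alignment: deterministic center-star progressive alignment built
## on the unit-cost global aligner. Every input sequence is aligned to a
## center sequence and the pairwise alignments are merged on the center's
## coordinates, so de-gapping any output row recovers its input exactly.

# Align each of `seqs` (named character) to `center`; return list with the
# gapped center row and gapped rows for seqs, as a named character vector.
.star_align <- function(center, seqs, band = 0L) {
  L <- nchar(center)
  n <- length(seqs)
  aligned <- matrix("-", nrow = n, ncol = L)
  ins <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- .align_pair_cpp(center, seqs[[i]], band)
    ca <- strsplit(pr$a, "", fixed = TRUE)[[1]]
    sa <- strsplit(pr$b, "", fixed = TRUE)[[1]]
    is_c <- ca != "-"
    pos <- cumsum(is_c)                       # center coordinate per column
    aligned[i, pos[is_c]] <- sa[is_c]
    if (any(!is_c)) ins[[i]] <- split(sa[!is_c], pos[!is_c])  # slot -> chars
  }
  maxins <- integer(L + 1)                     # insertion slot 0..L -> index+1
  for (i in seq_len(n)) for (nm in names(ins[[i]])) {
    k <- as.integer(nm) + 1L
    maxins[k] <- max(maxins[k], length(ins[[i]][[nm]]))
  }
  Lw <- L + sum(maxins)
  ccol <- cumsum(maxins[seq_len(L)]) + seq_len(L)  # output column of center char p
  out <- matrix("-", nrow = n + 1L, ncol = Lw)
  if (L > 0) out[1L, ccol] <- strsplit(center, "", fixed = TRUE)[[1]]
  slot_start <- c(1L, ccol + 1L)               # first output column of slot 0..L
  for (i in seq_len(n)) {
    if (L > 0) out[i + 1L, ccol] <- aligned[i, ]
    for (nm in names(ins[[i]])) {
      v <- ins[[i]][[nm]]
      s0 <- slot_start[as.integer(nm) + 1L]
      out[i + 1L, s0:(s0 + length(v) - 1L)] <- v
    }
  }
  rows <- apply(out, 1L, paste, collapse = "")
  list(center = rows[1L], rows = stats::setNames(rows[-1L], names(seqs)))
}

# deterministic center choice: medoid for small inputs, else the sequence of
# median length (ties by name order)
.pick_center <- function(seqs, band = 64L) {
  n <- length(seqs)
  if (n <= 12) {
    D <- .pairwise_edit_cpp(unname(seqs), as.integer(band))
    tot <- rowSums(D)
    cand <- which(tot == min(tot))
  } else {
    w <- nchar(seqs)
    cand <- which(abs(w - stats::median(w)) == min(abs(w - stats::median(w))))
  }
  cand[.ord(names(seqs)[cand])[1L]]
}

#' Multiple sequence alignment (center-star)
#'
#' Deterministic progressive alignment: every sequence is globally aligned to
#' a center sequence (the medoid for up to 12 sequences, else the
#' median-length sequence, or a user-supplied anchor such as the locus
#' reference) and merged on the center's coordinates. Removing all gaps from
#' any output row returns the corresponding input sequence unchanged.
#'
#' @param seqs named `DNAStringSet` or named character vector (>= 1).
#' @param center optional anchor sequence (character or `DNAString`). When it
#'   is not one of `seqs` it guides the alignment but is not returned as a
#'   row.
#' @return a [Biostrings::DNAMultipleAlignment] with one row per input.
#' @export
alignSequences <- function(seqs, center = NULL) {
  s <- .chr(if (is(seqs, "XStringSet")) as.character(seqs) else seqs)
  .stop_if(length(s) < 1, "at least one sequence is required")
  if (is.null(names(s))) names(s) <- sprintf("seq%d", seq_along(s))
  .stop_if(anyDuplicated(names(s)) > 0, "sequence labels must be unique")
  if (length(s) == 1L && is.null(center))
    return(Biostrings::DNAMultipleAlignment(Biostrings::DNAStringSet(s)))
  if (is.null(center)) {
    ci <- .pick_center(s)
    sa <- .star_align(s[[ci]], s[-ci])
    rows <- c(stats::setNames(sa$center, names(s)[ci]), sa$rows)[names(s)]
  } else {
    sa <- .star_align(as.character(center), s)
    rows <- sa$rows[names(s)]
  }
  Biostrings::DNAMultipleAlignment(Biostrings::DNAStringSet(rows))
}

# normalize an alignment-like object to a named character vector of rows
.aln_rows <- function(aln) {
  if (is(aln, "DNAMultipleAlignment")) aln <- as(aln, "DNAStringSet")
  if (is(aln, "XStringSet")) aln <- stats::setNames(as.character(aln), names(aln))
  .stop_if(!is.character(aln), "expected an alignment (DNAMultipleAlignment, DNAStringSet or character)")
  .stop_if(length(unique(nchar(aln))) > 1, "alignment rows must have equal width")
  if (is.null(names(aln))) names(aln) <- sprintf("seq%d", seq_along(aln))
  aln
}
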