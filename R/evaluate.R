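## Truth-based evaluation of pipeline output on simulated data: template
## recovery by the clustering/consensus stage, agreement of homeolog groups
## with truth subgenome labels, and donor-clade placement of phased rows.

# alignment identity between a consensus and a template, ignoring columns
# where the consensus is N: masked positions are declared ambiguity, not
# errors (variable sites are deliberately written as N)
.identity_no_n <- function(cons_seq, template) {
  pr <- .align_pair_cpp(as.character(cons_seq), as.character(template))
  a <- strsplit(pr$a, "", fixed = TRUE)[[1]]
  b <- strsplit(pr$b, "", fixed = TRUE)[[1]]
  keep <- a != "N"
  if (!any(keep)) return(0)
  mean(a[keep] == b[keep])
}

#' Template recovery by clustering and consensus
#'
#' For every truth template of a simulated dataset, finds the best-matching
#' consensus haplotype at the same (sample, locus) and reports whether it
#' reaches `min_identity`. Identity is computed from a global alignment with
#' `N` consensus positions excluded: masked columns are declared ambiguity,
#' not errors.
#'
#' @param truth the `truth` list of an [AmpliconSim-class] (or the object
#'   itself).
#' @param cons the [ConsensusSet-class] to evaluate.
#' @param min_identity identity at or above which a template counts as
#'   recovered.
#' @return list with `recovered_frac`, `mean_identity` (mean best identity
#'   over templates), and `per_template` data.frame.
#' @export
templateRecovery <- function(truth, cons, min_identity = 0.99) {
  tt <- if (is(truth, "AmpliconSim")) truth@truth$templates else truth$templates
  info <- consensusInfo(cons)
  seqs <- as.character(consensusSeqs(cons))
  best <- numeric(nrow(tt))
  for (i in seq_len(nrow(tt))) {
    j <- which(info$sample == tt$sample[i] & info$locus == tt$locus[i])
    best[i] <- if (length(j))
      max(vapply(seqs[j], .identity_no_n, 0, tt$sequence[i])) else 0
  }
  list(recovered_frac = mean(best >= min_identity),
       mean_identity = mean(best),
       per_template = data.frame(sample = tt$sample, locus = tt$locus,
                                 hap = tt$hap, best_identity = best,
                                 recovered = best >= min_identity))
}

#' Truth subgenome label of each consensus haplotype
#'
#' Assigns every consensus haplotype the subgenome label of its nearest
#' truth template at the same (sample, locus) (global alignment identity).
#'
#' @inheritParams templateRecovery
#' @return character vector parallel to the consensus set (`NA` where no
#'   truth template exists for the pair).
#' @export
truthLabels <- function(truth, cons) {
  tt <- if (is(truth, "AmpliconSim")) truth@truth$templates else truth$templates
  info <- consensusInfo(cons)
  seqs <- as.character(consensusSeqs(cons))
  out <- rep(NA_character_, nrow(info))
  for (i in seq_len(nrow(info))) {
    j <- which(tt$sample == info$sample[i] & tt$locus == info$locus[i])
    if (!length(j)) next
    ident <- vapply(tt$sequence[j], function(tp) .identity_no_n(seqs[i], tp), 0)
    out[i] <- tt$subgenome[j[which.max(ident)]]
  }
  out
}

#' Agreement between homeolog groups and truth subgenomes
#'
#' Mean Rand index between the inferred homeolog grouping and the truth
#' subgenome labels, over all (sample, locus) pairs with at least two
#' haplotypes.
#'
#' @param hg a [HomeologGroups-class] from simulated data.
#' @inheritParams templateRecovery
#' @return list with `mean_rand` and `per_pair` data.frame.
#' @export
homeologRand <- function(truth, hg) {
  a <- homeologAssignment(hg)
  lab <- truthLabels(truth, hg@consensus)
  info <- consensusInfo(hg@consensus)
  a$truth <- lab[match(a$hap, info$hap)]
  res <- list()
  for (k in unique(paste(a$sample, a$locus, sep = "\r"))) {
    sub <- a[paste(a$sample, a$locus, sep = "\r") == k, ]
    if (nrow(sub) < 2 || anyNA(sub$truth)) next
    res[[length(res) + 1L]] <- data.frame(
      sample = sub$sample[1], locus = sub$locus[1],
      rand = randIndex(sub$group, sub$truth))
  }
  per <- do.call(rbind, res)
  list(mean_rand = if (is.null(per)) NA_real_ else mean(per$rand),
       per_pair = per)
}

#' Donor-clade placement of phased subgenome rows
#'
#' Maps each subgenome label to a truth ancestral genome by majority vote
#' over the phasing trace, and reports, per label, the bootstrap support of
#' the clade formed by its rows in the subset tree, plus the fraction of
#' haplotype assignments agreeing with the label-to-donor map.
#'
#' @param bundle one element of [runSubsets()] output (`matrix` + `tree`).
#' @inheritParams templateRecovery
#' @param hg the [HomeologGroups-class] that was phased.
#' @return list with `clades` (label, donor, n_rows, support) and
#'   `assignment_accuracy`.
#' @export
donorCladeCheck <- function(truth, bundle, hg) {
  tr <- phasingTrace(bundle$matrix)
  lab <- truthLabels(truth, hg@consensus)
  info <- consensusInfo(hg@consensus)
  tr$truth <- lab[match(tr$hap, info$hap)]
  tr <- tr[!is.na(tr$truth), ]
  map <- vapply(split(tr$truth, tr$label), function(v)
    names(sort(table(v), decreasing = TRUE))[1L], "")
  acc <- mean(map[tr$label] == tr$truth)
  rows <- phasedRows(bundle$matrix)
  clades <- do.call(rbind, lapply(sort(unique(rows$label)), function(lb) {
    tips <- rows$row[rows$label == lb]
    supp <- if (!is.null(bundle$tree) && length(tips) >= 2)
      cladeSupport(bundle$tree, tips) else NA_real_
    data.frame(label = lb, donor = unname(map[lb]), n_rows = length(tips),
               support = supp, stringsAsFactors = FALSE)
  }))
  list(clades = clades, assignment_accuracy = acc)
}
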