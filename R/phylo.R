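## Distance matrices, neighbor-joining trees, nonparametric bootstrap,
## Newick I/O and Robinson-Foulds comparison. Tree construction is
## delegated to ape (nj) and phangorn (RF.dist); this module owns the
## distance models, the bootstrap resampling contract and the
## bipartition-support bookkeeping the phasing and introgression stages
## rely on.

#' Pairwise distance matrix from an alignment
#'
#' p-distance over columns where both rows are unambiguous bases (gaps and
#' `N`s excluded pairwise), optionally Jukes-Cantor corrected:
#' `d = -3/4 log(1 - 4p/3)`.
#'
#' @param aln alignment (`DNAMultipleAlignment`, equal-width `DNAStringSet`
#'   or character vector).
#' @param model `"p"` or `"JC69"`.
#' @param max_dist distance assigned (and flagged via the `"saturated"`
#'   attribute) when `p >= 0.75` makes the JC69 correction undefined.
#' @return symmetric numeric matrix with an `ncomp` attribute of comparable
#'   site counts.
#' @export
distanceMatrix <- function(aln, model = c("p", "JC69"), max_dist = 5) {
  model <- match.arg(model)
  rows <- .aln_rows(aln)
  .stop_if(length(rows) < 2, "at least two rows are required")
  pr <- .pdist_aln_cpp(unname(rows), integer(0))
  D <- pr$p
  dimnames(D) <- list(names(rows), names(rows))
  sat <- matrix(FALSE, nrow(D), ncol(D))
  if (model == "JC69") {
    sat <- !is.na(D) & D >= 0.75
    D[!sat] <- -0.75 * log(1 - 4 * D[!sat] / 3)
    D[sat] <- max_dist
  }
  D[is.na(D)] <- max_dist
  attr(D, "ncomp") <- pr$n
  attr(D, "saturated") <- any(sat)
  D
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (ape::nj) with deterministic input ordering.
#' Negative branch lengths are set to zero and the deficit is moved to the
#' sister edge (itself clamped at zero).
#'
#' @param D symmetric distance matrix with unique row/column names.
#' @return an unrooted `phylo` tree.
#' @export
njTree <- function(D) {
  .stop_if(!is.matrix(D) || nrow(D) != ncol(D), "D must be a square matrix")
  .stop_if(max(abs(D - t(D))) > 1e-8, "D must be symmetric")
  .stop_if(nrow(D) < 3, "at least 3 taxa are required")
  o <- .ord(rownames(D))
  tr <- ape::nj(stats::as.dist(D[o, o]))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    sib <- which(tr$edge[, 1] == tr$edge[e, 1] & seq_along(tr$edge.length) != e)
    if (length(sib)) tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate and reports, per internal bipartition of the reference
#' tree, the percentage of replicates containing it. Bipartitions subtended
#' by a zero-length internal branch carry no signal and are reported with
#' support 0. Deterministic given `seed`.
#'
#' @inheritParams distanceMatrix
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return the reference NJ `phylo` with integer `node.label` supports
#'   (0-100; `NA` at the root).
#' @export
bootstrapSupport <- function(aln, n_reps = 100L, seed = 1L,
                             model = c("p", "JC69"), max_dist = 5) {
  model <- match.arg(model)
  .stop_if(n_reps < 1, "n_reps must be >= 1")
  rows <- .aln_rows(aln)
  rows <- rows[.ord(names(rows))]     # support invariant to row permutation
  L <- nchar(rows[1])
  ref <- njTree(distanceMatrix(rows, model = model, max_dist = max_dist))
  set.seed(seed)
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    D <- .pdist_aln_cpp(unname(rows), as.integer(w))$p
    if (model == "JC69") {
      sat <- !is.na(D) & D >= 0.75
      D[!sat] <- -0.75 * log(1 - 4 * D[!sat] / 3)
      D[sat] <- max_dist
    }
    D[is.na(D)] <- max_dist
    dimnames(D) <- list(names(rows), names(rows))
    boots[[b]] <- njTree(D)
  }
  cnt <- ape::prop.clades(ref, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  supp <- round(100 * cnt / n_reps)
  ## zero-length internal branches carry no phylogenetic signal
  int_edges <- ref$edge[, 2] > ape::Ntip(ref)
  zero_nodes <- ref$edge[int_edges & ref$edge.length <= 1e-9, 2]
  supp[zero_nodes - ape::Ntip(ref)] <- 0
  supp[1] <- NA                        # root of the rooted representation
  ref$node.label <- supp
  ref
}

#' Robinson-Foulds distance between two trees
#'
#' Number of bipartitions present in exactly one of the two trees
#' (unnormalized), plus the normalized form in \[0, 1\] (divided by
#' `2(n-3)`).
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @param prune when the leaf sets differ, prune both trees to their
#'   intersection instead of raising an error.
#' @return list with `rf` (count) and `normalized`.
#' @export
rfDistance <- function(t1, t2, prune = FALSE) {
  l1 <- t1$tip.label; l2 <- t2$tip.label
  if (!setequal(l1, l2)) {
    common <- intersect(l1, l2)
    if (!prune) stop("leaf sets differ (", length(setdiff(l1, l2)), " / ",
                     length(setdiff(l2, l1)), " unshared tips); ",
                     "set prune = TRUE to compare on the ", length(common),
                     " shared tips", call. = FALSE)
    .stop_if(length(common) < 4, "fewer than 4 shared tips after pruning")
    t1 <- ape::drop.tip(t1, setdiff(l1, common))
    t2 <- ape::drop.tip(t2, setdiff(l2, common))
  }
  rf <- suppressMessages(
    phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2), check.labels = TRUE))
  n <- length(t1$tip.label)
  list(rf = rf, normalized = if (n > 3) rf / (2 * (n - 3)) else NA_real_)
}

#' Read / write Newick trees
#'
#' Thin wrappers over ape preserving branch lengths and integer support
#' labels.
#'
#' @param path file path.
#' @return `readNewick`: a `phylo`; `writeNewick`: the path, invisibly.
#' @export
readNewick <- function(path) ape::read.tree(path)

#' @rdname readNewick
#' @param tree a `phylo` object.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

## bipartition helpers ------------------------------------------------------

# list of tip-label sets, one per internal node (rooted representation),
# with that node's support label
.clade_table <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  supp <- if (!is.null(tree$node.label)) suppressWarnings(as.numeric(tree$node.label))
          else rep(NA_real_, tree$Nnode)
  list(clades = lapply(pp, function(i) labs[i]), support = supp, tips = labs)
}

#' Support of a clade in a tree
#'
#' Returns the bootstrap support of the bipartition separating `tips` from
#' the remaining leaves, or `NA` when that bipartition is absent from the
#' tree. The trivial split (all tips or a single tip) returns `NA`.
#'
#' @param tree a `phylo` with `node.label` supports.
#' @param tips character vector of leaf labels.
#' @return numeric support or `NA`.
#' @export
cladeSupport <- function(tree, tips) {
  ct <- .clade_table(tree)
  all_tips <- ct$tips
  .stop_if(!all(tips %in% all_tips), "tips absent from the tree")
  if (length(tips) <= 1 || length(tips) >= length(all_tips)) return(NA_real_)
  comp <- setdiff(all_tips, tips)
  for (i in seq_along(ct$clades)) {
    cl <- ct$clades[[i]]
    if (setequal(cl, tips) || setequal(cl, comp)) {
      s <- ct$support[i]
      return(if (is.na(s) && i == 1L) 100 else s)  # root clade = whole tree
    }
  }
  NA_real_
}
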