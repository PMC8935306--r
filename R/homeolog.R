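## Homeolog vs allele discrimination: partition the consensus haplotypes of
## each (sample, locus) into homeolog groups by complete-linkage
## agglomeration, on the assumption that divergence between allelic
## sequences is smaller than between homeologous sequences. The dendrogram
## is cut at the largest between-merge gap subject to at most expected_k
## groups; a virtual ceiling (`max_allelic_div`) bounds the one-group
## solution so that a lone allelic pair is not split when a homeolog is
## missing from the data.

#' Expected number of homeologous sequences
#'
#' Half the sample ploidy for autosomal, pseudoautosomal and sex-linked
#' loci; always 1 for a male-specific locus, which amplifies as a single
#' copy in males regardless of ploidy.
#'
#' @param ploidy even integer >= 2.
#' @param locus_class one of `autosomal`, `pseudoautosomal`, `sex_linked`,
#'   `male_specific`.
#' @return integer count.
#' @export
expectedHomeologCount <- function(ploidy, locus_class) {
  locus_class <- match.arg(locus_class, LOCUS_CLASSES)
  .stop_if(length(ploidy) != 1 || is.na(ploidy) || ploidy < 2 || ploidy %% 2 != 0,
           "ploidy must be an even integer >= 2")
  if (locus_class == "male_specific") 1L else as.integer(ploidy / 2)
}

# choose the number of groups g <= max_k at the largest between-merge gap;
# heights h ascending (length n-1). For g = 1 the upper bound of the gap is
# the allelic/homeolog divergence ceiling.
.choose_cut <- function(h, max_k, ceiling_div) {
  n <- length(h) + 1L
  gmax <- min(max_k, n)
  gaps <- vapply(seq_len(gmax), function(g) {
    upper <- if (g == 1L) ceiling_div else h[n - g + 1L]
    lower <- if (g == n) 0 else h[n - g]
    upper - lower
  }, 0)
  ## ties go to the finer partition (smaller maximum within-group distance)
  max(which(gaps >= max(gaps) - 1e-12))
}

#' Partition consensus haplotypes into homeolog groups
#'
#' Complete-linkage agglomeration on pairwise p-distances (computed on a
#' center-star alignment, excluding gapped and `N` sites pairwise), cut at
#' the largest between-merge gap with at most `expected_k` groups. Fewer
#' than `expected_k` groups are returned when the data support fewer
#' (missing homeologs are tolerated). Within each group the representative
#' is the haplotype with the most supporting reads (ties: fewest `N`s, then
#' name order).
#'
#' @param haps a [ConsensusSet-class] restricted to one (sample, locus), or
#'   a named `DNAStringSet`/character vector.
#' @param expected_k maximum number of homeolog groups (ploidy/2; 1 for a
#'   male-specific locus).
#' @param max_allelic_div divergence ceiling (substitutions/site) below
#'   which sequences are treated as allelic variants of one homeolog.
#' @param support optional supporting-read counts when `haps` is not a
#'   `ConsensusSet`.
#' @return list with `assignment` (data.frame `hap`, `group`,
#'   `representative`) and `stats` (group count, max within-group and min
#'   between-group divergence, separation ratio, `forced` and `excess`
#'   flags).
#' @export
partitionHomeologs <- function(haps, expected_k, max_allelic_div = 0.02,
                               support = NULL) {
  if (is(haps, "ConsensusSet")) {
    info <- consensusInfo(haps)
    seqs <- stats::setNames(as.character(consensusSeqs(haps)), info$hap)
    support <- stats::setNames(info$reads, info$hap)
  } else {
    seqs <- .chr(haps)
    if (is.null(names(seqs))) names(seqs) <- sprintf("hap%d", seq_along(seqs))
    if (is.null(support)) support <- stats::setNames(rep(1L, length(seqs)), names(seqs))
    else support <- stats::setNames(support, names(seqs))
  }
  .stop_if(length(seqs) == 0, "haps must be non-empty")
  .stop_if(expected_k < 1, "expected_k must be >= 1")
  seqs <- seqs[.ord(names(seqs))]           # input-order independence

  excess <- length(seqs) > 2L * expected_k
  if (excess) {
    warning("more haplotypes than 2 x expected_k; keeping the best supported ",
            "(possible contamination)", call. = FALSE)
    keep <- names(seqs)[.ord(-support[names(seqs)], names(seqs))][seq_len(2L * expected_k)]
    seqs <- seqs[sort(keep)]
  }
  n <- length(seqs)
  if (n == 1L) {
    return(list(assignment = data.frame(hap = names(seqs), group = 1L,
                                        representative = TRUE),
                stats = list(n_groups = 1L, max_within = 0,
                             min_between = NA_real_, separation = NA_real_,
                             forced = FALSE, excess = excess)))
  }
  aln <- .aln_rows(alignSequences(seqs))
  D <- .pdist_aln_cpp(unname(aln), integer(0))$p
  D[is.na(D)] <- 0
  dimnames(D) <- list(names(aln), names(aln))
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  h <- hc$height
  g <- .choose_cut(h, expected_k, max_allelic_div)
  grp <- stats::cutree(hc, k = g)[names(seqs)]
  ## would the ceiling alone have produced more than expected_k groups?
  forced <- sum(h >= max_allelic_div) + 1L > expected_k

  within <- 0; between <- NA_real_
  if (g > 1L) {
    same <- outer(grp, grp, "==")
    within <- max(c(0, D[same & upper.tri(D)]))
    between <- min(D[!same & upper.tri(D)])
  } else if (n > 1L) {
    within <- max(D[upper.tri(D)])
  }
  sep <- if (g > 1L) between / max(within, 1e-9) else NA_real_

  nN <- vapply(seqs, function(s) sum(strsplit(s, "", fixed = TRUE)[[1]] == "N"), 0L)
  rep_flag <- rep(FALSE, n)
  for (gg in seq_len(g)) {
    mem <- which(grp == gg)
    best <- mem[.ord(-support[names(seqs)[mem]], nN[mem], names(seqs)[mem])[1L]]
    rep_flag[best] <- TRUE
  }
  ## relabel groups deterministically by first member name
  first <- vapply(seq_len(g), function(gg) min(names(seqs)[grp == gg]), "")
  relab <- match(grp, seq_len(g)[.ord(first)])
  list(assignment = data.frame(hap = names(seqs), group = relab,
                               representative = rep_flag,
                               stringsAsFactors = FALSE),
       stats = list(n_groups = g, max_within = within, min_between = between,
                    separation = sep, forced = forced, excess = excess))
}

#' Resolve homeologs across all samples and loci
#'
#' Applies [partitionHomeologs()] to every (sample, locus) of a consensus
#' set, sizing `expected_k` from ploidy and locus class via
#' [expectedHomeologCount()].
#'
#' @param cons a [ConsensusSet-class] (typically the `retained` output of
#'   [depthFilter()]).
#' @param samples sample sheet with `sample` and `ploidy`.
#' @param loci a [LocusSet-class].
#' @param max_allelic_div see [partitionHomeologs()].
#' @return a [HomeologGroups-class].
#' @export
resolveHomeologs <- function(cons, samples, loci, max_allelic_div = 0.02) {
  info <- consensusInfo(cons)
  assign_l <- list(); diag_l <- list()
  key <- unique(info[, c("sample", "locus")])
  key <- key[.ord(key$sample, key$locus), , drop = FALSE]
  for (i in seq_len(nrow(key))) {
    sm <- key$sample[i]; loc <- key$locus[i]
    sub <- consensusSubset(cons, sample = sm, locus = loc)
    pl <- samples$ploidy[samples$sample == sm]
    k <- expectedHomeologCount(pl, locusClass(loci)[[loc]])
    pt <- partitionHomeologs(sub, expected_k = k,
                             max_allelic_div = max_allelic_div)
    a <- pt$assignment
    a$sample <- sm; a$locus <- loc
    assign_l[[i]] <- a[, c("sample", "locus", "hap", "group", "representative")]
    diag_l[[i]] <- data.frame(sample = sm, locus = loc,
                              n_haps = nrow(a), n_groups = pt$stats$n_groups,
                              max_within = pt$stats$max_within,
                              min_between = pt$stats$min_between,
                              separation = pt$stats$separation,
                              forced = pt$stats$forced, excess = pt$stats$excess,
                              stringsAsFactors = FALSE)
  }
  new("HomeologGroups", consensus = cons,
      assignment = do.call(rbind, assign_l),
      diagnostics = do.call(rbind, diag_l))
}

#' Within- vs between-group divergence diagnostic
#'
#' Summarizes, per (sample, locus), the maximum within-group (allelic) and
#' minimum between-group (homeolog) divergence, flagging pairs where the two
#' scales overlap (incomplete separation between sequence types).
#' Single-group pairs carry no between-group distance and are excluded.
#'
#' @param hg a [HomeologGroups-class].
#' @return data.frame with columns `sample`, `locus`, `max_within`,
#'   `min_between`, `overlap`.
#' @export
separationDiagnostic <- function(hg) {
  d <- hg@diagnostics
  d <- d[d$n_groups > 1L, , drop = FALSE]
  data.frame(sample = d$sample, locus = d$locus,
             max_within = d$max_within, min_between = d$min_between,
             overlap = d$max_within >= d$min_between,
             stringsAsFactors = FALSE)
}
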