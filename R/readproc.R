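## Read clustering and consensus calling: the per-(sample, locus)
## deconvolution of error-prone long reads into unique template sequences.
## Greedy farthest-point seeding followed by k-medoids-style refinement
## against interim consensus sequences, then a depth filter at
## `factor x ploidy` supporting reads.

# majority-vote consensus of member sequences star-aligned to a scaffold.
# Returns list(sequence, n_masked).
.vote_consensus <- function(scaffold, members, mask_ambiguous = TRUE,
                            mask_threshold = 0.7, band = 0L) {
  sa <- .star_align(scaffold, members, band = band)
  rows <- sa$rows
  m <- matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
              nrow = length(rows), byrow = TRUE)
  symbols <- c("A", "C", "G", "T", "N", "-")
  code <- matrix(match(m, symbols), nrow = nrow(m))
  counts <- vapply(seq_len(ncol(code)), function(j)
    tabulate(code[, j], nbins = 6L), integer(6))       # 6 x L
  top <- apply(counts, 2L, which.max)                   # ties: A<C<G<T<N<-
  keep <- top != 6L                                     # drop gap-majority columns
  base_tot <- colSums(counts[1:4, , drop = FALSE])
  maj_frac <- ifelse(base_tot > 0,
                     counts[cbind(pmin(top, 5L), seq_along(top))] / base_tot, 0)
  out <- symbols[top]
  if (mask_ambiguous) out[keep & top <= 4L & maj_frac < mask_threshold] <- "N"
  out <- out[keep & top <= 5L]
  list(sequence = paste(out, collapse = ""), n_masked = sum(out == "N"))
}

# consensus with a deterministic member subsample and iterative re-polish
.consensus_of <- function(seqs, scaffold, mask_ambiguous = TRUE,
                          mask_threshold = 0.7, max_reads = 50L, rounds = 2L,
                          band = 0L) {
  s <- .chr(seqs)
  if (length(s) > max_reads) s <- s[sort(names(s))[seq_len(max_reads)]]
  cons <- scaffold
  n_masked <- 0L
  for (r in seq_len(rounds)) {
    v <- .vote_consensus(cons, s, mask_ambiguous = mask_ambiguous && r == rounds,
                         mask_threshold = mask_threshold, band = band)
    cons <- v$sequence
    n_masked <- v$n_masked
  }
  list(sequence = cons, n_masked = n_masked)
}

#' Cluster the reads of one sample and locus
#'
#' Groups reads into clusters representing unique template sequences.
#' Clusters are seeded from the longest reads by farthest-point selection
#' (up to `expected_k + 1` seeds), then refined by reassigning every read to
#' the nearest interim consensus; near-identical clusters are merged, reads
#' below `identity_floor` to every centroid are set aside, and clusters
#' smaller than `min_cluster_reads` are dropped. The procedure is fully
#' deterministic.
#'
#' @param reads named `DNAStringSet` (or named character vector) of reads.
#' @param expected_k expected number of templates (ploidy/2 for regular
#'   loci, 1 for a male-specific locus).
#' @param identity_floor minimum alignment identity to any centroid for a
#'   read to be retained, in (0, 1).
#' @param min_cluster_reads minimum supporting reads per cluster.
#' @param seed accepted for interface stability; the algorithm is
#'   deterministic and draws no random numbers.
#' @param band band half-width for read alignments.
#' @param ref_length optional locus reference length; reads shorter than half
#'   of it are dropped as non-specific amplification products.
#' @param max_iter refinement iterations.
#' @param merge_identity consensus identity at or above which two clusters
#'   are considered variants of the same template and merged (default 0.99:
#'   allelic variants, an order of magnitude below homeolog divergence, are
#'   collapsed into one cluster whose variable sites the consensus masks
#'   with N, rather than split into under-supported consensuses).
#' @return list of [ReadCluster-class], ordered by decreasing size. May be
#'   empty when all reads are filtered.
#' @export
clusterReads <- function(reads, expected_k, identity_floor = 0.8,
                         min_cluster_reads = 5L, seed = 1L, band = 48L,
                         ref_length = NULL, max_iter = 3L,
                         merge_identity = 0.99) {
  .stop_if(identity_floor <= 0 || identity_floor >= 1,
           "identity_floor must lie in (0, 1)")
  .stop_if(expected_k < 1, "expected_k must be >= 1")
  s <- .chr(reads)
  .stop_if(length(s) == 0, "reads must be non-empty")
  if (is.null(names(s))) names(s) <- sprintf("read%05d", seq_along(s))
  if (!is.null(ref_length)) s <- s[nchar(s) >= 0.5 * ref_length]
  if (length(s) == 0) return(list())
  ord <- .ord(-nchar(s), names(s))
  s <- s[ord]

  ## farthest-point seeding from the longest read
  k2 <- min(length(s), expected_k + 1L)
  seed_idx <- 1L
  if (k2 > 1) {
    D <- .dist_to_centroids_cpp(unname(s), unname(s[seed_idx]), band)
    for (j in seq_len(k2 - 1L)) {
      dmin <- apply(D, 1L, min)
      if (max(dmin) == 0) break
      nxt <- which.max(dmin)
      seed_idx <- c(seed_idx, nxt)
      D <- cbind(D, .dist_to_centroids_cpp(unname(s), unname(s[nxt]), band))
    }
  }
  cents <- unname(s[seed_idx])

  assign_to <- function(cents) {
    D <- .dist_to_centroids_cpp(unname(s), cents, band)
    cl <- max.col(-D, ties.method = "first")
    ident <- 1 - D[cbind(seq_along(s), cl)] /
      pmax(nchar(s), nchar(cents)[cl])
    cl[ident < identity_floor] <- NA_integer_
    cl
  }

  cl <- assign_to(cents)
  for (it in seq_len(max_iter)) {
    keep <- !is.na(cl)
    sizes <- tabulate(cl[keep], nbins = length(cents))
    live <- which(sizes > 0)
    ## interim consensus per cluster, clusters ordered by size then centroid
    cents <- vapply(live, function(g) {
      mem <- s[keep & cl == g]
      .consensus_of(mem, cents[g], mask_ambiguous = FALSE, max_reads = 30L,
                    rounds = 1L, band = band)$sequence
    }, "")
    o <- .ord(-sizes[live], cents)
    cents <- cents[o]
    cl_new <- assign_to(cents)
    if (identical(cl_new, cl) && length(cents) == length(live)) { cl <- cl_new; break }
    cl <- cl_new
  }

  ## merge clusters whose consensuses are (near-)identical
  if (length(cents) > 1) {
    Dc <- .pairwise_edit_cpp(cents, band)
    parent <- seq_along(cents)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(cents)) for (j in seq_len(i - 1L)) {
      idn <- 1 - Dc[i, j] / max(nchar(cents[i]), nchar(cents[j]))
      if (idn >= merge_identity) parent[find(i)] <- find(j)
    }
    grp <- vapply(seq_along(cents), find, 1L)
    if (length(unique(grp)) < length(cents)) {
      cl <- match(grp[cl], sort(unique(grp)))
      cents <- cents[sort(unique(grp))]
    }
  }

  keep <- !is.na(cl)
  sizes <- tabulate(cl[keep], nbins = length(cents))
  ## dissolve under-supported clusters beyond expected_k: an extra cluster
  ## (over-seeded read, allelic split) is only kept as its own template when
  ## it can support an accurate consensus; otherwise its reads rejoin the
  ## nearest surviving cluster
  min_split <- max(2L, 2L * as.integer(min_cluster_reads))
  repeat {
    live_n <- which(sizes > 0)
    if (length(live_n) <= expected_k) break
    small <- live_n[.ord(sizes[live_n], cents[live_n])][1L]
    if (sizes[small] >= min_split) break
    others <- setdiff(live_n, small)
    if (!length(others)) break
    idx <- which(keep & cl == small)
    D1 <- .dist_to_centroids_cpp(unname(s[idx]), cents[others], band)
    for (r in seq_along(idx)) {
      b <- others[which.min(D1[r, ])]
      idn <- 1 - min(D1[r, ]) / max(nchar(s[idx[r]]), nchar(cents[b]))
      cl[idx[r]] <- if (idn >= identity_floor) b else NA_integer_
    }
    keep <- !is.na(cl)
    sizes <- tabulate(cl[keep], nbins = length(cents))
  }
  live <- which(sizes >= max(1L, min_cluster_reads))
  if (!length(live)) return(list())
  live <- live[.ord(-sizes[live], cents[live])]
  live <- utils::head(live, expected_k + 1L)
  lapply(live, function(g) {
    mem <- s[keep & cl == g]
    new("ReadCluster", ids = names(mem), seqs = Biostrings::DNAStringSet(mem),
        centroid = cents[g])
  })
}

#' Call a masked consensus for a read cluster
#'
#' Majority vote over a multiple alignment of the member reads (star-aligned
#' to the cluster centroid, re-polished once). Columns whose majority symbol
#' is a gap are deleted; with `mask_ambiguous`, base columns whose majority
#' fraction falls below `mask_threshold` are written as `N`.
#'
#' @param cluster a [ReadCluster-class].
#' @param mask_ambiguous mask low-agreement columns with `N`?
#' @param mask_threshold majority fraction below which a column is masked.
#' @param max_reads deterministic member subsample size for the alignment.
#' @param sample,locus optional identifiers recorded in the result.
#' @param hap haplotype label recorded in the result.
#' @return one-row [ConsensusSet-class].
#' @export
callConsensus <- function(cluster, mask_ambiguous = TRUE, mask_threshold = 0.7,
                          max_reads = 50L, sample = NA_character_,
                          locus = NA_character_, hap = "hap1", band = 48L) {
  .stop_if(!is(cluster, "ReadCluster"), "cluster must be a ReadCluster")
  cs <- .consensus_of(cluster@seqs, cluster@centroid,
                      mask_ambiguous = mask_ambiguous,
                      mask_threshold = mask_threshold, max_reads = max_reads,
                      band = band)
  nm <- paste(sample, locus, hap, sep = "|")
  new("ConsensusSet",
      seqs = Biostrings::DNAStringSet(stats::setNames(cs$sequence, nm)),
      info = data.frame(hap = nm, sample = sample, locus = locus,
                        reads = clusterSize(cluster), n_masked = cs$n_masked,
                        stringsAsFactors = FALSE))
}

#' Cluster and call consensus for every (sample, locus)
#'
#' Runs [clusterReads()] and [callConsensus()] over all read sets of a
#' simulated or loaded dataset, sizing `expected_k` from the sample ploidy
#' (ploidy/2; 1 at a male-specific locus).
#'
#' @param sim an [AmpliconSim-class] (or list with `reads`, `samples`,
#'   `loci`).
#' @param identity_floor,min_cluster_reads,mask_threshold,band tuning
#'   parameters, see [clusterReads()] and [callConsensus()].
#' @return a [ConsensusSet-class] over all samples and loci.
#' @export
processReads <- function(sim, identity_floor = 0.8, min_cluster_reads = 5L,
                         mask_threshold = 0.7, band = 48L) {
  reads <- if (is(sim, "AmpliconSim")) sim@reads else sim$reads
  samples <- if (is(sim, "AmpliconSim")) sim@samples else sim$samples
  loci <- if (is(sim, "AmpliconSim")) sim@loci else sim$loci
  out <- list()
  for (sm in names(reads)) {
    pl <- samples$ploidy[samples$sample == sm]
    for (loc in names(reads[[sm]])) {
      rs <- reads[[sm]][[loc]]
      if (length(rs) == 0) next
      cls <- locusClass(loci)[[loc]]
      k <- if (cls == "male_specific") 1L else as.integer(pl / 2)
      clusters <- clusterReads(rs, expected_k = k,
                               identity_floor = identity_floor,
                               min_cluster_reads = min_cluster_reads,
                               band = band,
                               ref_length = Biostrings::width(refSequences(loci)[loc]))
      for (i in seq_along(clusters)) {
        out[[length(out) + 1L]] <- callConsensus(
          clusters[[i]], mask_threshold = mask_threshold, band = band,
          sample = sm, locus = loc, hap = sprintf("hap%d", i))
      }
    }
  }
  if (!length(out)) {
    return(new("ConsensusSet", seqs = Biostrings::DNAStringSet(),
               info = data.frame(hap = character(0), sample = character(0),
                                 locus = character(0), reads = integer(0),
                                 n_masked = integer(0))))
  }
  new("ConsensusSet",
      seqs = do.call(c, lapply(out, consensusSeqs)),
      info = do.call(rbind, lapply(out, consensusInfo)))
}

#' Coverage filter at a multiple of the ploidy at the target locus
#'
#' Excludes a (sample, locus) when its total supporting reads are smaller
#' than `factor` times the ploidy at that locus; a pair exactly at the
#' threshold is retained. The ploidy at a regular locus is the sample's
#' ploidy; at a hemizygous male-specific locus it is 1 (the locus is
#' single-copy regardless of genome ploidy), which requires `loci` to be
#' supplied.
#'
#' @param cons a [ConsensusSet-class].
#' @param samples sample sheet with columns `sample` and `ploidy`.
#' @param factor coverage multiplier (default 10).
#' @param loci optional [LocusSet-class]; without it every locus is treated
#'   as a regular (non-hemizygous) locus.
#' @return list with `retained` (filtered `ConsensusSet`), `excluded`
#'   (data.frame of excluded pairs with depths) and `report` (all pairs).
#' @export
depthFilter <- function(cons, samples, factor = 10L, loci = NULL) {
  .stop_if(factor < 1, "factor must be >= 1")
  info <- consensusInfo(cons)
  unknown <- setdiff(unique(info$sample), samples$sample)
  .stop_if(length(unknown) > 0,
           paste("unknown ploidy for sample(s):", paste(unknown, collapse = ", ")))
  depth <- stats::aggregate(reads ~ sample + locus, data = info, FUN = sum)
  depth$ploidy <- samples$ploidy[match(depth$sample, samples$sample)]
  if (!is.null(loci)) {
    ms <- locusNames(loci)[locusClass(loci) == "male_specific"]
    depth$ploidy[depth$locus %in% ms] <- 1L
  }
  depth$threshold <- factor * depth$ploidy
  depth$retained <- depth$reads >= depth$threshold
  key <- paste(info$sample, info$locus)
  ok <- key %in% paste(depth$sample, depth$locus)[depth$retained]
  list(retained = new("ConsensusSet", seqs = consensusSeqs(cons)[ok],
                      info = info[ok, , drop = FALSE]),
       excluded = depth[!depth$retained,
                        c("sample", "locus", "reads", "ploidy", "threshold")],
       report = depth)
}
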