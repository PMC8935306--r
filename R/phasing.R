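## Sequential phylogeny-guided homeolog phasing. Diploid samples are
## unambiguous (one sequence per locus) and define subgenome anchor clades
## on the first locus's tree; at every further locus each sample's homeolog
## representatives are assigned to its subgenome rows by optimal bipartite
## matching of patristic distances to the anchor clades, homeologs matching
## no clade open a new (flagged) row, and loci missing for a sample are
## gap-filled. The result is a concatenated per-subgenome alignment.

# representatives of one locus as a data.frame
.locus_reps <- function(hg, locus) {
  r <- representatives(hg, locus)
  if (!nrow(r$info))
    return(data.frame(sample = character(0), hap = character(0),
                      seq = character(0)))
  data.frame(sample = r$info$sample, hap = r$info$hap,
             seq = as.character(r$seqs), stringsAsFactors = FALSE)
}

# alignment and patristic distances among this locus's representatives
.locus_geometry <- function(reps, ref) {
  aln <- .aln_rows(alignSequences(stats::setNames(reps$seq, reps$hap),
                                  center = ref))
  if (nrow(reps) >= 3) {
    D <- distanceMatrix(aln, model = "p")
    PD <- ape::cophenetic.phylo(njTree(D))
    PD <- PD[reps$hap, reps$hap, drop = FALSE]
  } else {
    PD <- .pdist_aln_cpp(unname(aln), integer(0))$p
    PD[is.na(PD)] <- 0
    dimnames(PD) <- list(names(aln), names(aln))
  }
  list(aln = aln, PD = PD)
}

# enumerate injective assignments of haps to labels (or NEW) and return the
# cheapest; deterministic enumeration order makes ties reproducible.
.best_matching <- function(haps, labels, cost, sample_rows, max_rows,
                           denovo_cost) {
  free_slots <- max_rows - length(sample_rows)
  best <- NULL; best_cost <- Inf; n_min <- 0L
  recurse <- function(i, used, new_used, acc, cur_cost) {
    if (cur_cost > best_cost + 1e-12) return()
    if (i > length(haps)) {
      if (cur_cost < best_cost - 1e-12) {
        best <<- acc; best_cost <<- cur_cost; n_min <<- 1L
      } else n_min <<- n_min + 1L
      return()
    }
    h <- haps[i]
    for (lb in labels) {
      if (lb %in% used) next
      is_new_row <- !(lb %in% sample_rows)
      if (is_new_row && new_used >= free_slots) next
      recurse(i + 1L, c(used, lb), new_used + is_new_row,
              c(acc, stats::setNames(lb, h)), cur_cost + cost(h, lb))
    }
    if (new_used < free_slots)                       # brand-new label
      recurse(i + 1L, used, new_used + 1L,
              c(acc, stats::setNames("NEW", h)), cur_cost + denovo_cost)
  }
  recurse(1L, character(0), 0L, character(0), 0)
  list(assign = best, cost = best_cost, tie = n_min > 1L)
}

.next_label <- function(labels) {
  cand <- c(LETTERS, paste0("S", seq_len(100)))
  cand[!cand %in% labels][1L]
}

#' Build the anchor frame from the first locus
#'
#' Aligns the first locus's homeolog representatives, builds its
#' neighbor-joining tree, clusters the diploid samples into subgenome anchor
#' clades (diploids carry exactly one sequence and are therefore
#' unambiguous), labels the clades `A`, `B`, ... and assigns every
#' polyploid's homeologs at that locus to the anchors by optimal matching.
#'
#' @param hg a [HomeologGroups-class].
#' @param samples sample sheet (`sample`, `ploidy`).
#' @param loci a [LocusSet-class].
#' @param locus identifier of the anchor locus.
#' @param max_allelic_div allelic divergence ceiling, see
#'   [partitionHomeologs()].
#' @param anchor_div divergence ceiling separating diploid anchor clades
#'   (default twice `max_allelic_div`).
#' @param denovo_cost patristic distance above which a homeolog opens a new
#'   subgenome row instead of joining an anchor clade.
#' @return a `PhasingState` list; feed to [phaseLocus()] and
#'   [buildPhasedMatrix()].
#' @export
anchorFrame <- function(hg, samples, loci, locus, max_allelic_div = 0.02,
                        anchor_div = 2 * max_allelic_div, denovo_cost = 0.05) {
  reps <- .locus_reps(hg, locus)
  .stop_if(nrow(reps) == 0, "no representatives at the anchor locus")
  dip <- samples$sample[samples$ploidy == 2]
  dip_present <- sort(intersect(dip, reps$sample))
  .stop_if(length(dip_present) < 2,
           "phasing needs at least two diploid anchor samples at the first locus")
  state <- list(samples = samples, loci = loci, hg = hg,
                params = list(max_allelic_div = max_allelic_div,
                              anchor_div = anchor_div,
                              denovo_cost = denovo_cost),
                labels = character(0),
                diploid_labels = character(0),
                rows = data.frame(sample = character(0), label = character(0)),
                segs = list(), widths = integer(0),
                trace = list(), loci_done = character(0))

  geom <- .locus_geometry(reps, as.character(refSequences(loci)[[locus]]))
  dip_haps <- reps$hap[match(dip_present, reps$sample)]
  Dd <- geom$PD[dip_haps, dip_haps, drop = FALSE]
  if (length(dip_present) == 2L) {
    g <- if (Dd[1, 2] <= anchor_div) c(1L, 1L) else c(1L, 2L)
  } else {
    ## anchors separate at an absolute scale: diploids of one ancestral
    ## genome differ at allelic divergence, anything beyond anchor_div is a
    ## different subgenome (a relative largest-gap rule would collapse
    ## shallow splits whenever one deep split dominates the dendrogram)
    hc <- stats::hclust(stats::as.dist(Dd), method = "complete")
    g <- stats::cutree(hc, h = anchor_div)
  }
  first <- vapply(seq_len(max(g)), function(k) min(dip_present[g == k]), "")
  g <- match(g, seq_len(max(g))[.ord(first)])
  state$labels <- LETTERS[seq_len(max(g))]
  state$diploid_labels <- stats::setNames(state$labels[g], dip_present)
  .phase_one(state, locus, reps, geom)
}

# core per-locus assignment step, shared by anchorFrame and phaseLocus
.phase_one <- function(state, locus, reps, geom) {
  PD <- geom$PD
  anchors <- lapply(stats::setNames(nm = state$labels), function(lb) {
    ds <- names(state$diploid_labels)[state$diploid_labels == lb]
    reps$hap[reps$sample %in% ds]
  })
  trace <- list()
  for (sm in sort(unique(reps$sample))) {
    haps <- sort(reps$hap[reps$sample == sm])
    pl <- state$samples$ploidy[state$samples$sample == sm]
    max_rows <- pl / 2
    .stop_if(length(haps) > max_rows,
             sprintf("%s at %s: %d representatives exceed ploidy/2 = %d",
                     sm, locus, length(haps), max_rows))
    sample_rows <- state$rows$label[state$rows$sample == sm]
    if (sm %in% names(state$diploid_labels)) {
      ## anchored diploid: its label is fixed
      lb <- state$diploid_labels[[sm]]
      asg <- stats::setNames(lb, haps[1L])
      tie <- FALSE; cost_tot <- 0
    } else {
      cost <- function(h, lb) {
        a <- setdiff(anchors[[lb]], reps$hap[reps$sample == sm])
        if (length(a)) min(PD[h, a]) else state$params$denovo_cost
      }
      m <- .best_matching(haps, state$labels, cost, sample_rows, max_rows,
                          state$params$denovo_cost)
      asg <- m$assign; tie <- m$tie; cost_tot <- m$cost
    }
    for (h in names(asg)) {
      lb <- asg[[h]]
      denovo <- FALSE
      if (lb == "NEW") {
        lb <- .next_label(state$labels)
        state$labels <- c(state$labels, lb)
        anchors[[lb]] <- character(0)
        denovo <- TRUE
      }
      if (!any(state$rows$sample == sm & state$rows$label == lb))
        state$rows <- rbind(state$rows, data.frame(sample = sm, label = lb))
      ## unlabeled diploids become anchors for subsequent loci
      if (pl == 2 && !(sm %in% names(state$diploid_labels)))
        state$diploid_labels[sm] <- lb
      row_id <- paste(sm, lb, sep = "|")
      state$segs[[locus]][[row_id]] <- geom$aln[[h]]
      trace[[length(trace) + 1L]] <- data.frame(
        locus = locus, sample = sm, hap = h, label = lb,
        cost = cost_tot, tie = tie, denovo = denovo, stringsAsFactors = FALSE)
    }
  }
  state$widths[[locus]] <- nchar(geom$aln[[1L]])
  state$trace[[locus]] <- do.call(rbind, trace)
  state$loci_done <- c(state$loci_done, locus)
  state
}

#' Phase one further locus into the current frame
#'
#' Aligns the locus's representatives, builds its tree, and assigns each
#' sample's homeologs to existing subgenome rows by minimizing the summed
#' patristic distance to the rows' anchor-clade members (optimal bipartite
#' matching). Homeologs farther than `denovo_cost` from every anchor open a
#' new, flagged row (never more than ploidy/2 rows per sample).
#'
#' @param state a `PhasingState` from [anchorFrame()].
#' @param locus locus identifier to phase.
#' @return the updated `PhasingState`.
#' @export
phaseLocus <- function(state, locus) {
  .stop_if(!length(state$labels), "anchor frame must be built first")
  reps <- .locus_reps(state$hg, locus)
  if (nrow(reps) == 0) {
    state$widths[[locus]] <- 0L
    state$loci_done <- c(state$loci_done, locus)
    return(state)
  }
  geom <- .locus_geometry(reps, as.character(refSequences(state$loci)[[locus]]))
  .phase_one(state, locus, reps, geom)
}

#' Assemble the phased matrix
#'
#' Concatenates the per-locus aligned segments row-wise; loci missing for a
#' row are filled with gaps. Rows present at fewer than `min_presence` of
#' the loci are dropped from the alignment (they remain in the trace).
#'
#' @param state a `PhasingState` after all loci are phased.
#' @param min_presence minimum fraction of loci a row must cover.
#' @return a [PhasedMatrix-class].
#' @export
buildPhasedMatrix <- function(state, min_presence = 0.5) {
  loci_use <- state$loci_done[vapply(state$loci_done,
                                     function(l) state$widths[[l]] > 0, TRUE)]
  rows <- state$rows[.ord(state$rows$sample, state$rows$label), , drop = FALSE]
  row_ids <- paste(rows$sample, rows$label, sep = "|")
  presence <- matrix(FALSE, nrow = length(row_ids), ncol = length(loci_use),
                     dimnames = list(row_ids, loci_use))
  seq_l <- stats::setNames(rep(list(character(0)), length(row_ids)), row_ids)
  for (loc in loci_use) {
    w <- state$widths[[loc]]
    seg <- state$segs[[loc]]
    for (r in row_ids) {
      piece <- seg[[r]]
      if (is.null(piece)) piece <- strrep("-", w) else presence[r, loc] <- TRUE
      seq_l[[r]] <- c(seq_l[[r]], piece)
    }
  }
  keep <- rowMeans(presence) >= min_presence
  rows_kept <- row_ids[keep]
  aln <- Biostrings::DNAStringSet(vapply(seq_l[rows_kept], paste, "", collapse = ""))
  names(aln) <- rows_kept
  starts <- cumsum(c(1L, unlist(state$widths[loci_use])))
  new("PhasedMatrix", alignment = aln,
      rowInfo = data.frame(row = rows_kept, sample = rows$sample[keep],
                           label = rows$label[keep], stringsAsFactors = FALSE),
      trace = do.call(rbind, state$trace),
      presence = presence[keep, , drop = FALSE],
      locusCols = data.frame(locus = loci_use,
                             start = starts[seq_along(loci_use)],
                             end = starts[-1L] - 1L))
}

# default locus ordering: anchor on the locus with the most diploid
# representatives, then by reference width
.default_locus_order <- function(hg, samples, loci, loci_sub) {
  dip <- samples$sample[samples$ploidy == 2]
  a <- homeologAssignment(hg)
  ndip <- vapply(loci_sub, function(l)
    length(unique(a$sample[a$locus == l & a$sample %in% dip])), 1L)
  w <- Biostrings::width(refSequences(loci)[loci_sub])
  loci_sub[.ord(-ndip, -w, loci_sub)]
}

#' Phase homeologs across a set of loci
#'
#' End-to-end phasing: anchor frame on the first locus, sequential
#' [phaseLocus()] over the remaining loci (in `locus_order`, by default the
#' locus richest in diploid anchors first, then by reference length), and
#' matrix assembly.
#'
#' @inheritParams anchorFrame
#' @param locus_order character vector of loci to phase, in order
#'   (default: all loci of `loci`, auto-ordered).
#' @param min_presence see [buildPhasedMatrix()].
#' @return a [PhasedMatrix-class].
#' @export
phaseHomeologs <- function(hg, samples, loci, locus_order = NULL,
                           max_allelic_div = 0.02,
                           anchor_div = 2 * max_allelic_div,
                           denovo_cost = 0.05, min_presence = 0.5) {
  if (is.null(locus_order))
    locus_order <- .default_locus_order(hg, samples, loci, locusNames(loci))
  .stop_if(length(locus_order) < 1, "at least one locus is required")
  state <- anchorFrame(hg, samples, loci, locus_order[1L],
                       max_allelic_div = max_allelic_div,
                       anchor_div = anchor_div, denovo_cost = denovo_cost)
  for (loc in locus_order[-1L]) state <- phaseLocus(state, loc)
  buildPhasedMatrix(state, min_presence = min_presence)
}

#' Phase subsets of loci and build their trees
#'
#' Runs the full phasing independently for the complete locus panel and for
#' the autosomal, pseudoautosomal and sex-linked subsets, builds a
#' bootstrapped neighbor-joining tree per subset, and reports which samples'
#' subgenome rows fall into which well-supported clades.
#'
#' @inheritParams phaseHomeologs
#' @param subsets named list mapping bundle names to locus-class vectors;
#'   the default mirrors \{all, autosomal, pseudoautosomal, sex_linked\}.
#' @param boot_reps bootstrap replicates per subset tree.
#' @param seed integer seed for the bootstrap.
#' @param support_threshold clade support (percent) for the membership
#'   report.
#' @return named list of bundles, each `list(matrix, tree, clades)`; empty
#'   subsets are skipped with a warning.
#' @export
runSubsets <- function(hg, samples, loci,
                       subsets = list(all = LOCUS_CLASSES,
                                      autosomal = "autosomal",
                                      pseudoautosomal = "pseudoautosomal",
                                      sex_linked = "sex_linked"),
                       boot_reps = 100L, seed = 1L, support_threshold = 95,
                       max_allelic_div = 0.02, denovo_cost = 0.05,
                       min_presence = 0.5) {
  out <- list()
  for (nm in names(subsets)) {
    loci_sub <- locusNames(loci)[locusClass(loci) %in% subsets[[nm]]]
    loci_sub <- intersect(loci_sub, unique(homeologAssignment(hg)$locus))
    if (!length(loci_sub)) {
      warning("subset '", nm, "' has no loci with data; skipped", call. = FALSE)
      next
    }
    ord <- .default_locus_order(hg, samples, loci, loci_sub)
    pm <- phaseHomeologs(hg, samples, loci, locus_order = ord,
                         max_allelic_div = max_allelic_div,
                         denovo_cost = denovo_cost, min_presence = min_presence)
    tree <- NULL; clades <- NULL
    if (length(phasedAlignment(pm)) >= 4) {
      tree <- bootstrapSupport(phasedAlignment(pm), n_reps = boot_reps,
                               seed = seed)
      ct <- .clade_table(tree)
      keep <- which(!is.na(ct$support) & ct$support >= support_threshold)
      clades <- data.frame(
        clade = sprintf("%s_c%02d", nm, seq_along(keep)),
        support = ct$support[keep],
        n_members = vapply(ct$clades[keep], length, 1L),
        members = vapply(ct$clades[keep], paste, "", collapse = ","),
        stringsAsFactors = FALSE)
    }
    out[[nm]] <- list(matrix = pm, tree = tree, clades = clades)
  }
  out
}

#' Locus-order sensitivity of the phasing
#'
#' Reruns the phasing under random locus orders and reports, per rerun, the
#' fraction of haplotype-to-row assignments identical to the default-order
#' result after the best per-sample subgenome relabeling.
#'
#' @inheritParams phaseHomeologs
#' @param n_orders number of random orders.
#' @param seed integer seed.
#' @return list with `fractions` (per rerun) and `mean`.
#' @export
phasingOrderDiagnostic <- function(hg, samples, loci, n_orders = 10L, seed = 1L,
                                   ...) {
  base <- phasingTrace(phaseHomeologs(hg, samples, loci, ...))
  ord0 <- .default_locus_order(hg, samples, loci,
                               intersect(locusNames(loci),
                                         unique(homeologAssignment(hg)$locus)))
  set.seed(seed)
  frac <- vapply(seq_len(n_orders), function(i) {
    ord <- c(ord0[1L], sample(ord0[-1L]))   # anchor locus kept first
    tr <- phasingTrace(phaseHomeologs(hg, samples, loci, locus_order = ord, ...))
    .assignment_agreement(base, tr)
  }, 0)
  list(fractions = frac, mean = mean(frac))
}

# fraction of identical (sample, locus, hap) -> label assignments after the
# best per-sample label bijection
.assignment_agreement <- function(tr1, tr2) {
  key <- function(tr) paste(tr$sample, tr$locus, tr$hap)
  common <- intersect(key(tr1), key(tr2))
  a <- tr1$label[match(common, key(tr1))]
  b <- tr2$label[match(common, key(tr2))]
  sm <- tr1$sample[match(common, key(tr1))]
  tot <- 0L
  for (s in unique(sm)) {
    i <- sm == s
    la <- a[i]; lb <- b[i]
    labs_a <- unique(la); labs_b <- unique(lb)
    if (length(labs_a) > 4 || length(labs_b) > 4) {   # match greedily
      tot <- tot + sum(la == lb); next
    }
    ## best bijection between label sets (small, enumerate)
    perms <- .permutations(labs_b)
    best <- 0L
    for (p in perms) {
      mp <- stats::setNames(p[seq_along(labs_a)], labs_a)
      best <- max(best, sum(mp[la] == lb, na.rm = TRUE))
    }
    tot <- tot + best
  }
  tot / length(common)
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  out
}
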