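## Male-specific (hemizygous Y) locus analysis: sex-specific
## presence/absence of amplification, shared-indel scoring on the Y
## alignment, and a two-tree discordance rule that flags Y introgression
## when a male's Y-locus placement is incompatible with every well-supported
## clade containing his genome-wide subgenome rows.

#' Sex-specific presence/absence of male-specific loci
#'
#' Tabulates, per sample and male-specific locus, whether a consensus was
#' recovered (`amplified`), absent (`absent`) or lost to the coverage filter
#' (`failed`), and issues a sex-linkage verdict per locus: `male_specific`
#' when at least `min_male_frac` of males amplified and no female or
#' monoecious sample did; `rejected` when any non-male amplified;
#' `undeterminable` without males in the panel. Males that did not amplify
#' are listed as exceptions.
#'
#' @param cons a [ConsensusSet-class] (post depth filter).
#' @param samples sample sheet with `sample` and `sex`.
#' @param loci a [LocusSet-class].
#' @param excluded optional data.frame of depth-filtered pairs
#'   (`sample`, `locus`), reported as `failed`.
#' @param min_male_frac fraction of males that must amplify.
#' @return list with `matrix` (long data.frame sample x locus), `verdict`
#'   (per locus) and `exceptions` (males without amplification).
#' @export
presenceAbsence <- function(cons, samples, loci, excluded = NULL,
                            min_male_frac = 0.8) {
  ms <- locusNames(loci)[locusClass(loci) == "male_specific"]
  .stop_if(length(ms) == 0, "no male_specific locus in the panel")
  .stop_if(!"sex" %in% names(samples), "sample sheet must carry sex phenotypes")
  info <- consensusInfo(cons)
  cells <- expand.grid(sample = samples$sample, locus = ms,
                       stringsAsFactors = FALSE)
  cells$sex <- samples$sex[match(cells$sample, samples$sample)]
  amp <- paste(info$sample, info$locus)
  fail <- if (!is.null(excluded) && nrow(excluded))
    paste(excluded$sample, excluded$locus) else character(0)
  key <- paste(cells$sample, cells$locus)
  cells$status <- ifelse(key %in% amp, "amplified",
                         ifelse(key %in% fail, "failed", "absent"))
  verdicts <- do.call(rbind, lapply(ms, function(loc) {
    cc <- cells[cells$locus == loc, ]
    males <- cc[cc$sex == "male", ]
    others <- cc[cc$sex != "male", ]
    v <- if (nrow(males) == 0) "undeterminable"
         else if (any(others$status == "amplified")) "rejected"
         else if (mean(males$status == "amplified") >= min_male_frac) "male_specific"
         else "inconclusive"
    data.frame(locus = loc, verdict = v,
               males_amplified = sum(males$status == "amplified"),
               males_total = nrow(males),
               nonmales_amplified = sum(others$status == "amplified"),
               stringsAsFactors = FALSE)
  }))
  exceptions <- cells[cells$sex == "male" & cells$status != "amplified",
                      c("sample", "locus", "status")]
  rownames(exceptions) <- NULL
  list(matrix = cells, verdict = verdicts, exceptions = exceptions)
}

#' Shared indel events in an alignment
#'
#' Reports maximal column runs with an identical gap/non-gap contrast across
#' rows, at least `min_len` columns long, together with the set of rows
#' carrying the event. With a designated outgroup row the events are
#' polarized: a gap in the outgroup makes the non-gapped rows insertion
#' carriers; a residue in the outgroup makes the gapped rows deletion
#' carriers. Without an outgroup events are reported unpolarized (kind
#' `indel`, carriers = gapped rows). Output is independent of row order.
#'
#' @param aln alignment of male-specific sequences (>= 3 rows).
#' @param min_len minimum event length in columns.
#' @param outgroup optional row label used for polarization.
#' @return data.frame: `start`, `length`, `kind`, `carriers`
#'   (comma-separated, sorted).
#' @export
sharedIndels <- function(aln, min_len = 2L, outgroup = NULL) {
  rows <- .aln_rows(aln)
  .stop_if(length(rows) < 3, "at least 3 aligned rows are required")
  rows <- rows[.ord(names(rows))]
  if (!is.null(outgroup))
    .stop_if(!outgroup %in% names(rows), "outgroup row not found")
  m <- matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
              nrow = length(rows), byrow = TRUE, dimnames = list(names(rows)))
  gap <- m == "-"
  pat <- apply(gap, 2L, paste, collapse = "")
  informative <- colSums(gap) > 0 & colSums(gap) < nrow(gap)
  r <- rle(paste(pat, informative))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$lengths)) {
    if (!informative[starts[i]] || r$lengths[i] < min_len) next
    gapped <- rownames(m)[gap[, starts[i]]]
    ungapped <- setdiff(rownames(m), gapped)
    if (is.null(outgroup)) {
      kind <- "indel"; carriers <- gapped
    } else if (outgroup %in% gapped) {
      kind <- "insertion"; carriers <- setdiff(ungapped, outgroup)
    } else {
      kind <- "deletion"; carriers <- setdiff(gapped, outgroup)
    }
    if (!length(carriers)) next
    out[[length(out) + 1L]] <- data.frame(
      start = starts[i], length = r$lengths[i], kind = kind,
      carriers = paste(sort(carriers), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(0), length = integer(0),
                      kind = character(0), carriers = character(0)))
  do.call(rbind, out)
}

# strongest support of a proper bipartition side grouping `a` with `b`
# while excluding every leaf in `exclude`; 0 when no such side exists.
.pair_support <- function(tree, a, b, exclude = character(0)) {
  ct <- .clade_table(tree)
  best <- 0
  for (i in seq_along(ct$clades)) {
    cl <- ct$clades[[i]]
    for (side in list(cl, setdiff(ct$tips, cl))) {
      if (length(side) >= length(ct$tips)) next
      if (!(a %in% side && b %in% side)) next
      if (any(exclude %in% side)) next
      s <- ct$support[i]; if (is.na(s)) s <- 0
      best <- max(best, s)
    }
  }
  best
}

#' Flag Y-chromosome introgression by tree incongruence
#'
#' The male-specific locus is hemizygous and descends from exactly one
#' subgenome, so a native Y should be nearest, on the Y tree, to the Y of a
#' diploid anchor male whose subgenome label (from the phased genome tree)
#' is among the focal male's own subgenome labels. For each focal male the
#' nearest diploid-male anchor is found by patristic distance; when its
#' label is foreign to every subgenome the focal sample carries, and the
#' placement is bootstrap-supported at `support_threshold`, the sample is
#' flagged as an introgression candidate (a supported placement with a
#' foreign label but weak support is reported as unsupported discordance).
#' The donor lineage's own males stay nearest their own label, which breaks
#' the donor/recipient symmetry. Also reports the Robinson-Foulds distance
#' between the Y tree and the genome tree reduced to one row per shared
#' sample.
#'
#' @param y_tree `phylo` on sample ids (male-specific locus), with bootstrap
#'   `node.label`s.
#' @param genome_tree `phylo` on subgenome rows (`sample|label`), with
#'   bootstrap `node.label`s.
#' @param samples sample sheet with `sample`, `lineage`, `sex` and `ploidy`.
#' @param focal sample ids to test (default: all leaves of `y_tree`).
#' @param support_threshold bootstrap support required for a discordance to
#'   be flagged (default 70).
#' @param shallow_frac a foreign-label placement only counts as introgression
#'   when the nearest anchor sits closer than this fraction of the smallest
#'   between-label anchor divergence (recent transfer signature); a
#'   foreign-label nearest anchor at ordinary species-level distance merely
#'   means the matching subgenome has no anchor male and is reported as
#'   `unresolved`.
#' @return list with `report` (per focal sample: nearest anchor, its label,
#'   own labels, support, status) and `rf` (tree distance).
#' @export
introgressionTest <- function(y_tree, genome_tree, samples, focal = NULL,
                              support_threshold = 70, shallow_frac = 0.5) {
  if (is.null(focal)) focal <- y_tree$tip.label
  .stop_if(!all(focal %in% y_tree$tip.label),
           "focal sample(s) absent from the male-specific tree")
  g_leaves <- genome_tree$tip.label
  g_sample <- sub("\\|.*$", "", g_leaves)
  g_label <- ifelse(grepl("\\|", g_leaves), sub("^.*\\|", "", g_leaves), g_leaves)
  labels_of <- split(g_label, g_sample)
  lineage_of <- stats::setNames(samples$lineage, samples$sample)
  anchors <- samples$sample[samples$ploidy == 2 & samples$sex == "male"]
  anchors <- sort(intersect(intersect(anchors, y_tree$tip.label), g_sample))
  Dy <- ape::cophenetic.phylo(y_tree)

  rep_rows <- vapply(split(g_leaves, g_sample), function(v) sort(v)[1L], "")
  shared <- intersect(names(rep_rows), y_tree$tip.label)
  rf <- if (length(shared) >= 4) {
    gt <- ape::keep.tip(genome_tree, unname(rep_rows[shared]))
    gt$tip.label <- g_sample[match(gt$tip.label, g_leaves)]
    rfDistance(ape::keep.tip(y_tree, shared), gt)
  } else list(rf = NA_integer_, normalized = NA_real_)

  report <- do.call(rbind, lapply(focal, function(f) {
    own <- labels_of[[f]]
    if (is.null(own))
      stop("focal sample '", f, "' has no rows in the genome tree", call. = FALSE)
    cand <- setdiff(anchors, f)
    if (!length(cand))
      return(data.frame(sample = f, lineage = unname(lineage_of[f]),
                        nearest_anchor = NA_character_,
                        anchor_label = NA_character_,
                        own_labels = paste(sort(own), collapse = ","),
                        support = NA_real_, status = "undeterminable",
                        stringsAsFactors = FALSE))
    d <- Dy[f, cand]
    a <- cand[.ord(d, cand)[1L]]
    lab <- sort(labels_of[[a]])[1L]
    own_anchors <- cand[vapply(cand, function(x)
      any(labels_of[[x]] %in% own), TRUE)]
    supp <- .pair_support(y_tree, f, a, exclude = setdiff(own_anchors, a))
    ## native Y divergence scale: smallest distance between anchors of
    ## different subgenome labels
    scale <- Inf
    if (length(anchors) >= 2) {
      for (i in seq_along(anchors)) for (j in seq_len(i - 1L)) {
        if (identical(labels_of[[anchors[i]]], labels_of[[anchors[j]]])) next
        scale <- min(scale, Dy[anchors[i], anchors[j]])
      }
    }
    shallow <- is.finite(scale) && unname(d[.ord(d, cand)[1L]]) <= shallow_frac * scale
    status <- if (lab %in% own) "concordant"
              else if (!shallow) "unresolved"
              else if (supp >= support_threshold) "introgression_candidate"
              else "unsupported_discordance"
    data.frame(sample = f, lineage = unname(lineage_of[f]),
               nearest_anchor = a, anchor_label = lab,
               own_labels = paste(sort(own), collapse = ","),
               support = supp, status = status, stringsAsFactors = FALSE)
  }))
  list(report = report, rf = rf)
}
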