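#' Target loci with chromosomal class labels
#'
#' A set of reference amplicon loci. Each locus carries one of the four
#' chromosomal classes: `autosomal`, `pseudoautosomal`, `sex_linked`
#' (inside the non-recombining region) or `male_specific` (hemizygous,
#' Y-linked, amplifying as a single copy in males regardless of ploidy).
#'
#' @slot seqs named [Biostrings::DNAStringSet] of reference sequences.
#' @slot locusClass named character vector of classes, parallel to `seqs`.
#' @export
setClass("LocusSet", representation(seqs = "DNAStringSet", locusClass = "character"))

setValidity("LocusSet", function(object) {
  msg <- character(0)
  nm <- names(object@seqs)
  if (length(object@seqs) == 0) msg <- c(msg, "at least one locus is required")
  if (is.null(nm) || anyDuplicated(nm)) msg <- c(msg, "locus names must be unique and non-empty")
  if (length(object@locusClass) != length(object@seqs))
    msg <- c(msg, "locusClass must be parallel to seqs")
  if (!all(object@locusClass %in% LOCUS_CLASSES))
    msg <- c(msg, paste("locus classes must be one of:", paste(LOCUS_CLASSES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a LocusSet
#' @param seqs named `DNAStringSet` (or named character vector) of references.
#' @param locusClass character vector of classes, recycled names from `seqs`.
#' @return a [LocusSet-class] object.
#' @export
LocusSet <- function(seqs, locusClass) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  obj <- new("LocusSet", seqs = seqs,
             locusClass = stats::setNames(as.character(locusClass), names(seqs)))
  validObject(obj)
  obj
}

#' @describeIn LocusSet-class locus identifiers
#' @param x a `LocusSet`.
#' @export
locusNames <- function(x) names(x@seqs)

#' @describeIn LocusSet-class chromosomal class per locus
#' @export
locusClass <- function(x) x@locusClass

#' @describeIn LocusSet-class reference sequences
#' @export
refSequences <- function(x) x@seqs

setMethod("show", "LocusSet", function(object) {
  cat("LocusSet with", length(object@seqs), "loci\n")
  print(table(object@locusClass))
})

#' Simulated amplicon dataset with ground truth
#'
#' Container produced by [simulateDataset()]: per-(sample, locus) reads, the
#' sample sheet, the locus definitions, and the truth tables (template
#' sequences with subgenome labels, read provenance, introgression flags).
#'
#' @slot reads nested list `sample -> locus -> DNAStringSet` of reads.
#' @slot samples data.frame with columns `sample`, `lineage`, `sex`, `ploidy`.
#' @slot loci a [LocusSet-class].
#' @slot truth list with elements `templates`, `reads`, `introgression`.
#' @slot config list of generator settings (history, error model, depth, seed).
#' @export
setClass("AmpliconSim", representation(
  reads = "list", samples = "data.frame", loci = "LocusSet",
  truth = "list", config = "list"))

setMethod("show", "AmpliconSim", function(object) {
  nr <- sum(vapply(object@reads, function(s) sum(vapply(s, length, 1L)), 1L))
  cat("AmpliconSim:", nrow(object@samples), "samples,",
      length(object@loci@seqs), "loci,", nr, "reads\n")
  cat("  ploidies:", paste(sort(unique(object@samples$ploidy)), collapse = "/"),
      " males:", sum(object@samples$sex == "male"), "\n")
  if (nrow(object@truth$introgression) > 0)
    cat("  introgression:", paste(object@truth$introgression$recipient,
        "<-", object@truth$introgression$donor), "\n")
})

#' @describeIn AmpliconSim-class sample sheet
#' @param x an `AmpliconSim`.
#' @export
sampleSheet <- function(x) x@samples

#' @describeIn AmpliconSim-class ground-truth tables
#' @export
simTruth <- function(x) x@truth

#' @describeIn AmpliconSim-class reads of one sample and locus
#' @param sample,locus identifiers.
#' @export
sampleReads <- function(x, sample, locus) x@reads[[sample]][[locus]]

#' A cluster of reads representing one template sequence
#'
#' @slot ids read identifiers of the members.
#' @slot seqs member reads.
#' @slot centroid polished centroid/consensus scaffold of the cluster.
#' @export
setClass("ReadCluster", representation(
  ids = "character", seqs = "DNAStringSet", centroid = "character"))

setValidity("ReadCluster", function(object) {
  if (length(object@ids) != length(object@seqs)) return("ids and seqs differ in length")
  if (length(object@ids) < 1) return("a cluster needs at least one read")
  TRUE
})

setMethod("show", "ReadCluster", function(object) {
  cat("ReadCluster of", length(object@ids), "reads, centroid",
      nchar(object@centroid), "bp\n")
})

#' @describeIn ReadCluster-class number of member reads
#' @param x a `ReadCluster`.
#' @export
clusterSize <- function(x) length(x@ids)

#' Consensus haplotypes across samples and loci
#'
#' One row per inferred unique template sequence at a (sample, locus), with
#' its supporting-read count. Sequences may contain `N` at positions masked
#' as ambiguous.
#'
#' @slot seqs named `DNAStringSet`, names `sample|locus|hapN`.
#' @slot info data.frame with columns `hap`, `sample`, `locus`, `reads`,
#'   `n_masked`.
#' @export
setClass("ConsensusSet", representation(seqs = "DNAStringSet", info = "data.frame"))

setValidity("ConsensusSet", function(object) {
  need <- c("hap", "sample", "locus", "reads", "n_masked")
  if (!all(need %in% names(object@info))) return("info is missing required columns")
  if (length(object@seqs) != nrow(object@info)) return("seqs and info differ in length")
  if (length(object@seqs) && any(Biostrings::width(object@seqs) == 0))
    return("consensus sequences must be non-empty")
  if (length(object@seqs) && any(object@info$reads < 1))
    return("supporting read counts must be >= 1")
  TRUE
})

setMethod("show", "ConsensusSet", function(object) {
  cat("ConsensusSet:", length(object@seqs), "consensus haplotypes over",
      length(unique(object@info$sample)), "samples x",
      length(unique(object@info$locus)), "loci\n")
})

#' @describeIn ConsensusSet-class metadata table
#' @param x a `ConsensusSet`.
#' @export
consensusInfo <- function(x) x@info

#' @describeIn ConsensusSet-class consensus sequences
#' @export
consensusSeqs <- function(x) x@seqs

#' @describeIn ConsensusSet-class subset by sample and/or locus
#' @param sample,locus optional identifiers to keep.
#' @export
consensusSubset <- function(x, sample = NULL, locus = NULL) {
  keep <- rep(TRUE, nrow(x@info))
  if (!is.null(sample)) keep <- keep & x@info$sample %in% sample
  if (!is.null(locus)) keep <- keep & x@info$locus %in% locus
  new("ConsensusSet", seqs = x@seqs[keep], info = x@info[keep, , drop = FALSE])
}

#' Homeolog grouping of consensus haplotypes
#'
#' The per-(sample, locus) partition of consensus haplotypes into homeolog
#' groups (allelic variants collapsed), with one representative per group and
#' separation diagnostics.
#'
#' @slot consensus the input [ConsensusSet-class].
#' @slot assignment data.frame: `sample`, `locus`, `hap`, `group`,
#'   `representative`.
#' @slot diagnostics data.frame: per (sample, locus) group counts,
#'   within/between divergences and flags.
#' @export
setClass("HomeologGroups", representation(
  consensus = "ConsensusSet", assignment = "data.frame", diagnostics = "data.frame"))

setMethod("show", "HomeologGroups", function(object) {
  cat("HomeologGroups:", nrow(object@assignment), "haplotypes in",
      sum(object@assignment$representative), "groups over",
      nrow(object@diagnostics), "(sample, locus) pairs\n")
})

#' @describeIn HomeologGroups-class grouping table
#' @param x a `HomeologGroups`.
#' @export
homeologAssignment <- function(x) x@assignment

#' @describeIn HomeologGroups-class representative sequences, optionally for
#'   one locus
#' @param locus optional locus id.
#' @export
representatives <- function(x, locus = NULL) {
  a <- x@assignment[x@assignment$representative, , drop = FALSE]
  if (!is.null(locus)) a <- a[a$locus %in% locus, , drop = FALSE]
  seqs <- consensusSeqs(x@consensus)[a$hap]
  list(info = a, seqs = seqs)
}

#' Phased multi-locus alignment
#'
#' Concatenated alignment in which each row is one subgenome copy of one
#' sample (`sample|label`), plus the per-locus assignment trace and presence
#' mask.
#'
#' @slot alignment named `DNAStringSet` of equal-width gapped rows.
#' @slot rowInfo data.frame: `row`, `sample`, `label`.
#' @slot trace data.frame: per placed haplotype `locus`, `sample`, `hap`,
#'   `label`, `cost`, `tie`, `denovo`.
#' @slot presence logical matrix rows x loci.
#' @slot locusCols data.frame: `locus`, `start`, `end` column ranges.
#' @export
setClass("PhasedMatrix", representation(
  alignment = "DNAStringSet", rowInfo = "data.frame", trace = "data.frame",
  presence = "matrix", locusCols = "data.frame"))

setValidity("PhasedMatrix", function(object) {
  if (length(object@alignment) &&
      length(unique(Biostrings::width(object@alignment))) != 1)
    return("alignment rows must have equal width")
  if (nrow(object@rowInfo) != length(object@alignment))
    return("rowInfo must be parallel to alignment")
  TRUE
})

setMethod("show", "PhasedMatrix", function(object) {
  cat("PhasedMatrix:", length(object@alignment), "subgenome rows x",
      if (length(object@alignment)) Biostrings::width(object@alignment)[1] else 0,
      "bp over", nrow(object@locusCols), "loci\n")
})

#' @describeIn PhasedMatrix-class concatenated alignment rows
#' @param x a `PhasedMatrix`.
#' @export
phasedAlignment <- function(x) x@alignment

#' @describeIn PhasedMatrix-class per-haplotype assignment trace
#' @export
phasingTrace <- function(x) x@trace

#' @describeIn PhasedMatrix-class row metadata (sample, subgenome label)
#' @export
phasedRows <- function(x) x@rowInfo
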