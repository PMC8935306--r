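## Plain-text I/O: per-(sample, locus) FASTQ, loci FASTA with class labels,
## sample sheet and truth TSVs, consensus/phased FASTA writers.

#' Write a simulated dataset to disk
#'
#' Writes per-(sample, locus) FASTQ files (placeholder qualities), the locus
#' FASTA (class label in the description), the sample sheet TSV and the
#' truth tables TSV.
#'
#' @param sim an [AmpliconSim-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
  for (sm in names(sim@reads)) for (loc in names(sim@reads[[sm]])) {
    rs <- sim@reads[[sm]][[loc]]
    if (!length(rs)) next
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(rs)))
    Biostrings::writeXStringSet(rs, file.path(dir, "reads",
                                              sprintf("%s__%s.fastq", sm, loc)),
                                format = "fastq", qualities = q)
  }
  loci <- sim@loci
  refs <- refSequences(loci)
  names(refs) <- paste(locusNames(loci), locusClass(loci))
  Biostrings::writeXStringSet(refs, file.path(dir, "loci.fasta"))
  utils::write.table(sim@samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim@truth$templates, file.path(dir, "truth_templates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim@truth$reads, file.path(dir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an amplicon dataset from disk
#'
#' Counterpart of [writeSimulation()]: expects `reads/<sample>__<locus>.fastq`
#' files, a locus FASTA whose description carries the chromosomal class, and
#' a tab-separated sample sheet with columns `sample`, `lineage`, `sex`,
#' `ploidy`.
#'
#' @param reads_dir directory of FASTQ files.
#' @param loci_fasta locus FASTA path.
#' @param sample_sheet sample sheet TSV path.
#' @return list with `reads`, `samples`, `loci`.
#' @export
readAmpliconData <- function(reads_dir, loci_fasta, sample_sheet) {
  .stop_if(!file.exists(sample_sheet),
           paste("sample sheet not found:", sample_sheet))
  .stop_if(!file.exists(loci_fasta), paste("locus FASTA not found:", loci_fasta))
  .stop_if(!dir.exists(reads_dir), paste("reads directory not found:", reads_dir))
  samples <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  raw <- Biostrings::readDNAStringSet(loci_fasta)
  toks <- strsplit(names(raw), "\\s+")
  ids <- vapply(toks, `[`, "", 1L)
  cls <- vapply(toks, function(t) if (length(t) > 1) t[2L] else NA_character_, "")
  names(raw) <- ids
  loci <- LocusSet(raw, cls)
  files <- list.files(reads_dir, pattern = "\\.fastq$", full.names = TRUE)
  reads <- list()
  for (f in files) {
    stem <- sub("\\.fastq$", "", basename(f))
    parts <- strsplit(stem, "__", fixed = TRUE)[[1]]
    .stop_if(length(parts) != 2,
             paste("FASTQ name not of the form sample__locus:", basename(f)))
    rs <- Biostrings::readDNAStringSet(f, format = "fastq")
    if (is.null(reads[[parts[1]]])) reads[[parts[1]]] <- list()
    reads[[parts[1]]][[parts[2]]] <- rs
  }
  list(reads = reads, samples = samples, loci = loci)
}

#' Write consensus haplotypes as FASTA
#'
#' Headers follow `sample|locus|hapN|reads=K`.
#'
#' @param cons a [ConsensusSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConsensusFasta <- function(cons, path) {
  info <- consensusInfo(cons)
  s <- consensusSeqs(cons)
  names(s) <- sprintf("%s|reads=%d", info$hap, info$reads)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Write a phased matrix as FASTA
#'
#' One gapped row per subgenome copy, labelled `sample|label`.
#'
#' @param pm a [PhasedMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhasedFasta <- function(pm, path) {
  Biostrings::writeXStringSet(phasedAlignment(pm), path)
  invisible(path)
}
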