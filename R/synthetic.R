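## Synthetic allopolyploid amplicon datasets with ground truth.
##
## The generative model: a set of ancestral diploid genomes diverge from a
## common root under Jukes-Cantor substitution plus occasional short indels;
## each lineage owns ploidy/2 ancestral subgenomes; every sample carries one
## homeolog template per subgenome at each locus, with shallow allelic
## heterozygosity within each homeolog; males additionally carry exactly one
## hemizygous male-specific (Y) template regardless of ploidy; an optional
## introgression event replaces one lineage's Y template lineage with a
## distant donor's. Reads are templates passed through a nanopore-like
## substitution/indel error model.

BASES <- c("A", "C", "G", "T")

#' Random target loci
#'
#' Generates random reference sequences for a panel of target loci with the
#' four chromosomal classes. Defaults mirror a 23-locus design: 8 autosomal,
#' 8 pseudoautosomal, 6 sex-linked and 1 male-specific locus.
#'
#' @param n_autosomal,n_pseudoautosomal,n_sex_linked,n_male_specific counts.
#' @param length reference length (bp) of regular loci.
#' @param ms_length reference length of the male-specific locus (default 707,
#'   a typical Y-amplicon size).
#' @param seed integer seed.
#' @return a [LocusSet-class].
#' @export
randomLoci <- function(n_autosomal = 8, n_pseudoautosomal = 8, n_sex_linked = 6,
                       n_male_specific = 1, length = 700, ms_length = 707,
                       seed = 1) {
  set.seed(seed)
  cls <- rep(LOCUS_CLASSES, c(n_autosomal, n_pseudoautosomal, n_sex_linked, n_male_specific))
  lens <- ifelse(cls == "male_specific", ms_length, length)
  ids <- sprintf("L%02d_%s", seq_along(cls), substr(cls, 1, 3))
  seqs <- vapply(lens, function(L) paste(sample(BASES, L, replace = TRUE), collapse = ""), "")
  LocusSet(stats::setNames(seqs, ids), cls)
}

#' Nanopore-like read error model
#'
#' Per-base substitution, insertion and deletion probabilities. Indel rates
#' may exceed the substitution rate, as is typical for nanopore reads.
#'
#' @param sub,ins,del per-base probabilities, each in \[0, 0.2\].
#' @return an object of class `ReadErrorModel` (a validated list).
#' @export
readErrorModel <- function(sub = 0.01, ins = 0.05, del = 0.05) {
  r <- c(sub = sub, ins = ins, del = del)
  .stop_if(any(r < 0 | r > 0.2), "error rates must lie in [0, 0.2]")
  structure(list(sub = sub, ins = ins, del = del), class = "ReadErrorModel")
}

#' Lineage specification for a history model
#'
#' @param name lineage id.
#' @param ploidy 2, 4 or 6.
#' @param donors ancestral genome names, one per subgenome (`ploidy/2`).
#' @param n_samples samples to simulate for this lineage.
#' @param sex_system `"dioecious"` (males/females), `"monoecious"` (no males)
#'   or `"androdioecious"` (males/monoecious).
#' @param donors_overrides optional named list `locus class -> donors`,
#'   allowing subgenome histories that differ between locus classes (e.g.
#'   discordant sex-linked histories).
#' @return a `LineageSpec` list.
#' @export
lineageSpec <- function(name, ploidy, donors, n_samples = 2,
                        sex_system = c("dioecious", "monoecious", "androdioecious"),
                        donors_overrides = NULL) {
  sex_system <- match.arg(sex_system)
  .stop_if(!ploidy %in% c(2, 4, 6), "ploidy must be 2, 4 or 6")
  .stop_if(length(donors) != ploidy / 2,
           sprintf("lineage '%s': number of subgenome donors (%d) must equal ploidy/2 (%d)",
                   name, length(donors), ploidy / 2))
  if (!is.null(donors_overrides)) {
    .stop_if(!all(names(donors_overrides) %in% LOCUS_CLASSES),
             "donors_overrides must be named by locus class")
    ok <- all(vapply(donors_overrides, length, 1L) == ploidy / 2)
    .stop_if(!ok, "each donors override must list ploidy/2 donors")
  }
  structure(list(name = name, ploidy = ploidy, donors = donors,
                 n_samples = n_samples, sex_system = sex_system,
                 donors_overrides = donors_overrides), class = "LineageSpec")
}

#' Allopolyploid history model
#'
#' Describes the lineages to simulate, the divergence between ancestral
#' subgenome donors, the within-subgenome allelic variation, and an optional
#' Y-introgression event at the male-specific locus.
#'
#' @param lineages list of [lineageSpec()] objects.
#' @param ancestral_divergence substitutions/site separating ancestral
#'   genomes (homeolog scale).
#' @param allelic_theta substitutions/site of allelic variation within a
#'   subgenome; must be smaller than `ancestral_divergence`.
#' @param extra_divergence optional named numeric: additional branch length
#'   for individual ancestors.
#' @param ancestor_clades optional shared-branch groups passed to
#'   [simulateAncestors()] (distant donor clades).
#' @param introgression optional `list(recipient =, donor =)` naming the
#'   recipient and donor lineages for the male-specific locus.
#' @return a `HistoryModel` list.
#' @export
historyModel <- function(lineages, ancestral_divergence = 0.08,
                         allelic_theta = 0.005, extra_divergence = NULL,
                         ancestor_clades = NULL, introgression = NULL) {
  .stop_if(!length(lineages), "at least one lineage is required")
  .stop_if(!all(vapply(lineages, inherits, TRUE, "LineageSpec")),
           "lineages must be built with lineageSpec()")
  .stop_if(ancestral_divergence <= allelic_theta,
           "ancestral_divergence must exceed allelic_theta")
  nms <- vapply(lineages, `[[`, "", "name")
  .stop_if(anyDuplicated(nms) > 0, "lineage names must be unique")
  if (!is.null(introgression)) {
    .stop_if(!all(c("recipient", "donor") %in% names(introgression)),
             "introgression needs 'recipient' and 'donor'")
    .stop_if(!all(unlist(introgression[c("recipient", "donor")]) %in% nms),
             "introgression lineages must be declared in the model")
  }
  structure(list(lineages = stats::setNames(lineages, nms),
                 ancestral_divergence = ancestral_divergence,
                 allelic_theta = allelic_theta,
                 extra_divergence = extra_divergence,
                 ancestor_clades = ancestor_clades,
                 introgression = introgression), class = "HistoryModel")
}

#' Default study-like design
#'
#' A 24-sample, 23-locus allopolyploid design: three annual-type ancestral
#' genomes at 8% divergence plus a distant perennial donor clade (two
#' ancestral genomes on a shared 7% branch); three diploid annual lineages,
#' two diploid perennial lineages, one monoecious allotetraploid (two
#' donors) and one androdioecious allohexaploid (three donors) whose
#' Y-linked locus was introgressed from one of the perennial lineages, so
#' the hexaploid Y nests inside the perennial Y clade.
#'
#' @return a `HistoryModel`.
#' @export
defaultDesign <- function() {
  historyModel(
    lineages = list(
      lineageSpec("annA", 2, "anc1", n_samples = 2, sex_system = "dioecious"),
      lineageSpec("annB", 2, "anc2", n_samples = 2, sex_system = "dioecious"),
      lineageSpec("annC", 2, "anc3", n_samples = 2, sex_system = "dioecious"),
      lineageSpec("perE", 2, "ancPE", n_samples = 2, sex_system = "dioecious"),
      lineageSpec("perR", 2, "ancPR", n_samples = 2, sex_system = "dioecious"),
      lineageSpec("tet",  4, c("anc1", "anc3"), n_samples = 6, sex_system = "monoecious"),
      lineageSpec("hex",  6, c("anc1", "anc2", "anc3"), n_samples = 8,
                  sex_system = "androdioecious")),
    ancestral_divergence = 0.08,
    allelic_theta = 0.005,
    ancestor_clades = list(perennial = list(members = c("ancPE", "ancPR"),
                                            length = 0.07)),
    introgression = list(recipient = "hex", donor = "perE"))
}

# ancestors referenced by a history model
.history_ancestors <- function(history) {
  sort(unique(unlist(lapply(history$lineages, function(l)
    c(l$donors, unlist(l$donors_overrides))))))
}

# Jukes-Cantor branch mutation plus geometric-length indels.
# bl = expected substitutions/site on the branch.
.mutate_seq <- function(s, bl, indel_factor = 0.1, indel_mean = 3) {
  if (bl <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  p_diff <- 0.75 * (1 - exp(-4 * bl / 3))
  hit <- which(stats::runif(L) < p_diff)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- BASES[((match(chars[hit], BASES) - 1L + shift) %% 4L) + 1L]
  }
  n_ind <- stats::rpois(1L, L * bl * indel_factor)
  for (k in seq_len(n_ind)) {
    len <- stats::rgeom(1L, 1 / indel_mean) + 1L
    if (stats::runif(1) < 0.5) {                       # deletion
      if (length(chars) > len + 1L) {
        at <- sample.int(length(chars) - len, 1L)
        chars <- chars[-(at:(at + len - 1L))]
      }
    } else {                                           # insertion
      at <- sample.int(length(chars) + 1L, 1L)
      chars <- append(chars, sample(BASES, len, replace = TRUE), after = at - 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Simulate ancestral genomes
#'
#' Evolves each locus reference along a star phylogeny: every ancestor sits
#' at branch length `divergence / 2` from the root (so each pair is separated
#' by `divergence` expected substitutions/site under Jukes-Cantor), plus
#' occasional short indels. `extra` adds branch length to named ancestors to
#' create a distant clade.
#'
#' @param loci a [LocusSet-class].
#' @param divergence expected substitutions/site between ancestor pairs.
#' @param ancestors character vector of ancestor names (>= 2).
#' @param extra optional named numeric of additional branch lengths.
#' @param clades optional list of shared-branch groups, each
#'   `list(members =, length =)`: the members descend from a common
#'   intermediate ancestor sitting `length` substitutions/site away from the
#'   root, forming a distant clade (e.g. a perennial donor clade).
#' @param indel_factor indel events per site per unit branch length, as a
#'   fraction of the substitution rate (default 0.1; 0 disables indels).
#' @param indel_mean mean indel length (geometric).
#' @param seed integer seed.
#' @return named list `ancestor -> DNAStringSet` of locus sequences.
#' @export
simulateAncestors <- function(loci, divergence, ancestors = c("anc1", "anc2"),
                              extra = NULL, clades = NULL, indel_factor = 0.1,
                              indel_mean = 3, seed = 1) {
  .stop_if(!is(loci, "LocusSet") || length(refSequences(loci)) == 0,
           "a non-empty LocusSet is required")
  .stop_if(length(ancestors) < 2, "at least two ancestors are required")
  .stop_if(divergence < 0, "divergence must be non-negative")
  set.seed(seed)
  refs <- .chr(refSequences(loci))
  stems <- list(root = refs)
  stem_of <- stats::setNames(rep("root", length(ancestors)), ancestors)
  for (gname in names(clades)) {
    g <- clades[[gname]]
    stems[[gname]] <- vapply(refs, .mutate_seq, "", bl = g$length,
                             indel_factor = indel_factor,
                             indel_mean = indel_mean)
    stem_of[g$members] <- gname
  }
  out <- lapply(ancestors, function(a) {
    bl <- divergence / 2 + if (!is.null(extra) && a %in% names(extra)) extra[[a]] else 0
    Biostrings::DNAStringSet(vapply(stems[[stem_of[[a]]]], .mutate_seq, "",
                                    bl = bl, indel_factor = indel_factor,
                                    indel_mean = indel_mean))
  })
  stats::setNames(out, ancestors)
}

# sexes for one lineage, deterministic
.lineage_sexes <- function(sex_system, n) {
  switch(sex_system,
    dioecious = rep(c("male", "female"), length.out = n),
    monoecious = rep("monoecious", n),
    androdioecious = rep(c("male", "monoecious"), length.out = n))
}

#' Simulate polyploid sample templates
#'
#' Draws, for every sample of every lineage, one homeolog template per
#' subgenome donor at each regular locus (with two allelic sequences per
#' homeolog at rate `allelic_theta`), and exactly one hemizygous template at
#' the male-specific locus for males (none for females/monoecious). When the
#' history configures introgression, the recipient lineage's male-specific
#' template descends from the donor lineage's ancestor.
#'
#' @param history a [historyModel()].
#' @param loci a [LocusSet-class].
#' @param seed integer seed.
#' @param ancestors optional precomputed ancestor set from
#'   [simulateAncestors()]; simulated from the history when `NULL`.
#' @param indel_factor,indel_mean passed to ancestor simulation.
#' @return list with `samples` (sample sheet data.frame) and `truth`
#'   (list of `templates`, `introgression`).
#' @export
simulatePolyploidSamples <- function(history, loci, seed = 1, ancestors = NULL,
                                     indel_factor = 0.1, indel_mean = 3) {
  .stop_if(!inherits(history, "HistoryModel"), "history must be a HistoryModel")
  anc_names <- .history_ancestors(history)
  set.seed(seed)
  if (is.null(ancestors)) {
    ancestors <- simulateAncestors(loci, history$ancestral_divergence,
                                   ancestors = anc_names,
                                   extra = history$extra_divergence,
                                   clades = history$ancestor_clades,
                                   indel_factor = indel_factor,
                                   indel_mean = indel_mean,
                                   seed = seed + 1L)
  }
  missing_anc <- setdiff(anc_names, names(ancestors))
  .stop_if(length(missing_anc) > 0,
           paste("lineage references unknown ancestor(s):",
                 paste(missing_anc, collapse = ", ")))
  ms_loci <- locusNames(loci)[locusClass(loci) == "male_specific"]
  if (!is.null(history$introgression))
    .stop_if(length(ms_loci) == 0,
             "introgression requires a male_specific locus in the panel")
  theta <- history$allelic_theta

  samples <- do.call(rbind, lapply(history$lineages, function(l) {
    data.frame(sample = sprintf("%s_%02d", l$name, seq_len(l$n_samples)),
               lineage = l$name,
               sex = .lineage_sexes(l$sex_system, l$n_samples),
               ploidy = l$ploidy, stringsAsFactors = FALSE)
  }))
  rownames(samples) <- NULL

  tmpl <- list()
  intro <- history$introgression
  for (l in history$lineages) {
    ids <- samples$sample[samples$lineage == l$name]
    for (si in seq_along(ids)) {
      sm <- ids[si]
      sex <- samples$sex[samples$sample == sm]
      for (loc in locusNames(loci)) {
        cls <- locusClass(loci)[[loc]]
        if (cls == "male_specific") {
          if (sex != "male") next
          y_lineage <- if (!is.null(intro) && l$name == intro$recipient)
            history$lineages[[intro$donor]] else l
          y_anc <- y_lineage$donors[1L]
          base <- as.character(ancestors[[y_anc]][[loc]])
          tseq <- .mutate_seq(base, theta, indel_factor = 0)
          tmpl[[length(tmpl) + 1L]] <- data.frame(
            sample = sm, locus = loc, hap = "y1", subgenome = y_anc,
            sequence = tseq, allele1 = tseq, allele2 = NA_character_,
            stringsAsFactors = FALSE)
        } else {
          donors <- if (!is.null(l$donors_overrides) && cls %in% names(l$donors_overrides))
            l$donors_overrides[[cls]] else l$donors
          for (di in seq_along(donors)) {
            base <- as.character(ancestors[[donors[di]]][[loc]])
            tseq <- .mutate_seq(base, theta, indel_factor = 0)
            tmpl[[length(tmpl) + 1L]] <- data.frame(
              sample = sm, locus = loc, hap = sprintf("t%d", di),
              subgenome = donors[di], sequence = tseq,
              allele1 = .mutate_seq(tseq, theta / 2, indel_factor = 0),
              allele2 = .mutate_seq(tseq, theta / 2, indel_factor = 0),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  templates <- do.call(rbind, tmpl)
  introgression <- if (is.null(intro)) {
    data.frame(recipient = character(0), donor = character(0), locus = character(0))
  } else {
    data.frame(recipient = intro$recipient, donor = intro$donor,
               locus = ms_loci[1L], stringsAsFactors = FALSE)
  }
  list(samples = samples,
       truth = list(templates = templates, introgression = introgression,
                    ancestors = ancestors))
}

# one noisy read from a template character vector
.noisy_read <- function(chars, sub, ins, del) {
  L <- length(chars)
  if (del > 0) chars <- chars[stats::runif(L) >= del]
  n <- length(chars)
  if (sub > 0 && n > 0) {
    hit <- which(stats::runif(n) < sub)
    if (length(hit)) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- BASES[((match(chars[hit], BASES) - 1L + shift) %% 4L) + 1L]
    }
  }
  if (ins > 0) {
    slot <- which(stats::runif(n + 1L) < ins)        # insert before position
    if (length(slot)) {
      vals <- c(chars, sample(BASES, length(slot), replace = TRUE))
      keys <- c(seq_len(n), slot - 0.5)
      chars <- vals[order(keys)]
    }
  }
  paste(chars, collapse = "")
}

#' Simulate reads from truth templates
#'
#' Each homeolog template emits a number of reads drawn around `depth`
#' (Poisson by default), split between its two allelic sequences; each read
#' is the allele passed through the error model. Read-to-template provenance
#' is recorded.
#'
#' @param truth the `truth` element of [simulatePolyploidSamples()].
#' @param error_model a [readErrorModel()].
#' @param depth nominal reads per template (>= 1).
#' @param seed integer seed.
#' @param dispersion `"poisson"` (default) or `"fixed"` (exactly `depth`
#'   reads per template).
#' @return list with `reads` (nested list `sample -> locus -> DNAStringSet`)
#'   and `read_truth` (data.frame of read provenance).
#' @export
simulateReads <- function(truth, error_model = readErrorModel(), depth = 20,
                          seed = 1, dispersion = c("poisson", "fixed")) {
  dispersion <- match.arg(dispersion)
  .stop_if(depth < 1, "depth must be >= 1")
  .stop_if(!inherits(error_model, "ReadErrorModel"),
           "error_model must be a ReadErrorModel")
  set.seed(seed)
  tt <- truth$templates
  reads <- list()
  prov <- list()
  key <- paste(tt$sample, tt$locus, sep = "\r")
  for (k in unique(key)) {
    rows <- tt[key == k, , drop = FALSE]
    sm <- rows$sample[1L]; loc <- rows$locus[1L]
    seqs <- character(0); nms <- character(0)
    pv <- list()
    for (i in seq_len(nrow(rows))) {
      nr <- if (dispersion == "poisson") stats::rpois(1L, depth) else as.integer(depth)
      if (nr == 0) next
      alleles <- c(rows$allele1[i], rows$allele2[i])
      alleles <- alleles[!is.na(alleles)]
      pick <- sample.int(length(alleles), nr, replace = TRUE)
      for (r in seq_len(nr)) {
        ch <- strsplit(alleles[pick[r]], "", fixed = TRUE)[[1]]
        seqs <- c(seqs, .noisy_read(ch, error_model$sub, error_model$ins, error_model$del))
      }
      pv[[length(pv) + 1L]] <- data.frame(
        sample = sm, locus = loc, hap = rows$hap[i],
        allele = pick, stringsAsFactors = FALSE)
    }
    if (!length(seqs)) {
      reads[[sm]][[loc]] <- Biostrings::DNAStringSet()
      next
    }
    pvdf <- do.call(rbind, pv)
    nms <- sprintf("%s|%s|r%04d", sm, loc, seq_along(seqs))
    pvdf$read <- nms
    if (is.null(reads[[sm]])) reads[[sm]] <- list()
    reads[[sm]][[loc]] <- Biostrings::DNAStringSet(stats::setNames(seqs, nms))
    prov[[length(prov) + 1L]] <- pvdf
  }
  list(reads = reads,
       read_truth = if (length(prov)) do.call(rbind, prov) else
         data.frame(sample = character(0), locus = character(0),
                    hap = character(0), allele = integer(0), read = character(0)))
}

#' Simulate a complete amplicon dataset
#'
#' Convenience wrapper: loci, ancestors, sample templates and reads in one
#' call, returned as an [AmpliconSim-class] with full ground truth.
#'
#' @param design a [historyModel()] (default [defaultDesign()]).
#' @param loci a [LocusSet-class] (default [randomLoci()] seeded from `seed`).
#' @param error_model a [readErrorModel()].
#' @param depth nominal reads per template.
#' @param seed integer seed driving every random draw.
#' @param dispersion read-count dispersion, see [simulateReads()].
#' @return an [AmpliconSim-class].
#' @export
simulateDataset <- function(design = defaultDesign(), loci = NULL,
                            error_model = readErrorModel(), depth = 30,
                            seed = 1, dispersion = "poisson") {
  if (is.null(loci)) loci <- randomLoci(seed = seed)
  sim <- simulatePolyploidSamples(design, loci, seed = seed + 2L)
  rd <- simulateReads(sim$truth, error_model, depth, seed = seed + 3L,
                      dispersion = dispersion)
  truth <- sim$truth
  truth$reads <- rd$read_truth
  new("AmpliconSim", reads = rd$reads, samples = sim$samples, loci = loci,
      truth = truth,
      config = list(depth = depth, seed = seed, dispersion = dispersion,
                    error_model = unclass(error_model)))
}

#' Truth templates as an error-free consensus set
#'
#' Packages the simulated truth templates as a [ConsensusSet-class], as if
#' clustering and consensus had recovered every template exactly. Useful for
#' exercising the homeolog-resolution, phasing and introgression stages
#' independently of read-level noise.
#'
#' @param sim an [AmpliconSim-class], or the `truth` list of
#'   [simulatePolyploidSamples()].
#' @param reads supporting-read count recorded per template.
#' @return a [ConsensusSet-class].
#' @export
truthConsensus <- function(sim, reads = 30L) {
  tt <- if (is(sim, "AmpliconSim")) sim@truth$templates else sim$templates
  nm <- paste(tt$sample, tt$locus, tt$hap, sep = "|")
  new("ConsensusSet",
      seqs = Biostrings::DNAStringSet(stats::setNames(tt$sequence, nm)),
      info = data.frame(hap = nm, sample = tt$sample, locus = tt$locus,
                        reads = as.integer(reads),
                        n_masked = 0L, stringsAsFactors = FALSE))
}

#' Toy design and loci for quick demonstrations
#'
#' A 6-sample, 4-locus allotetraploid design (two diploid anchor lineages
#' plus one tetraploid) with short loci, small enough for examples, fixtures
#' and end-to-end pipeline demonstrations.
#'
#' @return `toyDesign()`: a `HistoryModel`; `toyLoci()`: a
#'   [LocusSet-class].
#' @export
toyDesign <- function() {
  historyModel(
    lineages = list(
      lineageSpec("dipA", 2, "anc1", n_samples = 2, sex_system = "dioecious"),
      lineageSpec("dipB", 2, "anc2", n_samples = 2, sex_system = "dioecious"),
      lineageSpec("tet", 4, c("anc1", "anc2"), n_samples = 2,
                  sex_system = "androdioecious")))
}

#' @rdname toyDesign
#' @param seed integer seed.
#' @export
toyLoci <- function(seed = 1) {
  randomLoci(n_autosomal = 2, n_pseudoautosomal = 1, n_sex_linked = 0,
             n_male_specific = 1, length = 300, ms_length = 300, seed = seed)
}
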