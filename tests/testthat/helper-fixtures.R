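# Shared fixtures: small designs and constructed sequence sets, all built in
# code at test time.

# mutate a sequence at an exact proportion of sites (no indels), deterministic
# given the RNG state
mutate_frac <- function(s, frac) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- max(1L, round(length(ch) * frac))
  idx <- sample(length(ch), n)
  bases <- c("A", "C", "G", "T")
  ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(bases, b), 1), "")
  paste(ch, collapse = "")
}

random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")

# noisy copy of a template under the package's read error model semantics
noisy_copy <- function(tpl, sub = 0.01, ins = 0.05, del = 0.05) {
  em <- readErrorModel(sub, ins, del)
  truth <- list(templates = data.frame(
    sample = "s1", locus = "l1", hap = "t1", subgenome = "x",
    sequence = tpl, allele1 = tpl, allele2 = NA_character_))
  rd <- simulateReads(truth, em, depth = 1, seed = sample.int(1e6, 1),
                      dispersion = "fixed")
  as.character(rd$reads$s1$l1[[1]])
}

# small three-diploid + hexaploid design used by phasing tests
phasing_design <- function() {
  historyModel(lineages = list(
    lineageSpec("dipA", 2, "anc1", 2, "dioecious"),
    lineageSpec("dipB", 2, "anc2", 2, "dioecious"),
    lineageSpec("dipC", 2, "anc3", 2, "dioecious"),
    lineageSpec("hex", 6, c("anc1", "anc2", "anc3"), 2, "dioecious")))
}

small_loci <- function(n_aut = 5, len = 300, seed = 42, n_ms = 0) {
  randomLoci(n_autosomal = n_aut, n_pseudoautosomal = 0, n_sex_linked = 0,
             n_male_specific = n_ms, length = len, ms_length = len, seed = seed)
}

# reduced study-like design for introgression replicates: annual anchors,
# a two-lineage perennial donor clade, and an androdioecious hexaploid
intro_design <- function(introgress = TRUE) {
  historyModel(
    lineages = list(
      lineageSpec("annA", 2, "anc1", 2, "dioecious"),
      lineageSpec("annB", 2, "anc2", 2, "dioecious"),
      lineageSpec("annC", 2, "anc3", 2, "dioecious"),
      lineageSpec("perE", 2, "ancPE", 2, "dioecious"),
      lineageSpec("perR", 2, "ancPR", 2, "dioecious"),
      lineageSpec("hex", 6, c("anc1", "anc2", "anc3"), 4, "androdioecious")),
    ancestor_clades = list(per = list(members = c("ancPE", "ancPR"),
                                      length = 0.07)),
    introgression = if (introgress) list(recipient = "hex", donor = "perE"))
}

intro_loci <- function(seed) {
  randomLoci(n_autosomal = 5, n_pseudoautosomal = 0, n_sex_linked = 0,
             n_male_specific = 1, length = 500, ms_length = 500, seed = seed)
}

# template-level Y-introgression analysis on a simulated history; returns the
# introgression report plus the male-specific alignment
run_intro_rep <- function(seed, introgress, boot_reps = 60) {
  loci <- intro_loci(seed)
  sp <- simulatePolyploidSamples(intro_design(introgress), loci, seed = seed + 1)
  cons <- truthConsensus(sp$truth)
  hg <- resolveHomeologs(cons, sp$samples, loci)
  b <- runSubsets(hg, sp$samples, loci,
                  subsets = list(all = c("autosomal", "male_specific")),
                  boot_reps = boot_reps, seed = seed)
  ms <- locusNames(loci)[locusClass(loci) == "male_specific"]
  ycons <- consensusSubset(cons, locus = ms)
  yi <- consensusInfo(ycons)
  yseqs <- stats::setNames(as.character(consensusSeqs(ycons)), yi$sample)
  yaln <- alignSequences(yseqs, center = as.character(refSequences(loci)[[ms]]))
  ytree <- bootstrapSupport(yaln, n_reps = boot_reps, seed = seed)
  it <- introgressionTest(ytree, b$all$tree, sp$samples)
  list(report = it$report, rf = it$rf, yaln = yaln, samples = sp$samples)
}

# build a ConsensusSet from named sequences for one (sample, locus)
make_cons <- function(seqs, sample = "s1", locus = "l1", reads = 10L) {
  nm <- paste(sample, locus, names(seqs), sep = "|")
  new("ConsensusSet",
      seqs = Biostrings::DNAStringSet(stats::setNames(unname(seqs), nm)),
      info = data.frame(hap = nm, sample = sample, locus = locus,
                        reads = rep(as.integer(reads), length(seqs)),
                        n_masked = 0L, stringsAsFactors = FALSE))
}

aln_chr <- function(a) as.character(as(a, "DNAStringSet"))
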