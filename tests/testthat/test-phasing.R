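# Phylogeny-guided multilocus phasing (template-level simulations).

# run phasing on truth templates and attach truth subgenomes to the trace
phase_truth <- function(design, loci, seed, ...) {
  sp <- simulatePolyploidSamples(design, loci, seed = seed)
  cons <- truthConsensus(sp$truth)
  hg <- resolveHomeologs(cons, sp$samples, loci)
  pm <- phaseHomeologs(hg, sp$samples, loci, ...)
  tr <- phasingTrace(pm)
  tt <- sp$truth$templates
  tr$truth <- tt$subgenome[match(tr$hap, paste(tt$sample, tt$locus, tt$hap,
                                               sep = "|"))]
  list(pm = pm, trace = tr, samples = sp$samples, truth = sp$truth, hg = hg)
}

test_that("hexaploid subgenomes phase to their true donor clades", {
  loci <- small_loci(n_aut = 5, len = 300, seed = 42)
  res <- phase_truth(phasing_design(), loci, seed = 51)
  tr <- res$trace
  # every label maps to exactly one truth subgenome, and vice versa
  tab <- table(tr$label, tr$truth)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  # all hexaploid assignments agree with the label <-> subgenome bijection
  hexrows <- tr[grepl("^hex", tr$sample), ]
  map <- apply(tab, 1, function(r) colnames(tab)[which.max(r)])
  expect_true(all(map[hexrows$label] == hexrows$truth))
  expect_false(any(tr$denovo))
})

test_that("all-diploid input is trivially phased, one row per sample", {
  loci <- small_loci(n_aut = 3, len = 300, seed = 43)
  des <- historyModel(lineages = list(
    lineageSpec("dipA", 2, "anc1", 2), lineageSpec("dipB", 2, "anc2", 2)))
  res <- phase_truth(des, loci, seed = 52)
  rows <- phasedRows(res$pm)
  expect_equal(nrow(rows), 4L)
  expect_equal(sort(unique(rows$label)), c("A", "B"))
  expect_true(all(table(rows$sample) == 1))
})

test_that("a homeolog without a matching anchor opens a flagged de novo row", {
  loci <- small_loci(n_aut = 3, len = 300, seed = 44)
  des <- historyModel(lineages = list(
    lineageSpec("dipA", 2, "anc1", 2),
    lineageSpec("dipB", 2, "anc2", 2),
    lineageSpec("tet", 4, c("anc1", "anc3"), 1)))  # anc3 has no diploid
  res <- phase_truth(des, loci, seed = 53)
  tr <- res$trace
  tet <- tr[tr$sample == "tet_01", ]
  # the anc3 homeolog opened a flagged de novo row and stays on it
  expect_true(any(tet$denovo[tet$truth == "anc3"]))
  expect_equal(length(unique(tet$label[tet$truth == "anc3"])), 1L)
  expect_false(any(tet$denovo[tet$truth == "anc1"]))
  expect_false(unique(tet$label[tet$truth == "anc3"]) %in% c("A", "B"))
})

test_that("phasing is invariant to sample order up to label renaming", {
  loci <- small_loci(n_aut = 4, len = 300, seed = 45)
  sp <- simulatePolyploidSamples(phasing_design(), loci, seed = 54)
  cons <- truthConsensus(sp$truth)
  hg <- resolveHomeologs(cons, sp$samples, loci)
  pm1 <- phaseHomeologs(hg, sp$samples, loci)

  perm <- rev(seq_len(nrow(sp$samples)))
  info <- consensusInfo(cons)
  ord <- rev(seq_len(nrow(info)))
  cons2 <- new("ConsensusSet", seqs = consensusSeqs(cons)[ord],
               info = info[ord, ])
  hg2 <- resolveHomeologs(cons2, sp$samples[perm, ], loci)
  pm2 <- phaseHomeologs(hg2, sp$samples[perm, ], loci)
  expect_equal(homeophase:::.assignment_agreement(phasingTrace(pm1),
                                                  phasingTrace(pm2)), 1)
})

test_that("phasing is stable across locus orders on clean data", {
  loci <- small_loci(n_aut = 4, len = 300, seed = 46)
  sp <- simulatePolyploidSamples(phasing_design(), loci, seed = 55)
  hg <- resolveHomeologs(truthConsensus(sp$truth), sp$samples, loci)
  od <- phasingOrderDiagnostic(hg, sp$samples, loci, n_orders = 5, seed = 3)
  expect_gte(od$mean, 0.9)
})

test_that("discordant sex-linked histories yield discordant subset trees", {
  loci <- randomLoci(n_autosomal = 3, n_pseudoautosomal = 0, n_sex_linked = 3,
                     n_male_specific = 0, length = 300, seed = 47)
  des <- historyModel(lineages = list(
    lineageSpec("dipA", 2, "anc1", 2),
    lineageSpec("dipB", 2, "anc2", 2),
    lineageSpec("dipC", 2, "anc3", 2),
    lineageSpec("dipX", 2, "anc1", 2,
                donors_overrides = list(sex_linked = "anc3"))))
  sp <- simulatePolyploidSamples(des, loci, seed = 56)
  hg <- resolveHomeologs(truthConsensus(sp$truth), sp$samples, loci)
  b <- runSubsets(hg, sp$samples, loci, boot_reps = 40, seed = 2,
                  subsets = list(autosomal = "autosomal",
                                 sex_linked = "sex_linked"))
  rename <- function(tr) { tr$tip.label <- sub("\\|.*$", "", tr$tip.label); tr }
  rf <- rfDistance(rename(b$autosomal$tree), rename(b$sex_linked$tree))
  expect_gt(rf$rf, 0)
})

test_that("loci missing for a sample are gap-filled and tracked", {
  loci <- small_loci(n_aut = 3, len = 300, seed = 48)
  sp <- simulatePolyploidSamples(phasing_design(), loci, seed = 57)
  cons <- truthConsensus(sp$truth)
  info <- consensusInfo(cons)
  drop <- !(info$sample == "hex_01" & info$locus == locusNames(loci)[2])
  cons2 <- new("ConsensusSet", seqs = consensusSeqs(cons)[drop],
               info = info[drop, ])
  hg <- resolveHomeologs(cons2, sp$samples, loci)
  pm <- phaseHomeologs(hg, sp$samples, loci)
  pres <- pm@presence
  hexrows <- grep("^hex_01", rownames(pres))
  expect_true(all(!pres[hexrows, locusNames(loci)[2]]))
  # the gap-filled segment is all gaps
  seg <- pm@locusCols
  i <- which(seg$locus == locusNames(loci)[2])
  row1 <- as.character(phasedAlignment(pm)[[rownames(pres)[hexrows[1]]]])
  expect_true(all(strsplit(substr(row1, seg$start[i], seg$end[i]), "")[[1]] == "-"))
})

test_that("anchoring requires at least two diploid anchors", {
  loci <- small_loci(n_aut = 2, len = 300, seed = 49)
  des <- historyModel(lineages = list(
    lineageSpec("tetA", 4, c("anc1", "anc2"), 2),
    lineageSpec("tetB", 4, c("anc1", "anc2"), 2)))
  sp <- simulatePolyploidSamples(des, loci, seed = 58)
  hg <- resolveHomeologs(truthConsensus(sp$truth), sp$samples, loci)
  expect_error(phaseHomeologs(hg, sp$samples, loci), "diploid anchor")
})
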