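# Male-specific locus: presence/absence, shared indels, introgression.

test_that("presence/absence yields a male-specific verdict with exceptions", {
  loci <- small_loci(n_aut = 1, n_ms = 1, seed = 61)
  sp <- simulatePolyploidSamples(intro_design(FALSE), loci, seed = 62)
  cons <- truthConsensus(sp$truth)
  pa <- presenceAbsence(cons, sp$samples, loci)
  expect_equal(pa$verdict$verdict, "male_specific")
  expect_equal(nrow(pa$exceptions), 0L)

  # dropout: remove one male's Y consensus -> listed as exception
  ms <- locusNames(loci)[locusClass(loci) == "male_specific"]
  male1 <- sp$samples$sample[sp$samples$sex == "male"][1]
  info <- consensusInfo(cons)
  keep <- !(info$sample == male1 & info$locus == ms)
  cons2 <- new("ConsensusSet", seqs = consensusSeqs(cons)[keep],
               info = info[keep, ])
  pa2 <- presenceAbsence(cons2, sp$samples, loci)
  expect_true(male1 %in% pa2$exceptions$sample)
  expect_equal(pa2$verdict$verdict, "male_specific")  # 5/6 males >= 0.8

  # a female amplification rejects the locus
  fem <- sp$samples$sample[sp$samples$sex == "female"][1]
  extra <- make_cons(c(f1 = random_seq(300)), sample = fem, locus = ms)
  cons3 <- new("ConsensusSet",
               seqs = c(consensusSeqs(cons), consensusSeqs(extra)),
               info = rbind(consensusInfo(cons), consensusInfo(extra)))
  expect_equal(presenceAbsence(cons3, sp$samples, loci)$verdict$verdict,
               "rejected")

  # depth-filtered pairs are reported as failed
  pa4 <- presenceAbsence(cons2, sp$samples, loci,
                         excluded = data.frame(sample = male1, locus = ms))
  expect_equal(pa4$matrix$status[pa4$matrix$sample == male1], "failed")

  # no males: undeterminable
  mono <- sp$samples
  mono$sex <- "monoecious"
  expect_equal(presenceAbsence(cons, mono, loci)$verdict$verdict,
               "undeterminable")
})

test_that("shared indels are reported with carriers and polarity", {
  aln <- c(r1 = "ACGT----ACGTACGT",
           r2 = "ACGT----ACGTACGT",
           r3 = "ACGTTTTTACGTACGT")
  ev <- sharedIndels(aln, min_len = 2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 5L)
  expect_equal(ev$length, 4L)
  expect_equal(ev$kind, "indel")
  expect_equal(ev$carriers, "r1,r2")

  # private single-row gap
  aln2 <- c(r1 = "ACGTACGT", r2 = "AC--ACGT", r3 = "ACGTACGT")
  ev2 <- sharedIndels(aln2, min_len = 2)
  expect_equal(ev2$carriers, "r2")

  # polarized against an outgroup: gap in outgroup = insertion in carriers
  aln3 <- c(og = "ACGT----ACGT", in1 = "ACGTTTTTACGT", in2 = "ACGT----ACGT")
  ev3 <- sharedIndels(aln3, min_len = 2, outgroup = "og")
  expect_equal(ev3$kind, "insertion")
  expect_equal(ev3$carriers, "in1")
  ev3b <- sharedIndels(c(og = "ACGTTTTTACGT", in1 = "ACGT----ACGT",
                         in2 = "ACGTTTTTACGT"), min_len = 2, outgroup = "og")
  expect_equal(ev3b$kind, "deletion")
  expect_equal(ev3b$carriers, "in1")

  # row order does not matter
  ev4 <- sharedIndels(aln[c(3, 1, 2)], min_len = 2)
  expect_equal(ev4, ev)
  expect_error(sharedIndels(aln[1:2]), "3 aligned rows")
  expect_error(sharedIndels(aln, outgroup = "nope"), "outgroup")
})

test_that("the introgression rule on hand-built trees", {
  g <- ape::read.tree(text = "((d1|A:0.01,h1|A:0.01)100:0.1,(d2|B:0.01,h1|B:0.01)100:0.1);")
  samples <- data.frame(sample = c("d1", "d2", "h1"), lineage = c("L1", "L2", "L3"),
                        sex = "male", ploidy = c(2L, 2L, 4L))
  # concordant: h1's Y nearest anchor d1 carries label A, one of h1's own
  y_conc <- ape::read.tree(text = "((h1:0.01,d1:0.01)98:0.1,d2:0.1);")
  r1 <- introgressionTest(y_conc, g, samples, focal = "h1")
  expect_equal(r1$report$status, "concordant")
  expect_true(is.numeric(r1$rf$rf))

  # foreign-label nearest anchor at shallow depth, supported -> flagged
  g2 <- ape::read.tree(text = "((d1|A:0.01,h1|A:0.01)100:0.1,(d2|B:0.01,d3|B:0.01)100:0.1);")
  s2 <- data.frame(sample = c("d1", "d2", "d3", "h1"),
                   lineage = c("L1", "L2", "L2b", "L3"),
                   sex = "male", ploidy = c(2L, 2L, 2L, 4L))
  y_intro <- ape::read.tree(text = "((h1:0.005,d2:0.005)99:0.2,(d1:0.01,d3:0.1):0.05);")
  r2 <- introgressionTest(y_intro, g2, s2, focal = "h1")
  expect_equal(r2$report$status, "introgression_candidate")
  expect_equal(r2$report$anchor_label, "B")

  # same topology with weak support -> unsupported discordance
  y_weak <- ape::read.tree(text = "((h1:0.005,d2:0.005)40:0.2,(d1:0.01,d3:0.1):0.05);")
  r3 <- introgressionTest(y_weak, g2, s2, focal = "h1")
  expect_equal(r3$report$status, "unsupported_discordance")

  expect_error(introgressionTest(y_conc, g, samples, focal = "zz"), "absent")
})

test_that("simulated Y introgression is flagged for the recipient only", {
  rep1 <- run_intro_rep(301, introgress = TRUE)
  flagged <- rep1$report$sample[rep1$report$status == "introgression_candidate"]
  hex_males <- rep1$samples$sample[rep1$samples$lineage == "hex" &
                                   rep1$samples$sex == "male"]
  expect_setequal(flagged, hex_males)

  rep0 <- run_intro_rep(302, introgress = FALSE)
  expect_false(any(rep0$report$status == "introgression_candidate"))

  # the donor-clade indel pattern: an event separates {perennials + hex}
  # from the annual lineages on the Y alignment
  ev <- sharedIndels(rep1$yaln, min_len = 2)
  expect_gt(nrow(ev), 0)
  lin <- stats::setNames(rep1$samples$lineage, rep1$samples$sample)
  split_sets <- lapply(strsplit(ev$carriers, ","), function(cc)
    sort(unique(unname(lin[cc]))))
  per_side <- c("hex", "perE", "perR")
  ann_side <- c("annA", "annB", "annC")
  expect_true(any(vapply(split_sets, function(s)
    setequal(s, per_side) || setequal(s, ann_side), TRUE)))
})
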