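# Synthetic-data generator: divergence calibration, copy-number truth,
# introgression wiring, read error model, reproducibility.

test_that("ancestor divergence follows the Jukes-Cantor expectation", {
  loci <- LocusSet(c(L1 = random_seq(1000)), "autosomal")
  # zero divergence: all ancestors identical at every locus
  anc0 <- simulateAncestors(loci, divergence = 0, seed = 3)
  expect_identical(as.character(anc0$anc1[[1]]), as.character(anc0$anc2[[1]]))

  # d = 0.10: observed p within 3 s.e. of the multiple-hit-corrected value.
  # Independent oracle: two branches of d/2 compose to the JC marginal
  # p = 3/4 (1 - exp(-4 d / 3)); s.e. = sqrt(p (1 - p) / L).
  d <- 0.10; L <- 1000
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  anc <- simulateAncestors(loci, divergence = d, indel_factor = 0, seed = 7)
  a <- strsplit(as.character(anc$anc1[[1]]), "")[[1]]
  b <- strsplit(as.character(anc$anc2[[1]]), "")[[1]]
  p_obs <- mean(a != b)
  expect_lt(abs(p_obs - p_exp), 3 * se)

  # star phylogeny: three ancestors, all pairwise distances comparable
  anc3 <- simulateAncestors(loci, divergence = 0.05, indel_factor = 0,
                            ancestors = c("x", "y", "z"), seed = 11)
  ch <- lapply(anc3, function(s) strsplit(as.character(s[[1]]), "")[[1]])
  ps <- c(mean(ch$x != ch$y), mean(ch$x != ch$z), mean(ch$y != ch$z))
  p5 <- 0.75 * (1 - exp(-4 * 0.05 / 3))
  se5 <- sqrt(p5 * (1 - p5) / L)
  expect_true(all(abs(ps - p5) < 3 * se5))

  expect_error(simulateAncestors(LocusSet(Biostrings::DNAStringSet(), character(0)), 0.1),
               "non-empty")
})

test_that("template copy number follows ploidy and sex", {
  loci <- small_loci(n_aut = 2, n_ms = 1)
  des <- intro_design(introgress = FALSE)
  sp <- simulatePolyploidSamples(des, loci, seed = 5)
  tt <- sp$truth$templates
  ms <- locusNames(loci)[locusClass(loci) == "male_specific"]
  for (i in seq_len(nrow(sp$samples))) {
    sm <- sp$samples$sample[i]
    for (loc in locusNames(loci)) {
      n <- sum(tt$sample == sm & tt$locus == loc)
      if (loc %in% ms) {
        expect_equal(n, if (sp$samples$sex[i] == "male") 1L else 0L,
                     info = paste(sm, loc))
      } else {
        expect_equal(n, sp$samples$ploidy[i] / 2, info = paste(sm, loc))
      }
    }
  }
  # unknown ancestor reference errors
  bad <- historyModel(lineages = list(
    lineageSpec("a", 2, "anc1", 2), lineageSpec("b", 2, "ancZ", 2)))
  expect_error(
    simulatePolyploidSamples(bad, loci, seed = 1,
                             ancestors = simulateAncestors(loci, 0.05, seed = 1)),
    "unknown ancestor")
})

test_that("introgressed male-specific template descends from the donor", {
  loci <- small_loci(n_aut = 1, n_ms = 1)
  sp <- simulatePolyploidSamples(intro_design(TRUE), loci, seed = 9)
  tt <- sp$truth$templates
  anc <- sp$truth$ancestors
  ms <- sp$truth$introgression$locus
  hexm <- sp$samples$sample[sp$samples$lineage == "hex" &
                            sp$samples$sex == "male"][1]
  y <- tt$sequence[tt$sample == hexm & tt$locus == ms]
  d_donor <- editDist(y, as.character(anc$ancPE[[ms]]))
  d_own <- min(vapply(c("anc1", "anc2", "anc3"), function(a)
    editDist(y, as.character(anc[[a]][[ms]])), 0))
  expect_lt(d_donor, d_own)
  expect_equal(tt$subgenome[tt$sample == hexm & tt$locus == ms], "ancPE")
})

test_that("read simulation honours the error model and depth", {
  tpl <- random_seq(500)
  truth <- list(templates = data.frame(
    sample = "s1", locus = "l1", hap = "t1", subgenome = "x",
    sequence = tpl, allele1 = tpl, allele2 = NA_character_))
  # no errors, fixed depth: every read equals the template, exactly 5 reads
  rd0 <- simulateReads(truth, readErrorModel(0, 0, 0), depth = 5, seed = 2,
                       dispersion = "fixed")
  expect_length(rd0$reads$s1$l1, 5)
  expect_true(all(as.character(rd0$reads$s1$l1) == tpl))

  # indel-rich model: mean read length within 2 s.e. of L (1 + ins - del)
  rd <- simulateReads(truth, readErrorModel(0.01, 0.05, 0.05), depth = 200,
                      seed = 4, dispersion = "fixed")
  w <- Biostrings::width(rd$reads$s1$l1)
  expect_gt(length(w), 150)
  mu <- 500 * (1 + 0.05 - 0.05)
  se <- sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w) - mu), 2 * se + 1)

  # provenance covers every read
  expect_setequal(rd$read_truth$read, names(rd$reads$s1$l1))
  expect_error(simulateReads(truth, readErrorModel(), depth = 0), "depth")
  expect_error(readErrorModel(sub = 0.5), "0.2")
})

test_that("identical seeds give byte-identical FASTQ output", {
  d1 <- tempfile(); d2 <- tempfile()
  sim1 <- simulateDataset(toyDesign(), loci = toyLoci(3), depth = 8, seed = 21)
  sim2 <- simulateDataset(toyDesign(), loci = toyLoci(3), depth = 8, seed = 21)
  writeSimulation(sim1, d1); writeSimulation(sim2, d2)
  f1 <- list.files(file.path(d1, "reads"), full.names = TRUE)
  f2 <- list.files(file.path(d2, "reads"), full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("inter-homeolog distance grows with ancestral divergence", {
  loci <- small_loci(n_aut = 1, len = 200, seed = 8)
  mean_div <- function(divergence) {
    des <- historyModel(lineages = list(
      lineageSpec("dA", 2, "anc1", 1), lineageSpec("dB", 2, "anc2", 1),
      lineageSpec("tt", 4, c("anc1", "anc2"), 1)),
      ancestral_divergence = divergence)
    mean(vapply(1:20, function(r) {
      sp <- simulatePolyploidSamples(des, loci, seed = 100 + r)
      tt <- sp$truth$templates
      h <- tt$sequence[tt$sample == "tt_01"]
      editDist(h[1], h[2])
    }, 0))
  }
  expect_gt(mean_div(0.08), mean_div(0.02))
})
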