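# Read clustering, consensus calling and the coverage filter.

test_that("error-free reads cluster exactly by template", {
  set.seed(1)
  t1 <- random_seq(400)
  t2 <- mutate_frac(t1, 0.10)
  reads <- c(stats::setNames(rep(t1, 20), sprintf("a%02d", 1:20)),
             stats::setNames(rep(t2, 20), sprintf("b%02d", 1:20)))
  cl <- clusterReads(reads, expected_k = 2)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, clusterSize, 1L), c(20L, 20L))
  expect_setequal(vapply(cl, function(x) x@centroid, ""), c(t1, t2))
  # exhaustive nearest-template oracle: every read sits with its template
  for (x in cl) {
    tmpl <- if (editDist(x@centroid, t1) == 0) "a" else "b"
    expect_true(all(substr(x@ids, 1, 1) == tmpl))
  }
  # partition property: each retained read in exactly one cluster
  ids <- unlist(lapply(cl, function(x) x@ids))
  expect_equal(sort(ids), sort(names(reads)))

  # single template
  cl1 <- clusterReads(reads[1:20], expected_k = 1)
  expect_length(cl1, 1)
  expect_equal(clusterSize(cl1[[1]]), 20L)

  expect_error(clusterReads(reads, 2, identity_floor = 1.2), "identity_floor")
})

test_that("noisy reads from three templates are recovered at high identity", {
  set.seed(7)
  base <- random_seq(500)
  tpls <- c(base, mutate_frac(base, 0.08), mutate_frac(mutate_frac(base, 0.04), 0.04))
  reads <- character(0)
  for (k in 1:3) for (r in 1:30)
    reads <- c(reads, stats::setNames(noisy_copy(tpls[k]),
                                      sprintf("t%d_r%02d", k, r)))
  cl <- clusterReads(Biostrings::DNAStringSet(reads), expected_k = 3)
  expect_length(cl, 3)
  cons <- vapply(seq_along(cl), function(i)
    as.character(consensusSeqs(callConsensus(cl[[i]], mask_ambiguous = FALSE))), "")
  hit <- vapply(cons, function(cs) which.min(vapply(tpls, editDist, 0, cs)), 0L)
  expect_setequal(hit, 1:3)
  for (i in seq_along(cons))
    expect_gte(seqIdentity(cons[i], tpls[hit[i]]), 0.99)
})

test_that("consensus is a per-column majority with N-masking", {
  mk <- function(seqs) new("ReadCluster", ids = names(seqs),
                           seqs = Biostrings::DNAStringSet(seqs),
                           centroid = unname(seqs[1]))
  same <- stats::setNames(rep("ACGTACGT", 5), paste0("r", 1:5))
  expect_equal(unname(as.character(consensusSeqs(callConsensus(mk(same))))), "ACGTACGT")

  tri <- stats::setNames(c("ACGT", "ACGT", "ACTT"), paste0("r", 1:3))
  off <- callConsensus(mk(tri), mask_ambiguous = FALSE)
  expect_equal(unname(as.character(consensusSeqs(off))), "ACGT")   # majority
  on <- callConsensus(mk(tri), mask_ambiguous = TRUE, mask_threshold = 0.8)
  expect_equal(unname(as.character(consensusSeqs(on))), "ACNT")    # 2/3 < 0.8
  expect_equal(consensusInfo(on)$n_masked, 1L)
  expect_equal(consensusInfo(on)$reads, 3L)
})

test_that("small-input clustering matches the exhaustive partition oracle", {
  set.seed(3)
  base <- random_seq(150)
  tpls <- c(base, mutate_frac(base, 0.1), mutate_frac(mutate_frac(base, 0.05), 0.05))
  reads <- character(0)
  for (k in 1:3) for (r in 1:3)
    reads <- c(reads, stats::setNames(noisy_copy(tpls[k], 0.002, 0.005, 0.005),
                                      sprintf("t%d_r%d", k, r)))
  cl <- clusterReads(reads, expected_k = 3, min_cluster_reads = 1)
  got <- integer(length(reads)); names(got) <- names(reads)
  for (i in seq_along(cl)) got[cl[[i]]@ids] <- i

  # oracle: over all assignments of 9 reads to 3 labelled groups, minimize
  # the total within-group pairwise edit distance
  D <- matrix(0, 9, 9)
  for (i in 1:9) for (j in 1:9)
    D[i, j] <- editDist(reads[i], reads[j])
  best <- NULL; best_cost <- Inf
  grid <- expand.grid(rep(list(1:3), 8))
  for (r in seq_len(nrow(grid))) {
    asg <- c(1L, as.integer(grid[r, ]))     # fix read 1 in group 1 (symmetry)
    cost <- 0
    for (g in 1:3) {
      m <- which(asg == g)
      if (length(m) > 1) cost <- cost + sum(D[m, m]) / 2
    }
    if (cost < best_cost) { best_cost <- cost; best <- asg }
  }
  expect_equal(randIndex(got[names(reads)], best), 1)
})

test_that("the coverage filter applies the 10x-ploidy boundary exactly", {
  samples <- data.frame(sample = c("hex1", "dip1"), lineage = "l",
                        sex = "male", ploidy = c(6L, 2L))
  cons <- new("ConsensusSet",
    seqs = Biostrings::DNAStringSet(c(a = "ACGT", b = "ACGT", c = "ACGT")),
    info = data.frame(hap = c("a", "b", "c"),
                      sample = c("hex1", "hex1", "dip1"),
                      locus = c("L1", "L1", "L1"),
                      reads = c(30L, 29L, 20L), n_masked = 0L))
  flt <- depthFilter(cons, samples, factor = 10)
  # hexaploid at 59 < 60: excluded; diploid at 20 >= 20: retained
  expect_equal(flt$excluded$sample, "hex1")
  expect_equal(flt$excluded$reads, 59)
  expect_equal(unique(consensusInfo(flt$retained)$sample), "dip1")
  expect_error(depthFilter(cons, samples, factor = 0), "factor")
  expect_error(depthFilter(cons, samples[1, ], factor = 10), "unknown ploidy")
})

test_that("short contaminant reads are dropped before clustering", {
  set.seed(2)
  tpl <- random_seq(400)
  reads <- c(stats::setNames(rep(tpl, 8), paste0("ok", 1:8)),
             stats::setNames(rep(substr(tpl, 1, 120), 4), paste0("sh", 1:4)))
  cl <- clusterReads(reads, expected_k = 1, ref_length = 400,
                     min_cluster_reads = 1)
  expect_length(cl, 1)
  expect_true(all(startsWith(cl[[1]]@ids, "ok")))
})
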