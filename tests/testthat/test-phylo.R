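# Alignment, distances, neighbor joining, bootstrap, Robinson-Foulds.

test_that("center-star alignment is optimal on pairs and round-trips", {
  a1 <- alignSequences(c(x = "ACGTACGT", y = "ACGTACGT"))
  expect_false(grepl("-", paste(aln_chr(a1), collapse = "")))
  # Needleman-Wunsch oracle: one 1-bp gap, 7 matches, distance 1
  pr <- homeophase:::.align_pair_cpp("ACGTACGT", "ACGACGT")
  expect_equal(pr$dist, 1L)
  expect_equal(pr$length, 8L)
  expect_equal(sum(strsplit(pr$b, "")[[1]] == "-"), 1L)

  # de-gapping any row returns the input
  set.seed(5)
  seqs <- c(a = random_seq(200))
  seqs["b"] <- mutate_frac(seqs["a"], 0.1)
  seqs["c"] <- noisy_copy(seqs[["a"]], 0.02, 0.05, 0.05)
  aln <- as(alignSequences(seqs), "DNAStringSet")
  for (nm in names(seqs))
    expect_equal(gsub("-", "", as.character(aln[[nm]])), unname(seqs[nm]))
})

test_that("p-distance and JC69 behave as the closed forms dictate", {
  rows <- c(r1 = paste(rep("A", 100), collapse = ""),
            r2 = paste(c(rep("A", 98), "C", "G"), collapse = ""))
  D <- distanceMatrix(rows, model = "p")
  expect_equal(D["r1", "r2"], 0.02)
  expect_equal(distanceMatrix(rows[c(1, 1)], model = "p")[1, 2], 0)
  DJ <- distanceMatrix(rows, model = "JC69")
  expect_equal(DJ["r1", "r2"], -0.75 * log(1 - 4 * 0.02 / 3), tolerance = 1e-10)
  expect_equal(round(DJ["r1", "r2"], 4), 0.0203)

  # JC69 >= p always, equality only at p = 0
  set.seed(6)
  for (i in 1:5) {
    s <- random_seq(300)
    rws <- c(a = s, b = mutate_frac(s, runif(1, 0.01, 0.4)))
    al <- aln_chr(alignSequences(rws))
    p <- distanceMatrix(al, "p")[1, 2]
    j <- distanceMatrix(al, "JC69")[1, 2]
    expect_gte(j, p)
  }
  # saturation flagged
  sat <- c(x = "AAAA", y = "CCCC")
  DS <- distanceMatrix(sat, "JC69", max_dist = 7)
  expect_equal(DS[1, 2], 7)
  expect_true(attr(DS, "saturated"))
})

test_that("neighbor joining recovers additive trees exactly", {
  # hand-drawn 4-taxon tree ((A:1,B:2):1,(C:3,D:1)) -> additive matrix
  D <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- njTree(D)
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1));")
  expect_equal(rfDistance(tr, ref)$rf, 0)
  expect_equal(sum(tr$edge.length), 8)   # total length of the true tree
  # 3 taxa: closed-form star branch lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- njTree(D3)
  bl <- stats::setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.5, 1.5, 2.5))
  # ultrametric matrix: NJ topology equals the UPGMA topology
  DU <- matrix(c(0, 2, 8, 8, 2, 0, 8, 8, 8, 8, 0, 4, 8, 8, 4, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tu <- njTree(DU)
  hc <- stats::hclust(stats::as.dist(DU), method = "average")
  upgma <- ape::as.phylo(hc)
  expect_equal(rfDistance(tu, upgma)$rf, 0)
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 taxa")
})

test_that("NJ is consistent on random additive matrices", {
  set.seed(99)
  for (r in 1:30) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    D <- ape::cophenetic.phylo(tr)
    expect_equal(rfDistance(njTree(D), tr)$rf, 0)
  }
})

test_that("bootstrap support reflects signal strength and is deterministic", {
  set.seed(8)
  blockA <- function(ch) paste(rep(ch, 20), collapse = "")
  core <- random_seq(60)
  rows <- c(a1 = paste0(blockA("A"), core), a2 = paste0(blockA("A"), mutate_frac(core, 0.02)),
            a3 = paste0(blockA("A"), mutate_frac(core, 0.02)),
            b1 = paste0(blockA("T"), mutate_frac(core, 0.3)),
            b2 = paste0(blockA("T"), mutate_frac(core, 0.3)),
            b3 = paste0(blockA("T"), mutate_frac(core, 0.3)))
  aln <- aln_chr(alignSequences(rows))
  names(aln) <- names(rows)
  tr <- bootstrapSupport(aln, n_reps = 100, seed = 42)
  expect_gte(cladeSupport(tr, c("a1", "a2", "a3")), 95)
  expect_gte(cladeSupport(tr, c("b1", "b2", "b3")), 95)
  # identical sequences: no signal, supports reported as unsupported
  flat <- stats::setNames(rep(paste(rep("ACGT", 30), collapse = ""), 4),
                          paste0("s", 1:4))
  tf <- bootstrapSupport(flat, n_reps = 50, seed = 1)
  expect_true(all(na.omit(as.numeric(tf$node.label)) < 50))
  # determinism
  tr2 <- bootstrapSupport(aln, n_reps = 100, seed = 42)
  expect_identical(tr$node.label, tr2$node.label)
  # support invariant to row permutation
  tr3 <- bootstrapSupport(aln[rev(names(aln))], n_reps = 100, seed = 42)
  expect_identical(sort(as.numeric(tr$node.label)), sort(as.numeric(tr3$node.label)))
})

test_that("Robinson-Foulds distances match bipartition enumeration", {
  q1 <- ape::read.tree(text = "((A,B),(C,D));")
  q2 <- ape::read.tree(text = "((A,C),(B,D));")
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_equal(rfDistance(q1, q1)$rf, 0)
  expect_equal(rfDistance(q1, q2)$rf, 2)
  expect_equal(rfDistance(q1, q2)$normalized, 1)
  expect_equal(rfDistance(q1, star)$rf, 1)

  # independent oracle: symmetric difference of non-trivial bipartitions
  rf_oracle <- function(t1, t2) {
    splits <- function(tr) {
      ct <- homeophase:::.clade_table(tr)
      keep <- vapply(ct$clades, function(cl)
        length(cl) >= 2 && length(cl) <= length(ct$tips) - 2, TRUE)
      lapply(ct$clades[keep], function(cl) {
        side <- sort(cl); comp <- sort(setdiff(ct$tips, cl))
        paste(min(paste(side, collapse = ",") , paste(comp, collapse = ",")),
              max(paste(side, collapse = ","), paste(comp, collapse = ",")))
      })
    }
    s1 <- unique(unlist(splits(t1))); s2 <- unique(unlist(splits(t2)))
    length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  }
  set.seed(17)
  for (r in 1:5) {
    a <- ape::rtree(6); b <- ape::rtree(6)
    expect_equal(rfDistance(a, b)$rf, rf_oracle(a, b))
  }

  t5 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(rfDistance(q1, t5), "prune")
  pr <- rfDistance(ape::rtree(6), ape::rtree(5), prune = TRUE)
  expect_true(is.numeric(pr$rf))
})

test_that("Newick round-trips preserve branch lengths and supports", {
  tr <- ape::read.tree(text = "((A:1,B:2)95:0.5,(C:1,D:1)80:0.25);")
  f <- tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  tr2 <- readNewick(f)
  expect_equal(tr2$tip.label, tr$tip.label)
  expect_equal(tr2$edge.length, tr$edge.length)
  expect_equal(tr2$node.label, tr$node.label)
  unlink(f)
})
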