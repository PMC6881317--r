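test_that("newick parsing canonicalizes to an unrooted post-order tree", {
  tr <- read_newick(text = "(A:1,(B:2,C:3):0.5);")
  # 3 taxa: the rooted input collapses to the unrooted star with 3 branches
  expect_equal(n_branches(tr), 3L)
  expect_setequal(tree_taxa(tr), c("A", "B", "C"))
  tr4 <- read_newick(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);")
  expect_equal(n_branches(tr4), 5L)   # 2n - 3 for unrooted binary
})

test_that("#k marks are parsed onto the right branches and survive writing", {
  tr <- read_newick(text = "((A:1,D:1):0.5,(B:2,C:3)#1:0.5);")
  expect_length(tr$foreground, 1L)
  expect_equal(tr$foreground, stem_branch(tr, c("B", "C")))
  txt <- write_newick(tr)
  expect_match(txt, "#1")
  tr2 <- read_newick(text = txt)
  expect_equal(tr2$foreground, tr$foreground)

  # tip marks
  trt <- read_newick(text = "((A#1:1,D:1):0.5,(B:2,C:3):0.5);")
  expect_equal(trt$foreground, stem_branch(trt, "A"))
  expect_false(grepl("#", paste(tree_taxa(trt), collapse = "")))
})

test_that("newick round-trip is lossless for topology, lengths and marks", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    phy <- ape::rtree(n)
    tr <- phylo_tree(phy, foreground = sample(2 * n - 3, 1))
    tr2 <- read_newick(text = write_newick(tr))
    expect_equal(tr2$foreground, tr$foreground)
    expect_equal(sort(branch_lengths(tr2)), sort(branch_lengths(tr)),
                 tolerance = 1e-10)
    # identical splits: every branch's leafset must match
    ls1 <- lapply(seq_len(n_branches(tr)), function(b)
      branch_table(tr)$tips[b])
    ls2 <- lapply(seq_len(n_branches(tr2)), function(b)
      branch_table(tr2)$tips[b])
    expect_setequal(unlist(ls1), unlist(ls2))
  }
})

test_that("neighbor joining reproduces the 3-taxon closed form", {
  # codon alignment engineered so pairwise p-distances are known:
  # 90 nt, AB differ at 9, AC at 15, BC at 24 (disjoint) positions
  base <- strsplit(strrep("ATGGCACTG", 10), "")[[1]]
  A <- base
  B <- base; B[seq(1, 25, 3)] <- "T"          # 9 positions, all != base
  C <- base; C[seq(2, 44, 3)] <- "G"          # 15 positions, all != base
  stopifnot(sum(A != B) == 9, sum(A != C) == 15, sum(B != C) == 24)
  m <- rbind(A = paste(A, collapse = ""), B = paste(B, collapse = ""),
             C = paste(C, collapse = ""))
  aln <- codon_alignment(stats::setNames(m[, 1], rownames(m)))
  tr <- neighbor_joining(aln)
  d_ab <- 9 / 90; d_ac <- 15 / 90; d_bc <- 24 / 90
  bl <- branch_lengths(tr)
  edge_tip <- function(lbl) which(tr$phylo$edge[, 2] ==
                                    match(lbl, tree_taxa(tr)))
  expect_equal(bl[edge_tip("A")], (d_ab + d_ac - d_bc) / 2, tolerance = 1e-10)
  expect_equal(bl[edge_tip("B")], (d_ab + d_bc - d_ac) / 2, tolerance = 1e-10)
  expect_equal(bl[edge_tip("C")], (d_ac + d_bc - d_ab) / 2, tolerance = 1e-10)
})

test_that("neighbor joining recovers an additive 4-taxon topology", {
  # disjoint mutation sets make hamming distances additive on ((A,B),(C,D))
  n <- 120L
  base <- rep(c("A", "T", "G", "C", "A", "T"), length.out = 3 * n)
  flip <- function(x, idx) {
    x[idx] <- vapply(idx, function(i)
      setdiff(c("A", "C", "G", "T"), x[i])[1], "")
    x
  }
  seqs <- list(A = base, B = base, C = base, D = base)
  seqs$A <- flip(seqs$A, 1:6)
  seqs$B <- flip(seqs$B, 7:14)
  internal <- 15:26
  seqs$C <- flip(flip(seqs$C, internal), 27:34)
  seqs$D <- flip(flip(seqs$D, internal), 35:40)
  aln <- codon_alignment(vapply(seqs, paste, "", collapse = ""))
  tr <- neighbor_joining(aln)
  expect_equal(stem_branch(tr, c("C", "D")), stem_branch(tr, c("A", "B")))
  expect_false(is.na(stem_branch(tr, c("C", "D"))))
})

test_that("NJ recovers the generating topology from simulated data", {
  hits <- 0L
  for (seed in 1:8) {
    sim <- simulate_alignment(sim_config(tree6(), n_codons = 600,
                                         seed = 100 + seed))
    tr <- neighbor_joining(sim$alignment)
    ok <- !is.na(stem_branch(tr, c("A", "B"))) &&
      !is.na(stem_branch(tr, c("C", "D"))) &&
      !is.na(stem_branch(tr, c("E", "F")))
    hits <- hits + ok
  }
  expect_equal(hits, 8L)
})

test_that("JC distance errors on saturated pairs", {
  m <- rbind(a = "ATGGCA", b = "TACCGT", c = "ATGGCC")
  aln <- codon_alignment(stats::setNames(m[, 1], rownames(m)))
  expect_error(neighbor_joining(aln, distance = "JC"), "saturated")
})
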