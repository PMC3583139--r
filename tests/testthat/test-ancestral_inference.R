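test_that("leaf sets encode nucleotides and treat missing data as full ambiguity", {
  m <- leaf_sets(c(a = "ACGT", b = "N-GA"))
  expect_identical(m["a", ], c(1L, 2L, 4L, 8L))
  expect_identical(m["b", ], c(15L, 15L, 4L, 1L))
  expect_error(leaf_sets(c(a = "ACQT")), "non-nucleotide")
})

test_that("downpass reproduces textbook cases and the exhaustive oracle", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  # two cherries A,A | C,C: one unavoidable change, root {A,C}
  st <- fitch_downpass(tr, c(a = "A", b = "A", c = "C", d = "C"))
  expect_identical(st$sites, 3L)   # {A,C}
  expect_identical(st$score, 1L)
  # four distinct leaves: full root set, three changes (oracle-confirmed)
  aln <- c(a = "A", b = "C", c = "G", d = "T")
  st <- fitch_downpass(tr, aln)
  orc <- oracle_fitch(tr, leaf_sets(aln))
  expect_identical(st$sites, 15L)
  expect_identical(st$score, 3L)
  expect_identical(st$sites, orc$sets)
  expect_identical(st$score, orc$score)
  # constant column: no change
  st <- fitch_downpass(tr, c(a = "T", b = "T", c = "T", d = "T"))
  expect_identical(st$sites, 8L)
  expect_identical(st$score, 0L)
})

test_that("downpass root sets and scores match the oracle on random trees", {
  set.seed(13)
  for (n in 4:6) {
    for (rep in 1:4) {
      tr <- ape::rtree(n)
      aln <- random_tip_alignment(tr$tip.label, 6, amb_prob = 0.15)
      ls <- leaf_sets(aln)
      st <- fitch_downpass(tr, ls)
      orc <- oracle_fitch(tr, ls)
      expect_identical(st$sites, orc$sets)
      expect_identical(st$score, orc$score)
    }
  }
})

test_that("parsimony scores agree with phangorn's Fitch implementation", {
  set.seed(17)
  for (rep in 1:5) {
    tr <- ape::rtree(10)
    aln <- random_tip_alignment(tr$tip.label, 40)
    st <- fitch_downpass(tr, aln)
    chars <- do.call(rbind, strsplit(aln, ""))
    rownames(chars) <- names(aln)
    pd <- phangorn::phyDat(chars, type = "DNA")
    expect_identical(st$score,
                     as.integer(phangorn::parsimony(tr, pd, method = "fitch")))
  }
})

test_that("outgroup rooting defines the ingroup ancestor", {
  tr <- ape::read.tree(text = "(h,(a,(b,c)));")
  aln <- c(h = "ACG", a = "ATG", b = "TTG", c = "TTA")
  rooted <- root_with_outgroup(tr, "h")
  expect_true(ape::is.rooted(rooted))
  # rooting twice is stable up to topology
  again <- root_with_outgroup(rooted, "h")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(rooted), ape::unroot(again))), 0)
  # the ingroup state equals the downpass on the ingroup subtree alone
  st <- ingroup_root_state(tr, aln, "h")
  direct <- fitch_downpass(ape::read.tree(text = "(a,(b,c));"), aln[c("a", "b", "c")])
  expect_identical(st$sites, direct$sites)
  expect_identical(st$score, direct$score)
  expect_error(root_with_outgroup(tr, "z"), "not a leaf")
})

test_that("states at all edges are root-invariant in score and oracle-consistent", {
  # 3-leaf star: three edges, three candidate states
  star <- ape::read.tree(text = "(a,b,c);")
  aln3 <- c(a = "AC", b = "AG", c = "CG")
  sts <- states_at_all_nodes(star, aln3)
  expect_length(sts, 3L)
  # unrooted 4-leaf tree: 5 edges
  tr4 <- ape::read.tree(text = "((a,b),c,d);")
  aln4 <- c(a = "ACGT", b = "ACGA", c = "CCGT", d = "CTGA")
  sts4 <- states_at_all_nodes(tr4, aln4)
  expect_length(sts4, 5L)
  scores <- vapply(sts4, `[[`, integer(1), "score")
  expect_true(all(scores == scores[[1]]))
  # per-edge score equals the rooted score obtained by explicit rerooting
  rooted <- fitch_downpass(ape::read.tree(text = "((a,b),(c,d));"), aln4)
  expect_identical(scores[[1]], rooted$score)
  # random trees: every edge state matches rerooting the tree at that edge
  set.seed(23)
  for (rep in 1:3) {
    tr <- ape::unroot(ape::rtree(5))
    aln <- random_tip_alignment(tr$tip.label, 8, amb_prob = 0.1)
    sts <- states_at_all_nodes(tr, aln)
    scs <- vapply(sts, `[[`, integer(1), "score")
    expect_true(all(scs == scs[[1]]))
    # oracle score on an arbitrary rooting of the same topology
    orc <- oracle_fitch(ape::root(tr, outgroup = tr$tip.label[1],
                                  resolve.root = TRUE), leaf_sets(aln))
    expect_identical(scs[[1]], orc$score)
  }
})

test_that("adding a duplicate sister leaf never increases the parsimony score", {
  set.seed(29)
  base <- "(a,(b,(c,d)));"
  tr <- ape::read.tree(text = base)
  dup <- ape::read.tree(text = sub("c", "(c,c2)", base, fixed = TRUE))
  for (rep in 1:10) {
    aln <- random_tip_alignment(c("a", "b", "c", "d"), 10)
    aln2 <- c(aln, c2 = unname(aln["c"]))
    s1 <- fitch_downpass(tr, aln)$score
    s2 <- fitch_downpass(dup, aln2)$score
    expect_lte(s2, s1)
    expect_identical(s2, s1)  # identical sister adds no change
  }
})

test_that("IUPAC round trip preserves ambiguity sets", {
  set.seed(31)
  sites <- sample(1:15, 40, replace = TRUE)
  st <- ancestral_state(sites, node = "x", score = 0L)
  expect_identical(as_ancestral_state(state_to_iupac(st))$sites, sites)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_states_fasta(list(x = st), f)
  back <- read_states_fasta(f, positions = NULL)
  expect_identical(back$x$sites, sites)
})

test_that("codon masks select the requested positions", {
  expect_identical(codon_mask(6), c(1L, 2L, 4L, 5L))
  expect_identical(codon_mask(6, positions = 1:3), 1:6)
  expect_identical(codon_mask(9, positions = 3), c(3L, 6L, 9L))
  expect_error(codon_mask(7), "multiple of 3")
})
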