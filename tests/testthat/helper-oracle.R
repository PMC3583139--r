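# Independent brute-force oracles and in-code fixture builders shared
# across the test files.

BITS4 <- c(1L, 2L, 4L, 8L)

# Exhaustive minimum-labeling parsimony for a single site. Enumerates every
# assignment of one nucleotide per node (leaves constrained to their
# ambiguity sets), counts state changes along edges, and returns the set of
# root states attaining the minimum plus the minimum itself. Independent of
# the package's downpass.
oracle_fitch_site <- function(tree, site_masks) {
  nt <- length(tree$tip.label)
  choices <- lapply(seq_len(nt + tree$Nnode), function(i) {
    if (i <= nt) which(bitwAnd(BITS4, site_masks[[tree$tip.label[i]]]) != 0L)
    else 1:4
  })
  grid <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
  cost <- integer(nrow(grid))
  for (k in seq_len(nrow(tree$edge)))
    cost <- cost + (grid[, tree$edge[k, 1L]] != grid[, tree$edge[k, 2L]])
  mn <- min(cost)
  root_states <- sort(unique(grid[cost == mn, nt + 1L]))
  list(set = sum(BITS4[root_states]), score = mn)
}

oracle_fitch <- function(tree, lsets) {
  per <- lapply(seq_len(ncol(lsets)), function(j)
    oracle_fitch_site(tree, as.list(lsets[, j])))
  list(sets = vapply(per, `[[`, integer(1), "set"),
       score = sum(vapply(per, `[[`, integer(1), "score")))
}

random_tip_alignment <- function(tips, nsites, amb_prob = 0) {
  setNames(vapply(tips, function(t) {
    s <- sample(c("A", "C", "G", "T"), nsites, replace = TRUE)
    if (amb_prob > 0) s[runif(nsites) < amb_prob] <- "N"
    paste(s, collapse = "")
  }, character(1)), tips)
}

STOPLESS_CODONS <- local({
  n <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(n, n, paste0), n, paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
})

random_cds <- function(n_codons)
  paste(sample(STOPLESS_CODONS, n_codons, replace = TRUE), collapse = "")

# pad each sequence with gaps at random positions up to a common width
gapify <- function(seqs, width) {
  setNames(vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    out <- rep("-", width)
    out[sort(sample.int(width, length(chars)))] <- chars
    paste(out, collapse = "")
  }, character(1)), names(seqs))
}

# attach a distant outgroup leaf above the root of a rooted clade tree
add_outgroup <- function(tree, aln, outgroup_seq, label = "hydra") {
  nk <- sub(";$", "", ape::write.tree(tree))
  tree2 <- ape::read.tree(text = sprintf("(%s:1,%s:1);", label, nk))
  list(tree = tree2, aln = c(setNames(outgroup_seq, label), aln))
}

# write a complete pipeline bundle (two reference clades + query) built
# from the simulator; returns the config path
make_pipeline_bundle <- function(dir, L_codons = 10, d = 0.3, b = 0.15,
                                 seed = 101) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim1 <- simulate_clades(sim_scenario("common", L_codons = L_codons,
                                       n_a = 4, n_b = 6, b = b, d = d,
                                       seed = seed))
  sim2 <- simulate_clades(sim_scenario("common", L_codons = L_codons,
                                       n_a = 4, n_b = 4, b = b, d = d,
                                       seed = seed + 1))
  out_seq <- strsplit(sim2$root_b, "")[[1]]  # unrelated distant sequence
  ref1 <- add_outgroup(sim1$tree_a, sim1$aln_a, paste(rev(out_seq), collapse = ""))
  ref2 <- add_outgroup(sim2$tree_a, sim2$aln_a, paste(out_seq, collapse = ""))
  write_fasta(ref1$aln, file.path(dir, "ref1.fasta"))
  write_newick(ref1$tree, file.path(dir, "ref1.nwk"))
  write_fasta(ref2$aln, file.path(dir, "ref2.fasta"))
  write_newick(ref2$tree, file.path(dir, "ref2.nwk"))
  write_fasta(sim1$aln_b, file.path(dir, "query.fasta"))
  write_newick(ape::unroot(sim1$tree_b), file.path(dir, "query.nwk"))
  cfg <- file.path(dir, "config.yaml")
  writeLines(c(
    "references:",
    "  - name: ref1",
    "    alignment: ref1.fasta",
    "    tree: ref1.nwk",
    "    outgroup: hydra",
    "  - name: ref2",
    "    alignment: ref2.fasta",
    "    tree: ref2.nwk",
    "    outgroup: hydra",
    "query:",
    "  alignment: query.fasta",
    "  tree: query.nwk",
    "positions: [1, 2]",
    "alpha: 0.05",
    "quantile: 0.95",
    "seed: 7",
    "outdir: out"), cfg)
  cfg
}
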