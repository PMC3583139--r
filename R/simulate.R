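# Synthetic codon alignments for calibrating the relatedness test: two
# clades whose root sequences either descend from a shared ancestor at a
# stated divergence or are independent random draws, evolved site-
# independently under Jukes-Cantor along seed-controlled random-join trees.

NUC_CHARS <- c("A", "C", "G", "T")

.stopless_codons <- local({
  all3 <- expand.grid(NUC_CHARS, NUC_CHARS, NUC_CHARS,
                      stringsAsFactors = FALSE)
  cods <- apply(all3[, 3:1], 1, paste, collapse = "")
  setdiff(cods, c("TAA", "TAG", "TGA"))
})

#' Define a simulation scenario
#'
#' @param origin `"common"` (the two clade roots descend from one shared
#'   ancestral sequence separated by total divergence `d`) or
#'   `"independent"` (two unrelated random roots).
#' @param L_codons Codon count; default 86, the length of a
#'   structure/sequence-consensus test region over four helices.
#' @param n_a,n_b Leaves per clade (>= 2).
#' @param b Expected within-clade branch length, substitutions/site; edge
#'   lengths are exponential with this mean.
#' @param d Cross-clade divergence (substitutions/site separating the two
#'   clade roots; applied as `d/2` on each side). Ignored for
#'   `origin = "independent"`.
#' @param seed Integer seed; identical seeds give identical output.
#'   `NULL` leaves the RNG stream untouched (used inside replicated
#'   experiments that seed once).
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(origin = c("common", "independent"), L_codons = 86L,
                         n_a = 8L, n_b = 8L, b = 0.2, d = 0.5, seed = NULL) {
  origin <- match.arg(origin)
  stopifnot(L_codons >= 1L, n_a >= 2L, n_b >= 2L, b >= 0, d >= 0)
  structure(list(origin = origin, L_codons = as.integer(L_codons),
                 n_a = as.integer(n_a), n_b = as.integer(n_b),
                 b = b, d = d, seed = seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "Simulation scenario: origin=%s, %d codons, clades %d + %d, b=%g%s, seed=%s\n",
    x$origin, x$L_codons, x$n_a, x$n_b, x$b,
    if (x$origin == "common") sprintf(", d=%g", x$d) else "",
    ifelse(is.null(x$seed), "<RNG stream>", x$seed)))
  invisible(x)
}

# one Jukes-Cantor step of length t applied to an integer sequence (1..4)
.jc_evolve <- function(x, t) {
  if (t <= 0) return(x)
  p_change <- 0.75 * (1 - exp(-4 * t / 3))
  hit <- runif(length(x)) < p_change
  n <- sum(hit)
  if (n) x[hit] <- ((x[hit] - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  x
}

# rooted binary tree by sequential random joins, Exp(mean = b) edge lengths
.random_join_tree <- function(labels, b) {
  nodes <- as.list(labels)
  while (length(nodes) > 1L) {
    i <- sample.int(length(nodes), 2L)
    bl <- if (b > 0) rexp(2L, rate = 1 / b) else c(0, 0)
    merged <- sprintf("(%s:%.8f,%s:%.8f)",
                      nodes[[i[1L]]], bl[1L], nodes[[i[2L]]], bl[2L])
    nodes <- c(nodes[-i], list(merged))
  }
  ape::read.tree(text = paste0(nodes[[1L]], ";"))
}

# evolve an integer root sequence down a rooted tree; returns tip strings
.evolve_along <- function(tree, root_seq) {
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents precede children
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  seqs <- matrix(NA_integer_, nrow = nnode, ncol = length(root_seq))
  seqs[ntip + 1L, ] <- root_seq
  el <- tr$edge.length
  if (is.null(el)) el <- rep(0, nrow(tr$edge))
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    seqs[ch, ] <- .jc_evolve(seqs[p, ], el[k])
  }
  tips <- apply(seqs[seq_len(ntip), , drop = FALSE], 1, function(v)
    paste(NUC_CHARS[v], collapse = ""))
  setNames(tips, tr$tip.label)
}

.random_root <- function(L_codons) {
  cods <- sample(.stopless_codons, L_codons, replace = TRUE)
  match(strsplit(paste(cods, collapse = ""), "")[[1]], NUC_CHARS)
}

#' Simulate two clades of coding sequences
#'
#' Draws root sequences (uniform over stop-free codons), evolves them
#' site-independently under Jukes-Cantor along random-join trees, and
#' returns gap-free in-frame alignments, the true trees, and the true
#' clade-root sequences.
#'
#' @param scenario A [sim_scenario()].
#' @return List of class `sim_clades` with `aln_a`, `tree_a`, `root_a`,
#'   `aln_b`, `tree_b`, `root_b`, `root_common` (`NULL` for independent
#'   origin) and `scenario`.
#' @export
simulate_clades <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  L <- 3L * scenario$L_codons
  if (scenario$origin == "common") {
    root0 <- .random_root(scenario$L_codons)
    root_a <- .jc_evolve(root0, scenario$d / 2)
    root_b <- .jc_evolve(root0, scenario$d / 2)
  } else {
    root0 <- NULL
    root_a <- .random_root(scenario$L_codons)
    root_b <- .random_root(scenario$L_codons)
  }
  tree_a <- .random_join_tree(paste0("A", seq_len(scenario$n_a)), scenario$b)
  tree_b <- .random_join_tree(paste0("B", seq_len(scenario$n_b)), scenario$b)
  out <- list(
    aln_a = .evolve_along(tree_a, root_a), tree_a = tree_a,
    root_a = paste(NUC_CHARS[root_a], collapse = ""),
    aln_b = .evolve_along(tree_b, root_b), tree_b = tree_b,
    root_b = paste(NUC_CHARS[root_b], collapse = ""),
    root_common = if (is.null(root0)) NULL
                  else paste(NUC_CHARS[root0], collapse = ""),
    scenario = scenario)
  class(out) <- "sim_clades"
  out
}

#' @export
print.sim_clades <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("clade A: %d sequences of %d nt; clade B: %d sequences\n",
              length(x$aln_a), nchar(x$aln_a[[1]]), length(x$aln_b)))
  invisible(x)
}

#' Write a simulated data set to disk
#'
#' Emits FASTA alignments, Newick trees and a JSON manifest of the true
#' parameters, for use as pipeline input.
#'
#' @param sim A `sim_clades` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_clades <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$aln_a, file.path(dir, "clade_a.fasta"))
  write_fasta(sim$aln_b, file.path(dir, "clade_b.fasta"))
  write_newick(sim$tree_a, file.path(dir, "clade_a.nwk"))
  write_newick(sim$tree_b, file.path(dir, "clade_b.nwk"))
  manifest <- c(sim$scenario[c("origin", "L_codons", "n_a", "n_b", "b", "d")],
                list(seed = sim$scenario$seed,
                     root_a = sim$root_a, root_b = sim$root_b,
                     root_common = sim$root_common))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Rejection-rate calibration of the relatedness test
#'
#' For each scenario cell: simulate the two clades, reconstruct each
#' clade-root ancestral state by the Fitch downpass on the true tree,
#' mask the chosen codon positions, run [relatedness_test()], and record
#' the fraction of replicates rejecting at `alpha`, with a binomial
#' confidence interval. Independent-origin cells estimate the type-I
#' error; common-origin cells at varying `d` trace the power curve.
#'
#' @param d Numeric vector of cross-clade divergences (one cell each).
#'   Ignored (single cell) when `origin = "independent"`.
#' @param origin `"common"` or `"independent"`.
#' @param replicates Replicates per cell (>= 10).
#' @param alpha Significance level.
#' @param L_codons,n_a,n_b,b Scenario parameters, as in [sim_scenario()].
#' @param positions Codon positions entering the test (default 1 and 2).
#' @param seed Seed set once at entry.
#' @return Data frame with one row per cell: `origin`, `d`, `replicates`,
#'   `rejections`, `rate`, `ci_lo`, `ci_hi`.
#' @export
calibration_experiment <- function(d = 0.5, origin = c("common", "independent"),
                                   replicates = 200L, alpha = 0.05,
                                   L_codons = 86L, n_a = 8L, n_b = 8L, b = 0.2,
                                   positions = c(1L, 2L), seed = 1L) {
  origin <- match.arg(origin)
  stopifnot(replicates >= 10L)
  if (origin == "independent") d <- NA_real_
  set.seed(seed)
  rows <- lapply(d, function(dv) {
    scen <- sim_scenario(origin = origin, L_codons = L_codons, n_a = n_a,
                         n_b = n_b, b = b, d = ifelse(is.na(dv), 0, dv),
                         seed = NULL)
    rej <- 0L
    for (r in seq_len(replicates)) {
      sim <- simulate_clades(scen)
      mask <- codon_mask(3L * L_codons, positions)
      sa <- fitch_downpass(sim$tree_a, sim$aln_a, mask = mask)
      sb <- fitch_downpass(sim$tree_b, sim$aln_b, mask = mask)
      rt <- relatedness_test(sa, sb, alpha = alpha)
      if (rt$significant) rej <- rej + 1L
    }
    ci <- stats::binom.test(rej, replicates)$conf.int
    data.frame(origin = origin, d = dv, replicates = replicates,
               rejections = rej, rate = rej / replicates,
               ci_lo = ci[1], ci_hi = ci[2])
  })
  do.call(rbind, rows)
}
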