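# Fitch-parsimony ancestral inference on nucleotide ambiguity sets.
# Sets are encoded as 4-bit masks (A=1, C=2, G=4, T=8); set algebra is
# bitwAnd/bitwOr, vectorised over sites. Only the downpass ("preliminary")
# sets are computed: the relatedness test operates on ambiguity sets, not
# on resolved single-state reconstructions.

NUC_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L)
# IUPAC code for every nonempty subset of {A,C,G,T}, indexed by bitmask
IUPAC_BY_MASK <- c("A","C","M","G","R","S","V","T","W","Y","H","K","D","B","N")
MASK_BY_IUPAC <- setNames(seq_len(15L), IUPAC_BY_MASK)

#' Construct an ancestral state
#'
#' An ancestral state is an ordered sequence of nucleotide ambiguity sets
#' (nonempty subsets of A/C/G/T, stored as bitmasks) together with a site
#' mask selecting which positions enter the relatedness test.
#'
#' @param sites Integer vector of bitmasks in 1..15 (A=1, C=2, G=4, T=8).
#' @param mask Integer vector of 1-based site indices used for testing;
#'   defaults to all sites.
#' @param node Label of the tree node/edge the state belongs to.
#' @param score Parsimony score (total state changes) of the reconstruction.
#' @return Object of class `ancestral_state`.
#' @export
ancestral_state <- function(sites, mask = seq_along(sites), node = NA_character_,
                            score = NA_integer_) {
  sites <- as.integer(sites)
  if (length(sites) == 0L || any(sites < 1L | sites > 15L))
    stop("sites must be nonempty bitmasks in 1..15", call. = FALSE)
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) == 0L || any(mask < 1L | mask > length(sites)))
    stop("mask must index sites (1..", length(sites), ")", call. = FALSE)
  structure(list(sites = sites, mask = mask, node = node,
                 score = as.integer(score)),
            class = "ancestral_state")
}

#' @export
print.ancestral_state <- function(x, ...) {
  cat(sprintf("Ancestral state at %s: %d sites (%d masked), parsimony score %s\n",
              ifelse(is.na(x$node), "<unnamed node>", x$node),
              length(x$sites), length(x$mask),
              ifelse(is.na(x$score), "NA", x$score)))
  cat(" ", substr(state_to_iupac(x), 1, 60),
      if (length(x$sites) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Convert an ancestral state to an IUPAC ambiguity string
#' @param state An `ancestral_state`.
#' @return Character string, one IUPAC code per site.
#' @export
state_to_iupac <- function(state) paste(IUPAC_BY_MASK[state$sites], collapse = "")

#' Build an ancestral state from an IUPAC ambiguity string
#'
#' Singleton sites are plain A/C/G/T; ambiguity sets use IUPAC codes
#' (`N` or `-` = the full set). Used both to load reconstructed states and
#' to treat an extant sequence as a state of singleton sets.
#'
#' @param x Nucleotide/IUPAC string.
#' @param mask,node,score Passed to [ancestral_state()].
#' @return An `ancestral_state`.
#' @export
as_ancestral_state <- function(x, mask = NULL, node = NA_character_,
                               score = NA_integer_) {
  chars <- strsplit(toupper(x), "")[[1]]
  chars[chars == "-"] <- "N"
  masks <- MASK_BY_IUPAC[chars]
  if (anyNA(masks))
    stop("invalid IUPAC character(s): ",
         paste(unique(chars[is.na(masks)]), collapse = " "), call. = FALSE)
  ancestral_state(unname(masks), mask = if (is.null(mask)) seq_along(masks) else mask,
                  node = node, score = score)
}

#' Per-leaf nucleotide sets from an alignment
#'
#' A/C/G/T become singleton sets; `N` and `-` (missing data) become the
#' full set, which is parsimony-uninformative. Any other character is an
#' error.
#'
#' @param aln Named character vector: gap-tolerant nucleotide alignment.
#' @return Integer matrix of bitmasks (rows = sequences, columns = sites).
#' @export
leaf_sets <- function(aln) {
  aln <- as_alignment(aln)
  lut <- c(NUC_BIT, N = 15L, "-" = 15L)
  m <- matrix(0L, nrow = length(aln), ncol = nchar(aln[[1]]),
              dimnames = list(names(aln), NULL))
  for (id in names(aln)) {
    chars <- strsplit(aln[[id]], "")[[1]]
    v <- lut[chars]
    if (anyNA(v))
      stop("sequence '", id, "' contains non-nucleotide character(s): ",
           paste(unique(chars[is.na(v)]), collapse = " "), call. = FALSE)
    m[id, ] <- unname(v)
  }
  m
}

# Directed Fitch engine over a phylo tree's adjacency graph. sets(from, node)
# returns the downpass set (bitmask vector over sites) and score of the
# subtree containing `node` when approached from neighbour `from` (0 = none,
# i.e. treat `node` as root). Children at multifurcations are folded
# sequentially in adjacency order, a deterministic ladder resolution.
.fitch_engine <- function(tree, lsets) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  adj <- vector("list", nnode)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1L]; b <- tree$edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  missing <- setdiff(tree$tip.label, rownames(lsets))
  if (length(missing))
    stop("no sequence for leaf/leaves: ", paste(missing, collapse = ", "),
         call. = FALSE)
  memo <- new.env(parent = emptyenv())
  sets <- function(from, node) {
    key <- paste0(from, "_", node)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    if (node <= ntip) {
      res <- list(set = lsets[tree$tip.label[node], ], score = 0L)
    } else {
      kids <- setdiff(adj[[node]], from)
      res <- sets(node, kids[1L])
      for (w in kids[-1L]) {
        other <- sets(node, w)
        inter <- bitwAnd(res$set, other$set)
        empty <- inter == 0L
        if (any(empty))
          inter[empty] <- bitwOr(res$set[empty], other$set[empty])
        res <- list(set = inter,
                    score = res$score + other$score + sum(empty))
      }
    }
    memo[[key]] <- res
    res
  }
  list(sets = sets, adj = adj, ntip = ntip)
}

#' Fitch downpass: ancestral set at the root of a tree
#'
#' Bottom-up pass of Fitch (1971) small parsimony: at each internal node
#' the set is the intersection of its children's sets if nonempty,
#' otherwise their union with one extra state change. Branch lengths are
#' ignored. Multifurcations are folded deterministically into a
#' zero-length ladder.
#'
#' @param tree Rooted [ape::phylo] tree whose tip labels index `lsets`.
#' @param lsets Bitmask matrix from [leaf_sets()] (or an alignment, which
#'   is converted).
#' @param mask Site mask for the returned state; default all sites.
#' @return An [ancestral_state()] at the root, with total parsimony score.
#' @export
fitch_downpass <- function(tree, lsets, mask = NULL) {
  if (is.character(lsets)) lsets <- leaf_sets(lsets)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted; see root_with_outgroup()", call. = FALSE)
  eng <- .fitch_engine(tree, lsets)
  root <- eng$ntip + 1L
  res <- eng$sets(0L, root)
  ancestral_state(res$set,
                  mask = if (is.null(mask)) seq_along(res$set) else mask,
                  node = "root", score = res$score)
}

#' Root a tree on the edge subtending an outgroup leaf
#'
#' @param tree An [ape::phylo] tree.
#' @param outgroup_label Leaf label to root on.
#' @return Rooted tree: the root's two children are the outgroup leaf and
#'   the ingroup ancestor (the node ancestral states are built on).
#' @export
root_with_outgroup <- function(tree, outgroup_label) {
  if (!outgroup_label %in% tree$tip.label)
    stop("outgroup '", outgroup_label, "' is not a leaf of the tree",
         call. = FALSE)
  ape::root(ape::unroot(tree), outgroup = outgroup_label,
            resolve.root = TRUE)
}

#' Ancestral state of the ingroup under outgroup rooting
#'
#' Roots the tree on the outgroup, drops the outgroup leaf, and runs the
#' Fitch downpass on the ingroup subtree; the returned state belongs to
#' the most recent common ancestor of the ingroup.
#'
#' @inheritParams fitch_downpass
#' @param outgroup_label Leaf used only for rooting.
#' @return An `ancestral_state` at the ingroup root.
#' @export
ingroup_root_state <- function(tree, lsets, outgroup_label, mask = NULL) {
  if (is.character(lsets)) lsets <- leaf_sets(lsets)
  rooted <- root_with_outgroup(tree, outgroup_label)
  ingroup <- ape::drop.tip(rooted, outgroup_label)
  st <- fitch_downpass(ingroup, lsets, mask = mask)
  st$node <- "ingroup_root"
  st
}

#' Candidate ancestral states at every edge of an unrooted tree
#'
#' When no outgroup exists the ancestral node is unknown; every edge is a
#' candidate root position. For each edge the tree is rooted at that
#' edge's midpoint and the Fitch downpass root set is emitted. The
#' parsimony score is root-invariant, so all states carry the same score.
#'
#' @param tree An [ape::phylo] tree (unrooted; a rooted tree is unrooted
#'   first). Needs at least 3 leaves.
#' @param lsets Bitmask matrix from [leaf_sets()], or an alignment.
#' @param mask Site mask applied to every returned state.
#' @return List of `ancestral_state`, one per edge, named
#'   `edge_<parent>_<child>` in the unrooted tree's node numbering.
#' @export
states_at_all_nodes <- function(tree, lsets, mask = NULL) {
  if (is.character(lsets)) lsets <- leaf_sets(lsets)
  ut <- ape::unroot(tree)
  if (length(ut$tip.label) < 3L)
    stop("need at least 3 leaves", call. = FALSE)
  eng <- .fitch_engine(ut, lsets)
  out <- vector("list", nrow(ut$edge))
  for (k in seq_len(nrow(ut$edge))) {
    u <- ut$edge[k, 1L]; v <- ut$edge[k, 2L]
    a <- eng$sets(v, u)   # subtree on the parent side
    b <- eng$sets(u, v)   # subtree on the child side
    inter <- bitwAnd(a$set, b$set)
    empty <- inter == 0L
    if (any(empty)) inter[empty] <- bitwOr(a$set[empty], b$set[empty])
    out[[k]] <- ancestral_state(
      inter, mask = if (is.null(mask)) seq_along(inter) else mask,
      node = sprintf("edge_%d_%d", u, v),
      score = a$score + b$score + sum(empty))
  }
  names(out) <- vapply(out, `[[`, character(1), "node")
  out
}

#' Site mask selecting codon positions
#'
#' @param n_sites Number of nucleotide sites (a multiple of 3).
#' @param positions Codon positions to keep, subset of 1:3; the default
#'   keeps first and second positions, where substitutions are most often
#'   non-synonymous.
#' @return Integer vector of 1-based site indices.
#' @export
codon_mask <- function(n_sites, positions = c(1L, 2L)) {
  if (n_sites %% 3L != 0L)
    stop("n_sites (", n_sites, ") is not a multiple of 3", call. = FALSE)
  stopifnot(all(positions %in% 1:3))
  which(((seq_len(n_sites) - 1L) %% 3L + 1L) %in% positions)
}

#' Replace the site mask of a state with a codon-position mask
#' @param state An `ancestral_state` over in-frame nucleotide sites.
#' @param positions Codon positions to keep (default 1 and 2).
#' @return The state with its mask replaced.
#' @export
set_codon_mask <- function(state, positions = c(1L, 2L)) {
  state$mask <- codon_mask(length(state$sites), positions)
  state
}

#' Write ancestral states as IUPAC FASTA
#' @param states List of `ancestral_state` (named, or carrying node labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_states_fasta <- function(states, path) {
  if (inherits(states, "ancestral_state")) states <- list(states)
  nm <- names(states)
  if (is.null(nm)) nm <- vapply(states, `[[`, character(1), "node")
  seqs <- setNames(vapply(states, state_to_iupac, character(1)), nm)
  write_fasta(seqs, path)
}

#' Read ancestral states from an IUPAC FASTA file
#' @param path Input path.
#' @param positions Codon positions for the mask, or `NULL` for all sites.
#' @return Named list of `ancestral_state`.
#' @export
read_states_fasta <- function(path, positions = c(1L, 2L)) {
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) {
    st <- as_ancestral_state(as.character(set[[i]]), node = nm[i])
    if (!is.null(positions)) st <- set_codon_mask(st, positions)
    st
  })
  setNames(out, nm)
}
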