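#' paleohom: ancestral-state relatedness tests for deep protein homology
#'
#' Detecting homology between protein families whose pairwise sequence
#' identity has decayed below the twilight zone (15--30%) cannot rely on
#' alignment scores. This package implements an older, set-based route:
#' reconstruct the ancestral nucleotide ambiguity set of each family by Fitch
#' parsimony on its gene tree, then ask whether the two ancestral
#' set-sequences are more compatible than random re-pairing of their sites
#' would predict. The workhorse is [relatedness_test()]; supporting modules
#' read/write FASTA and Newick, screen homology-search hits, derive
#' structure/sequence-consensus test regions, reconstruct ancestral states
#' ([fitch_downpass()], [states_at_all_nodes()]), simulate calibration data
#' ([simulate_clades()], [calibration_experiment()]) and drive the whole
#' pipeline ([run_pipeline()]).
#'
#' All column and site indices in this package are 1-based and intervals are
#' inclusive, following the convention of ape and Biostrings.
#'
#' @importFrom stats pnorm quantile rexp runif setNames binom.test
#' @importFrom utils write.table head
#' @keywords internal
"_PACKAGE"

AA_CHARS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
              "S","T","V","W","Y","X","*","-")
DNA_CHARS <- c("A","C","G","T","N","-")

.check_alphabet <- function(seqs, moltype) {
  ok_chars <- if (moltype == "protein") AA_CHARS else DNA_CHARS
  for (id in names(seqs)) {
    chars <- unique(strsplit(seqs[[id]], "")[[1]])
    bad <- setdiff(chars, ok_chars)
    if (length(bad))
      stop(sprintf("sequence '%s' contains characters invalid for %s: %s",
                   id, moltype, paste(bad, collapse = " ")), call. = FALSE)
  }
  invisible(seqs)
}

#' Read sequences from a FASTA file
#'
#' Records are uppercased and returned in file order as a named character
#' vector (names are the first whitespace-delimited token of each header).
#'
#' @param path Path to a FASTA file.
#' @param moltype `"protein"` or `"dna"`; controls alphabet validation.
#'   Gaps (`-`) and full ambiguity (`X`/`N`) are always allowed.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, moltype = c("protein", "dna")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(seqs))) {
    empty <- names(seqs)[!nzchar(seqs)]
    stop("empty FASTA record(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  .check_alphabet(as.list(seqs), moltype)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width; 60 columns by default.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(setNames(as.character(seqs), names(seqs)))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Interpret a set of equal-length sequences as an alignment
#'
#' @param seqs Named character vector (e.g. from [read_fasta()]).
#' @return `seqs` unchanged, after checking that all rows have equal length.
#' @export
as_alignment <- function(seqs) {
  if (length(seqs) == 0L) stop("empty alignment", call. = FALSE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("alignment rows differ in length: ",
         paste(sprintf("%s=%d", names(seqs), widths), collapse = ", "),
         call. = FALSE)
  seqs
}

#' Read a tree in Newick format
#'
#' @param path Path to a Newick file (terminal semicolon required).
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("Newick parse error in ", path, call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in ", path, call. = FALSE)
  tree
}

#' Write a tree in Newick format
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Translate an in-frame coding sequence
#'
#' Standard genetic code. Codons containing `N` translate to `X`; the gap
#' codon `---` translates to `-`. Internal stop codons are an error; a
#' terminal stop is trimmed when `trim_stop = TRUE`.
#'
#' @param cds A nucleotide string with length a multiple of 3.
#' @param trim_stop Drop a terminal stop codon before translating.
#' @return The amino-acid string.
#' @export
translate_cds <- function(cds, trim_stop = TRUE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L)
    stop("CDS length ", n, " is not a positive multiple of 3", call. = FALSE)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- vapply(codons, function(cd) {
    if (cd == "---") return("-")
    if (grepl("-", cd, fixed = TRUE))
      stop("partial gap codon '", cd, "'", call. = FALSE)
    if (grepl("N", cd, fixed = TRUE)) return("X")
    out <- Biostrings::GENETIC_CODE[[cd]]
    if (is.null(out)) stop("unknown codon '", cd, "'", call. = FALSE)
    out
  }, character(1), USE.NAMES = FALSE)
  if (trim_stop && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*"))
    stop("internal stop codon at codon ", which(aa == "*")[1], call. = FALSE)
  paste(aa, collapse = "")
}

#' Thread coding sequences through a protein alignment
#'
#' Builds the in-frame nucleotide alignment implied by a protein alignment:
#' each aligned residue is replaced by its codon and each protein gap by
#' `---`. Every CDS must translate exactly to the ungapped protein row
#' (terminal stop codons are trimmed first); a mismatch is an error naming
#' the sequence and the first offending residue.
#'
#' @param protein_aln Named character vector: the protein alignment.
#' @param cds Named character vector of unaligned coding sequences covering
#'   every id in `protein_aln`.
#' @return An object of class `codon_alignment`: a list with elements
#'   `protein` and `nucleotide` (both named character vectors; the
#'   nucleotide alignment has 3x the protein column count).
#' @export
pair_codon_alignment <- function(protein_aln, cds) {
  protein_aln <- as_alignment(protein_aln)
  missing <- setdiff(names(protein_aln), names(cds))
  if (length(missing))
    stop("no CDS provided for: ", paste(missing, collapse = ", "), call. = FALSE)
  nuc <- character(length(protein_aln))
  names(nuc) <- names(protein_aln)
  for (id in names(protein_aln)) {
    cd <- toupper(cds[[id]])
    # trim terminal stop before the translation check
    if (nchar(cd) %% 3L == 0L && nchar(cd) >= 3L) {
      last <- substr(cd, nchar(cd) - 2L, nchar(cd))
      if (!grepl("-|N", last) && Biostrings::GENETIC_CODE[[last]] == "*")
        cd <- substr(cd, 1L, nchar(cd) - 3L)
    }
    prot <- gsub("-", "", protein_aln[[id]], fixed = TRUE)
    trans <- translate_cds(cd, trim_stop = FALSE)
    if (trans != prot) {
      tc <- strsplit(trans, "")[[1]]; pc <- strsplit(prot, "")[[1]]
      k <- min(length(tc), length(pc))
      pos <- which(tc[seq_len(k)] != pc[seq_len(k)])[1]
      if (is.na(pos)) pos <- k + 1L
      stop(sprintf(
        "CDS of '%s' does not translate to its protein row (first mismatch at residue %d)",
        id, pos), call. = FALSE)
    }
    cols <- strsplit(protein_aln[[id]], "")[[1]]
    codons <- substring(cd, seq(1L, nchar(cd), 3L), seq(3L, nchar(cd), 3L))
    out <- character(length(cols))
    j <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") out[i] <- "---"
      else { j <- j + 1L; out[i] <- codons[j] }
    }
    nuc[[id]] <- paste(out, collapse = "")
  }
  structure(list(protein = protein_aln, nucleotide = nuc),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment: %d sequences, %d protein columns (%d nt)\n",
              length(x$protein), nchar(x$protein[[1]]), nchar(x$nucleotide[[1]])))
  invisible(x)
}
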