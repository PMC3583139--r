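# Test-region selection: alignment columns whose positional homology is
# asserted simultaneously by a sequence alignment and a structure-derived
# alignment of a shared sequence subset. Agreement is operationalised as
# equality of residue-index tuples over the shared ids, which is the
# gap-robust formal reading of "the same positional homology".

#' Map alignment columns to ungapped residue indices
#'
#' @param aln Named character vector: an alignment.
#' @return Integer matrix (rows = sequences, columns = alignment columns)
#'   of 1-based ungapped residue indices, `NA` where a row is gapped.
#' @export
column_correspondence <- function(aln) {
  aln <- as_alignment(aln)
  ncol <- nchar(aln[[1]])
  m <- matrix(NA_integer_, nrow = length(aln), ncol = ncol,
              dimnames = list(names(aln), NULL))
  for (id in names(aln)) {
    chars <- strsplit(aln[[id]], "")[[1]]
    idx <- cumsum(chars != "-")
    m[id, chars != "-"] <- idx[chars != "-"]
  }
  m
}

.runs_to_blocks <- function(cols) {
  if (length(cols) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  brk <- c(TRUE, diff(cols) != 1L)
  grp <- cumsum(brk)
  start <- tapply(cols, grp, min)
  end <- tapply(cols, grp, max)
  data.frame(start = as.integer(start), end = as.integer(end),
             length = as.integer(end - start + 1L), row.names = NULL)
}

#' Columns on which two alignments agree
#'
#' A column of `seq_aln` is *consistent* when (a) every shared id is
#' ungapped there and (b) some column of `struct_aln` pairs exactly the
#' same residues (equal tuples of ungapped residue indices over
#' `shared_ids`). Consistent columns are reported as maximal runs.
#'
#' @param seq_aln,struct_aln Named character vectors: the sequence-based
#'   alignment and the structure-based alignment. `struct_aln` typically
#'   covers only the subset of sequences with solved structures.
#' @param shared_ids Ids present in both alignments; their ungapped
#'   sequences must be identical in the two.
#' @param min_block Drop blocks shorter than this many columns (default 1,
#'   i.e. keep all).
#' @return Data frame of blocks with 1-based inclusive `start`, `end`
#'   (columns of `seq_aln`) and `length`.
#' @export
consistent_columns <- function(seq_aln, struct_aln, shared_ids,
                               min_block = 1L) {
  seq_aln <- as_alignment(seq_aln)
  struct_aln <- as_alignment(struct_aln)
  missing <- c(setdiff(shared_ids, names(seq_aln)),
               setdiff(shared_ids, names(struct_aln)))
  if (length(missing))
    stop("shared id(s) absent from an alignment: ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  for (id in shared_ids) {
    a <- gsub("-", "", seq_aln[[id]], fixed = TRUE)
    b <- gsub("-", "", struct_aln[[id]], fixed = TRUE)
    if (a != b)
      stop("ungapped sequence of '", id,
           "' differs between the two alignments", call. = FALSE)
  }
  ms <- column_correspondence(seq_aln)[shared_ids, , drop = FALSE]
  mt <- column_correspondence(struct_aln)[shared_ids, , drop = FALSE]
  key <- function(m, j) paste(m[, j], collapse = ",")
  full_t <- which(colSums(is.na(mt)) == 0L)
  struct_keys <- vapply(full_t, function(j) key(mt, j), character(1))
  full_s <- which(colSums(is.na(ms)) == 0L)
  consistent <- full_s[vapply(full_s, function(j) key(ms, j) %in% struct_keys,
                              logical(1))]
  blocks <- .runs_to_blocks(consistent)
  blocks[blocks$length >= min_block, , drop = FALSE]
}

#' Total residue span of region blocks
#'
#' @param blocks Data frame with a `length` column, as returned by
#'   [consistent_columns()].
#' @return Total residue count, with attribute `nucleotides` = 3x that.
#' @export
region_length <- function(blocks) {
  total <- if (nrow(blocks)) sum(blocks$length) else 0L
  structure(as.integer(total), nucleotides = as.integer(3L * total))
}

#' Extract region columns from an alignment
#'
#' @param aln Named character vector.
#' @param blocks Block data frame (protein-alignment coordinates).
#' @param codon When `TRUE`, `aln` is an in-frame nucleotide alignment and
#'   protein block `[s, e]` maps to nucleotide columns `[3s-2, 3e]`.
#' @return The alignment restricted to the block columns.
#' @export
extract_region <- function(aln, blocks, codon = FALSE) {
  aln <- as_alignment(aln)
  cols <- integer(0)
  for (k in seq_len(nrow(blocks))) {
    if (codon)
      cols <- c(cols, (3L * blocks$start[k] - 2L):(3L * blocks$end[k]))
    else cols <- c(cols, blocks$start[k]:blocks$end[k])
  }
  vapply(aln, function(s)
    paste(strsplit(s, "")[[1]][cols], collapse = ""), character(1))
}
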