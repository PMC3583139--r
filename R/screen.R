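# Hit-screening rules applied to raw homology-search output before any
# phylogenetic work: retinal-binding lysine conservation, length bounds,
# and redundancy removal.

.screen_report <- function(kept, dropped_ids, reasons) {
  kept <- as.character(kept); dropped_ids <- as.character(dropped_ids)
  reasons <- as.character(reasons)
  df <- data.frame(
    id = c(kept, dropped_ids),
    status = c(rep("kept", length(kept)), rep("dropped", length(dropped_ids))),
    reason = c(rep(NA_character_, length(kept)), reasons),
    stringsAsFactors = FALSE
  )
  class(df) <- c("screen_report", "data.frame")
  df
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Screen report: %d kept, %d dropped\n",
              sum(x$status == "kept"), sum(x$status == "dropped")))
  if (any(x$status == "dropped"))
    print.data.frame(x[x$status == "dropped", , drop = FALSE], row.names = FALSE)
  invisible(x)
}

#' Check conservation of the retinal-binding lysine
#'
#' Rhodopsins bind retinal through a lysine in the seventh transmembrane
#' helix. Given an alignment of a query of known lysine position with
#' candidate hits, this maps the query's lysine to its alignment column and
#' reports, per row, whether that column also holds a lysine.
#'
#' @param aln Named character vector: protein alignment containing the query.
#' @param query_id Row id of the query.
#' @param lysine_pos 1-based ungapped residue index of the lysine in the
#'   query sequence.
#' @return Named logical vector over the alignment rows (the query maps to
#'   `TRUE`).
#' @export
check_retinal_lysine <- function(aln, query_id, lysine_pos) {
  aln <- as_alignment(aln)
  if (!query_id %in% names(aln))
    stop("query '", query_id, "' not in alignment", call. = FALSE)
  qchars <- strsplit(aln[[query_id]], "")[[1]]
  resno <- cumsum(qchars != "-")
  col <- which(qchars != "-" & resno == lysine_pos)
  if (length(col) != 1L)
    stop("query '", query_id, "' has no residue ", lysine_pos, call. = FALSE)
  if (qchars[col] != "K")
    stop(sprintf("query residue %d of '%s' is '%s', not lysine",
                 lysine_pos, query_id, qchars[col]), call. = FALSE)
  vapply(aln, function(s) substr(s, col, col) == "K", logical(1))
}

#' Filter protein sequences by ungapped length
#'
#' Keeps sequences whose ungapped length lies in `[min_len, max_len]`
#' (both bounds inclusive; the defaults keep 200- and 1000-residue
#' sequences and drop 199 and 1001).
#'
#' @param seqs Named character vector of protein sequences (gaps ignored).
#' @param min_len,max_len Inclusive length bounds.
#' @return A `screen_report` data frame with columns id, status, reason.
#' @export
length_filter <- function(seqs, min_len = 200L, max_len = 1000L) {
  len <- nchar(gsub("-", "", seqs, fixed = TRUE))
  short <- len < min_len
  long <- len > max_len
  rep <- .screen_report(names(seqs)[!short & !long],
                        names(seqs)[short | long],
                        ifelse(short[short | long], "too_short", "too_long"))
  # preserve input order
  rep[order(match(rep$id, names(seqs))), , drop = FALSE]
}

#' Drop redundant sequences
#'
#' Sequences with identical ungapped residue strings are redundant; the
#' first occurrence (input order) is kept, later copies are dropped.
#'
#' @param seqs Named character vector of sequences.
#' @return A `screen_report` data frame.
#' @export
dedupe <- function(seqs) {
  ungapped <- toupper(gsub("-", "", seqs, fixed = TRUE))
  dup <- duplicated(ungapped)
  rep <- .screen_report(names(seqs)[!dup], names(seqs)[dup],
                        rep("redundant", sum(dup)))
  rep[order(match(rep$id, names(seqs))), , drop = FALSE]
}

#' Screen candidate hits with all filters
#'
#' Applies, in order: retinal-lysine conservation (when `query_id` is
#' given), length bounds, and redundancy removal. The query row itself is
#' not screened.
#'
#' @inheritParams check_retinal_lysine
#' @inheritParams length_filter
#' @return A `screen_report` data frame over all non-query rows with drop
#'   reasons `no_lysine`, `too_short`, `too_long` or `redundant`.
#' @export
screen_candidates <- function(aln, query_id = NULL, lysine_pos = NULL,
                              min_len = 200L, max_len = 1000L) {
  seqs <- aln
  dropped <- character(0); reasons <- character(0)
  if (!is.null(query_id)) {
    hask <- check_retinal_lysine(aln, query_id, lysine_pos)
    seqs <- seqs[setdiff(names(seqs), query_id)]
    fail <- names(seqs)[!hask[names(seqs)]]
    dropped <- c(dropped, fail)
    reasons <- c(reasons, rep("no_lysine", length(fail)))
    seqs <- seqs[setdiff(names(seqs), fail)]
  }
  lf <- length_filter(seqs, min_len, max_len)
  dropped <- c(dropped, lf$id[lf$status == "dropped"])
  reasons <- c(reasons, lf$reason[lf$status == "dropped"])
  seqs <- seqs[lf$id[lf$status == "kept"]]
  dd <- dedupe(seqs)
  dropped <- c(dropped, dd$id[dd$status == "dropped"])
  reasons <- c(reasons, dd$reason[dd$status == "dropped"])
  kept <- dd$id[dd$status == "kept"]
  rep <- .screen_report(kept, dropped, reasons)
  ord <- if (is.null(query_id)) names(aln) else setdiff(names(aln), query_id)
  rep[order(match(rep$id, ord)), , drop = FALSE]
}
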