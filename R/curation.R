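# Reference-genome QC filtering and ANI-based dereplication.

check_records <- function(records) {
  check_columns(
    records, c("genome_id", "completeness", "contamination"),
    "genome record table"
  )
  if (any(records$completeness < 0 | records$completeness > 100) ||
      any(records$contamination < 0 | records$contamination > 100)) {
    stop_input("completeness/contamination percentages must lie in [0, 100]")
  }
  records
}

#' Quality-control filter for reference genomes
#'
#' Keeps genomes whose estimated completeness is at least
#' `min_completeness` percent (inclusive) and whose contamination is
#' strictly below `max_contamination` percent. The asymmetric boundary
#' semantics (>= for completeness, < for contamination) follow the
#' conventional phrasing of assembly QC thresholds.
#'
#' @param records data.frame with columns `genome_id`, `completeness`,
#'   `contamination` (percent, \[0, 100\]); extra columns pass through.
#' @param min_completeness Minimum completeness percent; default 90.
#' @param max_contamination Exclusive contamination ceiling; default 5.
#' @return The retained rows of `records`.
#' @examples
#' recs <- data.frame(
#'   genome_id = c("a", "b", "c"),
#'   completeness = c(90, 89.9, 99),
#'   contamination = c(4.9, 1, 5)
#' )
#' qc_filter(recs)$genome_id # "a" only
#' @export
qc_filter <- function(records, min_completeness = 90, max_contamination = 5) {
  records <- check_records(records)
  if (min_completeness < 0 || min_completeness > 100 ||
      max_contamination < 0 || max_contamination > 100) {
    stop_input("QC thresholds must lie in [0, 100]")
  }
  keep <- records$completeness >= min_completeness &
    records$contamination < max_contamination
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

symmetrize_ani <- function(ani) {
  ani <- as.matrix(ani)
  if (nrow(ani) != ncol(ani) ||
      is.null(rownames(ani)) || is.null(colnames(ani)) ||
      !identical(rownames(ani), colnames(ani))) {
    stop_input("ANI matrix must be square with matching row/column ids")
  }
  if (any(ani < 0 | ani > 100, na.rm = TRUE)) {
    stop_input("ANI values must lie in [0, 100]")
  }
  # Alignment-based ANI (e.g. ANIb) is asymmetric; take the elementwise
  # maximum, the conservative choice that merges more genome pairs.
  pmax(ani, t(ani))
}

#' Dereplicate a genome collection by pairwise ANI
#'
#' Reduces a genome collection so that no retained pair shares more than
#' `threshold` percent average nucleotide identity. Selection is
#' quality-ranked greedy: candidates are ordered by completeness
#' (descending), contamination (ascending), genome length (descending) and
#' finally genome id, and each candidate is accepted iff its ANI to every
#' already-accepted genome is at most the threshold. The result therefore
#' satisfies the pairwise constraint by construction and is maximal — every
#' rejected genome exceeds the threshold against some retained genome.
#'
#' Asymmetric input matrices are symmetrized by elementwise maximum before
#' comparison.
#'
#' @inheritParams qc_filter
#' @param ani Square numeric matrix of pairwise ANI percent values with
#'   genome ids as dimnames; must cover every record.
#' @param threshold Maximum tolerated pairwise ANI percent; default 98.
#' @return The retained rows of `records`, in acceptance order.
#' @export
dereplicate_by_ani <- function(records, ani, threshold = 98) {
  records <- check_records(records)
  ani <- symmetrize_ani(ani)
  if (nrow(records) == 0L) {
    return(records)
  }
  missing <- setdiff(records$genome_id, rownames(ani))
  if (length(missing) > 0) {
    stop_input(
      "genome(s) absent from ANI matrix: %s", paste(missing, collapse = ", ")
    )
  }
  len <- if ("length" %in% names(records)) records$length else rep(0, nrow(records))
  ord <- order(
    -records$completeness, records$contamination, -len,
    records$genome_id, method = "radix"
  )
  accepted <- character(0)
  for (i in ord) {
    id <- records$genome_id[i]
    if (length(accepted) == 0L || all(ani[id, accepted] <= threshold)) {
      accepted <- c(accepted, id)
    }
  }
  out <- records[match(accepted, records$genome_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
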