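# Relative abundances and clade-level series derived from coverage summaries.

check_summary <- function(summaries) {
  check_columns(
    summaries, c("sample_id", "genome_id", "q2q3_mean_depth", "breadth"),
    "coverage summary"
  )
  if (any(summaries$q2q3_mean_depth < 0)) {
    stop_input("q2q3_mean_depth must be non-negative")
  }
  if (!"detected" %in% names(summaries)) {
    summaries$detected <- detect_genome(summaries$breadth)
  }
  summaries
}

check_clade_map <- function(summaries, clades) {
  check_columns(clades, c("genome_id", "clade_id"), "clade map")
  unknown <- setdiff(unique(summaries$genome_id), clades$genome_id)
  if (length(unknown) > 0) {
    stop_input(
      "genome(s) without clade assignment: %s",
      paste(unknown, collapse = ", ")
    )
  }
  clades
}

#' Per-sample relative abundance of genomes
#'
#' Converts Q2Q3 mean depths into within-sample relative abundances. The
#' depth of every undetected genome is first set to zero, then each genome's
#' (zeroed) depth is divided by the sample total of the zeroed depths. A
#' sample where nothing is detected yields all-zero abundances rather than
#' an error: samples with no recruitment are an expected outcome on thinly
#' colonized mucosal surfaces.
#'
#' @param summaries Coverage summary data.frame from [summarize_profiles()]
#'   (columns `sample_id`, `genome_id`, `q2q3_mean_depth`, `breadth`,
#'   `detected`). May hold one or many samples.
#' @return The input with an added `rel_abundance` column in \[0, 1\];
#'   per-sample values sum to 1 whenever at least one genome is detected.
#' @examples
#' s <- data.frame(
#'   sample_id = "s1", genome_id = c("A", "B", "C"),
#'   q2q3_mean_depth = c(6, 2, 10), breadth = c(0.9, 0.8, 0.2),
#'   detected = c(TRUE, TRUE, FALSE)
#' )
#' relative_abundance(s)$rel_abundance # 0.75 0.25 0
#' @export
relative_abundance <- function(summaries) {
  summaries <- check_summary(summaries)
  zeroed <- ifelse(summaries$detected, summaries$q2q3_mean_depth, 0)
  totals <- tapply(zeroed, summaries$sample_id, sum)
  denom <- as.numeric(totals[summaries$sample_id])
  summaries$rel_abundance <- ifelse(denom > 0, zeroed / denom, 0)
  summaries
}

#' Clade-level abundance series
#'
#' Sums the Q2Q3 mean depth over the member genomes of each species clade,
#' per sample. By default raw depths are summed without detection zeroing
#' (the classifier-facing metric); `zero_undetected = TRUE` zeroes
#' undetected genomes first, which is the convention used for
#' relative-abundance heatmaps.
#'
#' @inheritParams relative_abundance
#' @param clades Clade map data.frame with columns `genome_id`, `clade_id`;
#'   every genome in `summaries` must be assigned.
#' @param zero_undetected Zero undetected genomes before summing?
#'   Default `FALSE`.
#' @return data.frame with columns `clade_id`, `sample_id`, `abundance`.
#' @export
clade_abundance <- function(summaries, clades, zero_undetected = FALSE) {
  summaries <- check_summary(summaries)
  clades <- check_clade_map(summaries, clades)
  depth <- summaries$q2q3_mean_depth
  if (zero_undetected) {
    depth <- ifelse(summaries$detected, depth, 0)
  }
  clade_of <- clades$clade_id[match(summaries$genome_id, clades$genome_id)]
  agg <- stats::aggregate(
    list(abundance = depth),
    by = list(clade_id = clade_of, sample_id = summaries$sample_id),
    FUN = sum
  )
  agg <- agg[order(agg$clade_id, agg$sample_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Clade-level detection series
#'
#' A clade is detected in a sample when the maximum breadth of coverage
#' among its member genomes reaches the threshold. Using the clade maximum
#' makes detection monotone in clade membership: adding a genome can only
#' add detections.
#'
#' @inheritParams clade_abundance
#' @param threshold Breadth detection threshold; default 0.5.
#' @return data.frame with columns `clade_id`, `sample_id`, `max_breadth`,
#'   `detected`.
#' @export
clade_detection <- function(summaries, clades, threshold = 0.5) {
  summaries <- check_summary(summaries)
  clades <- check_clade_map(summaries, clades)
  clade_of <- clades$clade_id[match(summaries$genome_id, clades$genome_id)]
  agg <- stats::aggregate(
    list(max_breadth = summaries$breadth),
    by = list(clade_id = clade_of, sample_id = summaries$sample_id),
    FUN = max
  )
  agg$detected <- detect_genome(agg$max_breadth, threshold)
  agg <- agg[order(agg$clade_id, agg$sample_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Species-level relative abundance
#'
#' Sums genome relative abundances over the member genomes of each clade,
#' so that per-sample totals are conserved exactly: the clade-level values
#' of a sample sum to the same total as its genome-level values.
#'
#' @param abundances Output of [relative_abundance()] (must contain
#'   `rel_abundance`).
#' @inheritParams clade_abundance
#' @return data.frame with columns `clade_id`, `sample_id`,
#'   `rel_abundance`.
#' @export
species_relative_abundance <- function(abundances, clades) {
  check_columns(
    abundances, c("sample_id", "genome_id", "rel_abundance"),
    "abundance table"
  )
  clades <- check_clade_map(abundances, clades)
  clade_of <- clades$clade_id[match(abundances$genome_id, clades$genome_id)]
  agg <- stats::aggregate(
    list(rel_abundance = abundances$rel_abundance),
    by = list(clade_id = clade_of, sample_id = abundances$sample_id),
    FUN = sum
  )
  agg <- agg[order(agg$clade_id, agg$sample_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
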