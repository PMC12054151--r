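#' Construct a per-base depth profile
#'
#' A depth profile records, for one genome in one metagenomic sample, the
#' number of recruited reads covering each nucleotide position. It is the
#' raw input from which breadth of coverage and the Q2Q3 interquartile mean
#' depth are computed.
#'
#' @param genome_id Genome identifier (single string).
#' @param sample_id Sample identifier (single string).
#' @param depths Integer-valued vector of non-negative per-position depths;
#'   its length is the genome length in bp.
#' @return An object of class `depth_profile`.
#' @examples
#' p <- depth_profile("g1", "s1", c(0, 1, 0, 2))
#' breadth_of_coverage(p)
#' @export
depth_profile <- function(genome_id, sample_id, depths) {
  if (length(genome_id) != 1L || length(sample_id) != 1L) {
    stop_input("genome_id and sample_id must be single strings")
  }
  depths <- as.numeric(depths)
  if (length(depths) < 1L) {
    stop_input("depth profile must contain at least one position")
  }
  if (anyNA(depths) || any(depths < 0) || any(depths != floor(depths))) {
    stop_input("depths must be non-negative integers")
  }
  structure(
    list(
      genome_id = as.character(genome_id),
      sample_id = as.character(sample_id),
      depths = depths
    ),
    class = "depth_profile"
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf(
    "<depth_profile> genome %s, sample %s: %d bp, breadth %.3f, Q2Q3 depth %.2f\n",
    x$genome_id, x$sample_id, length(x$depths),
    breadth_of_coverage(x), q2q3_mean_depth(x)
  ))
  invisible(x)
}

as_depths <- function(profile) {
  if (inherits(profile, "depth_profile")) {
    return(profile$depths)
  }
  d <- as.numeric(profile)
  if (length(d) < 1L) {
    stop_input("depth profile must contain at least one position")
  }
  if (anyNA(d) || any(d < 0)) {
    stop_input("depths must be non-negative")
  }
  d
}

#' Breadth of coverage
#'
#' Fraction of nucleotide positions covered by at least one mapped read.
#'
#' @param profile A [depth_profile()] or a bare numeric depth vector.
#' @return Fraction in \[0, 1\].
#' @examples
#' breadth_of_coverage(c(0, 1, 0, 2)) # 0.5
#' @export
breadth_of_coverage <- function(profile) {
  d <- as_depths(profile)
  mean(d >= 1)
}

#' Interquartile (Q2Q3) mean depth of coverage
#'
#' Ranks positions by depth, discards the lowest and highest quartiles
#' (`floor(L/4)` positions from each tail), and returns the arithmetic mean
#' of the retained middle slice. This midmean is robust to localized
#' coverage spikes caused by mobile elements or conserved regions
#' cross-recruiting reads from related taxa, and to partial genome dropout.
#'
#' The retained slice runs from rank `floor(L/4) + 1` through
#' `L - floor(L/4)` and is non-empty for every length L >= 1.
#'
#' @inheritParams breadth_of_coverage
#' @return Mean depth over the interquartile slice (x-coverage, >= 0).
#' @examples
#' q2q3_mean_depth(1:8)                         # mean of 3,4,5,6 = 4.5
#' q2q3_mean_depth(c(1:6, 1000, 2000))          # outliers trimmed: still 4.5
#' @export
q2q3_mean_depth <- function(profile) {
  d <- as_depths(profile)
  L <- length(d)
  t <- L %/% 4L
  s <- sort(d)
  mean(s[(t + 1L):(L - t)])
}

#' Genome detection from breadth of coverage
#'
#' A genome counts as detected in a sample when its breadth of coverage
#' reaches the threshold (inclusive). The default 50% threshold focuses on
#' well-represented populations while excluding spurious low-breadth
#' recruitment.
#'
#' @param breadth Breadth of coverage in \[0, 1\] (vectorized).
#' @param threshold Detection threshold in (0, 1\]; default 0.5.
#' @return Logical vector.
#' @examples
#' detect_genome(c(0.499, 0.5, 1)) # FALSE TRUE TRUE
#' @export
detect_genome <- function(breadth, threshold = 0.5) {
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold > 1) {
    stop_input("threshold must be a single value in (0, 1]")
  }
  breadth <- as.numeric(breadth)
  if (anyNA(breadth) || any(breadth < 0) || any(breadth > 1)) {
    stop_input("breadth values must lie in [0, 1]")
  }
  breadth >= threshold
}

#' Gene-level detection
#'
#' A gene is detected in a sample when at least `cov_fraction` of its
#' nucleotides have depth of at least `min_depth` (default: 90% of
#' positions at >= 1x). Coordinates are 1-based and inclusive on the
#' genome's own coordinate system; strand is irrelevant to coverage.
#'
#' @inheritParams breadth_of_coverage
#' @param start,end 1-based inclusive gene coordinates on the genome.
#' @param cov_fraction Required covered fraction of the gene; default 0.9.
#' @param min_depth Minimum per-position depth to count as covered;
#'   default 1.
#' @return Logical scalar.
#' @export
gene_detected <- function(profile, start, end, cov_fraction = 0.9,
                          min_depth = 1L) {
  d <- as_depths(profile)
  if (length(start) != 1L || length(end) != 1L ||
      start < 1 || end > length(d) || start > end) {
    stop_input(
      "gene interval [%s, %s] is outside genome bounds [1, %d]",
      format(start), format(end), length(d)
    )
  }
  seg <- d[start:end]
  mean(seg >= min_depth) >= cov_fraction
}

#' Summarize depth profiles into a coverage table
#'
#' Computes, for every (genome, sample) profile, the Q2Q3 interquartile mean
#' depth, the breadth of coverage, and the detection flag. The resulting
#' table is the central exchange format of the pipeline: abundance,
#' detection and habitat classification all consume it.
#'
#' @param profiles A list of [depth_profile()] objects with unique
#'   (genome, sample) pairs.
#' @param threshold Breadth threshold passed to [detect_genome()].
#' @return A data.frame with columns `sample_id`, `genome_id`,
#'   `q2q3_mean_depth`, `breadth`, `detected`.
#' @export
summarize_profiles <- function(profiles, threshold = 0.5) {
  if (length(profiles) == 0L) {
    return(data.frame(
      sample_id = character(), genome_id = character(),
      q2q3_mean_depth = numeric(), breadth = numeric(),
      detected = logical(), stringsAsFactors = FALSE
    ))
  }
  if (!all(vapply(profiles, inherits, logical(1), "depth_profile"))) {
    stop_input("profiles must be a list of depth_profile objects")
  }
  out <- data.frame(
    sample_id = vapply(profiles, `[[`, character(1), "sample_id"),
    genome_id = vapply(profiles, `[[`, character(1), "genome_id"),
    q2q3_mean_depth = vapply(profiles, q2q3_mean_depth, numeric(1)),
    breadth = vapply(profiles, breadth_of_coverage, numeric(1)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out[c("sample_id", "genome_id")]) > 0L) {
    stop_input("duplicate (genome, sample) pair among profiles")
  }
  out$detected <- detect_genome(out$breadth, threshold)
  rownames(out) <- NULL
  out
}
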