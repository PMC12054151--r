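# Habitat-preference classification by exhaustive bipartition of sampling
# sites. Every unordered two-group split of the site universe is scored with
# a two-sample statistic (Student's t on clade abundance, or the Rao score
# statistic on clade detection); the split with the largest absolute
# statistic defines the clade's habitat preference.

#' Enumerate unordered bipartitions of sampling sites
#'
#' Lists every way of splitting the site universe into two non-empty
#' groups. Bipartitions are unordered (a split and its mirror are the same
#' map), giving `2^(k-1) - 1` maps for k sites; for the default eight-site
#' classifier universe that is 127 maps. Enumeration order is
#' deterministic: sites are sorted and subsets are generated in binary
#' counting order over the sites after the first, with the first site
#' anchored in `group1`.
#'
#' @param sites Character vector of 2 to 20 distinct site codes.
#' @return A list of habitat maps, each a list with character vectors
#'   `group1` and `group2`.
#' @examples
#' length(enumerate_bipartitions(classifier_sites())) # 127
#' enumerate_bipartitions(c("a", "b", "c"))
#' @export
enumerate_bipartitions <- function(sites) {
  sites <- sort(unique(as.character(sites)))
  k <- length(sites)
  if (k < 2L || k > 20L) {
    stop_input("need between 2 and 20 distinct sites, got %d", k)
  }
  anchor <- sites[1L]
  rest <- sites[-1L]
  n_rest <- k - 1L
  maps <- vector("list", 2^n_rest - 1L)
  idx <- 0L
  # mask over `rest`: which of the remaining sites join the anchor's group.
  # mask == 2^n_rest - 1 would leave group2 empty and is excluded.
  for (mask in 0:(2^n_rest - 2L)) {
    take <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(n_rest) - 1L)))
    idx <- idx + 1L
    maps[[idx]] <- list(
      group1 = c(anchor, rest[take]),
      group2 = rest[!take]
    )
  }
  maps
}

group_values <- function(values, sample_sites, map) {
  list(
    g1 = values[sample_sites %in% map$group1],
    g2 = values[sample_sites %in% map$group2]
  )
}

#' Pooled-variance Student t statistic for one habitat map
#'
#' Two-sample Student t statistic (pooled variance, not Welch) comparing
#' per-sample clade abundance between the two site groups of a habitat map.
#' The sign is positive when the `group1` mean exceeds the `group2` mean.
#' When the pooled variance is zero the statistic is 0 for equal means and
#' signed infinity otherwise (a degenerate, perfectly separated map).
#'
#' @param values Numeric per-sample clade abundances.
#' @param sample_sites Character vector of the site code of each sample
#'   (parallel to `values`).
#' @param map A habitat map from [enumerate_bipartitions()].
#' @return The t statistic, or `NA` when either group has no samples or
#'   the combined degrees of freedom n1 + n2 - 2 are below 1 (such maps
#'   are skipped by the classifier, not scored as 0).
#' @examples
#' vals <- c(1, 2, 3, 4, 5, 6)
#' sites <- c("a", "a", "a", "b", "b", "b")
#' t_statistic_for_map(vals, sites, list(group1 = "a", group2 = "b"))
#' @export
t_statistic_for_map <- function(values, sample_sites, map) {
  g <- group_values(values, sample_sites, map)
  n1 <- length(g$g1)
  n2 <- length(g$g2)
  if (n1 == 0L || n2 == 0L || n1 + n2 - 2L < 1L) {
    return(NA_real_)
  }
  diff <- mean(g$g1) - mean(g$g2)
  ss <- sum((g$g1 - mean(g$g1))^2) + sum((g$g2 - mean(g$g2))^2)
  sp2 <- ss / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (diff == 0) {
      return(0)
    }
    return(sign(diff) * Inf)
  }
  diff / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Rao score statistic for one habitat map
#'
#' Score (Lagrange multiplier) statistic for the group term in a
#' binomial-logit model of per-sample clade detection on group membership.
#' For this single binary covariate the score statistic equals the Pearson
#' chi-square of the 2x2 group-by-detection table,
#' `N (ad - bc)^2 / (n1 n2 m1 m0)`, where a,b,c,d are the cell counts,
#' n1, n2 the group sizes and m1, m0 the detected/undetected margins.
#' Degenerate margins (all samples detected, or none) give 0: detection
#' carries no group information there.
#'
#' @param detections Logical per-sample clade detection flags.
#' @inheritParams t_statistic_for_map
#' @return The score statistic (>= 0), or `NA` when either group is empty.
#' @examples
#' det <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8))
#' sites <- rep(c("a", "b"), each = 10)
#' rao_statistic_for_map(det, sites, list(group1 = "a", group2 = "b")) # 7.2
#' @export
rao_statistic_for_map <- function(detections, sample_sites, map) {
  g <- group_values(as.logical(detections), sample_sites, map)
  n1 <- length(g$g1)
  n2 <- length(g$g2)
  if (n1 == 0L || n2 == 0L) {
    return(NA_real_)
  }
  a <- sum(g$g1)
  b <- n1 - a
  c_ <- sum(g$g2)
  d <- n2 - c_
  m1 <- a + c_
  m0 <- b + d
  if (m1 == 0L || m0 == 0L) {
    return(0)
  }
  n <- n1 + n2
  n * (a * d - b * c_)^2 / (n1 * n2 * m1 * m0)
}

#' Classify the habitat preference of one clade
#'
#' Evaluates every unordered bipartition of the site universe with the
#' chosen statistic and selects the map with the largest absolute value.
#' The preferred sites are the side of the winning map with the higher
#' central tendency: the higher mean abundance (abundance metric) or the
#' higher detection proportion (prevalence metric).
#'
#' Maps that leave a group without samples (or, for the t statistic,
#' without enough degrees of freedom) are skipped rather than scored 0.
#' Exact ties in the absolute statistic are broken deterministically in
#' favour of parsimony: fewer preferred sites first, then lexicographic
#' order of the joined preferred-site string.
#'
#' @param values Per-sample clade abundance (abundance metric) or logical
#'   detection flags (prevalence metric).
#' @param sample_sites Site code per sample, parallel to `values`; codes
#'   outside `sites` are dropped before classification.
#' @param metric `"abundance"` (Student t on values) or `"prevalence"`
#'   (Rao score statistic on detection flags).
#' @param sites Site universe to bipartition; default the eight classifier
#'   sites (hard palate excluded).
#' @param min_stat Maps are only assigned when the winning absolute
#'   statistic exceeds this threshold; below it the clade is reported as
#'   having no preference. Default 0 (a map is always assigned, as every
#'   clade is classified in practice).
#' @return A list with `metric`, `best_map`, `statistic`,
#'   `preferred_sites` and `no_preference`.
#' @export
classify_clade <- function(values, sample_sites,
                           metric = c("abundance", "prevalence"),
                           sites = classifier_sites(), min_stat = 0) {
  metric <- match.arg(metric)
  sample_sites <- as.character(sample_sites)
  if (length(values) != length(sample_sites)) {
    stop_input("values and sample_sites must have equal length")
  }
  keep <- sample_sites %in% sites
  values <- values[keep]
  sample_sites <- sample_sites[keep]
  if (length(unique(sample_sites)) < 2L) {
    stop_input("need samples from at least 2 sites to classify")
  }
  maps <- enumerate_bipartitions(sites)
  stat_fun <- if (metric == "abundance") {
    t_statistic_for_map
  } else {
    rao_statistic_for_map
  }
  stats <- vapply(
    maps, function(m) stat_fun(values, sample_sites, m), numeric(1)
  )
  if (all(is.na(stats))) {
    stop_input("no habitat map is scorable for this clade")
  }

  tendency <- function(map) {
    g <- group_values(values, sample_sites, map)
    if (metric == "abundance") {
      c(mean(g$g1), mean(g$g2))
    } else {
      c(mean(as.logical(g$g1)), mean(as.logical(g$g2)))
    }
  }
  preferred_of <- function(map) {
    mu <- tendency(map)
    if (mu[1] >= mu[2]) map$group1 else map$group2
  }

  best_abs <- max(abs(stats), na.rm = TRUE)
  cand <- which(!is.na(stats) & abs(stats) == best_abs)
  if (length(cand) > 1L) {
    prefs <- lapply(maps[cand], preferred_of)
    ord <- order(
      lengths(prefs),
      vapply(prefs, paste, character(1), collapse = ","),
      cand
    )
    cand <- cand[ord[1L]]
  }
  best <- maps[[cand]]
  pref <- preferred_of(best)
  no_pref <- best_abs <= min_stat && min_stat > 0
  list(
    metric = metric,
    best_map = best,
    statistic = stats[[cand]],
    preferred_sites = sort(pref),
    no_preference = no_pref
  )
}

#' Classify habitat preferences for all clades in a coverage summary
#'
#' Pipeline-level wrapper: derives per-clade abundance series (summed Q2Q3
#' depth) and detection series (maximum member breadth against the
#' threshold) from a coverage summary, then runs [classify_clade()] for
#' every clade under one or both metrics.
#'
#' @inheritParams clade_abundance
#' @param site_map data.frame with columns `sample_id`, `site`; every
#'   sample in `summaries` must be mapped and codes must come from
#'   [oral_sites()].
#' @param metric `"abundance"`, `"prevalence"` or `"both"` (default).
#' @param sites Site universe for the bipartitions.
#' @param threshold Breadth threshold for the detection series.
#' @param zero_undetected Zero undetected genomes before summing the
#'   abundance series? Default `FALSE`.
#' @param min_stat Passed to [classify_clade()].
#' @return data.frame with one row per (clade, metric): `clade_id`,
#'   `metric`, `group1`, `group2` (comma-joined), `statistic`,
#'   `preferred_sites` (comma-joined), `no_preference`.
#' @export
classify_habitats <- function(summaries, clades, site_map,
                              metric = c("both", "abundance", "prevalence"),
                              sites = classifier_sites(), threshold = 0.5,
                              zero_undetected = FALSE, min_stat = 0) {
  metric <- match.arg(metric)
  metrics <- if (metric == "both") c("abundance", "prevalence") else metric
  check_columns(site_map, c("sample_id", "site"), "site map")
  bad <- setdiff(unique(site_map$site), oral_sites())
  if (length(bad) > 0) {
    stop_input(
      "unknown site code(s): %s (expected one of %s)",
      paste(bad, collapse = ", "), paste(oral_sites(), collapse = ", ")
    )
  }
  unmapped <- setdiff(unique(summaries$sample_id), site_map$sample_id)
  if (length(unmapped) > 0) {
    stop_input(
      "sample(s) without site assignment: %s",
      paste(unmapped, collapse = ", ")
    )
  }

  ab <- clade_abundance(summaries, clades, zero_undetected = zero_undetected)
  det <- clade_detection(summaries, clades, threshold = threshold)
  site_of <- function(samples) {
    site_map$site[match(samples, site_map$sample_id)]
  }

  rows <- list()
  for (clade in sort(unique(ab$clade_id))) {
    for (m in metrics) {
      if (m == "abundance") {
        sub <- ab[ab$clade_id == clade, ]
        vals <- sub$abundance
      } else {
        sub <- det[det$clade_id == clade, ]
        vals <- sub$detected
      }
      res <- classify_clade(
        vals, site_of(sub$sample_id),
        metric = m, sites = sites, min_stat = min_stat
      )
      rows[[length(rows) + 1L]] <- data.frame(
        clade_id = clade,
        metric = m,
        group1 = paste(res$best_map$group1, collapse = ","),
        group2 = paste(res$best_map$group2, collapse = ","),
        statistic = res$statistic,
        preferred_sites = paste(res$preferred_sites, collapse = ","),
        no_preference = res$no_preference,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
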