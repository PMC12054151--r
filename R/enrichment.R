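# KEGG-style module completeness and habitat-group functional enrichment.

#' Define a metabolic module as a flattened step list
#'
#' A module is an ordered list of enzymatic steps; each step is a set of
#' alternative function accessions (orthologs), any one of which satisfies
#' the step. The full nested boolean grammar of module definitions is out
#' of scope: modules are supplied pre-flattened.
#'
#' @param module_id Module identifier.
#' @param steps List of non-empty character vectors of alternative
#'   accessions, one per step.
#' @return An object of class `module_definition`.
#' @examples
#' m <- module_definition("M1", list(c("K1", "K2"), "K3", "K4", "K5"))
#' module_completeness(c("K2", "K3", "K4"), m) # 0.75
#' @export
module_definition <- function(module_id, steps) {
  if (!is.list(steps) || length(steps) < 1L) {
    stop_input("a module needs at least one step")
  }
  steps <- lapply(steps, as.character)
  if (any(lengths(steps) == 0L)) {
    stop_input("every module step needs at least one alternative accession")
  }
  structure(
    list(module_id = as.character(module_id), steps = steps),
    class = "module_definition"
  )
}

#' Module completeness of a genome
#'
#' Fraction of a module's steps for which the genome carries at least one
#' alternative accession. A module counts as "complete" in a genome when
#' the fraction reaches the completion threshold (default 0.75, i.e. at
#' least 75% of the enzymatic steps present), boundary inclusive.
#'
#' @param accessions Character vector of function accessions annotated in
#'   the genome.
#' @param module A [module_definition()].
#' @return Completeness fraction in \[0, 1\].
#' @export
module_completeness <- function(accessions, module) {
  if (!inherits(module, "module_definition")) {
    stop_input("module must be a module_definition")
  }
  accessions <- as.character(accessions)
  satisfied <- vapply(
    module$steps, function(alts) any(alts %in% accessions), logical(1)
  )
  mean(satisfied)
}

#' Module completeness matrix for a genome collection
#'
#' @param function_table Long-format data.frame with columns `genome_id`,
#'   `accession`, `count`; presence is `count >= 1`.
#' @param modules List of [module_definition()] objects.
#' @param completion_threshold Completeness needed to flag a module
#'   complete; default 0.75 (inclusive).
#' @return data.frame with columns `genome_id`, `module_id`,
#'   `completeness`, `complete`.
#' @export
module_completeness_table <- function(function_table, modules,
                                      completion_threshold = 0.75) {
  check_columns(
    function_table, c("genome_id", "accession", "count"), "function table"
  )
  present <- function_table[function_table$count >= 1, ]
  genomes <- sort(unique(function_table$genome_id))
  acc_by_genome <- split(present$accession, factor(present$genome_id, genomes))
  rows <- lapply(modules, function(m) {
    comp <- vapply(
      genomes, function(g) module_completeness(acc_by_genome[[g]], m),
      numeric(1)
    )
    data.frame(
      genome_id = genomes, module_id = m$module_id, completeness = comp,
      complete = comp >= completion_threshold, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enrichment test for one function across habitat-preference groups
#'
#' Scores the association between the presence of one function (or the
#' completeness flag of one module) and the habitat-preference group of
#' the genomes. The enrichment score is the Rao score statistic for the
#' group factor in a binomial-logit model of presence on group; it equals
#' the Pearson chi-square of the groups-by-presence contingency table and
#' is referred to a chi-square distribution with (#groups - 1) degrees of
#' freedom. The associated groups are those whose presence proportion
#' exceeds the pooled proportion.
#'
#' @param presence Logical presence flags, one per genome.
#' @param groups Group label per genome (parallel to `presence`); at least
#'   2 groups, each with at least one genome.
#' @return A list with `score`, `p_value`, `associated_groups` and
#'   `proportions` (named per-group presence proportions).
#' @examples
#' enrichment_test(rep(c(TRUE, FALSE), each = 5),
#'                 rep(c("A", "B"), each = 5))
#' @export
enrichment_test <- function(presence, groups) {
  presence <- as.logical(presence)
  groups <- as.character(groups)
  if (length(presence) != length(groups)) {
    stop_input("presence and groups must have equal length")
  }
  if (anyNA(presence) || anyNA(groups)) {
    stop_input("presence and groups must not contain NA")
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2L) {
    stop_input("enrichment needs at least 2 groups")
  }
  n_g <- vapply(lev, function(l) sum(groups == l), numeric(1))
  x_g <- vapply(lev, function(l) sum(presence[groups == l]), numeric(1))
  p_pool <- sum(x_g) / sum(n_g)
  df <- length(lev) - 1L
  if (p_pool == 0 || p_pool == 1) {
    score <- 0
  } else {
    # Pearson chi-square of the groups x presence table: the score test of
    # the saturated group factor against the intercept-only logit model.
    e1 <- n_g * p_pool
    e0 <- n_g * (1 - p_pool)
    score <- sum((x_g - e1)^2 / e1 + ((n_g - x_g) - e0)^2 / e0)
  }
  p <- if (score == 0) 1 else stats::pchisq(score, df, lower.tail = FALSE)
  props <- x_g / n_g
  names(props) <- lev
  list(
    score = score,
    p_value = p,
    associated_groups = lev[props > p_pool],
    proportions = props
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values.
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @return q-values in \[0, 1\], monotone in p-rank.
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Habitat-group enrichment over a function table
#'
#' Binarizes per-genome occurrence counts (presence = count >= 1), runs
#' [enrichment_test()] for every function, and adjusts p-values with
#' Benjamini-Hochberg. The full result table is always returned;
#' significance is flagged at a strict `q < q_threshold` (default 0.01).
#' Module-completeness flags can be tested the same way by passing the
#' output of [module_completeness_table()] through `complete` as counts.
#'
#' @inheritParams module_completeness_table
#' @param groups data.frame with columns `genome_id`, `group`; every genome
#'   in the table must be labeled.
#' @param q_threshold Strict significance cutoff on the q-value;
#'   default 0.01.
#' @return data.frame with columns `accession`, `score`, `p_value`,
#'   `q_value`, `significant`, `associated_groups` (comma-joined) and one
#'   `prop_<group>` column per group.
#' @export
enrich_by_habitat <- function(function_table, groups, q_threshold = 0.01) {
  check_columns(
    function_table, c("genome_id", "accession", "count"), "function table"
  )
  check_columns(groups, c("genome_id", "group"), "group table")
  genomes <- sort(unique(groups$genome_id))
  unknown <- setdiff(unique(function_table$genome_id), genomes)
  if (length(unknown) > 0) {
    stop_input(
      "genome(s) without group label: %s", paste(unknown, collapse = ", ")
    )
  }
  group_of <- groups$group[match(genomes, groups$genome_id)]
  accs <- sort(unique(function_table$accession))
  if (length(accs) == 0L) {
    return(data.frame(
      accession = character(), score = numeric(), p_value = numeric(),
      q_value = numeric(), significant = logical(),
      associated_groups = character(), stringsAsFactors = FALSE
    ))
  }
  present <- function_table[function_table$count >= 1, ]
  pres_mat <- matrix(
    FALSE, nrow = length(accs), ncol = length(genomes),
    dimnames = list(accs, genomes)
  )
  if (nrow(present) > 0) {
    pres_mat[cbind(present$accession, present$genome_id)] <- TRUE
  }
  res <- lapply(accs, function(a) enrichment_test(pres_mat[a, ], group_of))
  out <- data.frame(
    accession = accs,
    score = vapply(res, `[[`, numeric(1), "score"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < q_threshold
  out$associated_groups <- vapply(
    res, function(r) paste(r$associated_groups, collapse = ","), character(1)
  )
  props <- do.call(rbind, lapply(res, `[[`, "proportions"))
  colnames(props) <- paste0("prop_", colnames(props))
  out <- cbind(out, as.data.frame(props))
  rownames(out) <- NULL
  out
}
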