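# Site-structured coverage simulator with known ground truth. Emulates the
# shape of read-recruitment depth data — per-site mean depths, partial
# genome dropout, and high-coverage outlier positions such as mobile
# elements — without simulating reads themselves.

#' Simulate a per-base depth profile
#'
#' Draws a depth vector for one genome in one sample. Baseline counts come
#' from a Poisson distribution with the given mean (`overdispersion = 0`)
#' or a negative binomial with variance `mean + overdispersion * mean^2`.
#' A `dropout` fraction of positions, chosen uniformly at random, is forced
#' to exactly 0 (uncovered genome regions); an `outlier_fraction` of the
#' remaining positions is drawn around `mean_depth * outlier_multiplier`
#' instead, mimicking mobile-element coverage spikes.
#'
#' Counts are generated by inversion (quantile transform of a fixed
#' uniform stream), so for a fixed seed the profile is bit-identical
#' across calls, and raising `mean_depth` can never lower any position's
#' depth — realized Q2Q3 mean depth is exactly monotone in `mean_depth`.
#'
#' @param length Genome length in bp (>= 1).
#' @param mean_depth Mean depth (reads/nt) of non-dropout baseline
#'   positions; >= 0.
#' @param dropout Fraction of positions forced to depth 0, in \[0, 1\].
#' @param outlier_fraction Fraction of non-dropout positions receiving
#'   outlier depth, in \[0, 0.25\].
#' @param outlier_multiplier Outlier mean is `mean_depth` times this;
#'   >= 1.
#' @param overdispersion Negative-binomial overdispersion; 0 gives
#'   Poisson counts.
#' @param seed Integer seed.
#' @param genome_id,sample_id Identifiers stamped on the returned profile.
#' @return A [depth_profile()].
#' @examples
#' p <- simulate_depth_profile(1000, mean_depth = 10, dropout = 0.6,
#'                             seed = 1)
#' breadth_of_coverage(p) # <= 0.4
#' @export
simulate_depth_profile <- function(length, mean_depth, dropout = 0,
                                   outlier_fraction = 0,
                                   outlier_multiplier = 1,
                                   overdispersion = 0, seed = 1L,
                                   genome_id = "genome",
                                   sample_id = "sample") {
  if (length < 1) stop_input("length must be >= 1")
  if (mean_depth < 0) stop_input("mean_depth must be >= 0")
  if (dropout < 0 || dropout > 1) stop_input("dropout must lie in [0, 1]")
  if (outlier_fraction < 0 || outlier_fraction > 0.25) {
    stop_input("outlier_fraction must lie in [0, 0.25]")
  }
  if (outlier_multiplier < 1) stop_input("outlier_multiplier must be >= 1")
  if (overdispersion < 0) stop_input("overdispersion must be >= 0")
  length <- as.integer(length)

  depths <- with_seed(seed, {
    u <- stats::runif(length)
    # position roles are drawn before any depth so that they depend only on
    # (seed, length, dropout, outlier_fraction) — changing mean_depth
    # re-uses the identical uniform stream and masks.
    n_drop <- round(dropout * length)
    drop_idx <- if (n_drop > 0) sample.int(length, n_drop) else integer(0)
    rest <- setdiff(seq_len(length), drop_idx)
    n_out <- round(outlier_fraction * length(rest))
    out_idx <- if (n_out > 0) rest[sample.int(length(rest), n_out)] else integer(0)

    qcount <- function(uu, mu) {
      if (mu == 0) {
        return(rep(0, length(uu)))
      }
      if (overdispersion == 0) {
        stats::qpois(uu, lambda = mu)
      } else {
        stats::qnbinom(uu, mu = mu, size = 1 / overdispersion)
      }
    }
    d <- qcount(u, mean_depth)
    if (length(out_idx) > 0) {
      d[out_idx] <- qcount(u[out_idx], mean_depth * outlier_multiplier)
    }
    d[drop_idx] <- 0
    d
  })
  depth_profile(genome_id, sample_id, depths)
}

#' Build a simulation configuration
#'
#' Bundles and validates the design of a simulated multi-site survey:
#' which sites are sampled and how often, which genomes belong to which
#' clade, and the clade-by-site mean depth and dropout structure that
#' encodes habitat preference.
#'
#' @param sites Character vector of site codes (see [oral_sites()]).
#' @param samples_per_site Named integer vector (names = sites) of sample
#'   counts per site, or a single count recycled to all sites.
#' @param genomes data.frame with columns `genome_id`, `clade_id`,
#'   `length` (bp >= 1).
#' @param preference Numeric matrix of mean depths, rows = clades,
#'   columns = sites (dimnames required).
#' @param dropout Matrix like `preference` of per-(clade, site) dropout
#'   fractions, or a single fraction recycled; default 0.
#' @param outlier_fraction,outlier_multiplier,overdispersion Scalar noise
#'   parameters shared by all profiles (see
#'   [simulate_depth_profile()]).
#' @param enriched_functions Optional data.frame for
#'   [simulate_function_table()] with columns `function_id`, `group`,
#'   `presence_prob_in`, `presence_prob_out`.
#' @param seed Integer global seed; per-(genome, sample) substreams are
#'   derived from it by hashing identifiers, so adding a sample never
#'   perturbs existing profiles.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(sites, samples_per_site, genomes, preference,
                              dropout = 0, outlier_fraction = 0,
                              outlier_multiplier = 1, overdispersion = 0,
                              enriched_functions = NULL, seed = 1L) {
  sites <- as.character(sites)
  if (length(sites) == 0L) stop_input("need at least one site")
  if (anyDuplicated(sites) > 0L) stop_input("duplicate site codes")
  if (length(samples_per_site) == 1L && is.null(names(samples_per_site))) {
    samples_per_site <- stats::setNames(
      rep(as.integer(samples_per_site), length(sites)), sites
    )
  }
  if (!all(sites %in% names(samples_per_site))) {
    stop_input("samples_per_site must name every site")
  }
  samples_per_site <- samples_per_site[sites]
  if (any(samples_per_site < 0)) stop_input("sample counts must be >= 0")

  check_columns(genomes, c("genome_id", "clade_id", "length"), "genome table")
  if (nrow(genomes) == 0L) stop_input("need at least one genome")
  if (any(genomes$length < 1)) stop_input("genome lengths must be >= 1")
  clades <- sort(unique(genomes$clade_id))

  preference <- as.matrix(preference)
  if (!all(clades %in% rownames(preference)) ||
      !all(sites %in% colnames(preference))) {
    stop_input("preference matrix must cover every clade (rows) and site (columns)")
  }
  if (any(preference < 0)) stop_input("mean depths must be >= 0")

  if (is.matrix(dropout)) {
    if (!all(clades %in% rownames(dropout)) ||
        !all(sites %in% colnames(dropout))) {
      stop_input("dropout matrix must cover every clade and site")
    }
  } else {
    dropout <- matrix(
      dropout, nrow = length(clades), ncol = length(sites),
      dimnames = list(clades, sites)
    )
  }
  if (any(dropout < 0 | dropout > 1)) {
    stop_input("dropout fractions must lie in [0, 1]")
  }

  structure(
    list(
      sites = sites, samples_per_site = samples_per_site, genomes = genomes,
      preference = preference, dropout = dropout,
      outlier_fraction = outlier_fraction,
      outlier_multiplier = outlier_multiplier,
      overdispersion = overdispersion,
      enriched_functions = enriched_functions,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# Ground-truth preferred sites of one clade: the sites whose programmed
# mean depth lies above the midpoint of the clade's depth range. A clade
# with a flat depth profile has no preference (empty set).
truth_sites <- function(pref_row) {
  rng <- range(pref_row)
  if (diff(rng) == 0) {
    return(character(0))
  }
  sort(names(pref_row)[pref_row > mean(rng)])
}

#' Simulate a multi-site community survey
#'
#' Generates one depth profile per (genome, sample) under the
#' configuration's clade-by-site preference structure, summarizes them
#' into a coverage table, and returns the ground truth of which sites
#' each clade was simulated to prefer.
#'
#' @param config A [simulation_config()].
#' @return A list with `summary` (coverage summary data.frame),
#'   `profiles` (list of [depth_profile()]), `site_map`, `clade_map`
#'   (data.frames), and `truth` (data.frame `clade_id`,
#'   `preferred_sites` comma-joined, empty string = no preference).
#' @export
simulate_community <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_input("config must be a simulation_config")
  }
  site_map <- do.call(rbind, lapply(config$sites, function(s) {
    n <- config$samples_per_site[[s]]
    if (n == 0L) {
      return(NULL)
    }
    data.frame(
      sample_id = sprintf("%s_%02d", s, seq_len(n)), site = s,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(site_map) || nrow(site_map) == 0L) {
    stop_input("configuration yields no samples")
  }
  genomes <- config$genomes
  profiles <- vector("list", nrow(site_map) * nrow(genomes))
  idx <- 0L
  for (i in seq_len(nrow(site_map))) {
    s <- site_map$site[i]
    sample_id <- site_map$sample_id[i]
    for (j in seq_len(nrow(genomes))) {
      clade <- genomes$clade_id[j]
      idx <- idx + 1L
      profiles[[idx]] <- simulate_depth_profile(
        length = genomes$length[j],
        mean_depth = config$preference[clade, s],
        dropout = config$dropout[clade, s],
        outlier_fraction = config$outlier_fraction,
        outlier_multiplier = config$outlier_multiplier,
        overdispersion = config$overdispersion,
        seed = substream_seed(config$seed, genomes$genome_id[j], sample_id),
        genome_id = genomes$genome_id[j],
        sample_id = sample_id
      )
    }
  }
  clades <- sort(unique(genomes$clade_id))
  truth <- data.frame(
    clade_id = clades,
    preferred_sites = vapply(clades, function(cl) {
      paste(truth_sites(config$preference[cl, config$sites]), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  list(
    summary = summarize_profiles(profiles),
    profiles = profiles,
    site_map = site_map,
    clade_map = genomes[c("genome_id", "clade_id")],
    truth = truth
  )
}

#' Simulate a genome-by-function presence table
#'
#' Draws a long-format function table with planted group-enriched
#' functions and uniform background functions. An enriched function is
#' present with probability `presence_prob_in` in genomes of its group and
#' `presence_prob_out` elsewhere; background functions share one presence
#' probability in every group.
#'
#' @param groups data.frame with columns `genome_id`, `group`.
#' @param enriched_functions data.frame with columns `function_id`,
#'   `group`, `presence_prob_in`, `presence_prob_out` (may have 0 rows).
#' @param background_functions Number of background functions; default 0.
#' @param background_prob Presence probability of background functions in
#'   all groups; default 0.5.
#' @param seed Integer seed.
#' @return data.frame with columns `genome_id`, `accession`, `count`
#'   (0/1), one row per (genome, function).
#' @export
simulate_function_table <- function(groups, enriched_functions = NULL,
                                    background_functions = 0,
                                    background_prob = 0.5, seed = 1L) {
  check_columns(groups, c("genome_id", "group"), "group table")
  if (anyDuplicated(groups$genome_id) > 0L) {
    stop_input("duplicate genome ids in group table")
  }
  if (is.null(enriched_functions)) {
    enriched_functions <- data.frame(
      function_id = character(), group = character(),
      presence_prob_in = numeric(), presence_prob_out = numeric(),
      stringsAsFactors = FALSE
    )
  }
  check_columns(
    enriched_functions,
    c("function_id", "group", "presence_prob_in", "presence_prob_out"),
    "enriched function table"
  )
  bad_group <- setdiff(enriched_functions$group, groups$group)
  if (length(bad_group) > 0) {
    stop_input(
      "enriched function group(s) not present among genomes: %s",
      paste(bad_group, collapse = ", ")
    )
  }
  probs <- c(
    enriched_functions$presence_prob_in, enriched_functions$presence_prob_out,
    background_prob
  )
  if (any(probs < 0 | probs > 1)) {
    stop_input("presence probabilities must lie in [0, 1]")
  }

  n_genome <- nrow(groups)
  with_seed(seed, {
    blocks <- list()
    for (i in seq_len(nrow(enriched_functions))) {
      fn <- enriched_functions[i, ]
      p <- ifelse(
        groups$group == fn$group, fn$presence_prob_in, fn$presence_prob_out
      )
      blocks[[length(blocks) + 1L]] <- data.frame(
        genome_id = groups$genome_id,
        accession = fn$function_id,
        count = as.integer(stats::runif(n_genome) < p),
        stringsAsFactors = FALSE
      )
    }
    if (background_functions > 0) {
      width <- max(4L, nchar(as.character(background_functions)))
      for (i in seq_len(background_functions)) {
        blocks[[length(blocks) + 1L]] <- data.frame(
          genome_id = groups$genome_id,
          accession = sprintf("BG%0*d", width, i),
          count = as.integer(stats::runif(n_genome) < background_prob),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- if (length(blocks) > 0) {
      do.call(rbind, blocks)
    } else {
      data.frame(
        genome_id = character(), accession = character(), count = integer(),
        stringsAsFactors = FALSE
      )
    }
    rownames(out) <- NULL
    out
  })
}
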