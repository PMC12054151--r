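# Shared fixtures built in code.

# Small coverage summary: 3 genomes x 2 samples, mixed detection.
toy_summary <- function() {
  data.frame(
    sample_id = rep(c("s1", "s2"), each = 3),
    genome_id = rep(c("A", "B", "C"), 2),
    q2q3_mean_depth = c(6, 2, 10, 0, 5, 5),
    breadth = c(0.9, 0.8, 0.2, 0.1, 0.7, 0.6),
    detected = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

toy_clades <- function() {
  data.frame(
    genome_id = c("A", "B", "C"),
    clade_id = c("c1", "c1", "c2"),
    stringsAsFactors = FALSE
  )
}

# Per-sample values and site labels for classifier tests: n samples at each
# of the given sites, values drawn by the supplied function(site).
site_series <- function(sites, n_per_site, value_fun) {
  sample_sites <- rep(sites, each = n_per_site)
  values <- unlist(lapply(sites, function(s) value_fun(s)))
  list(values = values, sites = sample_sites)
}

# Independent Pearson chi-square oracle for a 2x2 table given as counts
# (a = group1 detected, b = group1 not, c = group2 detected, d = group2 not).
# Computed from expected counts, not from the closed-form product formula
# used by the implementation.
pearson_chisq_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    return(0)
  }
  e <- outer(rs, cs) / n
  sum((tab - e)^2 / e)
}

# Rao score statistic from R's GLM machinery: the reference route through
# an actual binomial-logit fit.
glm_rao <- function(presence, groups) {
  df <- data.frame(y = as.numeric(presence), g = factor(groups))
  fit <- suppressWarnings(stats::glm(
    y ~ g, family = stats::binomial(), data = df,
    control = stats::glm.control(epsilon = 1e-13, maxit = 200)
  ))
  an <- suppressWarnings(stats::anova(fit, test = "Rao"))
  an$Rao[2]
}

# Strong-preference community configuration used by recovery tests: each
# clade prefers one site at high depth, with low off-site depth and mild
# noise.
strong_community_config <- function(preferred, seed,
                                    samples_per_site = 20,
                                    genome_length = 2000,
                                    sites = classifier_sites(),
                                    on_depth = 20, off_depth = 0.5) {
  clades <- names(preferred)
  pref <- matrix(
    off_depth, nrow = length(clades), ncol = length(sites),
    dimnames = list(clades, sites)
  )
  for (cl in clades) {
    pref[cl, preferred[[cl]]] <- on_depth
  }
  simulation_config(
    sites = sites,
    samples_per_site = samples_per_site,
    genomes = data.frame(
      genome_id = paste0(clades, "_g1"),
      clade_id = clades,
      length = genome_length,
      stringsAsFactors = FALSE
    ),
    preference = pref,
    dropout = 0.05,
    outlier_fraction = 0.05,
    outlier_multiplier = 10,
    overdispersion = 0.5,
    seed = seed
  )
}
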