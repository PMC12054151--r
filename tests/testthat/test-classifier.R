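test_that("bipartition enumeration matches 2^(k-1)-1 and brute force", {
  expect_length(enumerate_bipartitions(c("a", "b")), 1)
  expect_length(enumerate_bipartitions(classifier_sites()), 127)

  maps3 <- enumerate_bipartitions(c("a", "b", "c"))
  canon <- sort(vapply(maps3, function(m) {
    paste(sort(c(paste(m$group1, collapse = ""),
                 paste(m$group2, collapse = ""))), collapse = "|")
  }, character(1)))
  expect_equal(canon, c("a|bc", "ac|b", "ab|c")[order(c("a|bc", "ac|b", "ab|c"))])

  # brute-force oracle: unordered non-trivial subsets via combn
  brute_count <- function(k) {
    sites <- letters[1:k]
    subsets <- unlist(
      lapply(1:(k - 1), function(m) combn(sites, m, simplify = FALSE)),
      recursive = FALSE
    )
    canon <- unique(vapply(subsets, function(g1) {
      g2 <- setdiff(sites, g1)
      paste(sort(c(paste(sort(g1), collapse = ""),
                   paste(sort(g2), collapse = ""))), collapse = "|")
    }, character(1)))
    length(canon)
  }
  for (k in 2:10) {
    expect_length(enumerate_bipartitions(letters[1:k]), 2^(k - 1) - 1)
    expect_equal(brute_count(k), 2^(k - 1) - 1)
  }
  expect_error(enumerate_bipartitions("a"), "between 2 and 20")
})

test_that("every bipartition is a proper two-group cover of the universe", {
  sites <- classifier_sites()
  maps <- enumerate_bipartitions(sites)
  keys <- vapply(maps, function(m) {
    expect_gt(length(m$group1), 0)
    expect_gt(length(m$group2), 0)
    expect_length(intersect(m$group1, m$group2), 0)
    expect_setequal(c(m$group1, m$group2), sites)
    paste(sort(c(paste(sort(m$group1), collapse = ","),
                 paste(sort(m$group2), collapse = ","))), collapse = "|")
  }, character(1))
  expect_false(any(duplicated(keys)))
})

test_that("pooled-variance t statistic matches the textbook formula", {
  map <- list(group1 = "a", group2 = "b")
  t1 <- t_statistic_for_map(
    c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3), map
  )
  expect_equal(t1, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(t1, 3), -3.674)

  expect_equal(
    t_statistic_for_map(c(5, 5, 5, 5), c("a", "a", "b", "b"), map), 0
  )

  set.seed(3)
  for (i in 1:100) {
    n1 <- sample(2:10, 1)
    n2 <- sample(2:10, 1)
    x <- rnorm(n1)
    y <- rnorm(n2)
    vals <- c(x, y)
    sites <- c(rep("a", n1), rep("b", n2))
    mine <- t_statistic_for_map(vals, sites, map)
    ref <- unname(t.test(x, y, var.equal = TRUE)$statistic)
    expect_equal(mine, ref, tolerance = 1e-10)
    # antisymmetry under group swap
    expect_equal(
      t_statistic_for_map(vals, sites, list(group1 = "b", group2 = "a")),
      -mine,
      tolerance = 1e-12
    )
  }
})

test_that("t statistic handles degenerate groups as declared", {
  map <- list(group1 = "a", group2 = "b")
  # empty group -> NA (map skipped, not scored 0)
  expect_true(is.na(t_statistic_for_map(c(1, 2), c("a", "a"), map)))
  # df < 1 -> NA
  expect_true(is.na(t_statistic_for_map(c(1, 2), c("a", "b"), map)))
  # zero pooled variance, unequal means -> signed infinity
  expect_identical(
    t_statistic_for_map(c(4, 4, 1, 1), c("a", "a", "b", "b"), map), Inf
  )
})

test_that("Rao statistic equals Pearson chi-square on all small 2x2 tables", {
  map <- list(group1 = "a", group2 = "b")
  stat_of <- function(a, b, c, d) {
    det <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
    sites <- c(rep("a", a + b), rep("b", c + d))
    rao_statistic_for_map(det, sites, map)
  }
  expect_equal(stat_of(8, 2, 2, 8), 7.2)
  expect_equal(stat_of(5, 5, 5, 5), 0)
  expect_equal(stat_of(10, 0, 10, 0), 0) # degenerate margin

  for (n1 in 1:12) {
    for (n2 in 1:12) {
      for (a in 0:n1) {
        for (c_ in 0:n2) {
          expect_equal(
            stat_of(a, n1 - a, c_, n2 - c_),
            pearson_chisq_2x2(a, n1 - a, c_, n2 - c_),
            tolerance = 1e-10
          )
        }
      }
    }
  }
})

test_that("Rao statistic agrees with the GLM score test route", {
  set.seed(19)
  map <- list(group1 = "a", group2 = "b")
  checked <- 0
  while (checked < 25) {
    n1 <- sample(3:15, 1)
    n2 <- sample(3:15, 1)
    det <- runif(n1 + n2) < runif(1, 0.2, 0.8)
    sites <- c(rep("a", n1), rep("b", n2))
    if (all(det) || !any(det)) next
    checked <- checked + 1
    # agreement limited by IRLS convergence of the reference fit
    expect_equal(
      rao_statistic_for_map(det, sites, map),
      glm_rao(det, sites),
      tolerance = 1e-6
    )
  }
})

test_that("classify_clade recovers a constructed single-site preference", {
  sites <- classifier_sites()
  ser <- site_series(sites, 5, function(s) {
    if (s == "TD") c(19, 20, 21, 20, 20) else c(0, 0.2, 0, 0.1, 0)
  })
  res_ab <- classify_clade(ser$values, ser$sites, metric = "abundance")
  expect_equal(res_ab$preferred_sites, "TD")
  expect_setequal(
    c(res_ab$best_map$group1, res_ab$best_map$group2), sites
  )

  det <- site_series(sites, 5, function(s) rep(s == "TD", 5))
  res_pr <- classify_clade(det$values, det$sites, metric = "prevalence")
  expect_equal(res_pr$preferred_sites, "TD")
  expect_equal(res_pr$statistic, 40) # perfect 5/35 split: chi2 = N
})

test_that("classification is invariant to sample order and site relabeling", {
  sites <- classifier_sites()
  set.seed(5)
  ser <- site_series(sites, 6, function(s) {
    rnorm(6, mean = ifelse(s %in% c("SUPP", "SUBP"), 10, 1))
  })
  res <- classify_clade(ser$values, ser$sites, metric = "abundance")
  expect_setequal(res$preferred_sites, c("SUPP", "SUBP"))

  perm <- sample(seq_along(ser$values))
  res_perm <- classify_clade(
    ser$values[perm], ser$sites[perm], metric = "abundance"
  )
  expect_equal(res_perm$statistic, res$statistic)
  expect_equal(res_perm$preferred_sites, res$preferred_sites)

  # bijective site relabeling permutes names, not the statistic
  relabel <- setNames(rev(sites), sites)
  res_rel <- classify_clade(
    ser$values, unname(relabel[ser$sites]), metric = "abundance"
  )
  expect_equal(abs(res_rel$statistic), abs(res$statistic), tolerance = 1e-10)
  expect_equal(
    sort(unname(relabel[res$preferred_sites])), res_rel$preferred_sites
  )
})

test_that("exchangeable sites yield a no-preference call under min_stat", {
  sites <- classifier_sites()
  ser <- site_series(sites, 4, function(s) rep(2, 4))
  res <- classify_clade(
    ser$values, ser$sites, metric = "abundance", min_stat = 0.5
  )
  expect_equal(res$statistic, 0)
  expect_true(res$no_preference)
})

test_that("classify_habitats classifies every clade under both metrics", {
  cfg <- strong_community_config(
    c(c1 = "TD", c2 = "SUPP"), seed = 101, samples_per_site = 6,
    genome_length = 500
  )
  sim <- simulate_community(cfg)
  classes <- classify_habitats(sim$summary, sim$clade_map, sim$site_map)
  expect_equal(nrow(classes), 4)
  expect_setequal(classes$metric, c("abundance", "prevalence"))
  expect_equal(
    classes$preferred_sites[classes$clade_id == "c1"], c("TD", "TD")
  )
  expect_equal(
    classes$preferred_sites[classes$clade_id == "c2"], c("SUPP", "SUPP")
  )
  expect_error(
    classify_habitats(
      sim$summary, sim$clade_map,
      transform(sim$site_map, site = "XX")
    ),
    "unknown site code"
  )
})
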