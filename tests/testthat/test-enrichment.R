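test_that("module completeness counts satisfied steps with alternatives", {
  m4 <- module_definition("M1", list("K1", "K2", "K3", "K4"))
  expect_equal(module_completeness(c("K1", "K2", "K3"), m4), 0.75)
  expect_equal(module_completeness(c("K1", "K2"), m4), 0.5)
  malt <- module_definition("M2", list(c("K1", "K2"), "K3"))
  expect_equal(module_completeness("K2", malt), 0.5)
  expect_equal(module_completeness(c("K2", "K3"), malt), 1)
  expect_error(module_definition("M0", list()), "at least one step")
})

test_that("module completeness is monotone in genome annotations", {
  set.seed(13)
  accs <- paste0("K", 1:30)
  for (i in 1:50) {
    steps <- replicate(
      sample(2:6, 1), sample(accs, sample(1:3, 1)), simplify = FALSE
    )
    m <- module_definition("M", steps)
    have <- sample(accs, sample(0:20, 1))
    extra <- c(have, sample(accs, 1))
    expect_gte(
      module_completeness(extra, m), module_completeness(have, m)
    )
  }
})

test_that("module completeness table flags completion at 0.75 inclusively", {
  fn <- data.frame(
    genome_id = rep(c("g1", "g2"), each = 3),
    accession = c("K1", "K2", "K3", "K1", "K2", "K9"),
    count = c(1, 1, 1, 1, 1, 1)
  )
  mods <- list(module_definition("M1", list("K1", "K2", "K3", "K4")))
  tab <- module_completeness_table(fn, mods)
  expect_equal(tab$completeness[tab$genome_id == "g1"], 0.75)
  expect_true(tab$complete[tab$genome_id == "g1"])
  expect_equal(tab$completeness[tab$genome_id == "g2"], 0.5)
  expect_false(tab$complete[tab$genome_id == "g2"])
})

test_that("enrichment score matches Pearson chi-square on all small tables", {
  score_of <- function(a, b, c, d) {
    enrichment_test(
      c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d)),
      c(rep("A", a + b), rep("B", c + d))
    )
  }
  r <- score_of(5, 0, 0, 5)
  expect_equal(r$score, 10)
  expect_equal(r$associated_groups, "A")

  same <- score_of(3, 3, 3, 3)
  expect_equal(same$score, 0)
  expect_equal(same$p_value, 1)

  for (n1 in 1:12) {
    for (n2 in 1:12) {
      for (a in 0:n1) {
        for (c_ in 0:n2) {
          expect_equal(
            score_of(a, n1 - a, c_, n2 - c_)$score,
            pearson_chisq_2x2(a, n1 - a, c_, n2 - c_),
            tolerance = 1e-10
          )
        }
      }
    }
  }
})

test_that("enrichment score agrees with the GLM Rao route, 2 and 3 groups", {
  set.seed(23)
  checked <- 0
  while (checked < 20) {
    n_groups <- sample(2:3, 1)
    groups <- rep(LETTERS[1:n_groups], times = sample(4:10, n_groups, TRUE))
    presence <- runif(length(groups)) < 0.5
    if (all(presence) || !any(presence)) next
    checked <- checked + 1
    r <- enrichment_test(presence, groups)
    expect_equal(r$score, glm_rao(presence, groups), tolerance = 1e-6)
    expect_equal(
      r$p_value,
      if (r$score == 0) 1 else pchisq(r$score, n_groups - 1, lower.tail = FALSE),
      tolerance = 1e-12
    )
    # exchangeability: permuting genomes changes nothing
    perm <- sample(length(groups))
    r2 <- enrichment_test(presence[perm], groups[perm])
    expect_equal(r2$score, r$score)
    expect_equal(r2$p_value, r$p_value)
  }
})

test_that("BH adjustment matches a brute-force step-up implementation", {
  bh_brute <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- p[o] * m / seq_len(m)
    q_sorted <- rev(cummin(rev(q_sorted)))
    q <- numeric(m)
    q[o] <- pmin(q_sorted, 1)
    q
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(37)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("habitat enrichment flags planted functions and controls the null", {
  groups <- data.frame(
    genome_id = sprintf("g%02d", 1:20),
    group = rep(c("plaque", "tongue"), each = 10)
  )
  planted <- data.frame(
    function_id = paste0("ENR", 1:5), group = "plaque",
    presence_prob_in = 1, presence_prob_out = 0
  )
  fn <- simulate_function_table(
    groups, planted, background_functions = 500, seed = 41
  )
  res <- enrich_by_habitat(fn, groups)
  hits <- res$accession[res$significant]
  expect_true(all(paste0("ENR", 1:5) %in% hits))
  expect_equal(
    res$associated_groups[res$accession == "ENR1"], "plaque"
  )
  # null background: at most a stray handful of false flags
  expect_lte(sum(grepl("^BG", hits)), 5)
})

test_that("empty function tables give empty enrichment results", {
  groups <- data.frame(genome_id = c("g1", "g2"), group = c("A", "B"))
  empty <- data.frame(
    genome_id = character(), accession = character(), count = integer()
  )
  expect_equal(nrow(enrich_by_habitat(empty, groups)), 0)
  expect_error(
    enrichment_test(c(TRUE, FALSE), c("A", "A")), "at least 2 groups"
  )
})
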