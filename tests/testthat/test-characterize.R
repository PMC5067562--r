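test_that("cohens_d matches hand evaluation and its invariances", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  x <- c(2, 4, 6, 8)
  expect_equal(cohens_d(x, x), 0)
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(cohens_d(a + 5, b + 5), cohens_d(a, b))
  expect_error(cohens_d(c(1, 1), c(1, 1)),
               class = "eyestrat_undefined_effect_error")
  expect_error(cohens_d(1, c(1, 2)), class = "eyestrat_parameter_error")
})

make_assignment <- function(scores_by_group, group = "ASC",
                            cohort = "discovery") {
  labels <- rep(seq_along(scores_by_group),
                times = lengths(scores_by_group))
  totals <- unlist(scores_by_group, use.names = FALSE)
  tbl <- tibble::tibble(
    subject_id = sprintf("%s_%s_%03d", cohort, group, seq_along(totals)),
    group = group, cohort = cohort, total = totals,
    subgroup = as.integer(labels)
  )
  eyestrat:::new_subgroup_assignment(
    tbl, K = length(scores_by_group),
    mean_scores = vapply(scores_by_group, mean, numeric(1)),
    tree = NULL, params = list()
  )
}

test_that("effect grid has K_A x K_B cells with Bonferroni family size", {
  set.seed(7)
  a <- make_assignment(lapply(seq(8, 32, length.out = 5),
                              function(m) rnorm(25, m, 3)), group = "ASC")
  b <- make_assignment(lapply(seq(20, 34, length.out = 4),
                              function(m) rnorm(25, m, 3)), group = "TD",
                       cohort = "replication")
  g <- effect_size_grid(a, b)
  expect_s3_class(g, "effect_grid")
  expect_equal(nrow(g), 20)
  expect_equal(attr(g, "family_size"), 20)
  expect_false(any(g$untestable))
  # significance respects the corrected threshold
  expect_equal(g$significant, g$p_value < 0.05 / 20)
})

test_that("a subgroup compared with itself gives d = 0 and p = 1", {
  set.seed(9)
  one <- list(rnorm(30, 20, 4))
  a <- make_assignment(one)
  b <- make_assignment(one, group = "TD")
  g <- effect_size_grid(a, b)
  expect_equal(g$cohens_d, 0)
  expect_equal(g$p_value, 1)
})

test_that("small subgroups are flagged untestable, not dropped", {
  a <- make_assignment(list(c(10, 12, 14), 30))  # second subgroup n = 1
  b <- make_assignment(list(c(20, 22, 24)), group = "TD")
  g <- effect_size_grid(a, b)
  expect_equal(nrow(g), 2)
  expect_true(g$untestable[g$subgroup_a == 2])
  expect_false(g$untestable[g$subgroup_a == 1])
})

test_that("an independent covariate leaves effect sizes nearly unchanged", {
  set.seed(11)
  a <- make_assignment(lapply(c(10, 20, 30), function(m) rnorm(200, m, 5)))
  b <- make_assignment(lapply(c(15, 25), function(m) rnorm(200, m, 5)),
                       group = "TD")
  ids <- c(tibble::as_tibble(a)$subject_id, tibble::as_tibble(b)$subject_id)
  cov <- setNames(rnorm(length(ids)), ids)
  g0 <- effect_size_grid(a, b)
  g1 <- effect_size_grid(a, b, covariate = cov)
  expect_true(all(abs(g1$cohens_d - g0$cohens_d) < 0.1))
})

test_that("item difficulty profiles are subgroup percentages", {
  x <- rbind(c(1, 1), c(1, 0), c(1, 0), c(0, 0),   # subgroup 1: 75%, 25%
             c(1, 1), c(1, 1))                     # subgroup 2: 100%, 100%
  tbl <- binary_table(x)
  a <- make_assignment(list(rep(2, 4), rep(2, 2)))
  # align ids with the table
  attr_a <- tibble::as_tibble(a)
  attr_a$subject_id <- tbl$subject_id
  a2 <- eyestrat:::new_subgroup_assignment(attr_a, K = 2,
                                           mean_scores = c(2, 2),
                                           tree = NULL, params = list())
  prof <- item_difficulty(tbl, a2)
  expect_equal(prof$pct_correct[prof$subgroup == 1 & prof$item == "item_01"], 75)
  expect_equal(prof$pct_correct[prof$subgroup == 1 & prof$item == "item_02"], 25)
  expect_equal(prof$pct_correct[prof$subgroup == 2], c(100, 100))
  expect_true(all(prof$pct_correct >= 0 & prof$pct_correct <= 100))
})

test_that("difficulty profiles match planted probabilities at large n", {
  bank <- profile_bank("asc_like", seed = 1)
  tbl <- binarize_responses(simulate_cohort(bank, n = 500, seed = 13))
  at <- total_scores(tbl)
  at$subgroup <- tbl$.planted
  a <- eyestrat:::new_subgroup_assignment(
    at, K = bank$K, mean_scores = tapply(at$total, at$subgroup, mean),
    tree = NULL, params = list()
  )
  prof <- item_difficulty(tbl, a)
  sizes <- table(tbl$.planted)
  for (k in seq_len(bank$K)) {
    planted <- bank$profiles[k, ] * 100
    est <- prof$pct_correct[prof$subgroup == k][order(prof$item[prof$subgroup == k])]
    nk <- sizes[[k]]
    lo <- 100 * qbinom(0.0015, nk, bank$profiles[k, ]) / nk
    hi <- 100 * qbinom(0.9985, nk, bank$profiles[k, ]) / nk
    expect_true(all(est >= lo - 1e-9 & est <= hi + 1e-9))
  }
})

test_that("bh_fdr reproduces the step-up rule and matches the oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 6)), rep(FALSE, 6))
  expect_equal(bh_fdr(rep(0, 6)), rep(TRUE, 6))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "eyestrat_validation_error")

  set.seed(17)
  for (rep in 1:1000) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_identical(bh_fdr(p, q), bh_oracle(p, q))
  }
})

test_that("difficulty correlation grid is symmetric with unit diagonal", {
  set.seed(19)
  bank <- profile_bank("asc_like", seed = 1)
  tbl <- binarize_responses(simulate_cohort(bank, n = 250, seed = 19))
  sg <- stratify_cohort(tbl, min_cluster_size = 10)
  prof <- item_difficulty(tbl, sg)
  sp <- split_items(tbl)
  cg <- difficulty_correlations(prof, sp, "easy")
  k <- n_subgroups(sg)
  expect_equal(nrow(cg), k * k)
  expect_equal(cg$r[cg$subgroup_a == cg$subgroup_b], rep(1, k))
  m <- tidyr::pivot_wider(cg[, c("subgroup_a", "subgroup_b", "r")],
                          names_from = "subgroup_b", values_from = "r")
  mm <- as.matrix(m[, -1])
  expect_equal(mm, t(mm), ignore_attr = TRUE)
})

test_that("identical profiles correlate perfectly; independent noise rarely flags", {
  prof <- tibble::tibble(
    subgroup = rep(1:2, each = 6),
    item = rep(sprintf("item_%02d", 1:6), 2),
    pct_correct = rep(c(10, 30, 50, 60, 80, 95), 2),
    n = 20
  )
  class(prof) <- c("difficulty_profile", class(prof))
  sp <- structure(list(easy = sprintf("item_%02d", 1:3),
                       difficult = sprintf("item_%02d", 4:6), tree = NULL),
                  class = "item_split")
  cg <- difficulty_correlations(prof, sp, "easy")
  expect_equal(cg$r[cg$subgroup_a == 1 & cg$subgroup_b == 2], 1)

  # null simulation: independent profiles should seldom produce FDR flags
  set.seed(23)
  n_flagged <- 0
  for (rep in 1:100) {
    nullprof <- tibble::tibble(
      subgroup = rep(1:4, each = 20),
      item = rep(sprintf("item_%02d", 1:20), 4),
      pct_correct = runif(80, 20, 90),
      n = 50
    )
    class(nullprof) <- c("difficulty_profile", class(nullprof))
    spn <- structure(list(easy = sprintf("item_%02d", 1:20),
                          difficult = character(0), tree = NULL),
                     class = "item_split")
    cgn <- difficulty_correlations(nullprof, spn, "easy")
    if (any(cgn$significant[cgn$subgroup_a != cgn$subgroup_b], na.rm = TRUE)) {
      n_flagged <- n_flagged + 1
    }
  }
  expect_lte(n_flagged, 10)
})

test_that("cross-cohort dissimilarity orders subjects and conserves counts", {
  bank <- profile_bank("asc_like", seed = 1)
  pair <- simulate_cohort_pair(bank, n_discovery = 120, n_replication = 90,
                               seed = 29)
  tbls <- lapply(pair, binarize_responses)
  asn <- lapply(tbls, stratify_cohort, min_cluster_size = 8)
  cc <- cross_cohort_dissimilarity(tbls, asn)
  expect_equal(nrow(cc$d), 120 + 90)
  expect_equal(nrow(cc$index), 210)
  # subgroup rank order within each cohort, cohorts adjacent
  expect_true(all(diff(match(cc$index$cohort, unique(cc$index$cohort))) >= 0))
  for (co in unique(cc$index$cohort)) {
    expect_true(all(diff(cc$index$subgroup[cc$index$cohort == co]) >= 0))
  }

  # identical rows in a single subgroup give a zero off-diagonal block
  x <- matrix(rep(c(1L, 0L, 1L, 1L), each = 10), nrow = 10)
  tbl1 <- binary_table(x)
  a1 <- stratify_cohort(tbl1, min_cluster_size = 4)
  cc1 <- cross_cohort_dissimilarity(list(tbl1), list(a1))
  expect_true(all(cc1$d == 0))

  expect_error(cross_cohort_dissimilarity(tbls, asn, items = "item_99"),
               class = "eyestrat_validation_error")
})

test_that("within-subgroup distances undercut rank-extreme distances", {
  bank <- profile_bank("asc_like", seed = 1)
  pair <- simulate_cohort_pair(bank, n_discovery = 200, n_replication = 150,
                               seed = 31)
  tbls <- lapply(pair, binarize_responses)
  asn <- lapply(tbls, stratify_cohort, min_cluster_size = 10)
  sp <- split_items(tbls[[1]])
  for (subset in c("easy", "difficult")) {
    cc <- cross_cohort_dissimilarity(tbls, asn, items = sp[[subset]])
    k <- max(cc$index$subgroup)
    within <- c()
    for (b in c(1, k)) {
      idx <- which(cc$index$subgroup == b)
      within <- c(within, mean(cc$d[idx, idx][upper.tri(cc$d[idx, idx])]))
    }
    lo <- which(cc$index$subgroup == 1)
    hi <- which(cc$index$subgroup == k)
    between_extreme <- mean(cc$d[lo, hi])
    expect_lt(mean(within), between_extreme)
  }
})

test_that("phenotype tests reproduce closed-form statistics", {
  a <- make_assignment(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  ids <- tibble::as_tibble(a)$subject_id
  pheno <- tibble::tibble(subject_id = ids,
                          y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                          z = rep(1, 9),
                          sex = rep(c("M", "F", "M"), 3))
  res <- phenotype_tests(pheno, a, c(y = "anova", z = "kruskal_wallis",
                                     sex = "chi_square"))
  expect_equal(res$statistic[res$variable == "y"], 3)
  expect_equal(res$df[res$variable == "y"], 2)
  expect_equal(res$statistic[res$variable == "z"], 0)   # all ties
  expect_equal(res$statistic[res$variable == "sex"], 0) # proportional counts
  expect_error(phenotype_tests(pheno, a, c(nope = "anova")),
               class = "eyestrat_validation_error")
})
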