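test_that("ward linkage reproduces forced merges and minimal-pair choice", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  t2 <- ward_linkage(d2)
  expect_equal(t2$height, 0.4)

  d3 <- matrix(c(0, 0.1, 0.9,
                 0.1, 0, 0.9,
                 0.9, 0.9, 0), 3, 3)
  t3 <- ward_linkage(d3)
  expect_equal(sort(t3$merge[1, ]), c(-2, -1))   # {1,2} first
  expect_equal(t3$height[1], 0.1)

  expect_error(ward_linkage(matrix(0, 1, 1)),
               class = "eyestrat_parameter_error")
})

test_that("ward linkage matches the step-by-step Lance-Williams oracle", {
  set.seed(13)
  for (rep in 1:20) {
    d <- random_dissimilarity(12)
    tree <- ward_linkage(d)
    oracle <- ward_oracle(d)
    expect_equal(tree$height, oracle$heights, tolerance = 1e-10)
    expect_identical(hclust_merged_sets(tree), oracle$merged_sets)
  }
})

test_that("ward heights are nondecreasing on random inputs", {
  set.seed(17)
  for (rep in 1:5) {
    tree <- ward_linkage(random_dissimilarity(sample(10:30, 1)))
    expect_true(all(diff(tree$height) >= -1e-12))
  }
})

test_that("dynamic cut recovers two planted blocks exactly", {
  skip_if_not_installed("mclust")
  set.seed(19)
  pb <- planted_block_dissimilarity(c(30, 30))
  lab <- cut_tree_dynamic(ward_linkage(pb$d), pb$d, min_cluster_size = 10)
  expect_equal(length(unique(lab[lab > 0])), 2)
  expect_equal(mclust::adjustedRandIndex(lab, pb$labels), 1)
})

test_that("dynamic cut returns one cluster when no branch structure exists", {
  n <- 40
  d <- matrix(0.5, n, n); diag(d) <- 0
  lab <- cut_tree_dynamic(ward_linkage(d), d, min_cluster_size = 10)
  expect_equal(unname(unique(lab)), 1L)
})

test_that("dynamic cut recovers five planted blocks with graded separation", {
  skip_if_not_installed("mclust")
  set.seed(23)
  sizes <- c(25, 30, 35, 30, 25)
  lab_true <- rep(1:5, times = sizes)
  n <- length(lab_true)
  centers <- seq(0, 1, length.out = 5)
  d <- outer(centers[lab_true], centers[lab_true],
             function(a, b) abs(a - b) * 0.6 + 0.25)
  for (b in 1:5) d[lab_true == b, lab_true == b] <- 0.05
  noise <- matrix(runif(n * n, 0, 0.02), n, n)
  d <- d + (noise + t(noise)) / 2
  diag(d) <- 0
  lab <- cut_tree_dynamic(ward_linkage(d), d, min_cluster_size = 10)
  expect_equal(length(unique(lab[lab > 0])), 5)
  expect_gte(mclust::adjustedRandIndex(lab, lab_true), 0.9)
})

test_that("dynamic cut enforces minimum cluster sizes and label contract", {
  set.seed(29)
  pb <- planted_block_dissimilarity(c(25, 25, 4), between = 0.8)
  lab <- cut_tree_dynamic(ward_linkage(pb$d), pb$d, min_cluster_size = 10,
                          assign_outliers = FALSE)
  sizes <- table(lab[lab > 0])
  expect_true(all(sizes >= 10))
  expect_true(all(lab %in% 0:max(lab)))
  expect_error(
    cut_tree_dynamic(ward_linkage(pb$d), pb$d, min_cluster_size = 1),
    class = "eyestrat_parameter_error"
  )
  expect_error(
    cut_tree_dynamic(ward_linkage(pb$d), pb$d[1:10, 1:10]),
    class = "eyestrat_validation_error"
  )
})

test_that("deep split stringency is monotone in recovered cluster count", {
  bank <- profile_bank("asc_like", seed = 1)
  tbl <- binarize_responses(simulate_cohort(bank, n = 200, seed = 5))
  ks <- vapply(c(0, 2, 4), function(ds) {
    n_subgroups(stratify_cohort(tbl, min_cluster_size = 12, deep_split = ds))
  }, integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("rank ordering sorts subgroups by mean score", {
  labels <- c(1, 1, 2, 2, 3, 3)
  scores <- c(10, 10, 30, 30, 20, 20)
  rk <- rank_order_subgroups(labels, scores)
  expect_equal(rk$labels, c(1L, 1L, 3L, 3L, 2L, 2L))
  expect_equal(rk$K, 3)
  expect_equal(rk$mean_scores, c(10, 20, 30))

  single <- rank_order_subgroups(rep(1, 4), 1:4)
  expect_equal(single$K, 1)
  expect_equal(unique(single$labels), 1L)

  set.seed(31)
  for (rep in 1:10) {
    lab <- sample(0:4, 50, replace = TRUE)
    if (all(lab == 0)) lab[1] <- 1
    sc <- rnorm(50)
    rk <- rank_order_subgroups(lab, sc)
    expect_true(all(diff(rk$mean_scores) >= 0))
    expect_equal(lab == 0, rk$labels == 0)
  }
  expect_error(rank_order_subgroups(rep(0, 5), 1:5),
               class = "eyestrat_validation_error")
})

test_that("stratification is deterministic and equivariant to row order", {
  bank <- profile_bank("asc_like", seed = 1)
  tbl <- binarize_responses(simulate_cohort(bank, n = 120, seed = 7))
  s1 <- stratify_cohort(tbl, min_cluster_size = 10)
  s2 <- stratify_cohort(tbl, min_cluster_size = 10)
  expect_identical(tidy(s1), tidy(s2))

  set.seed(37)
  perm <- sample(nrow(tbl))
  s3 <- stratify_cohort(tbl[perm, ], min_cluster_size = 10)
  a1 <- tidy(s1)[, c("subject_id", "subgroup")]
  a3 <- tidy(s3)[, c("subject_id", "subgroup")]
  expect_equal(a3[order(a3$subject_id), ],
               a1[order(a1$subject_id), ])
})

test_that("a cohort of identical response rows forms a single subgroup", {
  x <- matrix(rep(c(1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L), each = 30), nrow = 30)
  sg <- stratify_cohort(binary_table(x), min_cluster_size = 5)
  expect_equal(n_subgroups(sg), 1)
})

test_that("item split recovers planted easy/difficult sets and labels them", {
  set.seed(41)
  p <- c(rep(0.9, 18), rep(0.25, 18))
  x <- matrix(rbinom(300 * 36, 1, rep(p, each = 300)), nrow = 300)
  tbl <- binary_table(x)
  sp <- split_items(tbl)
  expect_setequal(sp$easy, item_columns(tbl)[1:18])
  expect_setequal(sp$difficult, item_columns(tbl)[19:36])

  pct <- function(set) mean(as.matrix(tbl[, set]))
  expect_gte(pct(sp$easy), pct(sp$difficult))

  two <- binary_table(matrix(c(1L, 1L, 0L, 1L), 2, 2))
  sp2 <- split_items(two)
  expect_equal(sort(c(sp2$easy, sp2$difficult)), item_columns(two))
  expect_error(split_items(binary_table(matrix(1L, 3, 1))),
               class = "eyestrat_parameter_error")
})
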