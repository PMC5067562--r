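#' Cohen's d standardized mean difference
#'
#' \eqn{d = (\bar{x} - \bar{y}) / s_p} with the pooled standard deviation
#' \eqn{s_p^2 = [(n_x - 1) s_x^2 + (n_y - 1) s_y^2] / (n_x + n_y - 2)}.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return The standardized mean difference (first minus second).
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))  # -2
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("Each sample needs at least 2 observations.",
          class = "eyestrat_parameter_error")
  }
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 <= 0) {
    abort("Pooled variance is zero: effect size undefined.",
          class = "eyestrat_undefined_effect_error")
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

covariate_values <- function(covariate, subject_ids, call = rlang::caller_env()) {
  if (is.data.frame(covariate)) {
    if (!all(c("subject_id", "value") %in% names(covariate))) {
      abort("A covariate data frame needs columns `subject_id` and `value`.",
            class = "eyestrat_parameter_error", call = call)
    }
    covariate <- setNames(covariate$value, covariate$subject_id)
  }
  miss <- setdiff(subject_ids, names(covariate))
  if (length(miss) > 0) {
    abort(sprintf("Covariate missing for %d subject(s) (e.g. %s).",
                  length(miss), miss[1]),
          class = "eyestrat_validation_error", call = call)
  }
  unname(covariate[subject_ids])
}

#' Pairwise effect-size grid between two sets of subgroups
#'
#' For every pair of a subgroup from `a` and a subgroup from `b`, compares
#' total scores with a two-sample t-test (pooled-variance Student test by
#' default, matching the pooled-SD Cohen's d) and computes Cohen's d with
#' the sign convention first (`a`) minus second (`b`). Significance is
#' Bonferroni-corrected at family size \eqn{K_A \times K_B} — e.g. 20
#' comparisons for 5-by-4 subgroups. Cells with a subgroup smaller than 2
#' are flagged untestable rather than dropped, so the grid shape is always
#' \eqn{K_A \times K_B}.
#'
#' When a covariate is supplied (the verbal-IQ-controlled re-analysis),
#' scores of all subjects from both assignments are first residualized on
#' the covariate by least squares, and the tests and effect sizes are
#' computed on the residuals.
#'
#' @param a,b [subgroup_assignment][stratify_cohort] objects (e.g. the ASC
#'   and TD stratifications of one cohort).
#' @param covariate Optional per-subject covariate: a named numeric vector
#'   (names = subject IDs) or a data frame with `subject_id` and `value`,
#'   covering all subjects of both assignments.
#' @param alpha Family-wise significance level before Bonferroni division
#'   (default 0.05).
#' @param var_equal Pooled-variance Student test (default); `FALSE` gives
#'   Welch.
#' @return A tibble of class `effect_grid` with one row per cell:
#'   `subgroup_a`, `subgroup_b`, `n_a`, `n_b`, `mean_diff`, `statistic`,
#'   `df`, `p_value`, `cohens_d`, `significant`, `untestable`; attributes
#'   `family_size` and `alpha`.
#' @export
effect_size_grid <- function(a, b, covariate = NULL, alpha = 0.05,
                             var_equal = TRUE) {
  stopifnot(inherits(a, "subgroup_assignment"),
            inherits(b, "subgroup_assignment"))
  ta <- tibble::as_tibble(a)[tibble::as_tibble(a)$subgroup > 0, ]
  tb <- tibble::as_tibble(b)[tibble::as_tibble(b)$subgroup > 0, ]
  if (nrow(ta) == 0 || nrow(tb) == 0) {
    abort("Both assignments must contain assigned subjects.",
          class = "eyestrat_validation_error")
  }
  score_a <- ta$total
  score_b <- tb$total
  if (!is.null(covariate)) {
    ids <- c(ta$subject_id, tb$subject_id)
    v <- covariate_values(covariate, ids)
    res <- resid(lm(c(score_a, score_b) ~ v))
    score_a <- res[seq_len(nrow(ta))]
    score_b <- res[-seq_len(nrow(ta))]
  }
  ka <- attr(a, "K")
  kb <- attr(b, "K")
  family <- ka * kb
  cells <- tidyr::expand_grid(subgroup_a = seq_len(ka), subgroup_b = seq_len(kb))
  out <- purrr::pmap_dfr(cells, function(subgroup_a, subgroup_b) {
    x <- score_a[ta$subgroup == subgroup_a]
    y <- score_b[tb$subgroup == subgroup_b]
    row <- tibble::tibble(
      subgroup_a = subgroup_a, subgroup_b = subgroup_b,
      n_a = length(x), n_b = length(y),
      mean_diff = NA_real_, statistic = NA_real_, df = NA_real_,
      p_value = NA_real_, cohens_d = NA_real_,
      significant = NA, untestable = TRUE
    )
    if (length(x) < 2 || length(y) < 2) return(row)
    sp_ok <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) > 0
    if (!sp_ok) return(row)
    tt <- t.test(x, y, var.equal = var_equal)
    row$mean_diff <- mean(x) - mean(y)
    row$statistic <- unname(tt$statistic)
    row$df <- unname(tt$parameter)
    row$p_value <- tt$p.value
    row$cohens_d <- cohens_d(x, y)
    row$significant <- tt$p.value < alpha / family
    row$untestable <- FALSE
    row
  })
  structure(out, family_size = family, alpha = alpha,
            class = c("effect_grid", class(out)))
}

#' @export
print.effect_grid <- function(x, ...) {
  cat(sprintf("<effect-size grid: %d cells, Bonferroni family size %d, alpha %.3g>\n",
              nrow(x), attr(x, "family_size"), attr(x, "alpha")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Item-difficulty profiles per subgroup
#'
#' Item difficulty for a subgroup is the percentage of its members who
#' answered the item correctly. Unassigned subjects (subgroup 0) are
#' excluded.
#'
#' @param tbl A binarized response table covering the assignment's
#'   subjects.
#' @param assignment A [subgroup_assignment][stratify_cohort].
#' @return A tibble of class `difficulty_profile`: `subgroup`, `item`,
#'   `pct_correct` (0–100), `n` (subgroup size).
#' @export
item_difficulty <- function(tbl, assignment) {
  assert_binary_table(tbl)
  stopifnot(inherits(assignment, "subgroup_assignment"))
  at <- tibble::as_tibble(assignment)
  miss <- setdiff(at$subject_id, tbl$subject_id)
  if (length(miss) > 0) {
    abort("Assignment contains subjects absent from the response table.",
          class = "eyestrat_validation_error")
  }
  items <- item_columns(tbl)
  joined <- dplyr::inner_join(at[, c("subject_id", "subgroup")],
                              tbl[, c("subject_id", items)],
                              by = "subject_id")
  joined <- joined[joined$subgroup > 0, ]
  out <- joined |>
    tidyr::pivot_longer(dplyr::all_of(items), names_to = "item",
                        values_to = "correct") |>
    dplyr::group_by(.data$subgroup, .data$item) |>
    dplyr::summarise(pct_correct = 100 * mean(.data$correct),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$subgroup, .data$item)
  structure(out, class = c("difficulty_profile", class(out)))
}

#' Benjamini–Hochberg FDR flags
#'
#' Step-up false-discovery-rate control: with ordered p-values
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, find the largest \eqn{i} with
#' \eqn{p_{(i)} \le (i/m) q} and flag all hypotheses at or below it.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q Target false discovery rate (default 0.05).
#' @return Logical vector: `TRUE` where the hypothesis is rejected at FDR
#'   `q`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].", class = "eyestrat_validation_error")
  }
  p.adjust(p, method = "BH") <= q
}

#' Correlation grid of subgroup item-difficulty profiles
#'
#' Pearson (or Spearman) correlations between the item-difficulty vectors
#' of every unordered pair of subgroups, restricted to the easy or the
#' difficult item subset; significance flags control the FDR at `q` over
#' all off-diagonal pairs. High correlations mean two subgroups find the
#' same items hard; the diagonal is 1 by construction. Pairs with a
#' constant profile vector are flagged untestable.
#'
#' @param profile A [difficulty_profile][item_difficulty].
#' @param items An [item_split][split_items].
#' @param subset `"easy"` or `"difficult"`.
#' @param q FDR level (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A tibble of class `correlation_grid` with one row per cell
#'   (all ordered pairs, so the grid is symmetric with unit diagonal):
#'   `subgroup_a`, `subgroup_b`, `r`, `p_value`, `significant`,
#'   `untestable`.
#' @export
difficulty_correlations <- function(profile, items,
                                    subset = c("easy", "difficult"),
                                    q = 0.05, method = c("pearson", "spearman")) {
  stopifnot(inherits(profile, "difficulty_profile"),
            inherits(items, "item_split"))
  subset <- match.arg(subset)
  method <- match.arg(method)
  sel <- items[[subset]]
  if (length(sel) < 3) {
    abort("Need at least 3 items in the chosen subset.",
          class = "eyestrat_parameter_error")
  }
  wide <- tidyr::pivot_wider(profile[profile$item %in% sel,
                                     c("subgroup", "item", "pct_correct")],
                             names_from = "item", values_from = "pct_correct")
  groups <- sort(wide$subgroup)
  if (length(groups) < 2) {
    abort("Need at least 2 subgroups.", class = "eyestrat_parameter_error")
  }
  vecs <- lapply(groups, function(g) {
    as.numeric(wide[wide$subgroup == g, sel])
  })
  names(vecs) <- groups
  pairs <- utils::combn(length(groups), 2)
  est <- apply(pairs, 2, function(ab) {
    x <- vecs[[ab[1]]]; y <- vecs[[ab[2]]]
    if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(x, y, method = method))
    c(unname(ct$estimate), ct$p.value)
  })
  testable <- !is.na(est[2, ])
  sig <- rep(NA, ncol(pairs))
  if (any(testable)) sig[testable] <- bh_fdr(est[2, testable], q = q)
  cells <- tibble::tibble(
    subgroup_a = groups[pairs[1, ]], subgroup_b = groups[pairs[2, ]],
    r = est[1, ], p_value = est[2, ], significant = sig,
    untestable = !testable
  )
  grid <- dplyr::bind_rows(
    cells,
    dplyr::rename(cells, subgroup_a = "subgroup_b", subgroup_b = "subgroup_a"),
    tibble::tibble(subgroup_a = groups, subgroup_b = groups, r = 1,
                   p_value = NA_real_, significant = NA, untestable = FALSE)
  ) |>
    dplyr::arrange(.data$subgroup_a, .data$subgroup_b)
  structure(grid, q = q, subset = subset, method = method,
            class = c("correlation_grid", class(grid)))
}

#' Cross-cohort subject dissimilarity matrix
#'
#' Concatenates the subjects of several cohorts — ordered by subgroup rank
#' within each cohort, cohorts adjacent — and computes the full pairwise
#' Hamming distance matrix on a chosen item subset. The block index marks
#' where each (cohort, subgroup) run of subjects starts and ends, for
#' plotting and block summaries; homologous subgroups in different cohorts
#' end up in aligned positions along the diagonal.
#'
#' @param tables List of binarized response tables sharing one item list.
#' @param assignments List of matching
#'   [subgroup_assignment][stratify_cohort] objects (same length/order).
#' @param items Optional character vector of items (e.g. an easy or
#'   difficult subset); default all items.
#' @return A list of class `cross_cohort_dissimilarity`: `d` (the ordered
#'   distance matrix), `index` (tibble `subject_id`, `cohort`, `subgroup`
#'   in matrix order), `blocks` (tibble `cohort`, `subgroup`, `start`,
#'   `end`).
#' @export
cross_cohort_dissimilarity <- function(tables, assignments, items = NULL) {
  stopifnot(length(tables) == length(assignments), length(tables) >= 1)
  item_sets <- lapply(tables, item_columns)
  if (!is.null(items)) {
    for (s in item_sets) {
      if (!all(items %in% s)) {
        abort("`items` must be shared by every cohort table.",
              class = "eyestrat_validation_error")
      }
    }
  } else {
    if (length(unique(lapply(item_sets, sort))) != 1) {
      abort("Cohort tables must share one item list.",
            class = "eyestrat_validation_error")
    }
    items <- item_sets[[1]]
  }
  ordered <- purrr::map2_dfr(tables, assignments, function(tbl, a) {
    assert_binary_table(tbl)
    at <- tibble::as_tibble(a)
    at <- at[order(at$subgroup, at$subject_id), ]
    dplyr::inner_join(at[, c("subject_id", "cohort", "subgroup")],
                      tbl[, c("subject_id", items)], by = "subject_id")
  })
  d <- hamming_matrix(
    dplyr::bind_cols(ordered[, "subject_id"],
                     tibble::tibble(group = "all", cohort = ordered$cohort),
                     ordered[, items]),
    axis = "subjects"
  )
  blocks <- ordered |>
    dplyr::mutate(pos = dplyr::row_number()) |>
    dplyr::group_by(.data$cohort, .data$subgroup) |>
    dplyr::summarise(start = min(.data$pos), end = max(.data$pos),
                     .groups = "drop")
  structure(
    list(d = d,
         index = ordered[, c("subject_id", "cohort", "subgroup")],
         blocks = blocks),
    class = "cross_cohort_dissimilarity"
  )
}

#' @export
print.cross_cohort_dissimilarity <- function(x, ...) {
  cat(sprintf("<cross-cohort dissimilarity: %d subjects, %d blocks>\n",
              nrow(x$d), nrow(x$blocks)))
  print(x$blocks, ...)
  invisible(x)
}

#' Phenotype association tests across subgroups
#'
#' Tests whether phenotype variables differ between subgroups: one-way
#' ANOVA for approximately normal continuous variables, Kruskal–Wallis for
#' skewed ones (e.g. trait questionnaires), and a chi-square test of
#' observed versus expected counts for categorical variables such as sex.
#' Significant omnibus tests (p < `alpha`) are followed by
#' Bonferroni-corrected pairwise post-hocs (pairwise t-tests or Wilcoxon
#' tests).
#'
#' @param pheno A data frame with `subject_id` plus phenotype columns.
#'   Missing values are allowed and excluded per test, never imputed.
#' @param assignment A [subgroup_assignment][stratify_cohort].
#' @param tests Named character vector mapping a phenotype column to one of
#'   `"anova"`, `"kruskal_wallis"`, `"chi_square"`.
#' @param alpha Omnibus significance level gating post-hocs (default 0.05).
#' @return A tibble with one row per variable: `variable`, `test`,
#'   `statistic`, `df`, `p_value`, `untestable`; Bonferroni-corrected
#'   post-hoc p-value tables for significant omnibus tests are in the
#'   `posthoc` attribute (a named list).
#' @export
phenotype_tests <- function(pheno, assignment, tests, alpha = 0.05) {
  stopifnot(inherits(assignment, "subgroup_assignment"))
  if (!"subject_id" %in% names(pheno)) {
    abort("`pheno` needs a subject_id column.",
          class = "eyestrat_validation_error")
  }
  bad <- setdiff(names(tests), names(pheno))
  if (length(bad) > 0) {
    abort(sprintf("Phenotype variable(s) not found: %s.",
                  paste(bad, collapse = ", ")),
          class = "eyestrat_validation_error")
  }
  at <- tibble::as_tibble(assignment)
  dat <- dplyr::inner_join(at[at$subgroup > 0, c("subject_id", "subgroup")],
                           pheno, by = "subject_id")
  posthoc <- list()
  out <- purrr::imap_dfr(tests, function(test, variable) {
    v <- dat[[variable]]
    g <- factor(dat$subgroup)
    keep <- !is.na(v)
    v <- v[keep]; g <- droplevels(g[keep])
    row <- tibble::tibble(variable = variable, test = test,
                          statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, untestable = TRUE)
    if (test %in% c("anova", "kruskal_wallis")) {
      sizes <- table(g)
      if (length(sizes) < 2 || any(sizes < 2)) return(row)
      if (test == "anova") {
        fit <- summary(aov(v ~ g))[[1]]
        row$statistic <- fit[["F value"]][1]
        row$df <- fit[["Df"]][1]
        row$p_value <- fit[["Pr(>F)"]][1]
        if (!is.na(row$p_value) && row$p_value < alpha) {
          posthoc[[variable]] <<- stats::pairwise.t.test(
            v, g, p.adjust.method = "bonferroni")$p.value
        }
      } else if (sd(v) == 0) {
        # all observations tied: H degenerates to 0
        row$statistic <- 0
        row$df <- length(levels(g)) - 1
        row$p_value <- 1
      } else {
        kw <- kruskal.test(v, g)
        row$statistic <- unname(kw$statistic)
        row$df <- unname(kw$parameter)
        row$p_value <- kw$p.value
        if (!is.na(row$p_value) && row$p_value < alpha) {
          posthoc[[variable]] <<- suppressWarnings(stats::pairwise.wilcox.test(
            v, g, p.adjust.method = "bonferroni")$p.value)
        }
      }
      row$untestable <- FALSE
    } else if (test == "chi_square") {
      counts <- table(g, v)
      if (nrow(counts) < 2 || ncol(counts) < 2) return(row)
      cs <- suppressWarnings(chisq.test(counts))
      row$statistic <- unname(cs$statistic)
      row$df <- unname(cs$parameter)
      row$p_value <- cs$p.value
      row$untestable <- FALSE
    } else {
      abort(sprintf("Unknown test '%s' for variable '%s'.", test, variable),
            class = "eyestrat_parameter_error")
    }
    row
  })
  structure(out, posthoc = posthoc, alpha = alpha,
            class = c("phenotype_tests", class(out)))
}
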