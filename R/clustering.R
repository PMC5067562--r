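#' Ward agglomerative clustering of a dissimilarity matrix
#'
#' Agglomerative hierarchical clustering with Ward's minimum-variance
#' linkage via the Lance–Williams recurrence: after merging clusters
#' \eqn{i, j}, the dissimilarity to any cluster \eqn{k} becomes
#' \deqn{\frac{(n_i + n_k) d(i,k) + (n_j + n_k) d(j,k) - n_k d(i,j)}
#'       {n_i + n_j + n_k},}
#' and at every step the pair at minimal current dissimilarity is merged.
#' By default the recurrence is applied directly to the supplied
#' dissimilarity (the historical `"ward.D"` dialect used in the weighted
#' network analysis lineage); `squared = TRUE` selects the squared-distance
#' variant (`"ward.D2"`).
#'
#' @param d Symmetric dissimilarity matrix (at least 2 elements), e.g. from
#'   [tom_dissimilarity()].
#' @param squared Use the squared-dissimilarity Ward variant.
#' @return An [stats::hclust] tree.
#' @export
ward_linkage <- function(d, squared = FALSE) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 2) {
    abort("`d` must be a square dissimilarity matrix over at least 2 elements.",
          class = "eyestrat_parameter_error")
  }
  hclust(as.dist(d), method = if (squared) "ward.D2" else "ward.D")
}

# deepSplit stringency map for the dynamic hybrid cut. Higher deepSplit
# tolerates more within-branch scatter and demands a smaller gap below the
# parent merge, hence splits more finely. Scatter and gap are measured
# relative to the parent's merge height (scale-free within the tree); the
# constants are fixed by the planted-partition recovery suite.
deep_split_params <- function(deep_split) {
  if (!deep_split %in% 0:4) {
    abort("`deep_split` must be an integer in 0..4.",
          class = "eyestrat_parameter_error")
  }
  max_core_scatter <- c(0.40, 0.55, 0.70, 0.80, 0.90)[deep_split + 1]
  min_gap <- (1 - max_core_scatter) * 0.45
  list(max_core_scatter = max_core_scatter, min_gap = min_gap)
}

#' Cut a dendrogram into clusters with a dynamic hybrid tree cut
#'
#' Variable-height tree cutting: instead of one global cut height, each
#' branch is examined on its own scale. A branch is accepted as a cluster
#' when it is large enough (`min_cluster_size`), internally tight (its mean
#' within-branch merge height — the core scatter — is a small fraction of
#' the height at which it joins its sibling), and well separated (the gap
#' between its top merge and the parent merge is a large fraction of the
#' parent height). The stringency of the scatter/gap thresholds is a
#' monotone function of `deep_split` (0 = coarsest, 4 = finest). When no
#' branch structure passes the criteria the whole tree forms one cluster.
#'
#' Elements in small offshoot branches are initially unassigned (label 0);
#' with `assign_outliers = TRUE` each joins the cluster to which its mean
#' dissimilarity is smallest, provided that mean is within the cluster's
#' admission radius (the largest mean within-cluster dissimilarity of any
#' current member), in the spirit of the partitioning-around-medoids stage
#' of the hybrid method.
#'
#' @param tree An [stats::hclust] tree (e.g. from [ward_linkage()]).
#' @param d The dissimilarity matrix the tree was built from, used for
#'   outlier assignment; element names must match the tree labels.
#' @param min_cluster_size Minimum cluster size (default 20).
#' @param deep_split Split stringency, integer 0–4 (default 1).
#' @param assign_outliers Assign unlabelled elements to near enough
#'   clusters (default `TRUE`).
#' @return Integer label vector (named by element) in `0..K`; 0 marks
#'   unassigned elements.
#' @export
cut_tree_dynamic <- function(tree, d, min_cluster_size = 20, deep_split = 1,
                             assign_outliers = TRUE) {
  stopifnot(inherits(tree, "hclust"))
  if (min_cluster_size < 2) {
    abort("`min_cluster_size` must be >= 2.",
          class = "eyestrat_parameter_error")
  }
  pars <- deep_split_params(deep_split)
  n <- nrow(tree$merge) + 1L
  if (!is.matrix(d) || nrow(d) != n ||
      (!is.null(tree$labels) && !is.null(rownames(d)) &&
       !identical(tree$labels, rownames(d)))) {
    abort("`tree` and `d` must refer to the same elements in the same order.",
          class = "eyestrat_validation_error")
  }

  heights <- tree$height
  merge <- tree$merge
  # Leaves and summed internal merge heights per internal node.
  leaves <- vector("list", n - 1L)
  height_sum <- numeric(n - 1L)   # sum of merge heights within the branch
  n_merges <- integer(n - 1L)     # number of merges within the branch
  for (j in seq_len(n - 1L)) {
    pick <- function(child) {
      if (child < 0) {
        list(lv = -child, hs = 0, nm = 0L)
      } else {
        list(lv = leaves[[child]], hs = height_sum[child], nm = n_merges[child])
      }
    }
    c1 <- pick(merge[j, 1]); c2 <- pick(merge[j, 2])
    leaves[[j]] <- c(c1$lv, c2$lv)
    height_sum[j] <- c1$hs + c2$hs + heights[j]
    n_merges[j] <- c1$nm + c2$nm + 1L
  }

  labels <- integer(n)
  next_label <- 0L
  root <- n - 1L

  if (max(heights) <= 0 || diff(range(heights)) == 0) {
    # Degenerate tree (all merges at one height): one cluster.
    labels[] <- 1L
    names(labels) <- tree$labels
    return(labels)
  }

  branch_size <- function(child) if (child < 0) 1L else length(leaves[[child]])
  top_height <- function(child) if (child < 0) 0 else heights[child]
  core_scatter <- function(child) {
    # Mean merge height inside the branch; 0 for leaves.
    if (child < 0) 0 else height_sum[child] / n_merges[child]
  }

  eligible <- function(child, parent_height) {
    if (branch_size(child) < min_cluster_size) return(FALSE)
    scatter_rel <- core_scatter(child) / parent_height
    gap_rel <- (parent_height - top_height(child)) / parent_height
    scatter_rel <= pars$max_core_scatter && gap_rel >= pars$min_gap
  }

  make_cluster <- function(node) {
    next_label <<- next_label + 1L
    labels[leaves[[node]]] <<- next_label
  }

  walk <- function(node) {
    h <- heights[node]
    ch <- merge[node, ]
    el <- vapply(ch, eligible, logical(1), parent_height = h)
    small <- vapply(ch, branch_size, integer(1)) < min_cluster_size
    # eligible children (never leaves) are walked further; when one child
    # is eligible and its sibling is a small offshoot, the offshoot's
    # elements stay unassigned for the outlier stage
    if (el[1] && el[2]) {
      walk(ch[1]); walk(ch[2])
    } else if (el[1] && small[2]) {
      walk(ch[1])
    } else if (el[2] && small[1]) {
      walk(ch[2])
    } else {
      make_cluster(node)
    }
  }
  walk(root)

  if (assign_outliers && any(labels == 0L) && next_label > 0L) {
    out_idx <- which(labels == 0L)
    cand <- matrix(Inf, nrow = length(out_idx), ncol = next_label)
    radii <- rep(-Inf, next_label)
    for (k in seq_len(next_label)) {
      members <- which(labels == k)
      if (length(members) < 2) next
      intra <- rowSums(d[members, members, drop = FALSE]) / (length(members) - 1)
      radii[k] <- max(intra)
      cand[, k] <- rowMeans(d[out_idx, members, drop = FALSE])
    }
    for (i in seq_along(out_idx)) {
      best <- which.min(cand[i, ])
      if (is.finite(cand[i, best]) && cand[i, best] <= radii[best]) {
        labels[out_idx[i]] <- best
      }
    }
  }
  names(labels) <- tree$labels
  labels
}

#' Rank-order cluster labels by mean score
#'
#' Remaps raw cluster labels so that subgroup 1 has the lowest mean total
#' score and subgroup K the highest — the convention that makes subgroup
#' labels homologous (comparable by rank) across independently clustered
#' cohorts. Ties in mean score are broken by the smaller original label.
#' Unassigned elements (label 0) stay 0.
#'
#' @param labels Integer cluster labels (0 = unassigned).
#' @param scores Numeric scores aligned with `labels`.
#' @return List with `labels` (remapped integer vector), `K`, and
#'   `mean_scores` (per-subgroup mean total score, ascending).
#' @export
rank_order_subgroups <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    abort("`labels` and `scores` must be aligned.",
          class = "eyestrat_validation_error")
  }
  raw <- sort(unique(labels[labels > 0]))
  if (length(raw) == 0) {
    abort("No nonzero cluster labels to rank.",
          class = "eyestrat_validation_error")
  }
  means <- vapply(raw, function(k) mean(scores[labels == k]), numeric(1))
  ord <- order(means, raw)
  remap <- integer(max(raw))
  remap[raw[ord]] <- seq_along(raw)
  new_labels <- ifelse(labels > 0, remap[labels], 0L)
  list(
    labels = as.integer(new_labels),
    K = length(raw),
    mean_scores = means[ord]
  )
}

#' Stratify a cohort into performance subgroups
#'
#' The full unsupervised subject-stratification pipeline: Hamming distances
#' between subjects' binary item responses are converted to a topological
#' overlap similarity, its dissimilarity is clustered with Ward linkage,
#' the dendrogram is cut with the dynamic hybrid tree cut, and the
#' resulting subgroups are rank-ordered by mean total score (subgroup 1 =
#' lowest). Run it separately per diagnostic group and per cohort; the
#' procedure is fully deterministic given its inputs.
#'
#' @param tbl A binarized response table ([binarize_responses()]),
#'   optionally pre-filtered; `group`/`cohort` subset it further.
#' @param group,cohort Optional values to subset the corresponding meta
#'   columns before clustering.
#' @inheritParams cut_tree_dynamic
#' @param squared Use squared-dissimilarity Ward linkage (default `FALSE`).
#' @param seed Optional integer recorded in the provenance (the procedure
#'   itself draws no random numbers).
#' @return A `subgroup_assignment` object: a tibble of per-subject rows
#'   (`subject_id`, `group`, `cohort`, `total`, `subgroup`; subgroup 0 =
#'   unassigned) carrying the subgroup count `K`, per-subgroup mean scores,
#'   the linkage tree, and the parameters as attributes. See [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @examples
#' bank <- profile_bank("asc_like", seed = 1)
#' tbl <- binarize_responses(simulate_cohort(bank, n = 150, seed = 3))
#' sg <- stratify_cohort(tbl)
#' glance(sg)
#' @export
stratify_cohort <- function(tbl, group = NULL, cohort = NULL,
                            min_cluster_size = 20, deep_split = 1,
                            assign_outliers = TRUE, squared = FALSE,
                            seed = NULL) {
  assert_binary_table(tbl)
  if (!is.null(group)) tbl <- tbl[tbl$group %in% group, , drop = FALSE]
  if (!is.null(cohort)) tbl <- tbl[tbl$cohort %in% cohort, , drop = FALSE]
  if (nrow(tbl) < 2) {
    abort("Need at least 2 subjects to stratify.",
          class = "eyestrat_parameter_error")
  }
  dist_h <- hamming_matrix(tbl, axis = "subjects")
  tom <- topological_overlap(dist_h)
  dd <- tom_dissimilarity(tom)
  tree <- ward_linkage(dd, squared = squared)
  raw_labels <- cut_tree_dynamic(tree, dd, min_cluster_size = min_cluster_size,
                                 deep_split = deep_split,
                                 assign_outliers = assign_outliers)
  totals <- total_scores(tbl)
  ranked <- rank_order_subgroups(raw_labels, totals$total)
  out <- dplyr::mutate(totals, subgroup = ranked$labels)
  new_subgroup_assignment(
    out, K = ranked$K, mean_scores = ranked$mean_scores, tree = tree,
    params = list(min_cluster_size = min_cluster_size,
                  deep_split = deep_split,
                  assign_outliers = assign_outliers, squared = squared,
                  seed = seed)
  )
}

new_subgroup_assignment <- function(tbl, K, mean_scores, tree, params) {
  structure(tbl, K = K, mean_scores = mean_scores, tree = tree,
            params = params,
            class = c("subgroup_assignment", class(tbl)))
}

#' Number of subgroups in an assignment
#' @param x A `subgroup_assignment`.
#' @return Integer subgroup count K.
#' @export
n_subgroups <- function(x) {
  stopifnot(inherits(x, "subgroup_assignment"))
  attr(x, "K")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat(sprintf("<subgroup assignment: %d subjects, K = %d subgroups>\n",
              nrow(x), attr(x, "K")))
  cat("mean totals by subgroup:",
      sprintf("%.1f", attr(x, "mean_scores")), "\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @rdname stratify_cohort
#' @param x,.data A `subgroup_assignment`.
#' @param ... Unused.
#' @method tidy subgroup_assignment
#' @export
tidy.subgroup_assignment <- function(x, ...) {
  for (a in c("K", "mean_scores", "tree", "params")) attr(x, a) <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  tibble::as_tibble(x)
}

#' @rdname stratify_cohort
#' @method glance subgroup_assignment
#' @export
glance.subgroup_assignment <- function(x, ...) {
  tbl <- tibble::as_tibble(x)
  tibble::tibble(
    n_subjects = nrow(tbl),
    K = attr(x, "K"),
    n_unassigned = sum(tbl$subgroup == 0),
    min_size = min(table(tbl$subgroup[tbl$subgroup > 0])),
    score_range = diff(range(attr(x, "mean_scores")))
  )
}

#' Split items into easy and difficult subsets
#'
#' Applies the same clustering pipeline along the item axis: Hamming
#' distances between item columns, topological overlap, Ward linkage, and
#' the tree's top split into two branches. The branch with the higher
#' overall percent-correct is labelled `easy`.
#'
#' @param tbl A binarized response table.
#' @param squared Use squared-dissimilarity Ward linkage.
#' @return An `item_split`: list with character vectors `easy` and
#'   `difficult` (a partition of the item columns) and the item linkage
#'   `tree`.
#' @export
split_items <- function(tbl, squared = FALSE) {
  assert_binary_table(tbl)
  items <- item_columns(tbl)
  if (length(items) < 2) {
    abort("Need at least 2 items to split.", class = "eyestrat_parameter_error")
  }
  dist_h <- hamming_matrix(tbl, axis = "items")
  dd <- tom_dissimilarity(topological_overlap(dist_h))
  tree <- ward_linkage(dd, squared = squared)
  top <- cutree(tree, k = 2)
  pct <- vapply(split(items, top), function(set) {
    mean(as.matrix(tbl[, set])) * 100
  }, numeric(1))
  easy_branch <- names(pct)[which.max(pct)]
  structure(
    list(
      easy = items[top == as.integer(easy_branch)],
      difficult = items[top != as.integer(easy_branch)],
      tree = tree
    ),
    class = "item_split"
  )
}

#' @export
print.item_split <- function(x, ...) {
  cat(sprintf("<item split: %d easy, %d difficult>\n",
              length(x$easy), length(x$difficult)))
  invisible(x)
}
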