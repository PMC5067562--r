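default_config <- function() {
  list(
    # input: either paths to wide-format response CSVs covering both
    # groups, or NULL to simulate cohorts from the packaged profile banks
    discovery_path = NULL,
    replication_path = NULL,
    simulate = list(n_discovery = 400, n_replication = 250,
                    n_discovery_td = 320, n_replication_td = 200),
    groups = c("ASC", "TD"),
    timeout_threshold = 9,
    min_cluster_size = 20,
    deep_split = 1,
    alpha = 0.05,
    q = 0.05,
    rounds = 20,
    n_perm = 1000,
    seed = 1,
    out_dir = NULL
  )
}

read_run_config <- function(config) {
  base <- default_config()
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("Config file not found: '%s'.", config),
            class = "eyestrat_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("`config` must be a list or the path to a YAML config file.",
          class = "eyestrat_parameter_error")
  }
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")),
          class = "eyestrat_parameter_error")
  }
  modifyList(base, config)
}

load_or_simulate <- function(cfg) {
  if (!is.null(cfg$discovery_path)) {
    paths <- c(discovery = cfg$discovery_path,
               replication = cfg$replication_path)
    tables <- lapply(paths[!vapply(paths, is.null, logical(1))],
                     read_response_table)
    return(tables)
  }
  sim <- cfg$simulate
  asc <- simulate_cohort_pair(
    profile_bank("asc_like", seed = cfg$seed),
    n_discovery = sim$n_discovery, n_replication = sim$n_replication,
    group = "ASC", seed = cfg$seed
  )
  td <- simulate_cohort_pair(
    profile_bank("td_like", seed = cfg$seed),
    n_discovery = sim$n_discovery_td, n_replication = sim$n_replication_td,
    group = "TD", seed = cfg$seed + 1
  )
  list(
    discovery = dplyr::bind_rows(asc$discovery, td$discovery),
    replication = dplyr::bind_rows(asc$replication, td$replication)
  )
}

#' Run the full stratification analysis end to end
#'
#' Orchestrates the whole pipeline from a configuration list (or YAML
#' file): timeout filtering and binarization; independent stratification
#' of each diagnostic group in each cohort; ASC-versus-TD effect-size
#' grids per cohort; the easy/difficult item split and per-subgroup
#' item-difficulty profiles with FDR-controlled correlation grids;
#' cross-cohort subject dissimilarity matrices on the easy and difficult
#' subsets; and cross-cohort classification of rank-ordered subgroup
#' labels with a label-permutation test. Without input paths, two
#' discovery/replication cohort pairs are simulated from the packaged
#' profile banks. Rerunning with an identical configuration reproduces the
#' outputs exactly.
#'
#' @param config Named list overriding the defaults (see Details in the
#'   vignette), or a YAML file path. Unknown keys are rejected. Key
#'   parameters: `timeout_threshold` (9), `min_cluster_size` (20),
#'   `deep_split` (1), `alpha` (0.05), `q` (0.05), `rounds` (20), `n_perm`
#'   (1000), `seed`, `out_dir` (optional directory for CSV/JSON outputs).
#' @return A list of class `eyestrat_run` with elements `stratifications`
#'   (per cohort and group), `effect_grids`, `item_splits`,
#'   `difficulty`, `correlations`, `cross_cohort`, `classification`,
#'   `config`, and `summary` (a plain list also written as JSON when
#'   `out_dir` is set).
#' @export
run_full_analysis <- function(config = list()) {
  cfg <- read_run_config(config)
  tables <- load_or_simulate(cfg)
  cohorts <- names(tables)

  filtered <- lapply(tables, filter_timeouts, max_timeouts = cfg$timeout_threshold)
  binary <- lapply(filtered, binarize_responses)

  strat <- list()
  for (co in cohorts) {
    for (g in intersect(cfg$groups, unique(binary[[co]]$group))) {
      strat[[paste(co, g, sep = ".")]] <- stratify_cohort(
        binary[[co]], group = g,
        min_cluster_size = cfg$min_cluster_size,
        deep_split = cfg$deep_split, seed = cfg$seed
      )
    }
  }

  effect_grids <- list()
  for (co in cohorts) {
    a <- strat[[paste(co, "ASC", sep = ".")]]
    b <- strat[[paste(co, "TD", sep = ".")]]
    if (!is.null(a) && !is.null(b)) {
      effect_grids[[co]] <- effect_size_grid(a, b, alpha = cfg$alpha)
    }
  }

  item_splits <- list()
  difficulty <- list()
  correlations <- list()
  for (co in cohorts) {
    for (g in intersect(cfg$groups, unique(binary[[co]]$group))) {
      key <- paste(co, g, sep = ".")
      sub <- binary[[co]][binary[[co]]$group == g, ]
      item_splits[[key]] <- split_items(sub)
      difficulty[[key]] <- item_difficulty(sub, strat[[key]])
      if (attr(strat[[key]], "K") >= 2) {
        correlations[[key]] <- list(
          easy = difficulty_correlations(difficulty[[key]], item_splits[[key]],
                                         "easy", q = cfg$q),
          difficult = difficulty_correlations(difficulty[[key]],
                                              item_splits[[key]],
                                              "difficult", q = cfg$q)
        )
      }
    }
  }

  cross_cohort <- list()
  classification <- list()
  if (length(cohorts) == 2) {
    for (g in cfg$groups) {
      keys <- paste(cohorts, g, sep = ".")
      if (!all(keys %in% names(strat))) next
      tbls <- lapply(cohorts, function(co) {
        binary[[co]][binary[[co]]$group == g, ]
      })
      asn <- strat[keys]
      split_d <- item_splits[[keys[1]]]
      cross_cohort[[g]] <- list(
        easy = cross_cohort_dissimilarity(tbls, asn, items = split_d$easy),
        difficult = cross_cohort_dissimilarity(tbls, asn,
                                               items = split_d$difficult)
      )
      train <- dplyr::inner_join(
        tibble::as_tibble(asn[[1]])[tibble::as_tibble(asn[[1]])$subgroup > 0,
                                    c("subject_id", "subgroup")],
        tbls[[1]], by = "subject_id"
      )
      test <- dplyr::inner_join(
        tibble::as_tibble(asn[[2]])[tibble::as_tibble(asn[[2]])$subgroup > 0,
                                    c("subject_id", "subgroup")],
        tbls[[2]], by = "subject_id"
      )
      ka <- max(attr(asn[[1]], "K"), attr(asn[[2]], "K"))
      merges <- NULL
      if (ka >= 3) {
        merges <- list()
        for (cut in 2:(ka - 1)) {
          merges[[sprintf("1-%d_vs_%d-%d", cut, cut + 1, ka)]] <-
            list(seq_len(cut), seq(cut + 1, ka))
        }
      }
      classification[[g]] <- permutation_test(
        response_matrix(dplyr::select(train, -"subgroup")),
        train$subgroup,
        response_matrix(dplyr::select(test, -"subgroup")),
        test$subgroup,
        rounds = cfg$rounds, n_perm = cfg$n_perm, seed = cfg$seed,
        merges = merges
      )
    }
  }

  summary <- list(
    parameters = cfg[c("timeout_threshold", "min_cluster_size", "deep_split",
                       "alpha", "q", "rounds", "n_perm", "seed")],
    excluded_subjects = lapply(filtered, excluded_subjects),
    subgroups = lapply(strat, function(s) {
      list(K = attr(s, "K"),
           sizes = as.list(table(tibble::as_tibble(s)$subgroup)),
           mean_totals = round(attr(s, "mean_scores"), 4))
    }),
    effect_grids = lapply(effect_grids, function(g) {
      list(cells = nrow(g), family_size = attr(g, "family_size"),
           n_significant = sum(g$significant, na.rm = TRUE),
           d_range = round(range(g$cohens_d, na.rm = TRUE), 4))
    }),
    classification = lapply(classification, function(p) {
      out <- list(observed_accuracy = round(p$observed, 4),
                  p_value = p$p_value, p_raw = p$p_raw, n_perm = p$n_perm,
                  null_range = round(range(p$null), 4))
      if (!is.null(p$evaluation$merged)) {
        out$merged_accuracy <- as.list(setNames(
          round(p$evaluation$merged$accuracy, 4), p$evaluation$merged$merge))
      }
      out
    })
  )

  result <- structure(
    list(stratifications = strat, effect_grids = effect_grids,
         item_splits = item_splits, difficulty = difficulty,
         correlations = correlations, cross_cohort = cross_cohort,
         classification = classification, config = cfg, summary = summary),
    class = "eyestrat_run"
  )
  if (!is.null(cfg$out_dir)) {
    write_run_outputs(result, cfg$out_dir)
  }
  result
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  emit_csv <- function(tbl, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(tibble::as_tibble(tbl), path, progress = FALSE)
    manifest <<- c(manifest, name)
  }
  for (key in names(result$stratifications)) {
    emit_csv(result$stratifications[[key]],
             sprintf("subgroups_%s.csv", gsub("\\.", "_", key)))
  }
  for (key in names(result$effect_grids)) {
    emit_csv(result$effect_grids[[key]], sprintf("effect_grid_%s.csv", key))
  }
  for (key in names(result$difficulty)) {
    emit_csv(result$difficulty[[key]],
             sprintf("item_difficulty_%s.csv", gsub("\\.", "_", key)))
  }
  for (g in names(result$classification)) {
    p <- result$classification[[g]]
    emit_csv(tidy(p), sprintf("null_distribution_%s.csv", g))
    emit_csv(tibble::as_tibble(as.data.frame(p$evaluation$confusion)),
             sprintf("confusion_%s.csv", g))
  }
  summary <- result$summary
  summary$manifest <- c(manifest, "summary.json", "run_log.txt")
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_lines <- c(
    "eyestrat run log",
    sprintf("package version: %s",
            as.character(utils::packageVersion("eyestrat"))),
    sprintf("seed: %s", result$config$seed),
    sprintf("parameters: %s",
            paste(sprintf("%s=%s", names(summary$parameters),
                          unlist(summary$parameters)), collapse = ", ")),
    sprintf("outputs: %s", paste(summary$manifest, collapse = ", "))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(result)
}

#' @export
print.eyestrat_run <- function(x, ...) {
  cat("<eyestrat run>\n")
  for (key in names(x$stratifications)) {
    cat(sprintf("  %s: K = %d\n", key, attr(x$stratifications[[key]], "K")))
  }
  for (g in names(x$classification)) {
    p <- x$classification[[g]]
    cat(sprintf("  classification %s: accuracy %.3f, p = %.4g\n",
                g, p$observed, p$p_value))
  }
  invisible(x)
}
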