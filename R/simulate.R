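#' Build a bank of planted subgroup item-success profiles
#'
#' Constructs a latent-class generative description of a cohort: `K`
#' item-success probability profiles whose expected total scores ascend
#' approximately linearly, emulating the rank-ordered performance gradient
#' seen when clustering real item-level mentalizing data. Two banks are
#' provided:
#'
#' * `"asc_like"` — 5 profiles spanning near-chance to near-ceiling
#'   expected totals, the shape observed for autistic cohorts;
#' * `"td_like"` — 4 profiles with a higher floor, as in typically
#'   developing comparison cohorts.
#'
#' Profiles follow an item-knowledge model: each item has a difficulty and
#' each subgroup an ability; mastered items are answered correctly with
#' probability near the ceiling and unmastered items near `error_floor`.
#' Item difficulty blends a shared backbone (so some items are easier than
#' others for everyone) with a subgroup-specific component (so each
#' subgroup has its own atypically easy and hard items and mastery sets are
#' not simply nested); the subgroup abilities are calibrated so the
#' expected totals hit an evenly spaced ladder from `chance_floor * n_items`
#' up to near ceiling. Candidate profile sets whose minimum pairwise
#' root-mean-square difference falls below a distinctiveness floor are
#' redrawn, so every seed yields clearly distinct planted subgroups.
#'
#' @param kind `"asc_like"` or `"td_like"`.
#' @param n_items Number of items (default 36, the standard task length).
#' @param separation Positive scale factor on the spread of the expected
#'   total-score ladder about its midpoint; 1 gives the default gradient.
#' @param chance_floor Guessing rate anchoring the lowest expected total
#'   (default 0.25, a 4-alternative forced choice).
#' @param error_floor Minimal per-item success probability for unmastered
#'   items (default 0.05): errors on clearly-too-hard items are modelled as
#'   systematic (subjects converge on the same compelling foil), which
#'   yields the high within-subgroup response similarity seen in
#'   low-performing subgroups of real data, rather than independent
#'   guessing noise.
#' @param seed Integer seed fixing the difficulty backbone and the
#'   subgroup-specific components.
#' @return An object of class `cohort_spec`: a list with `kind`, `n_items`,
#'   `K`, `profiles` (K x n_items probability matrix, rows ordered by
#'   expected total), `chance_floor`, `error_floor`, `separation`, `seed`.
#' @examples
#' bank <- profile_bank("asc_like", seed = 1)
#' expected_totals(bank)
#' @export
profile_bank <- function(kind = c("asc_like", "td_like"), n_items = 36,
                         separation = 1, chance_floor = 0.25,
                         error_floor = 0.05, seed = 1) {
  kind <- match.arg(kind)
  if (n_items < 4) {
    abort("`n_items` must be at least 4.", class = "eyestrat_parameter_error")
  }
  if (!is.numeric(separation) || separation <= 0) {
    abort("`separation` must be > 0.", class = "eyestrat_parameter_error")
  }
  K <- if (kind == "asc_like") 5L else 4L
  ceiling_p <- 0.97
  # Expected-total ladder: near-chance (asc) or mid-range (td) up to near
  # ceiling, spread scaled by `separation` about the midpoint.
  lo <- if (kind == "asc_like") chance_floor * n_items + 1 else 0.55 * n_items
  hi <- 0.92 * n_items
  centre <- (lo + hi) / 2
  targets <- centre + separation * (seq(lo, hi, length.out = K) - centre)
  targets <- pmin(pmax(targets, error_floor * n_items + 0.5),
                  ceiling_p * n_items - 0.5)
  rho <- 0.9      # weight of the subgroup-specific difficulty component
  width <- 0.02   # sharpness of the mastery transition
  min_rms <- 0.36 # distinctiveness floor on pairwise profile differences

  build <- function(tau, K) {
    profiles <- matrix(0, nrow = K, ncol = n_items)
    for (k in seq_len(K)) {
      tau_k <- (1 - rho) * tau + rho * runif(n_items)
      gap <- function(theta) {
        sum(error_floor + (ceiling_p - error_floor) *
              plogis((theta - tau_k) / width)) - targets[k]
      }
      theta <- uniroot(gap, c(-3, 4))$root
      profiles[k, ] <- error_floor + (ceiling_p - error_floor) *
        plogis((theta - tau_k) / width)
    }
    profiles
  }
  min_pair_rms <- function(p) {
    pairs <- utils::combn(nrow(p), 2)
    min(apply(pairs, 2, function(ab) {
      sqrt(mean((p[ab[1], ] - p[ab[2], ])^2))
    }))
  }

  withr_seed(seed, {
    tau <- sample(seq(0.02, 0.98, length.out = n_items))
    best <- NULL
    best_rms <- -Inf
    for (try in 1:50) {
      cand <- build(tau, K)
      rms <- min_pair_rms(cand)
      if (rms > best_rms) {
        best <- cand
        best_rms <- rms
      }
      if (best_rms >= min_rms) break
    }
    profiles <- best
  })
  profiles <- profiles[order(rowSums(profiles)), , drop = FALSE]
  colnames(profiles) <- item_names(n_items)
  structure(
    list(kind = kind, n_items = as.integer(n_items), K = K,
         profiles = profiles, chance_floor = chance_floor,
         error_floor = error_floor, separation = separation,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

item_names <- function(n_items) {
  sprintf("item_%02d", seq_len(n_items))
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Expected total scores of a profile bank
#'
#' @param spec A [cohort_spec][profile_bank] object.
#' @return Numeric vector of length `K`: expected total score (sum of
#'   item-success probabilities) per planted subgroup, in label order.
#' @export
expected_totals <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rowSums(spec$profiles)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec: %s, %d profiles x %d items, separation %g>\n",
              x$kind, x$K, x$n_items, x$separation))
  cat("expected totals:", sprintf("%.1f", expected_totals(x)), "\n")
  invisible(x)
}

#' Simulate a latent-class cohort of item responses
#'
#' Draws each subject's responses as independent Bernoulli outcomes from the
#' item-success profile of their planted subgroup (conditional independence
#' given class). Optional per-subject ability jitter perturbs every item
#' probability on the logit scale; optional timeouts overwrite drawn codes
#' at a fixed per-cell rate, emulating non-response on a timed task.
#'
#' @param spec A [cohort_spec][profile_bank].
#' @param n Total number of subjects; divided as evenly as possible across
#'   the planted subgroups. Ignored when `sizes` is given.
#' @param sizes Optional integer vector of per-subgroup subject counts
#'   (length `K`, all positive).
#' @param group,cohort Tags stored in the table's meta columns.
#' @param ability_jitter SD of per-subject logit-scale ability noise
#'   (default 0: pure latent-class draws).
#' @param timeout_rate Per-cell probability that the drawn response is
#'   replaced by a timeout code (default 0).
#' @param seed Integer seed; (spec, arguments, seed) fully determine the
#'   output.
#' @return A wide-format response table (see [read_response_table()]) with
#'   an extra `.planted` integer column holding the planted subgroup label.
#' @examples
#' bank <- profile_bank("td_like", seed = 1)
#' tbl <- simulate_cohort(bank, n = 40, group = "TD", seed = 7)
#' table(tbl$.planted)
#' @export
simulate_cohort <- function(spec, n = NULL, sizes = NULL, group = "ASC",
                            cohort = "discovery", ability_jitter = 0,
                            timeout_rate = 0, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  K <- spec$K
  if (is.null(sizes)) {
    if (is.null(n)) {
      abort("Supply either `n` or `sizes`.", class = "eyestrat_parameter_error")
    }
    sizes <- diff(round(seq(0, n, length.out = K + 1)))
  }
  sizes <- as.integer(sizes)
  if (length(sizes) != K || any(sizes < 1)) {
    abort(sprintf("`sizes` must have %d positive entries (one per planted subgroup).", K),
          class = "eyestrat_parameter_error")
  }
  if (timeout_rate < 0 || timeout_rate >= 1) {
    abort("`timeout_rate` must be in [0, 1).", class = "eyestrat_parameter_error")
  }
  n_items <- spec$n_items
  labels <- rep(seq_len(K), times = sizes)
  n_tot <- length(labels)

  withr_seed(seed, {
    prob <- spec$profiles[labels, , drop = FALSE]
    if (ability_jitter > 0) {
      shift <- rnorm(n_tot, sd = ability_jitter)
      prob <- plogis(qlogis(pmin(pmax(prob, 1e-12), 1 - 1e-12)) + shift)
    }
    draw <- matrix(rbinom(n_tot * n_items, 1L, as.vector(prob)),
                   nrow = n_tot, ncol = n_items)
    codes <- matrix(ifelse(draw == 1L, response_codes[["correct"]],
                           response_codes[["incorrect"]]),
                    nrow = n_tot)
    if (timeout_rate > 0) {
      to <- matrix(runif(n_tot * n_items) < timeout_rate, nrow = n_tot)
      codes[to] <- response_codes[["timeout"]]
    }
  })
  colnames(codes) <- item_names(n_items)
  tbl <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = sprintf("%s_%s_%04d", cohort, group, seq_len(n_tot)),
      group = group, cohort = cohort
    ),
    tibble::as_tibble(codes),
    tibble::tibble(.planted = as.integer(labels))
  )
  tbl
}

#' Simulate a discovery/replication cohort pair from one profile bank
#'
#' Draws two independent cohorts from the same planted profiles, with
#' independently perturbed subgroup mixing proportions — the replication
#' design in which the same latent subgroup structure underlies two
#' separately collected samples.
#'
#' @inheritParams simulate_cohort
#' @param n_discovery,n_replication Cohort sizes (default 400 and 250,
#'   mirroring the scale of the original discovery/replication samples).
#' @param seed Integer seed; the two cohorts use independent streams
#'   derived from it.
#' @return Named list of two response tables, `discovery` and
#'   `replication`, each carrying its `.planted` labels.
#' @export
simulate_cohort_pair <- function(spec, n_discovery = 400, n_replication = 250,
                                 group = "ASC", ability_jitter = 0,
                                 timeout_rate = 0, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (n_discovery < spec$K || n_replication < spec$K) {
    abort("Each cohort needs at least one subject per planted subgroup.",
          class = "eyestrat_parameter_error")
  }
  mix_sizes <- function(n, s) {
    withr_seed(s, {
      w <- 1 + runif(spec$K, -0.3, 0.3)
    })
    p <- w / sum(w)
    sz <- pmax(1L, as.integer(round(p * n)))
    # adjust largest subgroup so sizes sum exactly to n
    sz[which.max(sz)] <- sz[which.max(sz)] + (n - sum(sz))
    sz
  }
  list(
    discovery = simulate_cohort(
      spec, sizes = mix_sizes(n_discovery, seed * 2 + 1), group = group,
      cohort = "discovery", ability_jitter = ability_jitter,
      timeout_rate = timeout_rate, seed = seed * 2 + 2
    ),
    replication = simulate_cohort(
      spec, sizes = mix_sizes(n_replication, seed * 2 + 3), group = group,
      cohort = "replication", ability_jitter = ability_jitter,
      timeout_rate = timeout_rate, seed = seed * 2 + 4
    )
  )
}
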