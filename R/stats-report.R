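# Group-level statistics: Mann-Whitney U, per-frequency FDR screening,
# per-animal aggregation, and simulation-based power analysis.

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two groups via [stats::wilcox.test()]: the exact
#' distribution is used when the smaller group has at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. The reported U counts pairs where an `a` value
#' exceeds a `b` value (so `a = 1:3`, `b = 4:6` gives U = 0).
#'
#' @param a,b Numeric vectors, both nonempty.
#' @return A one-row tibble: `u_statistic`, `p_value`, `n_a`, `n_b`, `exact`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    u_statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_a = length(a),
    n_b = length(b),
    exact = exact
  )
}

#' Two-group comparison of a metric with provenance
#'
#' Tidy wrapper around [mann_whitney_u()] for a long data frame: splits
#' `value` by the two levels of `group`, reports mean +/- SEM per group and
#' the U test.
#'
#' @param df A data frame.
#' @param value Column with the metric values (tidy-eval).
#' @param group Column with exactly two group levels (tidy-eval).
#' @param metric Optional metric name stored in the output.
#' @return A one-row tibble: `metric`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `mean_a`, `sem_a`, `mean_b`, `sem_b`, `u_statistic`, `p_value`.
#' @export
compare_groups <- function(df, value, group, metric = NULL) {
  v <- dplyr::pull(df, {{ value }})
  g <- dplyr::pull(df, {{ group }})
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- as.character(g[keep])
  lev <- sort(unique(g))
  if (length(lev) != 2L) {
    stop("group column must have exactly two levels", call. = FALSE)
  }
  a <- v[g == lev[1]]
  b <- v[g == lev[2]]
  mw <- mann_whitney_u(a, b)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  tibble::tibble(
    metric = metric %||% "value",
    group_a = lev[1], group_b = lev[2],
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), sem_a = sem(a),
    mean_b = mean(b), sem_b = sem(b),
    u_statistic = mw$u_statistic,
    p_value = mw$p_value
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Per-frequency group comparison with FDR screening
#'
#' Mann-Whitney U at each frequency step of per-session power spectra,
#' corrected for multiple comparisons with the Benjamini-Hochberg false
#' discovery rate: a step is significant when its BH-adjusted p-value is
#' below `q`.
#'
#' @param spectra Long tibble with columns `group`, `session_id`, `freq_hz`,
#'   `power` (e.g. rows of [session_power_spectrum()]).
#' @param q FDR level (default 0.05).
#' @param freqs Optional frequency subset; must lie within the spectra's
#'   range.
#' @return A tibble with one row per frequency: `freq_hz`, `p_value`,
#'   `q_value`, `significant`.
#' @export
per_frequency_comparison <- function(spectra, q = 0.05, freqs = NULL) {
  if (!is.null(freqs)) {
    rng <- range(spectra$freq_hz)
    if (any(freqs < rng[1] | freqs > rng[2])) {
      stop("requested frequencies fall outside the analyzed range",
           call. = FALSE)
    }
    spectra <- dplyr::filter(spectra, .data$freq_hz %in% freqs)
  }
  lev <- sort(unique(as.character(spectra$group)))
  if (length(lev) != 2L) {
    stop("spectra must contain exactly two groups", call. = FALSE)
  }
  n_per <- spectra |>
    dplyr::distinct(.data$group, .data$session_id) |>
    dplyr::count(.data$group)
  if (any(n_per$n < 3L)) {
    stop("need at least 3 sessions per group", call. = FALSE)
  }
  out <- spectra |>
    dplyr::group_by(.data$freq_hz) |>
    dplyr::group_modify(function(d, key) {
      mann_whitney_u(d$power[d$group == lev[1]],
                     d$power[d$group == lev[2]])[, "p_value"]
    }) |>
    dplyr::ungroup()
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < q
  out
}

#' Average session values into one value per animal
#'
#' Unweighted mean of each animal's session values, e.g. to re-test group
#' differences under the assumption that within-animal recordings are
#' dominated by volume-conducted currents.
#'
#' @param df A data frame with an animal identifier column.
#' @param value Value column (tidy-eval).
#' @param animal Animal identifier column (tidy-eval, default `animal_id`).
#' @param ... Additional grouping columns kept in the output (e.g. `group`).
#' @return A tibble with one row per animal (per extra grouping combination).
#' @export
aggregate_per_animal <- function(df, value, animal = animal_id, ...) {
  df |>
    dplyr::group_by({{ animal }}, ...) |>
    dplyr::summarise(value = mean({{ value }}, na.rm = TRUE),
                     .groups = "drop")
}

#' Simulation-based sample size for a target power
#'
#' Monte-Carlo estimate of the smallest equal group size at which the
#' two-sided Mann-Whitney U test rejects at level `alpha` with frequency at
#' least `power_target` (default 0.9). Power is estimated on a doubling grid
#' followed by bisection; when even `n_max` does not reach the target (e.g. a
#' null effect, where power equals alpha) the result is flagged unattainable.
#'
#' @param rdist_a,rdist_b Functions of `n` returning one simulated group.
#' @param power_target Target power (default 0.9).
#' @param alpha Test level (default 0.05).
#' @param reps Simulations per candidate n (>= 1000).
#' @param n_min,n_max Search bounds on the per-group sample size.
#' @param seed Optional seed for the simulation stream.
#' @return A list: `n` (NA when unattainable), `power` (estimated power at
#'   `n`), `attainable`, `alpha`, `power_target`, `reps`.
#' @export
power_sample_size <- function(rdist_a, rdist_b, power_target = 0.9,
                              alpha = 0.05, reps = 1000, n_min = 2,
                              n_max = 200, seed = NULL) {
  if (reps < 1000) stop("reps must be at least 1000", call. = FALSE)
  with_seed(seed, {
    est <- function(n) {
      rej <- logical(reps)
      for (r in seq_len(reps)) {
        rej[r] <- suppressWarnings(
          stats::wilcox.test(rdist_a(n), rdist_b(n))$p.value) < alpha
      }
      mean(rej)
    }
    n <- n_min
    pow <- est(n)
    while (pow < power_target && n < n_max) {
      n <- min(2 * n, n_max)
      pow <- est(n)
    }
    if (pow < power_target) {
      return(list(n = NA_integer_, power = pow, attainable = FALSE,
                  alpha = alpha, power_target = power_target, reps = reps))
    }
    lo <- max(n_min, n %/% 2) # smallest n known to fail, roughly
    hi <- n
    pow_hi <- pow
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      pm <- est(mid)
      if (pm >= power_target) {
        hi <- mid
        pow_hi <- pm
      } else {
        lo <- mid
      }
    }
    list(n = as.integer(hi), power = pow_hi, attainable = TRUE,
         alpha = alpha, power_target = power_target, reps = reps)
  })
}
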