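test_that("Mann-Whitney U matches enumeration and symmetry landmarks", {
  r <- mann_whitney_u(1:3, 4:6)
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 0.1) # 2/20 extreme assignments
  expect_true(r$exact)

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.99)

  set.seed(71)
  big <- mann_whitney_u(rnorm(30), rnorm(30) + 2)
  expect_lt(big$p_value, 0.001)

  # label symmetry
  a <- rnorm(12); b <- rnorm(15)
  expect_equal(mann_whitney_u(a, b)$p_value, mann_whitney_u(b, a)$p_value,
               tolerance = 1e-12)
  expect_equal(mann_whitney_u(a, b)$u_statistic,
               length(a) * length(b) - mann_whitney_u(b, a)$u_statistic)

  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("exact p-values equal brute-force enumeration for all small shapes", {
  set.seed(72)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      for (rep in 1:3) {
        vals <- sample(1:100, na + nb) # tie-free
        a <- vals[1:na]; b <- vals[-(1:na)]
        got <- mann_whitney_u(a, b)
        oracle <- brute_force_mwu(a, b)
        expect_equal(got$u_statistic, oracle$u, info = sprintf("n=%d,%d", na, nb))
        expect_equal(got$p_value, oracle$p, tolerance = 1e-12,
                     info = sprintf("n=%d,%d", na, nb))
      }
    }
  }
})

test_that("per-frequency screening localizes effects and calibrates under null", {
  freqs <- seq(0.4, 10, by = 0.2)
  make_spectra <- function(gain_at = NULL, seed) {
    set.seed(seed)
    rows <- list()
    for (g in c("A", "B")) {
      for (s in 1:8) {
        base <- 10 / freqs + rnorm(length(freqs), 0, 0.15)
        if (g == "B" && !is.null(gain_at)) {
          hit <- abs(freqs - gain_at) <= 0.3
          base[hit] <- base[hit] * 2
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group = g, session_id = paste0(g, s), freq_hz = freqs, power = base)
      }
    }
    dplyr::bind_rows(rows)
  }

  null_sp <- make_spectra(seed = 73)
  r0 <- per_frequency_comparison(null_sp)
  expect_identical(sum(r0$significant), 0L)

  eff_sp <- make_spectra(gain_at = 3.5, seed = 74)
  r1 <- per_frequency_comparison(eff_sp)
  expect_gt(sum(r1$significant), 0)
  expect_true(all(abs(r1$freq_hz[r1$significant] - 3.5) <= 0.4))

  # permutation calibration: shuffled labels rarely pass the FDR gate
  set.seed(75)
  fractions <- vapply(1:100, function(i) {
    shuf <- eff_sp
    key <- unique(shuf[c("group", "session_id")])
    key$new_group <- sample(key$group)
    shuf <- dplyr::left_join(shuf, key, by = c("group", "session_id"))
    shuf$group <- shuf$new_group
    mean(per_frequency_comparison(shuf)$significant)
  }, numeric(1))
  expect_lte(mean(fractions), 0.05)

  # BH monotonicity: discoveries at q = 0.01 survive at q = 0.05
  r_strict <- per_frequency_comparison(eff_sp, q = 0.01)
  r_loose <- per_frequency_comparison(eff_sp, q = 0.05)
  expect_true(all(!r_strict$significant | r_loose$significant))

  expect_error(per_frequency_comparison(eff_sp, freqs = c(50)), "outside")
  few <- dplyr::filter(eff_sp, session_id %in% c("A1", "A2", "A3", "B1"))
  expect_error(per_frequency_comparison(few), "3 sessions")
})

test_that("per-animal aggregation averages sessions and keeps direction", {
  df <- tibble::tibble(
    animal_id = c("a1", "a1", "a2", "b1", "b1", "b2"),
    group = c("A", "A", "A", "B", "B", "B"),
    value = c(0.1, 0.2, 0.3, 0.6, 0.8, 0.7)
  )
  agg <- aggregate_per_animal(df, value, animal_id, group)
  expect_identical(nrow(agg), 4L)
  expect_equal(agg$value[agg$animal_id == "a1"], 0.15)
  # one session per animal is the identity
  one <- aggregate_per_animal(df[c(3, 6), ], value, animal_id)
  expect_equal(sort(one$value), c(0.3, 0.7))
  # aggregation preserves the session-level direction of the effect
  cmp_sess <- compare_groups(df, value, group)
  cmp_anim <- compare_groups(agg, value, group)
  expect_identical(sign(cmp_sess$mean_b - cmp_sess$mean_a),
                   sign(cmp_anim$mean_b - cmp_anim$mean_a))
})

test_that("simulated power analysis finds minimal n and flags null effects", {
  ps <- power_sample_size(function(n) rnorm(n), function(n) rnorm(n, 3),
                          reps = 1000, seed = 76)
  expect_true(ps$attainable)
  expect_lte(ps$n, 6)
  expect_gte(ps$power, 0.9)

  ps0 <- power_sample_size(function(n) rnorm(n), function(n) rnorm(n),
                           reps = 1000, n_max = 16, seed = 77)
  expect_false(ps0$attainable)
  expect_true(is.na(ps0$n))

  # power is nondecreasing in n for a fixed positive effect (MC slack)
  set.seed(78)
  pow_at <- function(n, reps = 800) {
    mean(vapply(seq_len(reps), function(i) {
      suppressWarnings(stats::wilcox.test(rnorm(n), rnorm(n, 1.2))$p.value) <
        0.05
    }, logical(1)))
  }
  pows <- vapply(c(4, 8, 16), pow_at, numeric(1))
  expect_true(all(diff(pows) > -0.05))

  expect_error(power_sample_size(rnorm, rnorm, reps = 10), "1000")
})
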