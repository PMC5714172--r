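test_that("generators are pure functions of truth and seed, and leave
          the global RNG untouched", {
  f_grid <- seq(0, 1, by = 0.25)
  set.seed(999)
  before <- .Random.seed
  t1 <- gen_mixing_dataset("mm_13_24", "equilibrated", "strict_gate",
                           f_grid, noise_spec(sd = 0.05, seed = 5))
  expect_identical(.Random.seed, before)
  t2 <- gen_mixing_dataset("mm_13_24", "equilibrated", "strict_gate",
                           f_grid, noise_spec(sd = 0.05, seed = 5))
  t3 <- gen_mixing_dataset("mm_13_24", "equilibrated", "strict_gate",
                           f_grid, noise_spec(sd = 0.05, seed = 6))
  expect_identical(t1, t2)
  expect_false(isTRUE(all.equal(t1$SC, t3$SC)))
  expect_error(noise_spec(sd = 0.05), "seed")
})

test_that("noise-free generators reproduce the upstream curves exactly
          and satisfy their invariants", {
  f_grid <- seq(0, 1, by = 0.2)
  tab <- gen_mixing_dataset("dd_13_24", "equilibrated", "strict_gate",
                            f_grid, noise_spec(sd = 0, seed = 1))
  cv <- mix_curve("dd_13_24", "equilibrated", "strict_gate", f_grid)
  expect_equal(as.matrix(tab[, c("SC", "N", "L", "EX")]),
               curve_fractions(cv), ignore_attr = TRUE, tolerance = 1e-12)
  expect_s3_class(tab, "quant_table")

  times <- seq(0, 4, by = 1)
  tct <- gen_timecourse_dataset("mm_13_24", c("active", "dead"),
                                kinetic_rates(), times,
                                noise_spec(sd = 0, seed = 1))
  tc <- simulate_timecourse("mm_13_24", subunit_states = c("active", "dead"),
                            rates = kinetic_rates(), times = times)
  expect_equal(tct$N, tc$N, tolerance = 1e-12)

  ex0 <- gen_exchange_dataset(0.5, 1, c(0, 1e4), noise_spec(sd = 0, seed = 1))
  expect_equal(unlist(ex0[1, -1], use.names = FALSE), c(0.5, 0, 0.5))
  expect_equal(unlist(ex0[2, -1], use.names = FALSE), c(0.25, 0.5, 0.25),
               tolerance = 1e-9)
})

test_that("noisy lanes remain valid fractions summing to one", {
  tab <- gen_mixing_dataset("mm_12_34", "equilibrated", "strict_gate",
                            seq(0, 1, by = 0.1),
                            noise_spec(sd = 0.1, seed = 11))
  fr <- as.matrix(tab[, c("SC", "N", "L", "EX")])
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(rowSums(fr), rep(1, nrow(fr)), tolerance = 1e-12)
})

test_that("the exchange rate is recoverable within 25% from noisy
          series across 50 seeds", {
  truth <- 0.2
  times <- seq(0, 16, by = 1)
  est <- vapply(seq_len(50), function(s) {
    d <- gen_exchange_dataset(0.5, truth, times, noise_spec(0.02, seed = s))
    fit_exchange_rate(d)
  }, numeric(1))
  rel <- abs(est - truth) / truth
  expect_lt(stats::median(rel), 0.25)
  expect_gte(mean(rel <= 0.25), 0.9)
})

test_that("the gate leak factor is recoverable within a factor of two
          from noisy time courses across 50 seeds", {
  truth <- 0.1
  times <- seq(0, 4, by = 0.5)
  est <- vapply(seq_len(50), function(s) {
    d <- gen_timecourse_dataset("mm_13_24", c("active", "dead"),
                                kinetic_rates(leak = truth), times,
                                noise_spec(0.03, seed = 100 + s))
    fit_leak(d, "mm_13_24", c("active", "dead"), kinetic_rates())
  }, numeric(1))
  within2 <- est >= truth / 2 & est <= truth * 2
  expect_gte(mean(within2), 0.9)
  expect_true(stats::median(est) >= truth / 2 &&
              stats::median(est) <= truth * 2)
})
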