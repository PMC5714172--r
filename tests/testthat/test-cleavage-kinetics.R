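test_that("wild-type complexes complete excision; probability is
          conserved along the way", {
  tc <- simulate_timecourse("mm_13_24",
                            subunit_states = c("active", "active"),
                            rates = kinetic_rates(),
                            times = c(0, 0.5, 1, 2, 4, 50))
  expect_equal(tc$SC + tc$N + tc$L + tc$EX, rep(1, nrow(tc)),
               tolerance = 1e-8)
  expect_equal(tc$EX[nrow(tc)], 1, tolerance = 1e-6)
  expect_equal(unlist(tc[1, c("SC", "N", "L", "EX")], use.names = FALSE),
               c(1, 0, 0, 0))
  expect_true(all(diff(tc$SC) <= 1e-10))   # substrate only decays
  expect_true(all(diff(tc$EX) >= -1e-10))  # excision only accumulates
})

test_that("a crippled cis heterodimer reduces to the SC -> N -> L chain:
          nicked intermediate rises then falls, linear takes over", {
  k5 <- 3; k3 <- 3; leak <- 0.1
  rates <- kinetic_rates(k5 = k5, k3 = k3, leak = leak)
  times <- c(0, 0.25, 0.5, 1, 2, 4, 8, 200)
  tc <- simulate_timecourse("mm_13_24", subunit_states = c("active", "dead"),
                            rates = rates, times = times)
  # closed-form two-step chain with rates k5 then leak * k3
  a <- k5; b <- leak * k3
  expect_equal(tc$SC, exp(-a * times), tolerance = 1e-7)
  expect_equal(tc$N, a * (exp(-a * times) - exp(-b * times)) / (b - a),
               tolerance = 1e-7)
  expect_equal(tc$L, 1 - tc$SC - tc$N, tolerance = 1e-7)
  expect_equal(tc$EX, rep(0, length(times)))
  # rise-then-fall of the nicked intermediate (analytic peak ~0.774 at
  # t ~0.85 h), full conversion to linear
  expect_gt(max(tc$N), 0.7)
  expect_lt(tc$N[length(times)], 1e-6)
  expect_equal(tc$L[length(times)], 1, tolerance = 1e-6)
})

test_that("the trans heterodimer cannot linearize when 3' nicks require
          the same-end 5' nick (the kinetic discriminator)", {
  rates <- kinetic_rates(leak = 1, local_requirement = TRUE)
  for (states in list(c("active", "dead"), c("dead", "active"))) {
    tc <- simulate_timecourse("mm_14_23", subunit_states = states,
                              rates = rates, times = c(0, 1, 4, 100))
    expect_equal(tc$L, rep(0, 4), info = paste(states, collapse = ","))
    expect_equal(tc$EX, rep(0, 4))
    expect_equal(tc$N[4], 1, tolerance = 1e-6)  # stuck as open circle
  }
  # whereas the cis heterodimer linearizes under the same rule
  tc <- simulate_timecourse("mm_13_24", subunit_states = c("active", "dead"),
                            rates = rates, times = c(0, 100))
  expect_equal(tc$L[2], 1, tolerance = 1e-6)
})

test_that("kinetic endpoints coincide with the endpoint predictor:
          leak 0 = strict gate, leak 1 = per-end gate, leak 1 without
          the local requirement = unordered", {
  cases <- list(
    list(rates = kinetic_rates(leak = 0), ordering = "strict_gate"),
    list(rates = kinetic_rates(leak = 1), ordering = "per_end_gate"),
    list(rates = kinetic_rates(leak = 1, local_requirement = FALSE),
         ordering = "none")
  )
  fs <- seq(0, 1, length.out = 5)
  for (cs in cases) {
    for (nm in cleavage_model_names()) {
      for (f in fs) {
        tc <- simulate_timecourse(nm, scenario = "equilibrated", f = f,
                                  rates = cs$rates, times = 400)
        got <- unlist(tc[1, c("SC", "N", "L", "EX")])
        want <- predict_endpoint(nm, "equilibrated", cs$ordering, f)
        expect_equal(got, want, tolerance = 1e-6,
                     info = paste(nm, cs$ordering, "f =", f))
      }
    }
  }
})

test_that("adaptive integration matches the matrix-exponential solution
          on random rate draws", {
  skip_if_not_installed("Matrix")
  set.seed(20)
  for (rep in 1:6) {
    nm <- sample(cleavage_model_names(), 1)
    n_slots <- length(cleavage_model(nm)$slot_assignment)
    act <- stats::runif(n_slots) > 0.3
    rates <- kinetic_rates(k5 = stats::runif(1, 0.5, 5),
                           k3 = stats::runif(1, 0.5, 5),
                           leak = stats::runif(1),
                           k_ex_int = stats::runif(1, 0.2, 2))
    times <- c(0.3, 1.7)
    tc <- simulate_timecourse(nm, subunit_states = act, rates = rates,
                              times = times)
    Q <- marinercleave:::.kinetic_generator(cleavage_model(nm), act, rates)
    p0 <- c(1, rep(0, 16))
    for (i in seq_along(times)) {
      pe <- as.vector(Matrix::expm(t(Q) * times[i]) %*% p0)
      expect_equal(unname(attr(tc, "states")[i, ]), pe, tolerance = 1e-6,
                   info = paste(nm, "t =", times[i]))
    }
  }
})

test_that("5' nicks lead 3' nicks, and crippled heterodimers delay the
          3' chase relative to wild type", {
  times <- seq(0, 4, by = 0.25)
  rates <- kinetic_rates(k5 = 6, k3 = 1, leak = 0.1)
  wt <- strand_cleavage_fractions(
    simulate_timecourse("mm_13_24", subunit_states = c("active", "active"),
                        rates = rates, times = times))
  mut <- strand_cleavage_fractions(
    simulate_timecourse("mm_13_24", subunit_states = c("active", "dead"),
                        rates = rates, times = times))
  expect_equal(unlist(wt[1, -1], use.names = FALSE), c(0, 0))
  # ordering visible: 5' fraction bounds 3' fraction at every time
  expect_true(all(wt$frac_5p_nicked >= wt$frac_3p_nicked - 1e-10))
  expect_true(all(mut$frac_5p_nicked >= mut$frac_3p_nicked - 1e-10))
  # with k5 >> k3 the 5' wave clearly precedes the 3' wave
  expect_gt(wt$frac_5p_nicked[5], wt$frac_3p_nicked[5] + 0.2)
  # mutant 3' nicking delayed at every matched (positive) time
  expect_true(all(mut$frac_3p_nicked[-1] < wt$frac_3p_nicked[-1]))
})

test_that("the excision-to-integration rate does not alter class
          fractions (EX lumps both species)", {
  for (kei in c(0.1, 1, 10)) {
    tc <- simulate_timecourse("mm_13_24",
                              subunit_states = c("active", "active"),
                              rates = kinetic_rates(k_ex_int = kei),
                              times = c(0.5, 2))
    if (kei == 0.1) ref <- tc
    expect_equal(tc$EX, ref$EX, tolerance = 1e-9)
    expect_equal(tc$N, ref$N, tolerance = 1e-9)
  }
})

test_that("kinetics inputs are validated", {
  expect_error(kinetic_rates(leak = 1.5))
  expect_error(simulate_timecourse("mm_13_24", times = c(1, 0.5)),
               "increasing")
  expect_error(simulate_timecourse("mm_13_24",
                                   subunit_states = c("active")),
               "expected 2")
  expect_error(simulate_timecourse("mm_13_24"), "subunit_states or scenario")
})
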