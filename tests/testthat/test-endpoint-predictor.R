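grid101 <- seq(0, 1, length.out = 101)

test_that("exhaustive enumeration agrees with the closed forms at 101
          grid points for every derivable case", {
  for (nm in cleavage_model_names()) {
    for (sc in c("equilibrated", "homodimers_only")) {
      for (f in grid101) {
        cf <- closed_form_endpoint(nm, sc, "strict_gate", f)
        expect_false(is.null(cf))
        expect_equal(predict_endpoint(nm, sc, "strict_gate", f), cf,
                     tolerance = 1e-9, info = paste(nm, sc, f))
      }
    }
  }
  expect_null(closed_form_endpoint("mm_13_24", "equilibrated", "none", 0.5))
})

test_that("fully active complexes excise everything; fully dead leave
          supercoiled substrate", {
  for (nm in cleavage_model_names()) {
    for (sc in c("equilibrated", "homodimers_only")) {
      for (ord in c("strict_gate", "per_end_gate", "none")) {
        expect_equal(predict_endpoint(nm, sc, ord, 0),
                     c(SC = 0, N = 0, L = 0, EX = 1), info = paste(nm, sc, ord))
        expect_equal(predict_endpoint(nm, sc, ord, 1),
                     c(SC = 1, N = 0, L = 0, EX = 0), info = paste(nm, sc, ord))
      }
    }
  }
})

test_that("the graph equivalences hold: mm models collapse without
          pre-equilibration, per-end dd variants are indistinguishable,
          and the unique models stay unique", {
  fs <- seq(0, 1, by = 0.1)
  pred <- function(nm, sc) t(vapply(fs, function(f)
    predict_endpoint(nm, sc, "strict_gate", f), numeric(4)))
  # (i) all three mm models identical with homodimers only
  p_mm <- pred("mm_13_24", "homodimers_only")
  expect_equal(pred("mm_14_23", "homodimers_only"), p_mm, tolerance = 1e-12)
  expect_equal(pred("mm_12_34", "homodimers_only"), p_mm, tolerance = 1e-12)
  # (ii) dd_13_24 and dd_14_23 identical under both scenarios
  for (sc in c("homodimers_only", "equilibrated")) {
    expect_equal(pred("dd_14_23", sc), pred("dd_13_24", sc),
                 tolerance = 1e-12, info = sc)
  }
  # (iii) mm_13_24 and mm_14_23 identical under binomial mixing
  expect_equal(pred("mm_14_23", "equilibrated"),
               pred("mm_13_24", "equilibrated"), tolerance = 1e-12)
  # (iv) mm_12_34 differs from both on the open interval
  d <- abs(pred("mm_12_34", "equilibrated") - pred("mm_13_24", "equilibrated"))
  expect_gt(max(d[fs > 0 & fs < 1, ]), 0.05)
  # (v) dd_12_34 yields a unique distribution without pre-equilibration
  d <- abs(pred("dd_12_34", "homodimers_only") -
           pred("dd_13_24", "homodimers_only"))
  expect_gt(max(d[fs > 0 & fs < 1, ]), 0.05)
})

test_that("substrate consumption is monotone in the mutant fraction", {
  fs <- seq(0, 1, by = 0.05)
  for (nm in cleavage_model_names()) {
    for (sc in c("equilibrated", "homodimers_only")) {
      for (ord in c("strict_gate", "per_end_gate", "none")) {
        m <- t(vapply(fs, function(f) predict_endpoint(nm, sc, ord, f),
                      numeric(4)))
        expect_true(all(diff(m[, "SC"]) >= -1e-12), info = paste(nm, sc, ord))
        expect_true(all(diff(m[, "EX"]) <= 1e-12), info = paste(nm, sc, ord))
        expect_equal(rowSums(m), rep(1, length(fs)), tolerance = 1e-9)
      }
    }
  }
})

test_that("Monte-Carlo sampling of complexes reproduces the enumeration
          within 4 standard errors", {
  n <- 1e5
  cases <- list(
    list("mm_13_24", "equilibrated", "strict_gate", 0.5, 11),
    list("dd_13_24", "equilibrated", "strict_gate", 0.25, 12),
    list("dd_12_34", "homodimers_only", "strict_gate", 0.4, 13),
    list("mm_13_24", "equilibrated", "per_end_gate", 0.5, 14),
    list("mm_12_34", "equilibrated", "none", 0.3, 15)
  )
  for (cs in cases) {
    mc <- mc_endpoint(cs[[1]], cs[[2]], cs[[3]], cs[[4]], n, seed = cs[[5]])
    ex <- predict_endpoint(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    se <- sqrt(pmax(ex * (1 - ex), 1e-12) / n)
    expect_true(all(abs(mc - ex) <= 4 * se + 1e-12),
                info = paste(cs[[1]], cs[[2]], cs[[3]], "f =", cs[[4]]))
  }
})

test_that("mix_curve validates its grid and reproduces closed shapes", {
  expect_error(mix_curve("mm_13_24", f_grid = numeric(0)), "nonempty")
  expect_error(mix_curve("mm_13_24", f_grid = c(0.5, 0.2)), "increasing")
  expect_error(mix_curve("mm_13_24", f_grid = c(-0.1, 0.5)), "\\[0, 1\\]")
  cv <- mix_curve("mm_13_24", "homodimers_only", "strict_gate",
                  seq(0, 1, by = 0.1))
  expect_equal(cv$SC, cv$f, tolerance = 1e-12)  # linear Graph-1 shape
  ends <- mix_curve("dd_13_24", "equilibrated", "strict_gate", c(0, 1))
  expect_equal(unname(curve_fractions(ends)[1, ]), c(0, 0, 0, 1))
  expect_equal(unname(curve_fractions(ends)[2, ]), c(1, 0, 0, 0))
})

test_that("peak_product refines the grid maximum and breaks ties toward
          smaller mutant fractions", {
  cv <- mix_curve("dd_13_24", "equilibrated", "strict_gate",
                  seq(0, 1, by = 0.05))
  pk <- peak_product(cv, "L")
  expect_equal(unname(pk["f_at_max"]), 0.25, tolerance = 1e-4)
  expect_equal(unname(pk["max_fraction"]), 27 / 128, tolerance = 1e-8)

  cv <- mix_curve("mm_13_24", "equilibrated", "strict_gate",
                  seq(0, 1, by = 0.1))  # grid straddles the peak
  pk <- peak_product(cv, "N")
  expect_equal(unname(pk["f_at_max"]), 0.5, tolerance = 1e-4)
  expect_equal(unname(pk["max_fraction"]), 0.5, tolerance = 1e-8)

  cv <- mix_curve("mm_13_24", "homodimers_only", "strict_gate")
  pk <- peak_product(cv, "L")  # identically zero: smallest f wins
  expect_equal(unname(pk), c(0, 0))
  expect_error(peak_product(cv, "BB"), "invalid product")
})
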