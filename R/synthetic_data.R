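#' Densitometry noise specification
#'
#' Additive truncated-Gaussian noise applied to product fractions: each
#' fraction receives independent `N(0, sd)` noise, is clipped to
#' `[0, 1]`, and the lane is renormalized to sum to 1. The seed is a
#' mandatory part of the specification — every generator in the package
#' is a pure function of (truth, seed) and leaves the global RNG state
#' untouched.
#'
#' @param sd Nonnegative noise standard deviation (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd = 0.05, seed) {
  stopifnot(is.numeric(sd), length(sd) == 1L, sd >= 0)
  if (missing(seed)) stop("noise_spec requires an explicit seed",
                          call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_spec")
}

# run expr with a local RNG seed, restoring global state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.apply_fraction_noise <- function(fr, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sd == 0) return(fr)
  .with_seed(noise$seed, {
    noisy <- fr + matrix(stats::rnorm(length(fr), sd = noise$sd),
                         nrow = nrow(fr))
    noisy <- pmin(pmax(noisy, 0), 1)
    tot <- rowSums(noisy)
    tot[tot == 0] <- 1
    noisy / tot
  })
}

#' Synthetic mixing-series dataset
#'
#' Emulates the gel quantification of a transposase mixing experiment:
#' the endpoint [mix_curve()] of the generating truth plus per-lane
#' densitometry noise.
#'
#' @param model,scenario,ordering The generating truth (see
#'   [predict_endpoint()]).
#' @param f_grid Mutant-fraction grid (one lane each).
#' @param noise A [noise_spec()].
#' @return A [quant_table()] with `series = "mixing"`.
#' @examples
#' gen_mixing_dataset("mm_13_24", "equilibrated",
#'                    f_grid = seq(0, 1, by = 0.25),
#'                    noise = noise_spec(sd = 0.05, seed = 42))
#' @export
gen_mixing_dataset <- function(model, scenario = "equilibrated",
                               ordering = "strict_gate",
                               f_grid = seq(0, 1, by = 1 / 6),
                               noise = noise_spec(sd = 0.05, seed = 1)) {
  cv <- mix_curve(model, scenario, ordering, f_grid)
  fr <- .apply_fraction_noise(as.matrix(cv[, c("SC", "N", "L", "EX")]), noise)
  df <- data.frame(lane = seq_len(nrow(cv)), f = cv$f, fr)
  quant_table(df, series = "mixing",
              scenario_label = paste(attr(cv, "model"),
                                     .as_scenario(scenario)$mode,
                                     attr(cv, "ordering"), sep = "/"))
}

#' Synthetic kinetic time-course dataset
#'
#' Emulates sampling a transposition reaction over time: the
#' [simulate_timecourse()] of the generating truth plus densitometry
#' noise on the product fractions.
#'
#' @param model Cleavage model of the truth.
#' @param subunit_states Per-slot catalytic states (see
#'   [simulate_timecourse()]).
#' @param rates A [kinetic_rates()].
#' @param times Sampling times (hours).
#' @param noise A [noise_spec()].
#' @return A [quant_table()] with `series = "timecourse"`.
#' @export
gen_timecourse_dataset <- function(model,
                                   subunit_states = c("active", "active"),
                                   rates = kinetic_rates(),
                                   times = seq(0, 4, by = 0.5),
                                   noise = noise_spec(sd = 0.05, seed = 1)) {
  tc <- simulate_timecourse(model, subunit_states = subunit_states,
                            rates = rates, times = times)
  fr <- .apply_fraction_noise(as.matrix(tc[, c("SC", "N", "L", "EX")]), noise)
  df <- data.frame(lane = seq_len(nrow(tc)), time_h = tc$time_h, fr)
  quant_table(df, series = "timecourse",
              scenario_label = attr(tc, "model"))
}

#' Synthetic subunit-exchange dataset
#'
#' Emulates the dimer-species abundances measured during subunit
#' exchange of two homodimer pools (e.g. long/short tagged dimers on gel
#' filtration): the [exchange_timecourse()] trajectory plus additive
#' noise, clipped and renormalized per time point.
#'
#' @param f Fraction of species-Y monomers (0.5 for an equimolar mix).
#' @param exchange_rate Per-hour dissociation rate.
#' @param times Sampling times (hours).
#' @param noise A [noise_spec()].
#' @return Data frame with columns `time_h`, `p_XX`, `p_XY`, `p_YY`.
#' @export
gen_exchange_dataset <- function(f = 0.5, exchange_rate = 0.2,
                                 times = seq(0, 16, by = 1),
                                 noise = noise_spec(sd = 0.02, seed = 1)) {
  init <- c(XX = 1 - f, XY = 0, YY = f)
  tc <- exchange_timecourse(init, exchange_rate, times)
  fr <- .apply_fraction_noise(as.matrix(tc[, c("p_XX", "p_XY", "p_YY")]),
                              noise)
  out <- data.frame(time_h = tc$time_h, fr)
  names(out) <- c("time_h", "p_XX", "p_XY", "p_YY")
  out
}

#' Recover the exchange rate from a noisy species time course
#'
#' Least-squares estimate of the dissociation rate underlying an
#' exchange dataset, by golden-section search on the analytic
#' exponential-relaxation trajectory.
#'
#' @param data A data frame as produced by [gen_exchange_dataset()].
#' @param f Monomer fraction of species Y (defaults to the value implied
#'   by the first row).
#' @param interval Search interval for the rate (per hour).
#' @return Estimated rate (per hour).
#' @export
fit_exchange_rate <- function(data, f = NULL, interval = c(1e-4, 20)) {
  stopifnot(all(c("time_h", "p_XX", "p_XY", "p_YY") %in% names(data)))
  if (is.null(f)) f <- data$p_YY[1] + data$p_XY[1] / 2
  obs <- as.matrix(data[, c("p_XX", "p_XY", "p_YY")])
  init <- c(XX = 1 - f, XY = 0, YY = f)
  sse <- function(k) {
    pred <- exchange_timecourse(init, k, data$time_h)
    sum((obs - as.matrix(pred[, c("p_XX", "p_XY", "p_YY")]))^2)
  }
  stats::optimize(sse, interval = interval)$minimum
}

#' Recover the 3'-nick leak factor from a noisy time course
#'
#' Grid-search estimate of the global-gate leak multiplier from a
#' kinetic dataset generated by a catalytically crippled complex, with
#' the remaining rates held at their known values.
#'
#' @param data A [quant_table()] with `series = "timecourse"`.
#' @param model,subunit_states The (known) generating complex.
#' @param rates Known rates; the `leak` element is ignored and scanned.
#' @param leak_grid Candidate leak values.
#' @return The grid value minimizing the residual sum of squares.
#' @export
fit_leak <- function(data, model, subunit_states,
                     rates = kinetic_rates(),
                     leak_grid = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1)) {
  stopifnot(inherits(data, "quant_table"),
            identical(attr(data, "series"), "timecourse"))
  obs <- as.matrix(data[, c("SC", "N", "L", "EX")])
  sse <- vapply(leak_grid, function(lk) {
    r <- kinetic_rates(k5 = rates$k5, k3 = rates$k3, leak = lk,
                       k_ex_int = rates$k_ex_int,
                       local_requirement = rates$local_requirement)
    tc <- simulate_timecourse(model, subunit_states = subunit_states,
                              rates = r, times = data$time_h)
    sum((obs - as.matrix(tc[, c("SC", "N", "L", "EX")]))^2)
  }, numeric(1))
  leak_grid[which.min(sse)]
}
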