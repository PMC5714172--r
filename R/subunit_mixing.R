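#' Subunit-mixing scenario for transposase dimers
#'
#' The transposase is a stable dimer that exchanges subunits only slowly.
#' When two monomer pools X and Y (e.g. wild-type and catalytically dead)
#' are mixed, the dimer population depends on how much exchange has been
#' allowed:
#'
#' * `homodimers_only`: no exchange; the reaction contains only the two
#'   parental homodimers (mixing immediately before the reaction).
#' * `equilibrated`: full exchange; dimer composition is binomial in the
#'   pooled monomer fraction (overnight pre-incubation).
#' * `kinetic`: partial exchange after `duration` hours at a first-order
#'   dissociation rate `exchange_rate` (see [exchange_timecourse()]).
#'
#' @param mode One of `"homodimers_only"`, `"equilibrated"`, `"kinetic"`.
#' @param exchange_rate Per-hour dimer dissociation rate (kinetic mode).
#' @param duration Hours of pre-incubation (kinetic mode).
#' @return An object of class `mixing_scenario`.
#' @export
mixing_scenario <- function(mode = c("equilibrated", "homodimers_only",
                                     "kinetic"),
                            exchange_rate = NULL, duration = NULL) {
  mode <- match.arg(mode)
  if (mode == "kinetic") {
    stopifnot(is.numeric(exchange_rate), exchange_rate >= 0,
              is.numeric(duration), duration >= 0)
  }
  structure(list(mode = mode, exchange_rate = exchange_rate,
                 duration = duration),
            class = "mixing_scenario")
}

.as_scenario <- function(scenario) {
  if (inherits(scenario, "mixing_scenario")) return(scenario)
  mixing_scenario(scenario)
}

#' Dimer composition from a mixture of two monomer pools
#'
#' @param f Fraction of species-Y monomers in the pooled monomer
#'   population, in `[0, 1]`.
#' @param scenario A [mixing_scenario()] (or its mode string).
#' @return Named numeric vector `c(XX, XY, YY)` of dimer-species
#'   probabilities (sums to 1). `homodimers_only` gives `(1 - f, 0, f)`;
#'   `equilibrated` gives the binomial `((1-f)^2, 2 f (1-f), f^2)` — at
#'   `f = 0.5` the 1:2:1 pattern; `kinetic` gives the exchange time course
#'   endpoint at the scenario's `duration`.
#' @examples
#' dimer_distribution(0.5, "equilibrated")  # 0.25 0.50 0.25
#' dimer_distribution(0.3, "homodimers_only")
#' @export
dimer_distribution <- function(f, scenario = "equilibrated") {
  stopifnot(is.numeric(f), length(f) == 1L)
  if (is.na(f) || f < 0 || f > 1) {
    stop("monomer fraction f must be in [0, 1], got ", f, call. = FALSE)
  }
  scenario <- .as_scenario(scenario)
  out <- switch(scenario$mode,
    homodimers_only = c(XX = 1 - f, XY = 0, YY = f),
    equilibrated = c(XX = (1 - f)^2, XY = 2 * f * (1 - f), YY = f^2),
    kinetic = {
      init <- c(XX = 1 - f, XY = 0, YY = f)
      tc <- exchange_timecourse(init, scenario$exchange_rate,
                                scenario$duration)
      c(XX = tc$p_XX[nrow(tc)], XY = tc$p_XY[nrow(tc)],
        YY = tc$p_YY[nrow(tc)])
    })
  out
}

#' Subunit-exchange time course of a dimer mixture
#'
#' Dissociation-limited exchange: each dimer dissociates with first-order
#' rate `exchange_rate`; the freed monomers re-pair at random from the
#' pooled monomer population (re-association fast relative to
#' dissociation). In the deterministic limit every dissociation event
#' replaces a dimer with a draw from the binomial equilibrium
#' distribution, so each species probability relaxes exponentially,
#' `p(t) = p_eq + (p(0) - p_eq) exp(-k t)`, toward the binomial limit set
#' by the (conserved) monomer fraction. The rate controls only the speed
#' of equilibration, never the endpoint.
#'
#' @param initial Named numeric vector `c(XX, XY, YY)` summing to 1.
#' @param exchange_rate Per-hour dissociation rate, `>= 0`.
#' @param times Numeric vector of nonnegative times (hours).
#' @return Data frame with columns `time_h`, `p_XX`, `p_XY`, `p_YY`.
#' @examples
#' eq <- c(XX = 0.5, XY = 0, YY = 0.5)
#' exchange_timecourse(eq, exchange_rate = 1, times = c(0, 1, 2, 16))
#' @export
exchange_timecourse <- function(initial, exchange_rate, times) {
  initial <- .check_dimer_comp(initial)
  stopifnot(is.numeric(exchange_rate), length(exchange_rate) == 1L)
  if (exchange_rate < 0) stop("exchange_rate must be >= 0", call. = FALSE)
  stopifnot(is.numeric(times), length(times) >= 1L)
  if (any(times < 0)) stop("times must be nonnegative", call. = FALSE)

  f <- unname(initial["YY"] + initial["XY"] / 2)  # conserved monomer fraction
  p_eq <- c(XX = (1 - f)^2, XY = 2 * f * (1 - f), YY = f^2)
  relax <- exp(-exchange_rate * times)
  out <- data.frame(
    time_h = times,
    p_XX = p_eq["XX"] + (initial["XX"] - p_eq["XX"]) * relax,
    p_XY = p_eq["XY"] + (initial["XY"] - p_eq["XY"]) * relax,
    p_YY = p_eq["YY"] + (initial["YY"] - p_eq["YY"]) * relax,
    row.names = NULL
  )
  out
}

.check_dimer_comp <- function(p) {
  stopifnot(is.numeric(p), length(p) == 3L)
  if (is.null(names(p))) names(p) <- c("XX", "XY", "YY")
  p <- p[c("XX", "XY", "YY")]
  if (any(is.na(p)) || any(p < -1e-12) || abs(sum(p) - 1) > 1e-9) {
    stop("dimer composition must be 3 nonnegative probabilities summing to 1",
         call. = FALSE)
  }
  pmax(p, 0)
}
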