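#' Endpoint product distribution for a transposase mixing reaction
#'
#' The central simulation of the mixing-experiment analysis: for a given
#' cleavage-topology model, subunit-mixing scenario and nick-ordering
#' rule, enumerate every catalytic-complex configuration that can form at
#' mutant monomer fraction `f`, weight it by its probability, determine
#' which nicks occur at reaction endpoint, classify the product with
#' [classify_product()] and return the probability-weighted product
#' distribution.
#'
#' Each substrate molecule is processed by one independently drawn
#' complex. For `mm` models the complex is a single dimer whose
#' composition comes from [dimer_distribution()]; for `dd` models it is
#' two independently drawn dimers. Within a dimer the two subunits occupy
#' the two slots in either orientation with probability 1/2 each. A nick
#' occurs at endpoint iff its slot holds an active (wild-type) subunit
#' and the ordering rule permits it; gated nicks are fully blocked at
#' endpoint (leak-through is the province of [simulate_timecourse()]).
#'
#' @param model A [cleavage_model()] or model name.
#' @param scenario A [mixing_scenario()] or mode string.
#' @param ordering An [ordering_rule()] or mode string
#'   (default `"strict_gate"`).
#' @param f Mutant (catalytically dead) monomer fraction in `[0, 1]`.
#' @return Named numeric vector `c(SC, N, L, EX)` summing to 1.
#' @examples
#' predict_endpoint("mm_13_24", "equilibrated", "strict_gate", f = 0.5)
#' predict_endpoint("dd_13_24", "equilibrated", f = 0.25)["L"]  # 27/128
#' @export
predict_endpoint <- function(model, scenario = "equilibrated",
                             ordering = "strict_gate", f = 0) {
  model <- .as_cleavage_model(model)
  scenario <- .as_scenario(scenario)
  ordering <- .as_ordering(ordering)
  stopifnot(is.numeric(f), length(f) == 1L)
  if (is.na(f) || f < 0 || f > 1) {
    stop("mutant fraction f must be in [0, 1], got ", f, call. = FALSE)
  }
  pats <- .activity_patterns(model, scenario, f)
  out <- c(SC = 0, N = 0, L = 0, EX = 0)
  for (i in seq_len(nrow(pats$active))) {
    n <- .endpoint_nicks(model, pats$active[i, ], ordering$mode)
    cls <- classify_product(n)
    out[cls] <- out[cls] + pats$weight[i]
  }
  out
}

# Enumerate slot-activity patterns with probabilities.
# A dimer drawn from dimer_distribution(f, scenario) occupies two slots;
# the 50/50 orientation average splits the heterodimer weight equally
# between (active, dead) and (dead, active).
.activity_patterns <- function(model, scenario, f) {
  comp <- dimer_distribution(f, scenario)
  # per-dimer patterns over its two slots: (TT, TF, FT, FF)
  dw <- c(comp["XX"], comp["XY"] / 2, comp["XY"] / 2, comp["YY"])
  dp <- rbind(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE))
  if (model$arity == "dimer") {
    return(list(active = dp, weight = unname(dw)))
  }
  # dimer_of_dimers: two independent dimers, slots (1,2) and (3,4)
  k <- seq_len(4)
  idx <- expand.grid(a = k, b = k)
  active <- cbind(dp[idx$a, , drop = FALSE], dp[idx$b, , drop = FALSE])
  list(active = active, weight = unname(dw[idx$a] * dw[idx$b]))
}

#' Predicted product fractions over a grid of mutant fractions
#'
#' Row-wise application of [predict_endpoint()] over a mutant-fraction
#' grid; the returned curve carries its generating model, scenario and
#' ordering as attributes so that downstream consumers
#' ([peak_product()], [fit_mixing_data()]) can re-evaluate the continuous
#' predictor.
#'
#' @inheritParams predict_endpoint
#' @param f_grid Strictly increasing numeric vector within `[0, 1]`.
#' @return A data frame of class `mix_curve` with columns `f`, `SC`, `N`,
#'   `L`, `EX`.
#' @export
mix_curve <- function(model, scenario = "equilibrated",
                      ordering = "strict_gate",
                      f_grid = seq(0, 1, by = 0.05)) {
  if (length(f_grid) == 0L) stop("f_grid must be nonempty", call. = FALSE)
  stopifnot(is.numeric(f_grid))
  if (any(f_grid < 0 | f_grid > 1)) {
    stop("f_grid values must lie in [0, 1]", call. = FALSE)
  }
  if (length(f_grid) > 1L && any(diff(f_grid) <= 0)) {
    stop("f_grid must be strictly increasing", call. = FALSE)
  }
  model <- .as_cleavage_model(model)
  scenario <- .as_scenario(scenario)
  ordering <- .as_ordering(ordering)
  rows <- t(vapply(f_grid, function(f)
    predict_endpoint(model, scenario, ordering, f), numeric(4)))
  out <- data.frame(f = f_grid, rows)
  attr(out, "model") <- model$name
  attr(out, "scenario") <- scenario
  attr(out, "ordering") <- ordering$mode
  class(out) <- c("mix_curve", "data.frame")
  out
}

#' Locate the maximum of one product fraction over mutant fraction
#'
#' Finds the mutant fraction maximizing a chosen product class. The grid
#' maximum of the curve is refined by golden-section search
#' ([stats::optimize()]) on the continuous predictor between the
#' neighbouring grid points; ties are broken toward smaller `f`.
#'
#' @param curve A [mix_curve()].
#' @param product One of `"SC"`, `"N"`, `"L"`, `"EX"`.
#' @return Named numeric vector `c(f_at_max, max_fraction)`.
#' @examples
#' cv <- mix_curve("dd_13_24", "equilibrated", "strict_gate")
#' peak_product(cv, "L")  # f = 0.25, L = 27/128
#' @export
peak_product <- function(curve, product) {
  stopifnot(inherits(curve, "mix_curve"), nrow(curve) >= 1L)
  if (!product %in% c("SC", "N", "L", "EX")) {
    stop("invalid product label '", product,
         "' (expected SC, N, L or EX)", call. = FALSE)
  }
  model <- attr(curve, "model")
  scenario <- attr(curve, "scenario")
  ordering <- attr(curve, "ordering")
  fn <- function(f) predict_endpoint(model, scenario, ordering, f)[[product]]

  vals <- curve[[product]]
  i0 <- which.max(vals)  # first index on ties
  lo <- curve$f[max(1L, i0 - 1L)]
  hi <- curve$f[min(nrow(curve), i0 + 1L)]
  cand_f <- curve$f[i0]
  cand_v <- vals[i0]
  if (hi > lo) {
    opt <- stats::optimize(fn, lower = lo, upper = hi, maximum = TRUE,
                           tol = 1e-9)
    if (opt$objective > cand_v + 1e-12) {
      cand_f <- opt$maximum
      cand_v <- opt$objective
    }
  }
  # tie-break toward smaller f among grid points matching the maximum
  ties <- curve$f[vals >= cand_v - 1e-12]
  if (length(ties) && min(ties) < cand_f) {
    cand_f <- min(ties)
    cand_v <- fn(cand_f)
  }
  c(f_at_max = cand_f, max_fraction = cand_v)
}

#' Hand-derived closed-form endpoint distributions
#'
#' Independent algebraic forms of [predict_endpoint()] for the cases
#' where the enumeration collapses symbolically, used as test oracles.
#' With `q = 1 - f`:
#'
#' Equilibrated (binomial) mixing, strict gate — binomial composition
#' plus the 50/50 orientation makes every slot active independently with
#' probability `q`:
#' * `mm_13_24`, `mm_14_23`: `SC = f^2`, `N = 2 f q`, `EX = q^2`
#'   (a heterodimer places a single 5' nick, whichever slot is live,
#'   because the strict gate blocks the lone 3' nick).
#' * `mm_12_34`: `SC = f`, `N = f q`, `EX = q^2` (a dead 5'-role subunit
#'   performs no nick at all, so half the heterodimer orientations leave
#'   the substrate untouched).
#' * all `dd` models: `SC = f^2`, `N = 2 f q + q^2 f^2`, `L = 2 q^3 f`,
#'   `EX = q^4` (four independent active sites; the linear product needs
#'   both 5' slots live and exactly one 3' slot live, maximal
#'   `27/128` at `f = 1/4`).
#'
#' Homodimers-only mixing, strict gate — each dimer is all-active with
#' probability `q`:
#' * all `mm` models: `SC = f`, `EX = q`.
#' * `dd_13_24`, `dd_14_23`: `SC = f^2`, `N = 2 f q`, `EX = q^2` (a lone
#'   active per-end dimer places one 5' nick).
#' * `dd_12_34`: `SC = f`, `N = f q`, `EX = q^2` (a lone active 3'-role
#'   dimer is fully gated and leaves the substrate supercoiled).
#'
#' @inheritParams predict_endpoint
#' @return Named numeric vector `c(SC, N, L, EX)`, or `NULL` when no
#'   closed form is implemented for the requested combination.
#' @export
closed_form_endpoint <- function(model, scenario = "equilibrated",
                                 ordering = "strict_gate", f = 0) {
  model <- .as_cleavage_model(model)
  scenario <- .as_scenario(scenario)
  ordering <- .as_ordering(ordering)
  if (ordering$mode != "strict_gate") return(NULL)
  if (!scenario$mode %in% c("equilibrated", "homodimers_only")) return(NULL)
  stopifnot(is.numeric(f), length(f) == 1L, f >= 0, f <= 1)
  q <- 1 - f
  if (scenario$mode == "equilibrated") {
    out <- switch(model$name,
      mm_13_24 = ,
      mm_14_23 = c(SC = f^2, N = 2 * f * q, L = 0, EX = q^2),
      mm_12_34 = c(SC = f, N = f * q, L = 0, EX = q^2),
      dd_13_24 = ,
      dd_14_23 = ,
      dd_12_34 = c(SC = f^2, N = 2 * f * q + q^2 * f^2,
                   L = 2 * q^3 * f, EX = q^4))
  } else {
    out <- switch(model$name,
      mm_13_24 = ,
      mm_14_23 = ,
      mm_12_34 = c(SC = f, N = 0, L = 0, EX = q),
      dd_13_24 = ,
      dd_14_23 = c(SC = f^2, N = 2 * f * q, L = 0, EX = q^2),
      dd_12_34 = c(SC = f, N = f * q, L = 0, EX = q^2))
  }
  out
}
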