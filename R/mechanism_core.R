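#' Nick identities at the two transposon ends
#'
#' Excision of a mariner transposon from a plasmid requires four strand
#' hydrolysis events, two at each transposon end. The 5' nicks (recessed
#' inside the element) are `N1` at end A and `N2` at end B; the 3' nicks
#' (defining the transferred-strand termini) are `N3` at end A and `N4` at
#' end B. Nicks sharing an end are therefore `{N1, N3}` and `{N2, N4}`.
#'
#' @return A data frame with one row per nick: `label`, `end` (`"A"` or
#'   `"B"`) and `strand_chemistry` (`"five_prime"` or `"three_prime"`).
#' @examples
#' nick_ids()
#' @export
nick_ids <- function() {
  data.frame(
    label = c("N1", "N2", "N3", "N4"),
    end = c("A", "B", "A", "B"),
    strand_chemistry = c("five_prime", "five_prime",
                         "three_prime", "three_prime"),
    stringsAsFactors = FALSE
  )
}

.NICKS <- c("N1", "N2", "N3", "N4")
.END_A <- c("N1", "N3")
.END_B <- c("N2", "N4")
.FIVE <- c("N1", "N2")
.THREE <- c("N3", "N4")

# slot_assignment: list of character vectors, one per active-site slot.
# dd models group slots pairwise into two dimers (slots 1,2 = dimer alpha,
# slots 3,4 = dimer beta).
.MODEL_DEFS <- list(
  mm_13_24 = list(arity = "dimer",
                  slots = list(alpha = c("N1", "N3"), beta = c("N2", "N4"))),
  mm_14_23 = list(arity = "dimer",
                  slots = list(alpha = c("N1", "N4"), beta = c("N2", "N3"))),
  mm_12_34 = list(arity = "dimer",
                  slots = list(alpha = c("N1", "N2"), beta = c("N3", "N4"))),
  dd_13_24 = list(arity = "dimer_of_dimers",
                  slots = list(alpha1 = "N1", alpha2 = "N3",
                               beta1 = "N2", beta2 = "N4")),
  dd_14_23 = list(arity = "dimer_of_dimers",
                  slots = list(alpha1 = "N1", alpha2 = "N4",
                               beta1 = "N2", beta2 = "N3")),
  dd_12_34 = list(arity = "dimer_of_dimers",
                  slots = list(alpha1 = "N1", alpha2 = "N2",
                               beta1 = "N3", beta2 = "N4"))
)

# bracket aliases, e.g. "m/m[1+3/2+4]" for mm_13_24
.MODEL_ALIASES <- c(
  "m/m[1+3/2+4]" = "mm_13_24", "m/m[1+4/2+3]" = "mm_14_23",
  "m/m[1+2/3+4]" = "mm_12_34", "d/d[1+3/2+4]" = "dd_13_24",
  "d/d[1+4/2+3]" = "dd_14_23", "d/d[1+2/3+4]" = "dd_12_34"
)

#' Canonical cleavage-model names
#'
#' @return Character vector of the six model names. `mm` models assign the
#'   four nicks to the two active sites of a single transposase dimer; `dd`
#'   models assign them to the four active sites of a dimer-of-dimers. The
#'   digits give the nick assignment before/after the slash in the field's
#'   bracket notation, e.g. `mm_13_24` is `m/m[1+3/2+4]` (each monomer
#'   cleaves both strands at one transposon end).
#' @export
cleavage_model_names <- function() names(.MODEL_DEFS)

#' Construct a cleavage-topology model
#'
#' A cleavage model fixes which active-site slot of the catalytic complex
#' is responsible for each of the four strand nicks ([nick_ids()]). Single
#' dimer (`mm_*`) models have two slots with two nicks each;
#' dimer-of-dimers (`dd_*`) models have four slots with one nick each,
#' grouped into two dimers.
#'
#' @param name One of [cleavage_model_names()], or the equivalent bracket
#'   notation alias (e.g. `"m/m[1+3/2+4]"`).
#' @return An object of class `cleavage_model` with elements `name`,
#'   `arity`, `slot_assignment` (named list of nick-label vectors) and,
#'   for `dd` models, `dimer_of_slot` mapping slots to their dimer.
#' @examples
#' cleavage_model("mm_13_24")$slot_assignment
#' cleavage_model("d/d[1+2/3+4]")$name
#' @export
cleavage_model <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name %in% names(.MODEL_ALIASES)) name <- unname(.MODEL_ALIASES[name])
  if (!name %in% names(.MODEL_DEFS)) {
    stop("unknown cleavage model: '", name, "' (expected one of ",
         paste(names(.MODEL_DEFS), collapse = ", "),
         " or a bracket alias such as 'm/m[1+3/2+4]')", call. = FALSE)
  }
  def <- .MODEL_DEFS[[name]]
  obj <- list(name = name, arity = def$arity, slot_assignment = def$slots)
  if (def$arity == "dimer_of_dimers") {
    obj$dimer_of_slot <- c(alpha1 = "alpha", alpha2 = "alpha",
                           beta1 = "beta", beta2 = "beta")
  }
  class(obj) <- "cleavage_model"
  obj
}

#' @export
print.cleavage_model <- function(x, ...) {
  cat("<cleavage_model>", x$name, "(", x$arity, ")\n")
  for (s in names(x$slot_assignment)) {
    cat("  slot", s, "->", paste(x$slot_assignment[[s]], collapse = "+"), "\n")
  }
  invisible(x)
}

.as_cleavage_model <- function(model) {
  if (inherits(model, "cleavage_model")) model else cleavage_model(model)
}

#' Ordering rule for the four strand nicks
#'
#' Both 5' ends of the transposon are normally cleaved before either 3'
#' end. At reaction endpoint this ordering acts as a gate on the 3' nicks:
#'
#' * `strict_gate`: a 3' nick (N3/N4) can only occur once both N1 and N2
#'   have occurred (the default; the gate is fully blocking at endpoint).
#' * `per_end_gate`: a 3' nick only requires the 5' nick at its own end.
#' * `none`: all four nicks are independent.
#'
#' `leak` is a dimensionless multiplier in `[0, 1]` applied by the kinetic
#' model ([simulate_timecourse()]) to the 3'-nick rate while the global
#' gate is unsatisfied; endpoint prediction treats gated nicks as fully
#' blocked (`leak = 0`).
#'
#' @param mode `"strict_gate"`, `"per_end_gate"` or `"none"`.
#' @param leak Nonnegative scalar rate multiplier (kinetics only).
#' @return An object of class `ordering_rule`.
#' @export
ordering_rule <- function(mode = c("strict_gate", "per_end_gate", "none"),
                          leak = 0) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(leak), length(leak) == 1L, leak >= 0)
  structure(list(mode = mode, leak = leak), class = "ordering_rule")
}

.as_ordering <- function(ordering) {
  if (inherits(ordering, "ordering_rule")) return(ordering)
  ordering_rule(ordering)
}

#' Classify a plasmid molecule from its nick state
#'
#' Maps the set of nicks a substrate molecule has received onto the gel
#' band it would run as. No nick leaves the supercoiled substrate (`SC`);
#' one or more single-strand nicks give the open circular form (`N`); a
#' double-strand break at exactly one transposon end linearizes the
#' plasmid (`L`); double-strand breaks at both ends complete excision
#' (`EX`, lumping the liberated backbone, the excised transposon and all
#' downstream integration products).
#'
#' @param nicks Either a character vector of nick labels (subset of
#'   `N1..N4`, possibly empty) or a logical vector of length 4 (named or
#'   in `N1..N4` order).
#' @return One of `"SC"`, `"N"`, `"L"`, `"EX"`.
#' @examples
#' classify_product(character(0))        # "SC"
#' classify_product(c("N1", "N3"))       # "L"  (one end fully cut)
#' classify_product(c("N1", "N2"))       # "N"  (nicks at both ends)
#' classify_product(c("N1", "N2", "N3", "N4"))  # "EX"
#' @export
classify_product <- function(nicks) {
  occ <- .as_nick_state(nicks)
  end_a <- occ["N1"] && occ["N3"]
  end_b <- occ["N2"] && occ["N4"]
  if (end_a && end_b) return("EX")
  if (end_a || end_b) return("L")
  if (any(occ)) return("N")
  "SC"
}

.as_nick_state <- function(nicks) {
  if (is.logical(nicks)) {
    stopifnot(length(nicks) == 4L)
    if (is.null(names(nicks))) names(nicks) <- .NICKS
    return(nicks[.NICKS])
  }
  stopifnot(is.character(nicks) || length(nicks) == 0L)
  bad <- setdiff(nicks, .NICKS)
  if (length(bad)) stop("unknown nick label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stats::setNames(.NICKS %in% nicks, .NICKS)
}

#' Nick responsibilities of one active-site slot
#'
#' Returns the set of nicks a given slot performs under a cleavage model.
#' The `orientation` argument selects which physical subunit occupies
#' which slot: a dimer of subunits (1, 2) is loaded either as
#' `(1 -> first slot, 2 -> second slot)` (`orientation = 1`) or swapped
#' (`orientation = 2`). Both orientations are equally likely, so over the
#' two orientations each subunit is equally likely to occupy each slot;
#' the orientation does not change the nick set attached to the slot
#' itself, only which subunit sits in it.
#'
#' @param model A `cleavage_model` or model name.
#' @param slot Slot name (`"alpha"`, `"beta"` for `mm` models; `"alpha1"`,
#'   `"alpha2"`, `"beta1"`, `"beta2"` for `dd` models) or slot index.
#' @param orientation 1 or 2 (see above; recorded for provenance).
#' @return Character vector of nick labels.
#' @examples
#' nick_assignment("mm_13_24", "alpha")  # c("N1", "N3")
#' nick_assignment("mm_14_23", "beta")   # c("N2", "N3")
#' @export
nick_assignment <- function(model, slot, orientation = 1) {
  model <- .as_cleavage_model(model)
  stopifnot(orientation %in% c(1, 2))
  slots <- model$slot_assignment
  if (is.numeric(slot)) {
    if (slot < 1 || slot > length(slots)) {
      stop("slot index out of range for ", model$name, call. = FALSE)
    }
    return(slots[[slot]])
  }
  if (!slot %in% names(slots)) {
    stop("unknown slot '", slot, "' for model ", model$name, call. = FALSE)
  }
  slots[[slot]]
}

# slot index (within the model's slot list) responsible for each nick
.slot_of_nick <- function(model) {
  model <- .as_cleavage_model(model)
  out <- integer(4)
  names(out) <- .NICKS
  for (i in seq_along(model$slot_assignment)) {
    out[model$slot_assignment[[i]]] <- i
  }
  out
}

# Endpoint nick occurrence for one activity pattern.
# slot_active: logical vector, one entry per slot of `model`.
# Returns named logical over N1..N4.
.endpoint_nicks <- function(model, slot_active, mode) {
  sl <- .slot_of_nick(model)
  a <- slot_active[sl]          # activity of the slot owning each nick
  names(a) <- .NICKS
  n <- c(N1 = unname(a["N1"]), N2 = unname(a["N2"]), N3 = FALSE, N4 = FALSE)
  if (mode == "none") {
    n["N3"] <- a["N3"]; n["N4"] <- a["N4"]
  } else if (mode == "per_end_gate") {
    n["N3"] <- a["N3"] && n["N1"]
    n["N4"] <- a["N4"] && n["N2"]
  } else { # strict_gate
    gate <- n["N1"] && n["N2"]
    n["N3"] <- a["N3"] && gate
    n["N4"] <- a["N4"] && gate
  }
  n
}
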