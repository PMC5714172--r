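# Independent oracles, kept deliberately separate from the package's own
# code paths: a hand-written product-classification table, a Monte-Carlo
# sampler of mixing endpoints built directly from the model notation, and
# an agent-based simulation of subunit exchange.

# All 16 nick subsets and their gel classes, written out by hand.
oracle_classification <- function() {
  list(
    list(nicks = character(0), class = "SC"),
    list(nicks = "N1", class = "N"),
    list(nicks = "N2", class = "N"),
    list(nicks = "N3", class = "N"),
    list(nicks = "N4", class = "N"),
    list(nicks = c("N1", "N2"), class = "N"),
    list(nicks = c("N1", "N3"), class = "L"),
    list(nicks = c("N1", "N4"), class = "N"),
    list(nicks = c("N2", "N3"), class = "N"),
    list(nicks = c("N2", "N4"), class = "L"),
    list(nicks = c("N3", "N4"), class = "N"),
    list(nicks = c("N1", "N2", "N3"), class = "L"),
    list(nicks = c("N1", "N2", "N4"), class = "L"),
    list(nicks = c("N1", "N3", "N4"), class = "L"),
    list(nicks = c("N2", "N3", "N4"), class = "L"),
    list(nicks = c("N1", "N2", "N3", "N4"), class = "EX")
  )
}

# slot tables restated from the bracket notation, independent of the
# package's internal definitions
oracle_slots <- list(
  mm_13_24 = list(c(1, 3), c(2, 4)),
  mm_14_23 = list(c(1, 4), c(2, 3)),
  mm_12_34 = list(c(1, 2), c(3, 4)),
  dd_13_24 = list(1, 3, 2, 4),
  dd_14_23 = list(1, 4, 2, 3),
  dd_12_34 = list(1, 2, 3, 4)
)

oracle_classify_mask <- function(occ) {
  # occ: logical length 4 over nicks 1..4
  end_a <- occ[1] && occ[3]
  end_b <- occ[2] && occ[4]
  if (end_a && end_b) "EX" else if (end_a || end_b) "L"
  else if (any(occ)) "N" else "SC"
}

# Monte-Carlo sampler of endpoint product fractions: n complexes drawn
# from the stated mixing law, nick logic applied literally.
mc_endpoint <- function(model_name, scenario_mode, ordering_mode, f, n,
                        seed) {
  set.seed(seed)
  slots <- oracle_slots[[model_name]]
  n_dimers <- length(slots) / 2
  counts <- c(SC = 0, N = 0, L = 0, EX = 0)
  for (i in seq_len(n)) {
    active <- logical(length(slots))
    for (d in seq_len(n_dimers)) {
      pair <- if (scenario_mode == "homodimers_only") {
        rep(stats::runif(1) >= f, 2)          # whole dimer active or dead
      } else {
        stats::runif(2) >= f                  # binomial: subunits iid
      }
      if (stats::runif(1) < 0.5) pair <- rev(pair)  # orientation
      active[(2 * d - 1):(2 * d)] <- pair
    }
    slot_of <- integer(4)
    for (s in seq_along(slots)) slot_of[slots[[s]]] <- s
    occ <- logical(4)
    occ[1] <- active[slot_of[1]]
    occ[2] <- active[slot_of[2]]
    gate3 <- switch(ordering_mode,
      strict_gate = occ[1] && occ[2],
      per_end_gate = NA,  # handled per nick below
      none = TRUE)
    for (nick in 3:4) {
      ok <- if (ordering_mode == "per_end_gate") occ[nick - 2] else gate3
      occ[nick] <- active[slot_of[nick]] && ok
    }
    cls <- oracle_classify_mask(occ)
    counts[cls] <- counts[cls] + 1
  }
  counts / n
}

# Agent-based subunit exchange: n_dimers dimers, per-step dissociation
# with probability 1 - exp(-rate * dt); freed monomers pooled and
# re-paired at random.
agent_exchange <- function(f, rate, t_end, n_dimers = 1e5, dt = 0.02,
                           seed = 1) {
  set.seed(seed)
  n_y <- round(f * n_dimers)
  # monomer species per dimer slot: columns are the two subunits
  m <- cbind(rep(c(0L, 1L), c(n_dimers - n_y, n_y)),
             rep(c(0L, 1L), c(n_dimers - n_y, n_y)))
  p_diss <- 1 - exp(-rate * dt)
  steps <- round(t_end / dt)
  for (s in seq_len(steps)) {
    hit <- which(stats::runif(n_dimers) < p_diss)
    if (length(hit) < 2) next
    pool <- as.vector(m[hit, ])
    pool <- sample(pool)
    m[hit, ] <- matrix(pool, ncol = 2)
  }
  k <- rowSums(m)
  c(XX = mean(k == 0), XY = mean(k == 1), YY = mean(k == 2))
}

# small helper: product matrix of a mix_curve
curve_fractions <- function(cv) as.matrix(cv[, c("SC", "N", "L", "EX")])
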