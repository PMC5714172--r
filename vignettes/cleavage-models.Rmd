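---
title: "Cleavage-topology models for mariner transposition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleavage-topology models for mariner transposition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marinercleave)
```

## The problem

A mariner-family transposase must hydrolyze both DNA strands at each of
the two transposon ends — four nicks in all — before the element can be
excised from its donor plasmid and integrated elsewhere. Unlike Tn10/Tn5
or PiggyBac, mariner elements do not use a hairpin intermediate, so how a
homodimeric enzyme built on the single-strand-active RNase H fold cuts
strands of opposite polarity is a genuine mechanistic puzzle. The
experimental handle is subunit poisoning: mix active transposase with a
catalytically dead (D155A) point mutant in varying ratios, and compare
the distribution of reaction products against what each candidate
division of labour predicts. This package implements that computational
reasoning end to end: the candidate cleavage topologies, the mixing
statistics, the endpoint and kinetic predictions, the least-squares
discrimination against band quantifications, and the idealized B-DNA
geometry of the scissile phosphates.

## State space and product classes

The four nicks are labelled `N1`/`N2` (5' nicks at ends A/B, recessed
inside the element) and `N3`/`N4` (3' nicks at ends A/B). A substrate
molecule's state is the subset of nicks it carries; `classify_product()`
maps all 16 subsets onto the four gel bands: supercoiled substrate
(`SC`), open circular (`N`, any nicking short of a double-strand break),
linear plasmid (`L`, a double-strand break at exactly one end), and
completed excision (`EX`). `EX` deliberately lumps the liberated
backbone, the excised transposon fragment and all integration products:
the excised fragment does not accumulate as a distinct species, so a
finer partition would not be observable on the gels the analysis is
aimed at, and integration chemistry is out of scope.

## The six cleavage topologies

A cleavage model assigns each nick to an active-site slot. With one
dimer (two slots) there are three distinct assignments — `mm_13_24`
(each monomer cleaves both strands at one end), `mm_14_23` (each monomer
cleaves one 5' and the opposite end's 3' strand), and `mm_12_34` (one
monomer does both 5' nicks, the other both 3' nicks). The
dimer-of-dimers alternatives `dd_13_24`, `dd_14_23`, `dd_12_34`
distribute the four nicks over four slots grouped into two dimers. The
field's bracket notation (`m/m[1+3/2+4]` and so on) is accepted
everywhere a model name is.

## Mixing statistics

Transposase dimers are stable but exchange subunits over hours. The two
experimental regimes are `homodimers_only` (mixing immediately before
the reaction: dimer composition `(1-f, 0, f)` at dead-monomer fraction
`f`) and `equilibrated` (overnight pre-incubation: binomial
`((1-f)^2, 2f(1-f), f^2)`, the 1:2:1 pattern at `f = 0.5`). A third,
`kinetic`, regime interpolates using a dissociation-limited exchange
law: dimers dissociate at a first-order rate and the freed monomers
re-pair at random, so each species relaxes exponentially toward the
binomial limit while the monomer totals are conserved exactly. Only the
endpoint (binomial) is quantitatively constrained by observation;
whether exchange is dissociation-limited or collision-mediated is not,
so the simplest law consistent with slow equilibration and a binomial
endpoint was adopted, and the rate is a free parameter with no fitted
value claimed. The agent-based simulation used to validate the
deterministic trajectory lives in the test suite.

## Endpoint prediction

`predict_endpoint()` enumerates every complex configuration: dimer
composition(s) drawn from the mixing law (two independent dimers for
`dd` models), 50/50 slot orientation within each dimer (no evidence
supports biased loading), a nick occurring iff its slot holds an active
subunit and the ordering rule permits it, then classification. Each
substrate molecule is served by exactly one independently drawn complex;
transposase depletion, competition and overproduction inhibition are a
separate regulatory layer and deliberately not modelled.

The ordering rule encodes the observation that both 5' ends are
normally cleaved before either 3' end. The default, `strict_gate`,
blocks a 3' nick until both 5' nicks have occurred; it is the endpoint
limit of the kinetic constraint and uniquely reproduces the printed
dimer-of-dimers prediction (maximum linear fraction 27/128 ≈ 21.1% at
`f = 0.25`, within the "about 20%" peaking at 20–40% mutant), the
nicked-intermediate accumulation the dd models predict without
pre-equilibration, and the stated indistinguishabilities between model
pairs. `per_end_gate` (3' nick requires only its own end's 5' nick) and
`none` are available for sensitivity analysis.

Two properties of the enumeration are worth knowing. First, under
binomial mixing the composition-plus-orientation draw makes every slot
active independently with probability `1 - f`; consequently all three
dimer-of-dimers assignments produce identical endpoint curves in the
equilibrated scenario, and the `dd_12_34` topology is distinguishable
from its siblings only in the homodimers-only regime — which is exactly
the regime in which it is asserted unique. Second, `closed_form_endpoint()`
carries independently hand-derived polynomial forms for all twelve
strict-gate cases; the test suite checks enumeration against them at 101
grid points, and against a literal Monte-Carlo sampler at $10^5$ draws.

`peak_product()` refines the grid argmax by golden-section search on the
continuous predictor (tolerance `1e-9`) and breaks ties toward smaller
`f`, so that identically-zero curves report their peak at `f = 0`.

## Kinetics of ordered nicking

`simulate_timecourse()` solves the master equation over the 16 nick
states (plus an internal excised-to-integrated sub-state) with
`deSolve::lsoda` at tolerances `rtol 1e-10` / `atol 1e-12`. The ordering
constraint is factored into a hard local requirement — a 3' nick needs
the 5' nick at its own end, motivated by a single active site performing
5' then 3' chemistry at one end — and a soft global gate: until both 5'
nicks are done, 3' nicks run at `leak * k3`. The observations constrain
this factorization qualitatively (3' cleavage is greatly delayed but
eventually completes in crippled single-chain heterodimers) without
fixing `leak` numerically; no fitted value is claimed, and the
grid-search recovery of `leak` from synthetic data is the package's own
consistency experiment, not an inference about the real enzyme.

Setting `leak = 0` reproduces the strict-gate endpoint exactly;
`leak = 1` with and without the local requirement reproduces the
per-end-gate and unordered endpoints. The suite asserts this
correspondence across all six models at 11 mutant fractions, and checks
the integrator against matrix exponentials on random rate draws.

The kinetic discriminator the package reproduces: a single-chain
heterodimer under `mm_13_24` collapses to the chain SC → N → L with
rates `k5` and `leak * k3` (nicked intermediate rises to ~77% with the
defaults before draining into the linear form), whereas under
`mm_14_23` the live subunit's 3' nick sits at the never-nicked end and
the linear product cannot form at all. Default demonstration rates
(`k5 = 3/h`, `k3 = 3/h`, `leak = 0.1`, `k_ex_int = 1/h`) place that
behaviour inside a 4 h reaction window; they are illustrative. Because
`EX` lumps excised and integrated species, `k_ex_int` cannot affect any
reported class fraction — it is retained so the excision-to-integration
step is explicit in the state graph.

## Model discrimination

`fit_mixing_data()` scores candidates by unweighted least squares over
all four product fractions and all lanes. The candidate curves have no
free parameters, matching the parameter-free overlays the experimental
plots use; no fit criterion is stated for those overlays, so the
simplest one is adopted and the rejection threshold (default: RSS more
than twice the best class's) is exposed as configuration. Candidates
whose curves agree within `1e-9` on a dense grid are reported as one
equivalence class — the honest unit of inference, since analytically
identical models cannot be separated by any data. Designs containing
only pure lanes (`f` of 0 and 1) tie every candidate at zero RSS, as
they should.

## Idealized B-DNA geometry

`build_duplex()` places one phosphorus pseudo-atom per nucleotide on a
dyad-symmetric pair of helices: strand 1 at cylindrical coordinates
`(p_radius, p_azimuth_offset + twist*i, p_z_offset + rise*i)` and
strand 2 at its two-fold image. Twist (36°/bp) and rise (3.38 Å/bp) are
the canonical B-form fiber values; the three placement constants
(radius 9.5148 Å, azimuth 63.2298°, axial offset −0.6071 Å) were
calibrated once — the script is shipped in `inst/scripts/` — against
the three inter-strand scissile-phosphate distances of interest:
11.9 Å for the mariner pair staggered by 3 bp, 16.9 Å for the blunt
Tn10/Tn5 pair, 18.3 Å for the PiggyBac TTAA pair.

Two geometric decisions deserve a precise statement. First, the sign
convention: positive staggers step toward the minor-groove side (the
mariner 5'-overhang geometry); the blunt pair is stagger 0; the
PiggyBac pair lies across the **major** groove, which in a physical
helix is the opposite angular side — stagger −4 in this convention.
No dyad-symmetric helix can place an 18.3 Å pair at +4 while an
11.9 Å pair at +3 remains the global minimum; the groove descriptions
resolve the ambiguity, and `scissile_stagger()` records the three
assignments (`mariner = +3`, `tn10_5 = 0`, `piggybac = -4`, the latter
two being mechanistic inferences rather than printed staggers). Second,
the calibration trade-off: an exact three-distance solution exists but
moves the closest opposite-strand pair to stagger +4, contradicting the
observation that the mariner pair is the closest of all; the committed
constants therefore minimize the residuals subject to a unique minimum
at +3, landing all three distances within 0.15 Å (well inside the
0.3 Å acceptance band) at a plausible phosphate radius. Groove labels
reported by `groove_side()` are descriptive only.

## Synthetic data

The generators emulate the three measurement types of a mixing-based
cleavage analysis: endpoint
product fractions over a mutant-fraction series, product fractions over
a reaction time course, and dimer-species abundances during subunit
exchange. Noise is additive truncated-Gaussian per fraction (default sd
0.05, a plausible densitometry error; none is reported for the source
gels), followed by clipping to `[0, 1]` and renormalization. Seeds are
mandatory arguments and the generators restore the global RNG state, so
every dataset is a pure function of truth and seed. What the generators
do **not** emulate: lane-to-lane loading variation, the slowly reacting
nicked contaminant present in real plasmid preparations, background
linear product from integration events, or gel-image artefacts — so
passing recovery tests demonstrate the statistical identifiability of
the models under idealized densitometry error, not robustness to every
failure mode of real gels.

## Numerical choices and problem sizes

Enumeration is exact (4 or 16 complex configurations), so endpoint
curves carry no Monte-Carlo error. The ODE tolerances above keep
probability conservation below `1e-8` per row. Endpoint-consistency
checks evaluate the kinetics at `t = 400 h`, far beyond the slowest
relevant relaxation time at the default rates. The test suite's scales
— 101-point closed-form grids, $10^5$-draw Monte-Carlo checks,
$10^5$-dimer agent simulations, 100-replicate model-recovery and
50-seed parameter-recovery experiments at seven-lane designs — were
chosen so each check has clear statistical resolution (4 standard
errors for Monte-Carlo agreement, 3 for the exchange agent simulation)
while the whole suite stays desk-scale on one CPU.

## Known limitations

* Endpoint predictions assume one complex per substrate molecule and
  ignore transposase autoregulation; absolute rates are not fitted to
  any gel, so kinetic output is shape-accurate, not calibrated.
* The dimer-of-dimers enumeration treats the two dimers as independent
  draws; cooperative assembly of a specific tetramer would need a
  different composition law.
* The helix model is sequence-independent rigid fiber DNA; it is meant
  for inter-phosphate distance comparisons, not for modelling DNA
  deformation inside the transpososome.
* The exchange law is the simplest consistent with the observations;
  only its binomial endpoint is experimentally pinned.

## A worked session

```{r example}
# the printed model predictions
peak_product(mix_curve("dd_13_24", "equilibrated", "strict_gate"), "L")
peak_product(mix_curve("mm_13_24", "equilibrated", "strict_gate"), "N")

# discrimination on synthetic equilibrated data
tab <- gen_mixing_dataset("mm_13_24", "equilibrated", "strict_gate",
                          seq(0, 1, by = 1 / 6),
                          noise_spec(sd = 0.05, seed = 1))
fit_mixing_data(tab, candidate_set(scenario = "equilibrated"))

# scissile-phosphate geometry
tr <- build_duplex(helix_model(), n_bp = 30)
sapply(scissile_stagger(), function(s) interstrand_p_distance(tr, s))
min_distance_stagger(tr, -10:10)
```
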