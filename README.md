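# marinercleave

How does a homodimeric mariner-family transposase — an enzyme built on
the single-strand-active RNase H fold, with no hairpin intermediate —
cut both DNA strands at both transposon ends? `marinercleave` implements
the computational side of the classic way to answer such questions:
subunit-poisoning mixing experiments. Active transposase is mixed with a
catalytically dead point mutant at varying ratios, and the observed
distribution of excision products is compared against what each
candidate division of catalytic labour predicts. The package is aimed at
molecular biologists and modellers analyzing (or designing) such
experiments for transposases and other oligomeric nucleases.

## What it computes

**Cleavage topologies.** Excision needs four nicks: `N1`/`N2` (5' nicks
at transposon ends A/B) and `N3`/`N4` (3' nicks at A/B). A cleavage
model assigns nicks to active-site slots of either one dimer
(`mm_13_24`, `mm_14_23`, `mm_12_34`, i.e. `m/m[1+3/2+4]` etc.) or a
dimer-of-dimers (`dd_13_24`, `dd_14_23`, `dd_12_34`). The nick ordering
rule encodes that both 5' ends are normally cleaved before either 3'
end.

**Mixing statistics.** At dead-monomer fraction *f*, dimer compositions
are `(1-f, 0, f)` without subunit pre-equilibration and the binomial
`((1-f)², 2f(1-f), f²)` after it — the 1:2:1 pattern at *f* = 0.5 — with
a dissociation-limited exchange model covering the transition.

**Endpoint prediction.** `predict_endpoint()` enumerates all complex
configurations exactly. Under the strict 5'-before-3' gate the
dimer-of-dimers model predicts a maximum linear-product fraction of

    L(f) = 2 f (1 - f)^3,  max L = 27/128 ≈ 21.1% at f = 1/4,

while the single-dimer model predicts a heterodimer-derived nicked
intermediate `N(f) = 2 f (1 - f)` peaking at *f* = 1/2 — the two
signatures that discriminate the topologies experimentally.

**Kinetics.** `simulate_timecourse()` solves the master equation over
the 16 nick states with a leaky ordering gate, reproducing the
diagnostic behaviour of crippled single-chain heterodimers (a large,
slowly converting nicked intermediate under `mm_13_24`; no linear
product at all under `mm_14_23`).

**Model discrimination.** `fit_mixing_data()` scores all candidates by
parameter-free least squares against band-fraction tables, groups
analytically identical candidates into equivalence classes, and reports
exclusions.

**Geometry.** `build_duplex()` places scissile phosphates on idealized
B-DNA and reproduces, from one committed parameter set, the
inter-strand distances of the mariner (3-bp stagger, minor groove,
11.9 Å — the closest opposite-strand pair), Tn10/Tn5 (blunt, 16.9 Å)
and PiggyBac (4-bp TTAA stagger, major groove, 18.3 Å) cleavage
geometries.

**Synthetic data.** Seeded generators emulate the three measurement
types (mixing series, time courses, exchange series) with densitometry
noise, so every analysis stage is testable without any download.

## Worked example

```r
library(marinercleave)

dimer_distribution(0.5, "equilibrated")
#>   XX   XY   YY
#> 0.25 0.50 0.25

peak_product(mix_curve("dd_13_24", "equilibrated", "strict_gate"), "L")
#>     f_at_max max_fraction
#>    0.2500000    0.2109375

tab <- gen_mixing_dataset("mm_13_24", "equilibrated", "strict_gate",
                          seq(0, 1, by = 1/6), noise_spec(sd = 0.05, seed = 1))
fit_mixing_data(tab, candidate_set(scenario = "equilibrated"))
#> <fit_report> parameter-free least squares, rejection ratio 2x
#>      model     scenario    ordering     rss class rank excluded
#> 1 mm_13_24 equilibrated strict_gate 0.02879     1    1    FALSE
#> 2 mm_14_23 equilibrated strict_gate 0.02879     1    1    FALSE
#> 3 dd_13_24 equilibrated strict_gate 0.23108     3    2     TRUE
#> 4 dd_14_23 equilibrated strict_gate 0.23108     3    2     TRUE
#> 5 dd_12_34 equilibrated strict_gate 0.23108     3    2     TRUE
#> 6 mm_12_34 equilibrated strict_gate 0.44508     2    3     TRUE
#> excluded: dd_13_24, dd_14_23, dd_12_34, mm_12_34

tr <- build_duplex(helix_model(), n_bp = 30)
sapply(scissile_stagger(), function(s) interstrand_p_distance(tr, s))
#>  mariner   tn10_5 piggybac
#> 11.75730 17.03334 18.19459
```

Reading the fit report: the generating single-dimer class (`mm_13_24`
with its analytically indistinguishable partner `mm_14_23`) ranks
first; every dimer-of-dimers candidate — and the 5'/3'-split single
dimer — is excluded at more than twice the best residual. The geometry
distances sit within 0.15 Å of the 11.9/16.9/18.3 Å reference values.

A thin command-line wrapper over the same functions ships in
`inst/cli/marinercleave` (subcommands `predict`, `fit`, `kinetics`,
`geometry`, `synth`).

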