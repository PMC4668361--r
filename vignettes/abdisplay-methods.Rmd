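---
title: "Models and methods behind abdisplay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind abdisplay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abdisplay)
```

`abdisplay` models the computational steps of a framework-variant engineering
campaign: Kabat numbering and germline-deviation mining, design of a
single-variant library from natural somatic-hypermutation diversity,
stochastic simulation and quantification of multi-round fluorescence-gated
selections, and the two downstream biophysical readouts (thermal melts and
1:1 binding kinetics). This vignette explains each model, its assumptions,
the tunable parameters with their defaults, and the limits of what the
simulations can show.

## Kabat numbering and deviation calling

Sequences are numbered by global pairwise alignment (Needleman–Wunsch, affine
gaps) to a pre-numbered germline subgroup reference; each aligned residue
inherits the reference's Kabat coordinate, and residues aligned to reference
gaps receive insertion codes (`A`, `B`, ...) on the preceding number. A
profile-HMM would generalize better across distant subgroups, but a pairwise
alignment against the correct subgroup reference is fully deterministic,
transparent, and adequate when the repertoire is subgroup-matched, which is
the design condition here.

Parameters: gap opening 10 and extension 1 on BLOSUM62 (the standard protein
defaults; framework indels are rare so gap placement is rarely exercised),
and an alignment-score floor (default 0) below which a sequence is rejected
as unalignable rather than silently mis-numbered. CDR boundaries follow the
Kabat convention — light chains 24–34, 50–56, 89–97; heavy chains 31–35,
50–65, 95–102 — and a position with an insertion code belongs to the region
of its base number. Insertions at framework positions are numbered the same
way but raise a warning, since canonical insertion points lie inside CDRs.

The bundled references (`germline_fixture()`) are *synthetic*
subgroup-consensus sequences (kappa1/kappa4/VH2/VH3-like, 107 and 113
residues, no insertion codes). They carry the canonical germline identities
at the positions the workflow cares about (kappa M4; heavy E6, V37, V48) but
are not database alleles; any real analysis should substitute the
appropriate germline or subgroup consensus, which the TSV format makes
straightforward.

## Library design

`tally_natural_diversity()` counts each `(position, from, to)` deviation over
a numbered repertoire; `design_library()` retains observations that are (i)
in a framework region, (ii) buried, (iii) outside an a-priori exclusion list
(e.g. known paratope positions), and (iv) supported by at least `min_count`
sequences. Burial is consumed as a relative-solvent-accessibility table
rather than computed from structure, keeping the package free of 3D
dependencies; `rsa_max` defaults to 0.2, the common buried/exposed
convention. `min_count` defaults to 1 — any observed natural change is
eligible — and can be raised to model designs that demand recurrent somatic
mutations. Each alternative amino acid observed at a position becomes its own
library member; combinations are left to downstream screening. The filters
are monotone by construction: relaxing `rsa_max` or `min_count` can only grow
the library, a property the tests assert.

## Repertoire simulation

`simulate_repertoire()` generates germline copies, applies independent
per-position substitutions at `per_position_rate` (default 0.01 — a light
somatic-hypermutation load of roughly one substitution per domain), overlays
*planted* variants at controlled frequencies, and records the exact truth
table. Planted positions are shielded from background mutation so the truth
stays unambiguous. Substitutions default to uniform over the 19 alternatives;
a similarity-biased table exists but nothing downstream depends on it. There
are no indels by default (the variants of interest are all substitutions), no
clonal lineage structure, and no nucleotide-level hotspot model — the
generator emulates the *marginal* position-wise diversity a subgroup-matched
repertoire offers, not the mutational process that created it. Consequently,
pipeline tests on this generator demonstrate bookkeeping correctness
(numbering, tallying and filtering recover the planted truth exactly), not
fidelity to real repertoire statistics.

## Selection simulation

Single-cell fluorescence is a two-component lognormal mixture. With
probability `p_unpermeabilized` (default 0.3) a cell contributes background
only — the partial-permeabilization/autofluorescence mode that makes stained
bacterial populations bimodal; otherwise a binder's component has median

```
median = mu_background + scale * expression_fold^gamma
```

with `mu_background = 2` and `scale = 100` (arbitrary units; background ~2 %
of signal), lognormal shape `cv = 0.6`. Non-binders always draw from
background. The compression exponent `gamma` maps expression differences to
the much smaller mean-fluorescence differences a sorter sees:
`calibrate_gamma()` fits the through-origin log–log slope, and the measured
panel of 3.7/5.6/7.2-fold expression against 1.25/1.37/1.4-fold MFI gives
`gamma ≈ 0.17`, the default. Antigen occupancy is deliberately absent from
the model because staining is done at concentrations far above the KD, making
expression, not affinity, the signal driver.

A sort round draws `cells_analyzed_per_round` cells multinomially from the
population, assigns fluorescence, keeps the top `ceiling(gate_fraction * n)`
values (a sample quantile, as on a sorter, not a fixed threshold; ties have
probability zero for continuous values), and regrows the kept cells
multinomially to `regrow_to` — growth is neutral, with no fitness
differences between variants. Each post-round state records the gate
threshold and the within-round analyzed/kept compositions, which is what
makes the analytic gate cap (kept frequency at most analyzed frequency divided
by `gate_fraction`) checkable exactly.

Two properties of this model are worth stating plainly. First, the per-round
enrichment of a variant is governed by the ratio of lognormal upper-tail
probabilities at the gate threshold; with `cv = 0.6` and median ratios fixed
at 1.25/1.37/1.4, two rounds of top-1 % sorting concentrate the two brightest
variants to roughly 80 % of the population — reliably depleting the dimmest
variants, but not eliminating intermediate ones. Complete sweeps of the kind
seen in real two-round screens require either tighter gates, more rounds, or
narrower single-cell distributions than this calibration. Second, a rare
perfect binder can enrich at most `1/gate_fraction` per round in expectation,
and when it starts at one cell per million with ten million cells analyzed,
the handful of binder cells in the first analyzed sample makes the realized
two-round enrichment fluctuate around that `1e4` analytic compounding with a
~30 % relative spread. The acceptance suite asserts both statements at the
stated conditions and reports the outcomes as measured.

## Sort quantification

Dual-marker plating gives the abundance ratio
`marker / (total − marker)` with a log-scale Poisson standard error
`sqrt(1/marker + 1/(total − marker))`; fold enrichment across a sort is the
output:input ratio of these odds, which is also how the spiking readout is
defined. Clone frequencies from sequenced colonies carry 95 % Wilson score
intervals — preferred over Wald for the small counts typical of 96–226
sequenced clones. Enrichment calls compare first and last rounds:
`not_detected` (zero final count) is distinct from `depleted` (frequency
drop of at least `min_fold` with non-overlapping Wilson intervals), because
a clone can be convincingly depleted yet still present. No multiplicity
correction is applied by default; the analysis is descriptive over a few
dozen clones.

## Melt-curve analysis

Simulated melts are a linear baseline plus a sum of logistic transitions on
the standard 20–100 °C grid at 0.2 °C steps. Extraction smooths the signal
(centered moving average, window 1 °C), differentiates over a ±1 °C central
difference, smooths again, and takes derivative peaks as candidates; each is
refined by a local baseline-plus-logistic least-squares fit. A candidate
becomes a transition only if its fitted amplitude reaches `min_prominence`
(default 5 %) of the total signal range, its width is plausible
(0.2–6 °C), its midpoint stays within 3 °C of the derivative peak, and the
logistic beats a straight line on the window by at least a factor of two in
residual sum of squares — the last rule is what makes pure-baseline curves
fail with a clean no-transition error instead of returning noise bumps. The
Fab melt is assigned to the largest-amplitude transition, a convention
justified by the Fab being the dominant unfolding unit in these constructs;
CH2/CH3 transitions are reported alongside. Noiseless recovery is accurate to
one grid step for isolated transitions; the known limitation is overlap —
a minor transition within ~5 °C of a dominant one presents as a shoulder
without its own derivative maximum and is not resolved.

## Binding kinetics

Sensorgrams follow the 1:1 Langmuir closed forms per segment: association
from bound level `R0` relaxes to `Req = Rmax C/(C + KD)` at rate
`ka C + kd`; dissociation decays at `kd`. The two supported acquisition
designs mirror practice: a multi-cycle two-fold series (1.56–50 nM, 120 s
association, 1000 s dissociation, surface regenerated between cycles, so
`R0 = 0` each cycle) and a single-cycle three-fold series (6.17–500 nM,
120 s injections back-to-back with `R0` carried across, 300 s final
dissociation). The simulator is validated against an independent ODE
integration of the binding equation in the test suite.

Fitting is global nonlinear least squares over all segments with shared
`(ka, kd, Rmax)`, parameterized in log10 for the rates, with a multistart
over a log-spaced grid of initial `ka` in `[1e3, 1e7]` and `kd` in
`[1e-5, 1e-1]` (3×3 by default); the best converged objective wins.
Residuals are unweighted and the time grid is 1 s. Mass-transport and
bulk-shift terms are intentionally omitted — the data model is plain 1:1
kinetics, and fits of transport-limited data should be treated with the usual
suspicion. `KD` is derived as `kd/ka` exactly, reported in nM; printed-table
scale factors (`ka` in 1e5 1/(M s), `kd` in 1e-5 1/s) are handled by the
explicit `rates_from_table()`/`rates_to_table()` pair and tested round-trip.

## Problem sizes and determinism

The test suite and acceptance script run at desk scale by choice: repertoires
of 60–500 sequences, screens of 1e4–1e5 analyzed cells (1e7 for the spiking
bound), 50–200 replicate seeds for consensus statistics, and 16 noise-free
plus 20 noisy kinetic fits. Every stochastic component takes an explicit
seed: repertoire and screen configurations embed one, and samplers accept one,
so whole trajectories are bit-reproducible. Degenerate inputs fail loudly
(empty gates, degenerate plate ratios, unalignable sequences, baseline-only
melts, non-converged fits) rather than returning silent defaults.
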