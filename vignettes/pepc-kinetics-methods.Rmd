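---
title: "Models and methods for comparative PEPC kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for comparative PEPC kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4pepc)
```

## The biological problem

Phosphoenolpyruvate carboxylase (PEPC) catalyzes the carboxylation of
PEP by bicarbonate, the first committed step of the C4 photosynthetic
pathway. Grass lineages that evolved C4 photosynthesis recruited
existing (non-C4) PEPC genes and subsequently adapted them — and in the
genus *Alloteropsis*, some accessions instead acquired already-adapted
C4 PEPC genes from distant C4 lineages by lateral gene transfer (LGT).
Comparing the enzymes encoded by non-C4 orthologs, natively co-opted C4
copies, donor-lineage copies and laterally acquired copies requires two
kinds of computation, both provided here:

1. **Kinetic characterization** of each isoform from initial-rate assay
   data: turnover number $k_{cat}$, Michaelis constants for both
   substrates, catalytic efficiencies, and inhibition constants for the
   feedback inhibitors L-malate and L-aspartate.
2. **Sequence comparison** of the aligned protein (or CDS) panels:
   pairwise substitution and indel counts, and per-site classification
   of the replacements distinguishing focal C4 from non-C4 sequences.

Because the raw plate-reader data behind published characterizations are
rarely deposited, the package includes a first-class synthetic assay
generator so every stage of the analysis is testable end to end.

## The rate model

Inhibitor-free rates are described by the sequential bi-substrate
steady-state law

$$ v_0 = \frac{V_{max}\,[A]\,[B]}
  {[A][B] + K_A [B] + K_B [A] + K_{iA} K_B}, $$

with $[A]$ the PEP and $[B]$ the bicarbonate concentration (both in
µM internally), $K_A = K_M(\mathrm{PEP})$, $K_B = K_M(\mathrm{HCO_3^-})$
and a constant denominator term $K_{iA} K_B$. The product $K_{iA} K_B$
is **held fixed at 50 µM²** for every isoform rather than estimated:
with substrate grids that only modestly sample the low-concentration
corner, the constant term is poorly identified, and fixing it makes the
three remaining parameters comparable across isoforms. The value is a
configurable argument (`kia_kb`) for sensitivity analysis. The turnover
number is $k_{cat} = V_{max}/[E]_T$, with $[E]_T$ supplied in nM in the
assay table and converted to µM.

Two nuisance components are modeled alongside the kinetic parameters:

* **Per-run activity factors.** Rates measured with independently
  purified enzyme preparations differ by a multiplicative activity
  factor. One free factor $f_r > 0$ is estimated per non-reference run;
  the reference run (lexicographically first `run_id` unless configured)
  is fixed at $f = 1$ for identifiability.
* **Residual bicarbonate.** Sparging removes most background
  bicarbonate, but a residual offset $b_0 \ge 0$ remains and matters at
  the lowest added concentrations. When wells without added bicarbonate
  are present, $b_0$ is estimated and every well's effective
  bicarbonate is $[B] = B_{nominal} + b_0$. By default $b_0$ is
  estimated **jointly** with the kinetic parameters; a two-stage option
  (`two_stage = TRUE`) alternates between fitting with $b_0$ held fixed
  and re-estimating it from the zero-bicarbonate wells, which is
  coordinate descent on the same objective and converges to the same
  optimum on well-behaved data.

At a fixed bicarbonate concentration the law reduces exactly to a
single-substrate hyperbola with
$V^{app}_{max} = V_{max} B/(B + K_B)$ and
$K_M^{app} = (K_A B + K_{iA}K_B)/(B + K_B)$; this reduction
(`apparent_mm_at_fixed_b()`) underlies the inhibition analysis and is
tested as an algebraic identity at $10^{-12}$ relative tolerance.

## Fitting choices

The objective is **unweighted ordinary least squares on rates**.
Weighted alternatives are defensible, but unweighted fitting is the
default of the common nonlinear-regression tools used for this kind of
data and is the simplest assumption that treats all wells equally;
proportional-noise simulations confirm it recovers parameters well at
realistic noise levels.

Optimization is Levenberg–Marquardt (`minpack.lm::nls.lm`) on
log-transformed kinetic parameters and run factors, which enforces
positivity without constrained optimization, and a square-root
transform for $b_0$ (which may be exactly zero). Five deterministic
starting points are derived from data quantiles ($V_{max}$ from the
maximal observed rate scaled by 1.05–3; $K_A$, $K_B$ from the 10th–90th
percentiles of the substrate grids); the start with the lowest final
residual sum of squares wins, with ties broken by start index, and
non-convergence of all starts is reported as a flagged result rather
than silent output.

Standard errors come from the Gauss–Newton approximation to the
curvature at the optimum on the *natural* parameter scale: the
covariance is $\hat\sigma^2 (J^\top J)^{-1}$ with $J$ the Jacobian of
predictions and $\hat\sigma^2$ the residual variance. This matches what
standard nonlinear-regression software reports. $SE(k_{cat})$ follows
from $SE(V_{max})$ by the exact linear rescaling; efficiency SEs use
first-order propagation neglecting the (small) covariance between
$k_{cat}$ and $K_M$.

Negative blank-corrected rates are retained, never clipped: clipping
would bias the low-rate corner of the design upward, exactly where
$K_M(\mathrm{HCO_3^-})$ and $b_0$ are informed.

## Inhibition analysis

Malate and aspartate inhibition is summarized through secondary plots.
At a high fixed bicarbonate concentration (10 mM by default), rates
across PEP at each inhibitor concentration $[I]$ are fitted with a
hyperbola, giving an apparent efficiency
$(k_{cat}/K_m)^{app}$; the series of apparent efficiencies is then
fitted with

$$ (k_{cat}/K_m)^{app} = \frac{k_{cat}/K_m}{1 + [I]/K_I}. $$

Decisions made where the procedure is underdetermined:

* The secondary-plot model is fitted **to the efficiencies directly**,
  not to their reciprocals. A reciprocal (linearized) fit distorts the
  error structure exactly as double-reciprocal plots do in
  single-substrate kinetics; the direct nonlinear fit is the modern
  default. An inverse-variance weighted option is exposed because each
  point carries a propagated SE.
* The uninhibited point ($[I]=0$) **is shared across inhibitors**: the
  same uninhibited wells at the fixed bicarbonate concentration anchor
  both the malate and the aspartate series.
* A series with no resolvable decline is returned as a flagged
  *unbounded* result ($K_I = \infty$) with a rough lower bound — the
  smallest $K_I$ whose best-fitting curve stays within 5 % of every
  observed efficiency — rather than a spuriously large point estimate.

For simulation, the ground-truth mechanism is **competitive with
respect to PEP**: $K_A$ and $K_{iA}K_B$ are both scaled by
$(1 + [I]/K_I)$. Under this mechanism $V^{app}_{max}$ is unchanged and
$K_M^{app}$ scales exactly, so the secondary-plot relation holds
exactly and the planted $K_I$ is the estimand without approximation
error — which is what makes the noiseless round-trip test a strict
correctness check.

## The synthetic assay generator

`assay_design()` defaults describe the emulated experiment: PEP on a
log-spaced grid from 10 µM to 5 mM, added bicarbonate from 10 µM to
10 mM, inhibitors at 0/1/2.5/5/10/25 mM at 10 mM fixed bicarbonate,
enzyme at 4 nM (within the typical 2–9 nM initiation range), three
independent runs with three technical replicates, a true residual
bicarbonate of 30 µM, and run factors cycling through
1, 1.1, 0.9 — all configurable. The noise model is proportional
Gaussian noise with a 5 % CV plus an additive floor of 5×10⁻⁴ µM/s;
the floor keeps variance non-degenerate at the near-zero rates of
low-substrate and blank wells. Every generator takes an explicit seed
and restores the caller's RNG state, and identical seeds give
byte-identical tables.

`make_isoform_profiles()` supplies true parameters for the 14-isoform
panel. The magnitudes are **synthetic placeholders encoding only the
qualitative category pattern**, not measured values: co-opted native
copies have 1.87× / 2.26× the $k_{cat}$ of their non-C4 orthologs, the
laterally acquired copies have convergently high $k_{cat}$ (≥ 1.5× any
co-opted native) and high $K_M(\mathrm{PEP})$ (≥ 1.8× any native and
> 3.1× the co-opted copies they replaced), elevated
$K_M(\mathrm{HCO_3^-})$, each LGT clustering near its donor, while the
non-C4 *ppc-1P6* enzyme is the least inhibitor-sensitive (largest
$K_I$) and the non-C4 *ppc-1P3* enzymes the most sensitive.
`check_profile_orderings()` asserts this pattern programmatically.

The generator can also emulate the raw measurement: NADH-coupled
absorbance traces at 340 nm (`simulate_trace()`, Beer–Lambert with
ε = 6220 M⁻¹cm⁻¹ and 1 cm path by default, both configurable because
plate-reader effective path lengths vary), standard-curve calibration
(`calibrate_nadh()`), and initial-rate extraction
(`extract_initial_rate()`: least-squares slope over the first 10 % of
the trace or the time to 10 % NADH depletion, whichever is shorter,
sign-flipped, calibrated, blank-subtracted, with a quadratic curvature
warning for nonlinear windows).

What the generator does *not* emulate — and therefore what passing
recovery tests do not demonstrate about real data: coupling-enzyme lag
kinetics, instrument drift, temperature fluctuation, pipetting
covariance between wells of a plate, allosteric regulation
(glucose-6-phosphate activation, phosphorylation state), and any
systematic misspecification of the rate law itself (e.g. substrate
inhibition at high PEP).

## Sequence comparison rules

All sequence operations take **pre-aligned** input (alignment itself is
done with external tools) and use 1-based coordinates on the ungapped
reference sequence, the numbering convention used for PEPC site
comparisons (traditionally anchored to the *Zea mays* protein).

* **Substitutions** are counted over columns where both sequences carry
  unambiguous residues; any column with a gap in either sequence is
  excluded, so substitution counts and indel events are reported
  separately. **Indels** are maximal gap runs private to one sequence,
  counted as single events; columns gapped in both sequences are
  ignored entirely.
* **Ambiguity characters** (X for protein, N for nucleotide) are
  treated as missing data, excluded from both substitution counts and
  fixation assessment.
* At each site where the two focal (cloned) sequences differ, the C4
  residue is **ancestral** if it occurs in at least one non-C4 ortholog
  (*membership* rule; a *majority* rule is exposed as an option, but
  membership matches the question actually asked — could this residue
  have been drawn from standing non-C4 variation?), otherwise
  **novel**; it is **fixed** if every C4-group sequence with a residue
  at that column shares it, otherwise **polymorphic**.
* Sequences with internal stop codons are flagged pseudogene-like and
  excluded from fixation assessment by default (they no longer evolve
  under protein-level constraint), with an include switch.
* `extract_third_codon_positions()` reduces a CDS alignment to columns
  3, 6, 9, …, the positions used for phylogenies that avoid biases from
  convergent protein-level adaptation; gap runs whose length is not a
  multiple of 3 trigger a frame-shift warning naming the sequences.

Correctness of both counting and classification is established against
naive per-column brute-force re-implementations on hundreds of random
panels, and on toy panels with planted site classes
(`simulate_toy_panel()`).

## Reporting conventions

Fold changes between isoforms are plain ratios with first-order SE
propagation. Category-level “> x-fold” statements are operationalized
as the **minimum pairwise ratio** across members of the two categories,
i.e. as a lower bound that every member pair satisfies. Reports round
parameters to 3 significant figures and ratios to 2. The pipeline
(`run_pipeline()`) defaults to one pooled fit per isoform across runs
(run factors absorb preparation differences); per-run fits can be
obtained by filtering the assay table.

## Problem sizes and verification

The test suite and the acceptance script use deliberately compact
problem sizes chosen to exercise every code path with comfortable
statistical margins: 6×6 noiseless grids for exact recovery (errors
< 10⁻⁴ relative, in practice ~10⁻¹⁶), 100 simulated datasets at 5 %
proportional noise for Monte-Carlo recovery (median relative errors
1–4 %, bound 10 %), 40 replicate series per decade of $K_I$ over
0.5–50 mM (median error ~7 %, bound 15 %), 100 random panels per
sequence oracle, and the full 14-isoform pipeline under the default
three-runs-by-three-replicates design.

## Known limitations

* The fit assumes one enzyme concentration per isoform table; wells
  with differing $[E]_T$ are averaged for the $k_{cat}$ conversion and
  their activity differences are absorbed by run factors.
* The standalone residual-bicarbonate estimator ignores run factors;
  use the joint fit when multi-run data contain zero-bicarbonate wells.
* Only competitive inhibition is modeled; mixed or uncompetitive
  mechanisms, and activator effects, are out of scope.
* Site classification assumes the group assignment is correct and the
  alignment is reliable in the classified columns; unalignable terminal
  regions should be trimmed upstream.
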