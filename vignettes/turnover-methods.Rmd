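---
title: "Models and methods: SILAC pulse-chase turnover and IP-MS interactome filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: SILAC pulse-chase turnover and IP-MS interactome filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacturnover)
```

## The turnover model

The pulse-chase design labels the proteome to near-saturation with heavy
Lys/Arg, then switches to light medium. From the switch (chase time
t = 0), pre-existing ("old") protein carries the heavy label and newly
synthesized protein is light. In postmitotic cells there is no dilution
by division, so the heavy signal decays only by degradation. We model
each protein p in genotype g as first-order:

$$ H_{p}(t) = H_{p}(0)\, e^{-k_{p,g} t}, \qquad
   R_p(t) = \frac{H_p(t)}{H_p(0)} = e^{-k_{p,g} t}, \qquad
   t_{1/2} = \frac{\ln 2}{k}. $$

Under the **steady-state pool assumption** — synthesis balances
degradation, so total (heavy + light) abundance is constant over the
chase — the expected light signal is the complement of the heavy decay.
This assumption is what makes the peptide detectability (which tracks
total ion current) time-independent in the simulation, and it is the
standard reading of a chase in nondividing cultures. It would fail for
proteins being actively induced or repressed during the chase; the
analysis of ratios does not depend on it, but the generator does.

### From peptides to protein ratios

The per-peptide quantitative measure is the MS1 chromatographic peak
area. `rollup_protein_heavy()` averages heavy areas over a protein's
labeled peptides — arithmetic mean, singletons included — separately at
each time. `turnover_profiles()` then forms
`R(t) = rollup(t) / rollup(0)` subject to three filtering rules:

1. a protein-genotype needs the t = 0 anchor **and** at least one later
   time point;
2. individual ratios with `R(t) >= 1` are discarded (an "old" protein
   cannot exceed its starting amount under the model; such values are
   noise or identification artifacts);
3. a protein-genotype with no surviving ratio is dropped.

A zero heavy area is treated as the absence of a labeled peptide, not as
a measured zero: absent rollups are `NA`, never 0, so missingness cannot
masquerade as fast degradation.

Peptides are averaged without intensity weighting because the enrichment
and ratio statistics are defined per peptide, not per ion; an
intensity-weighted mean would let one high-responding peptide dominate a
protein. The protein-level ratio deliberately does **not** require the
same peptide set at both times (the rollup is a protein-level
abundance), whereas `peptide_level_comparison()` requires the matched
peptide at both times and normalizes each peptide by its own t = 0
value, so the peptide's ionization efficiency cancels exactly. These are
two different estimators with different robustness: the protein rollup
uses all data but is exposed to peptide-composition drift between
times; the peptide-level version is immune to composition drift but
needs the peptide re-observed.

### Persistence calls

At each time, proteins with a retained ratio in **both** genotypes form
the common set; a common protein *persists* when its mutant ratio is
strictly greater than control. Ties count as non-persisting — the call
is "more labeled", and with continuous areas exact ties essentially
only arise from degenerate inputs, where the conservative call is the
right one. Under a no-effect null the persistence fraction is 0.5 by
symmetry, which the test suite verifies by simulation; fractions well
above 0.5 indicate a genotype-wide slowdown. `persists_all` requires
commonality *and* persistence at every examined time — a deliberately
stringent intersection that mirrors drawing the cross-time Venn and
reading off its center.

No multiple-testing correction is applied to persistence calls: they
are descriptive set memberships, not hypothesis tests. The two t tests
(paired across proteins on normalized mean intensity; unpaired across
peptides for a single protein) are reported with raw p values; the
unpaired test defaults to Welch's form, with the classical
equal-variance form available (`var_equal = TRUE`) for parity with
spreadsheet-style analyses. Degenerate inputs (zero spread) are mapped
to p = 1 when means agree and p = 0 when they do not, instead of
erroring, so noiseless data flow through the same code path.

### Decay fitting

Since R(0) = 1 by construction, `fit_decay()` fits `ln R(t) = −k t`
through the origin: `k̂ = Σ t·(−ln R) / Σ t²` — closed form, no
initialization, no tolerance knobs. Points with R ≥ 1 were already
removed upstream and are not re-admitted (a through-origin fit would let
a single R > 1 at a late time drag k̂ negative). On noiseless input the
fit is exact to machine precision; under multiplicative log-normal noise
ln R is additive-noise linear, so k̂ stays unbiased — the suite checks
median |k̂−k|/k ≤ 10% at 20% CV noise with 10 peptides per protein.
Nonlinear or precursor-pool models were considered and rejected: with
four time points and one anchor they add parameters the design cannot
constrain.

## The interactome filter

Each genotype has three independent IP replicates, each a paired bait
(VCP) and IgG-control run of spectral counts. Per replicate:

- **exclusivity route**: present in the VCP run, absent from the IgG run
  (count 0; a configurable `igg_floor` can relax absence to "at most
  floor counts");
- **ratio route**: present in both, raw `VCP count / IgG count`
  **strictly** greater than 3. The boundary is exact: a ratio of
  exactly 3 fails, which the acceptance suite probes with planted
  3:1 counts.

The >3 ratio uses raw counts, not bait-normalized ones: both runs of a
pair come from the same lysate and instrument session, so their scales
are shared, and the ratio is defined as its own quantity. Bait
normalization (`count / bait count`, bait ↦ 1) is used where magnitudes
are compared **across** runs — the per-replicate `vcp_ratio` reported
with every call and the genotype-enrichment t tests. A protein counts as
a genuine interactor for a genotype only when it qualifies, by either
route, in **all** replicates; absence from a replicate's VCP run blocks
the call (absence is informative for presence calls) while the same
absence is `NA`, not 0, in ratio averaging (absence is not a magnitude).
Interactor sets are then partitioned into mutant-only / control-only /
shared, and the shared set is tested per protein with unpaired t tests
on the three bait-normalized ratios per genotype at α = 0.05,
uncorrected by default with a Benjamini–Hochberg option — the
uncorrected α is the fidelity choice for this screening step, and the
suite verifies its type-I rate is calibrated rather than silently
inflated.

## What the generators emulate — and what they do not

`simulate_turnover()` draws, in a single documented RNG-stream order:
protein abundances (log-normal, median 10⁶ area units), degradation
rates `k ~ 10^Normal(-0.89, 0.40)` per day, a slowed subset, peptide
counts and tryptic-looking sequences, per-peptide ionization factors
(log-normal, shared across every run so that peptide self-normalization
is meaningful), then per-cell noise and dropout. The rate distribution
was chosen by moment matching so that, in expectation over proteins,
half the heavy signal is gone by day 5 and ~15% remains at day 21 —
the decay regime of long-lived-protein studies in postmitotic neurons;
its defaults are study conditions, not free dials. Defaults
`label_efficiency = 0.9`, `noise_cv = 0.2`, and a logistic
intensity-dependent dropout (midpoint 4.7 on log₁₀ expected total area,
steepness 2, giving roughly 20% dropout for dim peptides and ~7% at the
median) are stated as defaults, not as estimates fitted to any real
dataset — the source experiments do not report their noise or
missingness magnitudes.

The generator does **not** emulate: ratio compression from co-eluting
light interference, charge-state and modification multiplicity, shared
peptides across protein groups (records are taken at face value),
arginine-to-proline conversion, or run-order batch drift.
Correspondingly, passing recovery tests shows the *rules and estimators*
are implemented correctly and behave as designed under realistic noise —
it does not certify performance on real Census-style exports, where
protein inference and interference add error modes the simulation
leaves out.

`simulate_ip()` plants true interactors with bait-proportional Poisson
counts (and zero IgG leak by default), background proteins with
comparable VCP/IgG Poisson counts, and genotype-exclusive subsets sized
153/709 and 157/709 by default so the partition machinery is exercised
at the composition scale of a real VCP screen. It does not model
crosslinker chemistry, antibody batch effects, or count overdispersion
beyond Poisson.

## Numerical and interface choices

- **Strict parsing.** Input TSVs are parsed cell-by-cell under C-locale
  rules (decimal point only); malformed numbers, unknown labels and
  duplicate run keys are structured errors carrying the row number.
  Duplicate peptide observations within one run are rejected, not
  summed — upstream quantifiers already aggregate per peptide, so a
  duplicate indicates a malformed export.
- **Determinism.** Writers emit canonically sorted TSV (UTF-8, LF) and a
  SHA-256 manifest; `run_pipeline()` with one config and seed reproduces
  identical digests, which the suite asserts.
- **Normalization is opt-in.** Census-style areas are carried raw;
  `normalize_runs()` (median-of-ratios against a per-peptide geometric
  mean reference) exists because scaling a single run demonstrably
  distorts ratios, but it is off by default since the canonical analysis
  defines ratios within protein and the source procedure does not
  normalize across runs.
- **Histogram convention.** Enrichment bins are half-open `[a, b)` with
  the final bin closed, so 100% peptides are counted once.

## Problem sizes in the test suite

Oracle-equivalence checks run 50 random tables of ≤10 proteins
(turnover) and ≤20 proteins × 3 replicates (interactome) against plain
brute-force loops. Recovery and calibration use 500-protein /
10-peptide simulations and 50 null seeds of 200 proteins — sizes at
which binomial and Monte-Carlo error are small compared to the asserted
bounds while the whole suite runs in about a minute.

## Known limitations

- **Day-1 sensitivity.** For slowly degrading proteins the
  mutant-control ratio gap after one day, `e^{-k t r} − e^{-k t}` at
  t = 1, is small compared to realistic measurement noise, and the
  mutant ratio sits close enough to 1 that the `R < 1` rule removes a
  share of genuinely slowed proteins. The all-times persistence set is
  therefore conservative at ≥10% measurement CV: the suite and the
  acceptance script compute the recall of planted slowed proteins, and
  at `noise_cv = 0.1` it falls well short of complete (about half),
  recovering to 100% only as noise approaches zero. Detecting subtle
  slowdowns of long-lived proteins needs either later first sampling or
  replicate-aware ratio averaging; single-table persistence calls at
  day 1 should be read as high-specificity, not high-sensitivity.
- The ratio-< 1 rule, applied per genotype, conditions the data before
  the genotype comparison and can bias per-time common sets toward
  faster-degrading proteins.
- Spectral-count enrichment tests with n = 3 per genotype have little
  power; the partition (presence/absence across all replicates) is the
  robust output, the volcano quantities are exploratory.
- Protein inference is out of scope: rows are taken at face value, and
  shared peptides double-count toward every accession they are listed
  under.
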