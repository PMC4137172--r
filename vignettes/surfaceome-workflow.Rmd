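---
title: "Determining a Gram-positive surfaceome: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining a Gram-positive surfaceome: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfaceomics)
```

## The problem

Gram-positive bacteria expose proteins on a single membrane wrapped in a
thick peptidoglycan wall. The surface-exposed subset — the surfaceome —
mediates transport, signalling, wall remodelling and, in metal-reducing
organisms, extracellular electron transfer. Two extraction strategies
dominate: enzymatic wall digestion (protoplast formation, releasing
wall-associated and outward-facing membrane proteins) and brief treatment of
intact cells with immobilized trypsin (cell shaving, with an enzyme-free
"shedding" control). Both inevitably lyse some cells, so the extracts mix
genuine surface proteins with abundant cytoplasmic contaminants, and the
central computational task is to separate the two using independent lines of
sequence-based evidence.

This vignette describes the models and procedures the package implements,
the tunable parameters and their defaults, what the synthetic generator does
and does not emulate, and the design decisions taken where the methodology
left room.

## Consensus localization

Three predictor families contribute one call per protein each:

* a transmembrane-helix scan (one-line records; `PredHel` and a topology
  string such as `i98-117o`), which can only assert "membrane" or abstain;
* a PSORTb-style classifier over {cytoplasm, cytoplasmic membrane, cell
  wall, extracellular}, which may also abstain (`Unknown`) or exclude the
  cytoplasm without naming a compartment (`Non-cytoplasmic`, kept as the
  distinct value `SURFACE_UNKNOWN`);
* a LocateP-style classifier, which additionally flags lipoproteins and
  LPxTG wall anchoring.

Calls are canonicalized through a fixed, editable mapping table
(`inst/extdata/label_map.tsv`) with keyword fallbacks, so vocabulary variants
("Lipid anchored", "Secretory (released)") land on the right compartment and
anything unrecognized maps to `UNKNOWN` with a warning rather than silently.

The consensus rule trusts an assignment supported by at least two tools.
Manual case-by-case adjudication of conflicts does not scale and is not
reproducible, so conflicts are resolved by a deterministic evidence
hierarchy and *labelled* as such (`confidence = "unresolved"`), keeping them
visible for curation:

1. ≥ 2 agreeing informative calls → that compartment, `consensus`.
2. Exactly one informative call → kept as `evidence_tiebreak`, except a
   lone cytoplasm call contradicted by a membrane anchor, which becomes
   `SURFACE_UNKNOWN` — the protein is potentially membrane bound, and a
   screen for surface proteins should keep it.
3. Mutually conflicting calls → `SURFACE_UNKNOWN` when a cytoplasm call
   stands against membrane evidence, or when the tools disagree only about
   *which* surface compartment; `UNKNOWN` when a cytoplasm call conflicts
   with a non-membrane surface call and no anchor exists to adjudicate.
   This last case is genuinely undecidable from the inputs, and defaulting
   it to either side would bias the partition; it is the one conflict class
   excluded from the surfaceome.

The rule is invariant to the order in which tools are supplied, and adding
an agreeing call never lowers confidence — both properties are tested.

`is_surface` is true for every compartment except `CYTOPLASM`, and for
`UNKNOWN` only when a membrane anchor is present.

### Membrane anchors

Helix topology is reduced to an anchor class: none, N-terminal anchor,
C-terminal anchor, or polytopic (≥ 2 helices). A single helix is assigned to
a terminus when it starts within `n_term_window = 35` residues of the
N-terminus or ends within `c_term_window = 40` residues of the C-terminus;
these windows cover typical signal-anchor and tail-anchor geometries and are
arguments, not constants. A mid-protein single helix — rare but possible —
is assigned to the terminus whose half contains its midpoint, a deterministic
tie-break that avoids a fifth ambiguous class. A single N-terminal helix is
treated as an anchor rather than a cleaved signal peptide unless the
predictor marks the protein secreted: an uncleaved signal anchor and a
signal peptide are indistinguishable in topology output alone.

### Binding mechanisms

Exactly one mechanism per protein, by fixed priority: covalent LPxTG wall
anchoring (reported by LocateP-style tools) beats any non-covalent wall
domain; among wall domains SLH (PF00395) > LysM (PF01476) > CWBD1 (PF01473)
> CWBD2 (PF04122) > GW (PF13457); then lipoprotein lipid anchor; then
transmembrane anchor; else none. Domain hits count only at independent
e-value ≤ `evalue_cutoff = 1e-5` — a conventional Pfam significance level,
configurable because the methodology itself fixes none. Pfam accession
versions are stripped at parse time so rule tables can use bare accessions;
the truncated accession "PF0039" is *not* accepted as the S-layer domain.

## Quantification

**Normalized total spectra.** Every sample's total spectral count is scaled
to the common value `mean(raw per-sample totals)`; scale factors multiply
each protein's count. Absence is treated as count 0, not missing data —
in spectral counting, absence of spectra is zero evidence. Totals after
scaling agree with the common value to a relative 1e-9 (tested; in practice
machine precision).

**The differential-expression rule.** Between two conditions with means
`hi ≥ lo`, a call requires all three of: `hi ≥ 2·lo` (fold), `hi − lo ≥ 5`
(absolute floor against low-count noise) and `(hi − err_hi) > (lo + err_lo)`.
The error estimators are the semi-difference `|x₁ − x₂|/2` for strict
duplicates and the sample standard deviation for pooled replicates; the
treatment duration of pooled replicates (60/120 min) is carried as metadata
only. "Accounting for the error" is formalized here as strict non-overlap of
the mean ± error intervals — the strictest natural reading; the choice is
recorded in the output (`separated` column) so a weaker reading can be
audited. With `lo = 0` the fold is reported as infinite and the fold clause
is considered satisfied, leaving the absolute and error clauses to decide.
Swapping the conditions flips the direction and changes nothing else
(tested exhaustively on a grid against an independent clause evaluator).

**Significance B.** Ratio spread in label-based proteomics shrinks with
intensity, so each protein is scored against an intensity-local null. Rows
are sorted by intensity and cut into consecutive bins of at least
`bin_size = 300` rows (remainder merged into the last bin; a short table is
one bin). Within a bin, with `m` the median and `u`, `l` the 84.13th and
15.87th percentiles (linear interpolation, the standard type-7 quantile),
the robust z is `(r − m)/(u − m)` above the median and `−(m − r)/(m − l)`
below; `p = erfc(|z|/√2)`, capped at 1, so the bin median scores exactly
p = 1. A degenerate side (`u = m` or `m = l`) scores z = 0 rather than
dividing by zero. Benjamini–Hochberg is used across all proteins — the
methodology names no multiple-testing procedure, and BH is the field
default. No ratio re-centering is applied by default; a median-centering
switch (`center = TRUE`) exists for uncalibrated mixes. Bin size 300 and the
interpolation rule are implementation choices, both configurable.

On 10,000 null standard-normal ratios the fraction with p < 0.05 is
0.051–0.053 across seeds: slightly above the nominal 0.05 because the bin
percentiles are estimated from 300 observations, within three Monte-Carlo
standard errors of nominal (tested at a fixed seed).

**ΔΔCt.** `ΔCt = Ct(target) − Ct(reference)` per condition,
`ΔΔCt = ΔCt_A − ΔCt_B`, relative expression `2^−ΔCt`, cross-condition fold
`2^−ΔΔCt` — exact closed forms, tested to machine precision.

## Membership and function tallies

`membership_tally()` is pure set arithmetic over the two experiments, with
every row split surface/cytoplasm; its identities
(`total = unique + shared`, `total = surface + cytoplasm`) hold by
construction. `crosstab_surfaceome()` tabulates the five function categories
against localization, experiment membership and differential-expression
class; every axis sums to the surface-protein total, and the printed total
row is recomputed from the body rather than trusted. Function assignment —
historically a manual judgement — is an ordered, first-match-wins rule table
over description keywords and domain accessions, shipped as plain data
(`inst/extdata/function_rules.tsv`) so it can be edited without code
changes. The default table is an approximation: category boundaries like
"protease" vs "other" are inherently fuzzy, and users with curated
annotations should replace it.

## The synthetic generator

`generator_config()` + `simulate_study()` emulate the study design: a
proteome with known compartments, per-tool calls drawn from truth-conditioned
confusion matrices, helix topology consistent with the truth, planted LysM/
SLH domains on cell-wall proteins, two extraction experiments × two
conditions × duplicate samples of negative-binomial spectral counts, lysis
contamination, and a dimethyl-ratio table in which every protein appears
twice with opposite label orientation.

Key default choices, made once:

* **Compartment proportions** 0.50 / 0.35 / 0.05 / 0.10 (cytoplasm /
  membrane / wall / extracellular): a cytoplasm-dominated proteome whose
  surface classes are led by the membrane, as in real Gram-positive
  surfaceomes.
* **Confusion matrices**: table-based predictors are 70–88% correct with
  8–17% abstention, hardest on the wall and extracellular classes; the
  helix scan only ever answers "membrane" or abstains, because its file
  format cannot express anything else. The noise-free limit
  (`identity_confusion()`) sets all three tools to the identity, and in that
  limit the consensus must — and does — recover the true surface partition
  exactly.
* **Contamination**: rate 0.5 at abundance factor 0.3. Lysis is severe in
  practice (neither extraction method avoids it), so the default deliberately
  stresses the classifier.
* **Counts**: negative binomial (dispersion 8) around log-normal baselines
  (median 30); `noise = "none"` replaces draws with their means for exact
  oracle tests.
* **Spikes**: 20 proteins at fold 4, half up in each condition, baselines
  floored at 20 — a differential protein far below the absolute-count floor
  would be undetectable by the rule's own design.
* **Ratio noise**: standard deviation `0.3/√(intensity/10⁶)`, matching the
  intensity-binned assumption behind significance B.

All draws come from R's Mersenne-Twister generator (inversion method for
normals) under the configured seed, in a private RNG scope that restores the
caller's random state; identical configurations give byte-identical files.

What the generator does **not** emulate: peptide-level identification (no
sequences, spectra or retention times), correlated predictor errors (tools
err independently, whereas real predictors share failure modes on unusual
topologies), compositional distortion of spectral counts, label impurity,
and protein-abundance covariance between the two extraction experiments.
Tests passing on synthetic data therefore demonstrate the correctness and
calibration of the algorithms under the stated model — not predictor
accuracy on any real proteome.

## Problem sizes and numerical notes

The test and acceptance workloads use 2,000-protein proteomes for recovery
checks, a 10,000-row ratio table for calibration, and an exhaustive
15,376-point grid for the differential rule — sizes at which every
behaviour of interest is exercised while a full run of suite plus
acceptance script completes in about a minute. Degenerate inputs are
decided, not left to chance: a single replicate has error 0; equal means
give fold 1 and no call; a zero-total sample is an error naming the sample;
an empty FASTA warns and returns zero rows; ties in intensity are broken by
protein id so binning never depends on row order.

## Limitations

* The consensus hierarchy encodes one defensible reading of "use the
  available evidence" for conflicts; other hierarchies are plausible, which
  is why every conflicted protein is flagged `unresolved` rather than
  silently resolved.
* Significance B's slight type-I inflation (≈ 0.052 at α = 0.05) is inherent
  to estimating bin percentiles from finite bins; larger `bin_size` reduces
  it at the cost of coarser intensity matching.
* The function rule table is keyword-based and first-match-wins; it is a
  transparent approximation of expert annotation, not a replacement.
* No peptide-to-protein inference, predictor execution, or spectra-level
  processing: the package starts where those tools' output tables end.
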