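---
title: "Differential HDX-MS analysis with hdxdiff: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential HDX-MS analysis with hdxdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxdiff)
library(dplyr)
```

## The measurement and the question

In hydrogen–deuterium exchange mass spectrometry (HDX-MS), a protein is
diluted into deuterated buffer and its backbone amide hydrogens exchange for
deuterium at rates governed by hydrogen bonding and solvent accessibility.
After a chosen labeling time the reaction is quenched, the protein is
digested by pepsin, and each peptic peptide's mass increase over its
undeuterated form (the *deuterium uptake*, in Da) is read off the centroid
of its isotopic envelope. Comparing uptake between two states of the same
protein localizes, at peptide-to-residue resolution, where conformational
dynamics change.

`hdxdiff` implements this differential workflow for the study design in
which it is most demanding: two MHC class I allotypes measured in a
conditional-ligand-**loaded** state, a peptide-**receptive** state produced
by UV hydrolysis of the conditional ligand, and a **rescued** state in which
excess high-affinity peptide is added back after hydrolysis. Each state is
labeled for 25 s, 2.1 min, 10.4 min, 52.1 min and 4.34 h, in triplicate.
Because no raw data accompany that design, the package also contains a
forward simulator that generates uptake tables with the same statistical
structure, so every downstream stage is testable end to end.

## Exchange model

The simulator works in the EX2 limit of the Linderstrøm-Lang model:
exchange events at different residues are independent and first-order, so a
residue $i$ with intrinsic rate $k_{int,i}$ and protection factor $P_i \ge 1$
contributes $1 - \exp(-(k_{int,i}/P_i)\,t)$ deuterons on average after time
$t$. The noiseless expected uptake of a peptide is

$$D(t) = \beta \cdot f_{D_2O} \sum_{i \in \mathcal{E}}
  \left(1 - e^{-(k_{int,i}/P_i)t}\right),$$

where $\mathcal{E}$ is the set of the peptide's exchange-competent residues,
$f_{D_2O}$ is the deuterium fraction of the labeling buffer (default 0.95,
reflecting a 20-fold dilution into D$_2$O buffer) and $\beta$ is a
multiplicative back-exchange recovery factor (default 0.7, a typical value
for a refrigerated LC setup). Replicates add Gaussian noise
(`uptake_sd`, default 0.05 Da — a typical between-replicate SD for a
well-behaved system) and are floored at zero.

Exchange-competent residues are all residues of the peptide except its
first residue and all prolines: proline has no backbone amide hydrogen, and
the N-terminal amide of a peptic fragment back-exchanges too fast to retain
label. The same rule defines the *maximum theoretical uptake*
(`exchangeable_amides()`), the denominator of relative fractional uptake.
Some laboratories exclude the first **two** residues instead; this is the
`first_residue_exclusion = 2` switch, and it propagates consistently from
`RunConfig` to every module. Residue 1 of the mature protein never
exchanges observably under either convention.

Intrinsic rates default to a uniform base rate (50 min$^{-1}$, the order of
magnitude of unstructured amide exchange at neutral pH) rather than full
sequence-dependent reference tables: the analysis pipeline never consumes
intrinsic rates, and recovery tests need known ground truth, not chemical
realism. Per-state protection factors carry all of the structure; the demo
scenario draws them log-uniformly over $10^{1.5}$–$10^{4.5}$ per residue so
that the five labeling times straddle the full range from
almost-instantaneous to barely-started exchange.

## The synthetic study

`demo_scenario_config()` encodes the study conditions: two heavy-chain
allotypes (275 residues, differing at six polymorphic groove positions) each
with an associated β2-microglobulin (98 residues), three states, five
labeling times, triplicates. The receptive state lowers protection only
inside configured sub-regions — by default residues 96–104 and 130–148 of
the heavy chains (fold-changes 12 and 25 for allotype A, 8 and 18 for
allotype B), mimicking the α1/α2-1 groove sub-helices that respond to
peptide loss, and residues 54–62 of β2m (fold 3), the β-strand patch that
responds weakly. The rescued state's protection profile is *identical* to
the loaded one, which is the model's statement that peptide rebinding fully
reverses the perturbation. Ground-truth regions are carried in the scenario
metadata so recovery can be scored.

Digestion maps are generated to hit a coverage target (98.5% for the heavy
chain, 100% for β2m) and a redundancy target (5.95 and 5.46 peptides per
covered residue) with mean peptide lengths of 14 and 13 residues — the map
statistics of a well-covered pepsin experiment. The generator tiles the
covered segments with overlapping peptides, tops up with random peptides
until the redundancy target is met, verifies itself with
`coverage_redundancy()` (tolerance: ±5 coverage points, ±20% redundancy)
and raises an explicit infeasibility error when the targets are
contradictory. Both allotypes of a protein share one digestion map (same
enzyme, near-identical sequences), which also gives the coordinate-based
common-peptide matching real work: polymorphic positions make sequences
differ inside shared intervals, and `common_peptides()` matches on
`(start, end)` while flagging the sequence differences.

What the simulator does **not** emulate: EX1/mixed kinetics in uptake
tables (bimodal envelopes exist only in the spectra module), intrinsic-rate
sequence dependence, correlated (structure-element) protection,
peptide-dependent noise, back-exchange variation across peptides, and
carry-over or mis-identification artifacts. Passing recovery tests
therefore demonstrates that the *analysis* is correct under the stated
statistical assumptions, not that those assumptions hold for any particular
instrument.

## From peptides to residues

Per-peptide replicate statistics use the sample (n−1) standard deviation;
single replicates are flagged. Between states, `differential_uptake()`
reports $\Delta D = \bar{D}_{pert} - \bar{D}_{ref}$, its relative fractional
form $\Delta D / D_{max}$, and the standard error of the difference
$\sqrt{s_{ref}^2/n_{ref} + s_{pert}^2/n_{pert}}$. Uptake above the
theoretical maximum is flagged, never clamped — it is evidence of a
convention mismatch and should stay visible.

Residue-level consolidation follows the heat-map rendering rules used for
overlapping peptide maps:

* a peptide `(s, e)` reports on residue `r` only if `s < r ≤ e` (its own
  N-terminal residue is never used);
* each residue takes its value from the **shortest** eligible peptide;
* ties are broken by the peptide whose C-terminal residue is greatest;
* residues with no eligible peptide are explicit gaps.

The tie-break phrase "residue closest to the protein C terminus" admits two
readings (greatest end vs. greatest start); `hdxdiff` implements greatest
*end* residue, the only parameter-free reading for interval data, and — for
the doubly-tied case that collapsed charge variants can produce — breaks
remaining ties by greatest start. Peptide selection is purely
coverage-based, so a residue's source peptide is identical across labeling
times, and the map is invariant to input ordering. The implementation
assigns peptides in rank order; the test suite checks it cell-for-cell
against a brute-force per-residue oracle on a thousand random maps.

A consequence worth knowing when reading heat maps: a residue whose
representative peptide straddles a perturbed-region boundary shows a
diluted (or smeared) value. In the demo scenario this limits how exactly
the top decile of |Δ-fractional-uptake| can recover the ground-truth
regions — Jaccard overlap is typically 0.5–0.8 at peptide-level resolution,
not 1.0. That is a property of peptide-resolved HDX itself, not of the
implementation.

## Dataset-level statistics

`coverage_redundancy()` computes map statistics with *full* interval
membership (no N-terminus exclusion — a coverage statistic, not a rendering
statistic): coverage is the percentage of residues under the union of
intervals, redundancy the mean peptide count over covered residues only.

`normalized_increase()` implements the normalization used for
membrane-proximal domains: the uptake increase caused by the perturbation
divided by the reference state's uptake, both at the longest labeling time
(4.34 h by default, exposed as `ref_time`). Per-replicate values pair
replicate indices in the numerator over a common mean-reference
denominator, so their mean equals the summary statistic. Non-positive
denominators exclude a peptide with a flag.

`paired_t_test()` is the standard paired two-tailed t over peptides
(df = n − 1), with zero-variance difference vectors reported as degenerate
rather than producing NaN. `peptide_state_comparison()` tests each
timepoint from replicate summary statistics and combines timepoints with
Benjamini–Hochberg correction. The per-timepoint statistic defaults to the
**pooled-variance** (Student) t rather than Welch: with triplicates the
Welch–Satterthwaite approximation is measurably conservative (empirical
size ≈ 0.03 at nominal 0.05), while the pooled test is exact under the
homoscedastic replicate-noise model that one instrument, one buffer and one
operator usually justify — and that the simulator instantiates. Welch
remains available (`method = "welch"`) for heteroscedastic designs. The
acceptance suite verifies both against `stats::t.test()` to 1e-10 and
checks the empirical type-I error of the default on 2000 null tests.

## Spectra

The spectra module models the deuteration envelope of a peptide with
$n$ exchange-competent sites as a binomial (or binomial-mixture)
distribution over the number of incorporated deuterons, with peak spacing
1.00628 Da per deuteron divided by charge. Natural isotope structure is
omitted by default — it convolves identically onto both states and cancels
in centroid differences — but a convolution hook (`isotope_envelope`)
exists. The centroid of a simulated envelope obeys the binomial-mean
identity $m = m_0 + n p \Delta m / z$ exactly, which the tests use as a
closed-form oracle.

`classify_modality()` distinguishes the single gradually-shifting envelope
of EX2 exchange from the two-population envelope that EX1 kinetics or
partial complex dissociation would produce. It fits one- and two-component
binomial mixtures by maximum likelihood (EM from three spread starts) after
normalizing intensities to a fixed pseudo-count of 1000 ions — the
normalization that makes the call invariant to uniform intensity scaling
and gives the BIC penalty a scale — and calls bimodality when BIC improves
by more than 2 and the fitted components are non-degenerate (weights above
1e-3, probabilities separated by more than 1e-3). On a seeded benchmark of
500 spectra with well-separated components (|p₁ − p₂| ≥ 0.4) and 2%
multiplicative intensity noise (a realistic instrument CV), the
misclassification rate is under 5%.

## Fluorescence polarization

Receptivity of the emptied binding groove is quantified from
fluorescence-polarization time courses of a labeled reporter peptide:
`mP = 1000(S − GP)/(S + GP)`. Two summaries are provided because both
appear in practice without a stated loss formula: the baseline-subtracted
receptive fraction `(mP_t − mP_unbound)/(mP_0 − mP_unbound)` with the
unbound-peptide level defaulting to 50 mP (the default metric for "loss of
binding sites"), and the raw ratio `mP_t/mP_0` ("percent of the initial
level"). They differ exactly by the baseline, and both are exposed.

## Numerical and interface conventions

* Coordinates are 1-based inclusive everywhere; residue 1 is the first
  residue of the mature protein (the first FASTA character).
* Times are minutes internally; readers and the CLI accept `"25s"`,
  `"2.1"`, `"4.34h"` and normalize.
* Uptake is Daltons above the undeuterated centroid; `max_uptake` is the
  exchangeable-amide count.
* The state-table CSV dialect is comma-separated UTF-8 with a mandatory
  header; DynamX-style column names are aliased. Files are read as text
  first so that unit-suffixed exposures are not mangled by numeric
  guessing.
* One master seed drives a deterministic child-seed hash per
  (protein, state) stream, so adding a protein to a scenario does not
  reshuffle another protein's noise.
* Degenerate inputs (zero-variance tests, empty peptide sets, all-zero
  spectra, infeasible digestion targets) raise flags or explicit errors;
  nothing is silently clamped or dropped.

## Problem sizes used by the test suite

The packaged checks run at desk scale by design: consolidation and
coverage oracles on 1000 random maps of up to 300 residues and 100
peptides; statistical calibration on 2000 null (peptide, time) tests;
localization and reversal on the full two-allotype demo scenario (about
5,000 rows per protein) with 60 null replicate scenarios for the reversal
threshold; 500 spectra in the modality benchmark; law-of-large-numbers
checks at 10,000 replicates. These sizes give the stochastic checks
comfortable margins while keeping a full run to a couple of minutes.

## Known limitations

* Residue-level values are representative-peptide values, not deconvolved
  single-residue rates; no overlap-based sub-peptide resolution is
  attempted.
* The EX2 assumption is global in the uptake simulator; mixed-kinetics
  uptake curves cannot be generated.
* `classify_modality()` assumes the spectrum's peaks are the consecutive
  deuteration states of a known base peak; it does not pick peaks from
  profile data.
* Back-exchange is a single scalar per experiment in the simulator and is
  deliberately *not* corrected out of measured uptake — the analysis
  reports relative quantities in which it largely cancels.
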