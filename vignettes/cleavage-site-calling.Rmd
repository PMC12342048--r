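---
title: "Calling protease cleavage sites from paired-digest quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling protease cleavage sites from paired-digest quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degradomics)
library(dplyr)
```

## The experimental design being modelled

A purified substrate is incubated with an active protease and, in parallel,
with its catalytically inactive E→Q point mutant. Both reactions are
trypsin-digested and quantified label-free by LC-MS/MS with a semi-tryptic
search (up to 3 missed tryptic cleavages). Because the two arms differ only
in protease activity, any peptide whose abundance is much higher with the
active enzyme — and whose non-tryptic terminus cannot be explained by
trypsin — is evidence that the protease cut there. This vignette walks
through the model, its parameters and the design decisions, in the order
the pipeline applies them.

## Ratios, singletons, z-scores

For each unique (peptide, preceding residue, following residue) record the
pipeline forms the abundance ratio active/control. Two conventions matter:

* **Singletons.** A peptide detected in only one condition has no finite
  ratio; it receives the fixed arbitrary ratio **100** (log₂ 100 = 6.64) on
  its directed scale. The convention is exact — no noise is ever applied to
  it — so singleton records are recognizable in any output.
* **Two directed scales.** Semi-tryptic discovery works on the
  active/control scale; spanning-tryptic corroboration works on the
  converse control/active scale. Both are computed in one pass, each with
  its own scale statistics.

The z-score of a record is

$$z = \frac{\log_2 r - \hat\mu}{\hat\sigma}$$

where $\hat\mu,\hat\sigma$ are the mean and standard deviation of the log₂
ratios of peptides found in **both** conditions. Singletons are excluded
from the estimate but receive a z-score (at log₂ 100). Two choices here
were genuinely open:

* z-scores are computed on **log₂ ratios, not raw ratios**. Published
  ratio/z pairs produced by this class of analysis are mutually consistent
  only on a log scale with a both-group mean near 0; solving the same pairs
  on the raw scale yields an impossible negative mean ratio.
* The **sample** (n−1) standard deviation is the default
  (`sd_type = "population"` is available); with the both-group population
  sizes involved (hundreds of peptides) the difference is negligible.

Degenerate inputs fail loudly: fewer than two both-group peptides, or a
zero both-group standard deviation, are errors rather than silent NaNs.

## From peptides to sites

`classify_termini()` labels each peptide terminus tryptic, non-tryptic, or
protein terminus. Trypsin cleaves C-terminal to K/R; suppression of
cleavage before proline is ON by default but exposed as `proline_rule`
because search engines differ in this setting and the original searches'
configuration is typically not reported. A protein terminus is
deliberately *non-evidentiary*: a peptide ending at the mature terminus is
not proteolytic evidence, so for peptide-level status it counts like a
tryptic terminus.

Candidates are all active-only semi-tryptic singletons (selected regardless
of z, since their z is an artifact of the convention) plus both-group
semi-tryptic records with z strictly above the threshold (default **2**).
Each candidate's non-tryptic terminus defines the boundary: a non-tryptic
N-terminus at start $s$ gives the site $(s-1, s)$, a non-tryptic C-terminus
at end $e$ gives $(e, e+1)$. Duplicate boundaries merge into one site
accumulating all evidence. Ordering is deterministic everywhere: sites by
position, peptides within a site by descending ratio then lexicographically.

Substrates with internal repeats can localize a peptide more than once. The
default policy is: prefer spans whose flanking residues match the recorded
context, call sites from the first span, and emit a warning listing the
alternatives — deterministic and auditable rather than silently arbitrary.

Semi-tryptic peptides enriched on the *control* side have no mechanistic
explanation under the design; they are reported in a separate
`unexplained_control` output, never suppressed.

`find_spanning_evidence()` attaches every fully tryptic record whose span
**strictly** contains the boundary (start ≤ P1 and end ≥ P1′; a peptide
ending exactly at P1 does not span). A spanning peptide corroborates the
site when it is control-only or its converse z exceeds the threshold.

```{r pipeline, eval = FALSE}
protein <- read_fasta(system.file("extdata", "comp_scaffold_synthetic.fasta",
                                  package = "degradomics"))
quant <- read_quant_table(system.file("extdata", "adamts4_comp_peptides.tsv",
                                      package = "degradomics"))
calls <- call_sites(quant, protein, z_threshold = 2)
tidy(calls)
```

The bundled substrate FASTA is a *synthetic scaffold*: every residue that
carries peptide evidence is fixed by published peptide sequences and their
flanking contexts, while stretches without evidence (including the signal
peptide) are deterministic filler from a reduced alphabet. Site positions,
counts and comparisons depend only on the evidence-bearing residues.

## Specificity profiling

`extract_windows()` reads P4–P4′ windows (the window half-width is
configurable; 4 covers every subsite position usually discussed) around
each site, with gap markers off the termini. `positional_enrichment()`
compares the observed residue frequency (%) at each position with a
background composition — by default a fixed, documented human Swiss-Prot
table (`aa_background()`), user-overridable, rather than a live lookup of
an external reference set that changes between releases. Significance is a
two-sided z-test from the normal approximation to the binomial
($p_0$ = background/100, $n$ = non-gap count) at α = 0.05 with **no
multiple-testing correction**, matching how percentage-scoring logo servers
are typically configured; the calibration test below shows what that
implies. Degenerate backgrounds ($p_0 \in \{0, 1\}$) yield no call rather
than an infinite statistic.

## Kinetics

Two single-parameter models are fitted by ordinary least squares
(Levenberg–Marquardt via `minpack.lm`), consistent with what graphing
software defaults would have produced:

* **Progress curves**: $P = 1 - e^{-[E]\,t\,k_{cat}/K_m}$, fraction
  cleaved vs time at known enzyme concentration, replicates pooled. The
  starting value comes from the log-linearized median; a curve with no
  measurable conversion is a non-identifiability error.
* **Morrison tight-binding**: fractional velocity vs inhibitor
  concentration at known total enzyme $E_t$. The discriminant is clamped
  at zero against floating-point negatives. The starting Ki uses the
  half-inhibition point ($I_{50} \approx K_i + E_t/2$ for a tight binder).
  Inputs are assumed pre-normalized vi/v0; `fit_v0 = TRUE` floats a scale
  nuisance parameter for raw-velocity series.

All concentrations are handled in molar internally. Standard-curve
interpolation for ELISA readouts is linear with out-of-range signals
flagged, not extrapolated, by default — a deliberate choice over 4PL
fitting, which is routine and orthogonal to the models here.

## What the synthetic generators emulate

`simulate_degradome()` reproduces the *structure* of a paired-digest
experiment: fully tryptic background peptides with log₂ ratios
Normal(0, sd 2 by default — the magnitude implied by published both-group
populations of this kind); injected cleavage events that emit the
semi-tryptic products flanking the bond up to the nearest tryptic terminus
(active-only with probability 0.9, else both-group with a +6 log₂ shift);
and site-spanning tryptic peptides that become control-only with
probability 0.5. Abundances are log-normal around a cosmetic base
intensity — only the ratio structure matters to the caller. The truth
record is versioned JSON so recovery can be diffed mechanically.

`simulate_progress_curves()` defaults mirror a neoepitope-ELISA versicanase
time course: 5.5 nM enzyme, seven time points over 0–20 min, three
replicates, Gaussian sd 0.02 on the cleaved fraction, truth
kcat/Km = 2.4 × 10⁵ M⁻¹s⁻¹. `simulate_inhibition_series()` mirrors a
quenched-fluorescence tight-binding titration: Et = 0.2 nM, inhibitor 0–8 nM
in duplicate with sd 0.03, truth Ki = 45 pM. The titration points cluster
around Et (0, 0.05, …, 0.5, 1, 2, 4, 8 nM) because that is where a
tight-binding series carries its information; a log-spaced grid far above
Et would leave Ki weakly identified, which is a property of the assay, not
of the fitter.

What these generators do **not** emulate: spectrum-level effects
(ionization efficiency, missed identifications correlated with sequence,
retention-time artifacts), inter-run normalization, or protease kinetics of
the digestion itself. Passing recovery tests therefore demonstrates the
statistical machinery is correct under the stated noise model, not that any
particular real dataset is free of those effects.

## Numerical choices and problem sizes

The test suite asserts, among others: exact closed-form values
(`morrison_velocity(0.2 nM, 0.2 nM, 0.045 nM) = 0.375`), agreement of the
digest enumeration with brute force on random sequences, agreement of the
site caller with an independent brute-force boundary check on simulated
data, exact recovery of both kinetic parameters from noiseless data,
Monte-Carlo recovery under the generators' default noise (kcat/Km within 5%
in ≥95% of 100 seeded runs; Ki within 15% in ≥90%), end-to-end site
recovery with zero false positives across 20 seeds at noise sd 1, and
type-I calibration of the specificity test under null sampling across 50
seeds. These problem sizes (100/50/20 seeds; 5000-point population checks)
keep the full suite under half a minute while leaving Monte-Carlo standard
errors small relative to the asserted margins.

## Limitations

* Site calling is bounded by trypsin coverage: a cleavage event whose
  products are too short, too long, or flanked so that no semi-tryptic
  peptide is observable cannot be called (detection efficiency in the
  generator models exactly this).
* I/L are indistinguishable by mass; the caller treats sequences as
  reported by the search engine and does not attempt disambiguation.
* The z-score model assumes a unimodal both-group ratio distribution; a
  control arm with substantial autolytic activity would violate it and
  shows up in the `unexplained_control` output.
* kcat and Km are not separable from depletion curves — only their ratio
  is estimated, by design.
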