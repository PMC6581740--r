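---
title: "Scoring AP-MS interactomes from fragment-level DIA intensities"
author: "baitprey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring AP-MS interactomes from fragment-level DIA intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baitprey)
```

# The analysis problem

Affinity-purification mass spectrometry (AP-MS) asks which proteins (the
*prey*) co-purify with an epitope-tagged receptor (the *bait*) beyond what
sticks to the resin non-specifically. When the purifications are quantified
by data-independent acquisition (DIA/SWATH), the raw observable is a
fragment-ion intensity for every (protein, peptide, fragment, injection)
combination. `baitprey` implements the full path from that fragment table to
biological statements: which preys are *specific* interactors, which of them
are *dynamic* (recruited or released upon stimulation), what fraction of
bait molecules each prey occupies (*interaction stoichiometry*), and — for
mixed two-cell SILAC experiments — from which cell each interactor
originates.

The intended design is a time course of receptor stimulation (e.g.
pervanadate, which drives maximal phosphorylation of ITIM/ITSM motifs and
thus recruitment of SH2-domain effectors) with paired biological
replicates, run once with the tagged bait and once with a matched
untagged-control background.

# Procedure

## Fragment reliability filtering

Fragment ions of the same peptide should rise and fall together across
injections; fragments that do not are interference or integration
artifacts. Two rules are applied per peptide, after a detection filter that
keeps a fragment's rows in a condition group (background x condition x
time) only when it was detected at least `minDetectPerCondition = 2` times
among that group's replicates:

1. **Correlation rule.** A reference profile is built as the across-fragment
   median of log2 intensities per sample; fragments whose Pearson
   correlation with the reference (over their shared observed samples) is
   below `minCorrelation = 0.25` are dropped.
2. **Deviation rule.** On the survivors the reference is recomputed and each
   fragment's mean absolute log2 deviation from it is measured *after
   removing the fragment's constant offset* — fragment ions of one peptide
   differ by fixed response factors, which say nothing about reliability.
   Fragments whose deviation exceeds `sdFactor = 2` times the
   across-fragment mean deviation are dropped.

The parameter names and defaults follow the established fragment-selection
conventions for DIA ("standard deviation factor" and "minimal correlation");
the exact formulas above are this package's documented contract, since
those options name parameters rather than equations. Each rule can be
disabled by setting its parameter to a permissive value (`minCorrelation =
-1`, large `sdFactor`).

Numerical choices: a fragment sharing fewer than 3 observed samples with
the reference, or with zero variance, is kept (a correlation computed on
less carries no information); when the deviation spread is at numerical
noise level (< 1e-6 log2 units) the fragments are effectively proportional
and the relative deviation rule does not fire. The rules are applied in one
pass and do not cascade.

## Roll-up, imputation, bait normalization

Peptide quantity is the sum of retained fragment intensities per sample,
protein quantity the sum of its peptide quantities; a quantity is missing
only when every constituent is missing. Missing entries of an analyte are
imputed with the `imputeQuantile = 0.01` quantile of that analyte's own
observed values across all samples — the convention that a non-detection
reflects signal near the analyte's observed low end. Quantiles use the
type-7 (linear interpolation) definition throughout for bit-stability.
Rows with no observation at all are dropped and reported. For the dynamic
analysis, quantities are divided by the bait's quantity in the same sample
(per-sample, not per-condition, so replicate pairing survives
normalization).

Phosphopeptides carry a modification token in their peptide id and are
routed to a synthetic protein id `<protein>@<peptide_id>` before testing,
so a regulated phosphopeptide is neither outvoted by its parent protein's
unmodified peptides nor removed as an "unreliable" analyte.

## Differential testing: paired t, aggregated by the median order statistic

Each peptide is tested with an ordinary paired t statistic on
per-replicate log2 differences between two condition groups sharing
replicate indices (n - 1 degrees of freedom, two-sided). The protein-level
p-value is the reproducibility-optimized aggregation: with n peptide
p-values and k = floor(n/2) + 1, the k-th smallest peptide p-value m is
referred to the Beta(k, n - k + 1) distribution — the null law of the k-th
order statistic of n uniforms — so a protein is significant only when its
*median* peptide is, rewarding effects reproduced across peptides. The
protein-level fold change is the median of the peptide log2 fold changes.
Benjamini–Hochberg adjustment is applied per contrast across all proteins
tested.

Degenerate inputs: imputation can create zero-variance difference vectors;
these get p = 1 when the mean difference is zero and p = 1e-15 otherwise
(a defined floor keeps the beta aggregation finite). The upper-median
convention k = floor(n/2) + 1 fixes the even-n ambiguity; the fold-change
median still uses the conventional mean of the two central values. A
moderated peptide-level statistic is a possible extension, deliberately
not the default: the aggregation, not variance shrinkage, is what carries
the reproducibility logic here.

## Two orthogonal filters for interactor calling

1. **Specific interactors.** A protein is enriched in a condition when its
   bait-vs-control fold change exceeds the preset threshold (3-fold for
   primary mouse T cells, 6-fold for Jurkat-type cell lines, which show
   stickier background) at BH FDR < 0.01; it is called specific when
   enriched in at least 2 independent conditions and not matched by the
   contaminant list. The enrichment gate is one-sided (bait over control).
   "Condition" means distinct bait-vs-control contrasts (time points);
   counting experiments instead is a parameter, since "independent
   conditions" is genuinely ambiguous.
2. **Dynamic interactors.** Among the specific interactors, a protein is
   dynamic when its bait-normalized quantity changes at least 2-fold in
   either direction (recruitment or loss) at FDR < 0.05 in at least one
   stimulated-vs-unstimulated contrast.

The bundled contaminant list holds the eleven recurrent AP background
proteins removed in the reference analysis plus prefix rules for the
keratin (KRT), myosin (MYH/MYL) and tubulin (TUB) families; it is fully
user-replaceable and deliberately does not bundle the community CRAPome
resource. Contaminant-matched proteins are flagged, never silently
dropped, and removal commutes with testing. The bait and its tag
pseudo-entry are excluded from calling but kept in every report.

## Stoichiometry by iBAQ

iBAQ divides a protein's summed intensity by its number of theoretically
observable tryptic peptides, giving a quantity proportional to molar
abundance; prey iBAQ over bait iBAQ is then the fraction of bait molecules
occupied by that prey, computed per condition from the mean over that
condition's replicates. Digestion cleaves after K/R except before P, fully
tryptic, 0 missed cleavages, counting peptides of length 6–30 — the
original iBAQ convention; all of it is configurable (and logged) because
published analyses rarely print these settings. When the tagged bait
sequence is supplied it is used for the bait's count; otherwise the native
sequence is used with a warning.

## SILAC origin calls

For two-cell-type experiments (light-labeled T cell bound to heavy-labeled
antigen-presenting cell), per-protein light/heavy ratios are computed per
replicate and averaged, after substituting undetected channel values with a
floor set at the 1% quantile of all detected intensities in the run. The
floor is derived from the data rather than fixed as an absolute number so
the rule ports across datasets; an explicit override is accepted, and the
floor actually used is reported. A protein with light fraction
ratio/(1+ratio) at or above 0.95 is called T-cell-exclusive, at or below
0.05 APC-exclusive, otherwise mixed; 0.95 is a convention standing in for
qualitative language ("exclusively", "mixed") and is a parameter. The
per-replicate-then-mean order matches the per-sample division phrasing of
the underlying protocol; the reported light fraction is derived from the
mean ratio so the two reported fields remain mutually consistent.

# The synthetic-data generator

Real deposited AP-MS raw data cannot be reprocessed at desk scale, so the
package ships a generator whose outputs have known truth for every claim
the pipeline makes. Fragment intensity is modeled as

    protein quantity x peptide weight x fragment weight x lognormal noise

with weights drawn once per analyte and fixed across samples — exactly the
correlation structure the reliability filter assumes. Key conditions, all
settable in `simConfig()`:

* a true interactor's expected tagged-arm quantity at time t is
  `baitAbundance * occupancy * kinetic(t) * (nPep_prey / nPep_bait)`; the
  peptide-count factor makes iBAQ exactly invertible, so recovered
  stoichiometry can be compared to programmed occupancy without a detour;
* its control-arm carry-over is the peak tagged level divided by
  `interactorFold` (default 8), so the programmed bait-vs-control log2
  fold change is `log2(interactorFold * kinetic(t))`;
* the bait itself carries over into untagged controls at 1/`baitFold`
  (default 64) of its tagged level — untagged bait is expressed and binds
  resin weakly, and enrichment volcanoes show the bait at a large but
  finite fold change; a structurally absent bait would make its fragment
  profiles noise-only and the correlation filter would then remove
  fragments at random;
* synthetic sequences are concatenations of valid tryptic peptides
  (6–24-mers ending in K, no internal K/R/P), so the digestion count is
  exact by construction; the bait gets the top of the peptide range,
  mirroring the maximal sequence coverage of the purified bait;
* peptide and fragment weights are lognormal (sd 0.3 on the log scale)
  normalized to sum one — quantified peptides of a protein, and the top
  5–6 extracted fragment ions of a peptide, respond within a few-fold
  range;
* background proteins are log-uniform over 10^-3 to 10^0.5 of the bait
  abundance (the dynamic range of an AP eluate), identical in expectation
  in both arms; simulated contaminants are enriched "sticky" binders with
  keratin/tubulin/myosin-style identifiers, because a protein equal in
  both arms can never be called and would leave list-based removal
  untested;
* each fragment measurement is missing independently with `missingRate`
  (default 0.1); an optional left-censored mode drops detection
  logistically below a limit at the `missingRate` quantile of expected
  intensities — the regime the low-quantile imputation rule presumes, and
  one that biases faint analytes low by construction;
* the bait carries a phospho/unmodified ITIM-like peptide pair (2% of its
  signal, split by a transient phosphorylation curve peaking near 2 min)
  so phospho routing and site profiles are exercised end to end;
* SILAC mode splits every tagged sample into light/heavy channel samples
  by each protein's programmed origin fraction before noise.

One integer seed drives a single deterministic generator; the global RNG
stream is never touched.

**What the generator does not emulate** — and what green tests therefore do
not show about real data: chromatographic effects (retention-time drift,
co-elution interference), charge states, injection-level total-intensity
variation (cross-run normalization is out of scope, so the generator omits
the systematic sample effects that would require it), peptide
detectability differences, incomplete SILAC incorporation, and
arginine-to-proline conversion.

# Benchmark conditions

The acceptance suite and `scripts/acceptance.R` use these problem sizes,
chosen as the package's standing benchmark:

* **Order-statistic calibration**: the beta-median aggregation against the
  binomial-tail closed form and a 10^6-draw Monte-Carlo order-statistic
  oracle, n in {1,3,5,7,9}, median p in {0.01, 0.1, 0.5, 0.9}.
* **Null calibration**: 2,000 background proteins, two time points, three
  paired replicates, cv 0.2, no missingness (the null design), no
  interactors; protein p-values should be near-uniform (KS < 0.05) and the
  full two-filter pipeline should stay silent. Under fragment dropout the
  detected fragment composition differs between paired samples and the t
  reference is mildly miscalibrated — a real property of sum-based roll-up,
  documented rather than patched; the calibration statement is about the
  statistical machinery itself.
* **Spike-in recovery**: 20 interactors (10 constitutive, 10 with a
  transient recruitment profile) at 8-fold enrichment among 500 background
  proteins, cv 0.2, 10% missingness.
* **Stoichiometry recovery**: programmed occupancies {13%, 1.4%, 69%}
  (the span of reported SH2-phosphatase stoichiometries) recovered within
  ±20% per run at full scale, with bias assessed over 20 seeds at 100
  background proteins.
* **SILAC origin**: programmed light fractions {1, 0.5, 0} classified at
  threshold 0.95.

# Known limitations

* Roll-up by summation makes protein quantities sensitive to which
  fragments happened to be detected; an intensity-weighted or
  consistent-set roll-up would be less variable but is outside the fixed
  contract.
* The imputation rule assumes missingness concentrates at an analyte's low
  end; under truly random dropout it is slightly anticonservative for the
  paired test (see the null-calibration note above).
* iBAQ stoichiometry inherits iBAQ's assumptions: equal detectability of
  countable peptides and linear response; fractions can exceed 1 for
  preys with extreme response factors.
* The SILAC floor bounds, but does not remove, the compression of ratios
  for proteins near the detection limit.
* Printed interactor counts from the original study cannot be reproduced
  here without its deposited quantitative tables; the filters that would
  reproduce them are implemented and parameterized (`callingParams("mouse")`
  / `callingParams("jurkat")`).
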