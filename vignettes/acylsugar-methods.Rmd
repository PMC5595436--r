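---
title: "Acylsugar metabolomics: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acylsugar metabolomics: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acylsugar)
```

Acylsugars are trichome-secreted defense metabolites of the Solanaceae: a
sucrose or hexose core esterified with short- to medium-chain aliphatic acyl
groups. A family-wide LC/MS survey of these compounds poses four
computational problems that this package addresses: (i) annotating observed
pseudomolecular ions with acylsugar compositions and checking them against
CID fragmentation; (ii) quantifying how diverse and how species-specific the
surface-metabolite profiles are; (iii) bounding the theoretical chemical
space that the biosynthetic enzymes could reach; and (iv) choosing
transcript regions for virus-induced gene silencing (VIGS) that will not
cross-silence related genes. This vignette explains each model, its
assumptions, the tunable parameters, and the choices made where the design
was genuinely open.

## Composition model and mass arithmetic

A composition is a sugar core plus a multiset of saturated acyl chains.
Esterifying one n-carbon chain adds CnH(2n−2)O (the acid minus the water of
condensation), so for a core of monoisotopic mass $M_0$ carrying $n$ chains
with $T$ total carbons the neutral mass is

$$M = M_0 + T\,(m_C + 2m_H) + n\,(m_O - 2m_H),$$

which depends only on $(n, T)$. Two consequences drive the design:

* **Branch degeneracy.** iso/anteiso/straight chains of equal carbon number
  are exactly mass-degenerate; compositions differing only in branch labels
  share a mass and a name. Annotations therefore report one row per carbon
  partition with all consistent labels attached.
* **Partition degeneracy.** Distinct carbon partitions with equal $(n, T)$ —
  say (2,8), (4,6) and (5,5) for a di-acylsucrose — are also exactly
  mass-degenerate. No mass measurement can rank one above another, so
  "recovered as the top annotation" is defined throughout as membership in
  the tied-minimum-|error| set. Resolving these ties requires fragment
  evidence, which `predict_fragments()`/`score_annotation()` provide.

Names follow the field's convention: `S3:15(5,5,5)` is a sucrose core with
three chains of fifteen total carbons, carbon counts listed ascending.
Chains run from 2 to 12 carbons; plant acylsugars carry two to six chains,
bounded above by the core's free hydroxyls (eight on sucrose, five on a
hexose). Hydroxylated, unsaturated and malonylated chains are outside the
default alphabet: annotated plant acylsugars in this family are saturated
aliphatics, and the alphabet is JSON-configurable for users who need more.

Atomic monoisotopic masses come from a single hard-coded IUPAC table;
nominal masses are mass numbers of the most abundant isotopes (not rounded
monoisotopic masses — the two agree for CHNO species up to roughly a
kilodalton, which covers every alphabet formula, and the agreement is
asserted in the tests over the alphabet rather than assumed). Adduct m/z
values use proton/electron-correct ion masses. Positive-mode ions are
`[M+NH4]+`; the negative-mode default is the formate adduct `[M+HCOO]-`,
standard for this LC gradient chemistry, with `[M-H]-` available.

## Annotation: decomposition, fragments, mass-defect screen

`decompose_mass()` inverts the mass identity above: for each chain count it
solves for the total carbon count within tolerance and expands the bounded
integer partitions of $T$ (at most partitions of 72 into 6 parts), which is
complete by construction; the tests verify equality with an exhaustive
enumeration of all ~5,000 carbon multisets. The default tolerance is 5 ppm,
typical for a TOF instrument.

Fragment prediction mirrors what CID spectra of acylsugars show. In
negative mode each distinct chain is lost from the `[M-H]-` ion as its
ester net addition (ketene-equivalent loss; acid-form losses are optionally
added, since either form appears in practice and the data rarely
distinguish them), down to the fully deacylated sugar ion. In positive mode
glycosidic cleavage of the `[M+NH4]+` ion releases the furanose ring as a
neutral hexose plus ammonia — 197 Da nominal when that ring is bare — so
each hypothesis "k chains on the departing ring" predicts one fragment.
Ring assignment stays at this hypothesis level: positional (R2 vs R4)
isomers are mass-invisible and NMR territory.

`acylsugar_like()` screens peaks for acylsugar-plausible masses. The mass
defect of acylsugars grows by ~0.0157 Da per added carbon, so over the full
theoretical m/z range (≈471–1480 for formate adducts) the defects of real
acylsugars sweep almost the whole unit interval and wrap past the integer
boundary near m/z 1420. A single global fractional-mass window is
therefore vacuous — it accepts nearly anything. The screen instead compares
an observation's fractional mass against the envelope of theoretical
acylsucroses within ±25 Da of it, padded by ±0.01 Da. Both the
neighbourhood and the padding are parameters, and an explicit global window
can be supplied to override the construction.

## Peak processing

The processing chain reproduces a standard untargeted workflow: peaks with
height strictly above 500 counts are kept (an empirical background cutoff;
strictness at the boundary is unit-tested), areas are normalised as
(area / internal-standard area) / dry weight, and samples are aligned by
greedy centroid grouping — peaks visited in decreasing height join the
nearest feature within both tolerances (default 0.02 Da, 0.1 min; the
instrument-class defaults, fully exposed) or found a new one, with
height-weighted consensus coordinates and deterministic tie-breaking. The
peak-sharing matrix reports, for each ordered sample pair, the percentage
of the row sample's features present in the column sample; it is
row-normalised and deliberately asymmetric. Presence means a strictly
positive matrix entry, consistent with the pre-filter semantics. Entropy
statistics run on peak height (intensity-as-count); area is retained for
quantification. No retention-time warping or gap-filling is attempted.

## Diversity statistics

With $P_{ij}$ the relative intensity of peak $i$ in sample $j$ (rows sum to
1), the suite computes, all in log base 2 with $0\log 0 \equiv 0$:

* per-sample Shannon entropy $H_j = -\sum_i P_{ij}\log_2 P_{ij}$;
* per-peak mean frequency $\bar P_i = \frac1t\sum_j P_{ij}$;
* peak specificity
  $S_i = \frac1t\sum_j (P_{ij}/\bar P_i)\log_2(P_{ij}/\bar P_i)$, zero for
  a peak equally frequent everywhere and $\log_2 t$ for a sample-unique
  peak;
* sample specialization $\delta_j = \sum_i P_{ij} S_i$.

All four are non-negative ($S_i \ge 0$ by Jensen's inequality since the
frequency ratios average to 1) and are verified against direct loop
re-evaluations of the formulas to 1e−9 on random matrices, plus their
closed forms. Producer/non-producer entropy distributions are compared with
a two-sample two-sided Kolmogorov–Smirnov test; the asymptotic p-value is
the default because realistic group sizes (tens of samples) are in the
asymptotic regime, with the exact variant available for small groups.

## Theoretical chemical space

`count_theoretical()` exposes both counting semantics because they answer
different questions. Positional mode treats acylation positions as
distinguishable — eight short chains at three pyranose positions and twelve
chains at the fourth gives 8·8·8·12 = 6144 tetra-acylsucroses — which is
the biosynthetically motivated estimate (each position is acylated by a
different enzyme with its own donor preferences). Multiset mode counts
unordered chain combinations, the resolution at which mass spectrometry
actually distinguishes compositions; it is never larger. Counts are checked
against explicit enumerations at desk scale.

## VIGS fragment design

The silencing-construct screen tiles the target transcript into overlapping
20-nt windows (step 1 — the densest, most conservative choice) and flags a
window when (a) some off-target sequence matches it on either strand with
identity strictly above 95%, or (b) its longest single-base run exceeds
50% of the window. Two strictness points matter and are boundary-tested:
19/20 identity is exactly 95% and is *not* flagged, and for the identity
rule at k = 20 "strictly above 0.95" reduces to perfect 20-mer matching, so
screening uses exact k-mer lookup over both strands rather than a full
aligner (mismatch-tolerant scanning via Biostrings engages automatically at
lower thresholds, and externally computed hit tables can be emulated by
lowering the threshold). A run of exactly 10 bases (50%) is not flagged;
11 is. The "homopolymeric stretch" wording is ambiguous between longest
run and dominant-base total; the longest-run reading is the default and the
alternative is a flag.

Maximal runs of at least 13 consecutive clean windows (">12") become
candidate regions, reported with a suggested 300-bp construct sub-interval
when long enough (leftmost placement; all placements within a clean run tie
on clean-window count). The target itself and declared homologs are
excluded from the off-target set. Coordinates are 1-based inclusive
throughout, the R/Bioconductor convention. A structural guarantee follows
from the construction: any shared 20-mer (or ≥11-nt run) lying wholly
inside a selected region would itself be a flagged window inside the
region, so selected regions can never contain one — the tests confirm this
on simulated transcriptomes with planted paralog blocks.

## Synthetic data: what it emulates, what it does not

The peak simulator encodes the study design the statistics assume: ten
producer and ten non-producer species, two tissue replicates each. Producer
species carry 100–300 true peaks whose m/z values are exact formate-adduct
masses of randomly drawn 2–6-chain compositions; panels are largely
species-specific (5% drawn from a shared pool), and each tissue replicate
carries each panel peak with probability 0.8, reproducing the
within-species peak sharing seen across tissues. True-peak heights are
log-normal (log10 mean 4.0, sd 0.6) floored above the 500 filter; every
sample also receives 10–30 noise peaks with heights log-normal around 500,
deliberately straddling the filter so its strict boundary is exercised.
Retention times are uniform over a 0.5–20 min gradient and consistent per
composition, so alignment can group them.

Measurement noise is modelled as m/z jitter with a 5-ppm normal spread
truncated at ±5 ppm, i.e. instrument error sits inside the default
annotation tolerance. An unbounded 5-ppm normal would place ~32% of
observations outside a 5-ppm window, which describes a mis-calibrated
search rather than a matched one; the truncation encodes the matched-
tolerance assumption explicitly rather than hiding it in a smaller sd.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: chromatographic peak shape and co-elution, isotope
patterns, in-source fragments and multiple adducts per compound, intensity
correlation between related compositions, retention-time drift between
runs, and real background chemistry richer than uniform-m/z noise. The
pipeline's recovery rates on simulated data are upper bounds.

The transcriptome simulator plants identical 40-nt paralog blocks in
exactly two transcripts each (exact sharing is the planted ground truth;
diverged paralogs below the identity threshold are intentionally not
modelled) and 12-nt homopolymer runs at recorded offsets, with plantings
kept non-overlapping.

## Problem sizes and numerical choices

The test and acceptance workloads use the default study design (20 + 20
samples, ~2,000–4,500 peaks per dataset), 100 decomposition targets against
a ~5,000-entry enumeration oracle, 50 random matrices for the formula
oracle, 100 seeded simulations for the entropy-separation property, and 20
seeded transcriptomes for region purity — sizes chosen so the whole suite
runs in minutes on one core while keeping the stochastic properties
well-resolved. Degenerate inputs are handled explicitly: all-zero samples
error in `relative_frequencies()`; features absent everywhere are excluded
from specificity with a warning and contribute zero to specialization;
zero-feature samples get a zero sharing row with a warning; sub-window
transcripts error at tiling. All simulations are reproducible from a single
integer seed, and the pipeline echoes its effective configuration as JSON.
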