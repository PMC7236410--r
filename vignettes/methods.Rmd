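---
title: "Methods: annotating F8 missense variants and testing inhibitor association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating F8 missense variants and testing inhibitor association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(f8missense)
```

## The problem

Missense variants of *F8* cause hemophilia A by degrading the function of
coagulation factor VIII, and patients under replacement therapy may
develop neutralizing alloantibodies (inhibitors). For a severe-hemophilia
cohort of annotated missense variants, this package asks three questions:
where on the FVIII protein do the substitutions fall; how chemically
drastic are they; and does either predicted deleteriousness or a change
of physicochemical class associate with inhibitor development. All
analysis is at the level of one row per annotated variant carrying a
protein change, a severity, an inhibitor status
(positive/negative/unknown), and optional raw outputs from five effect
predictors.

## Coordinates and domain model

Two residue numbering systems coexist in the hemophilia literature.
Legacy numbering counts from the first residue of the *mature* protein;
HGVS numbering includes the 19-residue signal peptide, so
`hgvs = legacy + 19`. The package's internal convention is legacy
(1..2332), because the classical landmark residues — the thrombin
activation sites Arg372, Arg740 and Arg1689 — are quoted in mature
coordinates. HGVS input is shifted on ingestion (`numbering = "hgvs"` in
`read_cohort()`), which confines the off-by-19 risk to a single
conversion point.

The domain architecture is data, not code (`read_architecture()`): the
default partitions 1..2332 into A1 1–372, A2 373–740, B 741–1647,
A3 1648–2019, C1 2020–2172, C2 2173–2332. FVIII is really
A1-a1-A2-a2-B-a3-A3-C1-C2, with three short acidic spacers; we merge a1,
a2 into the preceding A domain and a3 into A3. This is the only merged
convention under which the A-group length equals the published 1112
residues, which is why it was adopted. One consequence is deliberate:
the C-group then totals 313 residues, one more than the 312 sometimes
quoted. No contiguous partition ending at residue 2332 with A = 1112 and
B = 907 can give C = 312, so the package documents 313 and does not
force agreement. Domain tabulations exclude the B domain, which plays no
direct role in coagulation and is conventionally dropped from this
analysis.

## Physicochemical scoring

The four-class scheme — hydrophobic (A,V,F,P,M,I,L,W), polar uncharged
(S,Y,N,Q,C,T,H,G), acidic (D,E), basic (K,R) — ships as a plain-text
table and is injectable for sensitivity analyses. Tryptophan sits in the
hydrophobic class: the complete 20-residue listing places it there, and
the classifier requires a partition. A substitution within a class is
intra-class, across classes inter-class.

Grantham distance is the weighted Euclidean difference in
composition/polarity/volume space,

$$D_{ij} = \rho\sqrt{\alpha(c_i-c_j)^2 + \beta(p_i-p_j)^2 + \gamma(v_i-v_j)^2},$$

with the classical weights $\alpha = 1.833$, $\beta = 0.1018$,
$\gamma = 0.000399$ packaged as data. Rather than hard-coding the
published scale constant, $\rho$ is computed at load time so that the
mean over all 190 unordered residue pairs is exactly 100; the resulting
distances round to the published matrix (minimum L–I = 5, maximum
C–W = 215), and the test suite asserts the mean-100 normalization to
±0.5 and the semimetric properties.

GV/GD scoring generalizes the pairwise distance to an alignment column:
the observed residues span an axis-aligned range box in (c, p, v) space;
GV is the weighted norm of the box extents and GD the weighted norm of
the component-wise distance from the substituting residue to the nearest
box point (zero inside the box). On singleton columns this reduces
exactly to the pairwise Grantham distance — tested exhaustively over all
20 × 19 cases — and GD values are binned into C0…C65 by the
largest-threshold-below rule over {0, 15, 25, 35, 45, 55, 65}. This is a
method re-implementation for arbitrary user-supplied alignments, not a
claim of numerical equality with the Align-GVGD web service, whose
curated alignments are not redistributable.

## Predictor harmonization

Each tool's raw output is first binned into its published categories.
The published SIFT ranges (0.00–0.05, 0.051–0.10, 0.101–0.20, 0.201–1.00)
leave micro-gaps; we close them into contiguous upper-inclusive bins
[0, 0.05], (0.05, 0.10], (0.10, 0.20], (0.20, 1] so every score in
[0, 1] is classified with minimal deviation from the printed boundaries.
The PolyPhen-2 bands (benign 0.000–0.999, possibly damaging 1.500–1.999,
probably damaging ≥ 2.000) do not match the tool's usual 0–1 posterior
scale; they are implemented verbatim, and scores in the unmapped
[1.0, 1.5) band are flagged `undetermined` rather than silently
rescaled. Binary votes: SIFT intolerant/potentially-intolerant →
deleterious, borderline/tolerant → neutral; PolyPhen probably/possibly →
deleterious, benign → neutral, undetermined → abstain; Align-GVGD
C45–C65 → deleterious, C0–C25 → neutral, C35 → abstain (it belongs to
neither published range); KD4v and MutationTaster map one-to-one.

The default consensus strategy, `kd4v_primary`, adjudicates by KD4v
whenever present — KD4v is the only one of the five that also exploits
the 3D structure — falling back to a majority of the remaining votes.
`majority` and `unanimous` are provided purely for sensitivity analysis;
only the KD4v rule is anchored in the source analysis. Ties and
all-abstain sets yield `undetermined`, which is a value (excluded from
consensus-based tables, counted in the report notes), never an error.

## Conservation

`conservation_fraction()` is per-position identity: the fraction of
non-reference alignment rows matching the reference residue at the
mapped column, with gaps counting as mismatches (the conservative
choice). Whether "highly conserved" should mean full identity or a
windowed criterion is genuinely open; we implement per-position identity
with threshold 1.0 by default — the strictest reading — and expose the
threshold. A reference-only alignment returns 1.0 with a warning so
pipelines without ortholog data still run. Published conservation
percentages for the real cohort require the real UniProt ortholog
alignment and are therefore not reproducible from this package alone;
the module computes conservation only for alignments the user supplies.

## Association testing

Contingency tables are built from annotated cohort columns after
dropping unknown/undetermined records (the count dropped is recorded on
the table). Tests follow the classical toolkit: Pearson chi-square with
df = (r−1)(c−1); goodness-of-fit chi-square against stated proportions;
a pooled-variance two-proportion z test (whose square equals the
uncorrected chi-square statistic algebraically — asserted to 1e−9 in the
tests); and Fisher's exact test. The classical validity rule — every
expected count must exceed 5 — is carried as a `valid` flag on each
result, and whenever it fails on a 2×2 table the pipeline automatically
reports Fisher's exact alongside rather than silently substituting it.
All tests are two-sided (sidedness is otherwise unstated in this
literature), significance is flagged at p ≤ 0.05, and no
multiple-testing correction is applied, matching the source analysis.

The published p = 0.003 for the 28-vs-12 inter/intra comparison "under a
normal distribution" admits several constructions (goodness-of-fit,
one- or two-sided z, with or without continuity correction) that give
different values; the pipeline therefore reports all of its own
constructions with methods labelled and treats none of the published
p-values as ground truth.

## Synthetic cohorts and the deterministic fixture

The generator (`generate_cohort()`) draws each record causally: domain
group and domain by weight, position uniform within the domain interval,
a latent consensus (Bernoulli), a status (known with configured
probability; positive at the consensus-conditional rate), a substitution
class at the outcome-conditional inter fraction — realized by an actual
residue pair from documented pools, never a stored flag — and per-tool
predictor calls concordant with the latent consensus at a configured
rate. The generator's defaults are the study conditions (n = 407,
296/407 known, A/C weights 327/80, 229/296 deleterious, rates 31/229
and 9/67, 70% inter among positives); the 50% inter fraction among
non-positives is unconstrained by any printed count and was fixed once
as a neutral default. All randomness flows from one mandatory seed
through a scoped RNG, so identical seeds give identical cohorts and the
caller's RNG stream is untouched. Marginal recovery is tested at
n = 100,000 within three binomial standard errors.

The deterministic fixture (`build_study_fixture()`) encodes the printed
cohort marginals exactly: 407 records, 327/80 A/C, 296 known of which 40
positive, 229/67 deleterious/neutral among known with 31/9 positives,
and 28/12 inter/intra among positives. The (229, 31) reconstruction is
the unique integer solution to D + N = 296, x + y = 40 with
100x/D rounding to 13.54 and 100y/N to 13.43 — the test suite re-derives
this by exhaustive enumeration. Quantities no table prints are fixed by
documented arbitrary choices: the within-group domain split (A1 131,
A2 108, A3 88, C1 44, C2 36), a 2:1 inter-leaning class pattern outside
the positives, a ~3:1 deleterious split among unknown-status records,
and a fixed modular permutation (step 163, coprime with 407) scattering
domains across the status blocks. Predictors are fully concordant in the
fixture, so the kd4v-primary consensus realizes the intended 229/67
split. The fixture ships as a tab-delimited file with a recorded MD5
digest; a test verifies that the shipped file equals the builder's
output byte for byte.

What the synthetic data does *not* emulate: real per-variant predictor
disagreement patterns, CHAMP's full schema (cDNA HGVS, exon numbers,
references), non-missense mechanisms, and any linkage between position
and inhibitor risk beyond the configured strata. Passing tests on these
cohorts demonstrate that the pipeline's bookkeeping and statistics are
correct, not that the biological associations generalize.

## Numerical choices and problem sizes

Chi-square, goodness-of-fit and Fisher p-values come from `stats`;
permutation and enumeration oracles in the test suite are implemented
independently of those routines. The test suite runs the type-I error
simulation at 10,000 replicates of 200-per-arm tables (rejection rate
0.05 ± 0.01), the permutation oracle at 100,000 hypergeometric
resamples, and generator recovery at 100,000 records — sizes chosen so
the whole suite completes in well under a minute while keeping
Monte-Carlo error far below the asserted tolerances. The permutation
check carries a 0.05 comparison tolerance because the hypergeometric
null at the fixture's margins is discrete: the observed 31/9 split is
the most balanced achievable, so the permutation p saturates at 1 while
the normal-tail p is 0.98.

## Known limitations

* Per-domain (A1…C2) variant counts inside each group are not
  constrained by any printed number; analyses that depend on them test
  the package's arbitrary fixture split, not the real cohort.
* The C-group length discrepancy (313 vs 312) is documented, not
  resolved; the real C1/C2 boundary convention behind 312 is unstated.
* Raw per-variant outputs of the five predictors for the real cohort are
  not redistributable; the harmonization layer is exact on categories
  but cannot be validated against the original per-variant table.
* The package models protein-level missense substitutions only — no
  cDNA/genomic representation, no inversions, deletions or nonsense
  variants.
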