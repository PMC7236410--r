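# f8missense

Severe hemophilia A is caused by variants of the *F8* gene that abolish
coagulation factor VIII (FVIII) activity, and the gravest complication of
replacement therapy is the development of neutralizing anti-FVIII
alloantibodies ("inhibitors"). `f8missense` implements, as a tested and
reusable R pipeline, the in silico analysis of missense *F8* variants in a
CHAMP-style severe-hemophilia cohort (CHAMP: the CDC Hemophilia A Mutation
Project registry): where each substitution falls on the FVIII protein, how
chemically drastic it is, what five effect predictors jointly say about it,
and whether any of these features associates with inhibitor development.

It is aimed at coagulation geneticists and variant curators who want the
individual analysis steps — domain mapping, physicochemical scoring,
predictor harmonization, association testing — as composable, testable
functions rather than a one-off spreadsheet analysis.

## What it computes

* **Domain mapping.** Mature FVIII (2332 residues, legacy numbering; HGVS
  numbering = legacy + 19 for the signal peptide) is partitioned into
  A1 1–372, A2 373–740, B 741–1647, A3 1648–2019, C1 2020–2172,
  C2 2173–2332, with the acidic spacers a1/a2/a3 merged into the adjacent
  A domains so that the A-group totals 1112 residues. B-domain variants
  are excluded from domain tabulations.
* **Physicochemical classification.** The four side-chain classes —
  hydrophobic (A,V,F,P,M,I,L,W), polar uncharged (S,Y,N,Q,C,T,H,G), acidic
  (D,E), basic (K,R) — give each substitution an intra-/inter-class call.
  Grantham distance is computed as
  `D(i,j) = rho * sqrt(alpha*(c_i-c_j)^2 + beta*(p_i-p_j)^2 + gamma*(v_i-v_j)^2)`
  over composition/polarity/volume, with `rho` normalizing the 190-pair
  mean to 100; GV/GD range-box scores over alignment columns are binned
  into the C0…C65 classes.
* **Predictor harmonization.** SIFT, PolyPhen-2, Align-GVGD, KD4v and
  MutationTaster outputs are binned into their published categories and
  mapped to deleterious/neutral votes; the default consensus adjudicates
  by KD4v (with majority and unanimous strategies for sensitivity
  analysis).
* **Conservation.** Per-position identity fractions across aligned
  orthologs (FASTA or Clustal input), thresholded into a
  highly-conserved call.
* **Association tests.** Pearson chi-square (with the expected-count > 5
  validity rule), goodness-of-fit chi-square, pooled two-proportion z
  tests and Fisher's exact fallback, on contingency tables of consensus,
  domain and class-change against inhibitor status.
* **Synthetic data.** A seeded generator of CHAMP-like cohorts with
  controlled marginal rates, and a deterministic 407-record fixture whose
  margins equal the published cohort's printed marginals exactly.

## Worked example

```r
library(f8missense)

score_substitution("R593C")
#> $class_change "inter"; $grantham 179.8; $agvgd_bin "C65"; $domain "A2"

fixture <- build_study_fixture()   # deterministic 407-record cohort
report  <- run_pipeline(fixture)
print(report)
```

```
FVIII missense analysis report
  records: 407 in, 407 after filtering
  known inhibitor status: 296 (72.73%); positive: 40 (13.51% of known)
  domain groups (B excluded): A 327, C 80 (A share 80.34%)
  consensus among known: deleterious 229, neutral 67, undetermined 0
  inhibitor-positive rate: 13.54% (deleterious) vs 13.43% (neutral)
  class change among positives: inter 28, intra 12 (70.00% inter)
```

Reading the output: 72.73% of the 407 severe missense records carry a
known inhibitor status and 13.51% of those patients developed inhibitors;
variants pile up in the A domains (80.34% of A+C) roughly in proportion
to domain length; inhibitor rates barely differ between
consensus-deleterious and consensus-neutral carriers (13.54% vs 13.43%,
p ≈ 0.98 — no association between predicted deleteriousness and
inhibitors); but 70% of inhibitor-positive patients carry an inter-class
substitution, the report's strongest signal.

A command-line front end with `run`, `score`, `simulate` and `fixture`
subcommands ships in `inst/cli/f8missense.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","f8missense.R",package="f8missense"))')" \
    score R593C
```

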