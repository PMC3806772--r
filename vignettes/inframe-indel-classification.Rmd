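---
title: "Classifying in-frame coding indels with an interpretable decision tree"
author: "indeltree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying in-frame coding indels with an interpretable decision tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indeltree)
```

## The problem

Coding insertions and deletions come in two biologically distinct kinds.
Indels whose length is not divisible by 3 shift the reading frame and
corrupt everything downstream; indels with length divisible by 3 ("3n
indels") insert or delete whole amino acids — or, when they straddle codon
boundaries, substitute a short block of residues — and leave the rest of the
protein intact. Whether such an in-frame change damages gene function
depends on *where* it lands: inside a functional domain, inside flexible
disordered sequence, inside a tandem repeat born of polymerase slippage, or
next to evolutionarily conserved bases.

`indeltree` classifies 3n coding indels as **gene-damaging** or **neutral**
with a decision tree over four features, and ships the full machinery used
to build and evaluate such a classifier: feature extraction from standard
annotation files, a published-rules engine, a C4.5-style tree trainer,
cross-validation/resampling/selection experiments, and a synthetic fixture
generator so every stage runs self-contained.

Frameshifting and stop-gaining indels are deliberately out of scope: an
inserted `TGA`, for example, truncates the protein and behaves like a
frameshift, so such records are detected and routed to a side channel for a
frameshift-specific predictor.

## Coordinate preprocessing: left-normalization

An indel inside a tandem repeat can be written at several genomic positions
that all produce the same mutant sequence. Because every location-dependent
feature must be consistent, each indel is first shifted to the leftmost
equivalent position (`left_normalize()`): while the base 5' of the allele
equals the allele's last base, the allele rotates right and the position
decrements. This is idempotent, preserves the mutant sequence exactly, and
reduces to a no-op outside repeats. All downstream lookups — most
importantly the conservation score of the base 5' of the allele — use the
normalized position.

## Small exact tandem repeats

`find_repeat()` deems an indel repeat-associated when the allele, or a
substring of it, tiles as exact tandem copies across the allele and its
contiguous flanks. Every substring of the allele is a candidate unit; the
winning call is the qualifying run with the greatest total length
(period × copies), ties going to the smallest period, so `atcgg-CCC-ccacc`
is a mononucleotide (C)₅ rather than (CCC)₁. A run qualifies with at least
two copies and a period-specific minimum total length — 4 bases for
mononucleotide units, 6 for trinucleotide units, `max(4, 2·period)` in
general. Approximate (mismatched) repeats are deliberately not modelled;
the point of the detector is sensitivity to *small exact* repeats, the
pattern slippage generates, for which heavyweight tandem-repeat software is
tuned poorly.

Tunables: the flank window searched on each side defaults to 50 bp
(`repeat_context(..., window = )`), far beyond any qualifying small exact
repeat; matching is case-insensitive and reference-strand only. When total
length and period tie, the repeat geometry is unique but the reported unit
string may legitimately differ between equivalent decompositions.

## Protein consequences

`classify_coding_consequence()` maps an indel onto a transcript model
(single- or multi-exon, either strand), rebuilds the mutant coding
sequence, translates both alleles, and diffs the proteins with a maximal
common suffix, then prefix — which places the affected residue interval
leftmost, the protein-level analogue of left-normalization. Categories:
`aa_insertion`, `aa_deletion`, `block_substitution`, `early_stop`,
`frameshift`, `non_coding`. A pure insertion's span is anchored on the
residue immediately N-terminal of the insertion point (length 1, flagged
`pure_insertion`); an insertion before residue 1 anchors on residue 1.
Transcripts whose CDS length is not divisible by 3 are rejected as
invalid/incomplete. Minus-strand transcripts are handled by
reverse-complementing into CDS orientation; the standard nuclear codon
table is used throughout (selenocysteine is not modelled).

## The four features

* `pfam_fraction_affected` — of the domain intervals annotated on the
  protein, the fraction overlapping the affected residue span. Proteins
  with no annotated domains score 0, not missing: the published "no domain
  affected" branches must fire for domain-less proteins. Domain *instances*
  are counted, not distinct families.
* `in_repeat` — the repeat call above.
* `in_disorder` — whether a strict majority (> 50%) of the affected
  residues lie in annotated disorder intervals; for the single-residue
  spans of phase-0 events this is plain membership. The majority rule is
  our generalisation for multi-residue spans.
* `left_base_conservation` — the per-base conservation score (PhyloP-like)
  of the DNA base immediately 5' of the normalized allele. A missing score
  is an explicit `NA`, never silently 0; the rules engine resolves `NA` to
  the "not conserved" branch, the neutral-leaning default, and records that
  it did.

Annotation is consumed from files, never computed: domains and disorder as
BED in protein coordinates (column 1 = protein id, 0-based half-open on
disk), conservation as bedGraph or fixed-step wiggle. Running a disorder
predictor, Pfam scan or conservation pipeline is out of scope by design.

Additional features (for example physiochemical deltas of the affected
residues) plug in through `register_feature()`; the shipped
`feature_hydrophobicity_delta` uses the Kyte–Doolittle scale — our choice
of scale, made because the exact published feature definitions beyond the
four selected ones are not public.

## The classifier

Two interchangeable prediction routes:

**Published rules** (`classify_published()`). The shipped rule file encodes
the three public decision paths with their training support counts — no
domain + no repeat + disordered → neutral at confidence 0.918 (291/317); no
domain + no repeat + ordered + conservation ≤ 1.405 → neutral at 0.720
(59/82); domain affected + ordered → damaging at 0.894 (254/284) — plus
explicit default branches at confidence 0.5 for the uncovered combinations
(repeat-associated or conserved or domain-plus-disordered), each leaning
damaging because repeats and conservation associate with damage. The
defaults are an assumption, clearly tagged `default_*`, and replaceable by
supplying another rule file. Rules apply first-match in file order; the
non-default rules are checked for pairwise mutual exclusivity at load time.
A prediction's ROC ranking score is the leaf's damaging fraction.

**Trained tree** (`train_tree()`). C4.5-family binary induction: gain-ratio
split selection, numeric thresholds at midpoints between consecutive
distinct observed values, boolean splits for flags, and pessimistic-error
pruning using the binomial upper confidence limit at CF = 0.25 (the
Clopper–Pearson bound; for a zero-error leaf it reduces to the classic
`N(1 − CF^{1/N})`). Defaults mirror the J48 ones: CF 0.25, minimum 2
instances per branch, pruning on; subtree raising is not performed. Two
documented deviations from strict C4.5: missing numeric values follow the
majority branch rather than being split fractionally, and when *no* split
has positive gain at an impure node a zero-gain boolean split is attempted
so purely interacting flags (XOR structure) remain learnable — useless
fallback subtrees collapse again during pruning or the same-class merge.
Ties in gain ratio go to the earlier feature, then the lower threshold, so
training is deterministic given the input order. Trees serialize to an
indented text format that round-trips exactly (thresholds at 17 significant
digits).

## Evaluation machinery

Damaging is the positive class. `metrics()` computes sensitivity,
specificity, precision, accuracy and the Matthews correlation coefficient
from integer confusion counts (exact in double precision up to the final
division; any zero marginal makes the affected metric `NA`). `roc_auc()` is
the tie-aware Mann–Whitney statistic, identical to trapezoidal integration
of the ROC curve. `kfold_cv()` stratifies fold assignment by class —
the literature leaves the assignment unspecified; stratification keeps
every training split two-class — pools the held-out confusions so each
sample is tested exactly once, and reports per-stratum sub-reports (e.g.
insertions versus deletions) on request. `balanced_resampling()` repeats
"sample a neutral subset the size of the damaging set, cross-validate" and
reports each metric's mean ± SD. `greedy_feature_selection()` is simplified
best-first forward search on cross-validated MCC, stopping when no addition
*strictly* improves — a literal "until performance decreases" rule can
oscillate on plateaus, so the strict reading is used; ties break to the
earlier candidate. Display formatting follows the conventional table style:
percentages to whole numbers, MCC and AUC to two decimals.

## The synthetic fixture generator

`generate_fixture()` emits a complete, mutually consistent input bundle —
FASTA reference, GTF gene models, protein-space BED domain and disorder
tracks, bedGraph conservation, VCF indels, labels, and a JSON manifest with
md5 hashes — from a `fixture_spec()`. What it emulates, and what it does
not:

* One synthetic chromosome of single-exon genes built from stop-free
  codons, each indel in its own 8-codon window; genes grow as long as the
  window demand requires. Splice structure, UTRs, codon bias and real gene
  length distributions are *not* emulated, so passing tests say nothing
  about splice-proximal calls.
* All planted indels are phase-0 single-codon insertions or deletions — the
  dominant real pattern (half of repeat-associated disease indels are a
  single duplicated or collapsed codon). Block substitutions and longer 3n
  indels are exercised by unit tests, not by the generator.
* Class sizes default to 474 damaging versus 9,710 neutral (the ~1:20
  imbalance of the real training resources); repeat involvement defaults to
  43% versus 11%; insertion fractions to 89/474 and 211/474.
* Repeat-planted sites duplicate (insertions) or collapse (deletions) an
  adjacent identical codon and are written right-shifted in the VCF so the
  normalizer has real work; non-repeat sites are rejection-sampled until
  the detector, run exactly as extraction runs it, finds nothing.
* Domain and disorder intervals are placed around the *realized* affected
  span (computed with the same consequence caller the pipeline uses), and
  the conservation score is written at the *normalized* position − 1, so
  extraction reproduces the planted feature vector exactly.
* In rules mode the class is a deterministic decision list over the
  planted features (domain → damaging; else disorder → neutral; else
  repeat → damaging; else conservation vs. 1.405), with zone weights
  defaulting to 0.8/0.2 for damaging (rule-10 versus conserved; an
  optional `repeat_region` zone weight adds a stratum whose class is
  carried by the repeat flag alone) and 317:82 for neutral (the published
  rule-4/rule-5 supports). In the zones where conservation is not the
  decider it is drawn from exactly the rule-5 zone's distribution (the
  neutral-side Gaussian truncated below the deadband), so the score
  distinguishes neither class nor zone anywhere the threshold rule does
  not fire — the layout that makes feature-recovery experiments
  well-identified. The deciding zones draw
  from Gaussians truncated one `cons_margin` (default 0.2) away from the
  1.405 threshold: a fitted threshold always sits mid-gap between training
  values, so the generator leaves the gap empty, mirroring how a trained
  tree produced 1.405 in the first place.
* Label noise flips classes symmetrically, making the best achievable
  accuracy exactly `1 − label_noise` in rules mode
  (`planted_bayes_accuracy()`; in independent mode the same function
  integrates the per-cell posterior maxima by quadrature).
  `calibrate_label_noise()` inverts this to hit a target Bayes accuracy.

## Problem sizes used by the shipped experiments

The test-suite experiments run at deliberately modest sizes chosen for
statistical adequacy: noise-free cross-validation checks use a few hundred
indels per class; the calibrated-noise check uses the canonical balanced
948 (474 + 474) with 10-fold CV; the feature-recovery experiment uses 200
indels per class with 10-fold CV, four planted features against four
planted noise flags, and an exhaustive-subset oracle over all 255 candidate
subsets; oracle-equivalence sweeps use 1,000 random cases each and the
normalization invariants 10,000. Balanced-resampling demonstrations use
tens of repetitions; the full published design (1,000 repetitions) is a
single parameter.

The feature-recovery experiment uses a minimum leaf of 25 and a pruning
confidence of 0.1 (stricter than the J48 defaults of 2 and 0.25) and a
damaging "repeat" zone in its fixture, so that each feature resolves a
stratum large enough for its marginal cross-validated gain to be strictly
positive: greedy forward search is myopic, and a feature whose benefit
only materialises in combination with a later one would stall it on a
plateau. The stricter settings also stop chance splits — on the planted
noise flags, or on conservation inside cells where it is pure background —
from ever changing a held-out prediction, which is what makes "exactly the
planted features" a well-posed expectation: the decision-list splits
reduce error so much that they survive any reasonable pruning level, while
chance splits do not.

## Numerical and degenerate-input choices

* Confidences and leaf majorities round to 3 decimals (`correct/support`);
  a zero-support rule is an error, not a NaN.
* MCC with a zero marginal is `NA`, never 0; an empty confusion is an
  error.
* Indels touching a CDS boundary (partly coding deletions, insertions
  between CDS blocks) raise errors rather than guessing; indels wholly
  outside the CDS are `non_coding`.
* When several transcripts contain an indel and none is specified, the
  longest CDS wins and the choice is flagged; one-indel-per-gene thinning
  keeps the first indel in genomic order (the original selection rule is
  unpublished).
* VCF records are reduced to minimal representation by trimming the shared
  leading context first (the anchor base), then trailing context;
  multi-allelic records must be split upstream and substitutions are
  rejected as "not an indel".
* The reference store accepts a per-chromosome offset so worked examples at
  real genomic coordinates (e.g. chr12:132,547,088) run against a toy
  sequence window.

## Known limitations

* The published tree has ten rules; only three are public. The shipped
  default branches are sensible but *assumed*, and real-data predictions
  for the uncovered feature combinations carry confidence 0.5 accordingly.
* The complete-dataset MCC printed in the original performance table does
  not re-derive exactly from that table's own confusion counts (0.4914
  versus 0.50 printed); the reproducible quantities are the percentages.
* The trainer is not a byte-level J48 reimplementation: fractional missing-
  value handling and subtree raising are omitted, and whether the original
  configuration enabled subtree raising is unstated.
* Real HGMD / cross-species training data are license-gated; every
  empirical result in this package's tests is therefore computed on the
  synthetic fixtures, whose generating process is known exactly — that is
  their strength (planted truth, analytic Bayes rates) and their weakness
  (no claim transfers to real-data performance).
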