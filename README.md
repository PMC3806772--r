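# indeltree

Interpretable decision-tree classification of **in-frame (3n) coding
indels** — insertions and deletions whose length is divisible by 3, which
insert/delete amino acids or substitute a short residue block instead of
shifting the reading frame — as **gene-damaging** or **neutral**.

Who it is for: variant-annotation pipelines and method developers who need
(a) a transparent classifier for in-frame coding indels with per-call
confidence and the rule that fired, and (b) the full training/evaluation
machinery to re-derive such a classifier from labelled data.

## The method

Each 3n indel is preprocessed and scored as follows.

1. **Left-normalization.** An indel inside a tandem repeat has many
   equivalent genomic placements; it is shifted to the leftmost position
   producing the same mutant sequence, so every location-dependent feature
   is consistent.
2. **Consequence calling.** The mutant CDS is rebuilt and translated;
   indels causing early stops or frameshifts are routed to a side channel
   (they belong to a frameshift predictor), the rest are classified as
   amino-acid insertion/deletion or block substitution with an affected
   residue span.
3. **Four features.**
   - fraction of the protein's Pfam-style domain instances overlapped by
     the affected span;
   - whether the indel lies in a small exact tandem repeat (unit a
     substring of the allele tiling the allele and its contiguous flanks;
     minimum total length 4 for mononucleotide, 6 for trinucleotide units);
   - whether the affected residues lie (majority) in annotated disorder;
   - the conservation score of the DNA base 5′ of the normalized allele.
4. **Classification** by either the shipped published rules — e.g. *no
   domain affected, not in a repeat, in disorder → neutral* (confidence
   0.918 = 291/317), *domain affected, ordered → damaging* (0.894 =
   254/284), *no domain, no repeat, ordered, score ≤ 1.405 → neutral*
   (0.720 = 59/82) — or by a C4.5-style decision tree (gain-ratio splits,
   pessimistic-error pruning) trained with `train_tree()`.

Evaluation uses damaging as the positive class: sensitivity TP/(TP+FN),
specificity TN/(TN+FP), precision TP/(TP+FP), accuracy,
MCC = (TP·TN − FP·FN)/√((TP+FN)(TP+FP)(TN+FP)(TN+FN)), and the tie-aware
Mann–Whitney ROC AUC, with stratified k-fold CV, balanced resampling of an
unbalanced neutral pool, and greedy forward feature selection by CV MCC.

A synthetic fixture generator (`generate_fixture()`) emits a consistent
FASTA + GTF + BED + bedGraph + VCF bundle with planted rule structure and
analytic Bayes accuracy, so the entire pipeline is testable offline.

## Worked example

```r
library(indeltree)

# a toy window of chr12 carrying six GCA copies at 132,547,070-132,547,087
ref <- ref_store(c(chr12 = paste0("ACGT", "T", strrep("GCA", 6), "CTGACGTT")),
                 offsets = c(chr12 = 132547064))

x <- parse_indel_record("chr12", 132547087, "A", "AGCA")
x
#> insertion of 3 bp (GCA) at chr12:132547088

left_normalize(x, ref)
#> insertion of 3 bp (GCA) at chr12:132547070 [normalized]

find_repeat("CAT", "ctcctc", "catctg")
#> repeat (CAT)2: period 3, total length 6
find_repeat("CCC", "atcgg", "ccacc")
#> repeat (C)5: period 1, total length 5

classify_published(data.frame(pfam_fraction_affected = 0, in_repeat = FALSE,
                              in_disorder = TRUE,
                              left_base_conservation = 0.4))
#> neutral (confidence 0.918, rule_4)

metrics(confusion(tp = 386, fn = 88, tn = 387, fp = 87))
#> n=948  sensitivity=81%  specificity=82%  precision=82%  accuracy=82%  MCC=0.63  AUC=NA
```

The insertion written at position 132,547,088 sits 3′ of six GCA copies, so
its leftmost equivalent placement is 132,547,070 — the position all
downstream features use. The confusion example shows the metric layer
re-deriving a balanced-evaluation row (81% sensitivity, 82% specificity,
0.63 MCC) from its raw counts.

End-to-end runs go through `cmd_predict()` / `cmd_normalize()` /
`cmd_train()` / `cmd_evaluate()` / `cmd_select()` / `cmd_simulate()`, or the
shell shim:

```sh
Rscript inst/cli/indeltree.R predict \
  --reference ref.fa --transcripts genes.gtf --domains domains.bed \
  --disorder disorder.bed --conservation conservation.bedGraph \
  --vcf indels.vcf --out predictions.tsv
```

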