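---
title: "lcrep: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lcrep: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcrep)
```

# Scope and model

`lcrep` analyses monoclonal immunoglobulin light-chain (LC) variable-region
sequences from plasma cell dyscrasias. A rearranged LC gene is modelled as a
germline V segment joined to a germline J segment, subsequently diversified
by somatic hypermutation; every difference between an observed sequence and
its assigned germline genes is attributed to somatic change. The analysis is
protein-level throughout — nucleotide input is translated first — so that
protein-only depositions can be analysed alongside mRNA-derived sequences.
Allele-level variation is deliberately ignored: assignment and counting are
at gene level.

Two nomenclature rules are applied before any counting, because alignment
cannot distinguish the sequences involved:

* proximal/distal IGKV paralog pairs are counted under the proximal gene
  (e.g. IGKV1D-33 → IGKV1-33). The pairs are declared in the reference
  metadata (`paralog_canonical` column) rather than inferred from sequence
  identity, since the rule is nomenclature-driven and reference curators
  know their gene set;
* IGLJ2 and IGLJ3 encode indistinguishable proteins and are reported as the
  merged label `IGLJ2/IGLJ3`.

# Germline assignment

Each record is aligned against every same-locus concatenated V+J template
built from functional reference genes. The alignment is affine-gap BLOSUM62
(gap open 10, extend 1), global on the query and ends-free on the germline:
a truncated record therefore pays nothing for the germline it does not
cover, and the uncovered span is treated as missing coverage, not as
deletion mutations. V and J are chosen jointly as the best-scoring (V, J)
pair; ties break by fewest total edits, then lexicographic gene ids, so the
result is invariant to reference ordering. The best alignment must reach a
configurable identity floor (default 50%), below which the record is
excluded as unassignable.

Edit counting from the optimal alignment: a column with two differing
residues is a substitution, a gap in the germline an insertion, a gap in the
query within the covered span a deletion. One numerical subtlety deserves
note: an ends-free aligner may clip a *terminal* mismatch from both strings
at zero cost. `lcrep` repairs this by re-pairing clipped overhangs ungapped
(counting them as substitutions, or as terminal insertions once the germline
end is covered). A residual quirk remains when two substitutions fall in the
last few positions: the optimal path may convert one of them into an
insertion plus a one-residue germline clip of identical score. This affects
roughly one record in a few thousand at realistic mutation loads; the
affected record drops from the `complete` class, and the criterion tests
tolerate this at the observed rate rather than hiding it.

Nucleotide records are translated in each forward frame; frames with
internal stop codons are rejected (a functional LC cannot carry them), the
best-scoring clean frame is used, and a record with no clean frame is
excluded as non-productive.

## Coverage classes

* `complete` — full V–J germline span aligned, no missing or ambiguous
  residues;
* `incomplete` — V and J genes unambiguously assigned, at least 80
  contiguous unambiguous residues, and all three CDR windows covered by the
  aligned germline span;
* `excluded` — everything else (also: unassignable, non-productive, too
  short).

Complete and incomplete records enter gene-usage counting; mutation and
physicochemical statistics use complete records only. The CDR windows
default to the IMGT unique-numbering intervals 27–38, 56–65, 105–117 on the
V–J scale; they are configurable because references differ in gapping
conventions, and the bundled synthetic reference places 3 residues after
CDR3 so that small C-terminal truncations can still be classified.

## Duplicate collapsing

Repository depositions often contain the same clone several times. Records
with pairwise identity ≥ 0.98 (configurable within (0.9, 1]; the threshold
for "near-identical" is not externally prescribed, so it is exposed) are
clustered by single linkage and replaced by a per-column majority consensus
anchored on the longest member. A tied column makes the consensus ambiguous
and excludes the whole cluster. When the members agree wherever they
overlap, the longest record is retained as-is, nucleotide-derived preferred
over protein-only. Equal-length identity uses an exact mismatch count (a
one-hot crossproduct, so large cohorts stay fast); cross-length candidate
pairs are pre-screened by a shared terminus before an edit-distance check —
a deliberate heuristic: true deposition duplicates share at least one
terminus, and a full all-pairs alignment would be quadratic in cohort size.

# Statistics

## Gene-usage enrichment

Per-gene counts (complete + incomplete records, paralog-collapsed) are
compared between a case and a control cohort as a 2×2 table — gene versus
all other genes. The odds ratio, Wald 95% CI on the log scale and two-sided
Wald p-value follow the standard formulas; when any cell is zero the
Haldane–Anscombe correction adds 0.5 to all four cells. This per-gene 2×2
odds ratio is exactly the exponentiated coefficient of a single-indicator
binomial logistic regression; the acceptance suite verifies agreement with
an iterative maximum-likelihood fit to 1e-6 relative. Benjamini–Hochberg
adjustment is applied across all genes of both loci jointly, and the
step-up is implemented directly (and checked against brute force over all
subsets of a p-value panel) because it is itself part of the tested
surface. Genes never observed in either cohort are absent; an optional
minimum-count floor (default 1) drops ultra-rare genes before adjustment.

Cross-cohort usage profiles are compared by the Pearson correlation of
per-gene frequencies over the union of genes (missing genes contribute 0);
a zero-variance profile is an error rather than a silent `NA`.

## Mutation frequency

For substitutions S, insertions I, deletions D against an aligned germline
span of length L:

$$\mathrm{Fraction\ mutated} = 100\left(\frac{S}{L} +
\frac{I}{L+I} + \frac{D}{L-D}\right)\%$$

The three denominators are deliberate: insertions are normalised by the
length of the sequence they appear in (L+I), deletions by the residues that
remain (L−D). The source formula is typeset ambiguously; this additive
three-term reading matches its printed denominators and is the
implementation contract here. The statistic is strictly increasing in each
edit type, zero exactly at germline identity, and 100% for a fully
substituted record. The germline span is the V+J region (a configurable
choice; the V-only alternative is not implemented because all cohort
comparisons in scope use the full variable domain).

Cohort comparisons use a Kruskal–Wallis omnibus per grouping unit (locus or
individual V gene) and pairwise Wilcoxon rank-sum tests (normal
approximation with tie correction — exactness at tiny n is not needed at
repertoire scale), BH-adjusted jointly. Groups below 5 observations are
skipped with a logged reason, mirroring the minimum group size used in
per-gene comparisons of this kind.

## Physicochemical scores

The isoelectric point solves net charge = 0 by bisection on pH ∈ [0, 14] to
|charge| < 1e-4 (≤ 200 iterations; the charge curve is strictly decreasing,
so bisection always converges and the charge tolerance corresponds to well
under 0.01 pH for peptides with any ionizable content). The charge model is
Henderson–Hasselbalch over the EMBOSS pKa set (N-term 8.6, C-term 3.6,
K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1) with free termini —
values therefore differ from whole-chain calculations that include the
constant domain, which is out of scope. GRAVY is the plain mean of
Kyte–Doolittle residue values; unknown residues are excluded from numerator
and denominator. Reference pI values for the test peptides were computed
with an independent root-finder implementation before this one was written.

## Predictor evaluation

External amyloidogenicity predictions are scored against cohort labels:
AL-derived records are the positive class, MM and polyclonal controls
negative. Records without a returned prediction are excluded and counted.
Sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy
(tp+tn)/(tp+tn+fp+fn); a metric with an empty denominator is reported as
not-available, never as 0. Tools restricted to one chain type are scored on
that locus only via a capability map. Querying the prediction servers
themselves is out of scope — the module consumes a prediction table.

# The synthetic generator

`generate_cohort()` emulates what the real analysis consumes: cohorts of
rearranged, hypermutated, partially truncated, partially duplicated V–J
protein sequences with configurable per-gene usage. Substitutions are drawn
per residue (uniform replacement over the other 19 amino acids), insertions
and deletions as single-residue Poisson events (multi-residue indels are a
knob that was not needed: single-residue events keep every term of the
mutation formula directly checkable). Truncation removes a terminal block
while preserving (intended class `incomplete`) or violating (`excluded`)
the 80-residue/CDR rule; duplicates re-emit a record with at most one extra
substitution. Every record carries ground truth including a replayable edit
script.

The demo configuration emulates the stated world of the real cohorts at
test scale: three cohorts (AL-like cases, an MM-like comparator, a
polyclonal-style control), substitution rates 0.08–0.10 per residue
(repertoire median mutation loads of ~8–10% of the variable domain),
0.05 expected indels per sequence, 8% truncated and 4% fragment records
(roughly the published complete/incomplete/fragment proportions), 3%
duplicates, and two genes at strongly elevated usage in the cases. These
defaults were chosen once from the published cohort structure and are not
tuned against test outcomes.

What the generator does **not** emulate: SHM hotspot motifs and
transition/transversion structure, clonal lineages, codon-level mutation
(protein substitutions are drawn directly), realistic germline sequence
similarity (the bundled reference uses random sequences under real IMGT
names — real IGV genes within a family are far more similar, so real-data
assignment is harder than the synthetic benchmark), and repertoire-scale
abundance skew. A green assignment-recovery test therefore establishes
correctness of the machinery, not field accuracy on borderline real genes.

# Numerical and interface choices

* Alignment delegated to `Biostrings::pairwiseAlignment`; one vectorised
  call per template (not per record) keeps repertoire assignment at roughly
  10 ms/record on one CPU.
* Percentages intended for comparison with published tables are reported
  both as raw fractions and rounded half-away-from-zero at the printed
  precision (base R rounds half-to-even, which printed clinical tables do
  not).
* Seeds: every stochastic entry point takes an explicit seed; the pipeline
  derives per-cohort seeds deterministically from one master seed (kept
  below 2^31), and re-running a configuration reproduces every output table
  byte-for-byte.
* Errors name the offending record/gene/row; stage failures in the pipeline
  abort with the stage name.

# Known limitations

* The terminal-substitution alignment quirk described above (≈0.05% of
  records at 10% substitution load) can demote a fully covered record from
  `complete`.
* Gene-level only: no allele calls, no IMGT gapped numbering, no CDR3
  junction analysis.
* The per-gene 2×2 enrichment treats genes independently; a joint
  multinomial model over genes was considered and rejected as it changes
  the estimand away from the per-gene odds ratio being replicated.
* Constant-domain rules are recorded as metadata only; constant domains are
  not analysed.
* Published per-gene odds ratios from the motivating study are not
  reproducible from printed material (the underlying per-gene counts are
  not published); the package instead validates its estimator on synthetic
  cohorts with known truth.
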