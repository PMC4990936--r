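---
title: "Dissecting a flavonoid stimulon from regulator-knockout RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a flavonoid stimulon from regulator-knockout RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimulon)
```

## The biological question and the experimental design

Rhizobia read the flavonoids exuded by legume roots as a cue to switch on
their symbiotic program.  The flavonoid-activated regulator NodD1 binds
conserved promoter elements called *nod* boxes (NB) and turns on
nodulation genes — among them `ttsI`, whose product TtsI in turn binds
*tts* boxes (TB) and fires the type 3 secretion system.  A third
regulator, SyrM, itself NB-driven, is thought to act through its own box.
The full set of genes that respond to the inducer — directly or through
this cascade — is the *stimulon*.

The package analyses the classic three-strain dissection of such a
stimulon: RNA-seq libraries from the wild type and from `nodD1` and
`ttsI` knockouts, each grown with and without the inducer (genistein),
two biological replicates per cell — twelve libraries in all.  Every
treatment is contrasted against the wild-type no-inducer baseline, and
the *pattern* of induction across the three genetic backgrounds reveals
which promoter boxes are functional:

* a **NB** is active when its operon is induced in the wild type and the
  `ttsI` knockout but not in the `nodD1` knockout (NodD1 is required,
  TtsI is not);
* a **TB** is active when its operon is induced in the wild type only
  (both regulators are required, since TtsI expression itself needs
  NodD1);
* a TB whose operon stays induced after `ttsI` inactivation is a decoy:
  something else (e.g. a SyrM box in the same promoter region) drives
  the operon, and the box is called non-functional.

## Differential expression

### Normalization

Libraries differ in sequencing depth, so counts are scaled by
median-of-ratios size factors: each library's factor is the median, over
genes detected in every library, of the ratio between its count and the
gene's geometric mean across libraries.  We rescale factors to geometric
mean 1 so that normalized counts stay on the raw-count scale; the
estimator is otherwise the standard one (the suite cross-checks it
against DESeq2's implementation up to that rescaling).  When no gene is
positive everywhere — a pathological input — the estimator falls back to
total-count scaling and warns.

Median-of-ratios assumes most genes are unchanged between libraries.
Designs in which a majority of genes are induced (some of the stress
tests in this package do exactly that) violate the assumption, and those
tests pass the generator's true depth factors explicitly instead.

### The test

With two replicates per cell no per-gene dispersion is estimable, so
replicates are pooled within each side of a contrast and an exact,
fully enumerable test is used: conditional on the total count
$N = x_{\mathrm{trt}} + x_{\mathrm{base}}$ of a gene across both sides,
under the null of equal expression the treatment total is
$\mathrm{Binomial}(N, q)$ with $q$ the treatment share of the summed
size factors.  The two-sided p-value is the sum of the probabilities of
all outcomes no more probable than the observed one (the usual
$1+10^{-7}$ tie tolerance).  Raw counts enter the statistic; the size
factors act only through $q$.  For large $N$ the opposite-tail boundary
is located by binary search along the monotone flanks of the binomial
mass function — exact, but $O(\log N)$ instead of $O(N)$.

This conditioned-binomial test is the exact analogue of a Poisson model
for the counts.  It deliberately does not model overdispersion;
robustness to moderate overdispersion is probed by simulation (the
planted-recovery tests run at dispersion 0.05) rather than modelled.
An optional Benjamini–Hochberg adjustment is available behind a flag and
off by default, matching the raw-p calling convention of the original
analysis.

### Calling

A gene is differentially expressed when its fold-change — the ratio of
mean normalized counts, guarded by a pseudocount of 0.5 on each side's
mean — reaches 3 (or 1/3) *and* p < 0.05.  The threshold is on the
fold-change: a tiny p-value at a 2.9-fold change is not a DEG.  The
pseudocount guards the ratio against zero means only and never enters
the test.

## Promoter-box scanning

Box consensus sequences are degenerate patterns of literal IUPAC blocks
separated by fixed-length N spacers, e.g. `ATCN9GATN7ATCN6ATCGATN6AAT`
for the nod box (46 bp, 18 informative positions) and
`GTCAGN5CGN2AGN10TA` for the tts box (28 bp, 11 informative positions).
The scanner reports every window whose informative positions differ from
the pattern in at most a configured number of places; N positions are
pure length constraints and never count as mismatches.  The tts-box
`CGN2AG` core is marked *mandatory*: any mismatch inside it disqualifies
a hit regardless of budget, encoding the observation that non-functional
tts boxes are precisely the ones that fail to maintain this internal
motif.

The SyrM-box consensus is not part of the package's source material; the
built-in `syrmBoxPattern()` is a synthetic 66-bp stand-in (the length is
pinned by published upstream coordinates of two SyrM boxes, −223…−158
and −127…−62) and real analyses should supply the genuine consensus via
a pattern table (`readPatternTable()`).

Offsets follow the convention that −1 is the base immediately 5′ of the
first base of the start codon, so a 66-bp box ending 62 bp upstream
reports offsets −127…−62.

## From DEG lists to regulon groups

The inducer-affected gene set is the union of three routes: direct
wild-type DEGs; *operon rescue* — sub-threshold genes sitting in a
transcription unit that contains a direct DEG; and *conserved-box
rescue* — genes directly preceded by a perfect (0-mismatch) box whose
wild-type fold-change reaches 2.  Two artefact classes are then
discarded with logged reasons: genes antisense to a nod box immediately
3′ of it, and genes sequence-identical to a retained box-controlled gene
(the box-linked copy is kept).

Each retained gene is assigned to group **NB** (regulon of an active or
weakly active nod box), **TB** (regulon of an active tts box) or
**other**.  For group-other genes that are themselves wild-type DEGs,
dependence flags record whether induction is lost in each knockout;
genes induced in all three strains are independent of both regulators.
Mutant-background effects — genes shifted in the knockouts even without
inducer — are reported in a separate table rather than folded into the
groups, since they reflect regulator loss, not inducer response.

Design choices where the source analysis left the rule implicit:

* **Which gene speaks for a polycistron.**  Box induction is judged on
  the operon lead gene; when the lead alone falls short, the box is
  still evaluable if at least half the operon members are DEGs
  (majority rule).
* **Weak activity.**  A box with the correct epistasis sign pattern but
  a wild-type fold-change in `[2, 3)` (p < 0.05) is called
  `weakly_active` — the published example is a nod box driving a
  2.5-fold induction, described as active with low efficiency.  The
  lower bound 2 is a package choice; no cutoff was ever published.
* **Coverage floor.**  Boxes above genes with mean baseline normalized
  counts below 10 are `not_testable` ("low reads"), as are boxes with
  no downstream gene within the 1 kb linking distance.  The 1 kb
  distance is a configurable default chosen because all published box
  offsets are under 900 bp.
* **Conflicts.**  A gene claimed by both an active NB and an active TB
  (possible in synthetic data, not observed in the real genome) goes to
  the nearer box, with a warning.
* **SyrM boxes** are flagged but never functionally called — the
  epistasis design has no `syrM` knockout, so their activity is outside
  what these data can decide.

## The synthetic-data generator

Because the real deposited read data are not required, the package
carries a seeded generator that plants the same regulatory structure at
desk scale and emits FASTA, GFF3, a box table, a count matrix and a
machine-readable truth table.  The default configuration mirrors the
study system: seven replicons totalling about 200 kb with roughly 350
genes; a symbiotic-plasmid analogue carrying 15 nod boxes (11 active,
one weakly active at 2.5-fold, one silent, two with no downstream gene)
and 18 tts boxes (11 active, one TtsI-independent decoy, six with a
corrupted core); plus inducer-independent and mutant-background special
cases and unregulated background genes.

Counts are negative-binomial in the mean–dispersion parameterization,
`mean = baseline × effect × length/1kb × depth`, with dispersion 0.05
by default (0 recovers Poisson).  Depth factors are drawn log-uniformly
from [0.7, 1.4] so the normalization stage has real work to do.
Induction factors for planted functional boxes are drawn log-uniformly
from [8, 30], matching the strong inductions printed for functional
boxes (log2 fold-changes of roughly 3–4.7); at baseline means of a few
hundred counts this puts planted effects several standard deviations
above the 3-fold calling threshold, so recovery tests check the
classifier, not sampling luck.  The weak nod box is planted at exactly
2.5-fold.

What the generator does *not* emulate: read-level artefacts (mapping
bias, multimapping, rRNA carry-over), GC and length biases beyond the
linear length term, and correlated biological replicate structure.
Passing recovery tests therefore demonstrates the correctness of the
statistical machinery and the classification logic under the stated
generative model — not robustness to every artefact of real libraries.

The two benchmark configurations used by the acceptance analyses are
exported: `ttsBoxRecoveryConfig()` (18 planted tts boxes, of which 11
should be called active) and `boxlessDependenceConfig()` (30 boxless
responsive genes, of which 24 should be flagged NodD1-dependent).  Both
use baseline per-kb means of 400–800 over 0.6–1.2 kb genes, two
replicates per cell and dispersion 0.05.  These problem sizes — a few
hundred genes, twelve libraries — are the package's chosen desk scale;
all suite-wide simulations stay within a few hundred thousand bases of
sequence and at most 10^4 genes (the null-calibration check).

## qPCR validation

Fold-changes from Ct tables use the delta-delta-Ct method with
efficiency fixed at 2 (no efficiency correction was published):
technical replicates are averaged within biological replicates before
`dCt = Ct_target − Ct_16S` is formed, and the reported spread is the
range of per-biological-replicate fold-changes.  Concordance with
RNA-seq is a Pearson correlation of log2 fold-changes over shared genes
(at least 3 required), with sign-discordant genes flagged.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive (GFF3); minus-strand upstream
  windows are reverse-complemented so position −1 is always immediately
  5′ of the start codon, and windows truncate at replicon edges while
  keeping the −1 anchor.
* `N = 0` in the exact test yields p = 1; an observed split exactly at
  the conditional mode also yields p = 1.
* Scanner hits are sorted by start, plus strand first on ties; a
  sequence shorter than the pattern yields an empty hit set.
* Operon inference groups consecutive same-strand genes with intergenic
  gaps ≤ 200 bp by default; explicit operon tags in the input are never
  overridden and break chains for their untagged neighbours.
* All simulation randomness flows through explicit integer seeds;
  rerunning any pipeline configuration reproduces byte-identical
  outputs.

## Known limitations

The exact test is anti-conservative under strong overdispersion, which
is why the DEG rule keeps the fold-change threshold as the primary
filter, as in the source analysis.  With n = 2 replicates no per-gene
dispersion estimation is attempted — users with deeper designs should
reach for edgeR or DESeq2 for the DE stage and feed the called tables
into the classification functions.  The discard rules implement the two
published artefact classes only; the original analysis discarded 16
genes for "different reasons" that are not fully enumerated in the
source and therefore cannot all be encoded.
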