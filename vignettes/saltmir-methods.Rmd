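---
title: "saltmir: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{saltmir: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`saltmir` implements a desk-scale analysis chain for plant small-RNA
experiments with a four-treatment redox/salt design — control, NaCl,
NaCl + thiourea (TU, a thiol ROS scavenger), and TU alone, with two
biological replicates each. The chain discovers miRNA candidates from
size-selected small-RNA libraries by positional read clustering, screens
candidate precursors for hairpin structure, calls differential expression,
scores plant miRNA target sites, and ranks target genes to nominate "key
genes" whose expression shift under NaCl+TU versus TU best explains a
redox-primed salt-tolerance phenotype. A synthetic-data module plants
ground truth at every stage, so the whole chain is verifiable without any
external dataset.

This vignette records the model behind each stage, the tunable parameters
and their defaults, the numerical choices that were genuinely open, and
what the synthetic tests do and do not demonstrate about real data.

## Preprocessing and mapping

Reads are cleaned with a primitive 3'-adapter rule: the read is cut at the
leftmost position where a prefix of the adapter aligns exactly and the
aligned segment is at least `min_adapter_overlap = 8` nt (a full internal
adapter occurrence always qualifies). Reads without a qualifying hit are
kept but flagged; there is no single convention for whether adapter-less
reads should be kept, so the choice is explicit and configurable. Reads are then size-selected to 18–30 nt and filtered
against a contaminant ncRNA set by exact substring matching on either
strand — a conservative, fully testable stand-in for alignment against
rRNA/tRNA/repeat databases.

Surviving reads are collapsed to unique sequences with per-library counts
(total-count descending, ties broken lexicographically, so downstream
greedy passes are order-independent) and placed on the genome by exact,
ungapped, full-length matching on both strands (`Biostrings` pattern
dictionaries; a naive scan oracle checks every placement in the tests).
Exact matching replaces a mismatch-tolerant aligner: on same-genome
synthetic data mismatch tolerance buys nothing, and a minimal SAM import
path (`read_sam_min()`, one file per library) accepts externally computed
alignments for real data. Multi-mapped reads keep all placements with
full (not fractional) counts, and candidates containing several placements
of one read are flagged rather than silently resolved.

All internal coordinates are 0-based half-open; conversion to the 1-based
inclusive conventions of SAM and GFF3 happens only at the file boundary.
T and U are treated as the same base throughout. Reads containing N are
dropped at parse time with a logged count, because N breaks
complementarity scoring.

## Read clustering and hairpin candidates

Clustering is a greedy single pass. Alignments are sorted by total count
(descending; ties by chromosome, start, strand, sequence — making the pass
invariant to input order). The most frequent read founds the first
cluster, and the cluster's coordinates remain those of its founding read.
Every subsequent read joins the first existing same-strand cluster whose
window fully contains it, else founds a new cluster. The window extends
the founder by 3 nt before its start and 5 nt past its end *in strand
orientation* (minus-strand windows are mirrored), which is exactly the
slack needed to absorb isomiR 5'/3' end variation into the founder's
cluster. Full containment (not overlap) is required: partial overlap
would merge tandem clusters and destroy arm pairing.

A genuine pre-miRNA leaves two read clusters, one per processed arm, so
same-chromosome, same-strand cluster pairs with an edge-to-edge gap of at
least 0 and strictly less than 150 nt become hairpin candidates. Whether
that distance is edge-to-edge or midpoint-to-midpoint was an open reading;
edge-to-edge is implemented and configurable. A cluster may join only one
candidate: pairs are accepted greedily by smallest gap with ties resolved
toward the genomically left partner — deterministic and biologically
coherent for chained clusters. Overlapping clusters (negative gap) are
never paired, only tallied. The higher-count arm contributes its founder
sequence as the mature miRNA (20–24 nt enforced, bounds inclusive); the
other founder is the star.

## Structural screen

Candidate precursors (the span of both windows plus the gap) are folded by
base-pair maximisation — a Nussinov dynamic programme over Watson–Crick
plus G:U pairs with deterministic traceback (the 5' base prefers its
3'-most optimal partner). Base-pair maximisation is dependency-free and
exactly verifiable against exhaustive enumeration of nested structures,
which is what the tests do; it is *not* a thermodynamic model, and
`parse_dotbracket()` accepts externally computed dot-bracket structures
for real data.

Two numerical accommodations make the max-pair objective usable as a
screen. First, the pipeline folds precursors with a minimum hairpin loop
of `fold_min_loop = 10` nt (plant pre-miRNA terminal loops are rarely
smaller): with the permissive default of 3, the maximising fold fragments
genuine stems by recruiting loop nucleotides into spurious micro-hairpins.
Second, `hairpin_check()` prunes helices shorter than `min_helix = 4`
stacked pairs before assessing the structure — lonely-pair pruning;
helices this short are structurally marginal and, empirically, removing
them raises the screen's specificity on random sequence from roughly 95%
to 98–99% while leaving every planted stem intact. `fold_maxpair()`
itself keeps `min_loop = 3` as its general-purpose default.

The check passes a candidate iff (a) at least 60% of mature positions are
paired, (b) every paired mature position partners into the star half of
the precursor, and (c) the pruned structure has exactly one terminal loop
(no multiloop, no tandem stems). Structural screens of this kind have no
canonical numeric criteria, so these three are explicit artifact choices,
reported as metrics regardless of the verdict and configurable.

## Quantification and differential expression

A candidate's mature count per library is the sum of the per-library
counts of its mature cluster's member reads. Counts are normalised to
counts-per-million (CPM) per library; log2 fold changes are computed from
treatment-mean CPM with a pseudocount of 0.5 (finite with zeros), and the
p-value comes from a two-sided Fisher exact test on the pooled 2×2 table
(candidate counts vs the remaining library mass, treatment vs reference).
Benjamini–Hochberg FDR is attached per comparison. A candidate is called
up iff log2FC ≥ 1 *and* p < 0.05 (fold bound inclusive, p bound strict),
down symmetrically. Whether such a p threshold should apply to raw p or
to the FDR is a genuine design fork; calls use raw p, with the FDR
reported alongside so the stricter reading is auditable.

Two properties of this self-contained test matter in practice. It is
exactly checkable — the tests reproduce its p-values by brute-force
hypergeometric tail summation to 1e-10. And it assumes (near-)Poisson
counts: under strong overdispersion the pooled Fisher test is
anti-conservative, a known limitation that the simulator's dispersion knob
makes measurable. The calibration checks therefore run in the
near-Poisson regime (dispersion 1e-4) where the sampling model holds —
2,000 null rows give a false-positive rate around 5%, and planted 4-fold
rows at depth 500 are recovered essentially always. Real pipelines handle
overdispersion and compositional bias with NB-GLMs and TMM/median-of-ratio
normalisation; plain CPM deliberately does not, so fold changes in
mass-imbalanced libraries are compressed by the ratio of library totals.
The default synthetic design is composition-balanced (below) for exactly
this reason.

## Target-site scoring

A miRNA is aligned antiparallel against every transcript window whose
length is within one bulge of the miRNA length, under the canonical plant
scoring convention: match 0, G:U wobble 0.5, mismatch 1.0, bulge 2.0,
with penalties doubled at miRNA positions 2–13 and positions beyond
`hspsize = 20` unscored. Conventions differ on whether the doubled block
ends at position 12 or 13; 2–13 is the default and configurable. The alignment is a banded dynamic programme
(band ±2, at most one bulge, traceback preferring match > wobble >
mismatch > gap); the transcript-wide scan evaluates the same alignment
space in closed form with cumulative penalty arrays, and the tests pin
both against exhaustive enumeration of all banded alignments.

Sites scoring at most `target_max_expectation = 2.0` are emitted, sorted
by expectation then position, overlapping sites merged keeping the lower
expectation, and at most 200 sites reported per miRNA. One subtlety: a
bulge placed beyond the scored length is penalty-free under the stated
rules, so every perfect site has a zero-cost one-base-wider twin; at equal
expectation the merge prefers the bulge-free window. A mismatch or gap
anywhere in miRNA positions 9–11 classifies the site as translational
inhibition, otherwise cleavage. Accessibility flanks of 17 nt upstream
and 13 nt downstream (truncated at transcript ends) are attached so an
external accessibility tool could consume them; the ensemble-energy
accessibility filter itself is out of scope here.

## Coupling, ranking and key genes

Expression profiles are the four treatment values (replicate means,
fold-over-control, so the control entry is 1). Each miRNA:target pair
receives the Pearson correlation of the two profiles; r ≤ −0.25 is
classed canonical inverse regulation, r ≥ +0.25 decoupled (deviation from
miRNA-mediated repression), otherwise indeterminate. The ±0.25 bounds are
package choices — chosen so the weakest inverse case worth reporting
(around −0.27) classifies as inverse — and the raw r is always emitted.
Zero-variance profiles yield an explicit indeterminate, not a number.

Key genes are nominated in two audited stages: targets are ranked by
`delta_tu` = expression(NaCl+TU) − expression(TU), highest to lowest (ties
by id); the key-gene flag additionally requires the fold ratio between
NaCl+TU and NaCl expression (larger over smaller) to reach 2.0 *and*
`delta_tu` > 0. A 2-fold cut could defensibly apply to that ratio or to
the ranked delta itself; both quantities are reported per target so
either reading is auditable.
`end_to_end_keygenes()` joins DE miRNAs to their scored targets, attaches
couplings and ranks per organ; targets without expression are excluded
with a logged count. Term enrichment for selected target sets uses a
one-sided Fisher exact test per term with Bonferroni correction across
tested terms at a 0.05 threshold.

## The synthetic-data module

`make_genome()` plants 20–24 nt mature arms (length mode 23 > 21 > 22 nt)
in uniform-random chromosomes, each as mature arm + loop + star arm on a
random strand, hairpins at least 300 nt apart so clusters of different
hairpins can never pair. The star arm is the reverse complement of the
mature arm with two planted G:U wobbles by default: at least one wobble is
needed for the two arms to be distinguishable sequences (a perfect-revcomp
stem exact-maps each arm read onto both arms, duplicating every hairpin as
an antisense mirror), and two is a modest, realistic stem imperfection.
Loop sequences are drawn from a non-self-pairing A/C alphabet so the
planted terminal loop is genuinely unstructured.

`default_profile()` assigns treatment means: one `redox_rescued` hairpin
(1×, 2×, 0.2×, 1.8× of base depth over control/NaCl/NaCl+TU/TU — induced
by salt, suppressed when TU is co-applied), and a composition-balanced
background of `salt_up` (4× in NaCl and NaCl+TU, a planted log2FC of +2),
`salt_down` (0.25×, log2FC −2, four per up-regulated hairpin so the extra
and missing read mass cancel) and `flat` hairpins. Counts are negative
binomial (dispersion 0.05 by default, configurable down to Poisson);
per-arm abundance uses a star fraction of 0.1 — a free parameter reflecting
standard miRNA biology, not an estimate of any particular dataset.
`simulate_reads()` emits per-library FASTQ with the 3' adapter appended
and reads truncated to the instrument read length (default 40 nt, chosen
so the longest 30 nt insert still leaves the 8 nt minimum adapter
overlap); isomiR jitter draws 5' offsets in −3..+2 and 3' offsets in
−2..+5, truncated so every isomiR stays inside the clustering window of
the modal read and inside the size selection — making the noiseless truth
exactly one cluster per arm. Optional contaminant fragments and random
degradation reads exercise the filters.

`simulate_targets()` gives each miRNA one transcript with a perfect
(expectation 0) planted site, optionally degraded by planted G:U wobbles
outside the central positions. Target expression is an exactly affine map
of the miRNA profile — decreasing for inverse pairs (noiseless Pearson
r = −1), increasing for decoupled pairs (r = +1) — with the slope shrunk
per pair so expression stays positive without clipping, preserving exact
affinity. Decoupled pairs are drawn from non-induced hairpins so they
never out-rank the planted key gene. The `redox_rescued` target carries
the key-gene signature by construction: up under NaCl+TU, down under TU,
with a delta margin of roughly 2× over the nearest competitor, which
survives the 0.1-SD expression noise used in the recovery checks.

What passing these tests shows — and does not. The generator emulates
positional read structure, treatment design, count overdispersion,
adapter/contaminant/degradation artefacts, isomiR jitter and coupled
target expression. It does not emulate sequencing error, cross-mapping
between paralogous loci, mismatch-tolerant alignment, colorspace reads,
UTR/CDS structure in transcripts, or thermodynamically realistic folding
energies. Perfect recovery on synthetic data therefore validates the
algorithmic contracts, not performance on real libraries.

## Problem sizes and determinism

The shipped verification uses: 20 planted hairpins on 2 × 20 kb
chromosomes at depth ~1,000 reads per mature arm across 8 libraries;
200 random clustering instances (≤ 50 alignments) against a literal
transcription of the greedy steps; 500 short sequences against exhaustive
fold enumeration; 2,000 null and 300 planted rows for DE calibration and
power; 10^4 single-base degradations for score monotonicity; and 100
noisy expression datasets for key-gene recovery. Every simulation is
seeded; the pipeline writes only deterministic text tables, and two runs
under one seed are byte-identical, which the tests assert file by file.

## Known limitations

* The Fisher-exact DE stand-in is anti-conservative under strong
  overdispersion and plain CPM has no compositional correction; both are
  deliberate simplifications of the cited NB-GLM tools, documented above.
* Base-pair maximisation over-pairs relative to thermodynamic folding;
  the screen compensates with the minimum-loop and helix-pruning choices,
  and accepts external structures for real data.
* Exact mapping cannot place reads across sequence variants; real data
  should enter through the SAM path.
* Conserved-miRNA annotation against reference databases, two-tool
  consensus discovery, and the accessibility (UPE) filter are out of
  scope.
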