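---
title: "Synteny-anchored variant discovery and pan-genome analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny-anchored variant discovery and pan-genome analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`pansynt` re-implements, as a tested and reusable pipeline, the
comparative-genomics workflow used to analyse panels of de novo plant
genome assemblies against a conspecific reference: whole-genome synteny
blocks, synteny-anchored variant calling (SNPs, short indels, large
insertions/deletions, copy-number gains and losses, translocations),
multi-accession merging with reference-genotype imputation, pan-/core-
genome size curves with an asymptotic model fit, nucleotide-diversity and
gene-family statistics, and long-read breakpoint validation.  Because the
original sequencing data are not required, a first-class simulator
generates the inputs with a planted, exactly-known truth set; every
downstream claim the package makes about itself is measured against that
truth.

Coordinates are 0-based half-open everywhere inside the package and are
converted only at file-format boundaries (GFF3, VCF, chain, BED).  A
single convention avoids off-by-one drift between modules.

## The synthetic cohort

`sim_config()` collects every tunable.  The defaults are the package's
study conditions, fixed once:

* **Reference**: 2 Mb, one chromosome, random background at 40% GC with
  non-overlapping gene models per family label (half of each family in
  tandem clusters, mirroring the clustered organisation of NBS-LRR, NCR
  and related families) and transposon-like repeats copied at 85--99%
  identity from a few consensus elements.  CDS sequences are real ORFs
  (ATG, no internal stop, terminal stop; introns carry GT..AG ends), so
  functional-effect classification operates on meaningful material.
* **Accessions**: three, each with SNPs at 1% per bp (inside the 0.6--2.4%
  range observed between wild accessions and a conspecific reference),
  short indels at 0.1% per bp with geometric lengths (p = 0.3, capped at
  49 bp; the source data do not constrain this distribution, so it is an
  explicit, configurable stand-in), 20 large deletions and 20 large
  insertions of 50--5,000 bp, 5 tandem duplications (2--4 copies), 5
  translocations and 3 novel insertions per accession.  Planted variants
  never overlap on the reference, which keeps the truth oracle exact;
  repeat-copy complexity is exercised through the TE copies instead.
* **Assemblies**: each accession genome is cut into ~500 kb scaffolds
  whose contigs (uniform 0.4--1.4 x the 50 kb target N50) are joined by
  N-runs of 50--500 bp; 30% of the breaks are relocated into nearby
  repeat intervals.  Gaps are insertions of N only, so removing them
  restores the genome exactly -- the conservation invariant the tests
  assert.
* **Long reads**: log-normal lengths around 3 kb at 20-fold depth,
  substitution errors only.  Substitution-only errors keep read-to-genome
  diagonals exact, which is all the seed-and-vote placement model needs;
  indel-rich error models of specific instruments are out of scope.

For pan-genome studies the configuration can additionally declare a
**dispensable pool**: novel segments with fixed insertion points and
sequences, each carried by a random subset of accessions.  Carriers
share a segment identically, so the simulated pan-genome curve saturates
the way a real dispensable genome does instead of growing linearly with
fully private content; the 13-accession cohort used by the acceptance
script draws 40 such segments of 5--15 kb at carriage probability 0.4.

Every operation draws from its own RNG stream seeded by a hash of
`(master seed, accession, operation)`, so each stage is reproducible in
isolation and the whole cohort is a pure function of the configuration.

`mutate_genome()` constructs the truth set first and derives the
accession genome by replaying it through the same edit engine that
`apply_truth()` uses; the round-trip identity between the two is
therefore structural rather than approximate.

## Synteny blocks

Anchoring replaces an external local aligner with maximal runs of k-mers
unique in both genomes (default k = 15, both strands; minus-strand
anchors are stored against the reverse-complemented query so query and
target positions always increase together).  Runs on one diagonal that
overlap at base level are merged even when the k-mers between them are
not unique, because the union of two exact matches on one diagonal is
itself an exact match.  A second anchoring pass at k = 13, restricted to
query regions the first pass left uncovered, rescues alignment across
over-extended gaps.

Chaining is sparse dynamic programming maximising
`sum(anchor lengths) - sum(open + extend*|dq - dt| + diag*min(dq, dt))`
with `open = 50`, `extend = 0.5/bp`, `diag = 0.01/bp`; chains are
extracted greedily by descending score (each anchor used at most once)
and chains under 200 score are dropped.  Micro-homology at variant
breakpoints makes flanking anchors overlap by a few bases; the DP admits
overlaps up to 100 bp by conceptually clipping the later anchor, charging
the clipped bases against the score.

Netting keeps a single best alignment per reference position.  Occupancy
is tracked at *anchor* granularity: a chain that fits entirely inside a
large unaligned gap of a better chain survives untouched -- this is what
makes translocated segments callable as their own blocks.  Two guards
implement the "remove non-syntenic or overlapping blocks" clean-up: a
chain whose span crosses already-accepted anchors by more than 30% is
dropped outright (such chains are interleaved duplicates, typically built
from repeat copies that the masked rescue pass made spuriously unique),
and accepted anchors never overlap pairwise.  A query-space net of the
same chains plus agreement filtering (100 bp slop) yields the
reciprocal-best net.

Inter-anchor gaps up to 5,000 bp are resolved to base level.  Equal-sized
gaps are compared column-wise; unequal gaps are aligned globally with an
affine-gap aligner scoring match +1, mismatch -2, gap open -10, gap
extend -0.5.  The stiff mismatch and open costs are a deliberate choice:
with the milder (-1/-2) scheme the expected score of pairing two random
columns (-0.5) beats gapping them out (-1.0), and unrelated sequence
inside double gaps gets shredded into pseudo-matches -- which surfaced as
dense false SNP columns and fragmented false deletions.  With -2 the
preference flips, and open -10 stops spurious 3--5 bp match islands from
splitting one large indel into several.  Alignments whose aligned columns
still disagree (identity < 0.75) are demoted to unaligned double-gap
segments, i.e. SV candidates.  Double gaps larger than the fill limit (or
beyond the quadratic DP budget of ~1.2e8 cells) stay unaligned.

Cleaning excises alignment columns overlapping any N-gap and splits
blocks there; unaligned segments near a gap are flagged and later
discarded as SV candidates.  The coverage mask marks reference positions
covered by match/mismatch columns of clean blocks -- exactly the places
where the alignment supports the non-variant state, which is what
reference-genotype imputation requires.  Deleted spans are deliberately
not "covered": imputing a reference genotype under a deletion would be
wrong, and excluding them also makes deleted regions drop out of the
core genome.

## Variant calling

Mismatch columns become SNPs; gap runs of 1--49 bp become short indels,
left-aligned against the reference per VCF normalisation (the 49/50
split removes the ambiguity at exactly 50 bp).  Large-SV candidates come
from three sources: within-block gap runs and unaligned segments,
between-block discontinuities on one scaffold, and blocks whose reference
placement breaks the monotone order of their scaffold neighbourhood
(translocations; strand-discordant blocks fold into the same class).
Double-sided candidates are decomposed by the affine aligner when
feasible, with each resulting gap run classified independently; a
decomposition whose aligned columns disagree is rejected, and the
candidate falls back to coverage-aware handling (uncovered islands as
deletions) or a paired del+ins sharing one id -- the class list has no
"substitution" row, so complex events are represented as that pair.

Copy classification probes up to three 150 bp windows of the allele
against a k-mer index (k = 13) and verifies hits by alignment at >= 90%
identity: a deletion whose sequence persists elsewhere in the accession
is a copy loss; an insertion whose sequence matches the reference (the
source locus, for tandem duplications) is a copy gain.  Insertions whose
matched source overlaps a called translocation are its destination and
are suppressed, as are deletions at translocation edges.  Every SV needs
100 bp of aligned flank on both sides within one scaffold and no N-gap
within 100 bp of its span; discards are logged with reason codes.

Merging takes the union of sites keyed by position, class and alleles.
Unmatched accession/site combinations impute the reference genotype when
the coverage mask fully covers the site, and are missing otherwise;
provenance (`called`/`imputed`/`uncallable`) is kept per cell.

## Pan-genome and diversity

Novel segments are the >= 50 bp pieces of the gap-removed assembly not
covered by aligned columns, minus anything that still matches the
reference (a rescue check that keeps duplicated or translocated content
out of the novel set).  A DUST-style triplet score over 64-base windows
(threshold 2) and a short-period tandem detector (periods <= 12, arrays
>= 50 bp) mask low-complexity content; segments over 80% masked are
removed, others trimmed.  Novel-insertion sequence is simulated at 40%
GC specifically so that this filter does not eat truth segments, keeping
pan-genome recall measurable.  Redundancy collapses by greedy
single-linkage at >= 90% identity over >= 80% of the shorter segment;
the external multi-aligner this step replaces is only consumed through its
sharing partition, which the clustering reproduces.

`size_curves()` averages over accession orderings (all orders for <= 6
accessions, otherwise 20 seeded permutations): `core(k)` is the
reference bp covered in all of the first k accessions plus novel
clusters present in all of them; `pan(k)` the union analogue.  Whether
reference-aligned-but-variant bases belong to the pan-genome is not
fixed by the source description; here they do (pan = union of coverage
plus novel content), and the definition is asserted as set algebra every
run.  The asymptotic model `y = b0 + b1*(1 - exp(-exp(lrc)*x))` is
fitted to the mean curve by Levenberg-Marquardt least squares with
multi-start over an `lrc` grid from -3 to 1; a constant curve
degenerates to `b1 = 0`.

Diversity follows the classical estimators: per segregating site the
theta-pi contribution is (differing called pairs)/(called pairs) --
pairwise deletion of missing genotypes, a choice the merging semantics
make natural -- normalised by the callable length (positions covered in
at least two accessions; sites callable in fewer report missing, never
zero).  Indel and SV events count as one biallelic unit at their start
position.  `theta_w = S/(a_n L)` with the harmonic number `a_n`.  SNP
effects are classified codon-by-codon under the standard genetic code,
strand-aware, with splice sites at the conventional +/-2 bp of intron
boundaries; premature stop, stop loss, start loss and splice-site
changes are the large-effect classes.  Ortholog groups come in two
kinds: syntenic one-to-one groups (reference gene paired through the
reciprocal-best net, >= 50% of CDS mapped, groups in >= 10 accessions)
and similarity clusters (single-linkage at >= 70% identity over >= 50%
of the longer protein -- a deterministic stand-in for Markov clustering,
preferred because determinism matters more than cluster granularity at
this scale).  MPPD uses pairwise global alignments (identity scoring,
gap open -10, extend -0.5) rather than one multiple alignment; the
per-pair distance is 1 minus the identical-column fraction.
Copy-number CV uses the population standard deviation (divide by n),
zeros included for absent accessions.

## Long-read validation

A read supports a breakpoint when one contiguous placement covers the
closed +/-500 bp window around it; an SV is valid only when every
breakpoint has at least five supporting reads.  Deletions expose one
fused junction (tested once); insertion-like calls expose two junctions,
each tested independently -- the source description does not fix this
accounting, so it is explicit and configurable here.  Placements come
either from the simulator's truth or from a naive seed-and-vote mapper
(unique 21-mers, best diagonal); split or clipped placements do not
count, matching the intent that a validating read crosses the junction
in one piece.

## What the simulation does and does not show

Passing tests demonstrate that the algorithms recover what was planted
under the stated conditions: non-overlapping variants, substitution-only
read errors, single-haplotype accessions (the sequenced material was
selfed for generations, so heterozygosity is out of scope), no
contaminants (the contaminant-screening hook is left unimplemented), and
repeats that are younger copies of a few consensus elements.  Real
genomes add nested variation, diverged repeat families, heterozygosity
and assembly base errors; accuracy numbers measured here are therefore
upper bounds, and the validation-rate machinery (reads from the
unmutated haplotype rejecting planted false SVs) is the template for
estimating the gap on real data.

Problem sizes used by the test-suite and the acceptance script -- 2 Mb
references, 3 accessions for variant discovery, 13 accessions for the
pan-genome curves -- are the package's desk-scale study conditions; all
thresholds (50 bp SV boundary, 90% copy identity, 10-accession group
filter, +/-500 bp / 5-read validation rule) are the field-standard
values carried unchanged.

## Known limitations

* Translocations shorter than the minimum chain score (~200 bp) surface
  as a deletion plus a copy-gain insertion rather than a translocation
  call; the scoring of calls against truth accepts either signature.
* Inversions are folded into the translocation class (strand-discordant
  blocks); they are not reported separately.
* Counting of copy-number events follows events, not copies.
* The naive read mapper assumes substitution-dominated divergence; it is
  not a long-read aligner for indel-rich error models.
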