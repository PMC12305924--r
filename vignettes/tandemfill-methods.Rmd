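---
title: "tandemfill: models and methods"
author: "tandemfill authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tandemfill: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemfill)
```

# The problem

Long tandem-repeat arrays — centromeric satellites, subtelomeric repeats —
are the last stretches of eukaryotic genomes that routine HiFi + Hi-C
assembly pipelines leave as gaps. The repeat units are too similar for a
de novo assembler to thread, yet a high-quality reference genome of the
same species usually carries a complete copy of the homologous array.
`tandemfill` exploits that: it uses the reference only to *recruit* the
sequencing reads that belong to the target interval (the TOI, target area
of interest), then assembles those reads locally, places the resulting
contigs back onto the reference interval, and, for diploids, phases them
into two haplotypes with Hi-C. The flanking assembled sequence on the
query ("shores") anchors the phasing and is trimmed from the final
scaffolds.

The package implements the full pipeline plus the evaluation metrics
(completeness, correctness, an ordering-aware k-mer identity score,
reference-free improvement classifiers) and monomer-level population
analyses (consensus, variant profile, higher-order repeats, monomer-set
similarity). A deterministic synthetic-data generator drives every test.

# Read recall: the rare-k-mer hypothesis test

All reads partially aligned to the reference TOI are candidates. For one
alignment between reference region $R$ and read region $Q$, let $y$ be the
number of distinct *rare* canonical k-mers of the reference genome
(k = 21, genome-wide count at most 3) present in $R$, and $x$ the number
of those also present in $Q$. If $Q$ really derives from the homologous
locus, $x$ should be a predictable fraction of $y$: the model is
$X \sim N(\delta y, \sigma^2)$ with $0 \le \delta < 1$ a constant
capturing the expected divergence between individuals, and $\sigma^2$
absorbing sequencing error and sampling noise. Reads from *other* repeat
arrays share almost no rare k-mers with $R$ ($x \approx 0$) and fail a
two-sided test at level $\alpha$:
accept iff $x \in [\delta y - Z_{\alpha/2}\sigma,\; \delta y +
Z_{\alpha/2}\sigma]$. A read is recalled when any one of its alignments
passes.

$\delta$ and $\sigma^2$ are fitted by maximum likelihood from training
observations on homologous regions with trusted assemblies:
$\hat\delta = \sum y_i x_i / \sum y_i^2$ and
$\hat\sigma^2 = \sum (x_i - \hat\delta y_i)^2 / N$. The residual in the
variance estimate is squared: an unsquared residual sum is not a variance
(it can be negative), and the squared form is the actual maximiser of the
stated normal likelihood. Two practical points the implementation
surfaces:

* training should span **several** homologous regions. Rare-k-mer survival
  varies between regions by a few percent, and $\sigma^2$ must absorb that
  between-region spread or the test is anti-conservative on new regions
  (the generator's training helper spreads its observations over five
  independent templates for exactly this reason);
* $\sigma$ is modelled as constant while the natural noise scale grows with
  $y$, so very long single alignments are fragile. Aligners fragment
  alignments over tandem repeats anyway, and the one-passing-alignment
  rule makes the test robust at realistic fragment sizes (~3 kb).

A packaged fallback (`recall_model()`, $\delta = 0.85$, $\sigma^2 = 25$)
supports zero-configuration runs and is logged when used.

# Contig generation from the unitig graph

The recalled reads are assembled externally into a unitig graph (GFA) with
read paths (GAF); `tandemfill` turns that graph into contigs.

1. **Edge support.** Each oriented adjacency in a read path adds one count
   to its bidirected edge.
2. **Transitive edges.** An edge $v \to w$ is dropped when a longer
   supported path $v \to o \to \dots \to w$ exists (both the edge and the
   detour need at least `min_support` reads; the detour search is bounded
   to 5 hops). The contig then follows the longer path.
3. **Modified BFS.** Starting from all zero-indegree nodes (leftover cyclic
   components are seeded at their longest node), each node may be visited
   $\lfloor (id + od)/2 \rfloor$ times (floored at one visit so degree-1
   nodes are never orphaned). At a branching node, transitive successors
   are skipped; among the remaining successors with enough support only
   the best-supported one is taken on this visit (ties broken by node
   length, then id — deterministic); if none has enough support, all
   successors are taken. Every visit gets a timestamp.
4. **Timestamped DFS with cut flags.** The traversal graph is walked
   depth-first, always taking the not-exhausted successor with the
   earliest BFS timestamp. Branching nodes carry cut flags
   (one-in/many-out: cut outgoing; many-in/one-out: cut incoming;
   many-in/many-out: cut all); when a walk revisits a node and closes a
   loop, that node's flag is cleared — the loop is solvable and the walk
   may pass through the node twice. After the traversal, walks are severed
   at the surviving flags; each maximal unsevered stretch is a contig.

The two classic loop configurations behave as intended: a plain loop
hanging off a path yields one contig passing through the branching node
twice; adding an extra exit inside the loop leaves an unsolvable node
whose outgoing edges are cut, yielding three contigs.

Contig sequences concatenate node sequences (reverse-complemented per
orientation) with GFA overlap trimming. `min_support` defaults to 2 and is
shared by the transitive rule and the BFS successor rule; the printed
procedure names a single "enough supporting reads" notion and one knob
keeps the behaviour predictable.

# Contig placement on the reference TOI

Contigs whose reference alignments are dubious are discarded first: a
contig is kept only if its TOI-aligned length is at least 10% of its
length *and* at least twice its aligned length elsewhere on the reference.

Each alignment record of a kept contig is an *element* — an aligned pair
of a reference interval and a contig interval. Candidate positions are
windows of the contig's length anchored so that some element lines up
with its contig offset (minus-strand elements are mapped onto the
reverse-complemented contig first, so chain order is consistent). The
score of a window is the length of the longest non-decreasing subsequence
(LIS, patience sorting, $O(M \log M)$) of the contig-order ranks of the
window's elements read in reference order — the fast approximation of the
exact longest matching subsequence (LMS), which the package also ships as
a quadratic dynamic program and uses as the test oracle. Overlapping
windows (>50% of the window length) are merged keeping the best, and at
most 7 candidates per contig survive.

Selecting one candidate (or none) per contig is a combinatorial
optimisation solved by a genetic algorithm. With $l_t$ the total TOI
length at coverage $t$ and $d_{ij}$ the pairwise midpoint distances of the
placed contigs, the fitness ("adaptivity") is

$$f_{haploid} = 2(l_1 - l_0 - l_{>2}) + l_2 - 2.5\,l_{<0}
  + \tfrac12 \sum_{i<j} d_{ij}$$
$$f_{diploid} = 2(l_{\ge 2} - l_0) - l_1 - 2.5\,l_{<0}
  + \tfrac12 \sum_{i<j} d_{ij}$$

where $l_{<0}$ is zero-coverage length whose nearest placed neighbours on
both sides come from the same assembly-graph component — a gap that should
not exist, hence the stiffer penalty. The GA runs with 500 individuals,
fitness-proportional selection of 60 parents (fitness shifted so the
minimum maps to a small positive weight — selection needs positive
weights, which the verbal description leaves open), one-locus allele
swapping until 300 offspring exist, 5% per-offspring mutation (delete a
placed contig or insert an unplaced one), and replenishment with 140
fresh random individuals back to 500 (the 60 + 300 gap is unstated in the
verbal procedure; fresh randoms keep exploration alive). It stops when
the ten best fitnesses coincide or after 200 generations, and returns the
best individual ever seen (parent retention makes the best fitness
non-decreasing). On instances small enough to enumerate, the GA matches
exhaustive search.

# Phasing with Hi-C, HiFi and homology signals

Each placed contig takes one of four states: discarded, maternal,
paternal, or collapsed (a contig representing both haplotypes, counted in
both). Three signals feed the objective:

* `HIC`: Hi-C pairs anchored by *unique* 31-mers (k-mers occurring exactly
  once across contigs and shores). An end that hits unique k-mers of more
  than one sequence, or of none, drops the pair. Anchoring by unique
  k-mers rather than alignment is what makes the signal haplotype-specific
  inside a repeat array.
* `HIFI`: reads aligning to two contigs link them (+1 per read and pair).
* `H`: homology coefficients
  $h_{ij} = |S_i \cap S_j| / \min(|S_i|, |S_j|)$ over distinct canonical
  31-mer sets, with $\bar H$ the mean of the non-zero off-diagonal values.
  The text introduces a "global homology coefficient" and an "average
  value ... for all pairs"; both are read as this same non-zero mean.

The objective rewards Hi-C contacts between same-haplotype shores and
contigs (normalised by both lengths and the placement distance), rewards
HiFi links between low-homology same-haplotype contigs while penalising
links between high-homology pairs (that is the term that keeps
near-identical haplotype copies apart), and penalises maternal/paternal
length imbalance relative to the reference TOI length.

Two numerical choices matter and are deliberate:

* **Units.** Lengths and distances enter in kilobases. With unit weights
  and raw base pairs, the signal terms are ~10^6 times smaller than the
  balance term and the search degenerates into balance-only optimisation.
* **Weights.** $C_1 = C_3 = 1$, $C_2 = 5$ by default. The collapsed state
  costs nothing in the balance term (it adds the same length to both
  haplotypes) and always gains whatever Hi-C signal links a contig to the
  wrong haplotype's shores; the homology penalty is the only opposing
  force. Decomposing the objective on planted diploid instances shows that
  with $C_2 = 1$ the optimum collapses shore-adjacent contigs — wrong-side
  trans contacts divided by a small distance beat the penalty. $C_2$ must
  at least offset the cis:trans contact-mass ratio (about 5:1 in phased
  Hi-C data), hence 5. All three weights remain configurable.

The optimiser is restart hill climbing (the verbal procedure is
improvement-only acceptance, not temperature-based): random single-contig
state changes accepted only when they improve the objective, a local
optimum declared after 100 consecutive non-improving proposals, 50% of
the states randomised between restarts, best state over 1000 restarts
returned (the packaged default; validation studies on 16-contig instances
use 300 restarts, which already reaches the exhaustive optimum on every
enumerable instance tried). When the maternal/paternal signals are
perfectly symmetric the labelling is decided by whichever assignment the
search visits first; only the labelling, not the partition, is ambiguous.

Scaffolds concatenate each haplotype's contigs in reference order
(reverse-complementing minus placements) with 100 `N`s between
neighbours — the joining gap is a display choice, not an inference — and
shore-overhanging ends are trimmed wherever a terminal block (identity at
least 0.9, within 100 bp of the scaffold end) aligns to a shore.

# Evaluation metrics

*Completeness* is the truth-side union of continuously aligned blocks
divided by the truth length; *correctness* the assembly-side union divided
by the assembly length (unions are taken per sequence — blocks on
different contigs never merge). The *LIS identity score* takes the
canonical 31-mers unique within the truth and unique within the assembly,
orders the shared ones by assembly position and computes the longest
non-decreasing subsequence of their truth positions, divided by the
number of unique k-mers in the assembly: 1.0 means every unique k-mer is
present in a consistent order; rearrangements lower it even when content
is complete. Canonical k-mers make the score strand-tolerant; an exactly
reverse-complemented assembly scores by content but the positional chain
is interpreted on the canonical representation, so the score is read as a
consistency bound rather than a strand-resolved identity.

The reference-free improvement classifiers consume regional/structural
assembly-quality indices (R_AQI, S_AQI, e.g. from CRAQ) computed
externally: *strictly improved* iff $R_{new} > 1.1\,R_{ori}$; *loosely
improved* iff $R_{new} > R_{ori}$, or all of $R_{new} > R_{ori}/1.6$,
$S_{new} > S_{ori}$, and the new HiFi coverage closer to the genome-wide
coverage than the original. The AQI tools are not run by this package —
the classifiers are pure decision rules over a supplied table, which
keeps them unit-testable.

# Satellite and population analyses

The monomer scanner is a greedy left-to-right fit of the consensus (and
its reverse complement) into a local window, using a pattern-global /
window-local alignment with unit edit costs. A short window (1.35 units)
is tried first so that an adjacent cleaner copy cannot outcompete the
unit at the cursor; a wide window (2.2 units) recovers after gaps. A unit
is emitted when its edit distance is at most 25% of the unit length. The
scanner is an internal replacement for external repeat annotators and is
an approximation: heavily diverged or nested units at a window boundary
can be skipped, which the wide-window fallback mitigates but does not
eliminate.

Consensus building is column-majority voting, seeded from the most common
monomer length and refined once through per-monomer global alignments;
the per-column variant frequency is one minus the frequency of the most
frequent base (a deleted base counts as a variant; ties resolve to the
alphabetically first base).

A higher-order repeat (HOR) is a tandem duplication of at least three
consecutive monomers in which each duplicated monomer is within 5 edits
(Levenshtein) of its counterpart in the preceding block. For every start
and period the number of whole duplicated blocks is counted; HORs whose
monomer span is contained in an equal-period longer HOR are suppressed.
The detector is validated against exhaustive triple enumeration. A
monomer's *HOR score* is the number of HOR spans containing it divided by
the monomers in its region.

Monomer-set similarity is Jaccard over distinct strand-canonical
sequences (exact identity; the union denominator is one of two defensible
readings of "total number of monomers in both sets"). The sampling
experiment compares intra-region fractions (two disjoint tenths of one
region) against inter-region fractions, or whole regions grouped by
genome/chromosome. On populations generated with region-local variant
pools the intra/inter contrast is extreme; that is the synthetic analogue
of the local-similarity law, and it demonstrates the machinery, not the
biological effect size.

# The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults describe a
desk-scale satellite locus chosen to be realistic rather than easy:

| parameter | default | meaning |
|---|---|---|
| `monomer_len` | 181 | repeat-unit length (bp) |
| `n_monomers` | 200 | array size (~36 kb) |
| `hor_period` / `class_divergence` | 3 / 0.05 | monomer classes cycling along the array |
| `monomer_mut_rate` | 0.02 | private substitutions per copy (what makes k-mers locatable) |
| `haplotype_divergence` | 0.01 | SNPs+indels (8:1:1) between reference and each haplotype |
| `shore_len` | 5000 | unique flanking sequence |
| `hifi_depth` / `hifi_len_mean` / `hifi_err` | 30 / 10000 / 0.001 | HiFi reads, sub:ins:del = 2:1:1 |
| `hifi_aln_frag` | 3000 | planted alignments fragmented as aligners do over repeats |
| `hic_depth` / `hic_decay_exponent` / `hic_min_dist` | 20 / 1.5 / 1000 | cis contacts, truncated power-law separation |
| `inter_hap_noise` | 0.05 | trans contact fraction, uniform on the other haplotype |

Everything is reproducible bit-for-bit from the configuration seed; each
simulator stage derives its own stream from it, so stages are also
reproducible in isolation. Haplotypes carry base-level source maps back
to reference coordinates, which is how the generator emits *exact*
planted PAF/GFA/GAF/BED files without running any aligner — external
aligners and assemblers are consumed as file formats, never executed.
Three modelling choices are worth knowing when interpreting test results:

* HiFi reads are sampled across the whole haplotype chromosome including
  the shores, so coverage is flat at the array edges (sampling only the
  array would starve boundary contigs of linkage support);
* trans Hi-C contacts land uniformly on the other haplotype — random
  ligation has no distance structure; preserving the position across
  haplotypes would concentrate noise exactly on homologs and is the
  single most adversarial (and least realistic) alternative;
* the truth unitig graph is chopped from planted junctions (optionally
  staggered between haplotypes, as real assemblies fragment the two
  haplotypes at unrelated positions) rather than re-assembled, so the
  graph-simplification stage is testable in isolation.

What passing tests on this generator do **not** show: robustness to
alignment artefacts of a real long-read aligner, to chimeric reads, to
Hi-C restriction-site bias, or to reference arrays that are structurally
very different from the query's. The pipeline's empirical performance on
real satellite arrays is outside what desk-scale simulation can certify.

# Validation studies and problem sizes

The test suite validates every optimisation component against an
independent oracle: LIS against the exact LMS dynamic program and against
subset enumeration; the GA and the phasing search against exhaustive
enumeration on instances small enough to enumerate (up to 4 contigs x 3
candidates, and 6-contig 4^6 state spaces); the HOR detector against
triple enumeration on up to 30 monomers; the recall MLE against planted
parameters (N = 1000 observations, 20 replicates). End-to-end runs use a
~50 kb array (276 monomers) at 30x HiFi, haploid and diploid; the diploid
phasing study uses 8 contigs per haplotype with 5x intra-haplotype Hi-C
enrichment at 80x, and 16-contig recovery is scored up to the global
maternal/paternal swap. These sizes keep the full suite within minutes
while leaving every algorithmic branch exercised.

```{r eval = FALSE}
# the full self-contained validation run
out <- fill_simulated_region(seed = 1, ploidy = 2)
out$quality
```

# Known limitations

* The recall test assumes a constant $\sigma$; very long unfragmented
  alignments from an unusually diverged region can be rejected en bloc.
  Per-region $\delta$ estimation is a natural extension.
* The contig generator implements the published traversal rules; it is not
  a general-purpose string-graph simplifier (no bubble popping beyond the
  transitive rule).
* The phasing objective's weights are data-scale dependent; the defaults
  are calibrated for kilobase-scale loci with typical phased Hi-C
  enrichment and should be revisited for very deep or very shallow data.
* The monomer scanner is greedy; for publication-grade annotation of real
  arrays a dedicated annotator remains preferable, and the package accepts
  externally produced monomer tables wherever it accepts its own.
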