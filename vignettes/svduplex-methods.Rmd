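---
title: "Molecule-level SV junction detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecule-level SV junction detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind svduplex, the tunable parameters
and their defaults, what the bundled simulator does and does not emulate,
and the numerical and design choices made where more than one reasonable
option existed.

## The molecule model

A capture library is a population of source DNA molecules. Sequencing
observes each molecule as one or more read pairs; duplex (Y-adapter)
libraries additionally tag the two strands of a molecule with an ordered
pair of unique molecular identifiers (UMIs), so that a read pair's strand
of origin is recoverable from the UMI order and read orientation.

`collate_molecules()` reconstructs molecules from name-grouped alignments:

- Endpoint keys. The two outermost aligned positions of a read pair
  (segments above `mapq_min = 20` only) plus the outer soft-clip lengths
  form the molecule key. Keys agree when every coordinate differs by at
  most `allowance = 1` bp.
- UMI indexing. Observed UMIs map to an index 1–96 when exactly one
  expected UMI lies within Hamming distance 1; ambiguous or distant
  observations are rejected with the read pair. The shipped UMI set has
  pairwise distance ≥ 3, so a single sequencing error can never produce an
  ambiguous match.
- Strand semantics. In ligation mode, mirrored read-pair orientations with
  swapped UMI order are the two strands of one molecule; in tagmentation
  mode opposite orientations are independent Tn5 cleavage products and stay
  separate molecules (duplex assignment is impossible there).

Grouping is single-pass and anchored on the first-seen key, rather than a
transitive closure over all pairs. The anchored pass is deterministic and
linear; the two strategies provably agree whenever distinct molecule keys
are ≥ 3 bp apart, which the test suite verifies against an all-pairs
union-find oracle. With a 1 bp allowance and real endpoint dispersion the
difference is confined to pathological chains of keys exactly 2 bp apart.

### Consensus

Each strand family is downsampled (seeded per molecule, so reruns are
identical) to at most 11 read pairs; a column is called when the modal base
reaches a 0.667 fraction of the family, else masked `N`. The threshold is
compared as `fraction >= 0.667`, so 2 of 3 (0.6667) does *not* call a
base — the conservative literal reading. The duplex consensus keeps only
columns where both strand consensuses agree. With a 1% per-base read error
and three pairs per strand, the duplex consensus error rate is below
1e-4 per called base (verified by simulation in the test suite); base
qualities do not weight the vote, and the family members are reconciled to
the representative read pair (highest summed base quality) by their shared
outer endpoints, left-aligning 1 bp offsets.

## Junction nodes and candidates

A molecule is a path of aligned segments. Every segment contributes two
nodes `(chromosome, position, side)`, where the side (L/R) is the direction
the molecule occupies from that position: a `+` segment `[a, b]` yields
`(a, R)` and `(b, L)`. The outer two nodes identify the molecule; inner
nodes are junction evidence. Split evidence carries a junction-spanning
sequence; discordant mates whose junction fell in the unsequenced gap give
imprecise inner nodes at the inner aligned ends. SV type follows the
canonical node-side algebra on sorted nodes: `(L, R) = Del`, `(R, L) =
Dup`, equal sides `= Inv`, different chromosomes `= Trans`.

Two parameters matter here:

- `min_sv_size = 50` bp: same-chromosome deletion/duplication-type
  junctions below this are indel-scale and are not reported as SVs (display
  filters such as the 2 kb floor used in figure-level summaries are a
  filtering option, not a calling threshold).
- `max_proper_insert`: estimated per library as the 99.5th percentile of
  concordant pair spans (a stand-in for aligner-declared insert limits;
  overridable). It separates concordant from discordant pairs, breaks
  candidate clusters, and bounds gap-evidence attachment. The 0.5% of
  genuinely long proper molecules above it surface as single-molecule
  imprecise calls; molecule-count and size filters remove them.

## Cross-molecule discovery

Candidates from all co-analyzed samples are sorted by left node and split
into sets wherever consecutive left nodes are ≥ `max_proper_insert` apart
(or chromosome/side changes), then re-sorted and re-split on right nodes.
Within a set, each distinct exact split-read node pair becomes one SV call
(consensus realignment makes split supporters of one junction agree
exactly); gap molecules attach to the nearest compatible split junction
within the insert limit on each side, or form an imprecise call whose
nominal breakpoints are the innermost aligned ends over supporters.
Because consecutive-gap splitting is single-linkage, dense candidate
neighborhoods can chain unrelated gap molecules into one set; since
supporters of a single gap junction can only spread over the insert window
on each side, the two-pass split is re-applied recursively within
gap-only groups before a call is emitted.
Near-duplicate supporters (summed outer-endpoint distance strictly below
5 bp, within one sample) are purged, keeping the larger family.
"Closer than 5 bp in total" is read as a strict inequality on the sum over
both endpoints, so offsets of (3, 2) are kept.

Outer-clip recovery re-admits proper-looking molecules whose alignment ends
exactly at a precise breakpoint with ≥ 5 clipped bases matching the far
flank. The 5-base floor alone would admit ~1/1024 random matches, so the
comparison extends to `min(clip, 20)` bases, exact with N as wildcard.

### Microhomology metric

The junction consensus (cross-molecule column vote at the same 0.667
threshold, anchored on the junction column) is compared to the two
reference flanks by extension: `I1` = how far the left flank continues
past the nominal breakpoint along the consensus, `I2` symmetric, `ilen` =
unaligned bases between the flanking alignments. Valid breakpoint
placements number `I1 + I2 - ilen + 1`, so the metric is `I1 + I2 - ilen`:
microhomology when positive, blunt at 0, net de novo insertion when
negative (the inserted sequence is recorded). `N` columns stop extension,
which can only understate microhomology. An independent brute-force
placement enumerator (`junction_metric_oracle()`) checks every split point
explicitly; the suite requires exact agreement on 1000 random junctions.
The reference molecule for junction descriptions is the split supporter
whose junction is most central in its read, with ties broken by family
size then molecule id.

## Filters

`filter_spec()` defaults reproduce the headline screening configuration:
flanking MAPQ > 50, at least three read pairs, single co-analyzed sample.
`min_read_pairs` counts read pairs summed over strands of the
best-supported molecule — the quantity that separates chimeric PCR
(family size 1) from replicated molecules. Shared-endpoint exclusion drops
an SV only when *all* supporters are flagged, since a true SV can coexist
with one recombined artifact template. Predicates apply in a fixed order
with per-predicate attrition counts, and tightening any threshold can only
shrink the surviving set (a tested invariant).

## Genotypes and de novo variants

The internal pileup genotyper (stand-in for an external caller; VCF import
is also supported) calls a biallelic genotype at positions covered by
≥ `min_depth = 10` unique molecules, keeping alleles at fraction
≥ `min_allele_fraction = 0.2` (more than two qualifying alleles marks the
position uncallable). A consensus base differing from the reference *and*
absent from the haplotype allele set is a presumptive de novo SNV. Distance
from the junction is measured from the first non-microhomology base
(distance 1 = adjacent to the ambiguous stretch), fixing the convention
that a variant 11 bases inside a 1 bp microhomology has distance 11.

The permutation test draws `n = |variants|` distances from the
coverage-weighted distribution of informative positions in
variant-containing consensuses, over 10 000 iterations by default; the
p-value is the fraction of iterations whose median is strictly less than
the observed median (ties count against significance, the conservative
direction; a documented `finite_correction` option adds +1/(N+1)). The
weighting follows consensuses crossing each distance, not pooled bases —
the alternative per-base weighting would over-weight long fragments. Only
the one-sided proximity alternative is computed; a Mann–Whitney variant on
raw distances is available as a secondary test. Under the null the
p-values are calibrated (400-replicate check in the suite) despite median
ties, because 20-variant medians over ~150 distinct distances tie rarely.

## The simulator

`simulate_library()` emulates: capture enrichment as acceptance
probabilities by fragment class (T = 1, A = 0.3, elsewhere = 0.002 —
qualitative, chosen to expose the under-recovery of target-adjacent
junctions); fragment lengths ~ Normal(300, 50); 2 × 151 reads; zero-inflated
Poisson strand families; heterozygous clone deletions with planted
microhomology or insertions (flanking bases are forced so planted values
are exact, and the truth metric is recomputed from the genome); per-base
substitution errors; and the three artifact classes by mechanism:

- ligation chimeras join a captured fragment to a uniformly random genomic
  fragment before strand assignment (duplex-capable, blunt or single-base
  insertions that are A/T with probability 0.81);
- chimeric PCR products are sequencer-sized single-strand molecules with
  family size one, switching templates at a planted shared k-mer (k peaked
  at 8–9 bp) and sharing their left outer endpoint with an explicit proper
  partner molecule. Each artifact uses a distinct planted site — template
  switching is a unique late-cycle event, so recurrent identical chimeras
  are not modeled;
- tagmentation foldbacks are sub-kilobase same-side inversion junctions
  with planted reverse-complement homology.

Reads crossing a junction with a terminal block shorter than `min_align =
20` bp are emitted as soft-clipped single alignments, which is what makes
outer-clip recovery exercisable. Split reads are emitted as primary plus
supplementary records with SA tags at MAPQ 60 (a configurable low-MAPQ
fraction models ambiguous alignment; no aligner is run). Every emitted
read pair has exactly one ground-truth row.

What the simulator does *not* model: indel sequencing errors, base-quality
variation (qualities are flat, so quality-weighted merging is exercised by
unit fixtures rather than simulation), GC or length capture bias,
polymerase-slippage duplicates with endpoint jitter (collation replicates
are exact, so the 1 bp allowance is exercised by constructed fixtures), and
chance chimeras between homologous repeat copies. Passing tests therefore
demonstrate the pipeline's logic and its artifact separation under the
stated mechanisms, not performance on repeat-rich real genomes.

## Problem sizes

The validation suite scales the capture design down so each scenario runs
on one CPU in minutes while preserving the quantities that matter: the VAF
calibration uses five 3 kb targets at ~2000× molecule coverage with a 10%
clone heterozygous for 20 deletions (expected VAF 5%); artifact scenarios
use 250 kb chromosomes so that independent ligation events rarely fall
within one insert-size window of each other, mirroring the sparsity of a
full-genome background, with ≥ 200 junctions per artifact class. Larger
designs change runtimes, not logic.

## Known limitations

- Exotic multi-junction molecules (≥ 3 segments) contribute each adjacent
  node pair as an independent candidate; chained-junction phasing across
  molecules is not attempted.
- Gap-only calls have no junction metric and are excluded from
  junction-profile analyses, as their breakpoints are nominal.
- The shared-endpoint flag compares exact (±1 bp) outer positions; at very
  deep coverage chance endpoint collisions make it uninformative, which is
  why it is an optional filter rather than a default.
- CRAM input is out of scope (reference-dependent decoding); SAM/BAM are
  supported.
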