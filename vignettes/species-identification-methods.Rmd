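---
title: "Methods: genome-id Bloom filter indexing and coverage-cluster filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-id Bloom filter indexing and coverage-cluster filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`kmersig` answers a presence/absence question: given a universe of candidate
reference genomes and a shotgun metagenomic sample, which species are
actually in the sample? It does so in three stages — a k-mer index whose
entries carry genome identifiers, a per-read voting classifier, and a
coverage-clustering filter that removes false-positive species calls. This
vignette describes each stage's model and assumptions, the tunable
parameters and their defaults, the synthetic-data generator used for
validation, and the numerical and design choices behind the implementation.

## The index: a Bloom filter that stores genome ids

A classical Bloom filter stores set membership in an array of bits. Here the
array instead holds one signed integer per entry, with three states:

* `0` — never written;
* a positive id `g` — written only by k-mers of genome `g`;
* `-1` ("dirty") — written by k-mers of two or more distinct genomes.

`build_index()` processes each genome in turn. Every k-mer of every sequence
— on both the forward and the reverse-complement strand — is hashed by `n`
independent seeded hash functions to `n` positions in the array of size `m`,
and each position is updated by the rule: empty takes the id, same id is
unchanged, a different id becomes dirty, and dirty is absorbing. The final
array is therefore independent of the order in which genomes are inserted:
an entry ends as `g` iff exactly one genome ever wrote it, and `-1` iff two
or more did. k-mers containing `N` are skipped on both build and query,
since ambiguous bases carry no signature information.

`query_kmer()` reads the `n` entries of a k-mer and reports a genome only on
*unanimity*: all `n` entries must hold the same positive id. Any empty
entry, dirty entry, or disagreement discards the k-mer. Queries are
forward-only, because both strands were already inserted at build time.
(A canonical-k-mer mode was considered and rejected: inserting both strands
and querying forward-only keeps the query path branch-free and matches the
two-strand build definition above.)

Two properties follow directly from the update rule and are exercised by the
test suite against an exact k-mer dictionary oracle:

* **No wrong ids.** A k-mer that occurs in exactly one genome can only
  query to that genome or to discard — its entries were all written by the
  true genome, so they hold either its id or `-1`. Hash collisions can
  silence a signature (dirty) but never forge one for a k-mer the index has
  seen.
* **Monotone degradation.** Shrinking `m` increases collision pressure and
  converts unique-signature verdicts into discards, never into wrong ids.

False positives *are* possible for k-mers the index has never seen (e.g.
sequencing-error k-mers): their `n` positions may coincidentally all hold
the same id. This residual Bloom-filter behaviour is precisely what the
coverage filter downstream exists to absorb.

### Index parameters

* `k = 31` (default): the usual species-level discrimination length for
  bacterial genomes; shorter k trades specificity for sensitivity.
* `n_hash`: more hash functions make unanimity harder to satisfy by
  coincidence (fewer spurious verdicts) but write more entries (more dirt at
  fixed `m`). The package default is 3; the bundled study community uses 2,
  the appropriate choice for memory-lean indexes (see below).
* `m`: defaults to `2 * n_hash * D`, where `D = 2 * total_bp` estimates the
  distinct k-mer count over both strands. This keeps the expected per-entry
  write load at 0.5 (≈ 39% occupancy), a regime where dirty-by-collision
  entries are a small minority. `m` is the main memory/precision dial;
  practitioners sizing an index to available RAM will often operate far
  above load 0.5, at the cost of more discarded k-mers and more
  coincidental unanimity — which is also the regime in which the coverage
  filter earns its keep.

## Read classification: unanimity votes and a strict majority

`classify_sample()` slides a k-window over each read. Windows that fail the
quality gate (below) are skipped; the rest are queried, and discarded
verdicts are excluded from the vote. Let `V` be the kept votes. The read is
assigned to the modal id iff its share of `V` is *strictly* greater than the
majority threshold (default 0.5, i.e. "over 50%"). Everything else —
empty `V`, a modal tie, reads shorter than `k` — leaves the read discarded.
Two deliberate choices:

* The comparison is strict: exactly 50% does not identify. Ties between two
  modal ids are discarded rather than broken arbitrarily, keeping the
  classifier deterministic and conservative.
* Paired-end mates are classified independently. Nothing in the voting rule
  uses pair information, and treating mates as separate reads keeps the
  identified-read statistics well-defined for single- and paired-end inputs
  alike.

On error-free reads from indexed genomes, every kept vote is correct (the
no-wrong-id property lifts from k-mers to reads), so accuracy among
identified reads is 100% and only vote starvation (dirty entries) can
discard a read. With errors, most windows covering an error discard, and a
read is misassigned only in the rare case that its true votes are wiped out
while a handful of coincidental unanimity verdicts agree — the origin of the
low-coverage false species addressed next.

## The coverage filter

For each species with at least one identified read, the *approximate
coverage* is

```
coverage = total identified bases / genome length
```

i.e. the standard depth estimator restricted to identified reads (for
uniform read length this is `reads x read_length / genome_length`). Base
counts rather than read counts are used so that mixed read lengths are
handled correctly; for uniform reads the two differ only by a constant.

The model assumption is bimodal: species genuinely present have nontrivial
coverage, while false-positive species — fed only by sporadic misassigned
reads — have exceptionally low coverage. `cluster_coverages()` runs
one-dimensional K-means on `log10(coverage)` and `filter_species()` removes
the cluster with the lowest mean. Choices made where the design was open:

* **K = 2** by default: the model is present-vs-artifact. Larger `K` is
  accepted, but only the single lowest-mean cluster is ever removed.
* **log10 scale**: coverages span orders of magnitude; on a linear scale
  the split is dominated by the most abundant species and the low end
  collapses. Zero coverages cannot occur (zero-read species are not in the
  table), so the logarithm is always defined. A linear mode is available.
* **Degenerate inputs**: fewer species than `K`, or fewer distinct values
  than `K`, skip clustering and return a no-filtering sentinel (every
  species kept). With exactly `K` species the trivial one-per-cluster
  optimum is returned directly.
* **Numerics**: `stats::kmeans` (Lloyd) with 50 restarts under a recorded
  seed, `iter.max = 100`. In one dimension the K-means optimum is a
  contiguous split of the sorted values; the suite checks the
  implementation against an exhaustive contiguous-split WSS minimiser for
  up to 20 species. Ties in cluster means break towards the smallest label.

The filter is deliberately classifier-agnostic:
`ingest_external_assignments()` builds the same coverage table from any
tool's per-read species table plus genome lengths, so the filter can be
bolted onto other classifiers' outputs.

A known consequence of "always remove the lowest cluster": on a sample with
*no* false positives and well-spread true coverages, the filter will remove
the lowest-coverage block of genuine species. This is inherent to the
method, visible in its recall on sparse samples, and is the reason the
filter should be read as a precision device, not a sensitivity one.

## The quality gate

Sequencing errors generate the spurious k-mers that become false votes.
`min_kmer_quality` gates each window on the arithmetic mean of its per-base
Phred scores; the gate applies at query time only (references carry no
qualities) and 0 disables it. Because a mean over `k = 31` bases moves by
less than one unit when a single base is bad, the gate does not target
isolated miscalls — its operating point is whole low-quality regions and
degraded reads, whose windows fall below a mid-range threshold wholesale.
Raising the threshold can only remove votes (a per-read monotonicity the
suite asserts), trading identified reads for vote purity: species-level
precision rises, recall can fall.

## The synthetic community

All validation runs on simulated data with known ground truth, generated by
`community_spec()` / `simulate_community()`. The default study conditions,
chosen once as a realistic desk-scale mock community:

* a universe of 20 reference genomes of 25 kb each (i.i.d. uniform ACGT),
  10 of them present;
* present-species coverages log-spaced from 3x to 30x — an uneven community
  spanning one order of magnitude, as mock communities typically are;
* 75 bp single-end reads, positions and strands uniform;
* substitutions at 0.5% per base in the main read population, and a 10%
  *degraded* read fraction at 10x that error rate. Correct bases draw
  Phred ~ N(37, 2) in normal reads and ~ N(15, 4) in degraded reads;
  erroneous bases draw ~ N(8, 3); all scores clipped to [2, 40]. The
  two-population design reflects how short-read quality failures actually
  present (whole reads or long tails going bad, not isolated low-quality
  bases) and gives the mean-Phred gate a well-defined operating point
  between the two populations (~ 30);
* an optional related-pair mode copies a genome at a set divergence to
  plant shared k-mers between close relatives — the natural substrate of
  dirty entries.

The study community is indexed with `n_hash = 2` at default `m`. Under
these conditions a sample of ~ 41,000 reads typically yields a few dozen
misassigned reads spread over the universe, so the unfiltered species list
contains most of the 10 absent genomes at coverages below 0.1x — two orders
of magnitude under the sparsest true species. That separation is what the
acceptance checks exercise: the filter must recover exactly the present
set.

What the simulator does *not* emulate — and what passing tests therefore do
not show: real inter-genome homology structure (shared genes, horizontal
transfer) beyond the related-pair mode; indels and chimeric reads;
position-dependent error profiles of specific instruments; realistic
abundance distributions fitted to real microbiomes; and reference databases
at the thousands-of-genomes scale, where index load factors far above the
default sizing change the dirty-entry economics. Conclusions about ranking
against other tools on real data are out of scope of the simulation.

## Problem sizes used in validation

The suite's heaviest checks, sized for a single CPU: an exhaustive
k-mer-dictionary comparison over ten 20 kb genomes at `k = 15`,
`m = 2^22`; 5,000 error-free reads over a ten-genome universe; 50 seeded
replicates of the full 20-genome community pipeline; and 100 random
coverage vectors against the exhaustive clustering oracle. The script
`scripts/acceptance.R` re-runs the default community end-to-end from a
single seed and reports identification rate and species-level
precision/recall/F1 before and after filtering.

## Limitations

* The index stores ids, not counts: a k-mer present many times in one
  genome and once in another is simply dirty; no abundance profiling is
  attempted.
* Removal of exactly one cluster means the filter cannot express "no false
  positives present" except through the degenerate-input sentinels; see the
  recall caveat above.
* Species identity is by normalised name; no taxonomy tree is consulted,
  so strain-level aggregation or genus-level fallback are out of scope.
* Entry width is fixed at 32-bit signed integers (R's native type), which
  bounds `m` below 2^31 entries per index file.
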