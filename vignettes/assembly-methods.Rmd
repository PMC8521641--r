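---
title: "Methods: sparse de Bruijn graph assembly of HiFi-like reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse de Bruijn graph assembly of HiFi-like reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsedbg)
```

## The model

`sparsedbg` assembles low-error long reads through a sparse de Bruijn graph
built in homopolymer-compressed (HPC) space. The method rests on two
empirical properties of HiFi-class data: reads are long enough that large
k-mers (hundreds to thousands of HPC bases) are mostly unique in a genome,
and nearly all remaining errors change homopolymer run lengths rather than
the compressed character sequence. Compressing runs before any k-mer work
therefore removes most errors *before* they can fragment the graph, and the
discarded information — the run lengths — is retained as per-position
tallies and restored statistically at output time.

The pipeline stages, in order: HPC compression, minimizer winnowing with
window size `w`, node identification by 128-bit hashes of canonical k-mers,
edge creation between minimizers adjacent in reads, transitive-edge
cleaning, unitig condensation, run-length-consensus expansion, and GFA 1.0
output. Each stage is an exported function; `run_build()` composes them.

## Parameters that matter

* **`k`** (HPC bases, default 2001 in `run_build`): node k-mer size.
  Distances in HPC space are roughly 25% shorter than in base space (for the
  run-length distribution the simulator produces, about 1.33 bases per HPC
  character). Larger `k` resolves longer repeats but requires reads long and
  clean enough to contain error-free k-mers. Desk-scale analyses in the
  tests use `k` between 31 and 501.
* **`w`** (default 1000): winnowing window. Expected fraction of k-mer
  positions selected on random sequence is `2 / (w + 1)`
  (`expected_density()`), so `w` controls graph sparseness and hence run
  time and memory; `w = 1` reproduces the dense de Bruijn graph. The
  constraint `w <= k - 1` guarantees that consecutive selected k-mers
  overlap by at least one HPC base, so every edge is an overlap edge.
  Raising `w` also lowers how many selected k-mers cover each HPC position
  (on average `2k/(w+1)`), which thins the run-length tallies and can reduce
  consensus accuracy — the accuracy/speed trade-off is monotone in `w`.
* **`t`** (`clean_t`, default 0.25): transitive cleaning threshold, the
  maximum coverage of a direct edge relative to the weakest leg of its best
  two-edge detour. 0.25 comfortably separates error support (roughly the
  per-read error rate times coverage) from genuine repeat-induced triangles,
  whose direct edge is as well covered as the detour.
* **`min_node_cov` / `min_edge_cov`** (default 1): optional abundance
  pre-filters; the method itself keeps everything by default.

## Hashing choices

Two different hash functions serve two different roles.

*Winnowing order* uses a strand-symmetric rolling hash: an ntHash-style
rotate/xor recurrence per strand, combined as the minimum of the forward and
reverse-complement values, then passed through a splitmix64-type avalanche
finalizer. The finalizer matters: the raw rotate/xor values of adjacent
positions are rank-correlated (each is the predecessor rotated by one bit,
xored with one of sixteen constants), which measurably depresses minimizer
density below `2/(w+1)`. The bijective mix removes the correlation without
giving up O(1) updates. Constants are fixed in the source; no per-process
salt exists anywhere, so identical inputs give identical graphs on any
machine.

*Node identity* uses FNV-1a in 128 bits over the canonical k-mer string
(canonical = lexicographically smaller of the k-mer and its reverse
complement; palindromes count as forward). At 128 bits, collisions between
the at most ~2^40 distinct k-mers of any realistic dataset have probability
around 2^-48 or less; they are treated as impossible and neither detected
nor resolved. This is what allows nodes of arbitrary `k` to be stored in
constant space.

## Winnowing conventions

A window is `w` consecutive k-mer *start positions*; a position is selected
iff it is the minimum of at least one window, ties going to the leftmost
position of the window. Sequences with fewer than `w` positions form a
single window, so any read of at least `k` HPC bases contributes at least
one k-mer. No extra terminal selections are forced beyond the window
guarantee; the consequence is that up to `w - 1` HPC bases at each read end
may be unrepresented, which only shortens terminal unitigs (for circular
genomes with wrapping reads it has no effect at all). The leftmost tie-break
makes selection deterministic but, in the measure-zero case of equal hash
values inside one window (identical k-mers within `w` positions, i.e. a
tandem repeat with period below `w`), it is the one place where strand
symmetry of the selected *positions* can break; hash values themselves
remain strand-symmetric.

## Graph semantics

Nodes are hashes with coverage, the canonical k-mer string (kept so unitigs
can be spelled without a second pass over the reads), and a run-length tally
per canonical offset; observations from reverse-orientation occurrences are
mirrored into canonical coordinates. An edge is a bidirected object between
oriented nodes carrying its HPC overlap and coverage; an edge and its mirror
are stored once under the lexicographically smaller key, and the overlap is
part of the key, so two distinct overlaps between the same oriented pair are
distinct edges (tandem contractions produce exactly that). Construction
accumulates per-read chains and aggregates once at finalization; since all
aggregation is commutative and node ids are assigned in sorted hash order,
the finished graph — and every downstream file — is invariant under read
order and global strand flips.

## Transitive-edge cleaning

The error mechanism addressed is a read losing one minimizer occurrence:
its two flanking minimizers become adjacent in that read's chain, creating a
direct edge that bypasses the two-edge path through the lost node. The rule:
edge `e` is removed iff some oriented 2-path `u -> m -> v` not using `e`
has both legs at least as covered as `e`, and `coverage(e) <= max(1,
floor(t * min(legs)))` for the detour maximizing that minimum. Removals are
decided simultaneously against the pre-cleaning graph — no cascade — so the
result does not depend on evaluation order.

One subtlety is worth recording. Because `w <= k - 1`, consecutive selected
k-mer spans always overlap; an interior substitution therefore always
perturbs at least two selected k-mers, and in practice also promotes a few
erroneous k-mers into the selection (each perturbed window must re-resolve
somewhere). A single base error thus typically creates a short chain of
coverage-1 nodes alongside the topology, not a pure bypass edge. The pure
bypass — the canonical input to the cleaning rule — is exactly a chain
missing one occurrence, which is how the cleaning tests construct it (via
`thread_chain`). For literal substitutions the guarantee the tests assert is
the realistic one: after cleaning, no edge between two true (error-free)
nodes exists that the error-free graph lacks. Coverage-1 error nodes remain
unless `min_node_cov` is raised; tip and bubble removal are out of scope.

## Unitigs, consensus, output

A unitig extends through a junction iff the junction has exactly one
outgoing and its successor exactly one incoming edge in the bidirected
sense, parallel edges counting separately. Determinism requires breaking two
symmetries: a circular unitig (an isolated, everywhere-non-branching cycle)
is broken at its smallest constituent hash in forward orientation, and a
linear unitig keeps the lexicographically smaller of its two spellings.
Unitigs are then sorted (longest first, ties by sequence then first hash)
and named `utg0000001`, ... so that GFA output is byte-stable.

Spelling walks the path, appending `k - overlap` characters per node and
validating every junction character-for-character. Tallies are pooled onto
unitig positions, overlap positions receiving both adjacent nodes'
observations; per position the consensus run length is the mode, ties to the
smallest length (runs are small integers with a roughly symmetric ±1 error
channel, so the mode is the natural robust choice; observed lengths are
capped at 255 for fixed-width storage). A circular unitig is spelled as
exactly one traversal — the closing overlap is not repeated — and its GFA
self-link is therefore written with overlap `0M`; this keeps segment length
equal to cycle length.

For links between different unitigs the expanded overlap is the sum of the
source side's consensus runs over the shared HPC positions, validated to
spell identically from the target side. The two sides pool different
occurrence sets at a junction, so with errors their consensus can in
principle disagree; in that case the link overlap is shrunk to the longest
length on which suffix and prefix agree, with a warning. Error-free data
never takes that branch.

## The simulator

`random_genome()` draws run bases uniformly (each new run differing from its
predecessor) with truncated-geometric run lengths — extension probability
0.25 per base, capped at 6 — matching the magnitude of homopolymer structure
in real genomes while keeping a closed form the tests can verify. Circular
genomes never wrap a run across the origin, so rotation-based comparisons
are exact. `sample_reads()` draws uniform starts and strands and
normal-length reads, then perturbs each homopolymer run by ±1 (floor 1) with
the configured probability and applies rare substitutions, preferring
replacement bases that differ from both neighbors so the HPC structure is
not biased more than necessary. Defaults (100 kb genome, 20 kb ± 2 kb reads,
20x coverage) mirror a bacterial-scale HiFi experiment at desk size.

What the simulator does *not* emulate: chimeric reads, coverage biases,
quality values, systematic (non-±1) run-length errors, and multi-base
indels. Passing tests therefore demonstrate the algorithmic guarantees —
oracle equivalence, invariances, exact recovery under the stated error
model — not performance on arbitrary real data.

## Problem sizes and numerical notes

The test suite runs dense-graph oracle comparisons at 50 reads of ~2 kb HPC
(k = 31), winnowing density on 10^6 random HPC bases, end-to-end recovery of
a 100 kb circular genome from 20x error-free reads at k = 501, w = 250,
cleaning experiments at 50x over 20 kb, and 10,000-trial Monte-Carlo
consensus checks; these sizes make every stochastic assertion comfortably
stable (3-standard-error bands) while keeping the whole suite around two
minutes. Integer run lengths, integer coverages and string comparisons in
fixed-width hex avoid any floating-point path in graph construction; the
only floating-point output is the `dp:f:` coverage tag, printed with two
decimals.

## Known limitations

In-memory and single-threaded; no read-to-graph alignment; no error
correction beyond transitive-edge cleaning; FASTQ input is the 4-line form;
multi-line FASTQ is not supported. N-containing reads are split, so a
minimizer can never span an ambiguity code. Hash collisions, while
astronomically unlikely, would silently merge nodes if they occurred.
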