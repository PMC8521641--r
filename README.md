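# sparsedbg

Sparse de Bruijn graph construction and assembly for low-error long reads
(PacBio HiFi and similar), in R.

HiFi reads combine multi-kilobase length with error rates at or below those
of short reads, and their residual errors are overwhelmingly homopolymer
run-length errors. `sparsedbg` exploits both properties:

1. **Homopolymer compression (HPC).** Every maximal run of identical bases is
   collapsed to one character, which removes the dominant error mode; the
   observed run lengths are kept as per-position tallies.
2. **Minimizer winnowing.** In every window of *w* consecutive k-mer start
   positions of the compressed read, the k-mer with the smallest
   strand-symmetric rolling-hash value is selected. Every window contains at
   least one selection, consecutive selections overlap by at least
   *k − w* ≥ 1 HPC bases, and on random sequence the expected selected
   fraction is 2/(*w* + 1) — so *w* dials the sparseness of the graph,
   with *w* = 1 the classical dense de Bruijn graph.
3. **128-bit node hashes.** Each selected k-mer, in orientation-canonical
   form, is named by a 128-bit hash. Nodes are hashes, not strings, so *k*
   can grow to thousands of bases at constant per-node cost.
4. **Bidirected graph.** An edge joins two oriented nodes whenever the
   corresponding minimizers are adjacent in a read, with HPC overlap
   *k* − (distance between their start positions). Edges and their mirrors
   are one object; coverage counts supporting read pairs.
5. **Transitive-edge cleaning.** A read that loses a minimizer occurrence to
   a sequencing error connects its two flanking minimizers directly. Such an
   edge is removed when a two-edge detour exists whose legs are each at
   least as well covered and the direct edge's coverage is at most
   max(1, ⌊*t* · min(leg coverages)⌋), default *t* = 0.25.
6. **Unitigs and run-length consensus.** Maximal non-branching paths are
   condensed, spelled in HPC space, and expanded back to bases using, per
   position, the modal observed run length (ties to the smallest). Output is
   GFA 1.0 plus optional FASTA contigs.

A bundled simulator generates random genomes with realistic homopolymer
structure and HiFi-like reads whose errors are ±1 run-length perturbations
plus rare substitutions, with ground-truth intervals, so the whole pipeline
is testable without external data.

## Worked example

```r
library(sparsedbg)

cfg <- sim_config(genome_length = 50000, read_length_mean = 8000,
                  read_length_sd = 800, coverage = 20,
                  run_length_error_rate = 0.05, seed = 42)
run_simulate(cfg, "ecoli_like")
res <- run_build("ecoli_like.fasta", "asm.gfa", contigs_fasta = "asm.fa",
                 k = 201, w = 100)
```

which logs (stderr) and prints (stdout):

```
[simulate] 125 reads, realized coverage 20.28x
[simulate] perturbed runs 37573/748064, substitutions 0
[build] 125 read records, 748064 HPC bases
[build] 14413 selected minimizers -> 753 nodes, 753 edges
[clean] removed 0 transitive edges
[unitig] 1 unitigs, total 50000 bp, N50 50000 bp
[gfa] wrote asm.gfa (1 segments, 1 links)
reads=125
hpc_bases=748064
minimizers=14413
nodes=753
edges=753
edges_removed=0
unitigs=1
total_length=50000
n50=50000
```

The 50 kb circular genome comes back as a single circular unitig of exactly
50,000 bp: 5% of homopolymer runs were mis-measured in the reads, but the
per-position run-length consensus at 20x coverage restores every run. The
graph held 753 nodes for 748,064 HPC bases — the sparsification at
*w* = 100 (observed 14,413 selected minimizer occurrences, density ≈
2/101). The GFA contains one `S` line (with a `dp:f:` average-coverage tag)
and one self `L` line marking circularity.

The same pipeline is available from the shell via the installed script:

```sh
Rscript "$(Rscript -e 'cat(file.path(find.package("sparsedbg"), "exec", "sparsedbg"))')" \
    build -i ecoli_like.fasta -o asm.gfa -k 201 -w 100
```

## Scope

The package builds graphs and unitigs; it does not do read-to-graph
alignment, tip/bubble error correction beyond transitive-edge cleaning,
scaffolding, or haplotype separation. Construction is in-memory and
single-threaded.
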