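# bioconvr

Unified interconversion of bioinformatics file formats in R.

Life-science analyses shuttle data between dozens of text formats —
sequencing reads (FASTQ/FASTA/QUAL), multiple sequence alignments
(CLUSTAL/PHYLIP/Stockholm), trees (Newick/NEXUS), annotations and
variants (GFF3/BED/VCF) and read alignments (SAM/BAM). Each conversion is
small; collectively they are a swamp of ad-hoc scripts. bioconvr is for
anyone who needs those conversions to be one consistent, scriptable,
testable operation: bioinformaticians wiring pipelines together, and tool
developers who want to benchmark alternative conversion implementations.

At its core are four ideas:

* a **registry** mapping filename extensions to formats, so a conversion
  can be inferred implicitly from `in.fq.gz -> out.fasta`;
* a **plugin contract**: a conversion named `<input>2<output>` (gates
  with several inputs/outputs join names with `_`, e.g.
  `fasta_qual2fastq`) exposing one or more `method_*` functions, one of
  which is the default — discovery needs no registration code;
* a **conversion graph** over which missing direct conversions are
  planned transitively (`A -> B -> C`, minimum hops, deterministic
  tie-breaks);
* a **benchmark harness** that times all methods of a conversion N times
  (default 5, reporting mean ± sd of wall/CPU/peak-memory) and a
  multi-mode variant that repeats the whole exercise M times and keeps
  per-round medians.

Compression is transparent: `.gz` and `.bz2` files are detected by
suffix, verified by magic bytes, and handled on both sides of every
conversion.

## Worked example

```r
library(bioconvr)

# a deterministic synthetic input (4 reads, 20 bp, seed 42)
generate_fixture("fastq", "reads.fastq", n_records = 4, seq_length = 20, seed = 42)
readLines("reads.fastq")[1:4]
#> [1] "@read_1"              "AAAACTCCATGTGTAACTCC" "+"
#> [4] "D)=,4)C=0E<%<\"282%HH"

convert("fastq2fasta", "reads.fastq", "reads.fasta")
#> Warning: quality information is lost when converting from FastQ to FastA
#> <fastq2fasta [records]: 4 record(s) in, 4 out, 0.002s (lossy)>
```

The report says 4 records went in and 4 came out, which method ran
(`records`, the default of three), how long it took, and that the
conversion discards information (FASTA has no qualities). When no direct
converter exists, the graph finds a route:

```r
find_path("fastq", "faa")
#> <conversion_plan: fastq2fasta -> fasta2faa (lossy)>
```

The same operations from a shell, via the bundled wrapper
(`inst/bin/bioconv`):

```sh
bioconv reads.fastq reads.fasta      # implicit mode: inferred from extensions
bioconv fastq2fasta reads.fastq      # explicit mode: writes reads.fasta
bioconv -a reads.fastq reads.faa     # transitive mode (prints a loss warning)
bioconv reads.fastq r.fasta r.qual   # logical gate: two outputs
bioconv -b -N 5 -I reads.fastq out.fasta   # benchmark all methods, plot too
bioconv --show-methods fastq2fasta
# records *default*
# linewise
# buffer
```

Exit codes: 0 success, 1 usage/resolution error, 2 conversion error,
3 missing external tool. A TOML-style config (`-c`) can override default
methods and the external command templates (e.g. which samtools-like
binary backs `sam2bam`).

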