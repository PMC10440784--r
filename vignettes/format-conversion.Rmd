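---
title: "Design and methods of the bioconvr conversion framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and methods of the bioconvr conversion framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioconvr)
```

## The problem

Bioinformatics workflows constantly shuttle data between redundant or
complementary text formats: sequencing reads (FASTQ, FASTA, QUAL),
multiple sequence alignments (CLUSTAL, PHYLIP, Stockholm), phylogenetic
trees (Newick, NEXUS), genomic annotations and variants (GFF3, BED, VCF)
and read alignments (SAM/BAM). Each pairwise conversion is trivial in
isolation but collectively they form a swamp of one-off scripts with
inconsistent conventions. bioconvr puts one interface over all of them: a
registry maps filename extensions to formats, conversions are plugins
named `<input>2<output>`, and a single call — or a single shell command —
performs any registered conversion, directly or through intermediate
formats.

## The registry and implicit mode

A `format_descriptor` records a format's name, its accepted extensions
and a domain tag. The default registry covers 14 formats; each extension
belongs to at most one format, which keeps implicit mode deterministic:
the conversion for `reads.fq.gz -> reads.fasta` is inferred purely from
the names. Compression suffixes (`.gz`, `.bz2`) are peeled before the
format extension is read, and all file I/O goes through `open_auto()`, so
every converter transparently reads and writes compressed files. On read,
the file's magic bytes are checked against the suffix: a plain-text file
named `.gz` fails immediately with a codec error rather than producing
garbage downstream.

How ambiguous extensions shared by two formats should behave in implicit
mode is genuinely open; we resolve it by forbidding them in the default
registry (registration of a claimed extension is an error naming both
formats). Users with unconventional names fall back to explicit mode,
where the conversion is named on the command line.

## The converter plugin contract

A converter definition declares its `A2B`-style name (multi-port gates
join formats with `_`, e.g. `fasta_qual2fastq`) and one or more functions
whose element names carry the `method_` prefix; the identifier after the
prefix is the public method name. Discovery extracts the input/output
formats, the method list in declaration order, and the default method (a
declared `default`, otherwise the first method) — no per-converter
registration code exists. We use `method_` rather than a leading
underscore because a leading underscore is not a syntactic name in R;
the contract is otherwise the conventional one for this kind of
framework.

Several methods per conversion exist so they can be benchmarked against
each other. `fastq2fasta` ships three genuinely different mechanisms —
a record-object pipeline, a line-quadruple state machine, and
whole-buffer splitting — that are required (and tested) to produce
byte-identical output. Method multiplicity is only meaningful under that
equivalence invariant.

External tools are integrated through a command-template contract:
templates like `samtools view -b -o {output} {input}` live in
configuration, not code, so deployments can swap equivalent backends.
A missing executable is an environment error (CLI exit code 3) and the
method is flagged in listings rather than silently failing. BAM exists
only through this contract; no native BGZF codec is attempted.

## The conversion graph and transitive mode

Formats are nodes, converters are edges; multi-port gates are hyperedges
drawn through anonymous junction nodes in the DOT export. Although such
graphs are often described as acyclic, ours (like any useful one)
contains 2-cycles — `fasta2fastq` and `fastq2fasta` both exist — so the
implementation permits cycles.

`find_path()` plans transitive conversions over single-input/
single-output edges only: chaining semantics through multi-port gates are
undefined, so hyperedges are excluded from search. Plans are minimum-hop;
ties are broken by the lexicographically smallest sequence of format
names, which makes planning deterministic across runs and platforms. Path
length is unrestricted. The planner is verified against exhaustive path
enumeration on a thousand small random graphs. A transitive plan is
flagged lossy when any step is lossy, and the CLI prints a loss warning
(e.g. qualities do not survive `fastq -> fasta -> faa`).

## Format dialects and numerical conventions

The public format specifications leave dialect choices open; ours are:

* **FASTQ** quality is always Sanger Phred+33 (scores 0–93); no
  autodetection of the legacy +64 offset, though the offset is an
  argument to `phred_decode()`.
* **FASTA** output wraps at 80 columns by default (`wrap` option; 0
  disables wrapping).
* **PHYLIP** is written strict sequential with 10-character padded names;
  both sequential and interleaved layouts are accepted on read. Name
  truncation collisions are an error listing the colliding identifiers,
  not a silent rename.
* **GFF3** attributes are split on `;`, keyed on the first `=`, and
  percent-decoded per the GFF3 specification.
* **SAM**: only the 11 mandatory columns are interpreted; optional tags
  are carried verbatim and dropped when exporting reads. Secondary
  (0x100) and supplementary (0x800) alignments are excluded from read
  exports so no read is duplicated; the reverse-strand bit (0x10)
  triggers reverse-complementing the sequence and reversing the quality,
  restoring the original read orientation.
* **BED** output has exactly 6 columns (chrom, start, end, name, score,
  strand) — the smallest layout carrying name/score/strand. Intervals are
  0-based half-open internally, always; GFF3 (1-based inclusive) and VCF
  (1-based, spanning the reference allele) are converted at the boundary.
* **fasta2fastq** has no quality to preserve, so it assigns a constant
  documented placeholder of Q40 (`I`) to every base. This is a
  deterministic choice, not an inference about any original tool's
  behaviour.

## Benchmarking

Single mode runs every runnable method of a converter N times (default
N = 5) on identical inputs and reports per-method mean, standard
deviation (n−1 denominator), minimum and maximum of wall time, CPU time
and peak memory. Multi mode repeats single mode M times (default M = 10;
M is a free parameter and 10 balances runtime against stability) and
keeps one median wall time per round per method, giving a distribution of
medians that is robust to interference from concurrent processes. Where
the terms "standard error" and "standard deviation" could both describe
the error bars, this package reports the standard deviation and labels it
as such.

Measurement details: wall time comes from R's monotonic elapsed clock;
CPU time is user + system including child processes, so external-tool
methods are charged fairly; memory is the peak R allocation during the
run, measured by resetting and re-reading the garbage collector's
"max used" statistics. This yields a single number per run that grows
monotonically with added allocations (verified with an allocating mock);
it reflects R-managed memory rather than the OS resident set, which is
the appropriate quantity for in-process converters. Multi mode runs
in-process and sequentially rather than through a workflow engine: the
statistics are the same and no external scheduler is required. TSV is the
canonical report format; the plot (bars with standard-deviation error
bars, or one box per method in multi mode) is derived output.

The benchmark harness itself is calibrated in the test suite with mock
methods performing busy-work of d and 3d seconds (d = 0.02 s): the
measured mean ratio must land in [2, 4] and multi-mode ordering must be
stable. The tolerance is wide because short busy-loops on a shared
machine fluctuate.

## Synthetic data

`generate_fixture()` produces every supported format deterministically
from a single integer seed, with the caller's RNG state preserved: random
A/C/G/T sequences for sequencing formats (quality scores uniform on
[0, 40], a realistic printable range), equal-length gapped rows for MSA
formats, random binary trees with branch lengths for tree formats, sorted
non-overlapping features for GFF3/VCF, and coordinate-sorted paired
forward/reverse reads for SAM. `benchmark_input()` scales the same
generators to ~10^2 (small), ~10^4 (medium) and ~10^6 (large) records.

These fixtures emulate structure, not biology: no error profiles,
coverage models, realistic allele frequencies or genome coordinates.
Tests passing on them demonstrate format correctness, conservation of
records, and convention handling — not robustness to the pathologies of
real instrument output (wrapped FASTQ, CRLF line endings, unusual
characters in identifiers), which are out of scope.

## Test sizes and quality gates

The quality gates run entirely on generated data: 200 seeded files for
the lossless split/merge round trip, 50 for cross-method byte identity,
100 per format for field-by-field agreement with independent reference
parsers (Biostrings, Rsamtools, rtracklayer, VariantAnnotation — used
only as test oracles, never in the conversion path), all nine
plain/gzip/bzip2 pairings for every applicable converter, and 1000 random
graphs for the path planner. These sizes give stable results while
keeping a full run in the low minutes. Statement coverage of the package
is measured with a small built-in tracker (`cov_start()` / `cov_report()`)
that rewrites function bodies to count executed statements; the suite
requires at least 90% over a workload that exercises every module,
including error paths.

## Known limitations

* Multi-line (wrapped) FASTQ is not parsed; four lines per record is
  assumed, as produced by all modern instruments and by this package.
* NEXUS support covers TREES blocks (with Translate tables); character
  matrices in NEXUS are out of scope.
* Transitive conversion cannot pass through multi-port gates.
* BAM requires an external samtools-compatible tool; there is no native
  binary codec.
* The memory measure reports R-heap peaks and will not see allocations
  made by external processes.
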