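# Deterministic synthetic-data generator: small per-converter example
# files for testing plus larger seeded inputs for benchmarking. A single
# integer seed fully determines each file's bytes; the caller's RNG state
# is never disturbed.

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""),
    character(1))
}

# quality scores uniform on [0, 40]: the realistic printable range
random_quals <- function(n, length) {
  lapply(seq_len(n), function(i) sample(0:40, length, replace = TRUE))
}

#' Generate a synthetic example file
#'
#' Writes a valid file of the requested format: random DNA over
#' \{A,C,G,T\} for sequence formats, equal-length gapped rows for MSA
#' formats, random binary trees serialised as Newick for tree formats,
#' sorted non-overlapping features for GFF3/VCF, and paired
#' forward/reverse reads for SAM. Identical arguments always produce a
#' byte-identical file.
#'
#' @param format Target format name (any parseable format, plus "bed").
#' @param path Output path; a `.gz`/`.bz2` suffix (or the `compression`
#'   argument) compresses the file.
#' @param n_records Number of records (sequences, features, trees...).
#' @param seq_length Sequence length for sequence/MSA formats; feature
#'   span scale for interval formats.
#' @param seed Integer seed driving the pseudorandom stream for this file.
#' @param compression `"none"`, `"gz"` or `"bz2"`; appended to `path` if
#'   the path does not already carry the suffix.
#' @return The path written, invisibly.
#' @export
generate_fixture <- function(format, path, n_records = 10L, seq_length = 50L,
                             seed = 1L, compression = c("none", "gz", "bz2")) {
  compression <- match.arg(compression)
  if (compression != "none" && is.na(codec_of(path)))
    path <- paste0(path, ".", compression)
  n <- as.integer(n_records); len <- as.integer(seq_length)
  with_preserved_seed(seed, {
    switch(format,
      fastq = {
        ids <- sprintf("read_%d", seq_len(n))
        seqs <- random_dna(n, len); quals <- random_quals(n, len)
        recs <- mapply(function(i, s, q) seq_record(i, s, quality = q),
                       ids, seqs, quals, SIMPLIFY = FALSE)
        write_records("fastq", recs, path)
      },
      fasta = ,
      faa = {
        ids <- sprintf("seq_%d", seq_len(n))
        seqs <- if (format == "faa")
          vapply(random_dna(n, 3L * len), translate_dna, character(1))
        else random_dna(n, len)
        recs <- mapply(seq_record, ids, seqs, SIMPLIFY = FALSE)
        write_records("fasta", recs, path)
      },
      qual = {
        ids <- sprintf("read_%d", seq_len(n))
        quals <- random_quals(n, len)
        recs <- mapply(function(i, q)
          structure(list(id = i, description = "", sequence = NA_character_,
                         quality = q), class = "seq_record"),
          ids, quals, SIMPLIFY = FALSE)
        write_records("qual", recs, path)
      },
      clustal = ,
      phylip = ,
      stockholm = {
        aln <- random_alignment(max(n, 1L), len)
        write_records(format, list(aln), path)
      },
      newick = ,
      nexus = {
        trees <- lapply(seq_len(max(n, 1L)), function(k)
          list(label = sprintf("TREE%d", k),
               newick = random_newick(max(3L, min(len, 12L)))))
        write_records(format, list(tree_document(trees)), path)
      },
      gff3 = {
        write_records("gff3", random_features(n, len), path)
      },
      vcf = {
        write_records("vcf", random_variants(n, len), path)
      },
      bed = {
        ivs <- lapply(random_features(n, len), gff3_to_interval)
        write_records("bed", ivs, path)
      },
      sam = {
        sam <- random_sam(n, len)
        write_records("sam", sam$records, path, options = list(headers = sam$headers))
      },
      bc_stop("bc_usage_error", sprintf("cannot generate fixtures for format '%s'", format))
    )
  })
  invisible(path)
}

random_alignment <- function(n, len) {
  ids <- sprintf("taxon_%d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T", "-"), len, replace = TRUE,
                 prob = c(0.22, 0.22, 0.22, 0.22, 0.12)), collapse = ""),
    character(1))
  msa_alignment(mapply(seq_record, ids, seqs, SIMPLIFY = FALSE))
}

# random binary tree over n leaves with branch lengths
random_newick <- function(n_leaves) {
  nodes <- sprintf("t%d", seq_len(n_leaves))
  while (length(nodes) > 1L) {
    pick <- sample(length(nodes), 2L)
    merged <- sprintf("(%s:%.3f,%s:%.3f)", nodes[pick[1]], stats::runif(1),
                      nodes[pick[2]], stats::runif(1))
    nodes <- c(nodes[-pick], merged)
  }
  paste0(nodes, ";")
}

# sorted, non-overlapping features on one contig
random_features <- function(n, span) {
  starts <- cumsum(sample(5:50, n, replace = TRUE) +
                   sample(seq_len(max(span, 2L)), n, replace = TRUE))
  widths <- sample(seq_len(max(span, 2L)), n, replace = TRUE)
  lapply(seq_len(n), function(k)
    structure(list(seqid = "chr1", source = "bioconvr", type = "gene",
                   start = as.integer(starts[k]),
                   end = as.integer(starts[k] + widths[k]),
                   score = ".", strand = sample(c("+", "-"), 1L), phase = ".",
                   attributes = list(ID = sprintf("g%d", k))),
              class = "gff3_feature"))
}

random_variants <- function(n, span) {
  pos <- sort(sample.int(max(1000L, n * max(span, 2L)), n))
  bases <- c("A", "C", "G", "T")
  lapply(seq_len(n), function(k) {
    ref_len <- sample(c(1L, 1L, 1L, 3L), 1L)  # mostly SNVs, some deletions
    ref <- paste(sample(bases, ref_len, replace = TRUE), collapse = "")
    alt <- sample(setdiff(bases, substring(ref, 1L, 1L)), 1L)
    structure(list(chrom = "chr1", pos = pos[k], id = sprintf("rs%d", k),
                   ref = ref, alt = alt,
                   qual = sprintf("%.1f", stats::runif(1, 10, 99)),
                   filter = "PASS", info = ".", extra = character()),
              class = "vcf_variant")
  })
}

# paired forward/reverse reads, coordinate-sorted, on one reference
random_sam <- function(n, len) {
  ref_len <- 100000L
  headers <- c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:ref1\tLN:%d", ref_len))
  pos <- sort(sample.int(ref_len - 2L * len - 200L, n))
  records <- lapply(seq_len(n), function(k) {
    fwd <- k %% 2L == 1L
    sam_record(sprintf("pair_%d", (k + 1L) %/% 2L),
               flag = if (fwd) 0L else 16L,
               rname = "ref1", pos = pos[k], mapq = 60L,
               cigar = sprintf("%dM", len), rnext = "*", pnext = 0L, tlen = 0L,
               seq = random_dna(1L, len),
               qual = phred_encode(sample(0:40, len, replace = TRUE)))
  })
  list(headers = headers, records = records)
}

#' Generate a benchmark-sized input file
#'
#' Size classes: small is about 10^2 records, medium about 10^4 and large
#' about 10^6 (each scalable through `scale`); generated locally so no
#' download is needed.
#'
#' @param format Format name supported by [generate_fixture()].
#' @param size_class `"small"`, `"medium"` or `"large"`.
#' @param seed Integer seed.
#' @param path Output path (default: a tempfile with the format's
#'   canonical extension).
#' @param scale Multiplier applied to the class's record count.
#' @return The path written, invisibly.
#' @export
benchmark_input <- function(format, size_class = c("small", "medium", "large"),
                            seed = 1L, path = NULL, scale = 1) {
  size_class <- match.arg(size_class)
  n <- switch(size_class, small = 100L, medium = 10000L, large = 1000000L)
  n <- max(1L, as.integer(n * scale))
  if (is.null(path))
    path <- tempfile(fileext = default_extension(format))
  generate_fixture(format, path, n_records = n, seq_length = 100L, seed = seed)
  invisible(path)
}

#' Write a manifest for a set of fixtures
#'
#' @param paths Character vector of fixture paths.
#' @param formats Character vector of their formats.
#' @param n_records,seeds Integer vectors parallel to `paths`.
#' @param sink TSV path to write.
#' @return The manifest data.frame, invisibly.
#' @export
fixture_manifest <- function(paths, formats, n_records, seeds, sink) {
  manifest <- data.frame(path = paths, format = formats,
                         n_records = as.integer(n_records),
                         seed = as.integer(seeds),
                         checksum = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, sink, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
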