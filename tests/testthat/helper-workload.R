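# A compact functional walk through every module, used to measure
# statement coverage under instrumentation. It exercises both the happy
# paths and the documented error paths of the public surface; assertions
# about behaviour live in the per-module test files, so this walk only
# needs to execute, not verify.

swallow <- function(expr) {
  tryCatch(suppressWarnings(suppressMessages(expr)),
           error = function(e) invisible(NULL))
}

workload_registry <- function() {
  reg <- new_registry()
  register_format(reg, format_descriptor("fastq", c(".fastq", ".fq"), "sequencing"))
  swallow(register_format(reg, format_descriptor("fastq", ".z9", "sequencing")))
  swallow(register_format(reg, format_descriptor("dup", ".fq", "other")))
  swallow(format_descriptor("BAD", ".x", "other"))
  swallow(format_descriptor("bad", character(), "other"))
  swallow(format_descriptor("bad", "nodot", "other"))
  lookup_format(reg, "fastq"); lookup_format(reg, ".fq"); lookup_format(reg, ".nope")
  print(reg)

  r <- default_registry()
  infer_format("a.fastq", r); infer_format("a.fq.gz", r)
  swallow(infer_format("a.xyz", r))
  resolve_conversion("a.fastq", "a.fasta", r)
  resolve_conversion("r.fastq", c("r.fasta", "r.qual"), r)
  swallow(resolve_conversion("a.newick", "a.bed", r))
  swallow(resolve_conversion("a.fastq", "a.faa", r))  # hint path branch

  swallow(discover_converters(list(list(name = "a2b"))))
  swallow(discover_converters(list(list(name = "nozero"))))
  swallow(discover_converters(list(list(
    name = "a2b", default = "no", method_x = function(i, o, opts) NULL))))
  swallow(discover_converters(list(list(method_x = function(i, o, opts) NULL))))
  spec <- discover_converters(list(list(name = "a2b", lossy = TRUE,
                                        method_x = function(i, o, opts)
                                          list(records_in = 0L, records_out = 0L))))[[1]]
  print(spec)
  reg2 <- new_registry()
  swallow(register_converter(reg2, spec))
  register_format(reg2, format_descriptor("a", ".qa1", "other"))
  register_format(reg2, format_descriptor("b", ".qb1", "other"))
  register_converter(reg2, spec)
  register_converter(reg2, spec)  # re-register identical: allowed
  swallow(register_converter(reg2, discover_converters(list(list(
    name = "a2b", method_y = function(i, o, opts) NULL)))[[1]]))

  print(find_path("fastq", "faa", r))
  print(find_path("fastq", "fastq", r))
  swallow(find_path("newick", "bed", r))
  swallow(find_path("nosuch", "bed", r))

  export_graph(r, tempfile(fileext = ".dot"))
  export_graph(r, tempfile(fileext = ".dot"), annotate = TRUE)
  export_graph(new_registry(), tempfile(fileext = ".dot"))
  registry_formats_tsv(r); registry_conversions_tsv(r)
  invisible(NULL)
}

workload_formats <- function() {
  td <- tempfile("wl"); dir.create(td)
  pth <- function(x) file.path(td, x)

  grid <- c("fastq", "fasta", "qual", "faa", "clustal", "phylip", "stockholm",
            "newick", "nexus", "gff3", "vcf", "sam", "bed")
  for (fmt in grid)
    generate_fixture(fmt, pth(paste0("g.", fmt)), n_records = 5,
                     seq_length = 30, seed = 11)
  generate_fixture("fastq", pth("g0.fastq"), n_records = 0, seed = 1)
  generate_fixture("fastq", pth("gz.fastq"), n_records = 3, seed = 1,
                   compression = "gz")
  generate_fixture("fasta", pth("bz.fasta.bz2"), n_records = 3, seed = 1,
                   compression = "bz2")
  swallow(generate_fixture("nosuch", pth("x")))
  benchmark_input("fastq", "small", seed = 1, path = pth("bench.fastq"),
                  scale = 0.1)
  fixture_manifest(pth(c("g.fastq", "g.vcf")), c("fastq", "vcf"),
                   c(5, 5), c(11, 11), pth("manifest.tsv"))

  for (fmt in setdiff(grid, c("bed", "faa"))) {
    recs <- parse_records(fmt, pth(paste0("g.", fmt)))
    write_records(fmt, recs, pth(paste0("rt.", fmt)),
                  options = list(headers = attr(recs, "metadata")))
  }
  parse_records("fasta", pth("g.faa"))
  parse_records("fastq", pth("gz.fastq.gz"))
  parse_records("fasta", pth("bz.fasta.bz2"))
  swallow(parse_records("nosuchformat", pth("g.fastq")))
  swallow(write_records("nosuchformat", list(), pth("x")))

  # writer options and degenerate inputs
  recs <- make_seq_records(3, 25, 5, with_qual = TRUE)
  write_records("fasta", recs, pth("w0.fasta"), options = list(wrap = 0))
  write_records("fasta", recs, pth("w7.fasta"), options = list(wrap = 7))
  swallow(write_records("fastq", list(seq_record("x", "ACGT")), pth("e.fastq")))
  swallow(write_records("qual", list(seq_record("x", "ACGT")), pth("e.qual")))
  one <- msa_alignment(list(seq_record("solo", "AC-GT")))
  for (fmt in c("clustal", "phylip", "stockholm"))
    write_records(fmt, list(one), pth(paste0("one.", fmt)))
  swallow(write_records("phylip",
    list(msa_alignment(list(seq_record("sequence_long_1", "AC"),
                            seq_record("sequence_long_2", "GT")))), pth("c.phy")))
  swallow(write_records("clustal", list(seq_record("a", "AC"),
                                        seq_record("b", "ACGT")), pth("r.aln")))
  swallow(write_records("newick", list("not a tree"), pth("t.nwk")))

  # parser error branches
  bad <- function(lines, fmt, ext) {
    f <- pth(paste0("bad", abs(sum(utf8ToInt(paste(lines, collapse = "")))), ext))
    writeLines(lines, f)
    swallow(parse_records(fmt, f))
  }
  bad(c("@r", "ACGT", "+", "!!"), "fastq", ".fastq")
  bad(c("@r", "ACGT", "x", "!!!I"), "fastq", ".fastq")
  bad(c("xr", "ACGT", "+", "!!!I"), "fastq", ".fastq")
  bad(c("@r", "ACGT", "+"), "fastq", ".fastq")
  bad("ACGT", "fasta", ".fasta")
  bad(c(">q", "1 2 x"), "qual", ".qual")
  bad("no header", "clustal", ".aln")
  bad(c("CLUSTAL W", "", "onlyname"), "clustal", ".aln")
  bad(c("CLUSTAL W", ""), "clustal", ".aln")
  bad("bad header", "phylip", ".phy")
  bad(c(" 2 4", "a ACGT"), "phylip", ".phy")
  bad("", "phylip", ".phy")
  bad("no stockholm", "stockholm", ".sto")
  bad(c("# STOCKHOLM 1.0", "//"), "stockholm", ".sto")
  bad("", "newick", ".nwk")
  bad("((a,b);", "newick", ".nwk")
  bad("(a,b)", "newick", ".nwk")
  bad("not nexus", "nexus", ".nexus")
  bad(c("#NEXUS", "BEGIN CHARACTERS;", "END;"), "nexus", ".nexus")
  bad(c("#NEXUS", "BEGIN TREES;", "END;"), "nexus", ".nexus")
  bad("chr1\tonly\tthree", "gff3", ".gff3")
  bad("chr1\tsrc\tgene\tx\ty\t.\t+\t.\tID=g", "gff3", ".gff3")
  bad("chr1\tshort", "vcf", ".vcf")
  bad("chr1\tx\tid\tA\tT\t.\t.\t.", "vcf", ".vcf")
  bad("read\tonly", "sam", ".sam")
  bad("read\tx\tref\t1\t60\t4M\t*\t0\t0\tACGT\t!!!I", "sam", ".sam")
  bad("read\t0\tref\t1\t60\t4M\t*\t0\t0\tACGT\t!!", "sam", ".sam")

  # NEXUS with translate + rooting comment
  writeLines(c("#NEXUS", "BEGIN TREES;", "  TRANSLATE", "    1 a,", "    2 b;",
               "  TREE t1 = [&U] (1,2);", "END;"), pth("tr.nexus"))
  parse_records("nexus", pth("tr.nexus"))

  # transforms
  reverse_complement(c("AACG", "acgtn", "XQ"))
  phred_decode("!I~"); phred_encode(c(0L, 40L, 93L))
  swallow(phred_decode(" ", offset = 64))
  swallow(phred_encode(200L))
  sam_to_seqrecord(sam_record("r", 0, "ref", 1, 60, "4M", "*", 0, 0, "ACGT", "!!!I"))
  sam_to_seqrecord(sam_record("r", 16, "ref", 1, 60, "4M", "*", 0, 0, "ACGT", "*"))
  sam_to_seqrecord(sam_record("r", 256, "ref", 1, 60, "4M", "*", 0, 0, "ACGT", "!!!I"))
  sam_to_seqrecord(sam_record("r", 4, "*", 0, 0, "*", "*", 0, 0, "*", "*"))
  feat <- parse_records("gff3", pth("g.gff3"))[[1]]
  gff3_to_interval(feat)
  feat$strand <- "?"; feat$attributes <- list(); gff3_to_interval(feat)
  feat$start <- 0L; swallow(gff3_to_interval(feat))
  feat$start <- 9L; feat$end <- 3L; swallow(gff3_to_interval(feat))
  variant_to_interval(parse_records("vcf", pth("g.vcf"))[[1]])
  translate_dna("ATGGCCTGANNNAT"); translate_dna("AT")

  # record constructors and their guards
  print(seq_record("ok", "ACGT", quality = c(1L, 2L, 3L, 4L)))
  swallow(seq_record("bad id", "ACGT"))
  swallow(seq_record("x", "ACGT", quality = 1:3))
  swallow(seq_record("x", "ACGT", quality = c(1L, 2L, 3L, 99L)))
  swallow(msa_alignment(list()))
  swallow(tree_document(list()))
  swallow(genomic_interval("c", -1, 5))
  swallow(genomic_interval("c", 5, 5))
  swallow(genomic_interval("c", 1, 5, strand = "x"))
  swallow(sam_record("r", -1, "ref", 1, 60, "4M", "*", 0, 0, "ACGT", "!!!I"))
  swallow(sam_record("r", 0, "ref", 1, 60, "4M", "*", 0, 0, "ACGT", "!!"))

  # compression module
  con <- open_auto(pth("g.fastq"), "read"); close(con)
  for (ext in c(".txt", ".txt.gz", ".txt.bz2")) {
    f <- pth(paste0("codec", ext))
    con <- open_auto(f, "write"); writeLines("hello", con); close(con)
    con <- open_auto(f, "read"); readLines(con); close(con)
  }
  fake <- pth("fake.gz"); writeLines("plain", fake)
  swallow(open_auto(fake, "read"))
  fake2 <- pth("fake.bz2"); writeLines("plain", fake2)
  swallow(open_auto(fake2, "read"))
  swallow(open_auto(pth("absent.fq"), "read"))
  codec_of("x.gz"); codec_of("x")
  invisible(td)
}

workload_converters <- function(td) {
  pth <- function(x) file.path(td, x)
  r <- default_registry()
  src_for <- list(fastq = "g.fastq", fasta = "g.fasta", qual = "g.qual",
                  clustal = "g.clustal", phylip = "g.phylip",
                  stockholm = "g.stockholm", newick = "g.newick",
                  nexus = "g.nexus", gff3 = "g.gff3", vcf = "g.vcf",
                  sam = "g.sam")
  for (spec in r$converters) {
    if (any(!spec$inputs %in% names(src_for))) next
    ins <- pth(unlist(src_for[spec$inputs]))
    outs <- vapply(seq_along(spec$outputs), function(k)
      tempfile(fileext = paste0(".", spec$outputs[k])), character(1))
    for (m in spec$methods) {
      if (spec$name == "sam2bam" && Sys.which("samtools") == "") next
      swallow(print(convert(spec, ins, outs, method = m, registry = r)))
    }
  }
  swallow(convert("fastq2fasta", pth("g.fastq"), tempfile(), method = "nosuch"))
  swallow(convert("nosuch2conv", pth("g.fastq"), tempfile()))
  swallow(convert("fastq2fasta", c("a", "b"), "c"))
  swallow(fastq_gate(pth("g.fastq"), character()))
  swallow(fastq_gate(pth("g.fastq"),
                     c(tempfile(fileext = ".fasta"), tempfile(fileext = ".qual"))))
  swallow(fastq_gate(pth("g.fastq"), tempfile(fileext = ".qual")))

  # pairing failures
  fa <- tempfile(fileext = ".fasta"); qu <- tempfile(fileext = ".qual")
  writeLines(c(">a", "ACGT", ">b", "GG"), fa)
  writeLines(c(">b", "1 2", ">a", "1 2 3 4"), qu)
  swallow(convert("fasta_qual2fastq", c(fa, qu), tempfile(fileext = ".fastq")))
  writeLines(c(">a", "1 2 3"), qu)
  swallow(convert("fasta_qual2fastq", c(fa, qu), tempfile(fileext = ".fastq")))
  writeLines(c(">a", "1 2 3 4", ">b", "1 2"), qu)
  convert("fasta_qual2fastq", c(fa, qu), tempfile(fileext = ".fastq"))

  # malformed inputs through each fastq2fasta mechanism
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r", "ACGT", "+", "!!"), bad)
  for (m in c("records", "linewise", "buffer"))
    swallow(convert("fastq2fasta", bad, tempfile(), method = m))
  writeLines(c("@r", "ACGT", "+"), bad)
  for (m in c("records", "linewise", "buffer"))
    swallow(convert("fastq2fasta", bad, tempfile(), method = m))

  empty <- tempfile(fileext = ".fastq"); writeLines(character(), empty)
  for (m in c("records", "linewise", "buffer"))
    swallow(convert("fastq2fasta", empty, tempfile(fileext = ".fasta"), method = m))

  if (Sys.which("samtools") != "") {
    badsam <- tempfile(fileext = ".sam"); writeLines("garbage", badsam)
    swallow(convert("sam2bam", badsam, tempfile(fileext = ".bam")))
  }
  swallow(convert("sam2bam", pth("g.sam"), tempfile(fileext = ".bam"),
                  options = list(config = list(
                    external_binary = list(sam2bam = "no_such_binary_xyz")))))
  swallow(bioconvr:::run_external_template("nosuchspec", "a", "b"))
  invisible(NULL)
}

workload_benchmark <- function() {
  mock <- make_mock_spec(d = 0.001)
  inp <- tempfile(); writeLines("x", inp)
  s <- run_single(mock$spec, inp, benchmark_config(repeats = 2))
  print(s)
  benchmark_report(s, tempfile(fileext = ".tsv"), as_image = TRUE,
                   image_path = tempfile(fileext = ".png"))
  m <- run_multi(mock$spec, inp, benchmark_config(repeats = 2, multi_rounds = 2))
  print(m)
  benchmark_report(m, tempfile(fileext = ".tsv"), as_image = TRUE,
                   image_path = tempfile(fileext = ".png"))
  run_single(mock$spec, inp, benchmark_config(repeats = 1, include_methods = "fast"))
  swallow(run_single(mock$spec, inp, benchmark_config(include_methods = "zz")))
  swallow(benchmark_config(repeats = 0))
  swallow(benchmark_config(multi_rounds = 0))
  failing <- discover_converters(list(list(
    name = "mocka2mockb",
    external = c(gone = "no_such_binary_xyz"),
    method_ok = function(i, o, opts) { file.create(o); list(records_in = 1L, records_out = 1L) },
    method_bad = function(i, o, opts) bioconvr:::bc_stop("bc_parse_error", "boom"),
    method_gone = function(i, o, opts) NULL)))[[1]]
  print(run_single(failing, inp, benchmark_config(repeats = 1)))
  run_multi(failing, inp, benchmark_config(repeats = 1, multi_rounds = 1))
  run_single("fastq2fasta",
             { f <- tempfile(fileext = ".fastq")
               generate_fixture("fastq", f, 3, 20, seed = 2); f },
             benchmark_config(repeats = 1))
  invisible(NULL)
}

workload_cli <- function(td) {
  pth <- function(x) file.path(td, x)
  quiet <- function(argv) swallow(capture.output(main(argv)))
  quiet(c(pth("g.fastq"), tempfile(fileext = ".fasta")))
  quiet(c("fastq2fasta", pth("g.fastq"), tempfile(fileext = ".fasta")))
  quiet(c("-m", "buffer", pth("g.fastq"), tempfile(fileext = ".fasta")))
  quiet(c("-m", "nosuch", pth("g.fastq"), tempfile(fileext = ".fasta")))
  quiet(c(pth("g.fastq"), tempfile(fileext = ".fasta"), tempfile(fileext = ".qual")))
  quiet(c("-a", pth("g.fastq"), tempfile(fileext = ".faa")))
  quiet(c(pth("g.fastq"), tempfile(fileext = ".faa")))
  quiet(c(pth("g.fastq"), tempfile(fileext = ".newick")))
  quiet(c("badmode.xyz", "out.fasta"))
  quiet(c("fastq2fasta"))
  quiet(c("fastq2fasta_qual", pth("g.fastq")))
  quiet(character())
  quiet("one.fastq")
  quiet("--list"); quiet("--list-formats")
  quiet(c("--show-methods", "fastq2fasta"))
  quiet(c("--show-methods", "sam2bam"))
  quiet(c("--show-methods", "nope"))
  quiet(c("--graph", tempfile(fileext = ".dot")))
  quiet(c("-b", "-N", "1", "-I", pth("g.fastq"), tempfile(fileext = ".fasta")))
  quiet(c("-v", pth("g.fastq"), tempfile(fileext = ".fasta")))

  exists_out <- tempfile(fileext = ".fasta"); writeLines("x", exists_out)
  quiet(c(pth("g.fastq"), exists_out))
  quiet(c("-f", pth("g.fastq"), exists_out))

  cfg <- tempfile(fileext = ".toml")
  writeLines(c("# comment", "top = 1", "[default_methods]",
               'fastq2fasta = "buffer"', "[external_binary]",
               'sam2bam = "no_such_binary_xyz"'), cfg)
  quiet(c("-c", cfg, pth("g.fastq"), tempfile(fileext = ".fasta")))
  quiet(c("-c", cfg, pth("g.sam"), tempfile(fileext = ".bam")))
  quiet(c("-c", tempfile(), pth("g.fastq"), tempfile(fileext = ".fasta")))
  badcfg <- tempfile(); writeLines("no equals", badcfg)
  quiet(c("-c", badcfg, pth("g.fastq"), tempfile(fileext = ".fasta")))

  badfq <- tempfile(fileext = ".fastq")
  writeLines(c("@r", "ACGT", "+", "!!"), badfq)
  quiet(c(badfq, tempfile(fileext = ".fasta")))
  quiet(c("--keep-intermediates", "-a", badfq, tempfile(fileext = ".faa")))
  quiet(c("--badoption"))

  if (Sys.which("samtools") != "") {
    dir <- tempfile("cliw"); dir.create(dir)
    old <- setwd(dir); on.exit(setwd(old))
    generate_fixture("sam", "t.sam", n_records = 2, seq_length = 10, seed = 1)
    quiet(c("sam2bam", "t.sam"))
  }
  invisible(NULL)
}

workload_corners <- function(td) {
  pth <- function(x) file.path(td, x)
  # interleaved PHYLIP
  inter <- pth("inter.phy")
  writeLines(c(" 2 8", "tax_a     ACGT", "tax_b     TGCA", "", "GGGG", "CCCC"), inter)
  parse_records("phylip", inter)
  # sequential PHYLIP with wrapped sequence lines
  seqw <- pth("seqw.phy")
  writeLines(c(" 2 8", "tax_a     ACGT", "GGGG", "tax_b     TGCAGGGG"), seqw)
  parse_records("phylip", seqw)
  # translate table applied on newick output
  convert("nexus2newick", pth("tr.nexus"), tempfile(fileext = ".nwk"))
  # GFF3 attribute corners: empty, valueless flag, encoded characters
  gf <- pth("attrs.gff3")
  writeLines(c("chr1\ts\tg\t1\t5\t.\t+\t.\t.",
               "chr1\ts\tg\t6\t9\t.\t-\t.\tflagonly;ID=g2;Note=a%3Bb"), gf)
  feats <- parse_records("gff3", gf)
  write_records("gff3", feats, tempfile(fileext = ".gff3"))
  lapply(feats, gff3_to_interval)
  # parsing from an already-open connection
  con <- file(pth("g.fasta"), "rt")
  parse_records("fasta", con)
  close(con)
  con <- file(tempfile(fileext = ".bed"), "wt")
  write_records("bed", list(genomic_interval("c", 0, 5)), con)
  close(con)
  # stockholm annotation lines
  sto <- pth("anno.sto")
  writeLines(c("# STOCKHOLM 1.0", "#=GF ID demo", "tax_a  ACGT", "//"), sto)
  parse_records("stockholm", sto)
  swallow(check_newick(42))
  swallow(variant_to_interval(structure(list(chrom = "c", pos = NA_integer_,
                                             id = ".", ref = "A", qual = "."),
                                        class = "vcf_variant")))
  phred_decode(""); phred_encode(integer())
  bioconvr:::msa_records(list(seq_record("a", "AC")))
  swallow(bioconvr:::as_tree_document(list("neither")))
  swallow(bioconvr:::as_alignment_input(msa_alignment(list(seq_record("a", "AC")))))
  # failed-method rows in a report
  failing <- discover_converters(list(list(
    name = "mocka2mockb",
    method_bad = function(i, o, opts) bioconvr:::bc_stop("bc_parse_error", "boom"))))[[1]]
  inp <- tempfile(); writeLines("x", inp)
  s <- run_single(failing, inp, benchmark_config(repeats = 1))
  benchmark_report(s, tempfile(fileext = ".tsv"))
  benchmark_input("fastq", "small", seed = 3, scale = 0.05)
  invisible(NULL)
}

run_coverage_workload <- function() {
  workload_registry()
  for (seed in 1:3) {
    g <- random_graph_registry(seed)
    from <- g$nodes[1]; to <- g$nodes[length(g$nodes)]
    swallow(find_path(from, to, g$registry))
  }
  td <- workload_formats()
  workload_converters(td)
  workload_benchmark()
  workload_cli(td)
  workload_corners(td)
  invisible(NULL)
}
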