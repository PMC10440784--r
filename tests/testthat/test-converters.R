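test_that("convert() runs the default method and reports counts", {
  fq <- tmpfile(".fastq")
  generate_fixture("fastq", fq, n_records = 5, seq_length = 30, seed = 1)
  fa <- tmpfile(".fasta")
  rep <- NULL
  expect_warning(rep <- convert("fastq2fasta", fq, fa), class = "bc_lossy_warning")
  expect_equal(rep$records_in, 5)
  expect_equal(rep$records_out, 5)
  expect_match(rep$lossy_warning, "quality")

  got <- parse_records("fasta", fa)
  src <- parse_records("fastq", fq)
  expect_equal(lapply(got, `[[`, "id"), lapply(src, `[[`, "id"))
  expect_equal(lapply(got, `[[`, "sequence"), lapply(src, `[[`, "sequence"))
  expect_true(all(vapply(got, function(r) is.null(r$quality), logical(1))))
})

test_that("convert() handles empty inputs and bad method names", {
  fq <- tmpfile(".fastq")
  writeLines(character(), fq)
  fa <- tmpfile(".fasta")
  rep <- suppressWarnings(convert("fastq2fasta", fq, fa))
  expect_equal(c(rep$records_in, rep$records_out), c(0, 0))
  expect_true(file.exists(fa))
  expect_length(parse_records("fasta", fa), 0)

  err <- expect_error(convert("fastq2fasta", fq, fa, method = "nosuch"),
                      class = "bc_unknown_method")
  expect_match(conditionMessage(err), "records")
  expect_error(convert("nosuchconv", fq, fa), class = "bc_no_converter")
  expect_error(convert("fastq2fasta", c(fq, fq), fa), class = "bc_usage_error")
})

test_that("all fastq2fasta methods produce byte-identical FASTA", {
  spec <- default_registry()$converters$fastq2fasta
  expect_gte(length(spec$methods), 3)
  for (seed in 1:10) {
    fq <- tmpfile(".fastq")
    generate_fixture("fastq", fq, n_records = 12, seq_length = 130, seed = seed)
    outs <- lapply(spec$methods, function(m) {
      fa <- tmpfile(".fasta")
      suppressWarnings(convert(spec, fq, fa, method = m))
      read_file_bytes(fa)
    })
    for (k in seq_along(outs)[-1])
      expect_identical(outs[[k]], outs[[1]],
                       label = sprintf("method %s, seed %d", spec$methods[k], seed))
  }
})

test_that("one-record FASTQ converts to one-record FASTA", {
  fq <- tmpfile(".fastq")
  generate_fixture("fastq", fq, n_records = 1, seq_length = 10, seed = 3)
  fa <- tmpfile(".fasta")
  rep <- suppressWarnings(convert("fastq2fasta", fq, fa))
  expect_equal(rep$records_out, 1)
  expect_length(parse_records("fasta", fa), 1)
})

test_that("the FastQ gate splits and fasta_qual2fastq merges losslessly", {
  for (seed in 1:5) {
    fq <- tmpfile(".fastq")
    generate_fixture("fastq", fq, n_records = 7, seq_length = 40, seed = seed)
    fa <- tmpfile(".fasta"); qu <- tmpfile(".qual")
    rep <- fastq_gate(fq, c(fa, qu))
    expect_equal(rep$spec_name, "fastq2fasta_qual")
    expect_equal(rep$records_out, 7)

    fq2 <- tmpfile(".fastq")
    convert("fasta_qual2fastq", c(fa, qu), fq2)
    expect_identical(read_file_bytes(fq2), read_file_bytes(fq))
  }
})

test_that("single-output gate calls are lossy and score-faithful", {
  fq <- tmpfile(".fastq")
  generate_fixture("fastq", fq, n_records = 4, seq_length = 25, seed = 11)
  fa <- tmpfile(".fasta")
  w <- expect_warning(fastq_gate(fq, fa), class = "bc_lossy_warning")
  expect_match(conditionMessage(w), "quality")

  qu <- tmpfile(".qual")
  suppressWarnings(fastq_gate(fq, qu))
  src <- parse_records("fastq", fq)
  got <- parse_records("qual", qu)
  for (k in seq_along(src))
    expect_equal(got[[k]]$quality, src[[k]]$quality)
  expect_error(fastq_gate(fq, character()), class = "bc_usage_error")
})

test_that("fasta_qual2fastq reports pairing problems by record", {
  fa <- tmpfile(".fasta"); qu <- tmpfile(".qual"); fq <- tmpfile(".fastq")
  writeLines(c(">a", "ACGT", ">b", "GGGG"), fa)
  writeLines(c(">b", "1 2 3 4", ">a", "5 6 7 8"), qu)
  err <- expect_error(convert("fasta_qual2fastq", c(fa, qu), fq),
                      class = "bc_pairing_error")
  expect_match(conditionMessage(err), "record 1")

  writeLines(c(">a", "1 2 3", ">b", "5 6 7 8"), qu)
  err <- expect_error(convert("fasta_qual2fastq", c(fa, qu), fq),
                      class = "bc_pairing_error")
  expect_match(conditionMessage(err), "4 quality|3 quality")

  writeLines(c(">a", "1 2 3 4"), qu)
  expect_error(convert("fasta_qual2fastq", c(fa, qu), fq),
               class = "bc_pairing_error")
})

test_that("MSA conversions preserve ids, sequences and gaps", {
  for (seed in 1:5) {
    cl <- tmpfile(".aln")
    generate_fixture("clustal", cl, n_records = 4, seq_length = 33, seed = seed)
    fa <- tmpfile(".fasta")
    convert("clustal2fasta", cl, fa)
    cl2 <- tmpfile(".aln")
    convert("fasta2clustal", fa, cl2)
    expect_equal(parse_records("clustal", cl2), parse_records("clustal", cl))
  }

  one <- msa_alignment(list(seq_record("solo", "AC-GT")))
  for (fmt in c("clustal", "phylip", "stockholm")) {
    f <- tmpfile(paste0(".", fmt))
    write_records(fmt, list(one), f)
    got <- parse_records(fmt, f)[[1]]
    expect_equal(got$records[[1]]$sequence, "AC-GT")
  }

  ragged <- tmpfile(".fasta")
  writeLines(c(">a", "ACGT", ">b", "AC"), ragged)
  expect_error(convert("fasta2stockholm", ragged, tmpfile(".sto")),
               class = "bc_alignment_error")
})

test_that("tree conversions round-trip and honour translate tables", {
  nw <- tmpfile(".nwk")
  writeLines("(a,(b,c));", nw)
  nx <- tmpfile(".nexus")
  convert("newick2nexus", nw, nx)
  expect_true(any(grepl("(a,(b,c));", readLines(nx), fixed = TRUE)))
  nw2 <- tmpfile(".nwk")
  convert("nexus2newick", nx, nw2)
  expect_equal(readLines(nw2), "(a,(b,c));")

  withtr <- tmpfile(".nexus")
  writeLines(c("#NEXUS", "BEGIN TREES;", "  TRANSLATE", "    1 a,", "    2 b;",
               "  TREE t1 = (1,2);", "END;"), withtr)
  nw3 <- tmpfile(".nwk")
  convert("nexus2newick", withtr, nw3)
  expect_equal(readLines(nw3), "(a,b);")

  empty <- tmpfile(".nwk")
  writeLines(character(), empty)
  expect_error(convert("newick2nexus", empty, tmpfile(".nexus")),
               class = "bc_parse_error")
  bad <- tmpfile(".nwk")
  writeLines("((a,b);", bad)
  expect_error(convert("newick2nexus", bad, tmpfile(".nexus")),
               class = "bc_parse_error")
})

test_that("interval conversions emit one ordered BED row per feature", {
  gf <- tmpfile(".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1"), gf)
  bed <- tmpfile(".bed")
  suppressWarnings(convert("gff32bed", gf, bed))
  expect_equal(readLines(bed), "chr1\t0\t100\tg1\t.\t+")

  vf <- tmpfile(".vcf")
  generate_fixture("vcf", vf, n_records = 3, seed = 4)
  bed2 <- tmpfile(".bed")
  rep <- suppressWarnings(convert("vcf2bed", vf, bed2))
  expect_equal(rep$records_out, 3)
  expect_length(readLines(bed2), 3)

  # counting oracle: rows out == non-header rows in
  for (seed in 1:5) {
    vf <- tmpfile(".vcf")
    generate_fixture("vcf", vf, n_records = 11, seed = seed)
    bedn <- tmpfile(".bed")
    suppressWarnings(convert("vcf2bed", vf, bedn))
    raw <- readLines(vf)
    expect_length(readLines(bedn), sum(!startsWith(raw, "#") & nzchar(raw)))
  }
})

test_that("SAM read extraction restores orientation and drops secondaries", {
  sf <- tmpfile(".sam")
  write_demo_sam(sf)
  fq <- tmpfile(".fastq")
  suppressWarnings(convert("sam2fastq", sf, fq))
  recs <- parse_records("fastq", fq)
  expect_equal(vapply(recs, `[[`, character(1), "id"), c("r_fwd", "r_rev"))
  expect_equal(recs[[1]]$sequence, "ACGT")
  expect_equal(recs[[2]]$sequence, reverse_complement("ACGT"))
  expect_equal(recs[[2]]$quality, rev(c(0L, 0L, 0L, 40L)))

  fa <- tmpfile(".fasta")
  suppressWarnings(convert("sam2fasta", sf, fa))
  expect_length(parse_records("fasta", fa), 2)
})

test_that("sam2bam shells out through the external-method contract", {
  skip_if(Sys.which("samtools") == "", "samtools not on PATH")
  sf <- tmpfile(".sam")
  generate_fixture("sam", sf, n_records = 6, seq_length = 20, seed = 9)
  bam <- tmpfile(".bam")
  rep <- convert("sam2bam", sf, bam)
  expect_true(file.exists(bam))
  expect_equal(rep$records_in, 6)

  # external-tool oracle: sam -> bam -> sam preserves the alignment lines
  back <- tmpfile(".sam")
  bioconvr:::run_external_template("bam2sam", bam, back)
  orig <- readLines(sf)
  got <- readLines(back)
  expect_equal(got[!startsWith(got, "@")], orig[!startsWith(orig, "@")])
})

test_that("external failures carry stderr and missing binaries are environment errors", {
  sf <- tmpfile(".sam")
  generate_fixture("sam", sf, n_records = 2, seq_length = 10, seed = 2)
  expect_error(
    convert("sam2bam", sf, tmpfile(".bam"),
            options = list(config = list(external_binary = list(sam2bam = "no_such_binary_xyz")))),
    class = "bc_environment_error")
  skip_if(Sys.which("samtools") == "", "samtools not on PATH")
  bad <- tmpfile(".sam")
  writeLines("this is not sam", bad)
  expect_error(convert("sam2bam", bad, tmpfile(".bam")),
               class = "bc_external_tool_error")
})

test_that("a direct edge and a lossless 2-hop path agree record-for-record", {
  cl <- tmpfile(".aln")
  generate_fixture("clustal", cl, n_records = 5, seq_length = 40, seed = 21)
  direct <- tmpfile(".phy")
  suppressWarnings(convert("clustal2phylip", cl, direct))

  mid <- tmpfile(".fasta"); hop <- tmpfile(".phy")
  convert("clustal2fasta", cl, mid)
  suppressWarnings(convert("fasta2phylip", mid, hop))
  expect_equal(parse_records("phylip", hop), parse_records("phylip", direct))
})

test_that("fasta2fastq assigns the documented constant quality", {
  fa <- tmpfile(".fasta")
  generate_fixture("fasta", fa, n_records = 3, seq_length = 15, seed = 5)
  fq <- tmpfile(".fastq")
  convert("fasta2fastq", fa, fq)
  recs <- parse_records("fastq", fq)
  for (r in recs) expect_true(all(r$quality == 40L))
})

test_that("fasta2faa translates in frame 1 with the standard code", {
  expect_equal(translate_dna("ATGGCCTGA"), "MA*")
  expect_equal(translate_dna("atggcc"), "MA")
  expect_equal(translate_dna("ATGNCC"), "MX")
  expect_equal(translate_dna("AT"), "")
  fa <- tmpfile(".fasta")
  writeLines(c(">s", "ATGGCC"), fa)
  faa <- tmpfile(".faa")
  suppressWarnings(convert("fasta2faa", fa, faa))
  expect_equal(parse_records("fasta", faa)[[1]]$sequence, "MA")
})
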