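test_that("FASTQ parsing follows the four-line Phred+33 contract", {
  f <- tmpfile(".fastq")
  writeLines(c("@r1", "ACGT", "+", "!!!I"), f)
  recs <- parse_records("fastq", f)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$id, "r1")
  expect_equal(recs[[1]]$sequence, "ACGT")
  expect_equal(recs[[1]]$quality, c(0L, 0L, 0L, 40L))

  writeLines(c("@r1", "ACGT", "+", "!!!"), f)
  err <- expect_error(parse_records("fastq", f), class = "bc_parse_error")
  expect_equal(err$line, 4L)

  writeLines(c("@r1", "ACGT", "ACGT", "!!!I"), f)
  expect_error(parse_records("fastq", f), class = "bc_parse_error")

  writeLines(character(), f)
  expect_length(parse_records("fastq", f), 0)
})

test_that("PHYLIP parsing accepts sequential and interleaved layouts", {
  f <- tmpfile(".phy")
  writeLines(c(" 2 4", "seq_a     ACGT", "seq_b     TGCA"), f)
  aln <- parse_records("phylip", f)[[1]]
  expect_s3_class(aln, "msa_alignment")
  expect_length(aln$records, 2)
  expect_equal(aln$records[[1]]$sequence, "ACGT")
  expect_equal(aln$records[[2]]$id, "seq_b")

  # interleaved: two blocks of two taxa
  writeLines(c(" 2 8", "seq_a     ACGT", "seq_b     TGCA", "", "GGGG", "CCCC"), f)
  aln2 <- parse_records("phylip", f)[[1]]
  expect_equal(aln2$records[[1]]$sequence, "ACGTGGGG")
  expect_equal(aln2$records[[2]]$sequence, "TGCACCCC")

  writeLines(c("notanumber x", "seq_a ACGT"), f)
  expect_error(parse_records("phylip", f), class = "bc_parse_error")
})

test_that("round-trip parse(write(x)) preserves records across formats", {
  for (seed in 1:10) {
    # FASTQ and FASTA (several wrap widths)
    recs <- make_seq_records(5, 37, seed, with_qual = TRUE)
    f <- tmpfile(".fastq")
    expect_equal(write_records("fastq", recs, f), 5)
    expect_equal(parse_records("fastq", f), recs)

    for (wrap in c(0L, 10L, 80L)) {
      fa <- tmpfile(".fasta")
      plain <- lapply(recs, function(r) seq_record(r$id, r$sequence,
                                                   description = r$description))
      write_records("fasta", plain, fa, options = list(wrap = wrap))
      expect_equal(parse_records("fasta", fa), plain)
    }

    qf <- tmpfile(".qual")
    write_records("qual", recs, qf)
    back <- parse_records("qual", qf)
    expect_equal(lapply(back, `[[`, "quality"), lapply(recs, `[[`, "quality"))
    expect_equal(lapply(back, `[[`, "id"), lapply(recs, `[[`, "id"))

    # MSA formats
    aln <- make_alignment(4, 24, seed)
    for (fmt in c("clustal", "phylip", "stockholm")) {
      mf <- tmpfile(paste0(".", fmt))
      write_records(fmt, list(aln), mf)
      got <- parse_records(fmt, mf)[[1]]
      expect_equal(lapply(got$records, `[[`, "sequence"),
                   lapply(aln$records, `[[`, "sequence"),
                   label = sprintf("%s seed %d", fmt, seed))
      expect_equal(lapply(got$records, `[[`, "id"),
                   lapply(aln$records, `[[`, "id"))
    }
  }
})

test_that("tree, feature and alignment fixtures round-trip", {
  for (seed in 1:5) {
    nw <- tmpfile(".nwk")
    generate_fixture("newick", nw, n_records = 3, seq_length = 6, seed = seed)
    doc <- parse_records("newick", nw)[[1]]
    nx <- tmpfile(".nexus")
    write_records("nexus", list(doc), nx)
    doc2 <- parse_records("nexus", nx)[[1]]
    expect_equal(lapply(doc2$trees, `[[`, "newick"),
                 lapply(doc$trees, `[[`, "newick"))

    gf <- tmpfile(".gff3")
    generate_fixture("gff3", gf, n_records = 8, seed = seed)
    feats <- parse_records("gff3", gf)
    gf2 <- tmpfile(".gff3")
    write_records("gff3", feats, gf2, options = list(headers = attr(feats, "metadata")))
    expect_equal(unclass(parse_records("gff3", gf2)), unclass(feats),
                 ignore_attr = TRUE)

    vf <- tmpfile(".vcf")
    generate_fixture("vcf", vf, n_records = 8, seed = seed)
    vars <- parse_records("vcf", vf)
    vf2 <- tmpfile(".vcf")
    write_records("vcf", vars, vf2, options = list(headers = attr(vars, "metadata")))
    expect_equal(readLines(vf2), readLines(vf))

    sf <- tmpfile(".sam")
    generate_fixture("sam", sf, n_records = 6, seed = seed)
    sams <- parse_records("sam", sf)
    sf2 <- tmpfile(".sam")
    write_records("sam", sams, sf2, options = list(headers = attr(sams, "metadata")))
    expect_equal(readLines(sf2), readLines(sf))
  }
})

test_that("PHYLIP writer truncates names and reports collisions", {
  aln <- msa_alignment(list(seq_record("sequence_long_1", "ACGT"),
                            seq_record("sequence_long_2", "TTTT")))
  expect_error(write_records("phylip", list(aln), tmpfile(".phy")),
               class = "bc_name_collision")
  err <- tryCatch(write_records("phylip", list(aln), tmpfile(".phy")),
                  bc_name_collision = function(e) e)
  expect_match(conditionMessage(err), "sequence_long_1")
  expect_match(conditionMessage(err), "sequence_long_2")
})

test_that("MSA writers reject ragged alignments", {
  ragged <- list(seq_record("a", "ACGT"), seq_record("b", "AC"))
  expect_error(write_records("clustal", ragged, tmpfile(".aln")),
               class = "bc_alignment_error")
  expect_error(msa_alignment(list(seq_record("a", "AC"), seq_record("a", "GT"))),
               class = "bc_alignment_error")
})

test_that("reverse_complement is an involution that preserves unknowns", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AACG"), "CGTT")
  expect_equal(reverse_complement("ANRX"), "XYNT")  # IUPAC R->Y, X preserved
  set.seed(99)
  for (i in 1:1000) {
    s <- paste(sample(c("A","C","G","T","N","R","Y","a","c","g","t"),
                      sample(1:30, 1), replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("phred encode/decode are mutually inverse over the printable range", {
  expect_equal(phred_decode("!"), 0L)
  expect_equal(phred_decode("I"), 40L)
  codes <- 0:93
  expect_equal(phred_decode(phred_encode(codes)), codes)
  expect_error(phred_decode(""), class = "bc_phred_error")
  expect_error(phred_encode(100L), class = "bc_phred_error")
  expect_equal(phred_decode(""), integer())
  expect_equal(phred_encode(integer()), "")
})

test_that("sam_to_seqrecord honours orientation and alignment-class bits", {
  fwd <- sam_record("r", 0, "ref", 1, 60, "4M", "*", 0, 0, "ACGT", "!!!I")
  got <- sam_to_seqrecord(fwd)
  expect_equal(got$sequence, "ACGT")
  expect_equal(got$quality, c(0L, 0L, 0L, 40L))

  rev <- sam_record("r", 16, "ref", 1, 60, "4M", "*", 0, 0, "AACG", "!!!I")
  got <- sam_to_seqrecord(rev)
  expect_equal(got$sequence, "CGTT")
  expect_equal(got$quality, c(40L, 0L, 0L, 0L))

  expect_null(sam_to_seqrecord(
    sam_record("r", 256, "ref", 1, 60, "4M", "*", 0, 0, "ACGT", "!!!I")))
  expect_null(sam_to_seqrecord(
    sam_record("r", 2048, "ref", 1, 60, "4M", "*", 0, 0, "ACGT", "!!!I")))
  expect_null(sam_to_seqrecord(
    sam_record("r", 4, "*", 0, 0, "*", "*", 0, 0, "*", "*")))
  no_qual <- sam_to_seqrecord(
    sam_record("r", 0, "ref", 1, 60, "4M", "*", 0, 0, "ACGT", "*"))
  expect_null(no_qual$quality)
})

test_that("gff3_to_interval shifts 1-based inclusive to 0-based half-open", {
  feat <- structure(list(seqid = "chr1", source = ".", type = "gene",
                         start = 1L, end = 100L, score = ".", strand = "+",
                         phase = ".", attributes = list(ID = "g1")),
                    class = "gff3_feature")
  iv <- gff3_to_interval(feat)
  expect_equal(iv$start, 0L); expect_equal(iv$end, 100L)
  expect_equal(iv$name, "g1"); expect_equal(iv$strand, "+")

  feat$start <- 5L; feat$end <- 5L
  iv <- gff3_to_interval(feat)
  expect_equal(iv$start, 4L); expect_equal(iv$end, 5L)

  feat$start <- 0L
  expect_error(gff3_to_interval(feat), class = "bc_coordinate_error")
  feat$start <- 10L; feat$end <- 9L
  expect_error(gff3_to_interval(feat), class = "bc_coordinate_error")
  feat$start <- 1L; feat$end <- 100L; feat$strand <- "?"
  expect_equal(gff3_to_interval(feat)$strand, ".")
  feat$attributes <- list()
  expect_equal(gff3_to_interval(feat)$name, ".")
})

test_that("variant_to_interval spans the reference allele", {
  v <- structure(list(chrom = "chr2", pos = 10L, id = "rs1", ref = "A",
                      alt = "T", qual = "50", filter = "PASS", info = ".",
                      extra = character()), class = "vcf_variant")
  iv <- variant_to_interval(v)
  expect_equal(c(iv$start, iv$end), c(9L, 10L))
  expect_equal(iv$name, "rs1")

  v$pos <- 5L; v$ref <- "ACG"
  iv <- variant_to_interval(v)
  expect_equal(c(iv$start, iv$end), c(4L, 7L))

  f <- tmpfile(".vcf")
  writeLines(c("##fileformat=VCFv4.2", "chr1\tx\trs1\tA\tT\t.\t.\t."), f)
  expect_error(parse_records("vcf", f), class = "bc_parse_error")
})

test_that("GFF3 attribute strings are split and percent-decoded", {
  f <- tmpfile(".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1;Note=a%3Bb%2Cc"), f)
  feats <- parse_records("gff3", f)
  expect_equal(feats[[1]]$attributes$ID, "g1")
  expect_equal(feats[[1]]$attributes$Note, "a;b,c")
  expect_equal(attr(feats, "metadata"), "##gff-version 3")
})

test_that("headers are exposed as metadata, not records", {
  sf <- tmpfile(".sam")
  write_demo_sam(sf)
  sams <- parse_records("sam", sf)
  expect_length(sams, 4)
  expect_equal(length(attr(sams, "metadata")), 2)
  expect_true(all(startsWith(attr(sams, "metadata"), "@")))
})

test_that("native parsers agree field-by-field with reference parsers", {
  skip_if_not_installed("Biostrings")
  for (seed in 1:10) {
    fa <- tmpfile(".fasta")
    generate_fixture("fasta", fa, n_records = 8, seq_length = 61, seed = seed)
    mine <- parse_records("fasta", fa)
    ref <- Biostrings::readBStringSet(fa)
    expect_equal(vapply(mine, `[[`, character(1), "id"), unname(names(ref)))
    expect_equal(vapply(mine, `[[`, character(1), "sequence"),
                 unname(as.character(ref)))

    fq <- tmpfile(".fastq")
    generate_fixture("fastq", fq, n_records = 8, seq_length = 43, seed = seed)
    mine <- parse_records("fastq", fq)
    ref <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fq))
    expect_equal(vapply(mine, `[[`, character(1), "sequence"),
                 unname(as.character(ref)))
    refq <- as(Biostrings::quality(ref), "IntegerList")
    for (k in seq_along(mine))
      expect_equal(mine[[k]]$quality, unname(refq[[k]]))
  }
})
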