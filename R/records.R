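# In-memory record types shared by parsers, writers and converters.
# They are deliberately plain lists with a class attribute: cheap to build
# in streaming loops, easy to compare field by field in tests.

#' Sequence record
#'
#' The lingua franca of sequencing conversions: an identifier, an optional
#' free-text description, a sequence, and optionally one integer Phred
#' quality score per base (Sanger scale, 0--93).
#'
#' @param id Record identifier; a non-empty token without whitespace.
#' @param sequence Character scalar; residues are not validated.
#' @param quality Optional integer vector of Phred scores, one per base.
#' @param description Free text following the id on the header line.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, sequence, quality = NULL, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("[[:space:]]", id))
    bc_stop("bc_record_error", "record id must be a non-empty token without whitespace")
  if (!is.null(quality)) {
    quality <- as.integer(quality)
    if (length(quality) != nchar(sequence))
      bc_stop("bc_record_error",
              sprintf("quality length (%d) != sequence length (%d) for record '%s'",
                      length(quality), nchar(sequence), id))
    if (any(quality < 0L | quality > 93L))
      bc_stop("bc_record_error",
              sprintf("quality scores outside printable Phred range [0, 93] for record '%s'", id))
  }
  structure(list(id = id, description = description,
                 sequence = sequence, quality = quality),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s: %d bp%s>\n", x$id, nchar(x$sequence),
              if (is.null(x$quality)) "" else ", with quality"))
  invisible(x)
}

#' Multiple sequence alignment
#'
#' An ordered set of equal-length gapped sequences with unique ids.
#'
#' @param records List of [seq_record()] objects (qualities ignored).
#' @param metadata Optional named list of per-format annotations.
#' @return An object of class `msa_alignment`.
#' @export
msa_alignment <- function(records, metadata = list()) {
  if (length(records) < 1L)
    bc_stop("bc_record_error", "an alignment needs at least one sequence")
  lens <- vapply(records, function(r) nchar(r$sequence), integer(1))
  if (length(unique(lens)) != 1L)
    bc_stop("bc_alignment_error",
            sprintf("aligned sequences must have equal length (found lengths %s)",
                    paste(unique(lens), collapse = ", ")))
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    bc_stop("bc_alignment_error",
            sprintf("duplicate sequence ids in alignment: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  structure(list(records = records, metadata = metadata), class = "msa_alignment")
}

#' Phylogenetic tree document
#'
#' One or more labelled Newick strings plus an optional translate table
#' (token -> taxon name) as used by NEXUS TREES blocks.
#'
#' @param trees List of `list(label =, newick =)` pairs.
#' @param translate Optional named character vector mapping tokens to names.
#' @return An object of class `tree_document`.
#' @export
tree_document <- function(trees, translate = NULL) {
  if (length(trees) < 1L)
    bc_stop("bc_record_error", "a tree document needs at least one tree")
  for (tr in trees) check_newick(tr$newick)
  structure(list(trees = trees, translate = translate), class = "tree_document")
}

check_newick <- function(s) {
  if (!is.character(s) || length(s) != 1L)
    bc_stop("bc_parse_error", "newick tree must be a single string")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0L)
    bc_stop("bc_parse_error", sprintf("unbalanced parentheses in newick string '%s'", s))
  if (!grepl(";[[:space:]]*$", s))
    bc_stop("bc_parse_error", sprintf("newick string must end with ';': '%s'", s))
  invisible(TRUE)
}

#' Genomic interval (BED convention)
#'
#' Coordinates are always 0-based half-open inside this type; conversion
#' from 1-based formats (GFF3, VCF) happens at construction time in
#' [gff3_to_interval()] and [variant_to_interval()].
#'
#' @param chrom Chromosome/contig token.
#' @param start 0-based start, `>= 0`.
#' @param end End (exclusive), `> start`.
#' @param name Feature name or ".".
#' @param score Numeric score or ".".
#' @param strand One of "+", "-", ".".
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, name = ".", score = ".", strand = ".") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || start < 0L)
    bc_stop("bc_coordinate_error", sprintf("interval start must be >= 0 (got %s)", start))
  if (is.na(end) || end <= start)
    bc_stop("bc_coordinate_error",
            sprintf("interval end (%s) must be > start (%s)", end, start))
  if (!strand %in% c("+", "-", "."))
    bc_stop("bc_coordinate_error", sprintf("invalid strand '%s'", strand))
  structure(list(chrom = chrom, start = start, end = end,
                 name = name, score = score, strand = strand),
            class = "genomic_interval")
}

#' SAM alignment record
#'
#' The 11 mandatory SAM columns, with optional tags carried verbatim.
#'
#' @param qname,flag,rname,pos,mapq,cigar,rnext,pnext,tlen,seq,qual The
#'   mandatory SAM fields, in column order.
#' @param tags Character vector of optional tag fields, kept verbatim.
#' @return An object of class `sam_record`.
#' @export
sam_record <- function(qname, flag, rname, pos, mapq, cigar,
                       rnext, pnext, tlen, seq, qual, tags = character()) {
  flag <- as.integer(flag)
  if (is.na(flag) || flag < 0L)
    bc_stop("bc_record_error", sprintf("SAM flag must be a non-negative integer (read '%s')", qname))
  if (seq != "*" && qual != "*" && nchar(seq) != nchar(qual))
    bc_stop("bc_record_error",
            sprintf("SEQ and QUAL lengths differ for read '%s' (%d vs %d)",
                    qname, nchar(seq), nchar(qual)))
  structure(list(qname = qname, flag = flag, rname = rname,
                 pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
                 rnext = rnext, pnext = as.integer(pnext), tlen = as.integer(tlen),
                 seq = seq, qual = qual, tags = tags),
            class = "sam_record")
}
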