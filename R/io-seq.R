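# Native streaming parsers/writers for the sequencing formats
# (FASTA, FASTQ, QUAL) plus the generic parse/write dispatch.

# Chunked line reader: calls fn(lines, first_line_number) until EOF.
# Keeps memory bounded by the chunk size rather than the file size.
stream_lines <- function(con, fn, chunk = 20000L) {
  line_no <- 1L
  repeat {
    lines <- readLines(con, n = chunk, warn = FALSE)
    if (length(lines) == 0L) break
    fn(lines, line_no)
    line_no <- line_no + length(lines)
    if (length(lines) < chunk) break
  }
  invisible(NULL)
}

#' Parse records from a file or connection
#'
#' One entry point for all supported text formats. Sequence formats yield
#' [seq_record()]s, alignment formats a single [msa_alignment()], tree
#' formats a single [tree_document()], GFF3/VCF yield feature/variant
#' rows convertible with [gff3_to_interval()] / [variant_to_interval()],
#' and SAM yields [sam_record()]s. Header and comment lines (`#` in
#' GFF3/VCF, `@` in SAM) are exposed via the `"metadata"` attribute of
#' the result, not as records. FASTQ, FASTA, GFF3, VCF and SAM are parsed
#' in bounded-memory chunks.
#'
#' @param format One of `"fastq"`, `"fasta"`, `"qual"`, `"clustal"`,
#'   `"phylip"`, `"stockholm"`, `"nexus"`, `"newick"`, `"gff3"`, `"vcf"`,
#'   `"sam"`.
#' @param source Filename (codec auto-detected from the extension) or an
#'   open text connection.
#' @return A list of records (possibly empty); attribute `"metadata"`
#'   holds format-level header lines where applicable.
#' @export
parse_records <- function(format, source) {
  parser <- switch(format,
    fastq = parse_fastq, fasta = parse_fasta, qual = parse_qual,
    clustal = parse_clustal, phylip = parse_phylip, stockholm = parse_stockholm,
    nexus = parse_nexus, newick = parse_newick,
    gff3 = parse_gff3, vcf = parse_vcf, sam = parse_sam,
    bc_stop("bc_usage_error", sprintf("no parser for format '%s'", format)))
  src <- as_input_con(source)
  if (src$close) on.exit(close(src$con), add = TRUE)
  parser(src$con)
}

#' Write records to a file or connection
#'
#' Inverse of [parse_records()]. Writers are deterministic: given fixed
#' options the output is byte-reproducible. FASTA wraps sequence lines at
#' `options$wrap` columns (default 80, 0 disables wrapping); FASTQ always
#' emits Phred+33; PHYLIP writes strict sequential layout with 10-character
#' padded names; Stockholm frames records with `# STOCKHOLM 1.0` and `//`;
#' NEXUS wraps trees in a TREES block; BED emits 6 tab-separated columns.
#'
#' @param format Target format name (as in [parse_records()], plus `"bed"`).
#' @param records Records of the type [parse_records()] yields for that
#'   format (for `"bed"`, a list of [genomic_interval()]).
#' @param sink Filename (codec auto-detected) or open text connection.
#' @param options Named list of per-format options (e.g. `wrap`).
#' @return The number of records written, invisibly.
#' @export
write_records <- function(format, records, sink, options = list()) {
  writer <- switch(format,
    fastq = write_fastq, fasta = write_fasta, qual = write_qual,
    clustal = write_clustal, phylip = write_phylip, stockholm = write_stockholm,
    nexus = write_nexus, newick = write_newick,
    bed = write_bed, gff3 = write_gff3, vcf = write_vcf, sam = write_sam,
    bc_stop("bc_usage_error", sprintf("no writer for format '%s'", format)))
  out <- as_output_con(sink)
  if (out$close) on.exit(close(out$con), add = TRUE)
  n <- writer(records, out$con, options)
  invisible(n)
}

## ---- FASTQ ----------------------------------------------------------------

# Streaming FASTQ reader: calls callback(list-of-seq_record) per chunk.
fastq_stream <- function(con, callback, chunk_records = 5000L) {
  line_no <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_records, warn = FALSE)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L)
      bc_parse_error("truncated FASTQ record (line count not a multiple of 4)",
                     line = line_no + length(lines), format = "fastq")
    idx <- seq(1L, length(lines), by = 4L)
    recs <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (!startsWith(lines[i], "@"))
        bc_parse_error("FASTQ header line must start with '@'",
                       line = line_no + i, format = "fastq")
      if (!startsWith(lines[i + 2L], "+"))
        bc_parse_error("FASTQ separator '+' line missing",
                       line = line_no + i + 2L, format = "fastq")
      if (nchar(lines[i + 1L]) != nchar(lines[i + 3L]))
        bc_parse_error(sprintf("quality length (%d) != sequence length (%d)",
                               nchar(lines[i + 3L]), nchar(lines[i + 1L])),
                       line = line_no + i + 3L, format = "fastq")
      hdr <- split_header(substring(lines[i], 2L))
      recs[[k]] <- seq_record(hdr$id, lines[i + 1L],
                              quality = phred_decode(lines[i + 3L]),
                              description = hdr$description)
    }
    callback(recs)
    line_no <- line_no + length(lines)
    if (length(lines) < 4L * chunk_records) break
  }
  invisible(NULL)
}

parse_fastq <- function(con) {
  out <- list()
  fastq_stream(con, function(recs) out[seq_along(recs) + length(out)] <<- recs)
  out
}

split_header <- function(h) {
  sp <- regexpr("[[:space:]]", h)
  if (sp < 0L) list(id = h, description = "")
  else list(id = substring(h, 1L, sp - 1L),
            description = sub("^[[:space:]]+", "", substring(h, sp + 1L)))
}

format_header <- function(rec) {
  if (nzchar(rec$description)) paste(rec$id, rec$description) else rec$id
}

write_fastq <- function(records, con, options = list()) {
  for (rec in records) {
    if (is.null(rec$quality))
      bc_stop("bc_record_error",
              sprintf("record '%s' has no quality scores; cannot write FASTQ", rec$id))
    writeLines(c(paste0("@", format_header(rec)), rec$sequence,
                 "+", phred_encode(rec$quality)), con)
  }
  length(records)
}

## ---- FASTA ----------------------------------------------------------------

# Streaming FASTA reader with carry-over across chunk boundaries.
fasta_stream <- function(con, callback, chunk = 20000L) {
  carry_header <- NULL
  carry_seq <- character()
  flush_rec <- function() {
    hdr <- split_header(substring(carry_header, 2L))
    seq_record(hdr$id, paste(carry_seq, collapse = ""), description = hdr$description)
  }
  line_no <- 0L
  repeat {
    lines <- readLines(con, n = chunk, warn = FALSE)
    if (length(lines) == 0L) break
    recs <- list()
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (startsWith(ln, ">")) {
        if (!is.null(carry_header)) recs[[length(recs) + 1L]] <- flush_rec()
        carry_header <- ln
        carry_seq <- character()
      } else if (nzchar(ln)) {
        if (is.null(carry_header))
          bc_parse_error("sequence data before any '>' header",
                         line = line_no + i, format = "fasta")
        carry_seq[length(carry_seq) + 1L] <- ln
      }
    }
    if (length(recs)) callback(recs)
    line_no <- line_no + length(lines)
    if (length(lines) < chunk) break
  }
  if (!is.null(carry_header)) callback(list(flush_rec()))
  invisible(NULL)
}

parse_fasta <- function(con) {
  out <- list()
  fasta_stream(con, function(recs) out[seq_along(recs) + length(out)] <<- recs)
  out
}

wrap_sequence <- function(s, width) {
  if (width <= 0L || nchar(s) <= width) return(s)
  starts <- seq(1L, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1L, nchar(s)))
}

write_fasta <- function(records, con, options = list()) {
  width <- if (is.null(options$wrap)) 80L else as.integer(options$wrap)
  for (rec in records)
    writeLines(c(paste0(">", format_header(rec)),
                 wrap_sequence(rec$sequence, width)), con)
  length(records)
}

## ---- QUAL -----------------------------------------------------------------
# FASTA-like: '>' headers, then whitespace-separated integer Phred scores.

parse_qual <- function(con) {
  lines <- readLines(con, warn = FALSE)
  hdr_idx <- which(startsWith(lines, ">"))
  if (length(hdr_idx) == 0L) return(list())
  bounds <- c(hdr_idx, length(lines) + 1L)
  out <- vector("list", length(hdr_idx))
  for (k in seq_along(hdr_idx)) {
    body <- lines[seq(bounds[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[nzchar(body)]
    toks <- unlist(strsplit(paste(body, collapse = " "), "[[:space:]]+"))
    toks <- toks[nzchar(toks)]
    scores <- suppressWarnings(as.integer(toks))
    if (anyNA(scores))
      bc_parse_error("non-integer quality score in QUAL record",
                     line = hdr_idx[k], format = "qual")
    hdr <- split_header(substring(lines[hdr_idx[k]], 2L))
    # sequence is unknown in a QUAL file; store a placeholder of matching length
    out[[k]] <- structure(list(id = hdr$id, description = hdr$description,
                               sequence = NA_character_, quality = scores),
                          class = "seq_record")
  }
  out
}

write_qual <- function(records, con, options = list()) {
  for (rec in records) {
    if (is.null(rec$quality))
      bc_stop("bc_record_error",
              sprintf("record '%s' has no quality scores; cannot write QUAL", rec$id))
    writeLines(c(paste0(">", format_header(rec)),
                 paste(rec$quality, collapse = " ")), con)
  }
  length(records)
}
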