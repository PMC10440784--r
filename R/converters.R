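# The concrete conversion plugins, the unified convert() dispatch and the
# external-tool method contract.

#' Run a conversion
#'
#' Unified dispatch over all registered converters: picks the requested
#' (or default) method, handles compressed inputs/outputs transparently
#' through their extensions, and returns a report with record counts and
#' elapsed wall time. Lossy conversions emit a classed warning naming
#' what is lost.
#'
#' @param spec A `converter_spec` or the name of a registered conversion.
#' @param inputs,outputs Character vectors of file paths; arity must
#'   match the spec.
#' @param method Method identifier or `"default"`.
#' @param options Named list of options passed to the method (e.g. `wrap`
#'   for FASTA output, `template` for external methods).
#' @param registry Registry used to resolve `spec` given as a name.
#' @return An object of class `conversion_report`.
#' @export
convert <- function(spec, inputs, outputs, method = "default",
                    options = list(), registry = default_registry()) {
  if (is.character(spec)) {
    nm <- spec
    spec <- registry$converters[[nm]]
    if (is.null(spec))
      bc_stop("bc_no_converter", sprintf("no registered conversion named '%s'", nm))
  }
  if (length(inputs) != length(spec$inputs) || length(outputs) != length(spec$outputs))
    bc_stop("bc_usage_error",
            sprintf("'%s' takes %d input(s) and %d output(s); got %d and %d",
                    spec$name, length(spec$inputs), length(spec$outputs),
                    length(inputs), length(outputs)))
  if (identical(method, "default")) method <- spec$default_method
  if (!method %in% spec$methods)
    bc_stop("bc_unknown_method",
            sprintf("unknown method '%s' for '%s'; available: %s",
                    method, spec$name, paste(spec$methods, collapse = ", ")))
  binary <- external_binary_for(spec, method, options)
  if (!is.null(binary) && Sys.which(binary) == "")
    bc_stop("bc_environment_error",
            sprintf("method '%s' of '%s' needs external executable '%s', which is not on PATH",
                    method, spec$name, binary))
  fn <- spec$functions[[paste0(METHOD_PREFIX, method)]]
  t0 <- proc.time()[["elapsed"]]
  counts <- fn(inputs, outputs, options)
  elapsed <- proc.time()[["elapsed"]] - t0
  lossy_warning <- NULL
  if (spec$lossy) {
    lossy_warning <- if (!is.null(spec$lossy_warning)) spec$lossy_warning
                     else sprintf("conversion '%s' is lossy", spec$name)
    warning(warningCondition(lossy_warning, class = "bc_lossy_warning"))
  }
  structure(list(spec_name = spec$name, method = method,
                 records_in = counts$records_in, records_out = counts$records_out,
                 lossy_warning = lossy_warning, elapsed = elapsed),
            class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat(sprintf("<%s [%s]: %d record(s) in, %d out, %.3fs%s>\n",
              x$spec_name, x$method, x$records_in, x$records_out, x$elapsed,
              if (is.null(x$lossy_warning)) "" else " (lossy)"))
  invisible(x)
}

external_binary_for <- function(spec, method, options = list()) {
  ext <- spec$requires_external
  if (length(ext) == 0L || !method %in% names(ext)) return(NULL)
  override <- options$config$external_binary[[spec$name]]
  if (!is.null(override)) override else ext[[method]]
}

#' Convert a FASTQ file through the FastA/quality gate
#'
#' Writes the sequence part, the quality part, or both, depending on the
#' extensions of `outputs`: a single FASTA path triggers fastq2fasta, a
#' single QUAL path fastq2qual, and a FASTA + QUAL pair the two-output
#' fastq2fasta_qual gate (same record order in both files).
#'
#' @param input FASTQ path.
#' @param outputs One or two output paths among a FASTA and a QUAL file.
#' @param options,registry As in [convert()].
#' @return A `conversion_report`.
#' @export
fastq_gate <- function(input, outputs, options = list(),
                       registry = default_registry()) {
  if (length(outputs) < 1L)
    bc_stop("bc_usage_error", "fastq_gate needs at least one output")
  fmts <- vapply(outputs, function(p) infer_format(p, registry)$format, character(1))
  spec_name <- converter_name("fastq", fmts)
  convert(spec_name, input, outputs, options = options, registry = registry)
}

## ---- External-tool contract ------------------------------------------------

# Command templates live in configuration, not code, so deployments can
# swap equivalent backends. {input}/{output} placeholders are substituted.
DEFAULT_EXTERNAL_TEMPLATES <- list(
  sam2bam = "samtools view -b -o {output} {input}",
  bam2sam = "samtools view -h -o {output} {input}"
)

run_external_template <- function(spec_name, input, output, options = list()) {
  template <- options$template
  if (is.null(template)) template <- options$config$external[[spec_name]]
  if (is.null(template)) template <- DEFAULT_EXTERNAL_TEMPLATES[[spec_name]]
  if (is.null(template))
    bc_stop("bc_environment_error",
            sprintf("no command template configured for '%s'", spec_name))
  cmd <- gsub("{input}", input, gsub("{output}", output, template, fixed = TRUE),
              fixed = TRUE)
  parts <- strsplit(cmd, "[[:space:]]+")[[1]]
  res <- suppressWarnings(system2(parts[1], parts[-1], stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L)
    bc_stop("bc_external_tool_error",
            sprintf("external command failed (exit %d): %s\n%s",
                    status, cmd, paste(res, collapse = "\n")))
  if (!file.exists(output))
    bc_stop("bc_external_tool_error",
            sprintf("external command reported success but produced no output: %s", cmd))
  invisible(cmd)
}

## ---- Built-in converter definitions ----------------------------------------

# Shared FASTA emission used by the alternative fastq2fasta mechanisms so
# byte-identical output is a property of the data, not of luck.
fasta_block_lines <- function(headers, seqs, width) {
  out <- vector("list", length(headers))
  for (k in seq_along(headers))
    out[[k]] <- c(paste0(">", headers[k]), wrap_sequence(seqs[k], width))
  unlist(out, use.names = FALSE)
}

fastq2fasta_records <- function(inputs, outputs, options) {
  src <- as_input_con(inputs[1]); out <- as_output_con(outputs[1])
  on.exit({ if (src$close) close(src$con); if (out$close) close(out$con) })
  n <- 0L
  fastq_stream(src$con, function(recs) {
    write_fasta(recs, out$con, options)
    n <<- n + length(recs)
  })
  list(records_in = n, records_out = n)
}

fastq2fasta_linewise <- function(inputs, outputs, options) {
  # line-quadruple state machine over chunked reads
  width <- if (is.null(options$wrap)) 80L else as.integer(options$wrap)
  src <- as_input_con(inputs[1]); out <- as_output_con(outputs[1])
  on.exit({ if (src$close) close(src$con); if (out$close) close(out$con) })
  n <- 0L
  repeat {
    lines <- readLines(src$con, n = 20000L, warn = FALSE)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L)
      bc_parse_error("truncated FASTQ record", line = n * 4L + length(lines),
                     format = "fastq")
    h <- lines[seq(1L, length(lines), by = 4L)]
    s <- lines[seq(2L, length(lines), by = 4L)]
    p <- lines[seq(3L, length(lines), by = 4L)]
    q <- lines[seq(4L, length(lines), by = 4L)]
    bad <- which(!startsWith(h, "@") | !startsWith(p, "+") | nchar(s) != nchar(q))
    if (length(bad))
      bc_parse_error("malformed FASTQ record", line = n * 4L + bad[1] * 4L - 3L,
                     format = "fastq")
    writeLines(fasta_block_lines(substring(h, 2L), s, width), out$con)
    n <- n + length(h)
    if (length(lines) < 20000L) break
  }
  list(records_in = n, records_out = n)
}

fastq2fasta_buffer <- function(inputs, outputs, options) {
  # whole-buffer splitting: fastest on files that fit in memory
  width <- if (is.null(options$wrap)) 80L else as.integer(options$wrap)
  src <- as_input_con(inputs[1])
  lines <- readLines(src$con, warn = FALSE)
  if (src$close) close(src$con)
  if (length(lines) %% 4L != 0L)
    bc_parse_error("truncated FASTQ record", line = length(lines), format = "fastq")
  n <- length(lines) %/% 4L
  out <- as_output_con(outputs[1])
  on.exit(if (out$close) close(out$con))
  if (n > 0L) {
    h <- lines[seq(1L, length(lines), by = 4L)]
    s <- lines[seq(2L, length(lines), by = 4L)]
    p <- lines[seq(3L, length(lines), by = 4L)]
    q <- lines[seq(4L, length(lines), by = 4L)]
    bad <- which(!startsWith(h, "@") | !startsWith(p, "+") | nchar(s) != nchar(q))
    if (length(bad))
      bc_parse_error("malformed FASTQ record", line = bad[1] * 4L - 3L,
                     format = "fastq")
    writeLines(fasta_block_lines(substring(h, 2L), s, width), out$con)
  }
  list(records_in = n, records_out = n)
}

# Simple whole-file record pipeline: parse all, transform, write all.
pipeline <- function(in_format, out_format, transform = identity) {
  force(in_format); force(out_format); force(transform)
  function(inputs, outputs, options) {
    recs <- parse_records(in_format, inputs[1])
    out <- transform(recs)
    n_out <- write_records(out_format, out, outputs[1], options)
    list(records_in = count_records(recs), records_out = n_out)
  }
}

count_records <- function(recs) {
  if (length(recs) == 1L && inherits(recs[[1]], "msa_alignment"))
    return(length(recs[[1]]$records))
  if (length(recs) == 1L && inherits(recs[[1]], "tree_document"))
    return(length(recs[[1]]$trees))
  length(recs)
}

fastq2fasta_qual_gate <- function(inputs, outputs, options) {
  src <- as_input_con(inputs[1])
  fa <- as_output_con(outputs[1]); qu <- as_output_con(outputs[2])
  on.exit({ if (src$close) close(src$con)
            if (fa$close) close(fa$con); if (qu$close) close(qu$con) })
  n <- 0L
  fastq_stream(src$con, function(recs) {
    write_fasta(recs, fa$con, options)
    write_qual(recs, qu$con, options)
    n <<- n + length(recs)
  })
  list(records_in = n, records_out = n)
}

fasta_qual2fastq_gate <- function(inputs, outputs, options) {
  seqs <- parse_records("fasta", inputs[1])
  quals <- parse_records("qual", inputs[2])
  if (length(seqs) != length(quals))
    bc_stop("bc_pairing_error",
            sprintf("FASTA has %d record(s) but QUAL has %d", length(seqs), length(quals)))
  merged <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    s <- seqs[[k]]; q <- quals[[k]]
    if (s$id != q$id)
      bc_stop("bc_pairing_error",
              sprintf("record %d: FASTA id '%s' does not match QUAL id '%s'",
                      k, s$id, q$id))
    if (nchar(s$sequence) != length(q$quality))
      bc_stop("bc_pairing_error",
              sprintf("record %d ('%s'): sequence length %d but %d quality scores",
                      k, s$id, nchar(s$sequence), length(q$quality)))
    merged[[k]] <- seq_record(s$id, s$sequence, quality = q$quality,
                              description = s$description)
  }
  n <- write_records("fastq", merged, outputs[1], options)
  list(records_in = length(seqs), records_out = n)
}

sam_reads_pipeline <- function(out_format) {
  force(out_format)
  function(inputs, outputs, options) {
    sams <- parse_records("sam", inputs[1])
    reads <- Filter(Negate(is.null), lapply(sams, sam_to_seqrecord))
    if (out_format == "fastq") {
      no_qual <- vapply(reads, function(r) is.null(r$quality), logical(1))
      if (any(no_qual))
        bc_stop("bc_record_error",
                sprintf("read '%s' has no stored quality; cannot write FASTQ",
                        reads[[which(no_qual)[1]]]$id))
    }
    n <- write_records(out_format, reads, outputs[1], options)
    list(records_in = length(sams), records_out = n)
  }
}

interval_pipeline <- function(in_format, to_interval) {
  force(in_format); force(to_interval)
  function(inputs, outputs, options) {
    rows <- parse_records(in_format, inputs[1])
    ivs <- lapply(rows, to_interval)
    n <- write_records("bed", ivs, outputs[1], options)
    list(records_in = length(rows), records_out = n)
  }
}

builtin_converter_definitions <- function() {
  list(
    list(name = "fastq2fasta", lossy = TRUE,
         lossy_warning = "quality information is lost when converting from FastQ to FastA",
         default = "records",
         method_records = fastq2fasta_records,
         method_linewise = fastq2fasta_linewise,
         method_buffer = fastq2fasta_buffer),
    list(name = "fastq2qual", lossy = TRUE,
         lossy_warning = "sequence information is lost when converting from FastQ to QUAL",
         method_records = pipeline("fastq", "qual")),
    list(name = "fastq2fasta_qual", lossy = FALSE,
         method_records = fastq2fasta_qual_gate),
    list(name = "fasta_qual2fastq", lossy = FALSE,
         method_records = fasta_qual2fastq_gate),
    list(name = "fasta2fastq", lossy = FALSE,
         method_constant = function(inputs, outputs, options) {
           # no quality exists in FASTA; a constant documented placeholder
           # of Q40 ('I') is assigned to every base
           recs <- parse_records("fasta", inputs[1])
           recs <- lapply(recs, function(r)
             seq_record(r$id, r$sequence,
                        quality = rep(40L, nchar(r$sequence)),
                        description = r$description))
           n <- write_records("fastq", recs, outputs[1], options)
           list(records_in = length(recs), records_out = n)
         }),
    list(name = "fasta2faa", lossy = TRUE,
         lossy_warning = "nucleotide-level information is lost when translating to amino acids",
         method_translate = function(inputs, outputs, options) {
           recs <- parse_records("fasta", inputs[1])
           recs <- lapply(recs, function(r)
             seq_record(r$id, translate_dna(r$sequence), description = r$description))
           n <- write_records("fasta", recs, outputs[1], options)
           list(records_in = length(recs), records_out = n)
         }),
    list(name = "clustal2fasta", method_records = pipeline("clustal", "fasta", msa_records)),
    list(name = "fasta2clustal", method_records = pipeline("fasta", "clustal")),
    list(name = "fasta2phylip", lossy = TRUE,
         lossy_warning = "identifiers longer than 10 characters are truncated in PHYLIP output",
         method_records = pipeline("fasta", "phylip")),
    list(name = "phylip2fasta", method_records = pipeline("phylip", "fasta", msa_records)),
    list(name = "clustal2phylip", lossy = TRUE,
         lossy_warning = "identifiers longer than 10 characters are truncated in PHYLIP output",
         method_records = pipeline("clustal", "phylip")),
    list(name = "fasta2stockholm", method_records = pipeline("fasta", "stockholm")),
    list(name = "stockholm2fasta", method_records = pipeline("stockholm", "fasta", msa_records)),
    list(name = "newick2nexus", method_records = pipeline("newick", "nexus")),
    list(name = "nexus2newick", method_records = pipeline("nexus", "newick")),
    list(name = "gff32bed", lossy = TRUE,
         lossy_warning = "GFF3 source/type/phase and attributes beyond ID are lost in BED output",
         method_records = interval_pipeline("gff3", gff3_to_interval)),
    list(name = "vcf2bed", lossy = TRUE,
         lossy_warning = "VCF alleles, genotypes and INFO are lost in BED output",
         method_records = interval_pipeline("vcf", variant_to_interval)),
    list(name = "sam2fastq", lossy = TRUE,
         lossy_warning = "alignment information is lost when extracting reads from SAM",
         method_records = sam_reads_pipeline("fastq")),
    list(name = "sam2fasta", lossy = TRUE,
         lossy_warning = "alignment and quality information is lost when extracting reads from SAM",
         method_records = sam_reads_pipeline("fasta")),
    list(name = "sam2bam", lossy = FALSE,
         external = c(samtools = "samtools"),
         method_samtools = function(inputs, outputs, options) {
           run_external_template("sam2bam", inputs[1], outputs[1], options)
           n <- length(parse_records("sam", inputs[1]))
           list(records_in = n, records_out = n)
         })
  )
}

# unwrap a one-element alignment parse into plain FASTA-writable records
msa_records <- function(recs) {
  if (length(recs) == 1L && inherits(recs[[1]], "msa_alignment"))
    recs[[1]]$records
  else recs
}

## ---- Default registry -------------------------------------------------------

DEFAULT_FORMATS <- list(
  list("fastq", c(".fastq", ".fq"), "sequencing"),
  list("fasta", c(".fasta", ".fa", ".fna"), "sequencing"),
  list("qual", ".qual", "sequencing"),
  list("faa", ".faa", "sequencing"),
  list("clustal", c(".clustal", ".aln", ".clw"), "alignment-msa"),
  list("phylip", c(".phylip", ".phy"), "alignment-msa"),
  list("stockholm", c(".sto", ".stk", ".stockholm"), "alignment-msa"),
  list("nexus", c(".nexus", ".nx", ".nxs"), "phylogeny"),
  list("newick", c(".newick", ".nw", ".nwk"), "phylogeny"),
  list("gff3", c(".gff", ".gff3"), "annotation"),
  list("bed", ".bed", "annotation"),
  list("vcf", ".vcf", "variant"),
  list("sam", ".sam", "read-alignment"),
  list("bam", ".bam", "read-alignment", TRUE)
)

build_default_registry <- function() {
  reg <- new_registry()
  for (f in DEFAULT_FORMATS)
    register_format(reg, format_descriptor(f[[1]], f[[2]], f[[3]],
                                           binary = length(f) > 3L && f[[4]]))
  for (spec in discover_converters(builtin_converter_definitions()))
    register_converter(reg, spec)
  reg
}

.registry_cache <- new.env(parent = emptyenv())

#' The built-in registry of formats and conversions
#'
#' Built once per session from the packaged format descriptors and
#' converter plugin definitions.
#'
#' @return A `conversion_registry`.
#' @export
default_registry <- function() {
  if (is.null(.registry_cache$registry))
    .registry_cache$registry <- build_default_registry()
  .registry_cache$registry
}
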