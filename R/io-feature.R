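# Tabular genomic formats: GFF3, VCF, SAM (readers and writers) and the
# 6-column BED writer. Header/comment lines are carried as metadata, not
# records; writers accept them back through options$headers.

## ---- GFF3 -----------------------------------------------------------------

parse_gff3_attributes <- function(s) {
  if (!nzchar(s) || s == ".") return(list())
  out <- list()
  for (field in strsplit(s, ";", fixed = TRUE)[[1]]) {
    field <- trimws(field)
    if (!nzchar(field)) next
    eq <- regexpr("=", field, fixed = TRUE)
    if (eq < 0L) { out[[utils::URLdecode(field)]] <- ""; next }
    key <- utils::URLdecode(substring(field, 1L, eq - 1L))
    out[[key]] <- utils::URLdecode(substring(field, eq + 1L))
  }
  out
}

encode_gff3_attributes <- function(attrs) {
  if (length(attrs) == 0L) return(".")
  enc <- function(x) gsub(";", "%3B", gsub("=", "%3D", gsub("%", "%25", x)))
  paste(vapply(names(attrs), function(k) paste0(enc(k), "=", enc(attrs[[k]])),
               character(1)), collapse = ";")
}

parse_gff3 <- function(con) {
  out <- list(); headers <- character()
  stream_lines(con, function(lines, first) {
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (!nzchar(ln)) next
      if (startsWith(ln, "#")) { headers <<- c(headers, ln); next }
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 9L)
        bc_parse_error(sprintf("GFF3 row has %d columns, expected 9", length(f)),
                       line = first + i - 1L, format = "gff3")
      start <- suppressWarnings(as.integer(f[4]))
      end <- suppressWarnings(as.integer(f[5]))
      if (is.na(start) || is.na(end))
        bc_parse_error("non-integer GFF3 coordinates",
                       line = first + i - 1L, format = "gff3")
      out[[length(out) + 1L]] <<- structure(
        list(seqid = f[1], source = f[2], type = f[3],
             start = start, end = end, score = f[6], strand = f[7],
             phase = f[8], attributes = parse_gff3_attributes(f[9])),
        class = "gff3_feature")
    }
  })
  structure(out, metadata = headers)
}

write_gff3 <- function(records, con, options = list()) {
  headers <- options$headers
  if (is.null(headers)) headers <- "##gff-version 3"
  writeLines(headers, con)
  for (f in records)
    writeLines(paste(f$seqid, f$source, f$type, f$start, f$end, f$score,
                     f$strand, f$phase, encode_gff3_attributes(f$attributes),
                     sep = "\t"), con)
  length(records)
}

## ---- VCF ------------------------------------------------------------------

parse_vcf <- function(con) {
  out <- list(); headers <- character()
  stream_lines(con, function(lines, first) {
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (!nzchar(ln)) next
      if (startsWith(ln, "#")) { headers <<- c(headers, ln); next }
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 8L)
        bc_parse_error(sprintf("VCF row has %d columns, expected >= 8", length(f)),
                       line = first + i - 1L, format = "vcf")
      pos <- suppressWarnings(as.integer(f[2]))
      if (is.na(pos))
        bc_parse_error(sprintf("non-integer POS '%s' in VCF row", f[2]),
                       line = first + i - 1L, format = "vcf")
      out[[length(out) + 1L]] <<- structure(
        list(chrom = f[1], pos = pos, id = f[3], ref = f[4], alt = f[5],
             qual = f[6], filter = f[7], info = f[8],
             extra = if (length(f) > 8L) f[-(1:8)] else character()),
        class = "vcf_variant")
    }
  })
  structure(out, metadata = headers)
}

write_vcf <- function(records, con, options = list()) {
  headers <- options$headers
  if (is.null(headers))
    headers <- c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(headers, con)
  for (v in records)
    writeLines(paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, v$qual, v$filter,
                       v$info, v$extra), collapse = "\t"), con)
  length(records)
}

## ---- SAM ------------------------------------------------------------------

parse_sam <- function(con) {
  out <- list(); headers <- character()
  stream_lines(con, function(lines, first) {
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (!nzchar(ln)) next
      if (startsWith(ln, "@")) { headers <<- c(headers, ln); next }
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 11L)
        bc_parse_error(sprintf("SAM row has %d columns, expected >= 11", length(f)),
                       line = first + i - 1L, format = "sam")
      flag <- suppressWarnings(as.integer(f[2]))
      if (is.na(flag))
        bc_parse_error("non-integer SAM flag", line = first + i - 1L, format = "sam")
      rec <- tryCatch(
        sam_record(f[1], flag, f[3], f[4], f[5], f[6], f[7], f[8], f[9],
                   f[10], f[11],
                   tags = if (length(f) > 11L) f[-(1:11)] else character()),
        bioconvr_error = function(e)
          bc_parse_error(conditionMessage(e), line = first + i - 1L, format = "sam"))
      out[[length(out) + 1L]] <<- rec
    }
  })
  structure(out, metadata = headers)
}

write_sam <- function(records, con, options = list()) {
  headers <- options$headers
  if (!is.null(headers)) writeLines(headers, con)
  for (r in records)
    writeLines(paste(c(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar,
                       r$rnext, r$pnext, r$tlen, r$seq, r$qual, r$tags),
                     collapse = "\t"), con)
  length(records)
}

## ---- BED (writer only) ----------------------------------------------------

write_bed <- function(records, con, options = list()) {
  for (iv in records)
    writeLines(paste(iv$chrom, iv$start, iv$end, iv$name, iv$score, iv$strand,
                     sep = "\t"), con)
  length(records)
}
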