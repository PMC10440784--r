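# Multiple-sequence-alignment formats: CLUSTAL, PHYLIP, Stockholm.
# Parsers return a single msa_alignment wrapped in a one-element list so
# the parse/write dispatch stays uniform across formats.

as_alignment_input <- function(records) {
  if (length(records) == 1L && inherits(records[[1]], "msa_alignment"))
    return(records[[1]])
  if (inherits(records, "msa_alignment")) return(records)
  msa_alignment(records)  # validates equal lengths / unique ids
}

## ---- CLUSTAL --------------------------------------------------------------

parse_clustal <- function(con) {
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L || !grepl("^CLUSTAL", lines[1]))
    bc_parse_error("missing CLUSTAL header line", line = 1L, format = "clustal")
  seqs <- list()   # name -> accumulated sequence
  order <- character()
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    # conservation lines contain only alignment annotation characters
    if (grepl("^[[:space:]]", ln) && grepl("^[ .:*]*$", ln)) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)", ln))[[1]]
    if (length(m) != 3L)
      bc_parse_error("unparseable CLUSTAL alignment line", line = i, format = "clustal")
    name <- m[2]; chunk <- m[3]
    if (!name %in% order) order <- c(order, name)
    seqs[[name]] <- paste0(if (is.null(seqs[[name]])) "" else seqs[[name]], chunk)
  }
  if (length(order) == 0L)
    bc_parse_error("CLUSTAL file contains no sequences", line = 1L, format = "clustal")
  recs <- lapply(order, function(nm) seq_record(nm, seqs[[nm]]))
  list(msa_alignment(recs))
}

write_clustal <- function(records, con, options = list()) {
  aln <- as_alignment_input(records)
  width <- if (is.null(options$block_width)) 60L else as.integer(options$block_width)
  ids <- vapply(aln$records, `[[`, character(1), "id")
  pad <- max(nchar(ids)) + 3L
  writeLines(c("CLUSTAL W multiple sequence alignment", ""), con)
  len <- nchar(aln$records[[1]]$sequence)
  starts <- seq(1L, len, by = width)
  for (s in starts) {
    for (rec in aln$records) {
      chunk <- substring(rec$sequence, s, min(s + width - 1L, len))
      writeLines(sprintf("%-*s%s", pad, rec$id, chunk), con)
    }
    writeLines("", con)
  }
  length(aln$records)
}

## ---- PHYLIP ---------------------------------------------------------------
# Read: sequential and interleaved both accepted.
# Write: strict sequential, names padded to 10 characters, one line per taxon.

parse_phylip <- function(con) {
  lines <- readLines(con, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) == 0L)
    bc_parse_error("empty PHYLIP input", line = 1L, format = "phylip")
  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  m <- suppressWarnings(as.integer(hdr[2]))
  if (length(hdr) < 2L || is.na(n) || is.na(m))
    bc_parse_error("non-numeric PHYLIP header (expected '<ntaxa> <nsites>')",
                   line = 1L, format = "phylip")
  body <- lines[-1]
  rec <- try_phylip_sequential(body, n, m)
  if (is.null(rec)) rec <- try_phylip_interleaved(body, n, m)
  if (is.null(rec))
    bc_parse_error(sprintf("could not parse PHYLIP body as sequential or interleaved (%d taxa, %d sites)", n, m),
                   line = 2L, format = "phylip")
  list(msa_alignment(rec))
}

phylip_name_split <- function(ln) {
  # strict: first 10 columns are the name; relaxed: whitespace-delimited
  if (grepl("^\\S{1,10}\\s", ln) || nchar(ln) <= 10L) {
    m <- regmatches(ln, regexec("^(\\S+)\\s*(.*)$", ln))[[1]]
    list(name = m[2], rest = m[3])
  } else {
    list(name = trimws(substring(ln, 1L, 10L)), rest = substring(ln, 11L))
  }
}

try_phylip_sequential <- function(body, n, m) {
  recs <- vector("list", n)
  i <- 1L
  for (k in seq_len(n)) {
    if (i > length(body)) return(NULL)
    parts <- phylip_name_split(body[i])
    seq <- gsub("[[:space:]]", "", parts$rest)
    i <- i + 1L
    while (nchar(seq) < m) {
      if (i > length(body)) return(NULL)
      seq <- paste0(seq, gsub("[[:space:]]", "", body[i]))
      i <- i + 1L
    }
    if (nchar(seq) != m || !nzchar(parts$name)) return(NULL)
    recs[[k]] <- seq_record(parts$name, seq)
  }
  if (i <= length(body) && any(nzchar(trimws(body[i:length(body)])))) return(NULL)
  recs
}

try_phylip_interleaved <- function(body, n, m) {
  body <- body[nzchar(trimws(body))]
  if (length(body) %% n != 0L) return(NULL)
  names <- character(n); seqs <- character(n)
  for (i in seq_along(body)) {
    k <- ((i - 1L) %% n) + 1L
    if (i <= n) {
      parts <- phylip_name_split(body[i])
      names[k] <- parts$name
      seqs[k] <- gsub("[[:space:]]", "", parts$rest)
    } else {
      seqs[k] <- paste0(seqs[k], gsub("[[:space:]]", "", body[i]))
    }
  }
  if (any(!nzchar(names)) || any(nchar(seqs) != m)) return(NULL)
  mapply(seq_record, names, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

phylip_truncate_ids <- function(ids) {
  short <- substring(ids, 1L, 10L)
  if (anyDuplicated(short)) {
    dup <- ids[short %in% short[duplicated(short)]]
    bc_stop("bc_name_collision",
            sprintf("PHYLIP name truncation to 10 characters collides for: %s",
                    paste(dup, collapse = ", ")))
  }
  short
}

write_phylip <- function(records, con, options = list()) {
  aln <- as_alignment_input(records)
  ids <- vapply(aln$records, `[[`, character(1), "id")
  short <- phylip_truncate_ids(ids)
  m <- nchar(aln$records[[1]]$sequence)
  writeLines(sprintf(" %d %d", length(ids), m), con)
  for (k in seq_along(ids))
    writeLines(sprintf("%-10s%s", short[k], aln$records[[k]]$sequence), con)
  length(ids)
}

## ---- Stockholm ------------------------------------------------------------

parse_stockholm <- function(con) {
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[1]))
    bc_parse_error("missing '# STOCKHOLM 1.0' header", line = 1L, format = "stockholm")
  seqs <- list(); order <- character(); meta <- character()
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (ln == "//") break
    if (startsWith(ln, "#")) { meta <- c(meta, ln); next }
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)\\s*$", ln))[[1]]
    if (length(m) != 3L)
      bc_parse_error("unparseable Stockholm sequence line", line = i, format = "stockholm")
    name <- m[2]
    if (!name %in% order) order <- c(order, name)
    seqs[[name]] <- paste0(if (is.null(seqs[[name]])) "" else seqs[[name]], m[3])
  }
  if (length(order) == 0L)
    bc_parse_error("Stockholm file contains no sequences", line = 1L, format = "stockholm")
  recs <- lapply(order, function(nm) seq_record(nm, seqs[[nm]]))
  list(msa_alignment(recs, metadata = list(annotations = meta)))
}

write_stockholm <- function(records, con, options = list()) {
  aln <- as_alignment_input(records)
  ids <- vapply(aln$records, `[[`, character(1), "id")
  pad <- max(nchar(ids)) + 2L
  writeLines("# STOCKHOLM 1.0", con)
  for (rec in aln$records)
    writeLines(sprintf("%-*s%s", pad, rec$id, rec$sequence), con)
  writeLines("//", con)
  length(ids)
}
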