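# Phylogenetic tree formats: Newick and NEXUS (TREES block with optional
# Translate table). Parsers return a single tree_document in a one-element
# list, mirroring the MSA formats.

parse_newick <- function(con) {
  lines <- readLines(con, warn = FALSE)
  text <- paste(lines, collapse = "\n")
  # one tree per ';'-terminated statement; whitespace between trees ignored
  pieces <- strsplit(text, ";", fixed = TRUE)[[1]]
  pieces <- trimws(pieces)
  pieces <- pieces[nzchar(pieces)]
  if (length(pieces) == 0L)
    bc_parse_error("no trees found in newick input", line = 1L, format = "newick")
  trees <- lapply(seq_along(pieces), function(k) {
    nwk <- paste0(gsub("[[:space:]]", "", pieces[k]), ";")
    check_newick(nwk)
    list(label = sprintf("TREE%d", k), newick = nwk)
  })
  list(tree_document(trees))
}

write_newick <- function(records, con, options = list()) {
  doc <- as_tree_document(records)
  for (tr in doc$trees)
    writeLines(apply_translate(tr$newick, doc$translate), con)
  length(doc$trees)
}

as_tree_document <- function(records) {
  if (inherits(records, "tree_document")) return(records)
  if (length(records) == 1L && inherits(records[[1]], "tree_document"))
    return(records[[1]])
  bc_stop("bc_usage_error", "tree writers expect a tree_document")
}

# Substitute translate-table tokens for taxon names at label positions.
apply_translate <- function(newick, translate) {
  if (is.null(translate) || length(translate) == 0L) return(newick)
  out <- newick
  for (tok in names(translate)) {
    out <- gsub(sprintf("(?<=[(,])%s(?=[,):;])", tok),
                translate[[tok]], out, perl = TRUE)
  }
  out
}

parse_nexus <- function(con) {
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L || !grepl("^#NEXUS", lines[1], ignore.case = TRUE))
    bc_parse_error("missing #NEXUS header", line = 1L, format = "nexus")
  text <- paste(lines[-1], collapse = "\n")
  block <- regmatches(text, regexpr("(?is)begin\\s+trees\\s*;.*?end\\s*;", text, perl = TRUE))
  if (length(block) == 0L)
    bc_parse_error("no TREES block found in NEXUS input", line = 1L, format = "nexus")
  block <- block[[1]]

  translate <- NULL
  tr_match <- regmatches(block, regexpr("(?is)translate\\s+.*?;", block, perl = TRUE))
  if (length(tr_match) == 1L) {
    body <- sub("(?is)^translate\\s+", "", sub(";$", "", tr_match), perl = TRUE)
    entries <- strsplit(body, ",")[[1]]
    translate <- character()
    for (e in entries) {
      toks <- strsplit(trimws(e), "[[:space:]]+")[[1]]
      if (length(toks) >= 2L) translate[toks[1]] <- toks[2]
    }
  }

  # tree statements: "tree NAME = [&U] (...);" (rooting comment optional)
  stmts <- regmatches(block, gregexpr("(?i)\\btree\\s+[^=]+=[^;]*;", block, perl = TRUE))[[1]]
  if (length(stmts) == 0L)
    bc_parse_error("TREES block contains no tree statements", line = 1L, format = "nexus")
  trees <- lapply(stmts, function(s) {
    label <- trimws(sub("(?i)^\\s*tree\\s+([^=]+)=.*$", "\\1", s, perl = TRUE))
    nwk <- trimws(sub("(?i)^\\s*tree\\s+[^=]+=\\s*", "", s, perl = TRUE))
    nwk <- gsub("\\[[^]]*\\]", "", nwk)        # strip [&U]-style comments
    nwk <- gsub("[[:space:]]", "", nwk)
    check_newick(nwk)
    list(label = label, newick = nwk)
  })
  list(tree_document(trees, translate = translate))
}

write_nexus <- function(records, con, options = list()) {
  doc <- as_tree_document(records)
  writeLines(c("#NEXUS", "BEGIN TREES;"), con)
  for (k in seq_along(doc$trees)) {
    tr <- doc$trees[[k]]
    label <- if (nzchar(tr$label)) tr$label else sprintf("TREE%d", k)
    writeLines(sprintf("    TREE %s = %s", label,
                       apply_translate(tr$newick, doc$translate)), con)
  }
  writeLines("END;", con)
  length(doc$trees)
}
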