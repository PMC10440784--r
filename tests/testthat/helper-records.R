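# Shared fixture-building helpers. All inputs are generated in code,
# deterministically from explicit seeds.

tmpfile <- function(ext) tempfile(fileext = ext)

read_file_bytes <- function(path) {
  readBin(path, "raw", n = file.info(path)$size)
}

# Decompressed text content of a possibly compressed file.
decompressed_lines <- function(path) {
  con <- open_auto(path, "read")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

make_seq_records <- function(n, len, seed, with_qual = FALSE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    q <- if (with_qual) sample(0:40, len, replace = TRUE) else NULL
    seq_record(sprintf("rec_%d", i), s, quality = q,
               description = if (i %% 2L == 0L) sprintf("set %d", seed) else "")
  })
}

make_alignment <- function(n, len, seed) {
  set.seed(seed)
  msa_alignment(lapply(seq_len(n), function(i)
    seq_record(sprintf("tax_%d", i),
               paste(sample(c("A", "C", "G", "T", "-"), len, replace = TRUE),
                     collapse = ""))))
}

# A tiny but representative SAM file: forward read, reverse read,
# secondary alignment, and an unmapped mate without sequence.
write_demo_sam <- function(path) {
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:ref1\tLN:10000",
    "r_fwd\t0\tref1\t100\t60\t4M\t*\t0\t0\tACGT\t!!!I",
    "r_rev\t16\tref1\t200\t60\t4M\t*\t0\t0\tACGT\t!!!I",
    "r_sec\t256\tref1\t300\t60\t4M\t*\t0\t0\tGGGG\tIIII",
    "r_star\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"
  ), path)
  path
}

# Busy-wait mock converter with an invocation counter; used to calibrate
# the benchmark harness without relying on real conversion workloads.
make_mock_spec <- function(d, counter = new.env()) {
  counter$slow <- 0L; counter$fast <- 0L
  busy <- function(seconds) {
    t0 <- proc.time()[["elapsed"]]
    x <- 0
    while (proc.time()[["elapsed"]] - t0 < seconds) x <- x + 1
    invisible(x)
  }
  defs <- list(list(
    name = "mocka2mockb",
    method_fast = function(inputs, outputs, options) {
      counter$fast <- counter$fast + 1L
      busy(d); file.create(outputs)
      list(records_in = 1L, records_out = 1L)
    },
    method_slow = function(inputs, outputs, options) {
      counter$slow <- counter$slow + 1L
      busy(3 * d); file.create(outputs)
      list(records_in = 1L, records_out = 1L)
    }
  ))
  list(spec = discover_converters(defs)[[1]], counter = counter)
}

# Mock converter that allocates a numeric vector of the given length,
# for checking that the peak-memory measure responds to allocations.
make_alloc_spec <- function(n_doubles) {
  discover_converters(list(list(
    name = "mocka2mockb",
    method_alloc = function(inputs, outputs, options) {
      x <- numeric(n_doubles)
      x[1] <- 1
      file.create(outputs)
      list(records_in = 1L, records_out = 1L)
    })))[[1]]
}

# Brute-force shortest-path oracle: enumerate every simple path by DFS,
# keep the minimum-hop ones, break ties lexicographically on the node
# sequence. Independent of the BFS in the package.
brute_force_path <- function(edges, source, target) {
  if (source == target) return(character(0))
  best <- NULL
  recurse <- function(node, path) {
    if (node == target) {
      if (is.null(best) || length(path) < length(best) ||
          (length(path) == length(best) &&
           paste(path, collapse = "\x01") < paste(best, collapse = "\x01")))
        best <<- path
      return(invisible(NULL))
    }
    for (nb in sort(edges[[node]])) {
      if (!nb %in% path) recurse(nb, c(path, nb))
    }
  }
  recurse(source, source)
  best
}

# Random single-port registry over <= 8 nodes; returns the registry and
# the adjacency list used by the oracle.
random_graph_registry <- function(seed) {
  set.seed(seed)
  n <- sample(2:8, 1)
  nodes <- letters[seq_len(n)]
  reg <- new_registry()
  for (nd in nodes)
    register_format(reg, format_descriptor(nd, paste0(".", nd, "x"), "other"))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- pairs[runif(nrow(pairs)) < 0.3, ]
  adj <- setNames(vector("list", n), nodes)
  defs <- lapply(seq_len(nrow(keep)), function(i)
    list(inputs = keep$from[i], outputs = keep$to[i],
         method_noop = function(inputs, outputs, options)
           list(records_in = 0L, records_out = 0L)))
  if (nrow(keep))
    for (spec in discover_converters(defs)) {
      register_converter(reg, spec)
      adj[[spec$inputs]] <- c(adj[[spec$inputs]], spec$outputs)
    }
  list(registry = reg, adj = adj, nodes = nodes)
}
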