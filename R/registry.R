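# Format/converter registry: extension inference, converter discovery,
# the conversion graph and transitive path planning.

#' Describe a file format
#'
#' @param name Short lowercase token, unique per registry (e.g. "fastq").
#' @param extensions Character vector of lowercase filename extensions
#'   beginning with a dot, excluding compression suffixes.
#' @param domain One of "sequencing", "alignment-msa", "read-alignment",
#'   "phylogeny", "annotation", "variant", "other".
#' @param binary Whether the format is binary (e.g. BAM).
#' @return An object of class `format_descriptor`.
#' @export
format_descriptor <- function(name, extensions,
                              domain = c("sequencing", "alignment-msa",
                                         "read-alignment", "phylogeny",
                                         "annotation", "variant", "other"),
                              binary = FALSE) {
  domain <- match.arg(domain)
  if (!is.character(name) || length(name) != 1L || !nzchar(name) ||
      name != tolower(name) || grepl("[[:space:]]", name))
    bc_stop("bc_registration_error", "format name must be a short lowercase token")
  if (length(extensions) == 0L)
    bc_stop("bc_registration_error", "a format needs at least one extension")
  if (any(!startsWith(extensions, ".")) || any(extensions != tolower(extensions)))
    bc_stop("bc_registration_error",
            "extensions must be lowercase and begin with a dot")
  structure(list(name = name, extensions = unique(extensions),
                 domain = domain, binary = isTRUE(binary)),
            class = "format_descriptor")
}

#' Create an empty format/converter registry
#'
#' A registry owns format descriptors, the extension map used by implicit
#' mode, and the registered converters (the edges of the conversion graph).
#'
#' @return An object of class `conversion_registry`.
#' @export
new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$formats <- list()          # name -> format_descriptor
  reg$extensions <- character()  # extension -> format name
  reg$converters <- list()       # name -> converter_spec
  class(reg) <- "conversion_registry"
  reg
}

#' @export
print.conversion_registry <- function(x, ...) {
  cat(sprintf("<conversion_registry: %d formats, %d conversions>\n",
              length(x$formats), length(x$converters)))
  invisible(x)
}

#' Register a format
#'
#' @param registry A [new_registry()].
#' @param descriptor A [format_descriptor()].
#' @return The registry, invisibly.
#' @export
register_format <- function(registry, descriptor) {
  stopifnot(inherits(descriptor, "format_descriptor"))
  if (descriptor$name %in% names(registry$formats))
    bc_stop("bc_registration_error",
            sprintf("format '%s' is already registered", descriptor$name))
  taken <- descriptor$extensions %in% names(registry$extensions)
  if (any(taken)) {
    ext <- descriptor$extensions[taken][1]
    bc_stop("bc_extension_conflict",
            sprintf("extension '%s' requested by format '%s' is already claimed by format '%s'",
                    ext, descriptor$name, registry$extensions[[ext]]))
  }
  registry$formats[[descriptor$name]] <- descriptor
  for (ext in descriptor$extensions) registry$extensions[[ext]] <- descriptor$name
  invisible(registry)
}

#' Look up a format by name or extension
#'
#' @param registry A registry.
#' @param key Format name or extension (with leading dot).
#' @return The `format_descriptor`, or `NULL` when unknown.
#' @export
lookup_format <- function(registry, key) {
  if (key %in% names(registry$formats)) return(registry$formats[[key]])
  if (key %in% names(registry$extensions))
    return(registry$formats[[registry$extensions[[key]]]])
  NULL
}

#' Infer a file's format and compression codec from its name
#'
#' Compression suffixes (`.gz`, `.bz2`) are peeled first, then the
#' remaining final extension is resolved against the registry. The file
#' need not exist.
#'
#' @param path Filename.
#' @param registry A registry (defaults to the built-in one).
#' @return `list(format = <name>, codec = "gzip"/"bzip2"/NA)`.
#' @export
infer_format <- function(path, registry = default_registry()) {
  codec <- codec_of(path)
  stem <- strip_codec(path)
  ext <- tolower(file_ext_dot(stem))
  if (!nzchar(ext) || !(ext %in% names(registry$extensions)))
    bc_stop("bc_unresolvable_extension",
            sprintf("cannot resolve extension '%s' of '%s'; use explicit mode (name the conversion)",
                    ext, path))
  list(format = registry$extensions[[ext]], codec = codec)
}

## ---- Converter specs & discovery ------------------------------------------

converter_name <- function(inputs, outputs) {
  paste0(paste(inputs, collapse = "_"), "2", paste(outputs, collapse = "_"))
}

# Parse an "a_b2c_d" style name into input/output format lists.
parse_converter_name <- function(name) {
  parts <- strsplit(name, "2", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    bc_stop("bc_invalid_converter",
            sprintf("converter name '%s' is not of the form <in>2<out>", name))
  list(inputs = strsplit(parts[1], "_", fixed = TRUE)[[1]],
       outputs = strsplit(parts[2], "_", fixed = TRUE)[[1]])
}

METHOD_PREFIX <- "method_"

#' Build converter specs from plugin definitions
#'
#' A converter definition is a named list declaring `name` (an `A2B`-style
#' token) or explicit `inputs`/`outputs`, and one or more functions whose
#' element names carry the `method_` prefix; the identifier after the
#' prefix is the public method name. A declared `default` is honoured,
#' otherwise the first method in declaration order becomes the default.
#' No per-converter registration code is needed: discovery extracts
#' everything from the definition.
#'
#' @param definitions List of converter definitions.
#' @return List of `converter_spec` objects, in input order.
#' @export
discover_converters <- function(definitions) {
  lapply(definitions, function(def) {
    if (is.null(def$name) && (is.null(def$inputs) || is.null(def$outputs)))
      bc_stop("bc_invalid_converter",
              "converter definition needs a name or explicit inputs/outputs")
    io <- if (!is.null(def$inputs)) list(inputs = def$inputs, outputs = def$outputs)
          else parse_converter_name(def$name)
    name <- converter_name(io$inputs, io$outputs)
    method_idx <- which(startsWith(names(def), METHOD_PREFIX) &
                        vapply(def, is.function, logical(1)))
    if (length(method_idx) == 0L)
      bc_stop("bc_invalid_converter",
              sprintf("converter '%s' declares no '%s'-prefixed methods; at least one is required",
                      name, METHOD_PREFIX))
    methods <- substring(names(def)[method_idx], nchar(METHOD_PREFIX) + 1L)
    default <- if (!is.null(def$default)) def$default else methods[1]
    if (!default %in% methods)
      bc_stop("bc_invalid_converter",
              sprintf("declared default method '%s' of '%s' is not among its methods (%s)",
                      default, name, paste(methods, collapse = ", ")))
    requires_external <- if (is.null(def$external)) character() else def$external
    structure(list(name = name, inputs = io$inputs, outputs = io$outputs,
                   methods = methods, default_method = default,
                   lossy = isTRUE(def$lossy),
                   lossy_warning = def$lossy_warning,
                   requires_external = requires_external,
                   functions = def[method_idx]),
              class = "converter_spec")
  })
}

#' @export
print.converter_spec <- function(x, ...) {
  cat(sprintf("<converter %s: methods [%s], default '%s'%s>\n", x$name,
              paste(x$methods, collapse = ", "), x$default_method,
              if (x$lossy) ", lossy" else ""))
  invisible(x)
}

#' Register a converter spec
#'
#' @param registry A registry whose formats include the spec's endpoints.
#' @param spec A `converter_spec` from [discover_converters()].
#' @return The registry, invisibly.
#' @export
register_converter <- function(registry, spec) {
  stopifnot(inherits(spec, "converter_spec"))
  unknown <- setdiff(c(spec$inputs, spec$outputs), names(registry$formats))
  if (length(unknown))
    bc_stop("bc_registration_error",
            sprintf("converter '%s' references unregistered format(s): %s",
                    spec$name, paste(unknown, collapse = ", ")))
  existing <- registry$converters[[spec$name]]
  if (!is.null(existing) && !identical(existing[c("inputs", "outputs", "methods")],
                                       spec[c("inputs", "outputs", "methods")]))
    bc_stop("bc_registration_error",
            sprintf("a different converter named '%s' is already registered", spec$name))
  registry$converters[[spec$name]] <- spec
  invisible(registry)
}

#' Resolve a conversion from input/output filenames (implicit mode)
#'
#' @param input_paths,output_paths Filenames whose extensions determine
#'   the conversion.
#' @param registry A registry.
#' @return The matching `converter_spec`.
#' @export
resolve_conversion <- function(input_paths, output_paths,
                               registry = default_registry()) {
  ins <- vapply(input_paths, function(p) infer_format(p, registry)$format, character(1))
  outs <- vapply(output_paths, function(p) infer_format(p, registry)$format, character(1))
  name <- converter_name(ins, outs)
  spec <- registry$converters[[name]]
  if (is.null(spec)) {
    hint <- ""
    if (length(ins) == 1L && length(outs) == 1L) {
      plan <- tryCatch(find_path(ins, outs, registry), bioconvr_error = function(e) NULL)
      if (!is.null(plan) && length(plan$steps) > 0L)
        hint <- sprintf("; a transitive path exists: %s",
                        paste(vapply(plan$steps, `[[`, character(1), "name"),
                              collapse = " -> "))
    }
    bc_stop("bc_no_converter",
            sprintf("no registered conversion '%s'%s", name, hint))
  }
  spec
}

## ---- Conversion graph ------------------------------------------------------

# Single-port edges only (hyperedges are excluded from transitive search).
simple_edges <- function(registry) {
  specs <- Filter(function(s) length(s$inputs) == 1L && length(s$outputs) == 1L,
                  registry$converters)
  specs[order(vapply(specs, `[[`, character(1), "name"))]
}

#' Find a minimum-hop conversion plan between two formats
#'
#' Searches the conversion graph restricted to single-input/single-output
#' edges. Ties between equally short paths are broken by the
#' lexicographically smallest sequence of intermediate format names, so
#' the plan is deterministic across runs and platforms. The plan is lossy
#' when any step is lossy.
#'
#' @param source,target Registered format names.
#' @param registry A registry.
#' @return An object of class `conversion_plan` with elements `steps`
#'   (list of converter specs; empty when `source == target`) and `lossy`.
#' @export
find_path <- function(source, target, registry = default_registry()) {
  for (f in c(source, target))
    if (!f %in% names(registry$formats))
      bc_stop("bc_no_path", sprintf("format '%s' is not registered", f))
  if (source == target)
    return(structure(list(steps = list(), lossy = FALSE), class = "conversion_plan"))

  edges <- simple_edges(registry)
  adj <- list()  # from-format -> character vector of to-formats (sorted)
  edge_by_pair <- list()
  for (s in edges) {
    adj[[s$inputs]] <- sort(unique(c(adj[[s$inputs]], s$outputs)))
    edge_by_pair[[paste(s$inputs, s$outputs)]] <- s
  }
  # BFS over format names; expanding neighbours in sorted order while
  # recording the first (hence lexicographically smallest) predecessor
  # path per node yields the lexicographically smallest shortest path.
  best_path <- list(); best_path[[source]] <- source
  frontier <- source
  while (length(frontier) > 0L && is.null(best_path[[target]])) {
    nxt <- character()
    # expand in order of the current best path strings to keep lexicographic ties right
    frontier <- frontier[order(vapply(frontier, function(n)
      paste(best_path[[n]], collapse = "\x01"), character(1)))]
    for (node in frontier) {
      for (nb in adj[[node]]) {
        if (is.null(best_path[[nb]])) {
          best_path[[nb]] <- c(best_path[[node]], nb)
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  path <- best_path[[target]]
  if (is.null(path))
    bc_stop("bc_no_path",
            sprintf("no conversion path from '%s' to '%s'", source, target))
  steps <- lapply(seq_len(length(path) - 1L), function(i)
    edge_by_pair[[paste(path[i], path[i + 1L])]])
  structure(list(steps = steps,
                 lossy = any(vapply(steps, `[[`, logical(1), "lossy"))),
            class = "conversion_plan")
}

#' @export
print.conversion_plan <- function(x, ...) {
  if (length(x$steps) == 0L) cat("<conversion_plan: identity>\n")
  else cat(sprintf("<conversion_plan: %s%s>\n",
                   paste(vapply(x$steps, `[[`, character(1), "name"), collapse = " -> "),
                   if (x$lossy) " (lossy)" else ""))
  invisible(x)
}

#' Export the conversion graph in DOT syntax
#'
#' Nodes are formats; single-port converters become directed edges;
#' multi-port converters ("logical gates") are rendered through an
#' anonymous point-shaped junction node. With `annotate = TRUE` nodes are
#' coloured by domain and sized by degree.
#'
#' @param registry A registry.
#' @param sink Writable text connection or filename.
#' @param annotate Add domain colours and degree-based styling.
#' @return Invisibly, the DOT lines written.
#' @export
export_graph <- function(registry = default_registry(), sink = stdout(),
                         annotate = FALSE) {
  domain_colour <- c(sequencing = "lightblue", "alignment-msa" = "palegreen",
                     "read-alignment" = "khaki", phylogeny = "plum",
                     annotation = "salmon", variant = "orange", other = "white")
  degree <- integer(0)
  for (s in registry$converters)
    for (f in c(s$inputs, s$outputs))
      degree[f] <- (if (is.na(degree[f])) 0L else degree[f]) + 1L

  lines <- c("digraph conversions {")
  for (f in names(registry$formats)) {
    if (annotate) {
      col <- domain_colour[[registry$formats[[f]]$domain]]
      deg <- if (f %in% names(degree)) degree[[f]] else 0L
      lines <- c(lines, sprintf(
        "  \"%s\" [style=filled, fillcolor=%s, penwidth=%d];", f, col, 1L + deg))
    } else {
      lines <- c(lines, sprintf("  \"%s\";", f))
    }
  }
  gate_i <- 0L
  for (s in registry$converters) {
    if (length(s$inputs) == 1L && length(s$outputs) == 1L) {
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                                s$inputs, s$outputs, s$name))
    } else {
      gate_i <- gate_i + 1L
      gate <- sprintf("gate%d", gate_i)
      lines <- c(lines, sprintf("  \"%s\" [shape=point, label=\"\"];", gate))
      for (f in s$inputs) lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", f, gate))
      for (f in s$outputs) lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", gate, f))
    }
  }
  lines <- c(lines, "}")
  if (inherits(sink, "connection")) writeLines(lines, sink)
  else writeLines(lines, con = sink)
  invisible(lines)
}

#' Dump the registry as TSV
#'
#' `registry_formats_tsv()` lists format name, comma-joined extensions and
#' domain; `registry_conversions_tsv()` lists conversion name, inputs,
#' outputs, methods and default method.
#'
#' @param registry A registry.
#' @return A data.frame (written with [utils::write.table()] if `sink` given).
#' @export
registry_formats_tsv <- function(registry = default_registry()) {
  fs <- registry$formats[order(names(registry$formats))]
  data.frame(
    format = vapply(fs, `[[`, character(1), "name"),
    extensions = vapply(fs, function(f) paste(f$extensions, collapse = ","), character(1)),
    domain = vapply(fs, `[[`, character(1), "domain"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname registry_formats_tsv
#' @export
registry_conversions_tsv <- function(registry = default_registry()) {
  cs <- registry$converters[order(names(registry$converters))]
  data.frame(
    conversion = vapply(cs, `[[`, character(1), "name"),
    inputs = vapply(cs, function(s) paste(s$inputs, collapse = ","), character(1)),
    outputs = vapply(cs, function(s) paste(s$outputs, collapse = ","), character(1)),
    methods = vapply(cs, function(s) paste(s$methods, collapse = ","), character(1)),
    default = vapply(cs, `[[`, character(1), "default_method"),
    row.names = NULL, stringsAsFactors = FALSE)
}
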