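# Structured conditions: every error raised by the package carries a
# specific class under the common "bioconvr_error" class so callers (and
# the CLI) can react without parsing messages.

bc_stop <- function(class, msg, ..., call. = sys.call(-1)) {
  cond <- structure(
    class = c(class, "bioconvr_error", "error", "condition"),
    list(message = msg, call = call., ...)
  )
  stop(cond)
}

# Parse errors carry the 1-based line number where the problem was found.
bc_parse_error <- function(msg, line = NA_integer_, format = NA_character_) {
  bc_stop("bc_parse_error",
          sprintf("%s [%s, line %s]", msg, format, line),
          line = line, format = format, call. = sys.call(-2))
}
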