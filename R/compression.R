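# Transparent compressed I/O. Every reader/writer in the package opens
# files through open_auto(), so downstream code never sees a codec.

CODEC_EXTENSIONS <- c(".gz" = "gzip", ".bz2" = "bzip2")

#' Detect the compression codec implied by a filename
#'
#' Only the final suffix is examined; `reads.fq.gz` is gzip, `reads.fq`
#' is plain.
#'
#' @param path Filename (the file need not exist).
#' @return `"gzip"`, `"bzip2"`, or `NA_character_` for plain files.
#' @export
codec_of <- function(path) {
  ext <- tolower(file_ext_dot(path))
  if (ext %in% names(CODEC_EXTENSIONS)) unname(CODEC_EXTENSIONS[ext]) else NA_character_
}

# Final ".ext" of a filename including the dot ("" when none).
file_ext_dot <- function(path) {
  base <- basename(path)
  m <- regmatches(base, regexpr("\\.[^.]*$", base))
  if (length(m) == 0L) "" else m
}

# Strip a single codec suffix if present.
strip_codec <- function(path) {
  if (!is.na(codec_of(path))) sub("\\.[^.]*$", "", path) else path
}

#' Open a file with codec auto-detection
#'
#' Returns an open text-mode connection that decompresses on read or
#' compresses on write according to the filename's final suffix
#' (`.gz` = gzip, `.bz2` = bzip2, anything else plain). On read, the
#' file's magic bytes are checked against the promised codec so that a
#' mislabelled file fails immediately rather than downstream.
#'
#' @param path Filename.
#' @param mode `"read"` or `"write"`.
#' @return An open connection; the caller is responsible for closing it.
#' @export
open_auto <- function(path, mode = c("read", "write")) {
  mode <- match.arg(mode)
  codec <- codec_of(path)
  if (mode == "read") {
    if (!file.exists(path))
      bc_stop("bc_io_error", sprintf("input file does not exist: %s", path))
    if (!is.na(codec)) check_magic(path, codec)
    con <- switch(ifelse(is.na(codec), "plain", codec),
                  gzip  = gzfile(path, "rt"),
                  bzip2 = bzfile(path, "rt"),
                  plain = file(path, "rt"))
  } else {
    con <- switch(ifelse(is.na(codec), "plain", codec),
                  gzip  = gzfile(path, "wt"),
                  bzip2 = bzfile(path, "wt"),
                  plain = file(path, "wt"))
  }
  con
}

check_magic <- function(path, codec) {
  magic <- readBin(path, "raw", n = 3L)
  ok <- switch(codec,
               gzip  = length(magic) >= 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b),
               bzip2 = length(magic) >= 3L && rawToChar(magic) == "BZh")
  if (!ok)
    bc_stop("bc_codec_error",
            sprintf("extension of '%s' promises %s but the content is not %s-compressed",
                    path, codec, codec))
  invisible(TRUE)
}

# Resolve a path-or-connection argument to an open connection.
# Returns list(con =, close =): close is TRUE when we opened it here.
as_input_con <- function(source) {
  if (inherits(source, "connection")) list(con = source, close = FALSE)
  else list(con = open_auto(source, "read"), close = TRUE)
}

as_output_con <- function(sink) {
  if (inherits(sink, "connection")) list(con = sink, close = FALSE)
  else list(con = open_auto(sink, "write"), close = TRUE)
}
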