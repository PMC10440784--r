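# Benchmarking harness: times competing methods of a converter.
# Single mode runs every method N times (default 5) and reports mean and
# standard deviation; multi mode repeats the single mode M times and keeps
# one median wall-time per round per method.

#' Benchmark configuration
#'
#' @param repeats Number of runs per method within one single-mode
#'   benchmark (N; default 5).
#' @param multi_rounds Number of single-mode rounds in multi mode (M;
#'   default 10).
#' @param include_methods Optional subset of method names to benchmark.
#' @param measure Which measures to record, subset of
#'   `c("wall", "cpu", "memory")`.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(repeats = 5L, multi_rounds = 10L,
                             include_methods = NULL,
                             measure = c("wall", "cpu", "memory")) {
  repeats <- as.integer(repeats); multi_rounds <- as.integer(multi_rounds)
  if (is.na(repeats) || repeats < 1L)
    bc_stop("bc_usage_error", "repeats (N) must be an integer >= 1")
  if (is.na(multi_rounds) || multi_rounds < 1L)
    bc_stop("bc_usage_error", "multi_rounds (M) must be an integer >= 1")
  measure <- match.arg(measure, several.ok = TRUE)
  structure(list(repeats = repeats, multi_rounds = multi_rounds,
                 include_methods = include_methods, measure = measure),
            class = "benchmark_config")
}

# One timed execution. Wall time from the monotonic elapsed clock of
# proc.time(); CPU = user + system (including child processes, so external
# methods are charged fairly); memory = peak R allocation during the run,
# from gc(reset = TRUE) "max used" — a single number per run that grows
# monotonically with added allocations.
timed_run <- function(fn) {
  invisible(gc(reset = TRUE, full = FALSE))
  p0 <- proc.time()
  fn()
  p1 <- proc.time()
  g <- gc(full = FALSE)
  mem_bytes <- sum(g[, "max used"] * c(56, 8))  # Ncells, Vcells cell sizes
  cpu <- sum(p1[c("user.self", "sys.self", "user.child", "sys.child")] -
             p0[c("user.self", "sys.self", "user.child", "sys.child")], na.rm = TRUE)
  list(wall = unname(p1[["elapsed"]] - p0[["elapsed"]]),
       cpu = unname(cpu), memory = mem_bytes)
}

runnable_methods <- function(spec, config, options = list()) {
  methods <- spec$methods
  if (!is.null(config$include_methods)) {
    methods <- intersect(methods, config$include_methods)
    if (length(methods) == 0L)
      bc_stop("bc_usage_error",
              sprintf("include_methods excludes every method of '%s'", spec$name))
  }
  skipped <- character()
  for (m in methods) {
    binary <- external_binary_for(spec, m, options)
    if (!is.null(binary) && Sys.which(binary) == "")
      skipped <- c(skipped, m)
  }
  list(run = setdiff(methods, skipped), skipped = skipped)
}

#' Single-mode benchmark of a converter
#'
#' Runs every (runnable) method of `spec` `config$repeats` times on
#' identical inputs, writing outputs to throwaway paths, and summarises
#' wall-clock, CPU and peak-memory per method. External methods whose
#' binary is absent are reported as skipped, not failed; a method that
#' raises a conversion error is marked failed without affecting the rest.
#'
#' @param spec A `converter_spec` or registered conversion name.
#' @param inputs Input path(s) for the conversion.
#' @param config A [benchmark_config()].
#' @param options,registry As in [convert()].
#' @return An object of class `benchmark_summary`: per method, raw
#'   measurement vectors of length N plus mean/sd/min/max per measure
#'   (sd uses the n-1 denominator).
#' @export
run_single <- function(spec, inputs, config = benchmark_config(),
                       options = list(), registry = default_registry()) {
  if (is.character(spec)) spec <- registry$converters[[spec]]
  stopifnot(inherits(spec, "converter_spec"))
  avail <- runnable_methods(spec, config, options)
  results <- list()
  for (m in avail$run) {
    runs <- list(wall = numeric(0), cpu = numeric(0), memory = numeric(0))
    failed <- NULL
    for (i in seq_len(config$repeats)) {
      outs <- vapply(spec$outputs, function(fmt)
        tempfile(fileext = paste0(".", sub("^\\.", "", default_extension(fmt, registry)))),
        character(1))
      r <- tryCatch(
        timed_run(function() suppressWarnings(
          convert(spec, inputs, outs, method = m, options = options,
                  registry = registry))),
        bioconvr_error = function(e) e)
      unlink(outs)
      if (inherits(r, "bioconvr_error")) { failed <- conditionMessage(r); break }
      for (meas in names(runs)) runs[[meas]] <- c(runs[[meas]], r[[meas]])
    }
    results[[m]] <- if (is.null(failed)) {
      stats <- lapply(runs[config$measure], function(v)
        list(values = v, mean = mean(v),
             sd = if (length(v) > 1L) stats::sd(v) else 0,
             min = min(v), max = max(v)))
      list(status = "ok", measures = stats)
    } else list(status = "failed", error = failed)
  }
  structure(list(spec_name = spec$name, repeats = config$repeats,
                 methods = results, skipped = avail$skipped),
            class = "benchmark_summary")
}

default_extension <- function(format, registry = default_registry()) {
  fd <- registry$formats[[format]]
  if (is.null(fd)) paste0(".", format) else fd$extensions[1]
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("<benchmark %s: N = %d>\n", x$spec_name, x$repeats))
  for (m in names(x$methods)) {
    r <- x$methods[[m]]
    if (r$status == "ok") {
      w <- r$measures$wall
      cat(sprintf("  %-12s wall %.4fs +/- %.4fs\n", m, w$mean, w$sd))
    } else cat(sprintf("  %-12s FAILED: %s\n", m, r$error))
  }
  if (length(x$skipped))
    cat(sprintf("  skipped (missing binary): %s\n", paste(x$skipped, collapse = ", ")))
  invisible(x)
}

#' Multi-mode benchmark
#'
#' Repeats the single-mode benchmark `config$multi_rounds` times and
#' keeps, per method and per round, the median wall time across the N
#' runs of that round — a robust estimate of each method's run time.
#'
#' @inheritParams run_single
#' @return An object of class `multi_benchmark`: per method, a vector of
#'   M medians.
#' @export
run_multi <- function(spec, inputs, config = benchmark_config(),
                      options = list(), registry = default_registry()) {
  if (is.character(spec)) spec <- registry$converters[[spec]]
  medians <- list()
  for (round in seq_len(config$multi_rounds)) {
    s <- run_single(spec, inputs, config, options, registry)
    for (m in names(s$methods)) {
      r <- s$methods[[m]]
      med <- if (r$status == "ok") stats::median(r$measures$wall$values) else NA_real_
      medians[[m]] <- c(medians[[m]], med)
    }
  }
  structure(list(spec_name = spec$name, rounds = config$multi_rounds,
                 repeats = config$repeats, medians = medians),
            class = "multi_benchmark")
}

#' @export
print.multi_benchmark <- function(x, ...) {
  cat(sprintf("<multi-benchmark %s: M = %d rounds of N = %d>\n",
              x$spec_name, x$rounds, x$repeats))
  for (m in names(x$medians))
    cat(sprintf("  %-12s median-of-medians %.4fs\n", m,
                stats::median(x$medians[[m]])))
  invisible(x)
}

#' Write a benchmark report
#'
#' TSV is the canonical output: one row per (method, measure, run) with
#' the raw value, followed by summary rows (mean/sd/min/max). For a
#' multi-mode result, one row per (method, round) median. With
#' `as_image = TRUE` a plot is also written: bars with standard-deviation
#' error bars (single mode) or one box per method (multi mode).
#'
#' @param x A `benchmark_summary` or `multi_benchmark`.
#' @param sink Path of the TSV to write.
#' @param as_image Also write a plot.
#' @param image_path Path of the image (PNG); defaults to `sink` with a
#'   .png extension.
#' @return `sink`, invisibly.
#' @export
benchmark_report <- function(x, sink, as_image = FALSE, image_path = NULL) {
  rows <- benchmark_report_rows(x)
  utils::write.table(rows, sink, sep = "\t", quote = FALSE, row.names = FALSE)
  if (as_image) {
    if (is.null(image_path)) image_path <- paste0(sub("\\.tsv$", "", sink), ".png")
    grDevices::png(image_path, width = 800, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    benchmark_plot(x)
  }
  invisible(sink)
}

benchmark_report_rows <- function(x) {
  if (inherits(x, "benchmark_summary")) {
    rows <- list()
    for (m in names(x$methods)) {
      r <- x$methods[[m]]
      if (r$status != "ok") {
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, measure = "status", run = "failed", value = NA_real_)
        next
      }
      for (meas in names(r$measures)) {
        st <- r$measures[[meas]]
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, measure = meas, run = as.character(seq_along(st$values)),
          value = st$values)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, measure = meas, run = c("mean", "sd", "min", "max"),
          value = c(st$mean, st$sd, st$min, st$max))
      }
    }
    do.call(rbind, rows)
  } else {
    rows <- lapply(names(x$medians), function(m)
      data.frame(method = m, measure = "wall_median",
                 run = as.character(seq_along(x$medians[[m]])),
                 value = x$medians[[m]]))
    do.call(rbind, rows)
  }
}

benchmark_plot <- function(x) {
  if (inherits(x, "benchmark_summary")) {
    ok <- Filter(function(r) r$status == "ok", x$methods)
    means <- vapply(ok, function(r) r$measures$wall$mean, numeric(1))
    sds <- vapply(ok, function(r) r$measures$wall$sd, numeric(1))
    mids <- graphics::barplot(means, names.arg = names(ok),
                              ylab = "wall time (s)",
                              main = sprintf("%s (N = %d)", x$spec_name, x$repeats),
                              ylim = c(0, max(means + sds, 1e-6) * 1.2))
    has_sd <- sds > 0
    if (any(has_sd))
      graphics::arrows(mids[has_sd], (means - sds)[has_sd],
                       mids[has_sd], (means + sds)[has_sd],
                       angle = 90, code = 3, length = 0.05)
  } else {
    graphics::boxplot(x$medians, ylab = "median wall time per round (s)",
                      main = sprintf("%s (M = %d, N = %d)",
                                     x$spec_name, x$rounds, x$repeats))
  }
  invisible(NULL)
}
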