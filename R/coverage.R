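# Lightweight statement-coverage tracker used by the package's QA suite.
# It rewrites function bodies so that every statement increments a hit
# counter, temporarily installs the instrumented functions into a
# namespace, and reports the fraction of statements executed. It knows
# nothing about the code it instruments and is excluded from its own
# measurements.

cov_state <- new.env(parent = emptyenv())

cov_hit <- function(id) {
  cov_state$hits[[id]] <- TRUE
  invisible(NULL)
}

# Recursively instrument an expression. Returns the instrumented
# expression; registers one id per counted statement.
cov_instrument_expr <- function(expr, prefix) {
  count <- 0L
  register <- function() {
    count <<- count + 1L
    id <- sprintf("%s#%d", prefix, count)
    cov_state$total <- c(cov_state$total, id)
    id
  }
  walk <- function(e) {
    if (!is.call(e)) return(e)
    head <- as.character(e[[1]])[1]
    if (head == "{") {
      if (length(e) == 1L) return(e)
      for (i in 2:length(e)) {
        inner <- walk(e[[i]])
        id <- register()
        e[[i]] <- call("{", call("cov_hit", id), inner)
      }
      return(e)
    }
    if (head == "if") {
      e[[2]] <- walk(e[[2]])
      e[[3]] <- walk_block(e[[3]])
      if (length(e) == 4L) e[[4]] <- walk_block(e[[4]])
      return(e)
    }
    if (head == "for") { e[[4]] <- walk_block(e[[4]]); return(e) }
    if (head %in% c("while", "repeat")) {
      e[[length(e)]] <- walk_block(e[[length(e)]])
      return(e)
    }
    if (head == "function") {
      e[[3]] <- walk_block(e[[3]])
      return(e)
    }
    # instrument function-literal arguments (e.g. callbacks) in ordinary
    # calls; tryCatch guards against empty args like switch(x, a = , b = 1)
    if (length(e) > 1L) {
      for (i in 2:length(e)) {
        is_fn_literal <- tryCatch({
          arg <- e[[i]]
          is.call(arg) && as.character(arg[[1]])[1] == "function"
        }, error = function(err) FALSE)
        if (is_fn_literal) e[[i]] <- walk(e[[i]])
      }
    }
    e
  }
  walk_block <- function(e) {
    # ensure single-expression bodies are counted too
    if (is.call(e) && as.character(e[[1]])[1] == "{") return(walk(e))
    walk(call("{", e))
  }
  walk(expr)
}

cov_instrument_function <- function(fn, name) {
  body(fn) <- cov_instrument_expr(call("{", body(fn)), name)
  fn
}

#' Start statement-coverage tracking of a package namespace
#'
#' Every function in the namespace (except this tracker's own functions)
#' is replaced by an instrumented copy that records which statements
#' execute. Call [cov_report()] to read the result and [cov_stop()] to
#' restore the original functions.
#'
#' @param package Package name.
#' @param exclude Regular expression of function names to leave alone.
#' @param sync_from Environment whose lookup chain is also updated, so
#'   that callers holding copies of the package's bindings (e.g. a test
#'   harness evaluating code against a snapshot of the namespace) run the
#'   instrumented versions too. Defaults to the caller's environment.
#' @return Invisibly, the number of functions instrumented.
#' @export
cov_start <- function(package,
                      exclude = "^cov_|^bc_stop$|^bc_parse_error$|^replace_binding$",
                      sync_from = parent.frame()) {
  ns <- asNamespace(package)
  cov_state$hits <- new.env(parent = emptyenv())
  cov_state$total <- character()
  cov_state$originals <- list()
  cov_state$synced <- list()
  cov_state$package <- package
  fns <- ls(ns, all.names = TRUE)
  instrumented <- list()
  n <- 0L
  for (nm in fns) {
    if (grepl(exclude, nm)) next
    obj <- get(nm, envir = ns)
    if (!is.function(obj) || is.primitive(obj)) next
    cov_state$originals[[nm]] <- obj
    inst <- tryCatch(cov_instrument_function(obj, nm), error = function(e) NULL)
    if (is.null(inst)) { cov_state$originals[[nm]] <- NULL; next }
    environment(inst) <- environment(obj)
    replace_binding(nm, inst, ns)
    instrumented[[nm]] <- inst
    n <- n + 1L
  }
  sync_lookup_chain(sync_from, ns, instrumented)
  invisible(n)
}

# Walk the lookup chain from `env`, replacing any binding that still holds
# an original (pre-instrumentation) copy of a package function. Records
# what was replaced so cov_stop() can undo it.
sync_lookup_chain <- function(env, ns, instrumented) {
  seen <- 0L
  while (!identical(env, emptyenv()) && !identical(env, baseenv()) &&
         seen < 50L) {
    if (!identical(env, ns)) {
      for (nm in names(instrumented)) {
        if (exists(nm, envir = env, inherits = FALSE)) {
          cur <- get(nm, envir = env)
          if (identical(cur, cov_state$originals[[nm]])) {
            locked <- bindingIsLocked(nm, env)
            if (locked) unlockBinding(nm, env)
            assign(nm, instrumented[[nm]], envir = env)
            if (locked) lockBinding(nm, env)
            cov_state$synced[[length(cov_state$synced) + 1L]] <-
              list(env = env, name = nm)
          }
        }
      }
    }
    env <- parent.env(env)
    seen <- seen + 1L
  }
  invisible(NULL)
}

replace_binding <- function(name, value, ns) {
  if (bindingIsLocked(name, ns)) {
    unlockBinding(name, ns)
    assign(name, value, envir = ns)
    lockBinding(name, ns)
  } else assign(name, value, envir = ns)
  # keep the attached copy (if any) in sync so top-level calls are counted
  pkgenv <- paste0("package:", cov_state$package)
  if (pkgenv %in% search()) {
    env <- as.environment(pkgenv)
    if (exists(name, envir = env, inherits = FALSE)) {
      if (bindingIsLocked(name, env)) {
        unlockBinding(name, env)
        assign(name, value, envir = env)
        lockBinding(name, env)
      } else assign(name, value, envir = env)
    }
  }
  # S3 methods dispatch through the registration table, not the binding
  s3 <- ns$.__NAMESPACE__.$S3methods
  if (!is.null(s3) && name %in% paste(s3[, 1], s3[, 2], sep = ".")) {
    tbl <- ns$.__S3MethodsTable__.
    if (!is.null(tbl) && exists(name, envir = tbl, inherits = FALSE))
      assign(name, value, envir = tbl)
  }
  invisible(NULL)
}

#' Report statement coverage
#'
#' @param by_function Return a per-function breakdown instead of the
#'   overall summary.
#' @return A list with `hit`, `total` and `percent`, or a data.frame of
#'   per-function counts when `by_function = TRUE`.
#' @export
cov_report <- function(by_function = FALSE) {
  total <- cov_state$total
  hit_ids <- ls(cov_state$hits, all.names = TRUE)
  if (!by_function)
    return(list(hit = length(hit_ids), total = length(total),
                percent = if (length(total)) 100 * length(hit_ids) / length(total)
                          else NA_real_))
  fn_of <- function(ids) sub("#\\d+$", "", ids)
  tot <- table(fn_of(total))
  hit <- table(factor(fn_of(hit_ids), levels = names(tot)))
  df <- data.frame(fn = names(tot), total = as.integer(tot),
                   hit = as.integer(hit), stringsAsFactors = FALSE)
  df$percent <- 100 * df$hit / df$total
  df[order(df$percent, df$fn), ]
}

#' Stop coverage tracking and restore original functions
#'
#' @return Invisibly, the final [cov_report()] summary.
#' @export
cov_stop <- function() {
  ns <- asNamespace(cov_state$package)
  for (nm in names(cov_state$originals))
    replace_binding(nm, cov_state$originals[[nm]], ns)
  for (s in cov_state$synced) {
    locked <- bindingIsLocked(s$name, s$env)
    if (locked) unlockBinding(s$name, s$env)
    assign(s$name, cov_state$originals[[s$name]], envir = s$env)
    if (locked) lockBinding(s$name, s$env)
  }
  report <- cov_report()
  cov_state$originals <- list()
  cov_state$synced <- list()
  invisible(report)
}
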