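## Internal helpers: classed conditions, ids, deterministic RNG scope.

# Raise a classed error condition. `class` is the machine-readable code tests
# and callers dispatch on (e.g. "IllegalChildKind"); extra fields travel in
# the condition object.
xr_abort <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "expgraph_error")))
}

slugify <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical JSON used wherever byte-identical output is promised.
canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
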