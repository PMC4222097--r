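# Internal helpers shared across modules.

# Structured errors: every user-facing failure carries a condition class so
# callers (and the CLI) can react without matching message text.
maex_error <- function(msg, class = "maex_error", call. = FALSE) {
  cond <- errorCondition(msg, class = c(class, "maex_error"))
  stop(cond)
}

maex_log <- function(fmt, ..., stage = NULL) {
  prefix <- if (is.null(stage)) "" else sprintf("[%s] ", stage)
  message(prefix, sprintf(fmt, ...))
}

# Run code under a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) {
    maex_error(sprintf("file not found: %s", path), "maex_io_error")
  }
  sub("\r$", "", readLines(path, warn = FALSE, encoding = "UTF-8"))
}

# Numbers are serialized at full double precision so that written trees
# round-trip well below the 1e-9 tolerances used downstream.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

center_fun <- function(center) {
  switch(center,
    mean   = function(x) mean(x, na.rm = TRUE),
    median = function(x) stats::median(x, na.rm = TRUE),
    maex_error(sprintf("unknown center '%s' (use 'mean' or 'median')", center),
               "maex_config_error")
  )
}

match_enum <- function(value, choices, what) {
  if (!is.character(value) || length(value) != 1L || !value %in% choices) {
    maex_error(sprintf("%s must be one of: %s", what,
                       paste(choices, collapse = ", ")),
               "maex_config_error")
  }
  value
}
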