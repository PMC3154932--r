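# internal helpers: seeding, logging, atomic writes

# Run `expr` under a given seed without disturbing the caller's RNG state.
# `seed = NULL` leaves the current RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Split one master seed into named independent sub-seeds (< 2^31).
split_seed <- function(seed, names) {
  if (is.null(seed)) return(setNames(vector("list", length(names)), names))
  s <- with_seed(seed, sample.int(.Machine$integer.max, length(names)))
  setNames(as.list(s), names)
}

qn_log_level <- function() {
  lev <- getOption("quantnet.log_level", "warn")
  match(lev, c("debug", "info", "warn", "quiet"), nomatch = 3L)
}

qn_log <- function(level = "info", ...) {
  want <- match(level, c("debug", "info", "warn", "quiet"), nomatch = 2L)
  if (want >= qn_log_level())
    message(sprintf("[quantnet %s] ", level), ...)
  invisible(NULL)
}

# Atomic write: write to a sibling temp file, then rename into place, so an
# interrupted run never leaves a truncated artifact.
atomic_write_lines <- function(lines, path) {
  dir <- dirname(path)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."), tmpdir = dir)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# 17 significant digits: enough to round-trip an IEEE double through text.
fmt_num <- function(x) formatC(x, digits = 17, format = "g")

check_finite_numeric <- function(x, what = "values") {
  if (!is.numeric(x)) stop(sprintf("%s must be numeric", what), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("%s contain non-finite entries", what), call. = FALSE)
  invisible(x)
}
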