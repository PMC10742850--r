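# Internal helpers shared across modules.

# All package errors carry class "extrurtd_error" plus a specific subclass,
# so the CLI and tests can react to the condition type rather than the text.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "extrurtd_error")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current stream" (no save/restore).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name),
          "extrurtd_domain_error")
  }
  bad_lo <- if (strict_lower) x <= lower else x < lower
  bad_hi <- if (strict_upper) x >= upper else x > upper
  if (bad_lo || bad_hi) {
    abort(sprintf("`%s` = %g is outside its valid range", name, x),
          "extrurtd_domain_error")
  }
  x
}

# Write `lines`/data atomically: a writer callback fills a temp file in the
# destination directory, which is then renamed over `path`.
write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
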