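# Internal helpers shared across modules.

# Classed conditions so callers/tests can distinguish malformed files
# (format), inconsistent study designs (design), bad configuration (config)
# and runtime failures.
cdeg_stop <- function(msg, class = "cdeg_runtime_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "cdeg_error")))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

geometric_mean <- function(x) {
  exp(mean(log(x)))
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation calls do not perturb the session stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Derive a stage seed from a run seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% .Machine$integer.max)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
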