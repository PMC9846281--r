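# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers (and the command-line wrapper) can map
# failure classes to distinct exit codes.
mc_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("mitochar_", class, "_error"),
                                     "mitochar_error"),
                      call = call))
}

is_dna_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

# Reverse complement on plain character strings (A/C/G/T/N and gaps).
revcomp <- function(s) {
  stopifnot(is_dna_string(s))
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(s, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                     collapse = ""), "", USE.NAMES = FALSE))
}

# Run code under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Atomic file write: emit to a temp file in the target directory, then rename,
# so no partial report is left behind on failure.
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  file.rename(tmp, path)
  ok <- TRUE
  invisible(path)
}

write_tsv <- function(df, path) {
  write_atomic(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }, path)
}

write_json_report <- function(x, path) {
  write_atomic(function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }, path)
}
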