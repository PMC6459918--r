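## Internal helpers shared across modules.

# Reverse complement of an upper-case DNA string (A/C/G/T/N).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable 32-bit-safe integer hash of a string, used to derive per-stage
# seeds from one pipeline seed.  Horner scheme mod (2^31 - 1).
hash_seed <- function(seed, name) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% m
  as.integer(h)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# Validate a genome set: named character vector, upper-case A/C/G/T/N.
check_genomes <- function(genomes) {
  if (!is.character(genomes) || length(genomes) == 0)
    stop_fmt("genomes must be a non-empty named character vector")
  ids <- names(genomes)
  if (is.null(ids) || any(!nzchar(ids)))
    stop_fmt("every genome sequence must have a non-empty name")
  if (anyDuplicated(ids))
    stop_fmt("duplicate genome ids: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- grepl("[^ACGTN]", genomes)
  if (any(bad))
    stop_fmt("genome '%s' contains characters outside {A,C,G,T,N}",
             ids[which(bad)[1]])
  invisible(genomes)
}
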