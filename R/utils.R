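# RNA alphabet used internally everywhere; FASTA I/O converts T <-> U.
RNA_BASES <- c("A", "C", "G", "U")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed0 <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

# iid-uniform RNA string(s)
random_rna <- function(len) {
  vapply(len, function(l) {
    paste(sample(RNA_BASES, l, replace = TRUE), collapse = "")
  }, character(1))
}

# number of mismatching positions between two equal-length strings
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# positions (1-based) where two equal-length strings differ
mismatch_positions <- function(a, b) {
  which(charToRaw(a) != charToRaw(b))
}

assert_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-ACGU characters (first offender: '%s')",
                  what, x[bad][1]))
  }
  invisible(x)
}

dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))
rna_to_dna <- function(x) chartr("U", "T", toupper(x))

# stable site identifier used across the site table / ratio matrix / outputs
site_id <- function(target_id, position, pattern) {
  paste(target_id, position, pattern, sep = "|")
}
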