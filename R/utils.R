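# Internal sequence helpers. All coordinates inside the package are 0-based
# half-open; T and U are the same base (libraries are DNA-sequenced RNA).

# Normalise a nucleotide string for comparisons: upper case, U -> T.
dna_norm <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# Reverse each string in a character vector.
str_rev <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Reverse complement on T-normalised sequences.
revcomp <- function(x) str_rev(chartr("ACGTN", "TGCAN", dna_norm(x)))

# Split a string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Random nucleotide string(s).
random_seq <- function(n_len) {
  paste(sample(c("A", "C", "G", "T"), n_len, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stage-tagged condition helpers so pipeline failures name their stage.
saltmir_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
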