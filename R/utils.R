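# small internal helpers shared across modules

# reverse complement of one or more DNA strings (keeps non-ACGT as IUPAC)
revcomp <- function(x) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# one string -> character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# fraction of positions that are not unambiguous bases
ambiguous_frac <- function(x) {
  n <- nchar(x)
  if (n == 0L) return(0)
  (n - sum(seq_chars(x) %in% c("A", "C", "G", "T"))) / n
}

`%just%` <- function(x, y) x[x %in% y]

# deterministic sub-seed derivation; kept below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483647)
}
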