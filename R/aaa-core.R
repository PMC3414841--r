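# Core constants and string helpers used at package load time.

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")

## Complement of a vector of single bases (or strings, position-wise).
compBases <- function(x) chartr("ACGTN", "TGCAN", x)

## Reverse complement of a character vector of equal-length short strings.
## Implemented by position for speed on the fixed widths used here (2, 3 bp);
## falls back to Biostrings for arbitrary widths.
revcomp <- function(x) {
  w <- unique(nchar(x))
  if (length(x) == 0L) return(character(0))
  if (length(w) == 1L && w <= 3L) {
    parts <- lapply(seq_len(w), function(i) compBases(substr(x, i, i)))
    do.call(paste0, rev(parts))
  } else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  }
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
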