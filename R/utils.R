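# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

## Seeded evaluation that restores the caller's RNG state.
localSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(seed, code)
}

## Derive a stream of child seeds below 2^31 from one master seed.
deriveSeeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Order of chromosomes used throughout: lexicographic, positions ascending.
orderGenomic <- function(chrom, pos) order(chrom, pos, method = "radix")
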