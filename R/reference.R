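# Reference genome loading and trinucleotide context lookup.

#' @importFrom Biostrings readDNAStringSet DNAStringSet trinucleotideFrequency
#'   width subseq
NULL

## Collapse a 64-context trinucleotide count vector to the 32
## pyrimidine-central contexts (purine-central windows counted via their
## reverse complement).
collapseTriCounts <- function(counts64) {
  ctx <- contextLabels()
  out <- counts64[ctx] + counts64[revcomp(ctx)]
  names(out) <- ctx
  storage.mode(out) <- "integer"
  out
}

#' Read a reference genome from FASTA
#'
#' Sequences are folded to uppercase and must contain only A, C, G, T or N.
#' A genome-wide table of trinucleotide occurrence counts, collapsed to the
#' 32 pyrimidine-central contexts, is computed once and cached; windows
#' containing N are excluded.
#'
#' @param path Path to a FASTA file.
#' @return A \linkS4class{ReferenceGenome}.
#' @seealso [referenceFromSequences()] to build one from in-memory sequences.
#' @export
readReference <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  referenceFromSequences(seqs)
}

#' @param sequences A named \code{DNAStringSet} or named character vector of
#'   chromosome sequences.
#' @rdname readReference
#' @export
referenceFromSequences <- function(sequences) {
  if (!is.character(sequences)) sequences <- as.character(sequences)
  sequences <- tryCatch(Biostrings::DNAStringSet(toupper(sequences)),
                        error = function(e)
                          stopf("reference contains non-ACGTN characters"))
  af <- Biostrings::alphabetFrequency(sequences, collapse = TRUE)
  extra <- sum(af) - sum(af[c("A", "C", "G", "T", "N")])
  if (extra > 0)
    stopf("reference contains %d non-ACGTN character(s)", extra)
  c64 <- Biostrings::trinucleotideFrequency(sequences,
                                            simplify.as = "collapsed")
  new("ReferenceGenome", sequences = sequences,
      triCounts = collapseTriCounts(c64))
}

## Forward-strand bases at [start, end] (1-based inclusive) as a string.
getBases <- function(genome, chrom, start, end) {
  seqs <- genomeSequences(genome)
  if (!chrom %in% names(seqs)) stopf("unknown chromosome: %s", chrom)
  L <- length(seqs[[chrom]])
  start <- max(1L, start); end <- min(L, end)
  if (start > end) return("")
  as.character(Biostrings::subseq(seqs[[chrom]], start, end))
}

#' Forward-strand trinucleotide context at genomic positions
#'
#' Returns the reference bases at positions pos-1..pos+1 on the forward
#' strand.  Positions at a chromosome edge (pos < 2 or pos > length-1) are
#' an error.  Windows containing N are an error when \code{strict = TRUE}
#' (the default), otherwise returned as \code{NA} so callers can count and
#' exclude them.
#'
#' @param genome A \linkS4class{ReferenceGenome}.
#' @param chrom,pos Equal-length vectors of chromosome names and 1-based
#'   positions.
#' @param strict Error on N-containing windows?
#' @return Character vector of 3-base contexts.
#' @examples
#' g <- referenceFromSequences(c(chr1 = "AACGT"))
#' trinucleotideContext(g, "chr1", 3)  # "ACG"
#' @export
trinucleotideContext <- function(genome, chrom, pos, strict = TRUE) {
  stopifnot(length(chrom) == length(pos))
  if (length(pos) == 0L) return(character(0))
  seqs <- genomeSequences(genome)
  lens <- chromLengths(genome)
  unknown <- !chrom %in% names(lens)
  if (any(unknown)) stopf("unknown chromosome: %s", chrom[unknown][1])
  edge <- pos < 2L | pos > lens[chrom] - 1L
  if (any(edge))
    stopf("position at chromosome edge: %s:%d", chrom[edge][1],
          pos[edge][1])
  out <- character(length(pos))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    at <- IRanges::IRanges(start = pos[sel] - 1L, width = 3L)
    out[sel] <- as.character(Biostrings::extractAt(seqs[[cn]], at))
  }
  hasN <- grepl("N", out, fixed = TRUE)
  if (any(hasN)) {
    if (strict)
      stopf("undefined context (N in window) at %s:%d", chrom[hasN][1],
            pos[hasN][1])
    out[hasN] <- NA_character_
  }
  out
}

## Forward-strand single reference bases at positions (vectorized).
referenceBases <- function(genome, chrom, pos) {
  if (length(pos) == 0L) return(character(0))
  seqs <- genomeSequences(genome)
  out <- character(length(pos))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    at <- IRanges::IRanges(start = pos[sel], width = 1L)
    out[sel] <- as.character(Biostrings::extractAt(seqs[[cn]], at))
  }
  out
}
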