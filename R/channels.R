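# The 96-channel substitution classification scheme.
#
# Six pyrimidine-reference substitution classes (C>A, C>G, C>T, T>A, T>C,
# T>G) crossed with the 16 combinations of immediate 5' and 3' flanking
# bases give 96 mutated trinucleotide channels.  A substitution whose
# reference base is a purine is reverse-complemented (together with its
# context) before lookup, so both strand presentations of one event map to
# the same channel.

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.channelTable <- local({
  grid <- expand.grid(three = BASES, five = BASES, class = SUB_CLASSES,
                      stringsAsFactors = FALSE)
  ## class-major ordering, contexts lexicographic in (5' base, 3' base)
  grid <- grid[order(match(grid$class, SUB_CLASSES), grid$five, grid$three), ]
  ref <- substr(grid$class, 1, 1)
  alt <- substr(grid$class, 3, 3)
  data.frame(
    label   = sprintf("%s[%s]%s", grid$five, grid$class, grid$three),
    class   = grid$class,
    ref     = ref,
    alt     = alt,
    five    = grid$five,
    three   = grid$three,
    context = paste0(grid$five, ref, grid$three),
    index   = seq_len(96L),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
})

#' The 96 trinucleotide substitution channels
#'
#' Channel labels have the form \code{"X[C>Y]Z"}: the mutated pyrimidine and
#' its substitution class flanked by the immediate 5' (\code{X}) and 3'
#' (\code{Z}) reference bases.  Ordering is fixed: substitution classes in
#' the order C>A, C>G, C>T, T>A, T>C, T>G, and within each class the 16
#' flanking contexts lexicographic in (5' base, 3' base).
#'
#' @return \code{channelLabels()}: character vector of the 96 labels in
#'   canonical order.  \code{channelTable()}: data.frame with one row per
#'   channel and columns \code{label}, \code{class}, \code{ref}, \code{alt},
#'   \code{five}, \code{three}, \code{context} (the pyrimidine-central
#'   trinucleotide) and \code{index}.
#' @examples
#' head(channelLabels())
#' @export
channelLabels <- function() .channelTable$label

#' @rdname channelLabels
#' @export
channelTable <- function() .channelTable

#' The 32 pyrimidine-central trinucleotide contexts
#'
#' Strand-collapsed contexts in the order induced by [channelTable()].
#' @return Character vector of 32 trinucleotides with central C or T.
#' @export
contextLabels <- function() unique(.channelTable$context)

#' Classify substitutions into the 96 trinucleotide channels
#'
#' Maps each substitution, given its forward-strand trinucleotide context,
#' to one of the 96 pyrimidine-reference channels.  Purine-reference records
#' are reverse-complemented (bases and context) before lookup, so the two
#' strand presentations of one mutation are classified identically.
#'
#' @param ref,alt Character vectors of single reference/alternate bases.
#' @param context Character vector of forward-strand trinucleotides centred
#'   on the mutated base.
#' @return Integer vector of channel indices (1..96, see [channelTable()]);
#'   \code{NA} where the context contains a base outside ACGT and the
#'   substitution is therefore unclassifiable.
#' @examples
#' classifySubstitutions("C", "T", "ACG")  # A[C>T]G
#' classifySubstitutions("G", "A", "CGT")  # same channel, other strand
#' @export
classifySubstitutions <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  if (n == 0L) return(integer(0))
  if (any(nchar(context) != 3L, na.rm = TRUE))
    stopf("contexts must be 3-base strings")
  bad <- is.na(context) | !grepl("^[ACGT]{3}$", context)
  mid <- substr(context, 2, 2)
  if (any(!bad & mid != ref))
    stopf("context centre base disagrees with ref for %d record(s)",
          sum(!bad & mid != ref))
  flip <- ref %in% PURINES
  ref2 <- ifelse(flip, compBases(ref), ref)
  alt2 <- ifelse(flip, compBases(alt), alt)
  ctx2 <- context
  ctx2[flip & !bad] <- revcomp(context[flip & !bad])
  lab <- sprintf("%s[%s>%s]%s", substr(ctx2, 1, 1), ref2, alt2,
                 substr(ctx2, 3, 3))
  idx <- match(lab, .channelTable$label)
  idx[bad] <- NA_integer_
  idx
}

## Pyrimidine-collapsed class ("C>T" etc.) for ref/alt base vectors.
collapseClass <- function(ref, alt) {
  flip <- ref %in% PURINES
  paste0(ifelse(flip, compBases(ref), ref), ">",
         ifelse(flip, compBases(alt), alt))
}
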