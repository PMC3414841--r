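# Indel architecture: repeat- vs microhomology-mediated classification,
# length-distribution comparison, and the microhomology chance model.

#' @importFrom stats ks.test fisher.test pchisq
NULL

## Length of the common prefix of two strings.
commonPrefixLen <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "")[[1]][seq_len(n)]
  bv <- strsplit(b, "")[[1]][seq_len(n)]
  neq <- which(av != bv)
  if (length(neq)) neq[1L] - 1L else n
}

## Smallest unit length u such that seq is whole copies of its first u
## characters, or 0 when only the trivial full-length unit exists and
## u > maxUnit.
smallestRepeatUnit <- function(seq, maxUnit) {
  len <- nchar(seq)
  for (u in seq_len(min(maxUnit, len))) {
    if (len %% u != 0L) next
    unit <- substr(seq, 1L, u)
    if (identical(strrep(unit, len %/% u), seq)) return(unit)
  }
  NULL
}

## Number of whole copies of `unit` at the start of `s`.
leadingUnitCopies <- function(s, unit) {
  u <- nchar(unit)
  n <- 0L
  while (nchar(s) >= u * (n + 1L) &&
         substr(s, n * u + 1L, (n + 1L) * u) == unit)
    n <- n + 1L
  n
}

#' Classify indels as repeat-mediated, microhomology-mediated or neither
#'
#' Classification from the deleted/inserted sequence and its +/- 50 bp
#' reference flanks, with a total and deterministic precedence:
#' \enumerate{
#'   \item \strong{repeat}: the indel sequence is a whole number of copies
#'     of a unit of at most \code{maxUnit} bp and at least one additional
#'     whole unit lies immediately adjacent (3' or 5') in the reference —
#'     a slippage event within a tandem repeat tract.
#'   \item \strong{microhomology} (deletions only): the junction shows
#'     overlapping identity — the longest prefix of the deleted sequence
#'     matching the reference immediately 3' of the deletion, or the
#'     longest suffix matching the reference immediately 5', whichever is
#'     longer — of at least \code{mhMin} bp.
#'   \item \strong{none} otherwise.
#' }
#' Repeat takes precedence because a deletion within a tandem repeat
#' trivially carries junction identity.  Insertions are eligible for the
#' repeat class only.  Complex indels are not classified.
#'
#' @param indelTable data.frame of indel records (\code{chrom}, \code{pos}
#'   of the base immediately 5' of the event, \code{kind}, \code{seq},
#'   \code{length}); a \code{sample} column is carried through.
#' @param genome A \linkS4class{ReferenceGenome}.
#' @param mhMin Minimum junction identity for the microhomology class
#'   (default 2 bp; single-base matches arise by chance at almost half of
#'   junctions).
#' @param maxUnit Maximum tandem-repeat unit length (default 6).
#' @return The input table with added columns \code{class},
#'   \code{repeat_unit}, \code{adjacent_repeat_copies}, \code{mh_length}
#'   (junction identity, recorded for every deletion whatever its class)
#'   and \code{flank_truncated}.  Thresholds are echoed in
#'   \code{attr(, "params")}.
#' @export
classifyIndels <- function(indelTable, genome, mhMin = 2L, maxUnit = 6L) {
  n <- nrow(indelTable)
  class <- rep("none", n); unitOut <- rep("", n)
  copies <- integer(n); mh <- integer(n); trunc <- logical(n)
  lens <- chromLengths(genome)
  for (i in seq_len(n)) {
    kind <- indelTable$kind[i]
    if (kind == "complex") { class[i] <- "complex"; next }
    seq <- indelTable$seq[i]
    len <- indelTable$length[i]
    chrom <- indelTable$chrom[i]
    pos <- indelTable$pos[i]
    L <- lens[[chrom]]
    ## 5' flank ends at pos; 3' flank starts after the deleted bases (for
    ## deletions) or right after pos (for insertions)
    right0 <- if (kind == "deletion") pos + len + 1L else pos + 1L
    flank5 <- getBases(genome, chrom, pos - 50L + 1L, pos)
    flank3 <- getBases(genome, chrom, right0, right0 + 50L - 1L)
    trunc[i] <- (pos - 50L + 1L) < 1L || (right0 + 50L - 1L) > L
    ## junction identity is recorded for every deletion, whatever the
    ## final class (the chance model needs the full distribution)
    if (kind == "deletion") {
      pre <- commonPrefixLen(seq, flank3)
      revseq <- paste(rev(strsplit(seq, "")[[1]]), collapse = "")
      rev5r <- paste(rev(strsplit(flank5, "")[[1]]), collapse = "")
      suf <- commonPrefixLen(revseq, rev5r)
      mh[i] <- max(pre, suf)
    }
    unit <- smallestRepeatUnit(seq, maxUnit)
    if (!is.null(unit)) {
      rev5 <- paste(rev(strsplit(flank5, "")[[1]]), collapse = "")
      revu <- paste(rev(strsplit(unit, "")[[1]]), collapse = "")
      adj <- leadingUnitCopies(flank3, unit) + leadingUnitCopies(rev5, revu)
      if (adj >= 1L) {
        class[i] <- "repeat"; unitOut[i] <- unit; copies[i] <- adj
        next
      }
    }
    if (kind == "deletion" && mh[i] >= mhMin) class[i] <- "microhomology"
  }
  out <- cbind(indelTable,
               data.frame(class = class, repeat_unit = unitOut,
                          adjacent_repeat_copies = copies, mh_length = mh,
                          flank_truncated = trunc, stringsAsFactors = FALSE))
  attr(out, "params") <- list(mhMin = mhMin, maxUnit = maxUnit)
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of indel length distributions
#'
#' D is the supremum absolute difference between the two empirical CDFs;
#' the p-value comes from \code{\link[stats]{ks.test}} (exact for small
#' samples, asymptotic Kolmogorov distribution otherwise).
#'
#' @param lengthsA,lengthsB Numeric vectors (e.g. repeat-mediated vs
#'   microhomology-mediated indel lengths).
#' @return List with \code{D}, \code{p}, \code{nA}, \code{nB} (NA when a
#'   sample is empty).
#' @export
ksTwoSample <- function(lengthsA, lengthsB) {
  if (!length(lengthsA) || !length(lengthsB))
    return(list(D = NA_real_, p = NA_real_, nA = length(lengthsA),
                nB = length(lengthsB)))
  kt <- suppressWarnings(ks.test(lengthsA, lengthsB))
  list(D = unname(kt$statistic), p = kt$p.value, nA = length(lengthsA),
       nB = length(lengthsB))
}

## P(junction microhomology length = j) for a deletion of length L under
## the chance model: each side's identity run is geometric-like with
## per-position match probability pMatch, capped at L; the reported length
## is the max over the two independent sides.
mhChanceDistribution <- function(L, pMatch) {
  j <- 0:L
  ## one side: P(run >= j) = pMatch^j for j <= L
  pGe <- pMatch^j
  pMaxGe <- 1 - (1 - pGe)^2
  p <- c(-diff(pMaxGe), pMaxGe[L + 1L])
  names(p) <- as.character(j)
  p
}

#' Expected junction microhomology under the base-composition chance model
#'
#' Under the null that deletion junctions fall in random sequence, the
#' per-position probability that a deleted base matches the flanking base
#' is \code{pMatch = sum(p_b^2)} over the base composition.  Each side's
#' identity run length is then geometric with rate \code{pMatch} (capped at
#' the deletion length) and the junction microhomology is the maximum of
#' the two sides, matching the classification rule.  Expected counts per
#' microhomology length are accumulated over the observed deletions and
#' compared to the observed counts with a chi-square summary (bins pooled
#' above \code{maxJ}).
#'
#' @param classified Output of [classifyIndels()] (deletions are used).
#' @param composition Base frequencies (named A/C/G/T, summing to 1), e.g.
#'   estimated from deletion flanks; degenerate compositions are flagged
#'   but still defined.
#' @param maxJ Largest microhomology length tabulated separately.
#' @return List with \code{table} (data.frame: \code{mh}, \code{observed},
#'   \code{expected}), \code{pMatch}, \code{chisq}, \code{df}, \code{p},
#'   \code{degenerate}.
#' @export
expectedMicrohomology <- function(classified, composition, maxJ = 10L) {
  composition <- composition[BASES]
  if (any(is.na(composition)) || abs(sum(composition) - 1) > 1e-6)
    stopf("composition must be frequencies over A, C, G, T summing to 1")
  degenerate <- any(composition > 1 - 1e-9)
  pMatch <- sum(composition^2)
  del <- classified[classified$kind == "deletion", , drop = FALSE]
  nDel <- nrow(del)
  if (!nDel) stopf("no deletions to analyze")
  expected <- numeric(maxJ + 1L)  # mh = 0..maxJ, last bin pooled upward
  for (L in unique(del$length)) {
    p <- mhChanceDistribution(L, pMatch)
    m <- sum(del$length == L)
    pool <- c(p[seq_len(min(maxJ, L))],
              sum(p[-seq_len(min(maxJ, L))]))
    expected[seq_along(pool)] <- expected[seq_along(pool)] + m * pool
  }
  obs <- tabulate(pmin(del$mh_length, maxJ) + 1L, nbins = maxJ + 1L)
  ## chi-square with standard pooling of sparse cells (expected < 5 merged
  ## upward from the tail) so the asymptotic distribution applies
  pooledE <- pooledO <- numeric(0)
  accE <- accO <- 0
  for (i in rev(seq_along(expected))) {
    accE <- accE + expected[i]; accO <- accO + obs[i]
    if (accE >= 5 || i == 1L) {
      pooledE <- c(accE, pooledE); pooledO <- c(accO, pooledO)
      accE <- accO <- 0
    }
  }
  if (length(pooledE) >= 2L && pooledE[1L] < 5) {
    pooledE[2L] <- pooledE[2L] + pooledE[1L]
    pooledO[2L] <- pooledO[2L] + pooledO[1L]
    pooledE <- pooledE[-1L]; pooledO <- pooledO[-1L]
  }
  chisq <- sum((pooledO - pooledE)^2 / pooledE)
  df <- max(length(pooledE) - 1L, 1L)
  list(table = data.frame(mh = 0:maxJ, observed = obs, expected = expected),
       pMatch = pMatch, chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE), degenerate = degenerate)
}

#' Association between microhomology-mediated indels and sample groups
#'
#' Builds the 2x2 table (microhomology-mediated vs other classified
#' indels) x (group) and reports the Fisher exact p-value and sample odds
#' ratio (cross-product), e.g. to compare BRCA-null against sporadic
#' cancers.
#'
#' @param classified Output of [classifyIndels()] with a \code{sample}
#'   column.
#' @param groups Named vector mapping sample -> group label (exactly two
#'   groups).
#' @return List with \code{table}, per-group MH fractions, \code{or} and
#'   \code{p} (NA when fewer than two groups are present).
#' @export
indelGroupTest <- function(classified, groups) {
  cls <- classified[classified$class != "complex", , drop = FALSE]
  grp <- groups[cls$sample]
  if (length(unique(stats::na.omit(grp))) < 2L)
    return(list(table = NA, mhFraction = NA, or = NA_real_, p = NA_real_))
  isMH <- cls$class == "microhomology"
  tab <- table(group = grp, mh = factor(isMH, levels = c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab,
       mhFraction = tab[, "TRUE"] / rowSums(tab),
       or = or, p = ft$p.value)
}
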