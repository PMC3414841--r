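# Building 96-channel spectra, trinucleotide-corrected heatmap values, and
# the CpG-island methylation odds ratio.

## Label each substitution of one sample with the length of the maximal run
## of consecutive positions it belongs to (1 = isolated).  Used both to
## exclude multi-base events from the single-base spectrum and to find
## doublets.
runLengthsPerSub <- function(subs) {
  n <- nrow(subs)
  if (n == 0L) return(integer(0))
  newrun <- c(TRUE, !(subs$chrom[-1] == subs$chrom[-n] &
                        subs$pos[-1] == subs$pos[-n] + 1L))
  runid <- cumsum(newrun)
  len <- tabulate(runid)
  len[runid]
}

#' Build the 96 x M spectrum matrix from per-sample catalogs
#'
#' Each sample's substitutions are classified into the 96
#' pyrimidine-reference trinucleotide channels and tabulated.  Substitutions
#' whose context contains N are unclassifiable and excluded (their count is
#' recorded in the result's metadata), as are members of runs of two or more
#' consecutive substituted positions when \code{excludeAdjacent = TRUE} (the
#' default), so that each multi-base event is counted once by the doublet
#' machinery rather than as several independent substitutions.
#'
#' @param catalogs List of \linkS4class{MutationCatalog}.
#' @param genome A \linkS4class{ReferenceGenome}.
#' @param excludeAdjacent Drop members of adjacent runs (length >= 2)?
#' @return A \linkS4class{SpectrumMatrix}; column sums equal each sample's
#'   classifiable substitution count.  \code{metadata()} carries
#'   \code{unclassifiable} and \code{adjacentExcluded} per-sample counts.
#' @export
buildSpectrumMatrix <- function(catalogs, genome, excludeAdjacent = TRUE) {
  if (length(catalogs) == 0L) stopf("need at least one catalog")
  ids <- vapply(catalogs, sampleId, character(1))
  counts <- matrix(0L, 96L, length(catalogs),
                   dimnames = list(channelLabels(), ids))
  unclass <- adj <- integer(length(catalogs))
  for (j in seq_along(catalogs)) {
    s <- substitutions(catalogs[[j]])
    if (nrow(s) == 0L) {
      warning("sample ", ids[j], " has no substitutions; zero column")
      next
    }
    if (excludeAdjacent) {
      runlen <- runLengthsPerSub(s)
      adj[j] <- sum(runlen >= 2L)
      s <- s[runlen == 1L, , drop = FALSE]
    }
    if (nrow(s) == 0L) next
    ctx <- trinucleotideContext(genome, s$chrom, s$pos, strict = FALSE)
    idx <- classifySubstitutions(s$ref, s$alt, ctx)
    unclass[j] <- sum(is.na(idx))
    counts[, j] <- tabulate(idx[!is.na(idx)], nbins = 96L)
  }
  sm <- SpectrumMatrix(counts)
  S4Vectors::metadata(sm) <- list(unclassifiable = stats::setNames(unclass, ids),
                                  adjacentExcluded = stats::setNames(adj, ids))
  sm
}

#' Trinucleotide-corrected log mutation-rate heatmap values
#'
#' For each channel c of each sample, the value is
#' \code{log(count(c) / occurrences(context(c)))} where occurrences is the
#' genome-wide (strand-collapsed) count of the channel's trinucleotide
#' context.  This corrects the raw spectrum for the frequency of each
#' trinucleotide in the reference genome.  Zero-count cells are masked as
#' \code{NA} rather than mapped to -Inf.
#'
#' @param spectrum A \linkS4class{SpectrumMatrix}.
#' @param genome A \linkS4class{ReferenceGenome}; every context occurring in
#'   the scheme must have a positive genome count.
#' @return 96 x M numeric matrix with masked cells as \code{NA}.
#' @export
heatmapValues <- function(spectrum, genome) {
  counts <- spectrumCounts(spectrum)
  occ <- triContextCounts(genome)[channelTable()$context]
  if (any(occ == 0L))
    stopf("context absent from genome: %s",
          channelTable()$context[occ == 0L][1])
  v <- log(counts / occ)
  v[counts == 0L] <- NA_real_
  v
}

#' Odds ratio of XpCpG C>T mutation rates outside vs inside CpG islands
#'
#' Events are C>T substitutions whose strand-collapsed context is XpCpG
#' (i.e. NpCpG on either strand).  At-risk sites are all genome cytosines
#' within CpG dinucleotides on either strand, partitioned by CpG-island
#' membership.  The odds ratio is oriented outside/inside: values above 1
#' mean a higher per-site mutation rate outside islands, as expected when
#' island CpGs are unmethylated and therefore protected from
#' 5-methylcytosine deamination.  The 95\% CI is the Woolf log interval
#' \code{exp(log OR +/- 1.96 sqrt(sum 1/cell))}.
#'
#' @param catalogs List of \linkS4class{MutationCatalog} (aggregated).
#' @param genome A \linkS4class{ReferenceGenome}.
#' @param islands CpG island \code{GRanges} (see [readCpgIslands()]).
#' @return List with \code{or}, \code{ciLow}, \code{ciHigh}, the 2x2
#'   \code{table} (mutOut, riskOut, mutIn, riskIn) and \code{ciDefined}
#'   (FALSE with NA bounds when a cell is zero; no continuity correction is
#'   applied).
#' @export
cpgIslandOddsRatio <- function(catalogs, genome, islands) {
  if (is(catalogs, "MutationCatalog")) catalogs <- list(catalogs)
  ## at-risk: C of a forward CG (position of the C) and C on the reverse
  ## strand of a CG (position of the forward G)
  riskIn <- riskOut <- 0
  seqs <- genomeSequences(genome)
  for (cn in names(seqs)) {
    m <- Biostrings::matchPattern("CG", seqs[[cn]])
    if (length(m) == 0L) next
    sites <- c(BiocGenerics::start(m), BiocGenerics::start(m) + 1L)
    isl <- islands[GenomicRanges::seqnames(islands) == cn]
    inIsl <- IRanges::overlapsAny(IRanges::IRanges(sites, width = 1L),
                                  IRanges::ranges(isl))
    riskIn <- riskIn + sum(inIsl)
    riskOut <- riskOut + sum(!inIsl)
  }
  mutIn <- mutOut <- 0
  for (cat in catalogs) {
    s <- substitutions(cat)
    if (nrow(s) == 0L) next
    ctx <- trinucleotideContext(genome, s$chrom, s$pos, strict = FALSE)
    idx <- classifySubstitutions(s$ref, s$alt, ctx)
    lab <- channelTable()$label[idx]
    ev <- !is.na(lab) & grepl("^[ACGT]\\[C>T\\]G$", lab)
    if (!any(ev)) next
    hits <- IRanges::overlapsAny(
      GenomicRanges::GRanges(s$chrom[ev], IRanges::IRanges(s$pos[ev], width = 1L)),
      islands)
    mutIn <- mutIn + sum(hits)
    mutOut <- mutOut + sum(!hits)
  }
  a <- mutOut; b <- riskOut - mutOut; c <- mutIn; d <- riskIn - mutIn
  or <- (a / b) / (c / d)
  cells <- c(a, b, c, d)
  if (any(cells == 0)) {
    ciLow <- ciHigh <- NA_real_
    ciDefined <- FALSE
  } else {
    se <- sqrt(sum(1 / cells))
    ciLow <- exp(log(or) - 1.96 * se)
    ciHigh <- exp(log(or) + 1.96 * se)
    ciDefined <- TRUE
  }
  list(or = or, ciLow = ciLow, ciHigh = ciHigh,
       table = c(mutOut = a, riskOut = riskOut, mutIn = c, riskIn = riskIn),
       ciDefined = ciDefined)
}

#' Remove sequencing-artifact channels before factorization
#'
#' Zeroes the counts of a user-supplied channel blocklist (e.g. the
#' GpTpX T>G channels typical of phasing artifacts at Ts after G runs).
#' Artifact channels are identified by orthogonal re-sequencing evidence,
#' not detected automatically.
#'
#' @param spectrum A \linkS4class{SpectrumMatrix} or 96 x M matrix.
#' @param channels Character vector of channel labels (see
#'   [channelLabels()]) to blank.
#' @return Object of the same type with the listed channels zeroed.
#' @examples
#' applyChannelBlocklist(matrix(1L, 96, 2,
#'                              dimnames = list(channelLabels(), NULL)),
#'                       c("G[T>G]A", "G[T>G]C", "G[T>G]G", "G[T>G]T"))
#' @export
applyChannelBlocklist <- function(spectrum, channels) {
  bad <- setdiff(channels, channelLabels())
  if (length(bad)) stopf("unknown channel label(s): %s", bad[1])
  if (is(spectrum, "SpectrumMatrix")) {
    m <- spectrumCounts(spectrum)
    m[channels, ] <- 0L
    out <- SpectrumMatrix(m)
    S4Vectors::metadata(out) <- c(S4Vectors::metadata(spectrum),
                                  list(blockedChannels = channels))
    out
  } else {
    spectrum[channels, ] <- 0L
    spectrum
  }
}

#' Rescale sample columns to a common mutation total
#'
#' Optional pre-factorization normalization for cohorts with extreme
#' mutation-burden outliers (for instance one hypermutated genome an
#' order of magnitude above the rest): each column is scaled to the
#' median column total.  The default analysis uses raw counts.
#'
#' @param spectrum A \linkS4class{SpectrumMatrix} or 96 x M matrix.
#' @return Numeric 96 x M matrix with equal column sums.
#' @export
scaleSampleTotals <- function(spectrum) {
  m <- if (is(spectrum, "SpectrumMatrix")) spectrumCounts(spectrum) else
    spectrum
  tot <- colSums(m)
  target <- stats::median(tot[tot > 0])
  sweep(m, 2L, ifelse(tot > 0, tot, 1), "/") * target
}

#' Write a spectrum or heatmap matrix as TSV
#'
#' 96-row tab-delimited table with a channel column and one column per
#' sample; masked heatmap cells are written as NA.
#'
#' @param m A \linkS4class{SpectrumMatrix} or 96 x M matrix.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeSpectrum <- function(m, path) {
  if (is(m, "SpectrumMatrix")) m <- spectrumCounts(m)
  df <- data.frame(channel = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
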