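# Rainfall series, kataegis cluster calling, cluster spectrum/flank
# summaries, strand-processivity segmentation, and rearrangement
# colocalization.

#' Intermutation-distance (rainfall) series for one sample
#'
#' Orders the sample's substitutions genome-wide (chromosomes lexicographic,
#' positions ascending) and attaches to each the distance to the
#' substitution immediately before it on the same chromosome.  The first
#' mutation of each chromosome has no predecessor and an undefined (NA)
#' intermutation distance.
#'
#' @param catalog A \linkS4class{MutationCatalog}.
#' @return data.frame with columns \code{index}, \code{chrom}, \code{pos},
#'   \code{imd}, \code{class} (pyrimidine-collapsed, e.g. "C>T") and
#'   \code{change} (forward-strand, e.g. "G>A").
#' @export
rainfall <- function(catalog) {
  s <- substitutions(catalog)
  n <- nrow(s)
  if (n == 0L)
    return(data.frame(index = integer(0), chrom = character(0),
                      pos = integer(0), imd = integer(0),
                      class = character(0), change = character(0),
                      stringsAsFactors = FALSE))
  imd <- rep(NA_integer_, n)
  if (n > 1L) {
    same <- s$chrom[-1] == s$chrom[-n]
    d <- s$pos[-1] - s$pos[-n]
    imd[-1][same] <- d[same]
  }
  data.frame(index = seq_len(n), chrom = s$chrom, pos = s$pos, imd = imd,
             class = collapseClass(s$ref, s$alt),
             change = paste0(s$ref, ">", s$alt),
             stringsAsFactors = FALSE)
}

#' Call kataegis clusters from a rainfall series
#'
#' A kataegis microcluster is a maximal run of consecutive same-chromosome
#' substitutions whose successive intermutation distances are all at most
#' \code{imdThreshold}, of length at least \code{minSize}.  Called clusters
#' on the same chromosome separated by at most \code{macroGap} are
#' additionally aggregated into macroclusters.
#'
#' The thresholds are an operational rule for what the rainfall plots show
#' visually: microclusters are heavily mutated stretches of a few hundred
#' base pairs, so the defaults require >= 6 mutations each within 1 kb of
#' its predecessor.  Both knobs are exposed.
#'
#' @param series Rainfall series from [rainfall()].
#' @param minSize Minimum mutations per cluster (default 6).
#' @param imdThreshold Maximum successive intermutation distance in bp
#'   (default 1000).
#' @param macroGap Maximum gap between microclusters aggregated into one
#'   macrocluster (default 1e6).
#' @return List with \code{clusters} (data.frame: \code{cluster},
#'   \code{chrom}, \code{start}, \code{end}, \code{n}, \code{span},
#'   \code{meanImd}, \code{CtoT_fraction}, \code{CtoG_fraction},
#'   \code{members} list-column of series row indices) and \code{macro}
#'   (data.frame of aggregated regions).  Parameters are echoed in
#'   \code{attr(, "params")}.
#' @export
callKataegis <- function(series, minSize = 6L, imdThreshold = 1000L,
                         macroGap = 1e6) {
  if (minSize < 2L) stopf("minSize must be >= 2")
  if (imdThreshold < 1) stopf("imdThreshold must be positive")
  empty <- data.frame(cluster = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0), n = integer(0),
                      span = integer(0), meanImd = numeric(0),
                      CtoT_fraction = numeric(0), CtoG_fraction = numeric(0))
  empty$members <- list()
  out <- list(clusters = empty,
              macro = data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0), nClusters = integer(0),
                                 n = integer(0)))
  attr(out, "params") <- list(minSize = minSize,
                              imdThreshold = imdThreshold,
                              macroGap = macroGap)
  n <- nrow(series)
  if (n == 0L) return(out)
  ## linked[i]: mutation i is within threshold of its predecessor
  linked <- !is.na(series$imd) & series$imd <= imdThreshold
  runid <- cumsum(!linked)
  rows <- split(seq_len(n), runid)
  rows <- rows[lengths(rows) >= minSize]
  if (length(rows) == 0L) return(out)
  cl <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    cls <- series$class[r]
    data.frame(cluster = i, chrom = series$chrom[r[1L]],
               start = series$pos[r[1L]], end = series$pos[r[length(r)]],
               n = length(r),
               span = series$pos[r[length(r)]] - series$pos[r[1L]],
               meanImd = mean(series$imd[r[-1L]]),
               CtoT_fraction = mean(cls == "C>T"),
               CtoG_fraction = mean(cls == "C>G"),
               stringsAsFactors = FALSE)
  }))
  cl$members <- rows
  rownames(cl) <- NULL
  ## macrocluster aggregation per chromosome
  macro <- do.call(rbind, lapply(split(cl, cl$chrom), function(g) {
    g <- g[order(g$start), ]
    gap <- c(Inf, g$start[-1] - g$end[-nrow(g)])
    grp <- cumsum(gap > macroGap)
    do.call(rbind, lapply(split(g, grp), function(h)
      data.frame(chrom = h$chrom[1], start = min(h$start),
                 end = max(h$end), nClusters = nrow(h), n = sum(h$n),
                 stringsAsFactors = FALSE)))
  }))
  rownames(macro) <- NULL
  out$clusters <- cl
  out$macro <- macro
  out
}

#' Spectrum and flanking-base composition of a kataegis cluster
#'
#' For the cluster's C>X members (strand-collapsed so the mutated base is
#' presented as a pyrimidine), tallies the base composition at each
#' position of the +/- \code{flank} bp window around the mutated cytosine,
#' and reports the TpC fraction (members with T immediately 5') together
#' with substitution-class fractions over all members.
#'
#' @param members data.frame of the cluster's substitutions (\code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}), e.g. the catalog rows indexed by a
#'   [callKataegis()] cluster; an optional \code{phase} column (an input
#'   annotation, e.g. from read-level phasing done upstream) yields a
#'   same-phase concordance summary.
#' @param genome A \linkS4class{ReferenceGenome}.
#' @param flank Flank width in bp (default 10).
#' @return List with \code{composition} (4 x (2 flank + 1) matrix of base
#'   fractions, positions -flank..+flank), \code{TpC_fraction},
#'   \code{classFractions}, \code{nCtoX} and \code{samePhaseFraction}
#'   (largest phase group over cluster size; NA without phase
#'   annotations).  Composition and TpC fraction are NA when the cluster
#'   has no C>X members.
#' @export
clusterSpectrum <- function(members, genome, flank = 10L) {
  cls <- collapseClass(members$ref, members$alt)
  classFractions <- table(factor(cls, levels = SUB_CLASSES)) / nrow(members)
  samePhase <- if (!is.null(members$phase) && !all(is.na(members$phase)))
    max(table(members$phase)) / nrow(members) else NA_real_
  isC <- substr(cls, 1, 1) == "C"
  if (!any(isC)) {
    return(list(composition = NA, TpC_fraction = NA_real_,
                classFractions = classFractions, nCtoX = 0L,
                samePhaseFraction = samePhase))
  }
  m <- members[isC, , drop = FALSE]
  seqs <- genomeSequences(genome)
  width <- 2L * flank + 1L
  comp <- matrix(0L, 4L, width,
                 dimnames = list(BASES, as.character(-flank:flank)))
  tpc <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    win <- getBases(genome, m$chrom[i], m$pos[i] - flank, m$pos[i] + flank)
    if (nchar(win) != width) next  # truncated at chromosome edge
    if (m$ref[i] %in% PURINES) win <- revcomp(win)
    b <- strsplit(win, "")[[1]]
    for (p in seq_len(width))
      if (b[p] %in% BASES) comp[b[p], p] <- comp[b[p], p] + 1L
    tpc[i] <- b[flank] == "T"
  }
  list(composition = sweep(comp, 2L, pmax(colSums(comp), 1L), "/"),
       TpC_fraction = mean(tpc),
       classFractions = classFractions, nCtoX = nrow(m),
       samePhaseFraction = samePhase)
}

#' Maximal runs of identical forward-strand substitution classes
#'
#' Scans the sample's genome-ordered substitutions for maximal runs of
#' consecutive mutations sharing the identical forward-strand change (C>T
#' kept distinct from G>A), evidence of strand-processive mutagenesis.
#'
#' @param catalog A \linkS4class{MutationCatalog}.
#' @param region Optional list \code{(chrom, start, end)} restricting the
#'   scan.
#' @return data.frame with one row per segment: \code{chrom}, \code{start},
#'   \code{end}, \code{change}, \code{n}; the run-length distribution is
#'   attached as \code{attr(, "runLengths")}.
#' @export
processiveSegments <- function(catalog, region = NULL) {
  s <- substitutions(catalog)
  if (!is.null(region)) {
    s <- s[s$chrom == region$chrom & s$pos >= region$start &
             s$pos <= region$end, , drop = FALSE]
  }
  n <- nrow(s)
  if (n == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), change = character(0),
                      n = integer(0))
    attr(out, "runLengths") <- integer(0)
    return(out)
  }
  change <- paste0(s$ref, ">", s$alt)
  newrun <- c(TRUE, change[-1] != change[-n] | s$chrom[-1] != s$chrom[-n])
  runid <- cumsum(newrun)
  idx <- split(seq_len(n), runid)
  out <- data.frame(
    chrom = vapply(idx, function(r) s$chrom[r[1L]], character(1)),
    start = vapply(idx, function(r) s$pos[r[1L]], numeric(1)),
    end = vapply(idx, function(r) s$pos[r[length(r)]], numeric(1)),
    change = vapply(idx, function(r) change[r[1L]], character(1)),
    n = lengths(idx), row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "runLengths") <- out$n
  out
}

#' Colocalization of kataegis clusters with rearrangement breakpoints
#'
#' Rearrangements are expanded to single-ended breakpoints.  For each
#' cluster the distance to the nearest breakpoint on its chromosome is
#' reported (0 when a breakpoint falls inside the cluster).  For each
#' macrocluster region, breakpoints inside the region are counted against
#' the rest of the chromosome, with per-Mb rates and a one-sided binomial
#' enrichment p-value using the region's share of the chromosome length as
#' the null probability.
#'
#' @param calls Result of [callKataegis()].
#' @param rearrangements Rearrangement table (see [readRearrangements()]).
#' @param chromLengths Named vector of chromosome lengths.
#' @return List with \code{clusters} (nearest-breakpoint distances) and
#'   \code{macro} (counts, rates and enrichment p per macrocluster region).
#' @export
rearrangementColocalization <- function(calls, rearrangements,
                                        chromLengths) {
  bp <- data.frame(
    chrom = c(rearrangements$chromA, rearrangements$chromB),
    pos = c(rearrangements$posA, rearrangements$posB),
    stringsAsFactors = FALSE)
  cl <- calls$clusters
  nearest <- rep(NA_real_, nrow(cl))
  if (nrow(bp)) {
    for (i in seq_len(nrow(cl))) {
      p <- bp$pos[bp$chrom == cl$chrom[i]]
      if (!length(p)) next
      inside <- p >= cl$start[i] & p <= cl$end[i]
      nearest[i] <- if (any(inside)) 0 else
        min(pmin(abs(p - cl$start[i]), abs(p - cl$end[i])))
    }
  }
  clusters <- cbind(cl[c("cluster", "chrom", "start", "end", "n")],
                    nearestBreakpoint = nearest)
  mac <- calls$macro
  if (nrow(mac)) {
    res <- lapply(seq_len(nrow(mac)), function(i) {
      chromLen <- chromLengths[[mac$chrom[i]]]
      p <- bp$pos[bp$chrom == mac$chrom[i]]
      lenIn <- mac$end[i] - mac$start[i] + 1
      nIn <- sum(p >= mac$start[i] & p <= mac$end[i])
      nOut <- length(p) - nIn
      pv <- if (length(p) == 0L) NA_real_ else
        stats::binom.test(nIn, length(p), p = lenIn / chromLen,
                          alternative = "greater")$p.value
      data.frame(chrom = mac$chrom[i], start = mac$start[i],
                 end = mac$end[i], breakpointsInside = nIn,
                 breakpointsOutside = nOut,
                 rateInsidePerMb = nIn / (lenIn / 1e6),
                 rateOutsidePerMb = nOut / ((chromLen - lenIn) / 1e6),
                 enrichmentP = pv, stringsAsFactors = FALSE)
    })
    macro <- do.call(rbind, res)
  } else {
    macro <- data.frame()
  }
  list(clusters = clusters, macro = macro)
}
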