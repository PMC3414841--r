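# Double-nucleotide substitutions: identification, canonical spectrum, and
# the Monte Carlo adjacency-enrichment test.

#' Partition substitutions into singletons, doublets and complex runs
#'
#' Finds maximal runs of consecutive substituted positions per chromosome.
#' Runs of length 2 are double-nucleotide substitutions; runs of length 3
#' or more are complex events, kept separate and excluded from doublet
#' counts.  Every substitution belongs to exactly one of
#' singleton/doublet/complex.
#'
#' @param catalog A \linkS4class{MutationCatalog}.
#' @return List with \code{doublets} (data.frame: \code{chrom}, \code{pos}
#'   of the first base, \code{ref}, \code{alt} dinucleotides,
#'   \code{canonical} strand-collapsed label), \code{complexRuns}
#'   (data.frame: \code{chrom}, \code{start}, \code{end}, \code{n}) and
#'   \code{assignment} (per-substitution factor over
#'   singleton/doublet/complex, in catalog order).
#' @export
findAdjacentRuns <- function(catalog) {
  s <- substitutions(catalog)
  runlen <- runLengthsPerSub(s)
  assignment <- factor(ifelse(runlen == 1L, "singleton",
                              ifelse(runlen == 2L, "doublet", "complex")),
                       levels = c("singleton", "doublet", "complex"))
  firstOfPair <- if (nrow(s) >= 2L)
    which(runlen == 2L &
            c(diff(s$pos) == 1L & s$chrom[-1] == s$chrom[-nrow(s)], FALSE))
  else integer(0)
  if (length(firstOfPair)) {
    ref <- paste0(s$ref[firstOfPair], s$ref[firstOfPair + 1L])
    alt <- paste0(s$alt[firstOfPair], s$alt[firstOfPair + 1L])
    doublets <- data.frame(chrom = s$chrom[firstOfPair],
                           pos = s$pos[firstOfPair], ref = ref, alt = alt,
                           canonical = canonicalDoublet(ref, alt),
                           stringsAsFactors = FALSE)
  } else {
    doublets <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           canonical = character(0), stringsAsFactors = FALSE)
  }
  if (nrow(s)) {
    n <- nrow(s)
    newrun <- c(TRUE, !(s$chrom[-1] == s$chrom[-n] &
                          s$pos[-1] == s$pos[-n] + 1L))
    runid <- cumsum(newrun)
    big <- split(seq_len(n), runid)
    big <- big[lengths(big) >= 3L]
  } else big <- list()
  complexRuns <- if (length(big)) data.frame(
    chrom = vapply(big, function(r) s$chrom[r[1L]], character(1)),
    start = vapply(big, function(r) s$pos[r[1L]], numeric(1)),
    end = vapply(big, function(r) s$pos[r[length(r)]], numeric(1)),
    n = lengths(big), row.names = NULL, stringsAsFactors = FALSE)
  else data.frame(chrom = character(0), start = integer(0),
                  end = integer(0), n = integer(0))
  list(doublets = doublets, complexRuns = complexRuns,
       assignment = assignment)
}

#' Canonical strand-collapsed label for a dinucleotide change
#'
#' A doublet and its reverse-complement presentation share one canonical
#' label, chosen as the lexicographically smaller of \code{"RR>AA"} and its
#' reverse complement.  Enumerating all 144 raw dinucleotide changes (both
#' bases substituted) yields exactly 78 canonical classes.
#'
#' @param ref,alt Character vectors of reference/alternate dinucleotides.
#' @return Character vector of labels like \code{"CC>AA"}.
#' @export
canonicalDoublet <- function(ref, alt) {
  fwd <- paste0(ref, ">", alt)
  rev <- paste0(revcomp(ref), ">", revcomp(alt))
  ifelse(fwd <= rev, fwd, rev)
}

#' Spectrum of double substitutions over the 78 canonical classes
#'
#' @param doublets Doublet table from [findAdjacentRuns()].
#' @return Named integer vector over all 78 canonical classes (zeros
#'   included); \code{attr(, "byRefDinucleotide")} carries the collapsed
#'   summary over reference dinucleotides.
#' @export
doubletSpectrum <- function(doublets) {
  classes <- doubletClasses()
  counts <- table(factor(doublets$canonical, levels = classes))
  out <- as.integer(counts)
  names(out) <- classes
  byRef <- tapply(out, sub(">.*$", "", classes), sum)
  attr(out, "byRefDinucleotide") <- byRef
  out
}

#' All 78 canonical doublet classes
#' @return Character vector of canonical labels, sorted.
#' @export
doubletClasses <- function() {
  dinucs <- as.vector(outer(BASES, BASES, paste0))
  raw <- expand.grid(ref = dinucs, alt = dinucs, stringsAsFactors = FALSE)
  raw <- raw[substr(raw$ref, 1, 1) != substr(raw$alt, 1, 1) &
               substr(raw$ref, 2, 2) != substr(raw$alt, 2, 2), ]
  sort(unique(canonicalDoublet(raw$ref, raw$alt)))
}

#' Monte Carlo test of double-substitution enrichment over chance adjacency
#'
#' The observed statistic is the number of adjacent substituted position
#' pairs in the catalog.  Each simulation places, for every chromosome, the
#' observed number of that chromosome's mutations (per substitution class,
#' whose per-chromosome prevalences the placement preserves) uniformly at
#' random without positional collision, and records the simulated
#' adjacent-pair count.  The empirical p-value is
#' \code{(1 + #\{sims with count >= observed\}) / (nSims + 1)} — never
#' exactly zero — and fold enrichment is observed over the simulated mean.
#'
#' @param catalog A \linkS4class{MutationCatalog}.
#' @param chromLengths Named vector of chromosome lengths.
#' @param nSims Number of simulations (>= 100; the study scale is 1000).
#' @param seed Integer seed.
#' @return List with \code{observed}, \code{nSims}, \code{simMean},
#'   \code{simMax}, \code{fold} (Inf with \code{foldInfinite = TRUE} when
#'   the simulated mean is zero), \code{p}, \code{simCounts} and
#'   \code{seed}.
#' @export
monteCarloAdjacencyTest <- function(catalog, chromLengths, nSims = 1000L,
                                    seed = 1L) {
  if (nSims < 100L) stopf("nSims must be >= 100")
  s <- substitutions(catalog)
  perChrom <- table(s$chrom)
  for (cn in names(perChrom))
    if (is.null(chromLengths[[cn]]) || chromLengths[[cn]] < perChrom[[cn]])
      stopf("chromosome %s shorter than its mutation count", cn)
  countAdjacent <- function(pos) sum(diff(sort.int(pos)) == 1L)
  observed <- sum(vapply(split(s$pos, s$chrom), countAdjacent, numeric(1)))
  sims <- localSeed(seed, {
    vapply(seq_len(nSims), function(i) {
      tot <- 0L
      for (cn in names(perChrom)) {
        pos <- sample.int(chromLengths[[cn]], perChrom[[cn]])
        tot <- tot + countAdjacent(pos)
      }
      tot
    }, integer(1))
  })
  m <- mean(sims)
  list(observed = observed, nSims = nSims, simMean = m, simMax = max(sims),
       fold = if (m == 0) Inf else observed / m, foldInfinite = m == 0,
       p = (1 + sum(sims >= observed)) / (nSims + 1),
       simCounts = sims, seed = as.integer(seed))
}
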