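# Event injection into synthetic catalogs: kataegis clusters, double
# substitutions, indels with known architecture, strand bias and
# expression effects.  Each injector returns the augmented catalog plus a
# truth record for recovery testing.

## Positions of TpC-context cytosines (either strand) within a window:
## forward "TC" puts the mutated C at match+1 with the pyrimidine forward;
## forward "GA" is a reverse-strand TpC with the mutated base (forward G)
## at the match start.
tpcSitesInWindow <- function(genome, chrom, start, end) {
  win <- getBases(genome, chrom, start, end)
  tc <- gregexpr("TC", win)[[1]]
  ga <- gregexpr("GA", win)[[1]]
  tc <- tc[tc > 0]; ga <- ga[ga > 0]
  data.frame(pos = c(start + tc, start + ga - 1L),
             pyrForward = rep(c(TRUE, FALSE), c(length(tc), length(ga))))
}

#' Inject kataegis clusters with linked rearrangements
#'
#' Each cluster places \code{clusterSize} mutations at TpC-context
#' cytosines within a random window of \code{span} bp, as C>T (probability
#' \code{pCtoT}) or C>G changes on the pyrimidine strand — the
#' TpC-focused, C>T/C>G spectrum characteristic of regional hypermutation.
#' One rearrangement with both breakpoints within
#' \code{rearrangementOffset} bp of the cluster is added per cluster.
#' Cluster members carry a shared phase annotation in the truth record
#' (co-phased by construction).  Overlaps with existing mutations are
#' resolved by redrawing the window, erroring after 100 attempts.
#'
#' @param catalog A \linkS4class{MutationCatalog}.
#' @param genome A \linkS4class{ReferenceGenome}.
#' @param nClusters Number of clusters to inject.
#' @param clusterSize Mutations per cluster (default 15).
#' @param span Window width in bp (default 5000).
#' @param pCtoT Probability of C>T (vs C>G) per mutation.
#' @param rearrangementOffset Max distance of linked breakpoints (bp).
#' @param seed Integer seed.
#' @return List with \code{catalog} (augmented) and \code{truth}
#'   (data.frames \code{clusters} with intervals and \code{members} with
#'   per-mutation cluster id and phase).
#' @export
injectKataegis <- function(catalog, genome, nClusters = 3L,
                           clusterSize = 15L, span = 5000L, pCtoT = 0.7,
                           rearrangementOffset = 10000L, seed = 1L) {
  lens <- chromLengths(genome)
  s <- substitutions(catalog)
  existing <- new.env(hash = TRUE)
  for (k in paste0(s$chrom, ":", s$pos)) assign(k, TRUE, envir = existing)
  localSeed(seed, {
    clusters <- NULL; members <- NULL; rearr <- NULL
    for (ci in seq_len(nClusters)) {
      done <- FALSE
      for (attempt in 1:100) {
        cn <- sample(names(lens), 1L, prob = lens)
        st <- sample.int(max(lens[[cn]] - span - 2L * rearrangementOffset -
                               200L, 1L), 1L) + rearrangementOffset + 100L
        sites <- tpcSitesInWindow(genome, cn, st, st + span - 1L)
        free <- !vapply(paste0(cn, ":", sites$pos), exists, logical(1),
                        envir = existing)
        sites <- sites[free, , drop = FALSE]
        if (nrow(sites) < clusterSize) next
        pick <- sites[sort(sample.int(nrow(sites), clusterSize)), ]
        pick <- pick[order(pick$pos), ]
        isCtoT <- runif(clusterSize) < pCtoT
        altPyr <- ifelse(isCtoT, "T", "G")
        ref <- ifelse(pick$pyrForward, "C", "G")
        alt <- ifelse(pick$pyrForward, altPyr, compBases(altPyr))
        for (k in paste0(cn, ":", pick$pos))
          assign(k, TRUE, envir = existing)
        members <- rbind(members, data.frame(
          cluster = ci, chrom = cn, pos = pick$pos, ref = ref, alt = alt,
          phase = sprintf("phase%02d", ci), stringsAsFactors = FALSE))
        clusters <- rbind(clusters, data.frame(
          cluster = ci, chrom = cn, start = min(pick$pos),
          end = max(pick$pos), n = clusterSize, stringsAsFactors = FALSE))
        bpA <- max(1L, min(pick$pos) - sample.int(rearrangementOffset, 1L))
        bpB <- min(lens[[cn]], max(pick$pos) +
                     sample.int(rearrangementOffset, 1L))
        rearr <- rbind(rearr, data.frame(
          chromA = cn, posA = bpA, strandA = "+", chromB = cn, posB = bpB,
          strandB = "-", class = "inversion", stringsAsFactors = FALSE))
        done <- TRUE
        break
      }
      if (!done) stopf("could not place kataegis cluster %d", ci)
    }
    subs <- rbind(s, members[c("chrom", "pos", "ref", "alt")])
    newCat <- MutationCatalog(sampleId(catalog), subs,
                              indels(catalog),
                              rbind(rearrangements(catalog), rearr))
    list(catalog = newCat,
         truth = list(clusters = clusters, members = members,
                      seed = seed))
  })
}

#' Inject adjacent double substitutions
#'
#' Adds \code{n} adjacent same-sample substitution pairs at random
#' positions whose two reference bases are unambiguous, avoiding positions
#' adjacent to existing mutations (so every injected event is a clean
#' doublet, not an extension of an existing run).
#'
#' @param catalog A \linkS4class{MutationCatalog}.
#' @param genome A \linkS4class{ReferenceGenome}.
#' @param n Number of doublets.
#' @param seed Integer seed.
#' @return List with \code{catalog} and \code{truth} (first-base positions
#'   of injected doublets).
#' @export
injectDoublets <- function(catalog, genome, n, seed = 1L) {
  if (n == 0L)
    return(list(catalog = catalog,
                truth = list(doublets = data.frame(chrom = character(0),
                                                   pos = integer(0)))))
  lens <- chromLengths(genome)
  s <- substitutions(catalog)
  existing <- new.env(hash = TRUE)
  for (k in paste0(s$chrom, ":", s$pos)) assign(k, TRUE, envir = existing)
  localSeed(seed, {
    placed <- data.frame(chrom = character(0), pos = integer(0),
                         ref1 = character(0), ref2 = character(0),
                         stringsAsFactors = FALSE)
    guard <- 0L
    while (nrow(placed) < n) {
      guard <- guard + 1L
      if (guard > 100L * n) stopf("could not place %d doublets", n)
      cn <- sample(names(lens), 1L, prob = lens)
      p <- sample.int(lens[[cn]] - 3L, 1L) + 1L
      keys <- paste0(cn, ":", (p - 1L):(p + 2L))
      if (any(vapply(keys, exists, logical(1), envir = existing))) next
      refs <- strsplit(getBases(genome, cn, p, p + 1L), "")[[1]]
      if (!all(refs %in% BASES)) next
      assign(keys[2], TRUE, envir = existing)
      assign(keys[3], TRUE, envir = existing)
      placed <- rbind(placed, data.frame(chrom = cn, pos = p,
                                         ref1 = refs[1], ref2 = refs[2],
                                         stringsAsFactors = FALSE))
    }
    alt1 <- vapply(placed$ref1, function(b) sample(setdiff(BASES, b), 1L),
                   character(1))
    alt2 <- vapply(placed$ref2, function(b) sample(setdiff(BASES, b), 1L),
                   character(1))
    add <- data.frame(
      chrom = rep(placed$chrom, each = 2L),
      pos = as.integer(t(cbind(placed$pos, placed$pos + 1L))),
      ref = as.vector(t(cbind(placed$ref1, placed$ref2))),
      alt = as.vector(t(cbind(alt1, alt2))), stringsAsFactors = FALSE)
    newCat <- MutationCatalog(sampleId(catalog), rbind(s, add),
                              indels(catalog), rearrangements(catalog))
    list(catalog = newCat,
         truth = list(doublets = placed[c("chrom", "pos")], seed = seed))
  })
}

#' Simulate indels with known architecture
#'
#' Plants deletions (and insertions for the repeat class) whose true class
#' is guaranteed by construction from the reference sequence:
#' \describe{
#'   \item{repeat}{a deletion of one whole unit (1-3 bp) with at least one
#'     further adjacent copy in the reference, found by rejection sampling.}
#'   \item{microhomology}{a deletion (6-30 bp) whose first \code{mhLen}
#'     deleted bases equal the reference immediately 3' of the deletion,
#'     with a mismatch at position \code{mhLen + 1} on both sides, and no
#'     whole-unit adjacent repeat.}
#'   \item{none}{a deletion (1-10 bp) with no junction identity (first
#'     base differs on both sides) and no adjacent repeat copy.}
#' }
#'
#' @param genome A \linkS4class{ReferenceGenome}.
#' @param nRepeat,nMicrohomology,nNone Counts per class.
#' @param mhLen Planted junction identity length (default 3).
#' @param sampleId Sample name attached to the records.
#' @param seed Integer seed.
#' @return data.frame of indel records with a \code{true_class} column.
#' @export
simulateIndels <- function(genome, nRepeat = 30L, nMicrohomology = 30L,
                           nNone = 30L, mhLen = 3L, sampleId = "S1",
                           seed = 1L) {
  lens <- chromLengths(genome)
  drawPos <- function(margin) {
    cn <- sample(names(lens), 1L, prob = lens)
    list(chrom = cn, pos = sample.int(lens[[cn]] - 2L * margin, 1L) + margin)
  }
  localSeed(seed, {
    rows <- list()
    ## repeat: delete one unit that has an adjacent 3' copy
    made <- 0L
    while (made < nRepeat) {
      u <- sample(1:3, 1L)
      at <- drawPos(100L)
      seq <- getBases(genome, at$chrom, at$pos + 1L, at$pos + u)
      nxt <- getBases(genome, at$chrom, at$pos + u + 1L, at$pos + 2L * u)
      if (seq != nxt || grepl("N", seq)) next
      made <- made + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sampleId, chrom = at$chrom, pos = at$pos,
        kind = "deletion", seq = seq, length = u, true_class = "repeat",
        stringsAsFactors = FALSE)
    }
    ## microhomology: prefix identity of exactly >= mhLen, no adjacent
    ## whole-unit repeat of the deleted sequence
    made <- 0L
    while (made < nMicrohomology) {
      L <- sample(6:30, 1L)
      at <- drawPos(100L)
      del <- getBases(genome, at$chrom, at$pos + 1L, at$pos + L)
      after <- getBases(genome, at$chrom, at$pos + L + 1L,
                        at$pos + L + mhLen + 1L)
      if (grepl("N", del) || nchar(after) < mhLen + 1L) next
      if (substr(del, 1L, mhLen) != substr(after, 1L, mhLen)) next
      if (substr(del, mhLen + 1L, mhLen + 1L) ==
            substr(after, mhLen + 1L, mhLen + 1L)) next
      unit <- smallestRepeatUnit(del, 6L)
      if (!is.null(unit)) {
        nxt <- getBases(genome, at$chrom, at$pos + L + 1L,
                        at$pos + L + nchar(unit))
        prv <- getBases(genome, at$chrom, at$pos - nchar(unit) + 1L, at$pos)
        if (identical(nxt, unit) || identical(prv, unit)) next
      }
      made <- made + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sampleId, chrom = at$chrom, pos = at$pos,
        kind = "deletion", seq = del, length = L,
        true_class = "microhomology", stringsAsFactors = FALSE)
    }
    ## none: no junction identity at the first base on either side and no
    ## adjacent repeat copy
    made <- 0L
    while (made < nNone) {
      L <- sample(1:10, 1L)
      at <- drawPos(100L)
      del <- getBases(genome, at$chrom, at$pos + 1L, at$pos + L)
      if (grepl("N", del)) next
      after1 <- getBases(genome, at$chrom, at$pos + L + 1L, at$pos + L + 1L)
      before1 <- getBases(genome, at$chrom, at$pos, at$pos)
      if (substr(del, 1L, 1L) == after1) next
      if (substr(del, L, L) == before1) next
      unit <- smallestRepeatUnit(del, 6L)
      if (!is.null(unit)) {
        nxt <- getBases(genome, at$chrom, at$pos + L + 1L,
                        at$pos + L + nchar(unit))
        prv <- getBases(genome, at$chrom, at$pos - nchar(unit) + 1L, at$pos)
        if (identical(nxt, unit) || identical(prv, unit)) next
      }
      made <- made + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sampleId, chrom = at$chrom, pos = at$pos,
        kind = "deletion", seq = del, length = L, true_class = "none",
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Impose a transcriptional strand bias on one substitution class
#'
#' Thins transcribed-strand mutations of the given pyrimidine-collapsed
#' class inside gene bodies, keeping each with probability
#' \code{1 / ratio}, so the surviving untranscribed:transcribed ratio is
#' approximately \code{ratio} times the unbiased expectation — emulating
#' transcription-coupled repair of one damaged base.
#'
#' @param catalog A \linkS4class{MutationCatalog}.
#' @param genes Gene annotation \code{GRanges}.
#' @param class Pyrimidine-collapsed class, e.g. \code{"C>A"}.
#' @param ratio Injected untranscribed:transcribed fold (default 2).
#' @param seed Integer seed.
#' @return List with \code{catalog} (thinned) and \code{truth}.
#' @export
applyStrandBias <- function(catalog, genes, class, ratio = 2, seed = 1L) {
  a <- assignStrand(catalog, genes)
  drop <- localSeed(seed, {
    cand <- a$class == class & a$assignment == "transcribed"
    cand & runif(nrow(a)) > 1 / ratio
  })
  s <- substitutions(catalog)[!drop, , drop = FALSE]
  list(catalog = MutationCatalog(sampleId(catalog), s, indels(catalog),
                                 rearrangements(catalog)),
       truth = list(class = class, ratio = ratio, nDropped = sum(drop),
                    seed = seed))
}

#' Impose an expression-dependent mutation rate
#'
#' Thins gene-body mutations so the retention probability falls as
#' \code{2^(slope * (expr - min(expr)))} with the owning gene's mean log2
#' expression (negative slopes suppress mutations in highly expressed
#' genes, e.g. \code{slope = -0.5} halves the rate per +2 log2 units).
#'
#' @param catalog A \linkS4class{MutationCatalog}.
#' @param genes Gene annotation \code{GRanges}.
#' @param expression Expression table (see [readExpression()]).
#' @param slope Injected log2-rate slope per log2-expression unit.
#' @param seed Integer seed.
#' @return List with \code{catalog} and \code{truth}.
#' @export
applyExpressionEffect <- function(catalog, genes, expression, slope,
                                  seed = 1L) {
  a <- assignStrand(catalog, genes)
  ex <- tapply(expression$log2expr, expression$gene_id, mean)
  base <- min(ex)
  keepP <- rep(1, nrow(a))
  inGene <- !is.na(a$gene_id) & a$gene_id %in% names(ex)
  keepP[inGene] <- pmin(1, 2^(slope * (ex[a$gene_id[inGene]] - base)))
  keep <- localSeed(seed, runif(nrow(a)) < keepP)
  s <- substitutions(catalog)[keep, , drop = FALSE]
  list(catalog = MutationCatalog(sampleId(catalog), s, indels(catalog),
                                 rearrangements(catalog)),
       truth = list(slope = slope, nDropped = sum(!keep), seed = seed))
}

#' Inject the full event battery into a base catalog
#'
#' Convenience wrapper applying, in order: kataegis clusters, doublets,
#' indels, strand bias and expression effect, each only when its spec is
#' supplied, and collecting all truth records.
#'
#' @param catalog A \linkS4class{MutationCatalog}.
#' @param genome A \linkS4class{ReferenceGenome}.
#' @param kataegisSpec List of arguments for [injectKataegis()], or NULL.
#' @param nDoublets Number of doublets to inject (0 for none).
#' @param indelSpec List of arguments for [simulateIndels()], or NULL.
#' @param strandBias List of arguments for [applyStrandBias()], or NULL.
#' @param expressionEffect List of arguments for
#'   [applyExpressionEffect()], or NULL.
#' @param genes,expression Annotation inputs for the last two injectors.
#' @param seed Integer seed (children derived per injector).
#' @return List with \code{catalog} and \code{truth} (one entry per
#'   applied injector).
#' @export
injectEvents <- function(catalog, genome, kataegisSpec = NULL,
                         nDoublets = 0L, indelSpec = NULL,
                         strandBias = NULL, expressionEffect = NULL,
                         genes = NULL, expression = NULL, seed = 1L) {
  seeds <- deriveSeeds(seed, 5L)
  truth <- list()
  if (!is.null(kataegisSpec)) {
    r <- do.call(injectKataegis, c(list(catalog = catalog, genome = genome,
                                        seed = seeds[1]), kataegisSpec))
    catalog <- r$catalog; truth$kataegis <- r$truth
  }
  if (nDoublets > 0L) {
    r <- injectDoublets(catalog, genome, nDoublets, seed = seeds[2])
    catalog <- r$catalog; truth$doublets <- r$truth
  }
  if (!is.null(indelSpec)) {
    ind <- do.call(simulateIndels, c(list(genome = genome,
                                          sampleId = sampleId(catalog),
                                          seed = seeds[3]), indelSpec))
    catalog <- MutationCatalog(sampleId(catalog), substitutions(catalog),
                               ind[c("chrom", "pos", "kind", "seq",
                                     "length")],
                               rearrangements(catalog))
    truth$indels <- ind
  }
  if (!is.null(strandBias)) {
    r <- do.call(applyStrandBias, c(list(catalog = catalog, genes = genes,
                                         seed = seeds[4]), strandBias))
    catalog <- r$catalog; truth$strandBias <- r$truth
  }
  if (!is.null(expressionEffect)) {
    r <- do.call(applyExpressionEffect,
                 c(list(catalog = catalog, genes = genes,
                        expression = expression, seed = seeds[5]),
                   expressionEffect))
    catalog <- r$catalog; truth$expressionEffect <- r$truth
  }
  list(catalog = catalog, truth = truth)
}
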