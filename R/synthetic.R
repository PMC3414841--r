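# Synthetic genomes, annotations and signature-mixture catalogs with full
# ground truth.  Every output is a pure function of (spec, seed).

#' Generate a toy genome with CpG islands, genes and expression values
#'
#' Chromosome sequences are i.i.d. bases at the requested GC content.
#' Island intervals are rewritten with a first-order chain that elevates
#' the C-to-G transition probability, producing CpG-enriched islands
#' against a CpG-depleted-free background.  Genes are placed without
#' overlap, with strands assigned at random and log2 expression drawn per
#' gene from a normal distribution.
#'
#' @param chromLengths Named vector of chromosome lengths (each >= 10 kb).
#' @param gc Genome GC content (default 0.41, human-like).
#' @param nIslands,islandLength,cpgBoost Number, length (bp) and C->G
#'   transition probability of CpG islands.
#' @param cpgDepletion Fraction of background CpG dinucleotides retained
#'   per depletion pass (CpG-to-GpC swaps emulate the genome-wide CpG
#'   depletion left by germline deamination; together with the island
#'   boost this yields an order-of-magnitude in-island CpG enrichment).
#' @param nGenes,geneMeanLength,geneSdLog Gene count and log-normal length
#'   distribution parameters.
#' @param exprMean,exprSd Per-gene log2 expression distribution (defaults
#'   span the 6..12 range typical of array data).
#' @param sampleIds Samples for which expression records are emitted.
#' @param seed Integer seed; identical (spec, seed) give identical output.
#' @return List with \code{genome} (\linkS4class{ReferenceGenome}),
#'   \code{genes} (\code{GRanges}), \code{islands} (\code{GRanges}),
#'   \code{expression} (data.frame) and the echoed \code{spec}.
#' @export
generateGenome <- function(chromLengths = c(chr1 = 3e6, chr2 = 3e6,
                                            chr3 = 2e6, chr4 = 2e6),
                           gc = 0.41, nIslands = 40L, islandLength = 1000L,
                           cpgBoost = 0.45, cpgDepletion = 0.15,
                           nGenes = 300L,
                           geneMeanLength = 10000L, geneSdLog = 0.5,
                           exprMean = 9, exprSd = 1.5,
                           sampleIds = "S1", seed = 1L) {
  if (any(chromLengths < 1e4)) stopf("chromosome lengths must be >= 10 kb")
  chromLengths <- round(chromLengths)
  baseProb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  localSeed(seed, {
    seqs <- lapply(chromLengths, function(L)
      sample(BASES, L, replace = TRUE, prob = baseProb))
    ## CpG-deplete the background (as deamination has depleted real
    ## genomes) by swapping most CpG dinucleotides to GpC; the swap
    ## preserves base composition exactly.  Two passes take care of CpGs
    ## recreated at the swap boundaries.
    for (cn in names(seqs)) {
      s <- seqs[[cn]]
      for (pass in 1:2) {
        isCG <- which(s[-length(s)] == "C" & s[-1L] == "G")
        kill <- isCG[runif(length(isCG)) > cpgDepletion]
        s[kill] <- "G"; s[kill + 1L] <- "C"
      }
      seqs[[cn]] <- s
    }
    ## islands: uniform placement, non-overlapping, then CpG-enriched
    ## rewrite with P(next = G | current = C) = cpgBoost
    islands <- placeIntervals(chromLengths, nIslands,
                              rep(islandLength, nIslands))
    for (i in seq_len(nrow(islands))) {
      L <- islands$end[i] - islands$start[i] + 1L
      s <- character(L)
      s[1] <- sample(BASES, 1L, prob = baseProb)
      for (p in 2:L) {
        s[p] <- if (s[p - 1L] == "C" && runif(1) < cpgBoost) "G"
        else sample(BASES, 1L, prob = baseProb)
      }
      seqs[[islands$chrom[i]]][islands$start[i]:islands$end[i]] <- s
    }
    ## genes: non-overlapping, random strand
    geneLens <- pmax(2000L, round(stats::rlnorm(nGenes,
                                                log(geneMeanLength),
                                                geneSdLog)))
    if (sum(geneLens) > 0.8 * sum(chromLengths))
      stopf("gene footprint exceeds 80%% of the genome; reduce nGenes")
    genes <- placeIntervals(chromLengths, nGenes, geneLens)
    genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    expr <- stats::rnorm(nrow(genes), exprMean, exprSd)
    expression <- do.call(rbind, lapply(sampleIds, function(sm)
      data.frame(gene_id = genes$gene_id, sample = sm, log2expr = expr,
                 stringsAsFactors = FALSE)))
    genome <- referenceFromSequences(
      vapply(seqs, paste, character(1), collapse = ""))
    list(genome = genome,
         genes = genesFromTable(genes),
         islands = GenomicRanges::reduce(sort(GenomicRanges::GRanges(
           islands$chrom, IRanges::IRanges(islands$start, islands$end)))),
         expression = expression,
         spec = list(chromLengths = chromLengths, gc = gc,
                     nIslands = nIslands, islandLength = islandLength,
                     cpgBoost = cpgBoost, nGenes = nGenes, seed = seed))
  })
}

## Place n non-overlapping intervals of given lengths uniformly over the
## chromosomes (rejection sampling; error when packing fails).
placeIntervals <- function(chromLengths, n, lens) {
  chroms <- names(chromLengths)
  ## place longest first: greatly improves packing under rejection sampling
  ord <- order(lens, decreasing = TRUE)
  lens <- lens[ord]
  placed <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:500) {
      cn <- sample(chroms, 1L, prob = chromLengths)
      maxStart <- chromLengths[[cn]] - lens[i] - 100L
      if (maxStart < 101L) next
      st <- sample.int(maxStart, 1L) + 100L
      en <- st + lens[i] - 1L
      same <- placed$chrom == cn
      if (!any(same & placed$start <= en & placed$end >= st)) {
        placed <- rbind(placed, data.frame(chrom = cn, start = st, end = en,
                                           stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
    }
    if (!ok) stopf("could not place interval %d without overlap", i)
  }
  placed
}

## Index all genomic sites of each of the 32 collapsed contexts.
## Returns a list per context: data.frame(chrom, pos, pyrForward).
contextSiteIndex <- function(genome) {
  seqs <- genomeSequences(genome)
  ctxs <- contextLabels()
  sites <- setNames(vector("list", 32L), ctxs)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(c(ctxs, revcomp(ctxs))))
  for (cn in names(seqs)) {
    m <- Biostrings::matchPDict(pd, seqs[[cn]])
    starts <- BiocGenerics::start(m)
    for (i in seq_len(32L)) {
      fwd <- starts[[i]]
      rev <- starts[[i + 32L]]
      n <- length(fwd) + length(rev)
      df <- data.frame(chrom = rep(cn, n), pos = c(fwd, rev) + 1L,
                       pyrForward = rep(c(TRUE, FALSE),
                                        c(length(fwd), length(rev))),
                       stringsAsFactors = FALSE)
      sites[[i]] <- rbind(sites[[i]], df)
    }
  }
  sites
}

#' Simulate a multi-sample substitution catalog from a signature mixture
#'
#' For each sample, 96-channel counts are drawn multinomially from the
#' mixture \code{signatures \%*\% exposure}, and each channel's mutations
#' are placed uniformly at random, without replacement, among the genome
#' sites whose (strand-collapsed) trinucleotide context matches the
#' channel.  Sites are indexed on both strands, so purine- and
#' pyrimidine-strand presentations occur in their genomic proportions
#' (about 50/50).
#'
#' @param genome A \linkS4class{ReferenceGenome}.
#' @param signatures 96 x k nonnegative matrix, columns summing to 1.
#' @param exposuresTrue k x M matrix of per-sample signature weights
#'   (columns summing to 1).
#' @param nMutations Integer vector of per-sample total mutation counts.
#' @param sampleIds Sample names (default S01..SM).
#' @param seed Integer seed.
#' @param siteIndex Optional precomputed [contextSiteIndex()] (reused
#'   across calls for speed).
#' @return List with \code{catalogs} (list of
#'   \linkS4class{MutationCatalog}) and \code{truth} (list:
#'   \code{signatures}, \code{exposures}, \code{channelCounts},
#'   \code{nMutations}, \code{seed}).
#' @export
simulateCatalog <- function(genome, signatures, exposuresTrue, nMutations,
                            sampleIds = NULL, seed = 1L, siteIndex = NULL) {
  stopifnot(nrow(signatures) == 96L,
            ncol(signatures) == nrow(exposuresTrue))
  M <- ncol(exposuresTrue)
  if (length(nMutations) == 1L) nMutations <- rep(nMutations, M)
  stopifnot(length(nMutations) == M)
  if (is.null(sampleIds)) sampleIds <- sprintf("S%02d", seq_len(M))
  if (is.null(siteIndex)) siteIndex <- contextSiteIndex(genome)
  chTab <- channelTable()
  channelCounts <- matrix(0L, 96L, M,
                          dimnames = list(channelLabels(), sampleIds))
  catalogs <- localSeed(seed, {
    lapply(seq_len(M), function(j) {
      p <- as.vector(signatures %*% exposuresTrue[, j])
      p <- p / sum(p)
      counts <- as.vector(stats::rmultinom(1L, nMutations[j], p))
      channelCounts[, j] <<- counts
      rows <- vector("list", 32L)
      for (ctx in contextLabels()) {
        chIdx <- which(chTab$context == ctx)
        need <- counts[chIdx]
        tot <- sum(need)
        if (tot == 0L) next
        pool <- siteIndex[[ctx]]
        if (nrow(pool) < tot)
          stopf("context %s: need %d sites, only %d available", ctx, tot,
                nrow(pool))
        pick <- pool[sample.int(nrow(pool), tot), , drop = FALSE]
        altPyr <- rep(chTab$alt[chIdx], need)
        ref <- ifelse(pick$pyrForward, substr(ctx, 2, 2),
                      compBases(substr(ctx, 2, 2)))
        alt <- ifelse(pick$pyrForward, altPyr, compBases(altPyr))
        rows[[match(ctx, contextLabels())]] <-
          data.frame(chrom = pick$chrom, pos = pick$pos, ref = ref,
                     alt = alt, stringsAsFactors = FALSE)
      }
      subs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      MutationCatalog(sampleIds[j], subs)
    })
  })
  names(catalogs) <- sampleIds
  list(catalogs = catalogs,
       truth = list(signatures = signatures, exposures = exposuresTrue,
                    channelCounts = channelCounts,
                    nMutations = nMutations, seed = as.integer(seed)))
}

#' Study-shaped default signature set
#'
#' Five synthetic mutational signatures over the 96 channels mirroring the
#' qualitative architecture recovered from breast cancer genomes: an
#' XpCpG C>T deamination-like signature (A), a TpCpX C>T/C>G/C>A
#' APOBEC-like signature (B), a near-flat signature moderately enriched
#' for XpCpG C>T/C>G/C>A (C), a flat signature (D), and a TpCpX
#' C>G-dominated signature (E).
#'
#' @return 96 x 5 matrix with columns summing to 1, named A..E.
#' @export
studySignatures <- function() {
  tab <- channelTable()
  flat <- rep(1 / 96, 96)
  mass <- function(sel) ifelse(sel, 1, 0) / sum(sel)
  xpcpg <- tab$three == "G" & tab$ref == "C"
  tpcpx <- tab$five == "T" & tab$ref == "C"
  A <- 0.75 * mass(xpcpg & tab$class == "C>T") + 0.25 * flat
  B <- 0.45 * mass(tpcpx & tab$class == "C>T") +
    0.20 * mass(tpcpx & tab$class == "C>G") +
    0.15 * mass(tpcpx & tab$class == "C>A") + 0.20 * flat
  C <- 0.15 * mass(xpcpg & tab$class == "C>T") +
    0.30 * mass(xpcpg & tab$class == "C>G") +
    0.15 * mass(xpcpg & tab$class == "C>A") + 0.40 * flat
  D <- flat
  E <- 0.60 * mass(tpcpx & tab$class == "C>G") + 0.40 * flat
  W <- cbind(A = A, B = B, C = C, D = D, E = E)
  rownames(W) <- tab$label
  W
}

#' Study-shaped random exposures
#'
#' Signature weights for M samples: every signature dominates two anchor
#' samples (exposure 0.75 plus a Dirichlet remainder) — each mutational
#' process is the dominant one in some tumors — and the remaining samples
#' draw sparse Dirichlet mixtures.
#'
#' @param M Number of samples (default 21).
#' @param k Number of signatures (default 5).
#' @param alpha Dirichlet concentration for the mixed samples (default
#'   0.6; sparse mixtures).
#' @param seed Integer seed.
#' @return k x M matrix with columns summing to 1.
#' @export
studyExposures <- function(M = 21L, k = 5L, alpha = 0.6, seed = 1L) {
  localSeed(seed, {
    g <- matrix(stats::rgamma(k * M, alpha), k, M)
    E <- sweep(g, 2L, colSums(g), "/")
    nAnchor <- min(M, 2L * k)
    for (j in seq_len(nAnchor)) {
      sig <- (j - 1L) %% k + 1L
      E[, j] <- 0.25 * E[, j]
      E[sig, j] <- E[sig, j] + 0.75
    }
    E
  })
}

#' Generate the default study-shaped cohort end to end
#'
#' Convenience wrapper producing a 21-sample substitution cohort from the
#' five [studySignatures()] on a toy genome: exposures from
#' [studyExposures()], per-sample totals uniform between 2,000 and 10,000
#' mutations, positions placed by [simulateCatalog()].
#'
#' @param seed Integer seed controlling every random choice.
#' @param M Number of samples (default 21).
#' @param genome Optional \linkS4class{ReferenceGenome}; by default a
#'   10 Mb, 4-chromosome toy genome is generated (seed-derived).
#' @param siteIndex Optional precomputed site index for \code{genome}.
#' @return As [simulateCatalog()], plus the \code{genome} used.
#' @export
studyCohort <- function(seed = 1L, M = 21L, genome = NULL,
                        siteIndex = NULL) {
  seeds <- deriveSeeds(seed, 4L)
  if (is.null(genome))
    genome <- generateGenome(chromLengths = c(chr1 = 3e6, chr2 = 3e6,
                                              chr3 = 2e6, chr4 = 2e6),
                             seed = seeds[1])$genome
  W <- studySignatures()
  E <- studyExposures(M = M, seed = seeds[2])
  nMut <- localSeed(seeds[3], sample(2000:10000, M, replace = TRUE))
  sim <- simulateCatalog(genome, W, E, nMutations = nMut, seed = seeds[4],
                         siteIndex = siteIndex)
  sim$genome <- genome
  sim
}

#' Position-only synthetic catalog with injected adjacent doublets
#'
#' Places background substitutions uniformly (no positional collisions)
#' over the given chromosome lengths and injects the requested number of
#' adjacent-pair double substitutions, keeping the total mutation count as
#' specified.  Substitution classes are assigned at random; no reference
#' sequence is involved, which is sufficient for position-level analyses
#' (intermutation distances, adjacency enrichment).
#'
#' @param chromLengths Named vector of chromosome lengths.
#' @param nMutations Total substitutions in the catalog.
#' @param nDoublets Number of injected adjacent pairs (2 mutations each,
#'   counted within \code{nMutations}).
#' @param sampleId Sample name.
#' @param seed Integer seed.
#' @return List with \code{catalog} and \code{truth} (injected doublet
#'   first-base positions).
#' @export
simulatePositionCatalog <- function(chromLengths, nMutations,
                                    nDoublets = 0L, sampleId = "SIM",
                                    seed = 1L) {
  stopifnot(nMutations >= 2L * nDoublets)
  localSeed(seed, {
    nBg <- nMutations - 2L * nDoublets
    probs <- chromLengths / sum(chromLengths)
    bgChrom <- sample(names(chromLengths), nBg, replace = TRUE,
                      prob = probs)
    rows <- lapply(names(chromLengths), function(cn) {
      n <- sum(bgChrom == cn)
      if (!n) return(NULL)
      data.frame(chrom = cn, pos = sample.int(chromLengths[[cn]], n),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    taken <- new.env(hash = TRUE)
    for (i in seq_len(nrow(df)))
      assign(paste0(df$chrom[i], ":", df$pos[i]), TRUE, envir = taken)
    injected <- data.frame(chrom = character(0), pos = integer(0),
                           stringsAsFactors = FALSE)
    while (nrow(injected) < nDoublets) {
      cn <- sample(names(chromLengths), 1L, prob = probs)
      p <- sample.int(chromLengths[[cn]] - 2L, 1L)
      keys <- paste0(cn, ":", (p - 1L):(p + 2L))
      if (any(vapply(keys, exists, logical(1), envir = taken))) next
      assign(keys[2], TRUE, envir = taken)
      assign(keys[3], TRUE, envir = taken)
      injected <- rbind(injected, data.frame(chrom = cn, pos = p,
                                             stringsAsFactors = FALSE))
    }
    all <- rbind(df, data.frame(chrom = rep(injected$chrom, each = 2L),
                                pos = as.integer(t(cbind(injected$pos,
                                                         injected$pos + 1L)))))
    dup <- duplicated(paste(all$chrom, all$pos))
    all <- all[!dup, , drop = FALSE]
    ref <- sample(BASES, nrow(all), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L),
                  character(1))
    cat <- MutationCatalog(sampleId,
                           data.frame(chrom = all$chrom, pos = all$pos,
                                      ref = ref, alt = unname(alt),
                                      stringsAsFactors = FALSE))
    list(catalog = cat, truth = list(doublets = injected, seed = seed))
  })
}
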