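# Transcriptional strand bias, expression-binned mutation prevalence, and
# TSS-distance mutation profiles.

#' @importFrom stats binom.test glm poisson pnorm coef
NULL

subsAsGRanges <- function(s)
  GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, width = 1L))

#' Assign substitutions to the transcribed or untranscribed gene strand
#'
#' Each substitution is presented with its mutated pyrimidine: when the
#' reference base is C or T the pyrimidine lies on the forward strand,
#' otherwise on the reverse strand.  For a gene on the + strand the forward
#' strand is the untranscribed (coding) strand, so a forward-strand
#' pyrimidine is assigned "untranscribed"; for a - strand gene it is
#' assigned "transcribed"; both flip when the pyrimidine is on the reverse
#' strand.  Positions overlapping genes on both strands are "ambiguous"
#' (excluded from tests); positions in no gene are "intergenic".
#'
#' @param catalog A \linkS4class{MutationCatalog} (or substitution
#'   data.frame).
#' @param genes Gene annotation \code{GRanges} (see [readGenes()]).
#' @return The substitution table with added columns \code{class}
#'   (pyrimidine-collapsed), \code{assignment} and \code{gene_id} (NA
#'   outside genes or when ambiguous).
#' @export
assignStrand <- function(catalog, genes) {
  s <- if (is(catalog, "MutationCatalog")) substitutions(catalog) else catalog
  s$class <- collapseClass(s$ref, s$alt)
  s$assignment <- "intergenic"
  s$gene_id <- NA_character_
  if (nrow(s) == 0L) {
    s$assignment <- factor(s$assignment,
                           levels = c("transcribed", "untranscribed",
                                      "intergenic", "ambiguous"))
    return(s)
  }
  hits <- GenomicRanges::findOverlaps(subsAsGRanges(s), genes,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  strands <- as.character(GenomicRanges::strand(genes))[sh]
  plus <- tapply(strands == "+", qh, any)
  minus <- tapply(strands == "-", qh, any)
  idx <- as.integer(names(plus))
  both <- plus & minus
  s$assignment[idx[both]] <- "ambiguous"
  single <- idx[!both]
  geneStrand <- ifelse(plus[!both], "+", "-")
  pyrForward <- s$ref[single] %in% PYRIMIDINES
  s$assignment[single] <- ifelse(pyrForward == (geneStrand == "+"),
                                 "untranscribed", "transcribed")
  firstHit <- !duplicated(qh)
  ownGene <- setNames(genes$gene_id[sh[firstHit]], qh[firstHit])
  s$gene_id[single] <- ownGene[as.character(single)]
  s$assignment <- factor(s$assignment,
                         levels = c("transcribed", "untranscribed",
                                    "intergenic", "ambiguous"))
  s
}

## Per-strand at-risk pyrimidine content within gene footprints:
## counts of base `pyr` presented on the untranscribed and transcribed
## strands, summed over genes.
strandRiskContent <- function(genome, genes, pyr) {
  seqs <- genomeSequences(genome)
  untrans <- trans <- 0
  for (i in seq_along(genes)) {
    cn <- as.character(GenomicRanges::seqnames(genes))[i]
    span <- getBases(genome, cn, GenomicRanges::start(genes)[i],
                     GenomicRanges::end(genes)[i])
    nPyr <- lengths(regmatches(span, gregexpr(pyr, span)))
    nComp <- lengths(regmatches(span, gregexpr(compBases(pyr), span)))
    if (as.character(GenomicRanges::strand(genes))[i] == "+") {
      untrans <- untrans + nPyr; trans <- trans + nComp
    } else {
      untrans <- untrans + nComp; trans <- trans + nPyr
    }
  }
  c(transcribed = trans, untranscribed = untrans)
}

#' Exact binomial test of transcriptional strand bias
#'
#' Counts mutations of one pyrimidine-collapsed class on the transcribed
#' versus untranscribed strands of genes and tests the transcribed count
#' against the expected transcribed proportion with a two-sided exact
#' binomial test.  The expected proportion corrects for base composition:
#' it is the share of at-risk pyrimidines (the class's reference base)
#' presented on the transcribed strand within gene footprints.
#'
#' @param assigned Output of [assignStrand()] (pooled across samples as
#'   needed).
#' @param classPair Pyrimidine-collapsed class, e.g. \code{"C>A"} (which
#'   covers G>T presentations).
#' @param genome,genes Used to compute the expected proportion; pass
#'   \code{expected} directly to skip.
#' @param expected Optional expected transcribed proportion.
#' @return List with \code{transcribed}, \code{untranscribed},
#'   \code{expected}, \code{p} (NA when no mutations are assigned).
#' @export
strandBiasTest <- function(assigned, classPair, genome = NULL, genes = NULL,
                           expected = NULL) {
  if (!classPair %in% SUB_CLASSES)
    stopf("classPair must be one of: %s", paste(SUB_CLASSES, collapse = ", "))
  if (is.null(expected)) {
    if (is.null(genome) || is.null(genes))
      stopf("supply either expected or genome + genes")
    risk <- strandRiskContent(genome, genes, substr(classPair, 1, 1))
    expected <- risk[["transcribed"]] / sum(risk)
  }
  sel <- assigned$class == classPair &
    assigned$assignment %in% c("transcribed", "untranscribed")
  tr <- sum(assigned$assignment[sel] == "transcribed")
  un <- sum(sel) - tr
  if (tr + un == 0L)
    return(list(transcribed = 0L, untranscribed = 0L, expected = expected,
                p = NA_real_))
  p <- binom.test(tr, tr + un, p = expected,
                  alternative = "two.sided")$p.value
  list(transcribed = tr, untranscribed = un, expected = expected, p = p)
}

#' Mutation prevalence by gene-expression level, with trend test
#'
#' Genes with expression values are ranked by mean log2 expression across
#' samples and cut into \code{nBins} equal-gene bins; per bin the pooled
#' gene-body mutation count is expressed per Mb of binned gene footprint.
#' The expression trend is tested by a log-linear Poisson rate regression
#' of per-gene mutation counts on mean log2 expression with log gene length
#' as exposure offset; the one-sided p-value for a negative slope (fewer
#' mutations in highly expressed genes) is reported alongside the slope and
#' its standard error.
#'
#' @param catalogs List of \linkS4class{MutationCatalog} (pooled) or one
#'   catalog.
#' @param genes Gene annotation \code{GRanges}.
#' @param expression Expression table from [readExpression()].
#' @param nBins Number of equal-gene bins (default 8).
#' @param class Optional pyrimidine-collapsed class restriction, e.g.
#'   \code{"C>A"}.
#' @return List with \code{bins} (data.frame: \code{bin}, \code{meanExpr},
#'   \code{nGenes}, \code{mutations}, \code{footprintMb},
#'   \code{mutationsPerMb}) and \code{trend} (\code{slope}, \code{se},
#'   \code{pOneSided}).
#' @export
expressionPrevalence <- function(catalogs, genes, expression, nBins = 8L,
                                 class = NULL) {
  if (is(catalogs, "MutationCatalog")) catalogs <- list(catalogs)
  exprMean <- tapply(expression$log2expr, expression$gene_id, mean)
  keep <- genes$gene_id %in% names(exprMean)
  genes <- genes[keep]
  if (nBins > length(genes)) stopf("nBins exceeds gene count")
  ex <- exprMean[genes$gene_id]
  len <- GenomicRanges::width(genes)
  counts <- integer(length(genes))
  for (cat in catalogs) {
    s <- substitutions(cat)
    if (!is.null(class))
      s <- s[collapseClass(s$ref, s$alt) == class, , drop = FALSE]
    if (!nrow(s)) next
    hits <- GenomicRanges::findOverlaps(subsAsGRanges(s), genes,
                                        ignore.strand = TRUE)
    tab <- table(S4Vectors::subjectHits(hits))
    counts[as.integer(names(tab))] <- counts[as.integer(names(tab))] +
      as.integer(tab)
  }
  bin <- ceiling(rank(ex, ties.method = "first") / length(ex) * nBins)
  bins <- do.call(rbind, lapply(seq_len(nBins), function(b) {
    i <- bin == b
    mb <- sum(len[i]) / 1e6
    data.frame(bin = b, meanExpr = mean(ex[i]), nGenes = sum(i),
               mutations = sum(counts[i]), footprintMb = mb,
               mutationsPerMb = sum(counts[i]) / mb)
  }))
  fit <- glm(counts ~ ex + offset(log(len)), family = poisson())
  sm <- summary(fit)$coefficients
  slope <- sm["ex", "Estimate"]; se <- sm["ex", "Std. Error"]
  list(bins = bins,
       trend = list(slope = slope, se = se,
                    pOneSided = pnorm(slope / se)))
}

#' Fraction of genes mutated by distance downstream of the TSS
#'
#' Distances are measured from each gene's transcription start site in the
#' direction of transcription.  The coarse profile uses \code{coarseBin} bp
#' bins out to \code{maxDist}; the fine profile uses \code{fineBin} bp bins
#' within the first coarse bin.  A bin's value is the percentage of genes
#' carrying at least one substitution (any strand) in that bin; genes whose
#' transcript does not extend to a bin's far edge are excluded from that
#' bin's denominator.
#'
#' @param catalogs List of \linkS4class{MutationCatalog} or one catalog.
#' @param genes Gene annotation \code{GRanges}.
#' @param coarseBin,fineBin,maxDist Bin widths and range in bp.
#' @return List of data.frames \code{coarse} and \code{fine}, each with
#'   \code{binStart}, \code{binEnd} (distances, 0-based half-open),
#'   \code{nGenes}, \code{nMutated}, \code{percentMutated}.
#' @export
tssProfile <- function(catalogs, genes, coarseBin = 1000L, fineBin = 100L,
                       maxDist = 200000L) {
  if (is(catalogs, "MutationCatalog")) catalogs <- list(catalogs)
  if (length(genes) == 0L)
    return(list(coarse = data.frame(), fine = data.frame()))
  strand <- as.character(GenomicRanges::strand(genes))
  geneLen <- GenomicRanges::width(genes)
  ## per mutation x overlapping gene: distance downstream of the TSS
  dists <- vector("list", length(catalogs))
  for (ci in seq_along(catalogs)) {
    s <- substitutions(catalogs[[ci]])
    if (!nrow(s)) next
    hits <- GenomicRanges::findOverlaps(subsAsGRanges(s), genes,
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    d <- ifelse(strand[sh] == "+", s$pos[qh] - genes$tss[sh],
                genes$tss[sh] - s$pos[qh])
    dists[[ci]] <- data.frame(gene = sh, d = d)
  }
  dd <- do.call(rbind, dists)
  profileFor <- function(lo, hi) {
    eligible <- geneLen >= hi
    n <- sum(eligible)
    mutated <- if (is.null(dd)) 0L else
      length(unique(dd$gene[dd$d >= lo & dd$d < hi &
                              eligible[dd$gene]]))
    data.frame(binStart = lo, binEnd = hi, nGenes = n, nMutated = mutated,
               percentMutated = if (n) 100 * mutated / n else NA_real_)
  }
  coarseEdges <- seq(0L, maxDist, by = coarseBin)
  coarse <- do.call(rbind, Map(profileFor, coarseEdges[-length(coarseEdges)],
                               coarseEdges[-1]))
  fineEdges <- seq(0L, coarseBin, by = fineBin)
  fine <- do.call(rbind, Map(profileFor, fineEdges[-length(fineEdges)],
                             fineEdges[-1]))
  list(coarse = coarse, fine = fine)
}
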