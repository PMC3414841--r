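# Strand assignment, strand-bias testing, expression-binned prevalence and
# TSS-distance profiles.

twoGeneAnnotation <- function() {
  genesFromTable(data.frame(
    gene_id = c("plus", "minus", "far"),
    chrom = c("chr1", "chr1", "chr1"),
    start = c(1000L, 5000L, 20000L),
    end = c(2999L, 6999L, 29999L),
    strand = c("+", "-", "+")))
}

test_that("strand assignment follows the pyrimidine convention and partitions", {
  genes <- twoGeneAnnotation()
  subs <- data.frame(chrom = "chr1",
                     pos = c(1500L, 5500L, 10000L),
                     ref = c("C", "C", "C"), alt = c("T", "T", "T"))
  a <- assignStrand(MutationCatalog("S1", subs), genes)
  ## forward-strand pyrimidine: untranscribed in a + gene, transcribed in -
  expect_identical(as.character(a$assignment),
                   c("untranscribed", "transcribed", "intergenic"))
  ## purine presentation flips the assignment
  subs$ref <- "G"; subs$alt <- "A"
  a2 <- assignStrand(MutationCatalog("S1", subs), genes)
  expect_identical(as.character(a2$assignment),
                   c("transcribed", "untranscribed", "intergenic"))
  ## an overlapping +/- gene pair is ambiguous
  overlapping <- genesFromTable(data.frame(
    gene_id = c("a", "b"), chrom = "chr1", start = c(1000L, 1500L),
    end = c(3000L, 3500L), strand = c("+", "-")))
  a3 <- assignStrand(MutationCatalog("S1", data.frame(
    chrom = "chr1", pos = 2000L, ref = "C", alt = "T")), overlapping)
  expect_identical(as.character(a3$assignment), "ambiguous")
  expect_true(is.na(a3$gene_id))
})

test_that("assignment counts sum to catalog size and swap under strand flip", {
  bundle <- toyBundle()
  cat <- toyCohort()$catalogs[[1]]
  a <- assignStrand(cat, bundle$genes)
  expect_identical(nrow(a), nrow(substitutions(cat)))
  expect_false(anyNA(a$assignment))
  flipped <- bundle$genes
  GenomicRanges::strand(flipped) <-
    ifelse(as.character(GenomicRanges::strand(bundle$genes)) == "+", "-", "+")
  flipped$tss <- ifelse(as.character(GenomicRanges::strand(flipped)) == "+",
                        GenomicRanges::start(flipped),
                        GenomicRanges::end(flipped))
  b <- assignStrand(cat, flipped)
  expect_identical(sum(a$assignment == "transcribed"),
                   sum(b$assignment == "untranscribed"))
  expect_identical(sum(a$assignment == "untranscribed"),
                   sum(b$assignment == "transcribed"))
  expect_identical(a$assignment == "intergenic", b$assignment == "intergenic")
})

test_that("the strand-bias p-value is the exact binomial tail", {
  balanced <- data.frame(class = "C>A",
                         assignment = rep(c("transcribed", "untranscribed"),
                                          each = 50))
  res <- strandBiasTest(balanced, "C>A", expected = 0.5)
  expect_equal(res$p, 1)
  skewed <- data.frame(class = "C>A",
                       assignment = rep(c("transcribed", "untranscribed"),
                                        c(100, 10)))
  res2 <- strandBiasTest(skewed, "C>A", expected = 0.5)
  expect_equal(res2$p, binom.test(100, 110, 0.5)$p.value, tolerance = 1e-12)
  empty <- strandBiasTest(balanced[0, ], "C>A", expected = 0.5)
  expect_true(is.na(empty$p))
})

test_that("an injected 2:1 untranscribed bias is detected with the right direction", {
  bundle <- toyBundle()
  genes <- bundle$genes
  ## candidate C/G positions inside gene bodies
  seqs <- as.character(genomeSequences(bundle$genome))
  cand <- NULL
  for (i in seq_along(genes)) {
    cn <- as.character(GenomicRanges::seqnames(genes))[i]
    span <- GenomicRanges::start(genes)[i]:GenomicRanges::end(genes)[i]
    b <- strsplit(substr(seqs[[cn]], span[1], span[length(span)]), "")[[1]]
    sel <- b %in% c("C", "G")
    cand <- rbind(cand, data.frame(chrom = cn, pos = span[sel],
                                   ref = b[sel]))
  }
  cand <- cand[!duplicated(paste(cand$chrom, cand$pos)), ]
  detected <- 0L
  for (seed in 1:20) {
    sub <- withr::with_seed(seed, cand[sample.int(nrow(cand), 5000L), ])
    sub$alt <- ifelse(sub$ref == "C", "A", "T")  # C>A class both strands
    cat <- MutationCatalog("S1", sub)
    thin <- applyStrandBias(cat, genes, "C>A", ratio = 2, seed = seed + 100)
    a <- assignStrand(thin$catalog, genes)
    res <- strandBiasTest(a, "C>A", bundle$genome, genes)
    obsTransFrac <- res$transcribed / (res$transcribed + res$untranscribed)
    if (res$p < 1e-6 && obsTransFrac < res$expected)
      detected <- detected + 1L
  }
  expect_gte(detected, 19L)
})

test_that("expression-binned prevalence and the trend test behave under null and signal", {
  bundle <- toyBundle()
  genes <- bundle$genes
  expr <- bundle$expression
  ## null: uniform placement, slope within 2 SE of zero in most seeds
  nullOK <- 0L
  for (seed in 1:30) {
    sim <- simulatePositionCatalog(chromLengths(bundle$genome), 3000L,
                                   seed = seed)
    ep <- expressionPrevalence(sim$catalog, genes, expr, nBins = 5L)
    if (abs(ep$trend$slope) < 2 * ep$trend$se) nullOK <- nullOK + 1L
  }
  expect_gte(nullOK, 27L)  # ~95% coverage, allow slack
  ## single bin: prevalence equals total gene-body mutations per footprint
  sim <- simulatePositionCatalog(chromLengths(bundle$genome), 3000L,
                                 seed = 99)
  ep1 <- expressionPrevalence(sim$catalog, genes, expr, nBins = 1L)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(substitutions(sim$catalog)$chrom,
                           IRanges::IRanges(substitutions(sim$catalog)$pos,
                                            width = 1L)),
    genes, ignore.strand = TRUE)
  total <- length(unique(S4Vectors::queryHits(hits)))
  expect_gte(ep1$bins$mutations, total)  # nested genes may double-count
  expect_equal(ep1$bins$footprintMb,
               sum(GenomicRanges::width(genes)) / 1e6)
  expect_error(expressionPrevalence(sim$catalog, genes, expr,
                                    nBins = 1000L), "exceeds")
})

test_that("an injected negative expression slope is recovered", {
  bundle <- toyBundle()
  genes <- bundle$genes
  expr <- bundle$expression
  slopes <- numeric(10)
  for (seed in 1:10) {
    sim <- simulatePositionCatalog(chromLengths(bundle$genome), 12000L,
                                   seed = seed + 300)
    thin <- applyExpressionEffect(sim$catalog, genes, expr, slope = -0.5,
                                  seed = seed + 400)
    ep <- expressionPrevalence(thin$catalog, genes, expr, nBins = 5L)
    ## the generator thins by 2^(slope * expr): the Poisson log-rate slope
    ## recovered should be slope * log(2)
    slopes[seed] <- ep$trend$slope / log(2)
    expect_lt(ep$trend$pOneSided, 0.05)
  }
  expect_lt(abs(mean(slopes) - (-0.5)), 0.1)  # within 20%
})

test_that("the TSS profile bins distances downstream of the TSS", {
  genes <- twoGeneAnnotation()
  ## mutations exactly at TSS + 50500 of gene "far" (+ strand, TSS 20000)
  cat <- MutationCatalog("S1", data.frame(chrom = "chr1", pos = 25500L,
                                          ref = "C", alt = "T"))
  tp <- tssProfile(cat, genes, coarseBin = 1000L, maxDist = 10000L)
  nz <- which(tp$coarse$nMutated > 0)
  expect_identical(tp$coarse$binStart[nz], 5000L)  # bin 6: 5000..5999
  ## genes shorter than a bin's far edge leave its denominator
  expect_identical(tp$coarse$nGenes[1], 3L)   # all genes span >= 1 kb
  expect_identical(tp$coarse$nGenes[10], 1L)  # only "far" spans 10 kb
  expect_true(all(diff(tp$coarse$nGenes) <= 0L))
})

test_that("a near-TSS suppression ramp produces a rising fine profile", {
  ## 60 long + genes; mutation rate ramps linearly over the first 1 kb
  genes <- genesFromTable(data.frame(
    gene_id = sprintf("g%02d", 1:60), chrom = "chr1",
    start = seq(1L, by = 40000L, length.out = 60), strand = "+",
    end = seq(1L, by = 40000L, length.out = 60) + 29999L))
  detected <- 0L
  for (seed in 1:30) {
    pos <- withr::with_seed(seed, {
      d <- as.integer(1000 * sqrt(runif(1200)))  # density ~ distance
      g <- sample.int(60, 1200, replace = TRUE)
      unique(genes$tss[g] + d)
    })
    cat <- MutationCatalog("S1", data.frame(chrom = "chr1", pos = pos,
                                            ref = "C", alt = "T"))
    tp <- tssProfile(cat, genes, maxDist = 10000L)
    kt <- suppressWarnings(
      cor.test(tp$fine$percentMutated, seq_len(nrow(tp$fine)),
               method = "kendall", alternative = "greater"))
    if (kt$p.value < 0.05) detected <- detected + 1L
  }
  expect_gte(detected, 27L)
})
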