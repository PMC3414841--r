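# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## 300 kb two-chromosome toy genome with islands, genes and expression.
toyBundle <- function() fixture("bundle", function()
  generateGenome(chromLengths = c(chr1 = 2e5, chr2 = 1e5), nIslands = 12L,
                 islandLength = 800L, nGenes = 30L, geneMeanLength = 3000L,
                 sampleIds = c("S01", "S02"), seed = 42L))

toyGenome <- function() toyBundle()$genome

toySiteIndex <- function() fixture("siteIndex", function()
  mutforge:::contextSiteIndex(toyGenome()))

## Small signature-mixture cohort on the toy genome.
toyCohort <- function() fixture("cohort", function() {
  W <- studySignatures()
  E <- studyExposures(M = 6L, seed = 7L)
  simulateCatalog(toyGenome(), W, E, nMutations = 600L, seed = 11L,
                  siteIndex = toySiteIndex())
})

## Random substitution table helper (no genome involved).
randomSubs <- function(n, sample = "S1", chromLengths = c(chr1 = 1e6),
                       seed = 1) {
  withr::with_seed(seed, {
    chrom <- sample(names(chromLengths), n, replace = TRUE)
    pos <- integer(n)
    for (cn in unique(chrom))
      pos[chrom == cn] <- sample.int(chromLengths[[cn]], sum(chrom == cn))
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    df <- data.frame(sample = sample, chrom = chrom, pos = pos, ref = ref,
                     alt = unname(alt), stringsAsFactors = FALSE)
    df[!duplicated(paste(df$chrom, df$pos)), ]
  })
}

## Complement / reverse complement for oracles, independent of the package
## internals (nucleotide lookup table).
oracleRevcomp <- function(x) {
  vapply(x, function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
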