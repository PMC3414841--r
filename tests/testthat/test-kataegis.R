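# Rainfall series, kataegis calling, cluster summaries, processivity and
# rearrangement colocalization.

posCatalog <- function(pos, chrom = "chr1", ref = "C", alt = "T",
                       sample = "S1") {
  n <- length(pos)
  MutationCatalog(sample, data.frame(chrom = rep_len(chrom, n), pos = pos,
                                     ref = rep_len(ref, n),
                                     alt = rep_len(alt, n)))
}

test_that("intermutation distances are computed within chromosomes", {
  rf <- rainfall(posCatalog(c(10L, 110L, 1110L)))
  expect_identical(rf$imd, c(NA_integer_, 100L, 1000L))
  ## one mutation per chromosome: all IMDs undefined
  rf2 <- rainfall(posCatalog(c(50L, 60L, 70L),
                             chrom = c("chr1", "chr2", "chr3")))
  expect_true(all(is.na(rf2$imd)))
  ## input order does not matter: the catalog constructor sorts
  shuffled <- posCatalog(c(1110L, 10L, 110L))
  expect_identical(rainfall(shuffled), rf)
})

test_that("kataegis calls are maximal runs over the IMD threshold rule", {
  ## 20 mutations spaced 100 bp in a sparse background
  pos <- c(seq(50000L, by = 100L, length.out = 20L),
           seq(500000L, by = 100000L, length.out = 10L))
  calls <- callKataegis(rainfall(posCatalog(pos)))
  expect_identical(nrow(calls$clusters), 1L)
  expect_identical(calls$clusters$n, 20L)
  expect_identical(calls$clusters$start, 50000L)
  expect_identical(calls$clusters$span, 1900L)
  ## below the minimum size: no call
  pos5 <- c(seq(50000L, by = 100L, length.out = 5L),
            seq(500000L, by = 100000L, length.out = 10L))
  expect_identical(nrow(callKataegis(rainfall(posCatalog(pos5)))$clusters),
                   0L)
  ## maximality: the mutations flanking a called cluster violate the
  ## threshold
  cl <- calls$clusters
  rf <- rainfall(posCatalog(pos))
  members <- cl$members[[1]]
  before <- members[1] - 1L; after <- members[length(members)] + 1L
  if (before >= 1) expect_gt(rf$pos[members[1]] - rf$pos[before], 1000L)
  if (after <= nrow(rf)) expect_gt(rf$pos[after] - rf$pos[members[length(members)]], 1000L)
  expect_identical(nrow(callKataegis(rainfall(MutationCatalog("E")))$clusters), 0L)
})

test_that("microclusters separated by small gaps aggregate into macroclusters", {
  pos <- c(seq(1e6, by = 100L, length.out = 10L),
           seq(1.5e6, by = 100L, length.out = 10L),  # 0.5 Mb gap
           seq(9e6, by = 100L, length.out = 10L))    # far away
  calls <- callKataegis(rainfall(posCatalog(as.integer(pos))))
  expect_identical(nrow(calls$clusters), 3L)
  expect_identical(nrow(calls$macro), 2L)
  expect_identical(calls$macro$nClusters, c(2L, 1L))
})

test_that("false-positive kataegis calls are rare in uniform random catalogs", {
  chromLengths <- c(chr1 = 8e8, chr2 = 8e8, chr3 = 7e8, chr4 = 7e8)
  fp <- 0L
  for (seed in 1:100) {
    sim <- simulatePositionCatalog(chromLengths, 3000L, 0L, seed = seed)
    calls <- callKataegis(rainfall(sim$catalog))
    if (nrow(calls$clusters) > 0L) fp <- fp + 1L
  }
  expect_lte(fp, 5L)
})

test_that("injected clusters are recovered with their spectrum and phase", {
  bundle <- toyBundle()
  base <- simulatePositionCatalog(chromLengths(bundle$genome), 150L,
                                  seed = 5)$catalog
  inj <- injectKataegis(base, bundle$genome, nClusters = 3L,
                        clusterSize = 15L, span = 3000L, pCtoT = 1,
                        seed = 9)
  calls <- callKataegis(rainfall(inj$catalog))
  ## every injected interval overlaps a called cluster
  for (i in seq_len(nrow(inj$truth$clusters))) {
    tr <- inj$truth$clusters[i, ]
    hit <- calls$clusters$chrom == tr$chrom &
      calls$clusters$start <= tr$end & calls$clusters$end >= tr$start
    expect_true(any(hit))
  }
  ## the cluster spectrum reflects the injected TpC C>T process
  m <- inj$truth$members[inj$truth$members$cluster == 1L, ]
  cs <- clusterSpectrum(m, bundle$genome)
  expect_equal(cs$TpC_fraction, 1)
  expect_equal(unname(cs$classFractions["C>T"]), 1)
  expect_equal(sum(cs$classFractions), 1)
  expect_equal(unname(cs$composition["T", "-1"]), 1)
  ## phase annotations are consumed, not inferred: co-phased by truth
  expect_identical(unique(m$phase), "phase01")
  expect_equal(cs$samePhaseFraction, 1)
  expect_true(is.na(clusterSpectrum(m[setdiff(names(m), "phase")],
                                    bundle$genome)$samePhaseFraction))
})

test_that("cluster flank composition matches a brute-force tally", {
  bundle <- toyBundle()
  base <- simulatePositionCatalog(chromLengths(bundle$genome), 100L,
                                  seed = 6)$catalog
  inj <- injectKataegis(base, bundle$genome, nClusters = 1L,
                        clusterSize = 30L, span = 5000L, seed = 10)
  m <- inj$truth$members
  cs <- clusterSpectrum(m, bundle$genome, flank = 10L)
  seqs <- as.character(genomeSequences(bundle$genome))
  tal <- matrix(0L, 4L, 21L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nrow(m))) {
    win <- substr(seqs[[m$chrom[i]]], m$pos[i] - 10L, m$pos[i] + 10L)
    if (m$ref[i] %in% c("A", "G")) win <- oracleRevcomp(win)
    b <- strsplit(win, "")[[1]]
    for (p in 1:21) tal[b[p], p] <- tal[b[p], p] + 1L
  }
  expect_equal(unname(cs$composition), unname(sweep(tal, 2, colSums(tal), "/")))
})

test_that("processive segments are maximal runs of identical strand-specific changes", {
  subs <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
                     ref = c("C", "C", "C", "G", "G"),
                     alt = c("T", "T", "T", "A", "A"))
  seg <- processiveSegments(MutationCatalog("S1", subs))
  expect_identical(seg$n, c(3L, 2L))
  expect_identical(seg$change, c("C>T", "G>A"))
  ## alternating classes: all runs of length 1
  subs2 <- subs; subs2$ref <- c("C", "G", "C", "G", "C")
  subs2$alt <- c("T", "A", "T", "A", "T")
  expect_true(all(processiveSegments(MutationCatalog("S1", subs2))$n == 1L))
})

test_that("run lengths of an equiprobable two-class sequence match the geometric law", {
  n <- 10000L
  subs <- withr::with_seed(13, {
    cl <- sample(c("C", "G"), n, replace = TRUE)
    data.frame(chrom = "chr1", pos = seq(10L, by = 10L, length.out = n),
               ref = cl, alt = ifelse(cl == "C", "T", "A"))
  })
  seg <- processiveSegments(MutationCatalog("S1", subs))
  ## mean run length 2 with SE sqrt(var)/sqrt(#runs); var of geometric(1/2)
  ## run lengths is 2
  se <- sqrt(2 / nrow(seg))
  expect_lt(abs(mean(seg$n) - 2), 3 * se)
})

test_that("breakpoint colocalization reports distances and enrichment", {
  pos <- c(seq(1e6, by = 100L, length.out = 10L))
  calls <- callKataegis(rainfall(posCatalog(as.integer(pos))))
  rearr <- data.frame(chromA = "chr1", posA = as.integer(1e6 + 450),
                      strandA = "+", chromB = "chr2", posB = 5e6L,
                      strandB = "-", class = "translocation")
  res <- rearrangementColocalization(calls, rearr,
                                     c(chr1 = 171e6, chr2 = 200e6))
  expect_identical(res$clusters$nearestBreakpoint, 0)  # inside the cluster
  ## the study's chromosome-6 arithmetic: 17 breakpoints in 14 Mb vs 7 in
  ## the remaining 157 Mb gives a ~27.2-fold rate ratio
  mac <- data.frame(chrom = "chr1", start = 1L, end = 14000000L,
                    nClusters = 1L, n = 100L)
  fake <- list(clusters = calls$clusters[0, ], macro = mac)
  bp <- withr::with_seed(14, data.frame(
    chromA = "chr1", posA = c(sample.int(14000000L, 17L),
                              sample(14000001:171000000, 7L)),
    strandA = "+", chromB = "chrX", posB = 1L, strandB = "+",
    class = "x"))
  res2 <- rearrangementColocalization(fake, bp, c(chr1 = 171e6))
  ratio <- res2$macro$rateInsidePerMb / res2$macro$rateOutsidePerMb
  expect_equal(ratio, (17 / 14) / (7 / 157), tolerance = 0.01)
  expect_lt(res2$macro$enrichmentP, 1e-6)
})

test_that("breakpoint enrichment p-values are valid under uniform placement", {
  ## conservative calibration: the exact binomial test never rejects more
  ## often than nominal under the null
  mac <- data.frame(chrom = "chr1", start = 10000001L, end = 24000000L,
                    nClusters = 1L, n = 50L)
  fake <- list(clusters = data.frame(cluster = integer(0), chrom = character(0),
                                     start = integer(0), end = integer(0),
                                     n = integer(0)), macro = mac)
  ps <- vapply(1:200, function(seed) {
    bp <- withr::with_seed(2000 + seed, data.frame(
      chromA = "chr1", posA = sample.int(171000000L, 60L), strandA = "+",
      chromB = "chrX", posB = 1L, strandB = "+", class = "x"))
    rearrangementColocalization(fake, bp, c(chr1 = 171e6))$macro$enrichmentP
  }, numeric(1))
  for (alpha in c(0.01, 0.05, 0.1, 0.25))
    expect_lte(mean(ps <= alpha), alpha + 2 * sqrt(alpha * (1 - alpha) / 200))
})

test_that("injected clusters are recovered with high recall and precision over seeds", {
  chromLengths <- c(chr1 = 5e7, chr2 = 5e7)
  tp <- fp <- fn <- 0L
  for (seed in 1:10) {
    sim <- simulatePositionCatalog(chromLengths, 400L, seed = seed)
    ## inject 3 dense clusters directly (position-level)
    truth <- NULL
    s <- substitutions(sim$catalog)
    withr::with_seed(seed + 500, {
      for (ci in 1:3) {
        cn <- sample(names(chromLengths), 1)
        st <- sample.int(4e7, 1)
        pos <- sort(st + sample.int(2500L, 12L))
        s <- rbind(s, data.frame(chrom = cn, pos = pos, ref = "C", alt = "T"))
        truth <- rbind(truth, data.frame(chrom = cn, start = min(pos),
                                         end = max(pos)))
      }
    })
    s <- s[!duplicated(paste(s$chrom, s$pos)), ]
    calls <- callKataegis(rainfall(MutationCatalog("S1", s)))
    cl <- calls$clusters
    for (i in seq_len(nrow(truth))) {
      hit <- cl$chrom == truth$chrom[i] & cl$start <= truth$end[i] &
        cl$end >= truth$start[i]
      if (any(hit)) tp <- tp + 1L else fn <- fn + 1L
    }
    for (i in seq_len(nrow(cl))) {
      hit <- truth$chrom == cl$chrom[i] & truth$start <= cl$end[i] &
        truth$end >= cl$start[i]
      if (!any(hit)) fp <- fp + 1L
    }
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tp / (tp + fp), 0.95)
})
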