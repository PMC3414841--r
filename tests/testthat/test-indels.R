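# Indel architecture classification, KS comparison, microhomology chance
# model and group association.

## Genome with a known sequence around position 100 for hand-built cases.
craftedGenome <- function(core) {
  pad <- strrep("ACGT", 30)  # periodic flanks avoid accidental repeats
  referenceFromSequences(c(chr1 = paste0(pad, core, pad)))
}

test_that("whole-unit deletions inside tandem repeats classify as repeat", {
  ## ...CAG CAG CAG... : deleting one CAG leaves adjacent copies
  g <- craftedGenome("TTCAGCAGCAGTT")
  ## core starts at 121; deletion of bases 123..125 ("CAG")
  rec <- data.frame(sample = "S1", chrom = "chr1", pos = 122L,
                    kind = "deletion", seq = "CAG", length = 3L)
  cls <- classifyIndels(rec, g)
  expect_identical(cls$class, "repeat")
  expect_identical(cls$repeat_unit, "CAG")
  expect_identical(cls$adjacent_repeat_copies, 2L)
  ## insertions are eligible for the repeat class
  ins <- data.frame(sample = "S1", chrom = "chr1", pos = 125L,
                    kind = "insertion", seq = "CAG", length = 3L)
  expect_identical(classifyIndels(ins, g)$class, "repeat")
})

test_that("junction identity of mhMin or more classifies deletions as microhomology", {
  ## deleted ATGCC, reference after the deletion starts ATG -> mh 3
  g <- craftedGenome("TTATGCCATGAA")
  rec <- data.frame(sample = "S1", chrom = "chr1", pos = 122L,
                    kind = "deletion", seq = "ATGCC", length = 5L)
  cls <- classifyIndels(rec, g)
  expect_identical(cls$class, "microhomology")
  expect_identical(cls$mh_length, 3L)
  ## below mhMin: none
  cls2 <- classifyIndels(rec, g, mhMin = 4L)
  expect_identical(cls2$class, "none")
  ## complex records are not classified
  cpx <- data.frame(sample = "S1", chrom = "chr1", pos = 122L,
                    kind = "complex", seq = "XX", length = 2L)
  expect_identical(classifyIndels(cpx, g)$class, "complex")
})

test_that("classifier mh lengths agree with a brute-force string scan on random fixtures", {
  withr::with_seed(21, {
    s <- paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE),
               collapse = "")
  })
  g <- referenceFromSequences(c(chr1 = s))
  withr::with_seed(22, {
    pos <- sample(200:29000, 300)
    len <- sample(1:20, 300, replace = TRUE)
  })
  recs <- data.frame(sample = "S1", chrom = "chr1", pos = pos,
                     kind = "deletion",
                     seq = substring(s, pos + 1L, pos + len), length = len)
  cls <- classifyIndels(recs, g)
  bruteMh <- function(seqDel, before, after) {
    L <- nchar(seqDel)
    pre <- 0L
    while (pre < L && pre < nchar(after) &&
             substr(seqDel, pre + 1, pre + 1) ==
               substr(after, pre + 1, pre + 1)) pre <- pre + 1L
    suf <- 0L
    while (suf < L && suf < nchar(before) &&
             substr(seqDel, L - suf, L - suf) ==
               substr(before, nchar(before) - suf, nchar(before) - suf))
      suf <- suf + 1L
    max(pre, suf)
  }
  oracle <- vapply(seq_len(nrow(recs)), function(i)
    bruteMh(recs$seq[i], substr(s, pos[i] - 49L, pos[i]),
            substr(s, pos[i] + len[i] + 1L, pos[i] + len[i] + 50L)),
    integer(1))
  expect_identical(cls$mh_length, oracle)
  ## precedence is total: every record gets exactly one class
  expect_true(all(cls$class %in% c("repeat", "microhomology", "none")))
})

test_that("classification is invariant under reverse complementation of the locus", {
  withr::with_seed(23, {
    s <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
               collapse = "")
  })
  g <- referenceFromSequences(c(chr1 = s))
  rc <- oracleRevcomp(s)
  grc <- referenceFromSequences(c(chr1 = rc))
  withr::with_seed(24, {
    pos <- sample(100:4800, 100)
    len <- sample(1:12, 100, replace = TRUE)
  })
  cls <- classifyIndels(data.frame(sample = "S1", chrom = "chr1", pos = pos,
                                   kind = "deletion",
                                   seq = substring(s, pos + 1L, pos + len),
                                   length = len), g)
  ## same deletion on the reverse-complemented genome: deleted bases
  ## 5000-(pos+len)+1 .. 5000-pos, so pos' = 5000-(pos+len)
  pos2 <- 5000L - (pos + len)
  cls2 <- classifyIndels(data.frame(sample = "S1", chrom = "chr1",
                                    pos = pos2, kind = "deletion",
                                    seq = substring(rc, pos2 + 1L,
                                                    pos2 + len),
                                    length = len), grc)
  expect_identical(cls$class, cls2$class)
  expect_identical(cls$mh_length, cls2$mh_length)
})

test_that("generator-labeled indels are recovered accurately", {
  g <- toyGenome()
  ind <- simulateIndels(g, nRepeat = 120L, nMicrohomology = 120L,
                        nNone = 120L, seed = 31)
  cls <- classifyIndels(ind, g)
  acc <- mean(cls$class == cls$true_class)
  expect_gte(acc, 0.95)
})

test_that("the KS statistic equals the brute-force sup of ECDF differences", {
  expect_equal(ksTwoSample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ksTwoSample(c(1, 2), c(10, 11))$D, 1)
  expect_true(is.na(ksTwoSample(numeric(0), 1:3)$D))
  withr::with_seed(25, {
    a <- sample(1:30, 80, replace = TRUE)
    b <- sample(1:50, 60, replace = TRUE)
  })
  res <- ksTwoSample(a, b)
  grid <- sort(unique(c(a, b)))
  oracle <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  expect_equal(res$D, oracle, tolerance = 1e-12)
  ## repeat-mediated lengths (small) vs microhomology lengths (large)
  ## separate significantly, as in real genomes
  g <- toyGenome()
  ind <- simulateIndels(g, nRepeat = 100L, nMicrohomology = 100L,
                        nNone = 0L, seed = 32)
  cls <- classifyIndels(ind, g)
  ks <- ksTwoSample(cls$length[cls$class == "repeat"],
                    cls$length[cls$class == "microhomology"])
  expect_lt(ks$p, 1e-10)
})

test_that("the microhomology chance model has the closed form and matches Monte Carlo", {
  comp <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  dist5 <- mutforge:::mhChanceDistribution(5L, sum(comp^2))
  expect_equal(sum(dist5), 1)
  ## P(one side run >= 1) = 0.25 so P(max >= 1) = 1 - 0.75^2
  expect_equal(unname(1 - dist5[["0"]]), 1 - 0.75^2)
  ## Monte Carlo oracle: random junctions with uniform bases
  L <- 8L
  sims <- withr::with_seed(26, {
    n <- 1e5
    del <- matrix(sample(4L, n * L, replace = TRUE), n, L)
    after <- matrix(sample(4L, n * L, replace = TRUE), n, L)
    before <- matrix(sample(4L, n * L, replace = TRUE), n, L)
    runLen <- function(eq) {
      ## length of initial TRUE run per row
      firstFalse <- max.col(!eq, "first")
      ifelse(!eq[cbind(seq_len(n), firstFalse)], firstFalse - 1L, L)
    }
    pre <- runLen(del == after)
    suf <- runLen(del[, L:1, drop = FALSE] == before[, L:1, drop = FALSE])
    pmax(pre, suf)
  })
  mcDist <- tabulate(sims + 1L, nbins = L + 1L) / length(sims)
  model <- mutforge:::mhChanceDistribution(L, 0.25)
  big <- model > 5e-3
  expect_true(all(abs(mcDist[big] - model[big]) / model[big] <= 0.05))
})

test_that("expected microhomology counts integrate to the deletion count and calibrate", {
  g <- toyGenome()
  ind <- simulateIndels(g, nRepeat = 0L, nMicrohomology = 0L, nNone = 150L,
                        seed = 33)
  ## lengths vary; classify then compare observed mh to the chance model
  cls <- classifyIndels(ind, g)
  comp <- c(A = 0.295, C = 0.205, G = 0.205, T = 0.295)
  exp <- expectedMicrohomology(cls, comp)
  expect_equal(sum(exp$table$expected), nrow(cls), tolerance = 1e-9)
  expect_true(all(exp$table$expected >= 0))
  ## "none"-labeled deletions are mh < 2 by construction, so observed
  ## mass sits at 0-1; the chi-square detects that truncation but the
  ## table shape is still valid
  expect_identical(sum(exp$table$observed), nrow(cls))
})

test_that("microhomology chi-square p-values are roughly uniform under the chance model", {
  ## sample junction mh lengths directly from the chance model and test
  comp <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  pm <- sum(comp^2)
  ps <- vapply(1:100, function(seed) {
    lens <- withr::with_seed(seed + 40, sample(4:20, 200, replace = TRUE))
    mh <- vapply(lens, function(L) {
      p <- mutforge:::mhChanceDistribution(L, pm)
      sample(0:L, 1L, prob = p)
    }, integer(1))
    fake <- data.frame(kind = "deletion", length = lens, mh_length = mh)
    expectedMicrohomology(fake, comp)$p
  }, numeric(1))
  ## chi-square on discrete counts: require approximate uniformity
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("group association recovers odds ratios and detects enrichment", {
  cls <- data.frame(sample = rep(c("A", "B"), each = 100),
                    class = c(rep(c("microhomology", "none"), c(90, 10)),
                              rep(c("microhomology", "none"), c(10, 90))))
  groups <- c(A = "brca", B = "sporadic")
  res <- indelGroupTest(cls, groups)
  expect_equal(res$or, 81, tolerance = 1e-9)
  expect_lt(res$p, 1e-6)
  expect_equal(unname(res$mhFraction["brca"]), 0.9)
  ## identical fractions: OR ~ 1, p ~ 1
  cls2 <- data.frame(sample = rep(c("A", "B"), each = 100),
                     class = rep(rep(c("microhomology", "none"), c(50, 50)),
                                 2))
  res2 <- indelGroupTest(cls2, groups)
  expect_equal(res2$or, 1, tolerance = 1e-9)
  expect_gt(res2$p, 0.9)
  expect_true(is.na(indelGroupTest(cls, c(A = "g", B = "g"))$p))
})

test_that("a 5x injected microhomology rate is detected across seeds", {
  detected <- 0L
  for (seed in 1:20) {
    withr::with_seed(seed + 60, {
      nMH1 <- rbinom(1, 500, 0.25); nMH2 <- rbinom(1, 500, 0.05)
    })
    cls <- data.frame(
      sample = rep(c("A", "B"), each = 500),
      class = c(rep(c("microhomology", "none"), c(nMH1, 500 - nMH1)),
                rep(c("microhomology", "none"), c(nMH2, 500 - nMH2))))
    res <- indelGroupTest(cls, c(A = "brca", B = "sporadic"))
    if (res$p < 1e-6) detected <- detected + 1L
  }
  expect_gte(detected, 19L)
})
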