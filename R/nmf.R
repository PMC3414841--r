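# Nonnegative matrix factorization of the 96 x M spectrum with
# multiplicative updates, consensus/cophenetic rank selection, signature
# extraction and hierarchical clustering of samples by exposures.

#' @importFrom stats hclust cophenetic cor dist as.dist runif setNames
NULL

asCountMatrix <- function(A) {
  if (is(A, "SpectrumMatrix")) A <- spectrumCounts(A)
  storage.mode(A) <- "double"
  A
}

#' Factorize a spectrum matrix by Lee-Seung multiplicative updates
#'
#' Minimizes the Frobenius reconstruction error \code{||A - W H||_F} over
#' nonnegative W (96 x k) and H (k x M) by alternating multiplicative
#' updates.  Factors are initialized i.i.d. uniform(0, 1] scaled by
#' \code{mean(A)} under the given seed.  Iteration stops at \code{maxIter}
#' or when the relative change in error between iterations falls below
#' \code{tol}.  Denominators are guarded by a 1e-12 epsilon so all-zero
#' rows of A are permitted.
#'
#' @param A A \linkS4class{SpectrumMatrix} or nonnegative numeric matrix.
#' @param k Factorization rank (number of signatures), \code{2 <= k} allowed
#'   down to 1 for the rank-1 case; must not exceed \code{ncol(A)}.
#' @param seed Integer seed for the random initialization.
#' @param maxIter Maximum number of update iterations.
#' @param tol Relative error-change stopping threshold.
#' @return An \linkS4class{NMFRun}.
#' @examples
#' A <- matrix(rpois(96 * 6, 20), 96, 6)
#' nmfDecompose(A, k = 2, seed = 1)
#' @export
nmfDecompose <- function(A, k, seed = 1L, maxIter = 2000L, tol = 1e-9) {
  A <- asCountMatrix(A)
  if (any(A < 0)) stopf("A must be nonnegative")
  if (k < 1L || k > ncol(A))
    stopf("k must be between 1 and ncol(A) = %d", ncol(A))
  eps <- 1e-12
  N <- nrow(A); M <- ncol(A)
  scale <- mean(A)
  if (scale == 0) scale <- 1
  init <- localSeed(seed, list(W = matrix(runif(N * k), N, k) * scale,
                               H = matrix(runif(k * M), k, M) * scale))
  W <- init$W; H <- init$H
  err <- sqrt(sum((A - W %*% H)^2))
  trace <- numeric(maxIter + 1L); trace[1L] <- err
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    H <- H * (crossprod(W, A) / (crossprod(W, W %*% H) + eps))
    W <- W * (tcrossprod(A, H) / (W %*% tcrossprod(H) + eps))
    newErr <- sqrt(sum((A - W %*% H)^2))
    trace[it + 1L] <- newErr
    if (err > 0 && abs(err - newErr) / err < tol) {
      err <- newErr
      break
    }
    err <- newErr
  }
  new("NMFRun", W = W, H = H, seed = as.integer(seed),
      frobeniusError = err, errorTrace = trace[seq_len(it + 1L)],
      iterations = it)
}

## Consensus matrix over runs: samples co-assigned when their
## maximal-activity signature coincides (Brunet-style co-assignment).
consensusFromRuns <- function(runs, M) {
  C <- matrix(0, M, M)
  for (r in runs) {
    assign <- apply(r@H, 2L, which.max)
    C <- C + outer(assign, assign, "==")
  }
  C / length(runs)
}

copheneticCoefficient <- function(consensus) {
  d <- as.dist(1 - consensus)
  if (all(d == 0)) return(1)  # degenerate: identical assignments every run
  hc <- hclust(d, method = "average")
  suppressWarnings(co <- cor(as.vector(d), as.vector(cophenetic(hc))))
  if (is.na(co)) 1 else co
}

#' Select the number of signatures by cophenetic stability and error elbow
#'
#' For each candidate rank k, \code{nRuns} seeded NMF restarts are
#' performed; each run assigns every sample to its maximal-activity
#' signature and the M x M consensus matrix records co-assignment
#' frequencies.  The cophenetic correlation coefficient of each consensus
#' (agreement between consensus distances 1 - C and the cophenetic
#' distances of their average-linkage dendrogram) measures decomposition
#' stability.  The chosen rank is the largest stable k (cophenetic >=
#' \code{cophThreshold}, truncated at the first drop below the threshold)
#' whose step still reduces the per-k best reconstruction error by at
#' least \code{relTol} of its previous value, resolving ambiguity toward
#' the smaller k (adding a noise component reduces the error by only a few
#' percent, a true signature by far more).
#'
#' @param A Spectrum matrix (96 x M counts).
#' @param kRange Integer vector of candidate ranks (default 2..8).
#' @param nRuns Restarts per rank (>= 10; default 100).
#' @param seed Master seed; per-run seeds are derived from it.
#' @param cophThreshold Stability threshold on the cophenetic coefficient.
#' @param relTol Minimum relative reduction of the best reconstruction
#'   error that a rank must buy over k - 1 to count as a real signature
#'   (noise components reduce the error by only a few percent).
#' @param maxIter,tol Passed to [nmfDecompose()].
#' @return A \linkS4class{RankSelection}.
#' @export
selectRank <- function(A, kRange = 2:8, nRuns = 100L, seed = 1L,
                       cophThreshold = 0.95, relTol = 0.15,
                       maxIter = 500L, tol = 1e-7) {
  A <- asCountMatrix(A)
  if (nRuns < 10L) stopf("nRuns must be >= 10")
  kRange <- sort(as.integer(kRange))
  if (min(kRange) < 1L || max(kRange) > ncol(A))
    stopf("kRange outside valid bounds 1..%d", ncol(A))
  M <- ncol(A)
  seeds <- deriveSeeds(seed, length(kRange) * nRuns)
  dim(seeds) <- c(nRuns, length(kRange))
  coph <- meanErr <- minErr <- numeric(length(kRange))
  consensus <- vector("list", length(kRange))
  names(consensus) <- as.character(kRange)
  for (i in seq_along(kRange)) {
    runs <- lapply(seq_len(nRuns), function(r)
      nmfDecompose(A, kRange[i], seed = seeds[r, i], maxIter = maxIter,
                   tol = tol))
    errs <- vapply(runs, function(r) r@frobeniusError, numeric(1))
    meanErr[i] <- mean(errs); minErr[i] <- min(errs)
    consensus[[i]] <- consensusFromRuns(runs, M)
    coph[i] <- copheneticCoefficient(consensus[[i]])
  }
  tab <- data.frame(k = kRange, cophenetic = coph, meanError = meanErr,
                    minError = minErr, nRuns = nRuns)
  chosen <- chooseRank(tab, cophThreshold, relTol)
  new("RankSelection", table = tab, chosenK = as.integer(chosen),
      consensus = consensus)
}

## The selection rule, separated for testability.  Candidates are all ranks
## up to the last cophenetic-stable one: the stability collapse that rules
## out over-fitted ranks is terminal, whereas ranks between good models can
## be transiently unstable (they are wrong models) without capping the
## range.  Within the candidates the chosen rank is the largest whose step
## still reduces the best reconstruction error by at least relTol of its
## previous value: adding a true signature cuts the error by a large
## fraction, adding a noise component by only a few percent, so the
## relative step size separates the two regimes.
chooseRank <- function(tab, cophThreshold = 0.95, relTol = 0.15) {
  k <- tab$k
  stable <- tab$cophenetic >= cophThreshold
  if (!any(stable)) return(k[which.max(tab$cophenetic)])
  cand <- seq_len(max(which(stable)))
  relImp <- c(Inf, -diff(tab$minError) / utils::head(tab$minError, -1L))
  good <- cand[relImp[cand] >= relTol]
  k[max(good)]
}

#' Extract signatures and exposures at a fixed rank
#'
#' Runs \code{nRuns} seeded factorizations and keeps the best-error run.
#' Signature columns of W are normalized to sum to 1 with H rescaled
#' inversely, so \code{signatures \%*\% activity} equals the source run's
#' W H.  Exposures are also reported in mutation counts (columns summing to
#' each sample's classifiable mutation count) and as proportions.
#'
#' @param A Spectrum matrix (96 x M counts).
#' @param k Number of signatures (typically [chosenK()] of [selectRank()]).
#' @param nRuns Number of restarts.
#' @param seed Master seed.
#' @param maxIter,tol Passed to [nmfDecompose()].
#' @return A \linkS4class{SignatureSet}.
#' @export
extractSignatures <- function(A, k, nRuns = 20L, seed = 1L,
                              maxIter = 5000L, tol = 1e-10) {
  A <- asCountMatrix(A)
  seeds <- deriveSeeds(seed, nRuns)
  best <- NULL
  for (s in seeds) {
    run <- nmfDecompose(A, k, seed = s, maxIter = maxIter, tol = tol)
    if (is.null(best) || run@frobeniusError < best@frobeniusError)
      best <- run
  }
  scale <- colSums(best@W)
  empty <- which(scale < 1e-9 * max(scale, 1))
  if (length(empty))
    warning(length(empty), " numerically empty signature(s): ",
            paste(empty, collapse = ", "))
  scale[scale == 0] <- 1
  Wn <- sweep(best@W, 2L, scale, "/")
  Hr <- sweep(best@H, 1L, colSums(best@W), "*")
  tot <- colSums(Hr); tot[tot == 0] <- 1
  prop <- sweep(Hr, 2L, tot, "/")
  expo <- sweep(prop, 2L, colSums(A), "*")
  rownames(Wn) <- rownames(A)
  signames <- paste0("S", seq_len(k))
  colnames(Wn) <- rownames(Hr) <- rownames(prop) <- rownames(expo) <- signames
  colnames(Hr) <- colnames(prop) <- colnames(expo) <- colnames(A)
  new("SignatureSet", signatures = Wn, activity = Hr, exposures = expo,
      proportions = prop, frobeniusError = best@frobeniusError,
      emptySignatures = as.integer(empty))
}

#' Trinucleotide-frequency-corrected signature profiles
#'
#' Divides each signature entry by the genome frequency of its channel's
#' trinucleotide context and renormalizes columns to sum to 1.  This is a
#' display transformation: factorization always runs on raw counts.
#'
#' @param sigset A \linkS4class{SignatureSet} (or bare 96 x k matrix).
#' @param genome A \linkS4class{ReferenceGenome} with positive counts for
#'   every context.
#' @param uncorrect Apply the inverse transformation (multiply by context
#'   frequency) instead.
#' @return 96 x k corrected signature matrix with columns summing to 1.
#' @export
correctSignatures <- function(sigset, genome, uncorrect = FALSE) {
  W <- if (is(sigset, "SignatureSet")) signatures(sigset) else sigset
  occ <- triContextCounts(genome)[channelTable()$context]
  if (any(occ == 0L))
    stopf("context with zero genome frequency: %s",
          channelTable()$context[occ == 0L][1])
  f <- occ / sum(triContextCounts(genome))
  Wc <- if (uncorrect) W * f else W / f
  sweep(Wc, 2L, colSums(Wc), "/")
}

#' Hierarchically cluster samples by signature proportions
#'
#' Average-linkage agglomerative clustering on Euclidean distances between
#' per-sample signature-proportion vectors.  Ties in merge heights are
#' broken deterministically by \code{\link[stats]{hclust}}'s ordering of
#' observation indices, so the leaf order is reproducible.
#'
#' @param sigset A \linkS4class{SignatureSet}.
#' @return An \code{hclust} object.
#' @export
clusterSamples <- function(sigset) {
  P <- proportions(sigset)
  if (ncol(P) < 2L) stopf("need at least 2 samples to cluster")
  hclust(dist(t(P), method = "euclidean"), method = "average")
}

#' Match extracted signatures to reference signatures by cosine similarity
#'
#' Finds the permutation of extracted columns maximizing the total cosine
#' similarity to the reference columns (exhaustive over permutations,
#' intended for small k).
#'
#' @param W Extracted signature matrix (96 x k).
#' @param Wref Reference signature matrix (96 x k).
#' @return List with \code{perm} (extracted column matched to each
#'   reference column) and \code{cosines} per reference signature.
#' @export
matchSignatures <- function(W, Wref) {
  k <- ncol(Wref)
  stopifnot(ncol(W) == k)
  if (k > 7L) stopf("exhaustive matching supports k <= 7")
  cosm <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    num <- sum(Wref[, i] * W[, j])
    den <- sqrt(sum(Wref[, i]^2) * sum(W[, j]^2))
    cosm[i, j] <- if (den == 0) 0 else num / den
  }
  perms <- permutationsOf(k)
  scores <- vapply(perms, function(p) sum(cosm[cbind(seq_len(k), p)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  list(perm = best, cosines = cosm[cbind(seq_len(k), best)])
}

permutationsOf <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- permutationsOf(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 0L
  for (p in sub) for (pos in seq_len(k)) {
    i <- i + 1L
    out[[i]] <- append(p, k, after = pos - 1L)
  }
  out
}
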