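# S4 classes for mutation catalogs, reference genomes and spectra.

#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
NULL

## ---------------------------------------------------------------------------
## ReferenceGenome
## ---------------------------------------------------------------------------

#' ReferenceGenome: sequences plus cached trinucleotide occurrence counts
#'
#' Wraps a \link[Biostrings]{DNAStringSet} of chromosome sequences
#' (uppercase, alphabet ACGTN) together with a cached table of genome-wide
#' trinucleotide occurrence counts collapsed to the 32 pyrimidine-central
#' contexts.  Windows containing N are excluded from the counts, mirroring
#' their exclusion from mutation classification.
#'
#' @slot sequences A \code{DNAStringSet}, one entry per chromosome.
#' @slot triCounts Named integer vector of length 32 (see [contextLabels()]).
#' @seealso [readReference()], [trinucleotideContext()]
#' @export
setClass("ReferenceGenome",
  representation(sequences = "DNAStringSet", triCounts = "integer"))

setValidity("ReferenceGenome", function(object) {
  msgs <- character(0)
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    msgs <- c(msgs, "chromosome names must be present and unique")
  if (!identical(names(object@triCounts), contextLabels()))
    msgs <- c(msgs, "triCounts must be named by the 32 collapsed contexts")
  total <- sum(pmax(Biostrings::width(object@sequences) - 2L, 0L))
  if (sum(object@triCounts) > total)
    msgs <- c(msgs, "trinucleotide counts exceed the number of windows")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## MutationCatalog
## ---------------------------------------------------------------------------

#' MutationCatalog: one sample's somatic mutation records
#'
#' Per-sample container for somatic substitutions, indels and
#' rearrangements.  Substitutions are stored sorted by (chromosome, position)
#' with duplicate positions rejected, so intermutation-distance and
#' adjacency logic can assume unique increasing coordinates.
#'
#' Coordinates are 1-based inclusive (VCF convention) throughout.
#'
#' @slot sampleId Sample identifier.
#' @slot substitutions data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (single ACGT bases, \code{ref != alt}).
#' @slot indels data.frame with columns \code{chrom}, \code{pos} (base
#'   immediately 5' of the event), \code{kind} (deletion/insertion/complex),
#'   \code{seq}, \code{length}.
#' @slot rearrangements data.frame with columns \code{chromA}, \code{posA},
#'   \code{strandA}, \code{chromB}, \code{posB}, \code{strandB}, \code{class}.
#' @seealso [readSubstitutions()], [splitCatalogs()]
#' @export
setClass("MutationCatalog",
  representation(sampleId = "character", substitutions = "data.frame",
                 indels = "data.frame", rearrangements = "data.frame"))

setValidity("MutationCatalog", function(object) {
  msgs <- character(0)
  s <- object@substitutions
  if (length(object@sampleId) != 1L)
    msgs <- c(msgs, "sampleId must be a single string")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(s))) {
    msgs <- c(msgs, "substitutions need columns chrom, pos, ref, alt")
  } else if (nrow(s)) {
    if (!all(s$ref %in% BASES & s$alt %in% BASES))
      msgs <- c(msgs, "substitution alleles must be single ACGT bases")
    if (any(s$ref == s$alt)) msgs <- c(msgs, "ref must differ from alt")
    if (any(s$pos < 1L)) msgs <- c(msgs, "positions must be >= 1")
    o <- orderGenomic(s$chrom, s$pos)
    if (!identical(o, seq_len(nrow(s))))
      msgs <- c(msgs, "substitutions must be sorted by (chrom, pos)")
    if (anyDuplicated(paste(s$chrom, s$pos)))
      msgs <- c(msgs, "duplicate (chrom, pos) substitutions")
  }
  i <- object@indels
  if (nrow(i)) {
    if (!all(c("chrom", "pos", "kind", "seq", "length") %in% names(i)))
      msgs <- c(msgs, "indels need columns chrom, pos, kind, seq, length")
    else {
      if (!all(i$kind %in% c("deletion", "insertion", "complex")))
        msgs <- c(msgs, "indel kind must be deletion/insertion/complex")
      if (any(i$length < 1L | i$length > 50L))
        msgs <- c(msgs, "indel length must be in 1..50")
      simple <- i$kind != "complex"
      if (any(nchar(i$seq[simple]) != i$length[simple]))
        msgs <- c(msgs, "indel seq length must equal length")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MutationCatalog
#'
#' Records are sorted into canonical (chromosome, position) order; duplicate
#' substitution positions within the sample are an error.
#'
#' @param sampleId Sample identifier.
#' @param substitutions,indels,rearrangements data.frames as described in
#'   \linkS4class{MutationCatalog}; may be omitted.
#' @return A \linkS4class{MutationCatalog}.
#' @examples
#' MutationCatalog("S1", data.frame(chrom = "chr1", pos = c(5L, 2L),
#'                                  ref = c("C", "T"), alt = c("T", "G")))
#' @export
MutationCatalog <- function(sampleId,
                            substitutions = emptySubstitutions(),
                            indels = emptyIndels(),
                            rearrangements = emptyRearrangements()) {
  if (nrow(substitutions)) {
    substitutions <- substitutions[orderGenomic(substitutions$chrom,
                                                substitutions$pos), ,
                                   drop = FALSE]
    rownames(substitutions) <- NULL
    dup <- duplicated(paste(substitutions$chrom, substitutions$pos))
    if (any(dup))
      stopf("sample %s: %d duplicate substitution position(s), e.g. %s:%d",
            sampleId, sum(dup), substitutions$chrom[dup][1],
            substitutions$pos[dup][1])
  }
  new("MutationCatalog", sampleId = as.character(sampleId),
      substitutions = substitutions, indels = indels,
      rearrangements = rearrangements)
}

emptySubstitutions <- function()
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), stringsAsFactors = FALSE)
emptyIndels <- function()
  data.frame(chrom = character(0), pos = integer(0), kind = character(0),
             seq = character(0), length = integer(0), stringsAsFactors = FALSE)
emptyRearrangements <- function()
  data.frame(chromA = character(0), posA = integer(0), strandA = character(0),
             chromB = character(0), posB = integer(0), strandB = character(0),
             class = character(0), stringsAsFactors = FALSE)

## ---------------------------------------------------------------------------
## SpectrumMatrix
## ---------------------------------------------------------------------------

#' SpectrumMatrix: 96-channel substitution counts per sample
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with one assay
#' \code{"counts"}: 96 channel rows (rownames are [channelLabels()]) by M
#' sample columns of nonnegative integer counts.  Column sums equal each
#' sample's number of classifiable substitutions.
#'
#' @seealso [buildSpectrumMatrix()]
#' @export
setClass("SpectrumMatrix", contains = "SummarizedExperiment")

setValidity("SpectrumMatrix", function(object) {
  msgs <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (nrow(m) != 96L || !identical(rownames(m), channelLabels()))
    msgs <- c(msgs, "rows must be the 96 channels in canonical order")
  if (any(m < 0) || any(m != round(m)))
    msgs <- c(msgs, "counts must be nonnegative integers")
  if (length(msgs)) msgs else TRUE
})

#' @param counts 96 x M integer matrix with rownames [channelLabels()].
#' @rdname SpectrumMatrix-class
#' @export
SpectrumMatrix <- function(counts) {
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(channelTable()))
  new("SpectrumMatrix", se)
}

#' Extract the raw 96 x M count matrix
#' @param object A \linkS4class{SpectrumMatrix}.
#' @return Integer matrix of channel counts.
#' @export
setGeneric("spectrumCounts", function(object) standardGeneric("spectrumCounts"))

#' @rdname spectrumCounts
#' @export
setMethod("spectrumCounts", "SpectrumMatrix", function(object)
  SummarizedExperiment::assay(object, "counts"))

## ---------------------------------------------------------------------------
## NMF result containers
## ---------------------------------------------------------------------------

#' NMFRun: a single nonnegative matrix factorization fit
#'
#' Result of one seeded multiplicative-update factorization A ~ W H.
#'
#' @slot W,H Nonnegative factor matrices (96 x k and k x M).
#' @slot seed Integer seed of the run.
#' @slot frobeniusError Final value of ||A - WH||_F.
#' @slot errorTrace Frobenius error at each recorded iteration.
#' @slot iterations Number of update iterations performed.
#' @seealso [nmfDecompose()]
#' @export
setClass("NMFRun",
  representation(W = "matrix", H = "matrix", seed = "integer",
                 frobeniusError = "numeric", errorTrace = "numeric",
                 iterations = "integer"))

setValidity("NMFRun", function(object) {
  msgs <- character(0)
  if (any(object@W < 0) || any(object@H < 0))
    msgs <- c(msgs, "W and H must be nonnegative")
  if (ncol(object@W) != nrow(object@H))
    msgs <- c(msgs, "inner dimensions of W and H must agree")
  if (object@frobeniusError < 0)
    msgs <- c(msgs, "frobeniusError must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' RankSelection: model-selection summary over factorization ranks
#'
#' Per-rank cophenetic correlation coefficients, mean reconstruction errors
#' and consensus matrices from repeated seeded NMF restarts, plus the chosen
#' rank.
#'
#' @slot table data.frame with columns \code{k}, \code{cophenetic},
#'   \code{meanError}, \code{minError}, \code{nRuns}.
#' @slot chosenK The selected number of signatures.
#' @slot consensus Named list of M x M consensus matrices, one per k.
#' @seealso [selectRank()]
#' @export
setClass("RankSelection",
  representation(table = "data.frame", chosenK = "integer",
                 consensus = "list"))

#' SignatureSet: normalized signatures with per-sample exposures
#'
#' @slot signatures 96 x k matrix, columns sum to 1.
#' @slot activity k x M matrix rescaled so that
#'   \code{signatures \%*\% activity} reproduces the source run's W H.
#' @slot exposures k x M matrix in mutation counts (columns sum to each
#'   sample's classifiable mutation count).
#' @slot proportions k x M matrix, columns sum to 1.
#' @slot frobeniusError Reconstruction error of the source run.
#' @slot emptySignatures Indices of numerically zero signature columns.
#' @seealso [extractSignatures()]
#' @export
setClass("SignatureSet",
  representation(signatures = "matrix", activity = "matrix",
                 exposures = "matrix", proportions = "matrix",
                 frobeniusError = "numeric", emptySignatures = "integer"))

setValidity("SignatureSet", function(object) {
  msgs <- character(0)
  live <- setdiff(seq_len(ncol(object@signatures)), object@emptySignatures)
  if (length(live) && any(abs(colSums(object@signatures[, live, drop = FALSE]) - 1) > 1e-6))
    msgs <- c(msgs, "signature columns must sum to 1")
  if (any(object@proportions < -1e-12))
    msgs <- c(msgs, "proportions must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Accessors and show methods
## ---------------------------------------------------------------------------

#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' Accessors for MutationCatalog
#' @param object A \linkS4class{MutationCatalog}.
#' @return \code{sampleId}: the sample identifier; \code{substitutions},
#'   \code{indels}, \code{rearrangements}: the respective record tables.
#' @rdname catalog-accessors
#' @aliases sampleId
#' @export
setMethod("sampleId", "MutationCatalog", function(object) object@sampleId)

#' @export
setGeneric("substitutions", function(object) standardGeneric("substitutions"))
#' @rdname catalog-accessors
#' @export
setMethod("substitutions", "MutationCatalog",
          function(object) object@substitutions)

#' @export
setGeneric("indels", function(object) standardGeneric("indels"))
#' @rdname catalog-accessors
#' @export
setMethod("indels", "MutationCatalog", function(object) object@indels)

#' @export
setGeneric("rearrangements", function(object) standardGeneric("rearrangements"))
#' @rdname catalog-accessors
#' @export
setMethod("rearrangements", "MutationCatalog",
          function(object) object@rearrangements)

#' @export
setGeneric("chromLengths", function(object) standardGeneric("chromLengths"))
#' Accessors for ReferenceGenome
#' @param object A \linkS4class{ReferenceGenome}.
#' @return \code{chromLengths}: named integer vector of sequence lengths;
#'   \code{triContextCounts}: named length-32 integer vector of collapsed
#'   trinucleotide occurrence counts; \code{genomeSequences}: the underlying
#'   \code{DNAStringSet}.
#' @rdname genome-accessors
#' @aliases chromLengths
#' @export
setMethod("chromLengths", "ReferenceGenome", function(object) {
  w <- Biostrings::width(object@sequences)
  names(w) <- names(object@sequences)
  w
})

#' @export
setGeneric("triContextCounts",
           function(object) standardGeneric("triContextCounts"))
#' @rdname genome-accessors
#' @export
setMethod("triContextCounts", "ReferenceGenome",
          function(object) object@triCounts)

#' @export
setGeneric("genomeSequences", function(object) standardGeneric("genomeSequences"))
#' @rdname genome-accessors
#' @export
setMethod("genomeSequences", "ReferenceGenome",
          function(object) object@sequences)

setMethod("show", "MutationCatalog", function(object) {
  cat("MutationCatalog for sample", object@sampleId, "\n",
      " ", nrow(object@substitutions), "substitutions,",
      nrow(object@indels), "indels,",
      nrow(object@rearrangements), "rearrangements\n")
})

setMethod("show", "ReferenceGenome", function(object) {
  w <- chromLengths(object)
  cat("ReferenceGenome:", length(w), "sequence(s),",
      format(sum(w), big.mark = ","), "bp\n")
})

setMethod("show", "NMFRun", function(object) {
  cat("NMFRun: k =", ncol(object@W), ", error =",
      signif(object@frobeniusError, 6), "after", object@iterations,
      "iterations (seed", object@seed, ")\n")
})

setMethod("show", "RankSelection", function(object) {
  cat("RankSelection over k =", paste(range(object@table$k), collapse = ".."),
      "-> chosen k =", object@chosenK, "\n")
  print(object@table, row.names = FALSE, digits = 4)
})

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet:", ncol(object@signatures), "signatures x",
      ncol(object@exposures), "samples; reconstruction error",
      signif(object@frobeniusError, 6), "\n")
})

#' Accessors for NMF result containers
#'
#' @param object An \linkS4class{NMFRun}, \linkS4class{RankSelection} or
#'   \linkS4class{SignatureSet}.
#' @return The corresponding component (see slot documentation).
#' @name nmf-accessors
NULL

#' @rdname nmf-accessors
#' @export
setGeneric("signatures", function(object) standardGeneric("signatures"))
#' @rdname nmf-accessors
#' @export
setMethod("signatures", "SignatureSet", function(object) object@signatures)

#' @rdname nmf-accessors
#' @export
setGeneric("exposures", function(object) standardGeneric("exposures"))
#' @rdname nmf-accessors
#' @export
setMethod("exposures", "SignatureSet", function(object) object@exposures)

#' @rdname nmf-accessors
#' @export
setGeneric("proportions", function(object) standardGeneric("proportions"))
#' @rdname nmf-accessors
#' @export
setMethod("proportions", "SignatureSet", function(object) object@proportions)

#' @rdname nmf-accessors
#' @export
setGeneric("chosenK", function(object) standardGeneric("chosenK"))
#' @rdname nmf-accessors
#' @export
setMethod("chosenK", "RankSelection", function(object) object@chosenK)

#' @rdname nmf-accessors
#' @export
setGeneric("selectionTable", function(object) standardGeneric("selectionTable"))
#' @rdname nmf-accessors
#' @export
setMethod("selectionTable", "RankSelection", function(object) object@table)

#' @rdname nmf-accessors
#' @export
setGeneric("consensusMatrices",
           function(object) standardGeneric("consensusMatrices"))
#' @rdname nmf-accessors
#' @export
setMethod("consensusMatrices", "RankSelection",
          function(object) object@consensus)
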