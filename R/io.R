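# Readers and writers for the standard formats mutation catalogs travel in:
# VCF (substitutions, indels), BED (genes, CpG islands), tab-delimited
# tables (substitutions, expression, rearrangements).  Internal coordinates
# are 1-based inclusive; BED input is converted on load.

#' @importFrom utils read.table write.table
NULL

## ---------------------------------------------------------------------------
## Substitutions
## ---------------------------------------------------------------------------

#' Read somatic substitutions from VCF or TSV
#'
#' TSV input needs columns \code{sample}, \code{chrom}, \code{pos},
#' \code{ref}, \code{alt}.  VCF input is restricted to SNV rows
#' (\code{nchar(REF) == nchar(ALT) == 1}); multi-allelic rows are split into
#' one record per alternate allele.  When a genome is supplied, every
#' record's REF is validated against the reference base at its position.
#'
#' @param path Input file.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @param sample Sample identifier for VCF input (defaults to the file's
#'   base name); ignored for TSV, which carries a sample column.
#' @param genome Optional \linkS4class{ReferenceGenome} for REF validation.
#' @return data.frame with columns \code{sample}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, sorted by sample, chromosome and position.
#' @seealso [splitCatalogs()] to turn the table into per-sample
#'   \linkS4class{MutationCatalog} objects.
#' @export
readSubstitutions <- function(path, format = c("tsv", "vcf"), sample = NULL,
                              genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("sample", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(df)))
      stopf("substitution TSV needs columns: %s", paste(need, collapse = ", "))
    df <- df[need]
  } else {
    vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "xx"))
    vcf <- VariantAnnotation::expand(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(rr$REF)
    alt <- as.character(rr$ALT)
    keep <- nchar(ref) == 1L & nchar(alt) == 1L & ref %in% BASES &
      alt %in% BASES
    if (is.null(sample))
      sample <- sub("\\.vcf(\\.gz)?$", "", basename(path))
    df <- data.frame(sample = sample,
                     chrom = as.character(GenomicRanges::seqnames(rr))[keep],
                     pos = GenomicRanges::start(rr)[keep],
                     ref = ref[keep], alt = alt[keep],
                     stringsAsFactors = FALSE)
  }
  df$pos <- as.integer(df$pos)
  bad <- !(df$ref %in% BASES) | !(df$alt %in% BASES) | df$ref == df$alt |
    df$pos < 1L
  if (any(bad)) stopf("%d malformed substitution record(s)", sum(bad))
  if (!is.null(genome)) {
    obs <- referenceBases(genome, df$chrom, df$pos)
    mism <- obs != df$ref
    if (any(mism))
      stopf("REF mismatch against genome for %d record(s): %s",
            sum(mism),
            paste(utils::head(sprintf("%s:%d %s!=%s", df$chrom[mism],
                                      df$pos[mism], df$ref[mism], obs[mism]),
                              5), collapse = "; "))
  }
  df[order(df$sample, df$chrom, df$pos, method = "radix"), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Write substitutions to TSV or minimal VCF
#'
#' The VCF writer emits a minimal but valid VCFv4.2 file (with contig
#' headers when a genome is supplied) and requires a single-sample table;
#' the TSV writer round-trips the multi-sample table format of
#' [readSubstitutions()].
#'
#' @param df Substitution table (\code{sample}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}).
#' @param path Output file.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @param genome Optional \linkS4class{ReferenceGenome}, used for VCF contig
#'   header lines.
#' @return \code{path}, invisibly.
#' @export
writeSubstitutions <- function(df, path, format = c("tsv", "vcf"),
                               genome = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(df[c("sample", "chrom", "pos", "ref", "alt")], path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (length(unique(df$sample)) > 1L)
      stopf("VCF output requires a single-sample table")
    hdr <- c("##fileformat=VCFv4.2",
             "##source=mutforge")
    if (!is.null(genome)) {
      lens <- chromLengths(genome)
      hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(lens), lens))
    }
    hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", df$chrom, df$pos, df$ref,
                    df$alt)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Split a multi-sample record table into per-sample catalogs
#'
#' @param substitutions Substitution table as from [readSubstitutions()].
#' @param indels Optional indel table (\code{sample}, \code{chrom},
#'   \code{pos}, \code{kind}, \code{seq}, \code{length}).
#' @param rearrangements Optional rearrangement table as from
#'   [readRearrangements()].
#' @return Named list of \linkS4class{MutationCatalog}, one per sample.
#' @export
splitCatalogs <- function(substitutions, indels = NULL,
                          rearrangements = NULL) {
  samples <- sort(unique(c(substitutions$sample, indels$sample,
                           rearrangements$sample)))
  out <- lapply(samples, function(s) {
    sub <- substitutions[substitutions$sample == s,
                         c("chrom", "pos", "ref", "alt"), drop = FALSE]
    ind <- if (is.null(indels)) emptyIndels() else
      indels[indels$sample == s, c("chrom", "pos", "kind", "seq", "length"),
             drop = FALSE]
    rea <- if (is.null(rearrangements)) emptyRearrangements() else
      rearrangements[rearrangements$sample == s,
                     c("chromA", "posA", "strandA", "chromB", "posB",
                       "strandB", "class"), drop = FALSE]
    rownames(ind) <- rownames(rea) <- NULL
    MutationCatalog(s, sub, ind, rea)
  })
  names(out) <- samples
  out
}

## ---------------------------------------------------------------------------
## Indels
## ---------------------------------------------------------------------------

#' Read somatic indels from TSV
#'
#' Columns: \code{sample}, \code{chrom}, \code{pos} (base immediately 5' of
#' the event), \code{kind} (deletion/insertion/complex), \code{seq} (deleted
#' or inserted bases), \code{length}.
#'
#' @param path Input file.
#' @return data.frame of validated indel records.
#' @export
readIndels <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "pos", "kind", "seq", "length")
  if (!all(need %in% names(df)))
    stopf("indel TSV needs columns: %s", paste(need, collapse = ", "))
  df <- df[need]
  df$pos <- as.integer(df$pos); df$length <- as.integer(df$length)
  if (any(df$length < 1L | df$length > 50L))
    stopf("indel lengths must be in 1..50")
  simple <- df$kind != "complex"
  if (any(nchar(df$seq[simple]) != df$length[simple]))
    stopf("indel seq must have nchar equal to length")
  df
}

## ---------------------------------------------------------------------------
## Intervals (BED): CpG islands and gene annotation
## ---------------------------------------------------------------------------

readBed <- function(path, minCols) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < minCols)
    stopf("BED file %s has %d columns, need >= %d", path, ncol(df), minCols)
  if (any(df[[2]] >= df[[3]]))
    stopf("BED intervals must have start < end")
  df
}

#' Read CpG island intervals from BED
#'
#' BED is 0-based half-open; intervals are converted to the internal
#' 1-based inclusive convention and overlapping or adjacent islands merged
#' at load time.
#'
#' @param path BED file (chrom, start, end).
#' @return \code{GRanges} of disjoint island intervals.
#' @export
readCpgIslands <- function(path) {
  df <- readBed(path, 3L)
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  GenomicRanges::reduce(sort(gr))
}

#' Read gene annotation from BED
#'
#' Expects BED6 (chrom, start, end, name, score, strand).  Coordinates are
#' converted to 1-based inclusive; the transcription start site is the
#' interval start on + genes and the interval end on - genes.  Duplicate
#' gene ids are resolved to the longest transcript.
#'
#' @param path BED6 file.
#' @return \code{GRanges} with strand and metadata columns \code{gene_id}
#'   and \code{tss}.
#' @export
readGenes <- function(path) {
  df <- readBed(path, 6L)
  genesFromTable(data.frame(gene_id = df[[4]], chrom = df[[1]],
                            start = df[[2]] + 1L, end = df[[3]],
                            strand = df[[6]], stringsAsFactors = FALSE))
}

#' @param df data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive), \code{strand}.
#' @rdname readGenes
#' @export
genesFromTable <- function(df) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(df)))
  if (!all(df$strand %in% c("+", "-"))) stopf("gene strand must be + or -")
  if (any(df$start > df$end)) stopf("gene start must be <= end")
  len <- df$end - df$start + 1L
  df <- df[order(df$gene_id, -len), ]
  df <- df[!duplicated(df$gene_id), ]
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$gene_id <- df$gene_id
  gr$tss <- ifelse(df$strand == "+", df$start, df$end)
  sort(gr)
}

#' Write intervals as BED
#'
#' @param gr \code{GRanges}; gene_id and strand are written when present.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(gr$gene_id)) {
    df$name <- gr$gene_id
    df$score <- 0L
    df$strand <- as.character(GenomicRanges::strand(gr))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Expression and rearrangements
## ---------------------------------------------------------------------------

#' Read per-gene expression values
#'
#' Long-format TSV with columns \code{gene_id}, \code{sample},
#' \code{log2expr}.  Values must be finite and every gene must be present
#' in the annotation.
#'
#' @param path Input TSV.
#' @param genes Gene annotation (\code{GRanges} from [readGenes()]).
#' @return data.frame of expression records.
#' @export
readExpression <- function(path, genes = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "sample", "log2expr")
  if (!all(need %in% names(df)))
    stopf("expression TSV needs columns: %s", paste(need, collapse = ", "))
  df <- df[need]
  if (any(!is.finite(df$log2expr)))
    stopf("expression values must be finite")
  if (!is.null(genes)) {
    missing <- setdiff(df$gene_id, genes$gene_id)
    if (length(missing))
      stopf("%d expression gene id(s) absent from annotation, e.g. %s",
            length(missing), missing[1])
  }
  df
}

#' Read rearrangement breakpoints
#'
#' Native dialect: 8-column TSV with header \code{sample}, \code{chromA},
#' \code{posA}, \code{strandA}, \code{chromB}, \code{posB}, \code{strandB},
#' \code{class}.  BEDPE (0-based half-open, no header) is also accepted;
#' each end's breakpoint position is taken as the interval end.
#'
#' @param path Input file.
#' @param format \code{"tsv"} or \code{"bedpe"}.
#' @return data.frame of rearrangement records with a \code{sample} column.
#' @export
readRearrangements <- function(path, format = c("tsv", "bedpe")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("sample", "chromA", "posA", "strandA", "chromB", "posB",
              "strandB", "class")
    if (!all(need %in% names(df)))
      stopf("rearrangement TSV needs columns: %s",
            paste(need, collapse = ", "))
    df <- df[need]
  } else {
    raw <- read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (ncol(raw) < 10L) stopf("BEDPE needs >= 10 columns")
    df <- data.frame(sample = raw[[7]], chromA = raw[[1]],
                     posA = as.integer(raw[[3]]), strandA = raw[[9]],
                     chromB = raw[[4]], posB = as.integer(raw[[6]]),
                     strandB = raw[[10]], class = "unknown",
                     stringsAsFactors = FALSE)
  }
  df$posA <- as.integer(df$posA); df$posB <- as.integer(df$posB)
  if (any(df$posA < 1L | df$posB < 1L))
    stopf("breakpoint positions must be >= 1")
  df
}
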