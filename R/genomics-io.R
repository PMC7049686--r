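# Readers/writers and sequence encoding shared by all stages.
# Coordinates follow the BED dialect (0-based, half-open) at every file
# boundary; in memory, GRanges keep their native 1-based convention.

#' One-hot encode a DNA sequence to a fixed length
#'
#' Encodes a sequence as a 4 x L binary matrix in fixed base order
#' A,C,G,T.  Shorter sequences are centred with symmetric zero padding
#' (the extra base of an odd remainder goes to the right); longer
#' sequences are cropped around their centre.  Ambiguous bases (N or any
#' non-ACGT character) become all-zero columns, so column sums are 1 at
#' retained A/C/G/T positions and 0 elsewhere.
#'
#' @param seq single character DNA string.
#' @param targetLength encoded length L in nucleotides, in \[200, 2000\]
#'   (shorter lengths are permitted only via `strict = FALSE`, used by
#'   unit-scale examples).
#' @param strict enforce the 200-2000 nt bound on `targetLength`.
#' @return 4 x L numeric matrix with rownames A,C,G,T.
#' @examples
#' oneHotEncode("ACGT", 4, strict = FALSE)
#' @export
oneHotEncode <- function(seq, targetLength, strict = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 1L)
    stop("seq must be a single non-empty DNA string")
  targetLength <- as.integer(targetLength)
  if (strict && (targetLength < 200L || targetLength > 2000L))
    stop("targetLength must lie within [200, 2000]")
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n > targetLength) {            # centred crop
    off <- (n - targetLength) %/% 2L
    ch <- ch[(off + 1L):(off + targetLength)]
    padL <- 0L
  } else {                           # centred pad, odd remainder right
    padL <- (targetLength - n) %/% 2L
  }
  m <- matrix(0, 4L, targetLength, dimnames = list(BASE_ORDER, NULL))
  idx <- match(ch, BASE_ORDER)       # NA for ambiguous bases
  keep <- which(!is.na(idx))
  m[cbind(idx[keep], padL + keep)] <- 1
  m
}

#' Decode a one-hot matrix back to sequence
#'
#' Inverse of [oneHotEncode()] on the retained subsequence: unit columns
#' map to their base, all-zero (padded or ambiguous) columns to `"N"`.
#'
#' @param mat 4 x L one-hot matrix.
#' @return single character string of length L.
#' @export
oneHotDecode <- function(mat) {
  stopifnot(nrow(mat) == 4L)
  b <- rep("N", ncol(mat))
  unit <- colSums(mat) == 1
  b[unit] <- BASE_ORDER[apply(mat[, unit, drop = FALSE], 2L, which.max)]
  paste(b, collapse = "")
}

#' Reverse complement of character DNA sequences
#'
#' Method for plain character vectors delegating to Biostrings; accepts
#' only A,C,G,T,N (N maps to N) and rejects other characters.
#'
#' @param x character vector of DNA strings.
#' @param ... ignored.
#' @return character vector of reverse complements.
#' @examples
#' reverseComplement("AAAC")   # "GTTT"
#' @importFrom Biostrings reverseComplement
#' @export
setMethod("reverseComplement", "character", function(x, ...) {
  if (any(grepl("[^ACGTN]", toupper(x))))
    stop("sequences may contain only A, C, G, T, N")
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(x))))
  names(out) <- names(x)
  out
})

#' Read regions from BED and extract their sequences from FASTA
#'
#' BED intervals (0-based half-open) are extracted from the FASTA
#' contigs; minus-strand regions are reverse complemented.
#'
#' @param bed path to a BED file (name column used as region identifier).
#' @param fasta path to the genome FASTA.
#' @return `GRanges` named by region identifier with `mcols$sequence`
#'   (a `DNAStringSet`).
#' @export
readRegions <- function(bed, fasta) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(bed, format = "BED")
  chr <- as.character(GenomicRanges::seqnames(gr))
  if (!all(chr %in% names(genome)))
    stop("BED contig(s) missing from FASTA: ",
         paste(setdiff(chr, names(genome)), collapse = ", "))
  if (any(GenomicRanges::end(gr) > Biostrings::width(genome)[match(chr, names(genome))]) ||
      any(GenomicRanges::start(gr) < 1L))
    stop("BED interval out of contig bounds")
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    s <- as.character(Biostrings::subseq(genome[[chr[i]]],
                                         GenomicRanges::start(gr)[i],
                                         GenomicRanges::end(gr)[i]))
    if (as.character(GenomicRanges::strand(gr)[i]) == "-")
      reverseComplement(s) else s
  }, character(1)))
  nm <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
  names(gr) <- nm
  names(seqs) <- nm
  S4Vectors::mcols(gr)$sequence <- seqs
  gr
}

#' Read RPKM and label tables into labelled examples (sans encoding)
#'
#' Joins the per-replicate RPKM matrix with per-region class labels by
#' region identifier and log-transforms the regression targets as
#' `log(RPKM + pseudocount)`.
#'
#' @param rpkmTsv TSV with column `region` then one numeric column per
#'   replicate.
#' @param labelsTsv TSV with columns `region` and `label`.
#' @param pseudocount added before the log (default 1, so RPKM 0 maps to
#'   target 0).
#' @param logBase base of the logarithm (default natural).
#' @return list with `ids`, `targets` (log-RPKM matrix), `labels`
#'   (factor) aligned to the RPKM row order.
#' @export
readTables <- function(rpkmTsv, labelsTsv, pseudocount = 1, logBase = exp(1)) {
  rp <- utils::read.delim(rpkmTsv, check.names = FALSE)
  lb <- utils::read.delim(labelsTsv, check.names = FALSE)
  if (!"region" %in% names(rp) || !"region" %in% names(lb))
    stop("both tables need a 'region' identifier column")
  j <- match(rp$region, lb$region)
  if (anyNA(j))
    stop("identifier mismatch: regions missing from labels table")
  vals <- as.matrix(rp[, setdiff(names(rp), "region"), drop = FALSE])
  if (any(vals < 0)) stop("negative RPKM values")
  list(ids = rp$region,
       targets = log(vals + pseudocount, base = logBase),
       labels = factor(lb$label[j]))
}

#' Index single-base read positions from a BED file
#'
#' Reads width-1 BED features (read 5' ends or fragment midpoints --
#' whichever the caller produced; recorded in the returned metadata) into
#' per-chromosome sorted position lists supporting interval counting by
#' binary search.
#'
#' @param bed path to the BED file of read anchors.
#' @param anchor free-text description of what the positions are
#'   (default "midpoint").
#' @return object of class `readIndex`.
#' @export
readReadPositions <- function(bed, anchor = "midpoint") {
  gr <- rtracklayer::import(bed, format = "BED")
  pos0 <- GenomicRanges::start(gr) - 1L     # back to 0-based
  chrom <- as.character(GenomicRanges::seqnames(gr))
  idx <- lapply(split(pos0, chrom), sort)
  structure(list(positions = idx, total = length(gr), anchor = anchor),
            class = "readIndex")
}

#' Build a read index from in-memory read positions
#'
#' @param gr `GRanges` of width-1 read anchors.
#' @param anchor description of the anchor convention.
#' @return object of class `readIndex`.
#' @export
readIndexFromGRanges <- function(gr, anchor = "midpoint") {
  pos0 <- GenomicRanges::start(gr) - 1L
  chrom <- as.character(GenomicRanges::seqnames(gr))
  idx <- lapply(split(pos0, chrom), sort)
  structure(list(positions = idx, total = length(gr), anchor = anchor),
            class = "readIndex")
}

#' Count reads in a 0-based half-open interval
#'
#' @param index a `readIndex` from [readReadPositions()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval bounds.
#' @return integer read count in `[start, end)`.
#' @export
countReads <- function(index, chrom, start, end) {
  p <- index$positions[[chrom]]
  if (is.null(p) || length(p) == 0L) return(0L)
  findInterval(end - 1L, p) - findInterval(start - 1L, p)
}

#' @export
print.readIndex <- function(x, ...) {
  cat(sprintf("readIndex: %d reads on %d contig(s), anchor = %s\n",
              x$total, length(x$positions), x$anchor))
  invisible(x)
}
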