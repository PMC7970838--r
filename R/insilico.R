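## In-silico PCR: locate primer binding sites (IUPAC-aware) and extract
## predicted amplicons from a reference sequence.

#' Construct a PrimerAssay
#'
#' @param forward,reverse primer sequences 5'->3' (IUPAC codes allowed).
#'   Defaults are the herring-specific mt16S pair (forward
#'   CGCCCACCAATCACGAA, reverse ACGTTTGTGCCAGTATCACGTT).
#' @param maxMismatches mismatches tolerated per primer site (default 0).
#' @return a [PrimerAssay-class].
#' @export
PrimerAssay <- function(forward = "CGCCCACCAATCACGAA",
                        reverse = "ACGTTTGTGCCAGTATCACGTT",
                        maxMismatches = 0) {
  new("PrimerAssay", forward = toupper(forward), reverse = toupper(reverse),
      maxMismatches = maxMismatches)
}

#' Read a primer pair from a FASTA file
#'
#' The first record is taken as the forward primer and the second as the
#' reverse primer.
#'
#' @param path FASTA file with (at least) two records.
#' @param maxMismatches passed to [PrimerAssay()].
#' @return a [PrimerAssay-class].
#' @export
readPrimerPair <- function(path, maxMismatches = 0) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 2)
    stop("primer FASTA must contain a forward and a reverse record")
  PrimerAssay(as.character(seqs[[1]]), as.character(seqs[[2]]),
              maxMismatches = maxMismatches)
}

ampliconsOneStrand <- function(fwd, revRC, subject, maxMM, maxLen) {
  fhits <- Biostrings::matchPattern(fwd, subject, max.mismatch = maxMM,
                                    fixed = FALSE)
  rhits <- Biostrings::matchPattern(revRC, subject, max.mismatch = maxMM,
                                    fixed = FALSE)
  if (length(fhits) == 0 || length(rhits) == 0)
    return(NULL)
  out <- list()
  fs <- IRanges::start(fhits)
  re <- IRanges::end(rhits)
  rs <- IRanges::start(rhits)
  for (a in seq_along(fs)) {
    ## reverse site must start at or after the end of the forward site
    okr <- which(rs > fs[a] + length(fwd) - 1 &
                   re - fs[a] + 1 <= maxLen)
    for (b in okr) {
      out[[length(out) + 1]] <- data.frame(
        start = fs[a], end = re[b], length = re[b] - fs[a] + 1,
        sequence = as.character(Biostrings::subseq(subject, fs[a], re[b])),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' In-silico PCR against a reference sequence
#'
#' Searches both strands of the reference for a forward-primer site
#' followed downstream by the reverse complement of the reverse primer,
#' allowing up to \code{assay@maxMismatches} mismatches per site
#' (IUPAC-aware matching). Predicted amplicon lengths include both primer
#' footprints; only products up to \code{maxLength} are reported.
#'
#' @param assay a [PrimerAssay-class].
#' @param reference a DNAString, a single character string, or a path to
#'   a FASTA file (first record used).
#' @param maxLength amplicon length cap in nt (default 2000).
#' @return data.frame with columns start, end, length, strand, sequence.
#'   Coordinates are on the plus strand of the reference; minus-strand
#'   hits are mapped back.
#' @examples
#' amp <- paste0("CGCCCACCAATCACGAA", strrep("AT", 15),
#'               as.character(Biostrings::reverseComplement(
#'                 Biostrings::DNAString("ACGTTTGTGCCAGTATCACGTT"))))
#' inSilicoPCR(PrimerAssay(), amp)$length  # 69
#' @export
inSilicoPCR <- function(assay, reference, maxLength = 2000) {
  validObject(assay)
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)[[1]]
  } else if (is.character(reference)) {
    reference <- tryCatch(Biostrings::DNAString(toupper(reference)),
                          error = function(e)
                            stop("reference contains non-nucleotide characters",
                                 call. = FALSE))
  }
  if (length(reference) == 0) stop("reference sequence is empty")
  fwd <- Biostrings::DNAString(assay@forward)
  revRC <- Biostrings::reverseComplement(Biostrings::DNAString(assay@reverse))
  mm <- assay@maxMismatches
  L <- length(reference)

  plus <- ampliconsOneStrand(fwd, revRC, reference, mm, maxLength)
  if (!is.null(plus)) plus$strand <- "+"
  minusSubject <- Biostrings::reverseComplement(reference)
  minus <- ampliconsOneStrand(fwd, revRC, minusSubject, mm, maxLength)
  if (!is.null(minus)) {
    ## map coordinates back to the plus strand
    s <- L - minus$end + 1
    e <- L - minus$start + 1
    minus$start <- s; minus$end <- e
    minus$strand <- "-"
  }
  res <- rbind(plus, minus)
  if (is.null(res))
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), strand = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  res <- res[, c("start", "end", "length", "strand", "sequence")]
  rownames(res) <- NULL
  res
}

#' Path to the packaged synthetic herring mt16S reference
#'
#' A synthetic stand-in for the herring mitochondrial 16S region carrying
#' the assay's primer binding sites separated by a 30 nt insert, so the
#' predicted amplicon is the assay's 69 bp fragment. It is generated
#' text, not the GenBank record, and is intended for offline testing of
#' [inSilicoPCR()].
#'
#' @return file path of the FASTA reference.
#' @export
syntheticHerringReference <- function() {
  system.file("extdata", "herring_mt16S_synthetic.fasta",
              package = "predquant", mustWork = TRUE)
}
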