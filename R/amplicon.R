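#' Construct a ReferenceAmplicon from a DNA sequence
#'
#' Scans the (unconverted, top-strand) reference sequence of a bisulfite
#' amplicon and records the position of every CpG cytosine and of every
#' cytosine outside CpG context. The former carry the methylation signal;
#' the latter must read as T after complete bisulfite conversion and are used
#' to estimate per-clone conversion efficiency.
#'
#' @param sequence Character scalar: uppercase DNA over {A, C, G, T}, or a
#'   [Biostrings::DNAString].
#' @return A [ReferenceAmplicon-class] object. Coordinates are 1-based.
#' @examples
#' amp <- referenceAmplicon("ACGTCTA")
#' cpgPositions(amp)      # 2 (the C of the CpG at positions 2-3)
#' nonCpgCPositions(amp)  # 5
#' @export
referenceAmplicon <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single non-empty DNA string", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  isC <- chars == "C"
  nextG <- c(chars[-1] == "G", FALSE)
  cpg <- which(isC & nextG)
  nonCpg <- which(isC & !nextG)
  methods::new("ReferenceAmplicon",
               sequence = sequence,
               cpgPositions = as.integer(cpg),
               nonCpgCPositions = as.integer(nonCpg))
}

#' @rdname referenceAmplicon
#' @param x A \code{ReferenceAmplicon}.
#' @export
setMethod("ampliconSequence", "ReferenceAmplicon", function(x) x@sequence)

#' @rdname referenceAmplicon
#' @export
setMethod("cpgPositions", "ReferenceAmplicon", function(x) x@cpgPositions)

#' @rdname referenceAmplicon
#' @export
setMethod("nonCpgCPositions", "ReferenceAmplicon",
          function(x) x@nonCpgCPositions)

setMethod("show", "ReferenceAmplicon", function(object) {
  cat("ReferenceAmplicon of length", nchar(object@sequence), "bp\n")
  cat("  CpG sites:      ", length(object@cpgPositions), "\n")
  cat("  non-CpG Cs (QC):", length(object@nonCpgCPositions), "\n")
})

#' Read a reference amplicon from a FASTA file
#'
#' @param path Path to a FASTA file whose first record is the amplicon.
#' @return A [ReferenceAmplicon-class].
#' @export
readReferenceAmplicon <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 1L) stop("no sequence in ", path, call. = FALSE)
  referenceAmplicon(as.character(seqs[[1]]))
}
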