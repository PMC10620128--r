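#' Read a genome FASTA into an in-memory genome
#'
#' Sequences are uppercased and restricted to the {A,C,G,T,N} alphabet;
#' FASTA headers are truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  as_genome(g)
}

#' Coerce sequences to the genome container
#'
#' @param x named character vector or `DNAStringSet`.
#' @return uppercase `DNAStringSet` over {A,C,G,T,N}.
#' @export
as_genome <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  if (!methods::is(x, "DNAStringSet")) {
    stop("genome must be a named character vector or DNAStringSet",
         call. = FALSE)
  }
  if (is.null(names(x)) || anyDuplicated(names(x)) || any(!nzchar(names(x)))) {
    stop("genome sequences must have unique non-empty names", call. = FALSE)
  }
  freq <- Biostrings::alphabetFrequency(x, collapse = TRUE)
  extra <- freq[setdiff(names(freq), c("A", "C", "G", "T", "N"))]
  if (sum(extra) > 0) {
    stop("genome contains letters outside {A,C,G,T,N}", call. = FALSE)
  }
  x
}

#' Write a genome to FASTA
#' @param genome `DNAStringSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Fetch a plus-strand sequence slice
#'
#' @param genome `DNAStringSet`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open coordinates; a zero-length request is a
#'   validation error, out-of-bounds coordinates are a range error.
#' @return uppercase character string of length `end - start`.
#' @export
fetch_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop(sprintf("unknown chromosome '%s'", chrom), call. = FALSE)
  }
  if (is.na(start) || is.na(end) || start >= end) {
    stop("need 0 <= start < end for sequence retrieval", call. = FALSE)
  }
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (start < 0 || end > len) {
    stop(sprintf("interval %s:%d-%d outside chromosome length %d",
                 chrom, start, end, len), call. = FALSE)
  }
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

#' Reverse-complement DNA strings
#'
#' Vectorized; an involution (applying twice returns the input). Characters
#' outside {A,C,G,T,N} are a validation error.
#'
#' @param seq character vector of DNA strings.
#' @return reverse-complemented character vector.
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0) return(character())
  if (any(is.na(seq)) || any(grepl("[^ACGTN]", seq))) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# complement without reversal, used for the flank-profile mirror
.complement <- function(bases) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[bases]
}
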