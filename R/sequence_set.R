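#' Construct a set of named DNA sequences
#'
#' A `sequence_set` is the container consumed by the motif scanner and the
#' enrichment test: a named character vector of uppercase DNA sequences
#' (alphabet A, C, G, T, N) with unique, nonempty identifiers.
#'
#' @param sequences character vector of DNA sequences; lowercase input is
#'   uppercased.
#' @param ids character vector of unique identifiers; defaults to the names
#'   of `sequences`, or `seq_1 ... seq_n` when unnamed.
#' @return a named character vector of class `sequence_set`.
#' @examples
#' sequence_set(c(peak1 = "ggag", peak2 = "ACGT"))
#' @export
sequence_set <- function(sequences, ids = names(sequences)) {
  force(ids)  # capture names before as.character() strips them
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("sequence set must contain at least one sequence")
  if (is.null(ids)) ids <- paste0("seq_", seq_along(sequences))
  ids <- as.character(ids)
  if (length(ids) != length(sequences)) stop("ids and sequences differ in length")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(sequences))) {
    stop("empty sequence(s): ", paste(ids[!nzchar(sequences)], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("non-DNA characters in sequence(s): ", paste(ids[bad], collapse = ", "))
  }
  structure(stats::setNames(sequences, ids), class = c("sequence_set", "character"))
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set with", length(x), "sequences; lengths",
      min(nchar(x)), "-", max(nchar(x)), "bp\n")
  show_n <- min(6L, length(x))
  for (i in seq_len(show_n)) {
    s <- x[[i]]
    cat(sprintf("  %s (%d bp) %s%s\n", names(x)[i], nchar(s),
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x) > show_n) cat("  ...\n")
  invisible(x)
}

#' @export
`[.sequence_set` <- function(x, i, ...) {
  out <- NextMethod()
  class(out) <- c("sequence_set", "character")
  out
}

#' Read a FASTA file into a sequence set
#'
#' Identifiers are taken up to the first whitespace; sequences are
#' uppercased. Duplicate ids and empty records are rejected.
#'
#' @param path path to a FASTA file (wrapped or unwrapped records).
#' @return a [sequence_set].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(dss))
  if (any(Biostrings::width(dss) == 0L)) {
    stop("empty sequence record(s) in ", path, ": ",
         paste(ids[Biostrings::width(dss) == 0L], collapse = ", "))
  }
  sequence_set(as.character(dss), ids)
}

#' Write a sequence set as FASTA
#'
#' @param seqs a [sequence_set].
#' @param path output file path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(unclass(seqs))
  names(dss) <- names(seqs)
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Extract peak sequences from BED intervals and a genome FASTA
#'
#' Intervals are interpreted as 0-based half-open (standard BED). When
#' `use_strand` is TRUE and a 6th column is present, minus-strand intervals
#' are reverse-complemented. Ids come from the BED name column when present,
#' otherwise `chrom:start-end`.
#'
#' @param bed_path BED file with at least 3 columns (chrom, start, end).
#' @param genome_fasta_path FASTA file of the reference sequences.
#' @param use_strand honour the strand column if present.
#' @return a [sequence_set], one sequence per interval.
#' @export
extract_peak_sequences <- function(bed_path, genome_fasta_path, use_strand = TRUE) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 3L) stop("BED file must have at least 3 columns")
  genome <- Biostrings::readDNAStringSet(genome_fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom <- as.character(bed[[1]])
  start0 <- as.integer(bed[[2]])
  end0 <- as.integer(bed[[3]])
  ids <- if (ncol(bed) >= 4L) as.character(bed[[4]]) else paste0(chrom, ":", start0, "-", end0)
  strand <- if (ncol(bed) >= 6L) as.character(bed[[6]]) else rep("+", nrow(bed))
  missing_chr <- setdiff(chrom, names(genome))
  if (length(missing_chr)) stop("contig(s) absent from genome: ", paste(missing_chr, collapse = ", "))
  out <- character(nrow(bed))
  for (i in seq_len(nrow(bed))) {
    clen <- Biostrings::width(genome[chrom[i]])
    if (start0[i] < 0L || end0[i] > clen || start0[i] >= end0[i]) {
      stop(sprintf("interval %s:%d-%d outside contig bounds (length %d)",
                   chrom[i], start0[i], end0[i], clen))
    }
    s <- Biostrings::subseq(genome[[chrom[i]]], start = start0[i] + 1L, end = end0[i])
    if (use_strand && strand[i] == "-") s <- Biostrings::reverseComplement(s)
    out[i] <- as.character(s)
  }
  sequence_set(out, ids)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A, C, G, T, N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Fast generation of random DNA strings with given lengths and base
# probabilities. Draws one long character stream and splits it, which is an
# order of magnitude faster than per-sequence paste().
random_dna <- function(lengths, base_probs) {
  lengths <- as.integer(lengths)
  total <- sum(lengths)
  chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE, prob = base_probs)
  big <- paste(chars, collapse = "")
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  substring(big, starts, ends)
}
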