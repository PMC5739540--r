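#' IUPAC degenerate DNA motifs
#'
#' Compiles an IUPAC pattern (e.g. `"TGGAGNW"`) into a motif object holding
#' the pattern, its length and an equivalent regular expression. Degenerate
#' codes follow the IUPAC nucleotide alphabet: R = A/G, Y = C/T, S = C/G,
#' W = A/T, K = G/T, M = A/C, B/D/H/V = three-base sets, N = any base.
#' An `N` in a *subject* sequence never matches any motif position (motif
#' `N` matches the four unambiguous bases only), so unknown bases cannot
#' create matches.
#'
#' @param pattern a nonempty string of IUPAC DNA codes.
#' @return an object of class `iupac_motif` with elements `pattern`,
#'   `length` and `regex`.
#' @examples
#' iupac_motif("GGR")
#' @export
iupac_motif <- function(pattern) {
  pattern <- toupper(as.character(pattern))
  if (length(pattern) != 1L || !nzchar(pattern)) stop("pattern must be a single nonempty string")
  chars <- strsplit(pattern, "")[[1]]
  bad <- !chars %in% names(.iupac_sets)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid IUPAC character '%s' at position %d in pattern '%s'",
                 chars[i], i, pattern))
  }
  regex <- paste0(vapply(chars, function(ch) {
    bases <- .iupac_sets[[ch]]
    if (length(bases) == 1L) bases else paste0("[", paste(bases, collapse = ""), "]")
  }, character(1)), collapse = "")
  structure(list(pattern = pattern, length = nchar(pattern), regex = regex),
            class = "iupac_motif")
}

.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' @export
print.iupac_motif <- function(x, ...) {
  cat(sprintf("IUPAC motif %s (length %d)\n", x$pattern, x$length))
  invisible(x)
}

as_motif <- function(x) {
  if (inherits(x, "iupac_motif")) x else iupac_motif(x)
}

#' Test whether sequences contain a degenerate motif
#'
#' @param sequences character vector of DNA sequences (a [sequence_set] or
#'   plain strings).
#' @param motif an [iupac_motif] or IUPAC pattern string.
#' @param strand_mode `"sense"` scans the given strand only (the default:
#'   RIP peaks represent transcribed RNA); `"both"` also scans the reverse
#'   complement.
#' @return logical vector, one element per sequence: TRUE if the motif
#'   matches at one or more offsets.
#' @examples
#' contains_motif(c("TGGA", "GGC"), "GGR")
#' @export
contains_motif <- function(sequences, motif, strand_mode = c("sense", "both")) {
  strand_mode <- match.arg(strand_mode)
  motif <- as_motif(motif)
  hits <- grepl(motif$regex, sequences, perl = TRUE)
  if (strand_mode == "both") {
    hits <- hits | grepl(motif$regex, revcomp(as.character(sequences)), perl = TRUE)
  }
  unname(hits)
}

#' Proportion of sequences containing a motif
#'
#' Each sequence is counted at most once, regardless of how many times the
#' motif matches within it.
#'
#' @inheritParams contains_motif
#' @param seqs a [sequence_set] (or nonempty character vector).
#' @return fraction in \[0, 1\].
#' @export
motif_proportion <- function(seqs, motif, strand_mode = c("sense", "both")) {
  if (length(seqs) == 0L) stop("empty sequence set")
  mean(contains_motif(seqs, motif, strand_mode))
}

#' The default G-rich motif panel
#'
#' The five degenerate motifs used to characterise CNBP binding preferences
#' in RIP peaks: TGGAGNW, TGGAG, GGAGNW, GGAG and GGR.
#'
#' @return list of five [iupac_motif] objects.
#' @export
default_motif_panel <- function() {
  lapply(c("TGGAGNW", "TGGAG", "GGAGNW", "GGAG", "GGR"), iupac_motif)
}
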