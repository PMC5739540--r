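#' Filter genes downregulated upon knockdown
#'
#' Selects gene ids whose log2 fold change (knockdown vs control) lies
#' strictly below the threshold; the default -0.58 corresponds to about a
#' 1.5-fold decrease. "Below" is read as a strict inequality, so a gene
#' exactly at the threshold does not pass. Duplicate gene ids are collapsed
#' keeping the most-negative log2 fold change, with a warning.
#'
#' @param gene_id character vector of gene identifiers.
#' @param log2fc numeric vector of log2 fold changes, paired with
#'   `gene_id`.
#' @param threshold_log2fc strict upper bound on log2 fold change.
#' @return character vector of passing gene ids (normalised: trimmed and
#'   upper-cased).
#' @export
filter_downregulated <- function(gene_id, log2fc, threshold_log2fc = -0.58) {
  if (length(gene_id) == 0L) stop("no records supplied")
  if (length(gene_id) != length(log2fc)) stop("gene_id and log2fc must be paired")
  if (any(!is.finite(log2fc))) {
    stop("non-finite log2fc for gene(s): ",
         paste(gene_id[!is.finite(log2fc)], collapse = ", "))
  }
  gene_id <- normalize_gene_id(gene_id)
  if (anyDuplicated(gene_id)) {
    warning("duplicate gene ids collapsed keeping the most-negative log2fc")
    o <- order(gene_id, log2fc)
    gene_id <- gene_id[o]; log2fc <- log2fc[o]
    keep <- !duplicated(gene_id)
    gene_id <- gene_id[keep]; log2fc <- log2fc[keep]
  }
  gene_id[log2fc < threshold_log2fc]
}

#' Filter genes enriched in the RIP fraction
#'
#' Selects gene ids whose RIP signal is at least `min_fold` over the input
#' control; the default 4 reflects the requirement that bound transcripts
#' be 4-fold above input. "4-fold above" is read inclusively, so a gene at
#' exactly 4.0 passes.
#'
#' @param gene_id character vector of gene identifiers.
#' @param fold_over_input positive fold enrichment over input, paired with
#'   `gene_id`. Where several peaks map to one gene, the caller chooses the
#'   per-gene aggregation (maximum over peaks recommended) before calling.
#' @param min_fold inclusive lower bound on fold enrichment.
#' @return character vector of passing gene ids (normalised).
#' @export
filter_rip_enriched <- function(gene_id, fold_over_input, min_fold = 4.0) {
  if (length(gene_id) == 0L) stop("no records supplied")
  if (length(gene_id) != length(fold_over_input)) {
    stop("gene_id and fold_over_input must be paired")
  }
  if (any(!is.finite(fold_over_input)) || any(fold_over_input <= 0)) {
    stop("fold_over_input must be strictly positive for gene(s): ",
         paste(gene_id[!is.finite(fold_over_input) | fold_over_input <= 0],
               collapse = ", "))
  }
  gene_id <- normalize_gene_id(gene_id)
  if (anyDuplicated(gene_id)) {
    warning("duplicate gene ids collapsed keeping the maximum fold enrichment")
    o <- order(gene_id, -fold_over_input)
    keep <- !duplicated(gene_id[o])
    fold_over_input <- fold_over_input[o][keep]
    gene_id <- gene_id[o][keep]
  }
  unique(gene_id[fold_over_input >= min_fold])
}

normalize_gene_id <- function(x) toupper(trimws(as.character(x)))

#' Intersect downregulated and RIP-enriched gene sets
#'
#' The target-nomination step: candidate direct targets are the genes that
#' are both downregulated upon knockdown of the lncRNA and enriched in the
#' protein's RIP fraction. Gene identity is exact string equality after
#' whitespace trimming and case folding; no alias resolution is attempted.
#'
#' @param down character vector of downregulated gene ids (e.g. from
#'   [filter_downregulated()]).
#' @param enriched character vector of RIP-enriched gene ids (e.g. from
#'   [filter_rip_enriched()]).
#' @param provenance optional named list recording thresholds and input
#'   identities, stored with the result.
#' @return object of class `overlap_set`: list with `genes` (sorted,
#'   deduplicated intersection) and `provenance`.
#' @export
intersect_targets <- function(down, enriched, provenance = list()) {
  genes <- sort(intersect(normalize_gene_id(down), normalize_gene_id(enriched)),
                method = "radix")
  provenance$n_down <- length(unique(normalize_gene_id(down)))
  provenance$n_enriched <- length(unique(normalize_gene_id(enriched)))
  structure(list(genes = genes, provenance = provenance),
            class = "overlap_set")
}

#' @export
print.overlap_set <- function(x, ...) {
  cat(sprintf("Overlap of %d downregulated x %d RIP-enriched genes: %d targets\n",
              x$provenance$n_down, x$provenance$n_enriched, length(x$genes)))
  if (length(x$genes)) {
    shown <- utils::head(x$genes, 10L)
    cat("  ", paste(shown, collapse = ", "),
        if (length(x$genes) > 10L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Write an overlap set with its provenance header
#'
#' Writes a one-column gene list preceded by commented header lines that
#' record the thresholds and input identities used, so a run can be
#' reproduced from its output.
#'
#' @param overlap an [intersect_targets()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_overlap <- function(overlap, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(overlap$provenance)) {
    writeLines(sprintf("# %s: %s", key,
                       paste(overlap$provenance[[key]], collapse = " ")), con)
  }
  writeLines("gene_id", con)
  writeLines(overlap$genes, con)
  invisible(path)
}
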