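#' Scan sequences for G-rich regions with a GGAG core
#'
#' Slides a window of `window` bases along each sequence and flags windows
#' whose G fraction is at least `min_g_fraction` and that contain a run of
#' at least `min_g_run` consecutive Gs. Overlapping or adjacent qualifying
#' windows are merged into maximal regions, and each region is flagged for
#' containment of the GGAG core (a plain substring test on the sense
#' strand), the tetranucleotide preferred by CNBP within G-rich elements.
#'
#' Sequences shorter than the window are skipped with a warning.
#'
#' @param seqs a [sequence_set].
#' @param window window size in bases.
#' @param min_g_fraction minimum fraction of G within a window.
#' @param min_g_run minimum length of a consecutive G run within a window.
#' @return data.frame with one row per region: `sequence_id`, `start`,
#'   `end` (0-based half-open), `sequence` (the region's bases),
#'   `g_fraction`, `has_ggag_core`.
#' @examples
#' s <- sequence_set(c(x = "AAAAGGAGGGAAAA"))
#' scan_g_rich(s, window = 6, min_g_fraction = 0.6, min_g_run = 2)
#' @export
scan_g_rich <- function(seqs, window = 20L, min_g_fraction = 0.6,
                        min_g_run = 2L) {
  window <- as.integer(window)
  min_g_run <- as.integer(min_g_run)
  if (min_g_run < 1L || window < min_g_run) {
    stop("window must be >= min_g_run >= 1")
  }
  out <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    L <- nchar(s)
    if (L < window) {
      warning(sprintf("sequence '%s' (%d bp) shorter than window (%d bp); skipped",
                      id, L, window))
      next
    }
    starts <- seq_len(L - window + 1L)
    wins <- substring(s, starts, starts + window - 1L)
    g_count <- nchar(wins) - nchar(gsub("G", "", wins, fixed = TRUE))
    ok <- g_count / window >= min_g_fraction &
      grepl(strrep("G", min_g_run), wins, fixed = TRUE)
    if (!any(ok)) next
    # merge overlapping/adjacent qualifying windows into maximal regions
    qstart <- starts[ok]
    qend <- qstart + window - 1L
    brk <- c(TRUE, qstart[-1L] > qend[-length(qend)] + 1L)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      rs <- min(qstart[grp == g])
      re <- max(qend[grp == g])
      region <- substr(s, rs, re)
      gfrac <- (nchar(region) - nchar(gsub("G", "", region, fixed = TRUE))) /
        nchar(region)
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = id,
        start = rs - 1L,          # 0-based half-open
        end = re,
        sequence = region,
        g_fraction = gfrac,
        has_ggag_core = grepl("GGAG", region, fixed = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      g_fraction = numeric(0), has_ggag_core = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
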