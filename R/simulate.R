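#' Generate a synthetic peak sequence set with an optional planted motif
#'
#' Emulates a RIP-seq peak sequence set: `n_sequences` random DNA sequences
#' with a controllable length distribution and base composition, in which a
#' degenerate motif can be planted in a chosen fraction of sequences.
#' Exactly `round(planted_fraction * n_sequences)` sequences (chosen
#' without replacement) receive one planted instance at a uniformly random
#' valid offset; degenerate motif positions (N, R, W, ...) are instantiated
#' uniformly over their allowed bases at insertion time. Background
#' sequences may still contain the motif by chance, so the realised
#' (scanned) proportion is reported alongside the planted one.
#'
#' @param n_sequences number of sequences to generate.
#' @param lengths either a numeric vector of lengths in bp (length 1: all
#'   sequences that long; length `n_sequences`: used as-is; otherwise
#'   sampled with replacement), or a list distribution spec:
#'   `list(dist = "uniform", min =, max =)` for discrete-uniform lengths or
#'   `list(dist = "lognormal", meanlog =, sdlog =, min =)` for rounded
#'   lognormal lengths floored at `min`.
#' @param base_composition probability vector over A, C, G, T; must sum
#'   to 1.
#' @param planted_motif IUPAC pattern or [iupac_motif] to plant, or NULL.
#' @param planted_fraction fraction of sequences receiving a planted
#'   instance, in \[0, 1\].
#' @param seed integer seed (the global RNG state is restored on exit).
#' @return a [sequence_set] with attributes `planted_ids`,
#'   `planted_proportion` (exact at generation), `realized_proportion`
#'   (by scanning) and `seed`.
#' @examples
#' peaks <- gen_peak_set(20, lengths = 50, planted_motif = "GGAG",
#'                       planted_fraction = 0.5, seed = 7)
#' attr(peaks, "planted_proportion")
#' @export
gen_peak_set <- function(n_sequences, lengths = 50L,
                         base_composition = c(0.25, 0.25, 0.25, 0.25),
                         planted_motif = NULL, planted_fraction = 0,
                         seed = NULL) {
  n_sequences <- as.integer(n_sequences)
  if (n_sequences < 1L) stop("n_sequences must be positive")
  if (any(base_composition < 0) || abs(sum(base_composition) - 1) > 1e-9) {
    stop("base_composition entries must be nonnegative and sum to 1")
  }
  if (planted_fraction < 0 || planted_fraction > 1) {
    stop("planted_fraction must be in [0, 1]")
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))

  lens <- sample_lengths(lengths, n_sequences)
  motif <- if (is.null(planted_motif)) NULL else as_motif(planted_motif)
  if (!is.null(motif) && planted_fraction > 0) {
    too_short <- lens < motif$length
    if (any(too_short)) {
      stop(sprintf("sampled length %d shorter than planted motif %s (%d bp)",
                   min(lens[too_short]), motif$pattern, motif$length))
    }
  }

  seqs <- random_dna(lens, base_composition)
  planted_idx <- integer(0)
  if (!is.null(motif) && planted_fraction > 0) {
    n_plant <- round(planted_fraction * n_sequences)
    planted_idx <- sample.int(n_sequences, n_plant)
    for (i in planted_idx) {
      inst <- instantiate_motif(motif)
      offset <- sample.int(lens[i] - motif$length + 1L, 1L)
      substr(seqs[i], offset, offset + motif$length - 1L) <- inst
    }
  }
  ids <- sprintf("peak_%04d", seq_len(n_sequences))
  out <- sequence_set(seqs, ids)
  attr(out, "planted_ids") <- ids[sort(planted_idx)]
  attr(out, "planted_proportion") <- length(planted_idx) / n_sequences
  attr(out, "realized_proportion") <-
    if (is.null(motif)) NA_real_ else motif_proportion(out, motif)
  attr(out, "seed") <- seed
  out
}

sample_lengths <- function(lengths, n) {
  if (is.list(lengths)) {
    lens <- switch(lengths$dist,
      uniform = sample(seq.int(lengths$min, lengths$max), n, replace = TRUE),
      lognormal = pmax(as.integer(round(stats::rlnorm(n, lengths$meanlog,
                                                      lengths$sdlog))),
                       as.integer(lengths$min %||% 1L)),
      stop("unknown length distribution: ", lengths$dist)
    )
  } else if (length(lengths) == 1L) {
    lens <- rep.int(as.integer(lengths), n)
  } else if (length(lengths) == n) {
    lens <- as.integer(lengths)
  } else {
    lens <- sample(as.integer(lengths), n, replace = TRUE)
  }
  if (any(lens < 1L)) stop("sampled length ", min(lens), " is below 1 bp")
  lens
}

`%||%` <- function(a, b) if (is.null(a)) b else a

instantiate_motif <- function(motif) {
  chars <- strsplit(motif$pattern, "")[[1]]
  paste(vapply(chars, function(ch) {
    bases <- .iupac_sets[[ch]]
    bases[sample.int(length(bases), 1L)]
  }, character(1)), collapse = "")
}

#' Half-life presets for the decay simulator
#'
#' Named presets encoding the experimental conditions of the CCND1
#' stability experiments: control shRNA (5 h), LAST knockdown (3 h), LAST
#' over-expression (9 h), CNBP knockdown (3 h), the CCND1 5'UTR reporter
#' without cofactors (4 h) and the same reporter with LAST and CNBP
#' supplied (9 h).
#'
#' @return named numeric vector of half-lives in hours.
#' @export
decay_presets <- function() {
  c(control = 5,
    LAST_knockdown = 3,
    LAST_overexpression = 9,
    CNBP_knockdown = 3,
    utr5_reporter = 4,
    utr5_reporter_LAST_CNBP = 9)
}

#' Simulate an actinomycin-D chase decay course
#'
#' Generates replicate abundance measurements following first-order decay,
#' `A(t) = 2^(-t / half_life_hr)`, with multiplicative lognormal
#' measurement noise of mean 1 and coefficient of variation `noise_cv`
#' (t = 0 wells are noisy too, unless `noise_cv = 0`).
#'
#' @param half_life_hr true half-life in hours (> 0); alternatively give
#'   `preset`.
#' @param preset name of a [decay_presets()] entry.
#' @param timepoints_hr nondecreasing chase timepoints in hours, starting
#'   at 0.
#' @param n_replicates number of replicates.
#' @param noise_cv coefficient of variation of the lognormal noise (>= 0).
#' @param seed integer seed (the global RNG state is restored on exit).
#' @param condition condition label; defaults to the preset name.
#' @return a [decay_course] with attributes `half_life_true` and `seed`.
#' @examples
#' gen_decay_course(preset = "control", noise_cv = 0, seed = 1)
#' @export
gen_decay_course <- function(half_life_hr = NULL, preset = NULL,
                             timepoints_hr = c(0, 1, 2, 4, 8),
                             n_replicates = 3L, noise_cv = 0.05,
                             seed = NULL, condition = NULL) {
  if (!is.null(preset)) {
    presets <- decay_presets()
    if (!preset %in% names(presets)) {
      stop("unknown preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "))
    }
    half_life_hr <- half_life_hr %||% unname(presets[preset])
    condition <- condition %||% preset
  }
  condition <- condition %||% "sim"
  if (is.null(half_life_hr) || half_life_hr <= 0) {
    stop("half_life_hr must be a positive number of hours")
  }
  if (length(timepoints_hr) < 2L || timepoints_hr[1] != 0 ||
      is.unsorted(timepoints_hr)) {
    stop("timepoints_hr must be nondecreasing and start at 0")
  }
  if (n_replicates < 1L) stop("n_replicates must be at least 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (!is.null(seed)) withr::local_seed(as.integer(seed))

  tt <- rep(timepoints_hr, times = n_replicates)
  rr <- rep(paste0("rep", seq_len(n_replicates)), each = length(timepoints_hr))
  mu <- 2^(-tt / half_life_hr)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- stats::rlnorm(length(tt), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    ab <- mu * noise
  } else {
    ab <- mu
  }
  out <- decay_course(tt, ab, rr, condition)
  attr(out, "half_life_true") <- half_life_hr
  attr(out, "seed") <- seed
  out
}

#' Simulate paired differential-expression and RIP-enrichment gene tables
#'
#' Generates two tables over a shared gene universe in which a designated
#' subset of "true target" genes is simultaneously downregulated (log2 fold
#' change centred on `lfc_effect`, additive Gaussian noise) and
#' RIP-enriched (fold over input with geometric mean `enrich_effect`,
#' multiplicative lognormal noise so folds stay strictly positive).
#' Background genes are centred on log2FC 0 and fold 1. The true-target
#' list is recorded for recovery checks.
#'
#' @param n_genes total number of genes.
#' @param n_true_targets number of true targets (0 to `n_genes`).
#' @param lfc_effect mean log2 fold change of true targets (negative for
#'   downregulation).
#' @param lfc_noise_sd SD of additive Gaussian noise on log2 fold changes.
#' @param enrich_effect geometric-mean fold over input of true targets
#'   (> 1).
#' @param enrich_noise_sd SD of the natural-log fold enrichment (0 for
#'   noiseless tables).
#' @param seed integer seed (the global RNG state is restored on exit).
#' @return list with `diff_expr` (data.frame: `gene_id`, `log2fc`),
#'   `rip_enrich` (data.frame: `gene_id`, `fold_over_input`) and
#'   `true_targets` (character vector of planted target ids).
#' @export
gen_gene_tables <- function(n_genes, n_true_targets, lfc_effect = -1,
                            lfc_noise_sd = 0.2, enrich_effect = 8,
                            enrich_noise_sd = 0.3, seed = NULL) {
  n_genes <- as.integer(n_genes)
  n_true_targets <- as.integer(n_true_targets)
  if (n_true_targets < 0L || n_true_targets > n_genes) {
    stop("n_true_targets must be between 0 and n_genes")
  }
  if (enrich_effect <= 0) stop("enrich_effect must be positive")
  if (!is.null(seed)) withr::local_seed(as.integer(seed))

  ids <- sprintf("GENE_%05d", seq_len(n_genes))
  target_idx <- sort(sample.int(n_genes, n_true_targets))
  is_target <- seq_len(n_genes) %in% target_idx

  lfc <- ifelse(is_target, lfc_effect, 0) +
    if (lfc_noise_sd > 0) stats::rnorm(n_genes, 0, lfc_noise_sd) else 0
  log_fold <- log(ifelse(is_target, enrich_effect, 1)) +
    if (enrich_noise_sd > 0) stats::rnorm(n_genes, 0, enrich_noise_sd) else 0

  list(
    diff_expr = data.frame(gene_id = ids, log2fc = lfc,
                           stringsAsFactors = FALSE),
    rip_enrich = data.frame(gene_id = ids, fold_over_input = exp(log_fold),
                            stringsAsFactors = FALSE),
    true_targets = ids[is_target]
  )
}

#' Simulate a qPCR standard-curve dilution series
#'
#' Generates (log10 copies, Ct) pairs for a dilution series under the
#' amplification model `Ct = ct0 - log10(copies / ref_copies) /
#' log10(1 + efficiency) + noise`, where `efficiency` is the per-cycle
#' amplification efficiency (1 = perfect doubling).
#'
#' @param copies_per_dilution strictly positive template copy numbers.
#' @param efficiency amplification efficiency in (0, 1].
#' @param ct0 Ct at the reference copy number.
#' @param ref_copies reference copy number at which Ct equals `ct0`.
#' @param noise_sd SD of Gaussian Ct noise (cycles).
#' @param seed integer seed.
#' @return data.frame with columns `log10_copies` and `ct`.
#' @export
gen_standard_curve <- function(copies_per_dilution, efficiency = 1,
                               ct0 = 30, ref_copies = copies_per_dilution[1],
                               noise_sd = 0, seed = NULL) {
  if (any(copies_per_dilution <= 0)) stop("copy numbers must be strictly positive")
  if (efficiency <= 0 || efficiency > 1) stop("efficiency must be in (0, 1]")
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  ct <- ct0 - log10(copies_per_dilution / ref_copies) / log10(1 + efficiency)
  if (noise_sd > 0) ct <- ct + stats::rnorm(length(ct), 0, noise_sd)
  data.frame(log10_copies = log10(copies_per_dilution), ct = ct)
}
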