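test_that("planting at fraction 1 guarantees containment in every sequence", {
  peaks <- gen_peak_set(50, lengths = 50, planted_motif = "GGAG",
                        planted_fraction = 1.0, seed = 1)
  expect_length(peaks, 50L)
  expect_true(all(contains_motif(peaks, "GGAG")))
  expect_equal(attr(peaks, "planted_proportion"), 1.0)
})

test_that("forced all-G composition yields GGGG sequences containing GGR", {
  peaks <- gen_peak_set(10, lengths = 4, base_composition = c(0, 0, 1, 0),
                        seed = 2)
  expect_true(all(unclass(peaks) == "GGGG"))
  expect_true(all(contains_motif(peaks, "GGR")))
})

test_that("identical configs and seeds give byte-identical FASTA output", {
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(gen_peak_set(40, lengths = list(dist = "uniform", min = 30,
                                              max = 80),
                           planted_motif = "TGGAGNW",
                           planted_fraction = 0.3, seed = 31), f1)
  write_fasta(gen_peak_set(40, lengths = list(dist = "uniform", min = 30,
                                              max = 80),
                           planted_motif = "TGGAGNW",
                           planted_fraction = 0.3, seed = 31), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted count is exact and realised proportion is never smaller", {
  for (frac in c(0.25, 0.5, 0.8)) {
    peaks <- gen_peak_set(40, lengths = 60, planted_motif = "GGAG",
                          planted_fraction = frac, seed = 100 + frac * 100)
    expect_equal(attr(peaks, "planted_proportion"), round(frac * 40) / 40)
    expect_length(attr(peaks, "planted_ids"), round(frac * 40))
    expect_gte(attr(peaks, "realized_proportion"),
               attr(peaks, "planted_proportion"))
    expect_true(all(contains_motif(peaks[attr(peaks, "planted_ids")], "GGAG")))
  }
})

test_that("a planted motif longer than a sampled length is refused by name", {
  expect_error(gen_peak_set(10, lengths = c(3, 50), planted_motif = "TGGAGNW",
                            planted_fraction = 0.5, seed = 1),
               "length 3")
})

test_that("generator validates composition and fraction", {
  expect_error(gen_peak_set(5, base_composition = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(gen_peak_set(5, planted_motif = "GGAG", planted_fraction = 1.2),
               "planted_fraction")
})

test_that("length specs are honoured", {
  explicit <- gen_peak_set(3, lengths = c(10, 20, 30), seed = 4)
  expect_equal(unname(nchar(explicit)), c(10L, 20L, 30L))
  unif <- gen_peak_set(200, lengths = list(dist = "uniform", min = 40,
                                           max = 60), seed = 5)
  expect_true(all(nchar(unif) >= 40 & nchar(unif) <= 60))
  lnorm <- gen_peak_set(100, lengths = list(dist = "lognormal", meanlog = 4,
                                            sdlog = 0.3, min = 20), seed = 6)
  expect_true(all(nchar(lnorm) >= 20))
  expect_error(gen_peak_set(5, lengths = list(dist = "cauchy")), "unknown")
})

test_that("noiseless decay courses follow the closed form exactly", {
  c2 <- gen_decay_course(half_life_hr = 2, timepoints_hr = c(0, 2, 4),
                         n_replicates = 1, noise_cv = 0, seed = 1)
  expect_equal(c2$abundance, c(1, 0.5, 0.25))
  c5 <- gen_decay_course(half_life_hr = 5, timepoints_hr = c(0, 5),
                         n_replicates = 1, noise_cv = 0, seed = 1)
  expect_equal(c5$abundance[2], 0.5)
})

test_that("lognormal noise is unbiased: per-time means track the true curve", {
  # Monte-Carlo oracle: over 200 seeds, the grand mean at each timepoint
  # must sit within 3 standard errors of 2^(-t/5)
  tt <- c(0, 1, 2, 4, 8)
  per_seed_means <- t(vapply(1:200, function(s) {
    course <- gen_decay_course(half_life_hr = 5, noise_cv = 0.05,
                               n_replicates = 3, timepoints_hr = tt,
                               seed = 5000 + s)
    tapply(course$abundance, course$time_hr, mean)[as.character(tt)]
  }, numeric(length(tt))))
  truth <- 2^(-tt / 5)
  grand <- colMeans(per_seed_means)
  se <- apply(per_seed_means, 2, sd) / sqrt(200)
  expect_true(all(abs(grand - truth) <= 3 * se))
})

test_that("decay simulator validates its configuration", {
  expect_error(gen_decay_course(half_life_hr = -1), "positive")
  expect_error(gen_decay_course(half_life_hr = 5, noise_cv = -0.1), "noise_cv")
  expect_error(gen_decay_course(half_life_hr = 5,
                                timepoints_hr = c(1, 2)), "start at 0")
  expect_error(gen_decay_course(preset = "no_such"), "unknown preset")
})

test_that("decay presets encode the experimental half-lives", {
  p <- decay_presets()
  expect_equal(unname(p[c("control", "LAST_knockdown",
                          "LAST_overexpression", "utr5_reporter")]),
               c(5, 3, 9, 4))
})

test_that("gene-table generator is seeded and records its truth", {
  a <- gen_gene_tables(200, 20, seed = 1)
  b <- gen_gene_tables(200, 20, seed = 1)
  expect_identical(a, b)
  expect_length(a$true_targets, 20L)
  expect_true(all(a$true_targets %in% a$diff_expr$gene_id))
  expect_equal(a$diff_expr$gene_id, a$rip_enrich$gene_id)
  expect_true(all(a$rip_enrich$fold_over_input > 0))
  expect_error(gen_gene_tables(10, 11), "between 0 and n_genes")
})
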