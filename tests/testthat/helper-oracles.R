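# Independent oracles used across the suite. These deliberately avoid the
# package's own matching code paths.

.oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# Full literal expansion of a degenerate pattern (<= 4^L strings).
expand_motif <- function(pattern) {
  sets <- .oracle_iupac[strsplit(pattern, "")[[1]]]
  grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  do.call(paste0, grid)
}

# Containment by exhaustive fixed-string search over the expansion.
oracle_contains <- function(sequences, pattern) {
  literals <- expand_motif(pattern)
  hits <- rep(FALSE, length(sequences))
  for (lit in literals) {
    hits <- hits | grepl(lit, sequences, fixed = TRUE)
  }
  hits
}

# Transfer-matrix (KMP automaton) probability that an i.i.d. random string
# of length L contains the literal `pattern`.
dp_contain_prob <- function(pattern, L, probs = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  pat <- strsplit(pattern, "")[[1]]
  m <- length(pat)
  # automaton transition: from prefix-state s (0..m-1) on base b, the new
  # longest prefix of `pattern` that is a suffix of the text
  trans <- matrix(0L, nrow = m, ncol = 4)
  for (s in 0:(m - 1)) {
    for (b in seq_along(bases)) {
      k <- min(s + 1L, m)
      while (k > 0L) {
        cand <- c(if (s - k + 2L <= s) pat[seq.int(s - k + 2L, s)], bases[b])
        if (length(cand) == k && all(cand == pat[seq_len(k)])) break
        k <- k - 1L
      }
      trans[s + 1L, b] <- k
    }
  }
  state <- c(1, rep(0, m))  # probability over states 0..m (m = matched)
  for (i in seq_len(L)) {
    nxt <- rep(0, m + 1L)
    nxt[m + 1L] <- state[m + 1L]
    for (s in 0:(m - 1)) {
      for (b in 1:4) {
        nxt[trans[s + 1L, b] + 1L] <- nxt[trans[s + 1L, b] + 1L] +
          state[s + 1L] * probs[b]
      }
    }
    state <- nxt
  }
  state[m + 1L]
}

# Brute-force sliding-window G-rich qualification used to cross-check
# scan_g_rich: returns qualifying window start positions (1-based).
brute_grich_windows <- function(s, window, min_g_fraction, min_g_run) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < window) return(integer(0))
  ok <- logical(n - window + 1L)
  for (i in seq_len(n - window + 1L)) {
    win <- ch[i:(i + window - 1L)]
    gf <- mean(win == "G")
    runs <- rle(win)
    has_run <- any(runs$values == "G" & runs$lengths >= min_g_run)
    ok[i] <- gf >= min_g_fraction && has_run
  }
  which(ok)
}

# Profile-likelihood grid search for the decay constant: for each k the
# optimal intercept is closed-form, so the grid scans k only.
grid_search_k <- function(time_hr, abundance, k_grid = seq(1e-4, 2, by = 1e-4)) {
  y <- log(abundance)
  rss <- vapply(k_grid, function(k) {
    c0 <- mean(y + k * time_hr)
    sum((y - (c0 - k * time_hr))^2)
  }, numeric(1))
  k_grid[which.min(rss)]
}
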