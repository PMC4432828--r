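# Independent oracles: each recomputes a quantity by a route different from
# the implementation it checks.

# Two-sided Fisher p by explicit hypergeometric enumeration
# (minimum-likelihood method).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  N <- a + b + c + d
  lo <- max(0, r1 + c1 - N)
  hi <- min(r1, c1)
  x <- lo:hi
  probs <- dhyper(x, c1, N - c1, r1)
  pobs <- dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Yates-corrected chi-square by the textbook formula, correction floored.
oracle_yates <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum(pmax(abs(m - E) - 0.5, 0)^2 / E)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Closed-form simple linear regression.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- syy - slope * sxy
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- slope / se
  list(slope = slope, intercept = intercept,
       r_squared = if (syy > 0) sxy^2 / (sxx * syy) else 0,
       p_value = 2 * pt(-abs(tstat), n - 2))
}

# Welch two-sample t by hand.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tstat, p_value = 2 * pt(-abs(tstat), df))
}

# Paired t on log10 ratios by hand.
oracle_ratio_paired_t <- function(a, b) {
  d <- log10(a) - log10(b)
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(t = tstat, p_value = 2 * pt(-abs(tstat), n - 1))
}

# Sliding-window dinucleotide count.
oracle_dinuc <- function(sequence, pattern) {
  n <- nchar(sequence)
  if (n < 2) return(0L)
  windows <- substring(sequence, 1:(n - 1), 2:n)
  sum(windows == pattern)
}

# Independent semi-global alignment score: Biostrings pairwiseAlignment with
# the read global and the subject local ("global-local"), same scoring.
oracle_align_score <- function(read, consensus, match = 1, mismatch = -1,
                               gap_open = 2, gap_ext = 0.5) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(read),
    subject = Biostrings::DNAString(consensus),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext)
  Biostrings::score(pa)
}

# Brute-force all-pairs site-to-gene boundary distance (half-open intervals).
oracle_gene_distance <- function(pos, genes) {
  if (nrow(genes) == 0) return(NA_real_)
  d <- vapply(seq_len(nrow(genes)), function(i) {
    if (pos >= genes$start[i] && pos < genes$end[i]) return(0)
    if (pos < genes$start[i]) return(genes$start[i] - pos)
    pos - (genes$end[i] - 1)
  }, numeric(1))
  min(d)
}

random_dna <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}
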