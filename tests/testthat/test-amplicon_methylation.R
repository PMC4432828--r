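test_that("LINE-1 primers delimit the full 429 b consensus amplicon", {
  l1 <- consensus_amplicon("line1")
  def <- locate_amplicon(l1$primers, l1$consensus, bisulfite_space = TRUE)
  expect_equal(def$length, 429L)
  expect_equal(def$fwd_mismatches, 0L)
  expect_equal(def$rev_mismatches, 0L)
  # the printed consensus is in reverse-primer orientation
  expect_equal(def$orientation, "-")
})

test_that("Alu primers require bisulfite-space matching", {
  alu <- consensus_amplicon("alu")
  def <- locate_amplicon(alu$primers, alu$consensus, bisulfite_space = TRUE)
  expect_equal(def$orientation, "+")
  expect_equal(def$start, 0L)
  expect_equal(def$length, 219L)  # printed consensus is one base short of 220
  expect_equal(def$fwd_mismatches, 0L)
  expect_equal(def$rev_overhang, 1L)
  # literal matching cannot place the bisulfite-designed reverse primer
  expect_error(locate_amplicon(alu$primers, alu$consensus,
                               bisulfite_space = FALSE), "primer not found")
})

test_that("degenerate and scrambled primer cases behave as specified", {
  cons <- random_dna(80, seed = 90)
  full <- locate_amplicon(list(forward = cons,
                               reverse = bsmethr:::revcomp(cons)), cons)
  expect_equal(full$start, 0L)
  expect_equal(full$end, 80L)
  expect_error(
    locate_amplicon(list(forward = strrep("ACGTT", 5),
                         reverse = bsmethr:::revcomp(cons)), cons),
    "primer not found")
})

test_that("semi-global alignment handles identity and substrings", {
  cons <- random_dna(200, seed = 91)
  self <- semi_global_align(cons, cons)
  expect_equal(self$identity_percent, 100)
  expect_equal(self$gap_columns, 0L)
  expect_equal(self$score, 200)

  sub <- substr(cons, 51, 150)
  aln <- semi_global_align(sub, cons)
  expect_equal(aln$subject_start, 50L)
  expect_equal(aln$subject_end, 150L)
  expect_equal(aln$identity_percent, 100)
  expect_equal(aln$score, 100)
})

test_that("alignment scores match an independent implementation", {
  for (i in 1:20) {
    read <- random_dna(withr::with_seed(300 + i, sample(5:30, 1)),
                       seed = 400 + i)
    cons <- random_dna(withr::with_seed(500 + i, sample(10:30, 1)),
                       seed = 600 + i)
    expect_equal(semi_global_align(read, cons)$score,
                 oracle_align_score(read, cons),
                 tolerance = 1e-9)
  }
})

test_that("length filter keeps the boundary and counts duplicates", {
  reads <- data.frame(id = c("a", "b", "c"),
                      sequence = c(strrep("A", 99), strrep("C", 100),
                                   strrep("G", 101)),
                      stringsAsFactors = FALSE)
  f <- filter_and_dedup(reads, 100)
  expect_equal(nrow(f$reads), 2L)
  expect_equal(f$n_too_short, 1L)
  expect_equal(f$reads$id, c("b", "c"))

  dup <- filter_and_dedup(data.frame(id = c("a", "b"),
                                     sequence = rep("ACGTACGT", 2),
                                     stringsAsFactors = FALSE), 2)
  expect_equal(f2 <- dup$n_exact_duplicates, 1L)
  expect_equal(dup$reads$id, "a")

  empty <- filter_and_dedup(data.frame(id = character(),
                                       sequence = character()), 100)
  expect_equal(nrow(empty$reads), 0L)
  expect_equal(empty$n_too_short, 0L)
})

test_that("per-read dinucleotide frequencies use overlapping windows", {
  rows <- per_read_dinucleotide(data.frame(id = c("a", "b"),
                                           sequence = c("ACGCGT", "TGTGTG"),
                                           stringsAsFactors = FALSE))
  expect_equal(rows$n_cg, c(2L, 0L))
  expect_equal(rows$cg_pct[1], 40)
  expect_equal(rows$n_tg[2], 3L)
  expect_equal(rows$tg_pct[2], 60)
  expect_equal(rows$cg_pct_of_cgtg[1], 100)

  expect_error(per_read_dinucleotide(
    data.frame(id = "x", sequence = "A")), "shorter than 2")

  seqs <- vapply(1:100, function(i) random_dna(200, seed = 700 + i),
                 character(1))
  rows2 <- per_read_dinucleotide(data.frame(id = as.character(1:100),
                                            sequence = seqs,
                                            stringsAsFactors = FALSE))
  expect_equal(rows2$n_cg,
               vapply(seqs, oracle_dinuc, integer(1) * 1L, pattern = "CG",
                      USE.NAMES = FALSE))
  expect_equal(rows2$n_tg,
               vapply(seqs, oracle_dinuc, integer(1) * 1L, pattern = "TG",
                      USE.NAMES = FALSE))
})

test_that("distribution summaries normalize to unit mass", {
  h <- distribution_summary(c(5, 5, 15), bin_width = 10, origin = 0)
  expect_equal(h$share, c(2 / 3, 1 / 3))

  single <- distribution_summary(7)
  expect_equal(sum(single$share), 1)
  expect_equal(nrow(single), 1L)

  vals <- withr::with_seed(92, runif(500, 0, 30))
  expect_equal(sum(distribution_summary(vals, 2.5)$share), 1,
               tolerance = 1e-9)
  expect_error(distribution_summary(numeric(0)), "empty")
})

test_that("tail-shift test reproduces the goodness-of-fit arithmetic", {
  ctl <- c(rep(5, 50), rep(10, 900), rep(15, 50))
  matched <- c(rep(5, 5), rep(10, 90), rep(15, 5))
  same <- tail_shift_test(ctl, matched, c(low = 8, high = 12))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  trt <- c(rep(5, 150), rep(10, 700), rep(15, 150))
  res <- tail_shift_test(ctl, trt, c(low = 8, high = 12))
  expect_equal(res$statistic, 100^2 / 50 + 200^2 / 900 + 100^2 / 50,
               tolerance = 1e-9)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$expected, c(50, 900, 50))

  expect_error(tail_shift_test(rep(10, 100), trt, c(low = 8, high = 12)),
               "zero count")

  split <- tail_shift_test(ctl, trt, c(split = 7.5))
  expect_equal(length(split$observed), 2L)

  perm <- tail_shift_test(ctl, withr::with_seed(93, sample(trt)),
                          c(low = 8, high = 12))
  expect_identical(perm$p_value, res$p_value)
})

test_that("mixture fitting forces k = 1 on tiny or degenerate input", {
  small <- fit_methylation_mixture(withr::with_seed(94, rnorm(10, 5)))
  expect_equal(small$k_selected, 1L)

  expect_warning(flat <- fit_methylation_mixture(rep(4, 50)),
                 "zero-variance")
  expect_equal(flat$k_selected, 1L)
  expect_gt(flat$components$sd, 0)
})

test_that("mixture selection separates unimodal from bimodal draws", {
  uni <- fit_methylation_mixture(withr::with_seed(95, rnorm(500, 10, 1)),
                                 seed = 1)
  expect_equal(uni$k_selected, 1L)

  bi <- fit_methylation_mixture(
    withr::with_seed(96, c(rnorm(250, 5, 1), rnorm(250, 15, 1))), seed = 1)
  expect_equal(bi$k_selected, 2L)
  expect_equal(bi$components$mean, c(5, 15), tolerance = 0.5)

  # AICc variant stays available for continuous-valued data
  bi2 <- fit_methylation_mixture(
    withr::with_seed(97, c(rnorm(250, 5, 1), rnorm(250, 15, 1))),
    seed = 1, selection = "aicc")
  expect_equal(bi2$k_selected, 2L)
})

test_that("generator mixtures drive the end-to-end mixture verdict", {
  alu <- consensus_amplicon("alu")
  bim <- simulate_amplicon_reads(alu, weights = c(0.5, 0.5),
                                 levels = c(0.2, 0.9),
                                 dispersion = c(80, 80), n_molecules = 2000,
                                 seed = 98)
  pr <- per_read_dinucleotide(filter_and_dedup(bim$reads, 100)$reads)
  fit <- fit_methylation_mixture(pr$cg_pct, seed = 1)
  expect_equal(fit$k_selected, 2L)

  uni <- simulate_amplicon_reads(alu, weights = 1, levels = 0.65,
                                 dispersion = 50, n_molecules = 1500,
                                 seed = 99)
  pru <- per_read_dinucleotide(filter_and_dedup(uni$reads, 100)$reads)
  expect_equal(fit_methylation_mixture(pru$cg_pct, seed = 1)$k_selected, 1L)
})

test_that("CpG-TpG correlation is exact on a line and negative on reads", {
  rows <- data.frame(cg_pct = c(1, 2, 3, 4), tg_pct = c(9, 8, 7, 6))
  res <- cg_tg_correlation(rows)
  expect_equal(res$slope, -1, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)

  expect_error(cg_tg_correlation(data.frame(cg_pct = rep(1, 5),
                                            tg_pct = 1:5)), "constant")

  alu <- consensus_amplicon("alu")
  slopes <- vapply(1:5, function(s) {
    sim <- simulate_amplicon_reads(alu, weights = 1, levels = 0.5,
                                   dispersion = 3, n_molecules = 400,
                                   seed = 800 + s)
    pr <- per_read_dinucleotide(filter_and_dedup(sim$reads, 100)$reads)
    res <- cg_tg_correlation(pr)
    expect_lt(res$p_value, 0.01)
    res$slope
  }, numeric(1))
  expect_true(all(slopes < 0))
})

test_that("mean methylation comparison detects a level shift in both metrics", {
  rows <- data.frame(cg_pct = c(1, 2, 3), tg_pct = c(3, 2, 1))
  same <- compare_mean_methylation(rows, rows)
  expect_equal(same$t, c(0, 0))
  expect_equal(same$p_value, c(1, 1))
  expect_error(compare_mean_methylation(rows[1, ], rows), "n >= 2")

  alu <- consensus_amplicon("alu")
  lo <- simulate_amplicon_reads(alu, weights = 1, levels = 0.7,
                                dispersion = 60, n_molecules = 500,
                                seed = 101)
  hi <- simulate_amplicon_reads(alu, weights = 1, levels = 0.9,
                                dispersion = 60, n_molecules = 500,
                                seed = 102)
  pr_lo <- per_read_dinucleotide(filter_and_dedup(lo$reads, 100)$reads)
  pr_hi <- per_read_dinucleotide(filter_and_dedup(hi$reads, 100)$reads)
  cmp <- compare_mean_methylation(pr_lo, pr_hi)
  cg <- cmp[cmp$metric == "cg_pct", ]
  tg <- cmp[cmp$metric == "tg_pct", ]
  expect_lt(cg$p_value, 0.001)
  expect_gt(cg$mean_treated, cg$mean_control)
  expect_lt(tg$mean_treated, tg$mean_control)

  hand_a <- data.frame(cg_pct = c(1, 2, 4), tg_pct = c(1, 1, 2))
  hand_b <- data.frame(cg_pct = c(2, 5, 6), tg_pct = c(2, 3, 1))
  cmp2 <- compare_mean_methylation(hand_a, hand_b)
  orc <- oracle_welch(hand_a$cg_pct, hand_b$cg_pct)
  expect_equal(cmp2$t[1], orc$t, tolerance = 1e-10)
  expect_equal(cmp2$p_value[1], orc$p_value, tolerance = 1e-10)
})
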