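test_that("reference generation is seed-deterministic and respects composition", {
  a <- generate_reference(10, seed = 42)
  b <- generate_reference(10, seed = 42)
  expect_identical(a$sequence, b$sequence)
  expect_error(generate_reference(0), ">= 1")

  at_only <- generate_reference(500, gc_fraction = 0, seed = 1)
  expect_false(grepl("[CG]", at_only$sequence))
})

test_that("CpG rate matches the binomial baseline at cpg_factor 1", {
  ref <- generate_reference(100000, gc_fraction = 0.5, cpg_factor = 1, seed = 3)
  n_cpg <- oracle_dinuc(ref$sequence, "CG")
  n_win <- nchar(ref$sequence) - 1
  expect_lt(abs(n_cpg - n_win / 16), 3 * sqrt(n_win * (1 / 16) * (15 / 16)))
})

test_that("cytosine contexts follow the three-base rule on both strands", {
  ctx <- bsmethr:::cytosine_contexts("CCGTAG")
  # plus: pos0 C (next C, then G) -> CHG; pos1 C (next G) -> CpG
  plus <- ctx[ctx$strand == "+", ]
  expect_equal(plus$pos, c(0L, 1L))
  expect_equal(plus$context, c("CHG", "CpG"))
  # minus: pos2 G preceded by C -> CpG; pos5 G (prev A, prev2 T) -> CHH
  minus <- ctx[ctx$strand == "-", ]
  expect_equal(minus$pos, c(2L, 5L))
  expect_equal(minus$context, c("CpG", "CHH"))
})

test_that("methylome assignment honours boundary probabilities and overrides", {
  ref <- generate_reference(2000, seed = 5)
  all_on <- assign_methylome(ref, p_cpg = 1, p_chg = 0, p_chh = 0, seed = 1)
  cpg <- all_on[all_on$context == "CpG", ]
  expect_true(all(cpg$methylated))
  expect_false(any(all_on$methylated[all_on$context != "CpG"]))

  none <- assign_methylome(ref, 0, 0, 0, seed = 1)
  expect_false(any(none$methylated))

  pos0 <- cpg$pos[1]
  ov <- assign_methylome(ref, 1, 0, 0,
                         site_overrides = setNames(0, pos0), seed = 1)
  expect_false(any(ov$methylated[ov$pos == pos0]))
  expect_error(
    assign_methylome("AAAA", 1, site_overrides = setNames(1, 2)),
    "non-cytosine")
})

test_that("methylated CpG fraction matches the binomial oracle at p = 0.8", {
  ref <- generate_reference(10000, seed = 6)
  me <- assign_methylome(ref, p_cpg = 0.8, seed = 7)
  cpg <- me[me$context == "CpG", ]
  n <- nrow(cpg)
  expect_gt(n, 500)
  expect_lt(abs(mean(cpg$methylated) - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("bisulfite conversion touches only cytosines, C to T only", {
  st <- data.frame(pos = 1L, context = "CpG", methylated = FALSE)
  expect_equal(bisulfite_convert("ACGT", st, under_conversion = 0)$sequence,
               "ATGT")
  st$methylated <- TRUE
  expect_equal(bisulfite_convert("ACGT", st, over_conversion = 0)$sequence,
               "ACGT")
  st$methylated <- FALSE
  expect_equal(bisulfite_convert("ACGT", st, under_conversion = 1)$sequence,
               "ACGT")
  expect_error(bisulfite_convert("ACGT", st[0, ], 0.05),
               "no methylation state")

  ref <- generate_reference(5000, seed = 8)
  me <- assign_methylome(ref, 0.5, 0.1, 0.1, seed = 9)
  conv <- convert_both_strands(ref, me, 0.05, 0.01, seed = 10)
  from <- bsmethr:::seq_chars(ref$sequence)
  to <- bsmethr:::seq_chars(conv$plus)
  changed <- which(from != to)
  expect_true(all(from[changed] == "C"))
  expect_true(all(to[changed] == "T"))
  # A and G counts on the converted strand are unchanged
  expect_equal(sum(to == "A"), sum(from == "A"))
  expect_equal(sum(to == "G"), sum(from == "G"))
})

test_that("retained fraction at unmethylated cytosines estimates u", {
  ref <- generate_reference(50000, gc_fraction = 0.5, seed = 11)
  me <- assign_methylome(ref, 0, 0, 0, seed = 12)
  conv <- convert_both_strands(ref, me, under_conversion = 0.2, seed = 13)
  ev <- conv$events
  n <- nrow(ev)
  expect_gt(n, 10000)
  retained <- mean(!ev$converted)
  expect_lt(abs(retained - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("genomic read simulation is self-consistent with its truth sidecar", {
  ref <- generate_reference(10000, seed = 14)
  me <- assign_methylome(ref, 0.7, seed = 15)
  conv <- convert_both_strands(ref, me, 0.05, seed = 16)

  empty <- simulate_genomic_reads(conv, 0, 100, seed = 17)
  expect_equal(nrow(empty$reads), 0L)
  expect_equal(nrow(empty$truth), 0L)
  expect_error(simulate_genomic_reads(conv, 10, 10001), "exceeds")

  sim <- simulate_genomic_reads(conv, 1000, 80, seed = 18)
  L <- conv$length
  for (i in seq_len(nrow(sim$reads))) {
    tr <- sim$truth[i, ]
    expected <- if (tr$strand == "+") {
      substr(conv$plus, tr$start + 1, tr$end)
    } else {
      substr(conv$minus, L - tr$end + 1, L - tr$start)
    }
    if (sim$reads$sequence[i] != expected) {
      fail(sprintf("read %d does not match its truth slice", i))
    }
  }
  succeed()
})

test_that("read start positions are uniform (chi-square, 20 bins)", {
  ref <- generate_reference(10000, seed = 19)
  me <- assign_methylome(ref, 0, seed = 20)
  conv <- convert_both_strands(ref, me, 0.05, seed = 21)
  sim <- simulate_genomic_reads(conv, 50000, 50, seed = 22)
  n_pos <- conv$length - 50 + 1
  bin <- cut(sim$truth$start, breaks = seq(0, n_pos, length.out = 21),
             include.lowest = TRUE, right = FALSE)
  p <- chisq.test(table(bin))$p.value
  expect_gt(p, 0.01)
})

test_that("paired mode emits mate pairs with a revcomp-oriented mate 2", {
  ref <- generate_reference(5000, seed = 23)
  me <- assign_methylome(ref, 0.7, seed = 24)
  conv <- convert_both_strands(ref, me, 0.05, seed = 25)
  sim <- simulate_genomic_reads(conv, 200, 60, paired = TRUE, seed = 26)
  expect_equal(nrow(sim$reads), 400L)
  m2 <- sim$truth$mate == 2
  expect_true(all(sim$truth$orient[m2] == "revcomp"))
  L <- conv$length
  i <- which(m2)[1]
  tr <- sim$truth[i, ]
  slice <- if (tr$strand == "+") {
    substr(conv$plus, tr$start + 1, tr$end)
  } else {
    substr(conv$minus, L - tr$end + 1, L - tr$start)
  }
  expect_equal(bsmethr:::revcomp(sim$reads$sequence[i]), slice)
})

test_that("molecule-resolved reads realise per-site intermediate methylation", {
  ref <- generate_reference(8000, seed = 27)
  sim <- simulate_methylome_reads(ref, p_cpg = 0.6, under_conversion = 0.05,
                                  n_reads = 6000, read_len = 100, seed = 28)
  sim2 <- simulate_methylome_reads(ref, p_cpg = 0.6, under_conversion = 0.05,
                                   n_reads = 6000, read_len = 100, seed = 28)
  expect_identical(sim$reads$sequence, sim2$reads$sequence)

  # reads differ from the reference slice only by C -> T
  L <- nchar(ref$sequence)
  minus <- bsmethr:::revcomp(ref$sequence)
  for (i in head(seq_len(nrow(sim$reads)), 50)) {
    tr <- sim$truth[i, ]
    tmpl <- if (tr$strand == "+") {
      substr(ref$sequence, tr$start + 1, tr$end)
    } else {
      substr(minus, L - tr$end + 1, L - tr$start)
    }
    a <- bsmethr:::seq_chars(tmpl)
    b <- bsmethr:::seq_chars(sim$reads$sequence[i])
    ch <- a != b
    expect_true(all(a[ch] == "C" & b[ch] == "T"))
  }

  # per-site percentages are intermediate, centred on 100 * (p + (1-p) u)
  calls <- call_sites(sim$reads, sim$truth, ref, context_filter = "CpG")
  deep <- calls[calls$n_meth + calls$n_unmeth >= 10, ]
  expect_gt(nrow(deep), 200)
  expect_gt(mean(deep$methylation_percent > 5 &
                   deep$methylation_percent < 95), 0.5)
  expect_lt(abs(mean(calls$methylation_percent) - 100 * (0.6 + 0.4 * 0.05)),
            1.5)

  expect_equal(nrow(simulate_methylome_reads(ref, 0.5, n_reads = 0,
                                             read_len = 50)$reads), 0L)
  expect_error(simulate_methylome_reads(ref, 0.5, n_reads = 5,
                                        read_len = 9000), "exceeds")
  expect_error(simulate_methylome_reads("AAAA", 0.5,
                                        site_overrides = setNames(1, 0),
                                        n_reads = 2, read_len = 2),
               "non-cytosine")
})

test_that("amplicon simulation respects boundary methylation levels", {
  alu <- consensus_amplicon("alu")
  n_cpg <- length(simulate_amplicon_reads(alu, n_molecules = 1,
                                          seed = 1)$cpg_positions)
  expect_gt(n_cpg, 0)

  full <- simulate_amplicon_reads(alu, weights = 1, levels = 1,
                                  dispersion = 50, over_conversion = 0,
                                  n_molecules = 50, p_full_length = 1,
                                  seed = 2)
  pr <- per_read_dinucleotide(full$reads)
  expect_true(all(pr$n_cg == n_cpg))

  none <- simulate_amplicon_reads(alu, weights = 1, levels = 0,
                                  dispersion = 50, under_conversion = 0,
                                  n_molecules = 50, p_full_length = 1,
                                  seed = 3)
  pr0 <- per_read_dinucleotide(none$reads)
  expect_true(all(pr0$n_cg == 0))
  native_tg <- oracle_dinuc(none$template, "TG")
  expect_true(all(pr0$n_tg == n_cpg + native_tg))
})

test_that("CG + TG at full length is conserved across methylation levels", {
  alu <- consensus_amplicon("alu")
  n_cpg <- length(simulate_amplicon_reads(alu, n_molecules = 1,
                                          seed = 1)$cpg_positions)
  sim <- simulate_amplicon_reads(alu, weights = c(0.5, 0.5),
                                 levels = c(0.2, 0.9),
                                 dispersion = c(50, 50),
                                 under_conversion = 0.07,
                                 n_molecules = 300, p_full_length = 1,
                                 seed = 4)
  pr <- per_read_dinucleotide(sim$reads)
  native_tg <- oracle_dinuc(sim$template, "TG")
  expect_true(all(pr$n_cg + pr$n_tg == n_cpg + native_tg))
})

test_that("per-read CG percentage increases with the true methylation level", {
  alu <- consensus_amplicon("alu")
  sim <- simulate_amplicon_reads(alu, weights = 1, levels = 0.5,
                                 dispersion = 5, n_molecules = 500,
                                 p_full_length = 1, seed = 5)
  pr <- per_read_dinucleotide(sim$reads)
  ct <- cor.test(pr$cg_pct, sim$truth$level[match(pr$read_id,
                                                  sim$truth$read_id)],
                 method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("synthetic genes are non-overlapping and inside the genome", {
  genes <- generate_genes(30, 100000, seed = 30)
  expect_true(all(genes$start >= 0 & genes$end <= 100000))
  expect_true(all(diff(genes$start) > 0))
  expect_true(all(genes$start[-1] > genes$end[-nrow(genes)]))
})
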