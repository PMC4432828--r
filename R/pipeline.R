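#' Default run configuration
#'
#' One configuration drives both the genome-scale and the amplicon pipelines.
#' Defaults encode the study conditions: 5% bisulfite conversion error
#' calibrated on an unmethylated spike-in, per-site Fisher testing at
#' alpha = 0.01, a 100-base minimum amplicon read length, a 5 kb gene-distance
#' dichotomy and 100-base flank radius. The synthetic amplicon tail
#' thresholds are matched to the CpG density of the shipped consensus
#' amplicons (see the methods vignette); the treated Alu arm is a
#' two-component mixture (bidirectional change), the LINE-1 arms a mean
#' shift.
#'
#' @return Nested list of class `bs_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    qc = list(
      spike_in_length = 20000L, n_reads = 10000L, read_len = 100L,
      under_conversion = 0.05, min_efficiency_percent = 95
    ),
    global = list(
      reference_length = 50000L, gc_fraction = 0.42, cpg_factor = 1.0,
      p_cpg = list(control = 0.75, treated = 0.85),
      p_chg = 0.005, p_chh = 0.005,
      under_conversion = 0.05, over_conversion = 0,
      n_reads = 20000L, read_len = 100L,
      alpha = 0.01, conversion_error = 0.05,
      gene_count = 12L, gene_mean_len = 2000L,
      annotation_distance = 5000L, flank_radius = 100L,
      bin_width = 10L
    ),
    amplicon = list(
      under_conversion = 0.05, over_conversion = 0,
      min_len = 100L, n_molecules = 1500L,
      p_full_length = 0.7, min_observed_len = 60L,
      alu = list(
        control = list(weights = 1, levels = 0.65, dispersion = 50),
        treated = list(weights = c(0.3, 0.7), levels = c(0.35, 0.9),
                       dispersion = c(80, 80)),
        tails = c(low = 3.0, high = 6.5)
      ),
      line1 = list(
        control = list(weights = 1, levels = 0.45, dispersion = 60),
        treated = list(weights = 1, levels = 0.75, dispersion = 60),
        tails = c(split = 1.5)
      )
    )
  ), class = "bs_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `bs_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), cfg)
  # yaml flattens named vectors to lists; restore tail threshold vectors
  for (amp in c("alu", "line1")) {
    cfg$amplicon[[amp]]$tails <- unlist(cfg$amplicon[[amp]]$tails)
  }
  cfg <- structure(cfg, class = "bs_config")
  validate_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param config A `bs_config` list.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  # YAML drops names from atomic vectors; store threshold vectors as maps
  for (amp in c("alu", "line1")) {
    cfg$amplicon[[amp]]$tails <- as.list(cfg$amplicon[[amp]]$tails)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks threshold ranges and mixture validity before any computation.
#'
#' @param config A `bs_config` list.
#' @return `config`, invisibly; errors on the first violated constraint.
#' @export
validate_config <- function(config) {
  chk <- function(cond, msg) if (!cond) stop("config error: ", msg, call. = FALSE)
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed must be one integer")
  q <- config$qc
  chk(q$under_conversion >= 0 && q$under_conversion <= 1,
      "qc.under_conversion must be in [0,1]")
  chk(q$min_efficiency_percent >= 0 && q$min_efficiency_percent <= 100,
      "qc.min_efficiency_percent must be in [0,100]")
  g <- config$global
  for (arm in c("control", "treated")) {
    chk(g$p_cpg[[arm]] >= 0 && g$p_cpg[[arm]] <= 1,
        paste0("global.p_cpg.", arm, " must be in [0,1]"))
  }
  chk(g$alpha > 0 && g$alpha < 1, "global.alpha must be in (0,1)")
  chk(g$conversion_error >= 0 && g$conversion_error <= 1,
      "global.conversion_error must be in [0,1]")
  chk(g$read_len <= g$reference_length, "global.read_len exceeds reference")
  a <- config$amplicon
  chk(a$min_len >= 1, "amplicon.min_len must be >= 1")
  for (amp in c("alu", "line1")) {
    for (arm in c("control", "treated")) {
      m <- a[[amp]][[arm]]
      chk(abs(sum(m$weights) - 1) < 1e-9,
          paste0("amplicon.", amp, ".", arm, " weights must sum to 1"))
      chk(all(m$levels >= 0 & m$levels <= 1),
          paste0("amplicon.", amp, ".", arm, " levels must be in [0,1]"))
    }
  }
  invisible(config)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  writeLines(msg, con)
}

#' Run the genome-scale methylation pipeline on synthetic data
#'
#' Simulates two sample arms (control/treated methylomes over one shared
#' reference), an unmethylated spike-in for conversion QC, and executes the
#' full genome-scale analysis: conversion-efficiency estimation, per-site
#' calls, C-count summaries, methylation-bin profiles, differential sites
#' with the conversion-error reality screen, gene annotation and flank
#' extraction. All stage outputs are written as TSV/FASTA plus a JSON run
#' summary and a plain-text log; the run is deterministic for a fixed
#' `config$seed`.
#'
#' @param config A `bs_config` list (see [default_config()]).
#' @param outdir Output directory (created; must be empty or absent).
#' @return The run summary list, invisibly.
#' @export
run_global <- function(config = default_config(), outdir) {
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(log_con))
  g <- config$global
  seeds <- derive_seeds(config$seed, 12L)
  log_line(log_con, "run_global start; seed=", config$seed)

  # spike-in conversion QC (one per arm; fully unmethylated molecules)
  spike <- generate_reference(config$qc$spike_in_length, 0.5, 1,
                              seed = seeds[1], id = "spike_in")
  qc_rows <- list()
  qc_pass <- TRUE
  for (i in seq_along(c("control", "treated"))) {
    arm <- c("control", "treated")[i]
    sim <- simulate_methylome_reads(
      spike, p_cpg = 0, p_chg = 0, p_chh = 0,
      under_conversion = config$qc$under_conversion,
      n_reads = config$qc$n_reads, read_len = config$qc$read_len,
      seed = seeds[2] + i)
    est <- estimate_under_conversion(sim$reads, sim$truth, spike)
    v <- qc_verdict(est, config$qc$min_efficiency_percent, sample = arm)
    qc_rows[[arm]] <- v$report
    qc_pass <- qc_pass && v$pass
    log_line(log_con, "QC ", arm, ": efficiency ",
             sprintf("%.2f%%", est$efficiency_percent), " (", v$report$verdict, ")")
  }
  qc_report <- do.call(rbind, qc_rows)
  write_tsv(qc_report, file.path(outdir, "conversion_qc.tsv"))

  # shared reference, per-arm methylomes
  ref <- generate_reference(g$reference_length, g$gc_fraction, g$cpg_factor,
                            seed = seeds[3], id = "chrS")
  genes <- generate_genes(g$gene_count, g$reference_length, g$gene_mean_len,
                          chrom = "chrS", seed = seeds[4])
  write_intervals(genes, file.path(outdir, "genes.bed"))
  calls <- list()
  total_bases <- list()
  for (i in 1:2) {
    arm <- c("control", "treated")[i]
    sim <- simulate_methylome_reads(
      ref, p_cpg = g$p_cpg[[arm]], p_chg = g$p_chg, p_chh = g$p_chh,
      under_conversion = g$under_conversion,
      over_conversion = g$over_conversion,
      n_reads = g$n_reads, read_len = g$read_len, seed = seeds[9] + i)
    calls[[arm]] <- call_sites(sim$reads, sim$truth, ref)
    total_bases[[arm]] <- sum(nchar(sim$reads$sequence))
    write_tsv(as.data.frame(calls[[arm]]),
              file.path(outdir, paste0("site_calls_", arm, ".tsv")))
    log_line(log_con, "arm ", arm, ": ", nrow(calls[[arm]]), " sites called")
  }

  summaries <- lapply(c("control", "treated"), function(arm) {
    s <- c_count_summary(calls[[arm]], total_bases[[arm]])
    data.frame(sample = arm, meth_c_percent = s$meth_c_percent,
               unmeth_c_percent = s$unmeth_c_percent,
               meth_unmeth_ratio = s$ratio, flag = s$flag,
               stringsAsFactors = FALSE)
  })
  c_counts <- do.call(rbind, summaries)
  write_tsv(c_counts, file.path(outdir, "c_count_summary.tsv"))

  profiles <- lapply(c("control", "treated"), function(arm) {
    p <- methylation_bin_profile(
      calls[[arm]][calls[[arm]]$context == "CpG", ], g$bin_width)
    p$sample <- arm
    p
  })
  write_tsv(do.call(rbind, profiles), file.path(outdir, "bin_profiles.tsv"))

  diff <- suppressWarnings(differential_sites(
    calls$control, calls$treated, alpha = g$alpha,
    conversion_error = g$conversion_error))
  write_tsv(diff, file.path(outdir, "differential_sites.tsv"))
  flagged <- diff[diff$flagged, , drop = FALSE]
  log_line(log_con, nrow(flagged), " differential site(s) of ",
           sum(diff$tested), " tested")

  ann <- suppressWarnings(
    annotate_sites(flagged, genes, g$annotation_distance))
  write_tsv(ann, file.path(outdir, "differential_sites_annotated.tsv"))
  if (nrow(flagged)) {
    flanks <- extract_flanks(flagged, ref, g$flank_radius)
    write_sequences(
      data.frame(id = sprintf("flank_%s_%d", flanks$chrom, flanks$site_pos),
                 sequence = flanks$sequence, stringsAsFactors = FALSE),
      file.path(outdir, "flanks.fasta"), "FASTA")
  }

  summary <- list(
    pipeline = "global", seed = config$seed,
    parameters = g[c("alpha", "conversion_error", "annotation_distance",
                     "flank_radius", "bin_width", "under_conversion",
                     "p_cpg")],
    qc = list(pass = qc_pass,
              efficiency_percent = setNames(qc_report$efficiency_percent,
                                            qc_report$sample)),
    n_sites = vapply(calls, nrow, integer(1)),
    c_count_ratio = setNames(c_counts$meth_unmeth_ratio, c_counts$sample),
    n_tested = sum(diff$tested), n_flagged = nrow(flagged),
    intergenic_fraction = if (nrow(ann)) mean(ann$label2 == "intergenic")
      else NA_real_
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(log_con, "run_global done")
  invisible(summary)
}

#' Run the repeat-amplicon methylation pipeline on synthetic data
#'
#' For each shipped consensus amplicon (Alu, LINE-1) and each sample arm,
#' simulates amplicon molecules from the configured methylation-level
#' mixture, filters and deduplicates reads, computes per-read CpG/TpG
#' frequencies, histograms, tail-shift chi-square tests, one- versus
#' two-component mixture fits, CpG-TpG correlations and mean-methylation
#' comparisons, writing TSV tables and a JSON summary.
#'
#' @inheritParams run_global
#' @return The run summary list, invisibly.
#' @export
run_amplicon <- function(config = default_config(), outdir) {
  validate_config(config)
  if (config$amplicon$n_molecules < 1) {
    stop("config error: amplicon.n_molecules must be >= 1", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(log_con))
  a <- config$amplicon
  seeds <- derive_seeds(config$seed + 1L, 8L)
  summary <- list(pipeline = "amplicon", seed = config$seed,
                  parameters = a[c("min_len", "under_conversion",
                                   "n_molecules")])
  si <- 0L
  for (amp in c("alu", "line1")) {
    amp_def <- consensus_amplicon(amp)
    rows <- list()
    filt_stats <- list()
    for (arm in c("control", "treated")) {
      si <- si + 1L
      mix <- a[[amp]][[arm]]
      sim <- simulate_amplicon_reads(
        amp_def, weights = mix$weights, levels = mix$levels,
        dispersion = mix$dispersion,
        under_conversion = a$under_conversion,
        over_conversion = a$over_conversion,
        n_molecules = a$n_molecules, p_full_length = a$p_full_length,
        min_observed_len = a$min_observed_len, seed = seeds[si])
      filt <- filter_and_dedup(sim$reads, a$min_len)
      filt_stats[[arm]] <- c(n_too_short = filt$n_too_short,
                             n_exact_duplicates = filt$n_exact_duplicates)
      pr <- per_read_dinucleotide(filt$reads)
      pr$sample <- arm
      rows[[arm]] <- pr
      write_tsv(pr, file.path(outdir, sprintf("per_read_%s_%s.tsv", amp, arm)))
      hist <- distribution_summary(pr$cg_pct, bin_width = 0.5, origin = 0)
      hist$sample <- arm
      write_tsv(hist, file.path(outdir, sprintf("hist_%s_%s.tsv", amp, arm)))
      log_line(log_con, amp, "/", arm, ": ", nrow(pr), " reads kept (",
               filt$n_too_short, " too short, ", filt$n_exact_duplicates,
               " duplicates)")
    }
    tails <- a[[amp]]$tails
    shift <- tail_shift_test(rows$control$cg_pct, rows$treated$cg_pct, tails)
    fits <- lapply(rows, function(r) {
      fit_methylation_mixture(r$cg_pct, seed = seeds[si])
    })
    cors <- lapply(rows, cg_tg_correlation)
    means <- compare_mean_methylation(rows$control, rows$treated)
    write_tsv(means, file.path(outdir, sprintf("mean_comparison_%s.tsv", amp)))
    summary[[amp]] <- list(
      tails = as.list(tails),
      filter = filt_stats,
      tail_shift = list(observed = shift$observed,
                        expected = shift$expected,
                        statistic = shift$statistic, p_value = shift$p_value),
      k_selected = lapply(fits, function(f) f$k_selected),
      mixture_components = lapply(fits, function(f) f$components),
      correlation = lapply(cors, function(cr) {
        list(slope = cr$slope, r_squared = cr$r_squared,
             p_value = cr$p_value, sign = ifelse(cr$slope < 0,
                                                 "negative", "non-negative"))
      }),
      mean_comparison = means
    )
    log_line(log_con, amp, ": tail-shift p = ",
             format(shift$p_value, digits = 3), "; k = ",
             fits$control$k_selected, " (control), ",
             fits$treated$k_selected, " (treated)")
  }
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(log_con, "run_amplicon done")
  invisible(summary)
}
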