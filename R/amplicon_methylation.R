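#' Locate a primer-delimited amplicon on a consensus sequence
#'
#' Finds the forward primer on one strand of the consensus and the reverse
#' primer (as its reverse complement) downstream; the amplicon spans from the
#' forward-primer start to the end of the reverse-primer site. Both
#' orientations of the consensus are searched, since repeat consensus
#' amplicons are sometimes written in the reverse-primer orientation; the
#' orientation with fewer total mismatches wins.
#'
#' With `bisulfite_space = TRUE`, matching allows the asymmetric degeneracy of
#' primers designed against bisulfite-converted DNA:
#' a primer C whose primer context is CpG must match C (designed methylated);
#' a primer C outside CpG also matches a consensus T; a primer T also matches
#' a consensus C that would convert (a non-CpG C); and on the reverse-primer
#' site (bottom-strand chemistry seen from the top strand) a primer A matches
#' a consensus G outside a CpG dyad. The reverse-primer site may overhang the
#' consensus end by up to `max_overhang` bases, each counted as a mismatch,
#' with the amplicon clipped to the consensus.
#'
#' @param primers List with `forward` and `reverse` primer strings (5'->3' as
#'   synthesized).
#' @param consensus Record data frame (as from [read_sequences()]) or plain
#'   sequence string.
#' @param bisulfite_space Use bisulfite-space degenerate matching.
#' @param max_mismatches Maximum mismatches tolerated per primer (default 3).
#' @param max_overhang Maximum reverse-site overhang past the consensus end.
#' @return List of class `bs_amplicon`: `consensus_id`, `orientation` (`"+"`
#'   if the forward primer matched the consensus as given, `"-"` if its
#'   reverse complement), `start`, `end` (0-based half-open, in the
#'   coordinates of the consensus as given), `length`, `fwd_mismatches`,
#'   `rev_mismatches`, `rev_overhang`.
#' @export
locate_amplicon <- function(primers, consensus, bisulfite_space = FALSE,
                            max_mismatches = 3, max_overhang = 2) {
  cons_seq <- if (is.data.frame(consensus)) consensus$sequence[[1]] else consensus
  cons_id <- if (is.data.frame(consensus)) consensus$id[[1]] else "consensus"
  if (!nzchar(cons_seq)) stop("empty consensus", call. = FALSE)
  fwd <- toupper(primers$forward)
  rev <- toupper(primers$reverse)
  hits <- list(
    "+" = locate_on_strand(fwd, rev, cons_seq, bisulfite_space,
                           max_mismatches, max_overhang),
    "-" = locate_on_strand(fwd, rev, revcomp(cons_seq), bisulfite_space,
                           max_mismatches, max_overhang)
  )
  ok <- !vapply(hits, is.null, logical(1))
  if (!any(ok)) {
    # rerun on the printed orientation to produce the informative error
    locate_on_strand(fwd, rev, cons_seq, bisulfite_space,
                     max_mismatches, max_overhang, error = TRUE)
  }
  total_mm <- vapply(hits, function(h) {
    if (is.null(h)) Inf else h$fwd_mm + h$rev_mm
  }, numeric(1))
  orientation <- names(which.min(total_mm))  # tie -> printed orientation
  h <- hits[[orientation]]
  L <- nchar(cons_seq)
  if (orientation == "+") {
    start <- h$start; end <- h$end
  } else {
    start <- L - h$end; end <- L - h$start
  }
  structure(
    list(consensus_id = cons_id, orientation = orientation,
         start = start, end = end, length = end - start,
         fwd_mismatches = h$fwd_mm, rev_mismatches = h$rev_mm,
         rev_overhang = h$overhang),
    class = "bs_amplicon"
  )
}

#' @export
print.bs_amplicon <- function(x, ...) {
  cat(sprintf(
    "Amplicon on %s (%s strand): [%d, %d), length %d (fwd mm %d, rev mm %d)\n",
    x$consensus_id, x$orientation, x$start, x$end, x$length,
    x$fwd_mismatches, x$rev_mismatches))
  invisible(x)
}

# Scan one strand for the forward primer and the reverse primer's reverse
# complement; returns NULL when either primer has no acceptable placement.
locate_on_strand <- function(fwd, rev, strand_seq, bisulfite_space,
                             max_mismatches, max_overhang, error = FALSE) {
  s <- seq_chars(strand_seq)
  L <- length(s)
  fwd_hit <- best_primer_hit(seq_chars(fwd), s, L, mode = if (bisulfite_space)
    "top" else "literal", max_overhang = 0)
  if (is.null(fwd_hit) || fwd_hit$mm > max_mismatches) {
    if (error) stop("primer not found: forward primer '", fwd, "'",
                    call. = FALSE)
    return(NULL)
  }
  rc <- seq_chars(revcomp(rev))
  rev_hit <- best_primer_hit(rc, s, L, mode = if (bisulfite_space)
    "bottom" else "literal", max_overhang = max_overhang,
    min_start = fwd_hit$start)
  if (is.null(rev_hit) || rev_hit$mm > max_mismatches) {
    if (error) stop("primer not found: reverse primer '", rev, "'",
                    call. = FALSE)
    return(NULL)
  }
  if (rev_hit$start < fwd_hit$start) {
    if (error) stop("orientation error: reverse-primer site upstream of the ",
                    "forward primer", call. = FALSE)
    return(NULL)
  }
  list(start = fwd_hit$start, end = min(rev_hit$start + length(rc), L),
       fwd_mm = fwd_hit$mm, rev_mm = rev_hit$mm, overhang = rev_hit$overhang)
}

# Best (fewest-mismatch, ties leftmost) placement of a primer character
# vector on a strand. mode "top": bisulfite top-strand rules; "bottom":
# bottom-strand rules applied to the reverse-complemented reverse primer;
# "literal": exact base identity.
best_primer_hit <- function(p, s, L, mode, max_overhang = 0, min_start = 0L) {
  plen <- length(p)
  if (plen > L + max_overhang) return(NULL)
  p_next <- c(p[-1], NA)   # primer base following each position
  p_prev <- c(NA, p[-plen])
  starts <- seq.int(min_start, max(min_start, L - plen + max_overhang))
  starts <- starts[starts <= L - plen + max_overhang & starts >= 0]
  if (!length(starts)) return(NULL)
  best <- NULL
  for (st in starts) {
    idx <- st + seq_len(plen)          # 1-based consensus index
    inside <- idx <= L
    overhang <- sum(!inside)
    if (overhang > max_overhang) next
    cb <- s[idx[inside]]
    pb <- p[inside]
    if (mode == "literal") {
      mm <- sum(pb != cb)
    } else {
      cb_next <- ifelse(idx[inside] + 1 <= L, s[pmin(idx[inside] + 1, L)], NA)
      cb_prev <- ifelse(idx[inside] - 1 >= 1, s[pmax(idx[inside] - 1, 1)], NA)
      match <- pb == cb
      if (mode == "top") {
        # primer T matches a convertible (non-CpG) consensus C
        match <- match | (pb == "T" & cb == "C" &
                            (is.na(cb_next) | cb_next != "G"))
        # primer C outside primer-CpG tolerates consensus T
        match <- match | (pb == "C" & cb == "T" &
                            (is.na(p_next[inside]) | p_next[inside] != "G"))
      } else {
        # bottom strand seen from the top: converted bottom C = top G -> A
        match <- match | (pb == "A" & cb == "G" &
                            (is.na(cb_prev) | cb_prev != "C"))
        match <- match | (pb == "G" & cb == "A" &
                            (is.na(p_prev[inside]) | p_prev[inside] != "C"))
      }
      mm <- sum(!match)
    }
    mm <- mm + overhang
    if (is.null(best) || mm < best$mm) {
      best <- list(start = st, mm = mm, overhang = overhang)
    }
    if (best$mm == 0 && overhang == 0) break  # leftmost perfect hit
  }
  best
}

#' Semi-global alignment of a read against a consensus
#'
#' Optimal affine-gap alignment in which the read is aligned end to end while
#' gaps at either end of the consensus are free (the read matches a
#' consecutive stretch of the consensus) — the Supermatcher-style comparison
#' used for amplicon QC. Dynamic programming runs in compiled code.
#'
#' @param read,consensus Sequence strings (read length >= 1).
#' @param match,mismatch,gap_open,gap_ext Scoring scheme; a gap of length k
#'   costs `gap_open + k * gap_ext` (defaults +1/-1/-2/-0.5).
#' @return List: `score`, `subject_start`, `subject_end` (0-based half-open
#'   span on the consensus), `matches`, `mismatches`, `gap_columns`,
#'   `aligned_columns`, `identity_percent` (matches over all aligned columns,
#'   gap columns included).
#' @export
semi_global_align <- function(read, consensus, match = 1, mismatch = -1,
                              gap_open = -2, gap_ext = -0.5) {
  stopifnot(nchar(read) >= 1, nchar(consensus) >= 1)
  .semi_global_align_cpp(read, consensus, match, mismatch, gap_open, gap_ext)
}

#' Length filter and exact-duplicate screen for amplicon reads
#'
#' Removes reads shorter than `min_len` (the boundary length is kept) and
#' counts exact sequence duplicates, keeping the first occurrence — mirroring
#' the amplicon QC in which only sequences of at least 100 bases enter the
#' analysis and duplicate molecules would indicate resequencing of one
#' product.
#'
#' @param reads Data frame (`id`, `sequence`).
#' @param min_len Minimum kept length (default 100).
#' @return List with `reads` (kept), `n_too_short`, `n_exact_duplicates`.
#' @export
filter_and_dedup <- function(reads, min_len = 100) {
  if (nrow(reads) == 0) {
    return(list(reads = reads, n_too_short = 0L, n_exact_duplicates = 0L))
  }
  len <- nchar(reads$sequence)
  short <- len < min_len
  kept <- reads[!short, , drop = FALSE]
  dup <- duplicated(kept$sequence)
  list(reads = {
    out <- kept[!dup, , drop = FALSE]
    rownames(out) <- NULL
    out
  }, n_too_short = sum(short), n_exact_duplicates = sum(dup))
}

#' Per-read CpG and TpG dinucleotide frequencies
#'
#' Counts CG and TG dinucleotides over all overlapping windows of each read
#' and expresses them as percentages of the `L - 1` windows — the per-molecule
#' methylation measure for bisulfite amplicons (methylated CpG reads as CG;
#' converted CpG as TG). Windows containing N are not counted. An alternative
#' denominator, `100 * n / (n_cg + n_tg)`, is reported alongside as
#' `cg_pct_of_cgtg` / `tg_pct_of_cgtg` (`NA` when a read has neither).
#'
#' @param reads Data frame (`id`, `sequence`); every read must be at least 2
#'   bases long.
#' @return Data frame: `read_id`, `length`, `n_cg`, `n_tg`, `cg_pct`,
#'   `tg_pct`, `cg_pct_of_cgtg`, `tg_pct_of_cgtg`.
#' @export
per_read_dinucleotide <- function(reads) {
  if (nrow(reads) == 0) {
    return(data.frame(read_id = character(), length = integer(),
                      n_cg = integer(), n_tg = integer(),
                      cg_pct = numeric(), tg_pct = numeric(),
                      cg_pct_of_cgtg = numeric(), tg_pct_of_cgtg = numeric(),
                      stringsAsFactors = FALSE))
  }
  len <- nchar(reads$sequence)
  if (any(len < 2)) {
    stop("read(s) shorter than 2 bases have no dinucleotide windows: ",
         paste(head(reads$id[len < 2], 5), collapse = ", "), call. = FALSE)
  }
  dn <- Biostrings::dinucleotideFrequency(
    Biostrings::DNAStringSet(reads$sequence), step = 1)
  n_cg <- dn[, "CG"]
  n_tg <- dn[, "TG"]
  cgtg <- n_cg + n_tg
  data.frame(
    read_id = reads$id,
    length = len,
    n_cg = unname(n_cg),
    n_tg = unname(n_tg),
    cg_pct = unname(100 * n_cg / (len - 1)),
    tg_pct = unname(100 * n_tg / (len - 1)),
    cg_pct_of_cgtg = unname(ifelse(cgtg > 0, 100 * n_cg / cgtg, NA_real_)),
    tg_pct_of_cgtg = unname(ifelse(cgtg > 0, 100 * n_tg / cgtg, NA_real_)),
    stringsAsFactors = FALSE
  )
}

#' Relative-frequency histogram of per-read values
#'
#' Histogram over half-open bins (the last bin closed) with shares normalized
#' to sum to 1, so samples with different read counts are comparable.
#'
#' @param values Non-empty numeric vector.
#' @param bin_width Bin width (default 1.0).
#' @param origin Left edge of the first bin (default `floor(min/width) *
#'   width`).
#' @return Data frame: `bin_low`, `bin_high`, `count`, `share`.
#' @export
distribution_summary <- function(values, bin_width = 1.0, origin = NULL) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  stopifnot(bin_width > 0)
  if (is.null(origin)) origin <- floor(min(values) / bin_width) * bin_width
  nbins <- max(1L, as.integer(ceiling((max(values) - origin) / bin_width)))
  if (origin + nbins * bin_width < max(values)) nbins <- nbins + 1L
  bin <- pmin(floor((values - origin) / bin_width), nbins - 1L)
  count <- tabulate(bin + 1L, nbins)
  data.frame(
    bin_low = origin + (seq_len(nbins) - 1L) * bin_width,
    bin_high = origin + seq_len(nbins) * bin_width,
    count = count,
    share = count / sum(count),
    stringsAsFactors = FALSE
  )
}

#' Distribution-shift chi-square test on tail fractions
#'
#' Categorizes values by tail thresholds — either two (`low`/`high`, giving
#' categories below-low / middle / above-high) or a single `split` (below /
#' at-or-above) — and tests whether the treated sample's category counts
#' deviate from the expectation defined by the control sample's proportions
#' (chi-square goodness of fit).
#'
#' @param control_values,treated_values Non-empty numeric vectors.
#' @param thresholds Either `c(low = 8, high = 12)` (the default, a
#'   two-sided tail scheme) or `c(split = 7.5)`.
#' @return List: `categories`, `observed` (treated counts), `expected` (from
#'   control proportions at the treated sample size), `control_counts`,
#'   `statistic`, `df`, `p_value`.
#' @export
tail_shift_test <- function(control_values, treated_values,
                            thresholds = c(low = 8, high = 12)) {
  if (!length(control_values) || !length(treated_values)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  th <- as.list(thresholds)
  if (!is.null(th$split)) {
    cut_fun <- function(v) {
      factor(ifelse(v < th$split, "below", "at_or_above"),
             levels = c("below", "at_or_above"))
    }
  } else if (!is.null(th$low) && !is.null(th$high)) {
    stopifnot(th$low < th$high)
    cut_fun <- function(v) {
      factor(ifelse(v < th$low, "low_tail",
                    ifelse(v > th$high, "high_tail", "middle")),
             levels = c("low_tail", "middle", "high_tail"))
    }
  } else {
    stop("`thresholds` must be c(low=, high=) or c(split=)", call. = FALSE)
  }
  ctl <- table(cut_fun(control_values))
  trt <- table(cut_fun(treated_values))
  if (any(ctl == 0)) {
    stop("control category with zero count (",
         paste(names(ctl)[ctl == 0], collapse = ", "),
         "); expected count undefined - widen the thresholds", call. = FALSE)
  }
  props <- as.numeric(ctl) / sum(ctl)
  ct <- suppressWarnings(chisq.test(as.numeric(trt), p = props))
  list(
    categories = names(ctl),
    observed = as.numeric(trt),
    expected = props * sum(trt),
    control_counts = as.numeric(ctl),
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value)
  )
}

#' One- versus two-component Gaussian mixture fit of per-read methylation
#'
#' Fits one- and two-component Gaussian mixtures to a per-read frequency
#' distribution (via [gaussian_em()]) and selects between them, detecting
#' bidirectional methylation change as a two-component verdict. With fewer
#' than 20 values the two-component fit is not attempted and k = 1 is forced;
#' zero-variance input yields k = 1 with a floored SD and a warning.
#'
#' The default selector (`"f_test"`) fits both model curves to the
#' relative-frequency histogram by least squares and compares them with the
#' nested-model extra-sum-of-squares F statistic — the best-curve-fit
#' selection of graphing software applied to a frequency plot. It is robust
#' to the quantization of per-read percentages (integer dinucleotide counts
#' over a shared read length put much of the mass on exact lattice values,
#' onto which a raw-value information criterion collapses a spurious
#' near-zero-SD component). The small-sample-corrected Akaike criterion on
#' the raw values remains available as `selection = "aicc"` and is
#' appropriate for continuous-valued input.
#'
#' @param values Numeric vector of per-read percentages.
#' @param k_max Maximum components (1 or 2).
#' @param seed Integer seed (fit is deterministic given the seed).
#' @param restarts EM restarts for the two-component fit.
#' @param selection `"f_test"` (default) or `"aicc"`.
#' @param f_alpha Evidence threshold for the F-test selector (default 0.001).
#'   The histogram residuals the F statistic is computed from are correlated,
#'   so its nominal calibration is optimistic; a two-component verdict is
#'   required to carry strong evidence. Well-separated mixtures give
#'   p-values many orders of magnitude below this threshold, while unimodal
#'   generator data stays well above it.
#' @param bin_width Histogram bin width for the F-test variant.
#' @return List of class `bs_mixture_fit`: `k_selected`, `components` (data
#'   frame weight/mean/sd for the selected model), `fits` (both raw fits),
#'   `loglik` (named), `aicc` (named, AICc selection), `selection`,
#'   `f_statistic`/`f_p_value` (F-test selection), `n`.
#' @export
fit_methylation_mixture <- function(values, k_max = 2, seed = 1L,
                                    restarts = 10, selection = c("f_test", "aicc"),
                                    f_alpha = 0.001, bin_width = NULL) {
  selection <- match.arg(selection)
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  zero_var <- diff(range(x)) == 0
  if (zero_var) {
    warning("zero-variance input; forcing k = 1 with floored SD")
  }
  fit1 <- gaussian_em(x, 1L)
  if (k_max < 2 || n < 20 || zero_var) {
    return(structure(
      list(k_selected = 1L,
           components = data.frame(weight = 1, mean = fit1$means,
                                   sd = fit1$sds),
           fits = list(k1 = fit1),
           loglik = c(k1 = fit1$loglik), aicc = c(k1 = aicc(fit1$loglik, 2, n)),
           selection = selection, n = n),
      class = "bs_mixture_fit"
    ))
  }
  fit2 <- gaussian_em(x, 2L, restarts = restarts, seed = seed)
  ll <- c(k1 = fit1$loglik, k2 = fit2$loglik)
  crit <- c(k1 = aicc(fit1$loglik, 2, n), k2 = aicc(fit2$loglik, 5, n))
  out <- list(fits = list(k1 = fit1, k2 = fit2), loglik = ll, aicc = crit,
              selection = selection, n = n)
  if (selection == "aicc") {
    out$k_selected <- if (crit["k2"] < crit["k1"]) 2L else 1L
  } else {
    ft <- mixture_f_test(x, fit1, fit2, bin_width = bin_width)
    out$f_statistic <- ft$statistic
    out$f_p_value <- ft$p_value
    out$k_selected <- if (!is.na(ft$p_value) && ft$p_value < f_alpha) 2L else 1L
  }
  sel <- if (out$k_selected == 2L) fit2 else fit1
  out$components <- data.frame(weight = sel$weights, mean = sel$means,
                               sd = sel$sds)
  structure(out, class = "bs_mixture_fit")
}

aicc <- function(loglik, n_par, n) {
  if (n - n_par - 1 <= 0) return(Inf)
  -2 * loglik + 2 * n_par + 2 * n_par * (n_par + 1) / (n - n_par - 1)
}

# Extra-sum-of-squares F-test between the 1- and 2-component mixture density
# curves evaluated against the relative-frequency histogram.
mixture_f_test <- function(x, fit1, fit2, bin_width = NULL) {
  if (is.null(bin_width)) bin_width <- diff(range(x)) / 20
  if (bin_width <= 0) return(list(statistic = NA_real_, p_value = NA_real_))
  h <- distribution_summary(x, bin_width = bin_width)
  mid <- (h$bin_low + h$bin_high) / 2
  dens <- h$share / bin_width
  pred <- function(fit) {
    rowSums(vapply(seq_along(fit$weights), function(j) {
      fit$weights[j] * dnorm(mid, fit$means[j], fit$sds[j])
    }, numeric(length(mid))))
  }
  rss1 <- sum((dens - pred(fit1))^2)
  rss2 <- sum((dens - pred(fit2))^2)
  df1 <- length(mid) - 2
  df2 <- length(mid) - 5
  if (df2 <= 0 || rss2 <= 0) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  f <- ((rss1 - rss2) / (df1 - df2)) / (rss2 / df2)
  list(statistic = f,
       p_value = stats::pf(f, df1 - df2, df2, lower.tail = FALSE))
}

#' @export
print.bs_mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit (n = %d): k = %d selected by %s\n",
              x$n, x$k_selected, x$selection))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' CpG-TpG frequency correlation across reads
#'
#' Ordinary least-squares regression of per-read TpG frequency on CpG
#' frequency. Bisulfite chemistry turns a converted CpG into TpG, so genuine
#' methylation differences produce a negative slope; native TpG content
#' attenuates but does not reverse it.
#'
#' @param per_read_rows Data frame from [per_read_dinucleotide()].
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
cg_tg_correlation <- function(per_read_rows) {
  if (nrow(per_read_rows) < 3) stop("need at least 3 reads", call. = FALSE)
  if (var(per_read_rows$cg_pct) == 0) {
    stop("constant cg_pct; correlation undefined", call. = FALSE)
  }
  ols_fit(per_read_rows$cg_pct, per_read_rows$tg_pct)
}

#' Compare mean per-read methylation between two samples
#'
#' Per-sample means of CpG and TpG frequency with a two-sample (Welch) t-test
#' per metric.
#'
#' @param control_rows,treated_rows Data frames from
#'   [per_read_dinucleotide()], n >= 2 each.
#' @param welch Use the Welch correction (default `TRUE`).
#' @return Data frame with one row per metric (`cg_pct`, `tg_pct`):
#'   `mean_control`, `mean_treated`, `t`, `p_value`.
#' @export
compare_mean_methylation <- function(control_rows, treated_rows,
                                     welch = TRUE) {
  if (nrow(control_rows) < 2 || nrow(treated_rows) < 2) {
    stop("need n >= 2 reads in each sample", call. = FALSE)
  }
  one <- function(metric) {
    tt <- two_sample_t(control_rows[[metric]], treated_rows[[metric]],
                       welch = welch)
    data.frame(metric = metric, mean_control = tt$mean_a,
               mean_treated = tt$mean_b, t = tt$t, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  }
  rbind(one("cg_pct"), one("tg_pct"))
}
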