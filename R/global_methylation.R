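#' Base composition of a sequence set
#'
#' Counts A, C, G, T and N over all sequences (the Compseq-style nucleotide
#' content table). Percentages are of the total base count including N, and
#' sum to 100.
#'
#' @param sequences Character vector of sequences, or a record data frame with
#'   a `sequence` column.
#' @param dinucleotides Also return overlapping dinucleotide counts (summed
#'   over sequences; pairs containing N are not counted).
#' @return List of class `bs_composition` with `counts` (named A/C/G/T/N),
#'   `percent`, `total`, and optionally `dinucleotide_counts`.
#' @export
base_composition <- function(sequences, dinucleotides = FALSE) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  if (length(sequences) == 0 || all(!nzchar(sequences))) {
    stop("base_composition needs a non-empty sequence set", call. = FALSE)
  }
  set <- Biostrings::DNAStringSet(sequences)
  af <- Biostrings::alphabetFrequency(set, collapse = TRUE)
  counts <- af[c("A", "C", "G", "T", "N")]
  other <- sum(af) - sum(counts)
  if (other > 0) stop("sequences contain letters outside {A,C,G,T,N}",
                      call. = FALSE)
  total <- sum(counts)
  out <- list(counts = counts, percent = 100 * counts / total, total = total)
  if (dinucleotides) {
    out$dinucleotide_counts <-
      colSums(Biostrings::dinucleotideFrequency(set, step = 1))
  }
  structure(out, class = "bs_composition")
}

#' Per-base composition change between two samples
#'
#' Relative per-base change of a treated sample against a control normalized
#' to 1 (ratio of base percentages), with significance per base from a
#' 2x2 test of (count of the base vs all other bases) across samples:
#' chi-square with Yates correction on the raw counts, and the Fisher exact
#' test alongside.
#'
#' @param table_treated,table_control `bs_composition` objects.
#' @param fisher Also compute Fisher exact p per base (exact but slower on
#'   very deep counts; default `TRUE`).
#' @return Data frame with one row per base (A, C, G, T, N): counts and
#'   percentages in both samples, `ratio` (treated over control, control = 1;
#'   `NA` and `flag = "undefined"` when the control count is zero),
#'   `chisq_yates_p`, and `fisher_p`.
#' @export
composition_delta <- function(table_treated, table_control, fisher = TRUE) {
  stopifnot(inherits(table_treated, "bs_composition"),
            inherits(table_control, "bs_composition"))
  bases <- names(table_treated$counts)
  ratio <- ifelse(table_control$percent > 0,
                  table_treated$percent / table_control$percent, NA_real_)
  chisq_p <- rep(NA_real_, length(bases))
  fisher_p <- rep(NA_real_, length(bases))
  for (i in seq_along(bases)) {
    tab <- c(table_treated$counts[i], table_treated$total - table_treated$counts[i],
             table_control$counts[i], table_control$total - table_control$counts[i])
    if (tab[1] + tab[3] == 0) next  # base absent from both samples
    chisq_p[i] <- tryCatch(chi_square_yates(tab)$p_value,
                           error = function(e) NA_real_)
    if (fisher) {
      fisher_p[i] <- tryCatch(fisher_exact_2x2(tab)$p_value,
                              error = function(e) NA_real_)
    }
  }
  data.frame(
    base = bases,
    count_treated = unname(table_treated$counts),
    count_control = unname(table_control$counts),
    percent_treated = unname(table_treated$percent),
    percent_control = unname(table_control$percent),
    ratio = unname(ratio),
    flag = ifelse(is.na(ratio), "undefined", "ok"),
    chisq_yates_p = chisq_p,
    fisher_p = fisher_p,
    stringsAsFactors = FALSE
  )
}

#' Call per-cytosine methylation from reads with truth alignments
#'
#' For each cytosine of the (unconverted) reference covered by reads of its
#' strand, a read base C increments the methylated count and T the
#' unmethylated count; other read bases are ignored. Both strands are handled
#' symmetrically (minus-strand cytosines appear as G on the plus strand;
#' minus-strand reads are assessed in their own orientation against the
#' reverse complement). Coordinates in the output are 0-based plus-strand
#' positions of the cytosine.
#'
#' @param reads Data frame (`id`, `sequence`).
#' @param truth Truth sidecar (`read_id`, `start`, `end`, `strand`, optional
#'   `orient`) as from [simulate_genomic_reads()].
#' @param reference Original (unconverted) reference record or sequence
#'   string.
#' @param context_filter Optional subset of contexts to keep, e.g. `"CpG"`.
#' @return Data frame of class `bs_site_calls`: `chrom`, `pos`, `strand`,
#'   `context`, `n_meth`, `n_unmeth`, `methylation_percent`. Sites with zero
#'   C/T coverage are absent.
#' @export
call_sites <- function(reads, truth, reference, context_filter = NULL) {
  sequence <- if (is.data.frame(reference)) reference$sequence[[1]] else reference
  chrom <- if (is.data.frame(reference)) reference$id[[1]] else "ref"
  L <- nchar(sequence)
  ref_plus <- seq_chars(sequence)
  ref_minus <- seq_chars(revcomp(sequence))
  tr <- truth[match(reads$id, truth$read_id), , drop = FALSE]
  if (anyNA(tr$start)) {
    stop("truth sidecar is missing read id(s)", call. = FALSE)
  }
  if (any(tr$start < 0 | tr$end > L)) {
    stop("truth interval(s) outside the reference", call. = FALSE)
  }
  orient <- if (!is.null(tr$orient)) tr$orient else rep("template", nrow(tr))
  # accumulators indexed by strand-frame position (1-based)
  meth <- list("+" = integer(L), "-" = integer(L))
  unmeth <- list("+" = integer(L), "-" = integer(L))
  is_c <- list("+" = ref_plus == "C", "-" = ref_minus == "C")
  for (i in seq_len(nrow(reads))) {
    rd <- reads$sequence[[i]]
    if (orient[i] == "revcomp") rd <- revcomp(rd)
    rchars <- seq_chars(rd)
    st <- tr$strand[i]
    frame_pos <- if (st == "+") {
      (tr$start[i] + 1L):tr$end[i]
    } else {
      (L - tr$end[i] + 1L):(L - tr$start[i])
    }
    cc <- is_c[[st]][frame_pos]
    pos_c <- frame_pos[cc]
    base_c <- rchars[cc]
    m <- base_c == "C"
    u <- base_c == "T"
    if (any(m)) {
      tm <- tabulate_at(pos_c[m], L)
      meth[[st]] <- meth[[st]] + tm
    }
    if (any(u)) {
      tu <- tabulate_at(pos_c[u], L)
      unmeth[[st]] <- unmeth[[st]] + tu
    }
  }
  ctx <- cytosine_contexts(sequence)
  frame_idx <- ifelse(ctx$strand == "+", ctx$pos + 1L, L - ctx$pos)
  n_meth <- ifelse(ctx$strand == "+", meth[["+"]][frame_idx],
                   meth[["-"]][frame_idx])
  n_unmeth <- ifelse(ctx$strand == "+", unmeth[["+"]][frame_idx],
                     unmeth[["-"]][frame_idx])
  keep <- (n_meth + n_unmeth) > 0
  out <- data.frame(
    chrom = chrom,
    pos = ctx$pos[keep], strand = ctx$strand[keep],
    context = ctx$context[keep],
    n_meth = n_meth[keep], n_unmeth = n_unmeth[keep],
    stringsAsFactors = FALSE
  )
  out$methylation_percent <- 100 * out$n_meth / (out$n_meth + out$n_unmeth)
  if (!is.null(context_filter)) {
    out <- out[out$context %in% context_filter, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("bs_site_calls", class(out))
  out
}

tabulate_at <- function(pos, n) tabulate(pos, nbins = n)

#' Cytosine-count summary in CpG context
#'
#' The GeneSpring-style "C count (%)" metrics: methylated and unmethylated
#' CpG cytosine observations as a percentage of all sequenced bases, and the
#' methylated:unmethylated ratio. The denominator is the total number of
#' sequenced bases (the Fig-1B-style definition), supplied by the caller.
#'
#' @param site_calls A `bs_site_calls` data frame.
#' @param total_bases Total sequenced bases (> 0).
#' @return List with `meth_c_percent`, `unmeth_c_percent`, `ratio`,
#'   `n_meth_obs`, `n_unmeth_obs`, `flag` (`"ok"` or `"infinite_ratio"`).
#' @export
c_count_summary <- function(site_calls, total_bases) {
  stopifnot(total_bases > 0)
  cg <- site_calls[site_calls$context == "CpG", , drop = FALSE]
  n_meth <- sum(cg$n_meth)
  n_unmeth <- sum(cg$n_unmeth)
  ratio <- if (n_unmeth == 0) Inf else n_meth / n_unmeth
  list(
    meth_c_percent = 100 * n_meth / total_bases,
    unmeth_c_percent = 100 * n_unmeth / total_bases,
    ratio = ratio,
    n_meth_obs = n_meth,
    n_unmeth_obs = n_unmeth,
    flag = if (is.infinite(ratio)) "infinite_ratio" else "ok"
  )
}

#' Methylation-frequency bin profile
#'
#' Bins sites by methylation percentage (default deciles `[0,10), ...,
#' [90,100]`; the last bin is closed) and reports each bin's share of the
#' methylated cytosine observations — the binned C-count profile over
#' methylation-frequency classes.
#'
#' @param site_calls A `bs_site_calls` data frame (coverage > 0 by
#'   construction).
#' @param bin_width Bin width in percentage points; must divide 100.
#' @return Data frame: `bin_low`, `bin_high`, `n_sites`, `meth_c_count`,
#'   `c_count_percent` (share of methylated observations, summing to 100 when
#'   any exist).
#' @export
methylation_bin_profile <- function(site_calls, bin_width = 10) {
  if (100 %% bin_width != 0) {
    stop("`bin_width` must divide 100", call. = FALSE)
  }
  nbins <- as.integer(100 / bin_width)
  bin <- pmin(floor(site_calls$methylation_percent / bin_width), nbins - 1L)
  n_sites <- tabulate(bin + 1L, nbins)
  meth_count <- vapply(seq_len(nbins) - 1L, function(b) {
    sum(site_calls$n_meth[bin == b])
  }, numeric(1))
  total <- sum(meth_count)
  data.frame(
    bin_low = (seq_len(nbins) - 1L) * bin_width,
    bin_high = seq_len(nbins) * bin_width,
    n_sites = n_sites,
    meth_c_count = meth_count,
    c_count_percent = if (total > 0) 100 * meth_count / total else 0,
    stringsAsFactors = FALSE
  )
}

#' Differential methylation calling between two samples
#'
#' Per shared site, a 2x2 Fisher exact test of (methylated, unmethylated)
#' counts across the samples. Before testing, each site must show methylation
#' distinguishable from bisulfite conversion error in at least one sample: a
#' one-sided binomial test of the methylated count against retention
#' probability `conversion_error` at level `alpha` (the screen that makes
#' apparent methylation "real" given the spike-in-calibrated error rate).
#' Sites failing the screen in both samples are never tested. No
#' multiple-testing correction is applied by default, matching a per-site
#' Fisher threshold; set `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param calls_a,calls_b `bs_site_calls` data frames from the two samples.
#' @param alpha Significance threshold for both the screen and the Fisher
#'   test (default 0.01).
#' @param conversion_error Retention probability of an unmethylated C under
#'   failed conversion (default 0.05, the spike-in-derived rate).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame of tested sites: coordinates, counts in both samples,
#'   screen outcomes, `fisher_p`, (`fisher_p_adj`,) `flagged`. The sites
#'   present in only one sample are attached as attribute `"orphans"`.
#' @export
differential_sites <- function(calls_a, calls_b, alpha = 0.01,
                               conversion_error = 0.05, adjust = "none") {
  key_a <- paste(calls_a$chrom, calls_a$pos, calls_a$strand)
  key_b <- paste(calls_b$chrom, calls_b$pos, calls_b$strand)
  shared <- intersect(key_a, key_b)
  if (length(shared) == 0) {
    stop("no shared sites between the two samples (mismatched coordinate ",
         "universes)", call. = FALSE)
  }
  orphans <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
  if (length(orphans)) {
    warning(length(orphans), " site(s) covered in only one sample were ",
            "excluded from testing")
  }
  a <- calls_a[match(shared, key_a), , drop = FALSE]
  b <- calls_b[match(shared, key_b), , drop = FALSE]
  screen_p <- function(n_meth, n_total) {
    pbinom(n_meth - 1L, n_total, conversion_error, lower.tail = FALSE)
  }
  real_a <- screen_p(a$n_meth, a$n_meth + a$n_unmeth) < alpha
  real_b <- screen_p(b$n_meth, b$n_meth + b$n_unmeth) < alpha
  tested <- real_a | real_b
  p <- rep(NA_real_, length(shared))
  idx <- which(tested)
  p[idx] <- vapply(idx, function(i) {
    fisher_exact_2x2(c(a$n_meth[i], a$n_unmeth[i],
                       b$n_meth[i], b$n_unmeth[i]))$p_value
  }, numeric(1))
  out <- data.frame(
    chrom = a$chrom, pos = a$pos, strand = a$strand, context = a$context,
    n_meth_a = a$n_meth, n_unmeth_a = a$n_unmeth,
    n_meth_b = b$n_meth, n_unmeth_b = b$n_unmeth,
    meth_percent_a = a$methylation_percent,
    meth_percent_b = b$methylation_percent,
    screen_pass_a = real_a, screen_pass_b = real_b, tested = tested,
    fisher_p = p,
    stringsAsFactors = FALSE
  )
  if (identical(adjust, "BH")) {
    out$fisher_p_adj <- NA_real_
    out$fisher_p_adj[tested] <- stats::p.adjust(p[tested], method = "BH")
    out$flagged <- !is.na(out$fisher_p_adj) & out$fisher_p_adj < alpha
  } else {
    out$flagged <- !is.na(out$fisher_p) & out$fisher_p < alpha
  }
  attr(out, "orphans") <- orphans
  out
}

#' Annotate sites relative to gene intervals
#'
#' Labels each site `genic` (inside a gene), `proximal` (within `distance`
#' bases of the nearest gene edge, boundary inclusive) or `intergenic`.
#' Distance is measured between the cytosine base and the nearest gene
#' boundary base under half-open arithmetic. A two-way label matching the
#' dichotomy "intergenic = farther than `distance` from any gene" is also
#' emitted.
#'
#' @param sites Data frame with `chrom` and `pos` (0-based site coordinate).
#' @param genes Gene intervals (`chrom`, `start`, `end`, 0-based half-open),
#'   e.g. from [read_intervals()] or [generate_genes()].
#' @param distance Proximity threshold in bases (default 5000).
#' @return `sites` with added `gene_distance` (0 inside a gene; `NA` when the
#'   chromosome has no genes), `label` (genic/proximal/intergenic) and
#'   `label2` (genic_or_proximal/intergenic).
#' @export
annotate_sites <- function(sites, genes, distance = 5000) {
  validate_intervals(genes)
  no_genes <- !(sites$chrom %in% genes$chrom)
  if (any(no_genes)) {
    warning("chromosome(s) absent from the gene annotation: ",
            paste(unique(sites$chrom[no_genes]), collapse = ", "),
            "; their sites are labelled intergenic")
  }
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$pos + 1L, width = 1L))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  d <- rep(NA_real_, nrow(sites))
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(site_gr, gene_gr, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits)
  gap <- S4Vectors::mcols(hits)$distance
  # GRanges gap distance counts bases strictly between; the boundary-base
  # distance of the half-open convention is gap + 1 outside, 0 inside
  d[qh] <- ifelse(gap == 0 & overlaps_any(site_gr, gene_gr)[qh], 0, gap + 1)
  label <- ifelse(is.na(d), "intergenic",
                  ifelse(d == 0, "genic",
                         ifelse(d <= distance, "proximal", "intergenic")))
  sites$gene_distance <- d
  sites$label <- label
  sites$label2 <- ifelse(label == "intergenic", "intergenic",
                         "genic_or_proximal")
  sites
}

overlaps_any <- function(query, subject) {
  IRanges::overlapsAny(query, subject, ignore.strand = TRUE)
}

#' Extract non-overlapping flanking windows around sites
#'
#' Windows `[pos - radius, pos + radius + 1)` around each site, clipped to the
#' chromosome; sites are processed left to right and a window overlapping the
#' previously emitted one is skipped (greedy rule, preserving fixed-width
#' windows).
#'
#' @param sites Data frame with `chrom`, `pos` (0-based), sorted or sortable
#'   by position.
#' @param genome Named list or vector of chromosome sequences (names =
#'   chromosome ids), or a record data frame from [read_sequences()].
#' @param radius Flank radius in bases (default 100, i.e. 201-base windows).
#' @return Data frame `chrom`, `start`, `end`, `site_pos`, `sequence`.
#' @export
extract_flanks <- function(sites, genome, radius = 100) {
  if (is.data.frame(genome)) {
    genome <- setNames(as.list(genome$sequence), genome$id)
  }
  out <- list()
  for (ch in unique(sites$chrom)) {
    if (is.null(genome[[ch]])) {
      stop("no genome sequence for chromosome '", ch, "'", call. = FALSE)
    }
    L <- nchar(genome[[ch]])
    pos <- sort(sites$pos[sites$chrom == ch])
    start <- pmax(pos - radius, 0L)
    end <- pmin(pos + radius + 1L, L)
    keep <- logical(length(pos))
    prev_end <- -1L
    for (i in seq_along(pos)) {
      if (start[i] >= prev_end) {
        keep[i] <- TRUE
        prev_end <- end[i]
      }
    }
    out[[ch]] <- data.frame(
      chrom = ch, start = start[keep], end = end[keep], site_pos = pos[keep],
      sequence = substring(genome[[ch]], start[keep] + 1L, end[keep]),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
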