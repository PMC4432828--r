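#' Generate a random reference sequence with tunable CpG density
#'
#' Draws a first-order Markov sequence whose stationary base composition is set
#' by `gc_fraction` and whose CpG dinucleotide rate is multiplied by
#' `cpg_factor` relative to the independence baseline (`cpg_factor = 1` gives
#' i.i.d. bases, so the CpG rate is `(gc/2)^2`; values < 1 emulate the CpG
#' depletion of mammalian genomes, values > 1 CpG-island-like density).
#'
#' @param length Number of bases (>= 1).
#' @param gc_fraction G+C fraction in `[0, 1]`.
#' @param cpg_factor Multiplier (>= 0) on the baseline `P(G | previous C)`.
#' @param seed Integer seed; output is reproducible for a fixed seed.
#' @param id Sequence id for the returned record.
#' @return One-row data frame (`id`, `sequence`, `description`, `quality`).
#' @export
generate_reference <- function(length, gc_fraction = 0.5, cpg_factor = 1,
                               seed = 1L, id = "ref") {
  stopifnot_scalar_number(length, "length")
  if (length < 1) stop("`length` must be >= 1", call. = FALSE)
  stopifnot(gc_fraction >= 0, gc_fraction <= 1, cpg_factor >= 0)
  bases <- c("A", "C", "G", "T")
  p0 <- c((1 - gc_fraction) / 2, gc_fraction / 2,
          gc_fraction / 2, (1 - gc_fraction) / 2)
  # transition rows: identical to p0 except out of C, where P(G) is tilted
  p_g_after_c <- min(cpg_factor * gc_fraction / 2, 1)
  rest <- p0[-3]
  p_from_c <- numeric(4)
  p_from_c[3] <- p_g_after_c
  p_from_c[-3] <- if (sum(rest) > 0) rest / sum(rest) * (1 - p_g_after_c) else 0
  trans <- rbind(p0, p_from_c, p0, p0)  # rows: previous A, C, G, T
  out <- with_seed(seed, {
    x <- integer(length)
    x[1] <- sample.int(4L, 1L, prob = p0)
    if (length > 1) {
      u <- runif(length - 1L)
      cum <- t(apply(trans, 1, cumsum))
      for (i in 2:length) {
        x[i] <- findInterval(u[i - 1L], cum[x[i - 1L], ]) + 1L
      }
    }
    paste(bases[x], collapse = "")
  })
  data.frame(id = id, sequence = out, description = "synthetic reference",
             quality = NA_character_, stringsAsFactors = FALSE)
}

# Context of every cytosine on both strands of a reference, by the standard
# three-base rule (CpG = C followed by G; CHG = CxG; CHH otherwise; H = A/C/T).
# Positions are 0-based plus-strand coordinates of the cytosine itself; minus
# strand cytosines appear as G on the plus strand. Truncated contexts at the
# sequence ends and contexts interrupted by N fall back to CHH (conservative:
# N is never counted as G).
cytosine_contexts <- function(sequence) {
  s <- seq_chars(sequence)
  L <- length(s)
  ctx_one <- function(next1, next2) {
    ifelse(!is.na(next1) & next1 == "G", "CpG",
           ifelse(!is.na(next2) & next2 == "G", "CHG", "CHH"))
  }
  plus <- which(s == "C")
  minus <- which(s == "G")
  n1p <- ifelse(plus + 1 <= L, s[pmin(plus + 1, L)], NA)
  n2p <- ifelse(plus + 2 <= L, s[pmin(plus + 2, L)], NA)
  # minus strand read 3'->5' on plus = complement; next base on minus strand
  # at plus position i is plus position i-1 complemented (G -> C etc.)
  n1m <- ifelse(minus - 1 >= 1, s[pmax(minus - 1, 1)], NA)
  n2m <- ifelse(minus - 2 >= 1, s[pmax(minus - 2, 1)], NA)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  df <- rbind(
    data.frame(pos = plus - 1L, strand = rep("+", length(plus)),
               context = ctx_one(n1p, n2p), stringsAsFactors = FALSE),
    data.frame(pos = minus - 1L, strand = rep("-", length(minus)),
               context = ctx_one(unname(comp[n1m]), unname(comp[n2m])),
               stringsAsFactors = FALSE)
  )
  df[order(df$pos, df$strand), , drop = FALSE]
}

#' Assign a methylome to a reference
#'
#' Every cytosine on both strands receives a context label (CpG/CHG/CHH, by
#' the standard three-base rule) and a Bernoulli methylation state drawn with
#' the context's probability. Per-site overrides replace the context
#' probability at named plus-strand coordinates (both strands of a CpG dyad
#' are overridden when both carry a cytosine at that coordinate).
#'
#' @param reference One-row record (as from [generate_reference()] or
#'   [read_sequences()]) or a plain sequence string.
#' @param p_cpg,p_chg,p_chh Methylation probabilities per context, in `[0,1]`.
#' @param site_overrides Optional named numeric vector: names are 0-based
#'   plus-strand positions of cytosines (on either strand), values are
#'   probabilities. An override at a non-cytosine position is an error.
#' @param seed Integer seed.
#' @return Data frame (`pos`, `strand`, `context`, `p_meth`, `methylated`),
#'   one row per cytosine; class `bs_methylome`.
#' @export
assign_methylome <- function(reference, p_cpg, p_chg = 0, p_chh = 0,
                             site_overrides = NULL, seed = 1L) {
  sequence <- if (is.data.frame(reference)) reference$sequence[[1]] else reference
  stopifnot(all(c(p_cpg, p_chg, p_chh) >= 0), all(c(p_cpg, p_chg, p_chh) <= 1))
  ctx <- cytosine_contexts(sequence)
  p <- c(CpG = p_cpg, CHG = p_chg, CHH = p_chh)[ctx$context]
  if (!is.null(site_overrides)) {
    ov_pos <- as.integer(names(site_overrides))
    missing <- setdiff(ov_pos, ctx$pos)
    if (length(missing)) {
      stop("site_overrides at non-cytosine position(s): ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    }
    idx <- match(ctx$pos, ov_pos)
    p[!is.na(idx)] <- site_overrides[idx[!is.na(idx)]]
  }
  ctx$p_meth <- unname(p)
  ctx$methylated <- with_seed(seed, runif(nrow(ctx)) < ctx$p_meth)
  class(ctx) <- c("bs_methylome", class(ctx))
  ctx
}

#' In-silico bisulfite conversion of one strand
#'
#' Applies bisulfite chemistry to the given strand: an unmethylated cytosine
#' converts to T with probability `1 - under_conversion`; a methylated
#' cytosine erroneously converts with probability `over_conversion`. Only C
#' positions can change, and only to T. The companion event log records every
#' cytosine's outcome.
#'
#' @param sequence Sequence string of the strand being converted, in its own
#'   5'->3' orientation.
#' @param states Methylome rows for this strand with `pos` given in the
#'   coordinates of `sequence` (0-based) — i.e. rows where
#'   `substr(sequence, pos + 1, pos + 1) == "C"`. Every C must be covered.
#' @param under_conversion Probability `u` in `[0,1]` that an unmethylated C
#'   fails to convert (retained as C).
#' @param over_conversion Probability `v` in `[0,1]` that a methylated C
#'   converts.
#' @param seed Integer seed.
#' @return List with `sequence` (converted string) and `events` (data frame
#'   `pos`, `context`, `methylated`, `converted`).
#' @export
bisulfite_convert <- function(sequence, states, under_conversion = 0.05,
                              over_conversion = 0, seed = 1L) {
  stopifnot(under_conversion >= 0, under_conversion <= 1,
            over_conversion >= 0, over_conversion <= 1)
  s <- seq_chars(sequence)
  c_pos <- which(s == "C") - 1L
  missing <- setdiff(c_pos, states$pos)
  if (length(missing)) {
    stop("no methylation state for C position(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  st <- states[match(c_pos, states$pos), , drop = FALSE]
  p_convert <- ifelse(st$methylated, over_conversion, 1 - under_conversion)
  converted <- with_seed(seed, runif(length(c_pos)) < p_convert)
  s[c_pos[converted] + 1L] <- "T"
  list(
    sequence = paste(s, collapse = ""),
    events = data.frame(pos = c_pos, context = st$context,
                        methylated = st$methylated, converted = converted,
                        stringsAsFactors = FALSE)
  )
}

#' Bisulfite-convert both strands of a reference
#'
#' The two strands of bisulfite-treated DNA are no longer complementary; the
#' minus strand is converted by applying [bisulfite_convert()] to the reverse
#' complement (so minus-strand conversions appear as G->A when viewed from the
#' plus strand).
#'
#' @inheritParams bisulfite_convert
#' @param reference Record or sequence string (plus strand).
#' @param methylome Full two-strand methylome from [assign_methylome()], in
#'   plus-strand coordinates.
#' @return List with `plus`, `minus` (converted strand sequences, each in its
#'   own 5'->3' orientation), `length`, `chrom`, and `events` (both strands,
#'   plus-strand coordinates).
#' @export
convert_both_strands <- function(reference, methylome, under_conversion = 0.05,
                                 over_conversion = 0, seed = 1L) {
  sequence <- if (is.data.frame(reference)) reference$sequence[[1]] else reference
  chrom <- if (is.data.frame(reference)) reference$id[[1]] else "ref"
  L <- nchar(sequence)
  seeds <- derive_seeds(seed, 2L)
  plus_states <- methylome[methylome$strand == "+", , drop = FALSE]
  minus_states <- methylome[methylome$strand == "-", , drop = FALSE]
  conv_p <- bisulfite_convert(sequence, plus_states, under_conversion,
                              over_conversion, seeds[1])
  minus_frame <- minus_states
  minus_frame$pos <- L - 1L - minus_states$pos  # into revcomp coordinates
  conv_m <- bisulfite_convert(revcomp(sequence), minus_frame, under_conversion,
                              over_conversion, seeds[2])
  ev_m <- conv_m$events
  ev_m$pos <- L - 1L - ev_m$pos  # back to plus-strand coordinates
  ev_p <- conv_p$events
  ev_p$strand <- "+"
  ev_m$strand <- "-"
  list(plus = conv_p$sequence, minus = conv_m$sequence, length = L,
       chrom = chrom, events = rbind(ev_p, ev_m))
}

#' Simulate genomic bisulfite reads with truth intervals
#'
#' Reads start uniformly along the genome and derive from either converted
#' strand with equal probability. A minus-strand read is the corresponding
#' slice of the converted minus strand (i.e. reverse-complement orientation
#' relative to plus coordinates). With `paired = TRUE`, each fragment yields a
#' mate-1 read from the fragment start (template orientation) and a mate-2
#' read from the fragment end, sequenced toward the start — mate 2 is the
#' reverse complement of the converted template slice, recorded in the truth
#' sidecar as `orient = "revcomp"` so downstream counting can normalise it.
#'
#' @param converted Output of [convert_both_strands()].
#' @param n_reads Number of reads (or fragments when `paired = TRUE`).
#' @param read_len Read length; must not exceed the genome length.
#' @param paired Generate mate pairs.
#' @param insert_len Fragment length for paired mode (default `2.5 * read_len`,
#'   clipped to the genome).
#' @param seed Integer seed.
#' @return List with `reads` (data frame `id`, `sequence`) and `truth`
#'   (data frame `read_id`, `chrom`, `start`, `end`, `strand`, `mate`,
#'   `orient`; coordinates 0-based half-open on the plus strand).
#' @export
simulate_genomic_reads <- function(converted, n_reads, read_len,
                                   paired = FALSE, insert_len = NULL,
                                   seed = 1L) {
  L <- converted$length
  if (read_len > L) stop("`read_len` exceeds genome length", call. = FALSE)
  if (n_reads == 0) {
    empty_reads <- data.frame(id = character(), sequence = character(),
                              stringsAsFactors = FALSE)
    empty_truth <- data.frame(read_id = character(), chrom = character(),
                              start = integer(), end = integer(),
                              strand = character(), mate = integer(),
                              orient = character(), stringsAsFactors = FALSE)
    return(list(reads = empty_reads, truth = empty_truth))
  }
  if (paired) {
    if (is.null(insert_len)) insert_len <- min(L, as.integer(2.5 * read_len))
    insert_len <- max(insert_len, read_len)
    if (insert_len > L) insert_len <- L
  }
  span <- if (paired) insert_len else read_len
  sim <- with_seed(seed, {
    start <- sample.int(L - span + 1L, n_reads, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    list(start = start, strand = strand)
  })
  slice <- function(strand, start, end) {
    # sequence of the converted strand over plus interval [start, end),
    # in the strand's own orientation
    ifelse(strand == "+",
           substring(converted$plus, start + 1L, end),
           substring(converted$minus, L - end + 1L, L - start))
  }
  start1 <- sim$start
  end1 <- start1 + read_len
  if (!paired) {
    ids <- sprintf("read_%06d", seq_len(n_reads))
    reads <- data.frame(id = ids, sequence = slice(sim$strand, start1, end1),
                        stringsAsFactors = FALSE)
    truth <- data.frame(read_id = ids, chrom = converted$chrom,
                        start = start1, end = end1, strand = sim$strand,
                        mate = 1L, orient = "template",
                        stringsAsFactors = FALSE)
    return(list(reads = reads, truth = truth))
  }
  start2 <- sim$start + insert_len - read_len
  end2 <- start2 + read_len
  ids1 <- sprintf("frag_%06d/1", seq_len(n_reads))
  ids2 <- sprintf("frag_%06d/2", seq_len(n_reads))
  seq1 <- slice(sim$strand, start1, end1)
  seq2 <- revcomp(slice(sim$strand, start2, end2))
  reads <- data.frame(id = c(ids1, ids2), sequence = c(seq1, seq2),
                      stringsAsFactors = FALSE)
  truth <- data.frame(
    read_id = c(ids1, ids2), chrom = converted$chrom,
    start = c(start1, start2), end = c(end1, end2),
    strand = rep(sim$strand, 2),
    mate = rep(c(1L, 2L), each = n_reads),
    orient = rep(c("template", "revcomp"), each = n_reads),
    stringsAsFactors = FALSE
  )
  list(reads = reads, truth = truth)
}

#' Simulate molecule-resolved genomic bisulfite reads
#'
#' Every read derives from a distinct DNA molecule, as in a real bisulfite
#' library: per read, each covered cytosine draws its methylation state from
#' the per-context (or overridden per-site) probability and then its
#' conversion outcome independently. Per-site methylation percentages across
#' reads therefore centre on `100 * (p * (1 - v) + (1 - p) * u)`, with
#' binomial read-sampling noise — the model the downstream per-site analysis
#' assumes. (By contrast, [simulate_genomic_reads()] slices one frozen
#' converted genome, i.e. a single molecule resequenced.)
#'
#' @inheritParams assign_methylome
#' @inheritParams bisulfite_convert
#' @param reference Record (as from [generate_reference()]) or sequence
#'   string.
#' @param n_reads Number of single-end reads.
#' @param read_len Read length (<= reference length).
#' @param seed Integer seed.
#' @return List with `reads` and `truth` in the same layout as
#'   [simulate_genomic_reads()].
#' @export
simulate_methylome_reads <- function(reference, p_cpg, p_chg = 0, p_chh = 0,
                                     site_overrides = NULL,
                                     under_conversion = 0.05,
                                     over_conversion = 0,
                                     n_reads, read_len, seed = 1L) {
  sequence <- if (is.data.frame(reference)) reference$sequence[[1]] else reference
  chrom <- if (is.data.frame(reference)) reference$id[[1]] else "ref"
  L <- nchar(sequence)
  if (read_len > L) stop("`read_len` exceeds genome length", call. = FALSE)
  empty <- list(
    reads = data.frame(id = character(), sequence = character(),
                       stringsAsFactors = FALSE),
    truth = data.frame(read_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       strand = character(), mate = integer(),
                       orient = character(), stringsAsFactors = FALSE))
  if (n_reads == 0) return(empty)
  ctx <- cytosine_contexts(sequence)
  p_site <- c(CpG = p_cpg, CHG = p_chg, CHH = p_chh)[ctx$context]
  if (!is.null(site_overrides)) {
    ov_pos <- as.integer(names(site_overrides))
    missing <- setdiff(ov_pos, ctx$pos)
    if (length(missing)) {
      stop("site_overrides at non-cytosine position(s): ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    }
    idx <- match(ctx$pos, ov_pos)
    p_site[!is.na(idx)] <- site_overrides[idx[!is.na(idx)]]
  }
  # per strand frame: sorted C positions (0-based in the frame) and their p
  frames <- list()
  plus_rows <- ctx$strand == "+"
  o <- order(ctx$pos[plus_rows])
  frames[["+"]] <- list(pos = ctx$pos[plus_rows][o],
                        p = unname(p_site[plus_rows][o]),
                        seq = sequence)
  minus_rows <- !plus_rows
  mpos <- L - 1L - ctx$pos[minus_rows]
  o <- order(mpos)
  frames[["-"]] <- list(pos = mpos[o], p = unname(p_site[minus_rows][o]),
                        seq = revcomp(sequence))
  sim <- with_seed(seed, {
    start <- sample.int(L - read_len + 1L, n_reads, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    # frame-coordinate window start of each read
    fstart <- ifelse(strand == "+", start, L - (start + read_len))
    base <- substring(ifelse(strand == "+", frames[["+"]]$seq,
                             frames[["-"]]$seq),
                      fstart + 1L, fstart + read_len)
    mat <- matrix(unlist(strsplit(base, "", fixed = TRUE), use.names = FALSE),
                  nrow = n_reads, byrow = TRUE)
    for (st in c("+", "-")) {
      rows <- which(strand == st)
      if (!length(rows)) next
      fr <- frames[[st]]
      lo <- findInterval(fstart[rows] - 0.5, fr$pos)       # Cs before window
      hi <- findInterval(fstart[rows] + read_len - 0.5, fr$pos)
      k <- hi - lo
      has <- k > 0
      if (!any(has)) next
      read_idx <- rep(rows[has], k[has])
      c_idx <- sequence(k[has]) + rep(lo[has], k[has])
      meth <- runif(length(c_idx)) < fr$p[c_idx]
      r2 <- runif(length(c_idx))
      converted <- ifelse(meth, r2 < over_conversion,
                          r2 < 1 - under_conversion)
      off <- fr$pos[c_idx] - fstart[read_idx] + 1L
      hit <- converted
      if (any(hit)) mat[cbind(read_idx[hit], off[hit])] <- "T"
    }
    list(start = start, strand = strand,
         seqs = apply(mat, 1, paste, collapse = ""))
  })
  ids <- sprintf("read_%06d", seq_len(n_reads))
  list(
    reads = data.frame(id = ids, sequence = sim$seqs,
                       stringsAsFactors = FALSE),
    truth = data.frame(read_id = ids, chrom = chrom, start = sim$start,
                       end = sim$start + read_len, strand = sim$strand,
                       mate = 1L, orient = "template",
                       stringsAsFactors = FALSE)
  )
}

#' Simulate repeat-amplicon bisulfite reads from a mixture of methylation
#' levels
#'
#' Emulates bisulfite PCR of a repeat family followed by long-read sequencing
#' of the products. Each molecule draws a mixture component, then a
#' per-molecule CpG methylation level from that component's beta distribution
#' (mean `levels[j]`, concentration `dispersion[j]`), then independent
#' Bernoulli states at every CpG cytosine of the amplicon template; non-CpG
#' cytosines are unmethylated. Conversion applies per molecule with the given
#' under-/over-conversion rates. Incomplete sequencing is emulated by
#' truncating a fraction of reads to a uniform length >= `min_observed_len`.
#'
#' @param amplicon List as from [consensus_amplicon()] (elements `consensus`
#'   and `primers`), or a list with `template` — a plain sequence string
#'   already in read orientation — to bypass primer location.
#' @param weights,levels,dispersion Mixture specification: component weights
#'   (summing to 1), per-component mean CpG methylation levels in `[0,1]`, and
#'   beta concentration parameters (higher = tighter). 1 to 4 components.
#' @param under_conversion,over_conversion Conversion error rates, as in
#'   [bisulfite_convert()].
#' @param n_molecules Number of product molecules to simulate.
#' @param p_full_length Probability a molecule is sequenced full length;
#'   otherwise its read is truncated to a uniform length in
#'   `[min_observed_len, L]`.
#' @param min_observed_len Truncation floor (>= 1).
#' @param pcr_bias Optional per-molecule rejection probability applied when a
#'   molecule carries an unmethylated CpG inside a priming region (off by
#'   default; emulates amplification bias against unmethylated priming sites).
#' @param seed Integer seed.
#' @param bisulfite_space Passed to [locate_amplicon()] when primers are
#'   located (default `TRUE`, matching bisulfite-PCR primer design).
#' @return List with `reads` (`id`, `sequence`), `truth` (`read_id`,
#'   `component`, `level`, `length`), `template` (the amplicon template in
#'   read orientation) and `cpg_positions` (0-based, template coordinates).
#' @export
simulate_amplicon_reads <- function(amplicon, weights = 1, levels = 0.7,
                                    dispersion = 50,
                                    under_conversion = 0.05,
                                    over_conversion = 0,
                                    n_molecules = 1000,
                                    p_full_length = 0.7,
                                    min_observed_len = 60,
                                    pcr_bias = 0,
                                    seed = 1L,
                                    bisulfite_space = TRUE) {
  k <- length(weights)
  stopifnot(k >= 1, k <= 4, length(levels) == k, length(dispersion) == k,
            abs(sum(weights) - 1) < 1e-9, all(levels >= 0), all(levels <= 1),
            min_observed_len >= 1)
  if (n_molecules < 1) stop("`n_molecules` must be >= 1", call. = FALSE)
  if (!is.null(amplicon$template)) {
    template <- amplicon$template
    primer_len <- c(0L, 0L)
  } else {
    def <- locate_amplicon(amplicon$primers, amplicon$consensus,
                           bisulfite_space = bisulfite_space)
    cons_seq <- amplicon$consensus$sequence[[1]]
    template <- substring(cons_seq, def$start + 1L, def$end)
    if (def$orientation == "-") template <- revcomp(template)
    primer_len <- c(nchar(amplicon$primers$forward),
                    nchar(amplicon$primers$reverse))
  }
  L <- nchar(template)
  tchars <- seq_chars(template)
  ctx <- cytosine_contexts(template)
  plus_c <- ctx[ctx$strand == "+", , drop = FALSE]
  cpg_pos <- plus_c$pos[plus_c$context == "CpG"]
  nonCpG_pos <- plus_c$pos[plus_c$context != "CpG"]
  seeds <- derive_seeds(seed, 1L)
  out <- with_seed(seeds[1], {
    comp <- sample.int(k, n_molecules, replace = TRUE, prob = weights)
    level <- rbeta(n_molecules, levels[comp] * dispersion[comp],
                   (1 - levels[comp]) * dispersion[comp])
    # degenerate beta (level 0 or 1) returns NaN; pin to the mean
    level[!is.finite(level)] <- levels[comp[!is.finite(level)]]
    n_cpg <- length(cpg_pos)
    meth <- matrix(runif(n_molecules * n_cpg) < level, n_molecules, n_cpg)
    # conversion outcomes: methylated convert w.p. v; unmethylated w.p. 1-u
    conv_cpg <- matrix(runif(n_molecules * n_cpg), n_molecules, n_cpg)
    converted_cpg <- ifelse(meth, conv_cpg < over_conversion,
                            conv_cpg < 1 - under_conversion)
    n_non <- length(nonCpG_pos)
    converted_non <- matrix(runif(n_molecules * n_non) < 1 - under_conversion,
                            n_molecules, n_non)
    keep <- rep(TRUE, n_molecules)
    if (pcr_bias > 0 && n_cpg > 0) {
      in_primer <- cpg_pos < primer_len[1] | cpg_pos >= L - primer_len[2]
      has_unmeth_priming <- rowSums(!meth[, in_primer, drop = FALSE]) > 0
      keep <- !(has_unmeth_priming & runif(n_molecules) < pcr_bias)
    }
    full <- runif(n_molecules) < p_full_length
    obs_len <- ifelse(full, L,
                      min_observed_len +
                        floor(runif(n_molecules) * (L - min_observed_len + 1)))
    m <- matrix(tchars, n_molecules, L, byrow = TRUE)
    if (n_cpg > 0 && any(converted_cpg)) {
      idx <- which(converted_cpg, arr.ind = TRUE)
      m[cbind(idx[, 1], cpg_pos[idx[, 2]] + 1L)] <- "T"
    }
    if (n_non > 0 && any(converted_non)) {
      idx <- which(converted_non, arr.ind = TRUE)
      m[cbind(idx[, 1], nonCpG_pos[idx[, 2]] + 1L)] <- "T"
    }
    seqs <- apply(m, 1, paste, collapse = "")
    seqs <- substring(seqs, 1L, obs_len)
    list(comp = comp, level = level, seqs = seqs, obs_len = obs_len,
         keep = keep)
  })
  ids <- sprintf("mol_%06d", seq_len(n_molecules))
  reads <- data.frame(id = ids[out$keep], sequence = out$seqs[out$keep],
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = ids[out$keep], component = out$comp[out$keep],
                      level = out$level[out$keep],
                      length = as.integer(out$obs_len[out$keep]),
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, template = template,
       cpg_positions = cpg_pos)
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping gene intervals uniformly along a chromosome, for use
#' as the BED annotation consumed by [annotate_sites()].
#'
#' @param n_genes Number of genes to attempt (overlapping draws are dropped).
#' @param genome_length Chromosome length in bases.
#' @param mean_len Mean gene length (exponential with this mean, floored at
#'   200 b).
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return Interval data frame (`chrom`, `start`, `end`, `name`, `strand`).
#' @export
generate_genes <- function(n_genes, genome_length, mean_len = 2000,
                           chrom = "ref", seed = 1L) {
  with_seed(seed, {
    len <- pmax(200L, as.integer(stats::rexp(n_genes, 1 / mean_len)))
    len <- pmin(len, genome_length)
    start <- as.integer(floor(runif(n_genes) * (genome_length - len + 1)))
    o <- order(start)
    start <- start[o]; len <- len[o]
    end <- start + len
    keep <- logical(n_genes)
    last_end <- -1L
    for (i in seq_len(n_genes)) {
      if (start[i] > last_end) {
        keep[i] <- TRUE
        last_end <- end[i]
      }
    }
    data.frame(chrom = chrom, start = start[keep], end = end[keep],
               name = sprintf("gene_%04d", seq_len(sum(keep))),
               strand = "+", stringsAsFactors = FALSE)
  })
}
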