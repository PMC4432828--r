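#' Estimate the bisulfite under-conversion rate from an unmethylated spike-in
#'
#' The spike-in (phage-lambda-like control) is fully unmethylated by
#' construction, so every cytosine retained as C in a read reflects a
#' conversion failure. The estimator accumulates, over all reads placed on the
#' spike-in by their truth intervals, the number of reference-C positions read
#' as C (`c_c_matches`) and the total read coverage of reference-C positions
#' (`c_coverage`); the under-conversion rate is their ratio and conversion
#' efficiency is `100 * (1 - rate)`.
#'
#' Only the strand a read derives from contributes cytosine positions:
#' minus-strand reads are assessed against the reverse complement of the
#' reference (conversion is strand-specific chemistry). Read bases `N` are
#' excluded from coverage.
#'
#' @param reads Data frame (`id`, `sequence`) of spike-in reads.
#' @param truth Truth sidecar (`read_id`, `start`, `end`, `strand`, and
#'   optionally `orient`) as produced by [simulate_genomic_reads()].
#' @param spike_in_reference Record or sequence string of the spike-in.
#' @return List of class `bs_conversion_estimate` with `c_c_matches`,
#'   `c_coverage`, `under_conversion_rate`, `efficiency_percent`.
#' @export
estimate_under_conversion <- function(reads, truth, spike_in_reference) {
  sequence <- if (is.data.frame(spike_in_reference)) {
    spike_in_reference$sequence[[1]]
  } else {
    spike_in_reference
  }
  L <- nchar(sequence)
  ref_plus <- seq_chars(sequence)
  ref_minus <- seq_chars(revcomp(sequence))
  tr <- truth[match(reads$id, truth$read_id), , drop = FALSE]
  if (anyNA(tr$start)) {
    stop("truth sidecar is missing read id(s): ",
         paste(head(reads$id[is.na(tr$start)], 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(tr$start < 0 | tr$end > L)) {
    stop("truth interval(s) outside the spike-in reference", call. = FALSE)
  }
  orient <- if (!is.null(tr$orient)) tr$orient else rep("template", nrow(tr))
  matches <- 0L
  coverage <- 0L
  for (i in seq_len(nrow(reads))) {
    rd <- reads$sequence[[i]]
    if (orient[i] == "revcomp") rd <- revcomp(rd)
    rchars <- seq_chars(rd)
    if (tr$strand[i] == "+") {
      refw <- ref_plus[(tr$start[i] + 1L):tr$end[i]]
    } else {
      refw <- ref_minus[(L - tr$end[i] + 1L):(L - tr$start[i])]
    }
    is_c <- refw == "C" & rchars != "N"
    coverage <- coverage + sum(is_c)
    matches <- matches + sum(is_c & rchars == "C")
  }
  if (coverage == 0) {
    stop("no cytosine positions covered by the spike-in reads", call. = FALSE)
  }
  rate <- matches / coverage
  structure(
    list(c_c_matches = matches, c_coverage = coverage,
         under_conversion_rate = rate,
         efficiency_percent = 100 * (1 - rate)),
    class = "bs_conversion_estimate"
  )
}

#' @export
print.bs_conversion_estimate <- function(x, ...) {
  cat(sprintf(
    "Bisulfite conversion estimate: %d/%d C-C matches (rate %.4f, efficiency %.2f%%)\n",
    x$c_c_matches, x$c_coverage, x$under_conversion_rate,
    x$efficiency_percent))
  invisible(x)
}

#' Conversion-efficiency QC verdict
#'
#' @param estimate A `bs_conversion_estimate` from
#'   [estimate_under_conversion()].
#' @param min_efficiency_percent Pass threshold (default 95, the efficiency
#'   the spike-in is expected to certify); the boundary passes.
#' @param sample Sample label for the report row.
#' @return List with `pass` (logical) and `report` (one-row data frame:
#'   sample, c_c_matches, c_coverage, under_conversion_rate,
#'   efficiency_percent, verdict).
#' @export
qc_verdict <- function(estimate, min_efficiency_percent = 95,
                       sample = "sample") {
  stopifnot(inherits(estimate, "bs_conversion_estimate"))
  pass <- estimate$efficiency_percent >= min_efficiency_percent
  report <- data.frame(
    sample = sample,
    c_c_matches = estimate$c_c_matches,
    c_coverage = estimate$c_coverage,
    under_conversion_rate = estimate$under_conversion_rate,
    efficiency_percent = estimate$efficiency_percent,
    verdict = if (pass) "pass" else "fail",
    stringsAsFactors = FALSE
  )
  list(pass = pass, report = report)
}
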