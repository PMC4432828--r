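#' Read sequences from FASTA or FASTQ
#'
#' Parses a FASTA or FASTQ file into a plain data frame of records. Sequences
#' are upper-cased; FASTA line wrapping is collapsed. Parsing is delegated to
#' Biostrings, which enforces the standard formats (a FASTQ record whose
#' quality string length differs from its sequence length is rejected).
#'
#' @param path Path to the file.
#' @param format `"FASTA"` or `"FASTQ"` (case-insensitive).
#' @return A data frame with columns `id`, `sequence`, `description` and, for
#'   FASTQ, `quality` (character; `NA` for FASTA input). Records appear in file
#'   order.
#' @seealso [write_sequences()]
#' @export
read_sequences <- function(path, format = c("FASTA", "FASTQ")) {
  format <- toupper(match.arg(toupper(format), c("FASTA", "FASTQ")))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "FASTA") {
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) stop("FASTA parse error in '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    qual <- rep(NA_character_, length(set))
  } else {
    validate_fastq_layout(path)
    # suppressWarnings: Biostrings warns about dropped metadata columns when
    # materialising the quality strings
    parsed <- suppressWarnings(tryCatch({
      set <- Biostrings::readQualityScaledDNAStringSet(path)
      list(set = set, qual = as.character(Biostrings::quality(set)))
    }, error = function(e) stop("FASTQ parse error in '", path, "': ",
                                conditionMessage(e), call. = FALSE)))
    set <- parsed$set
    qual <- parsed$qual
  }
  full <- names(set)
  if (is.null(full)) full <- rep("", length(set))
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids in '", path, "': ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  data.frame(
    id = id,
    sequence = toupper(as.character(set)),
    description = desc,
    quality = qual,
    stringsAsFactors = FALSE
  )
}

#' Write sequences to FASTA or FASTQ
#'
#' @param records Data frame with columns `id` and `sequence`; optional
#'   `description` (appended to the header) and `quality` (FASTQ only; when
#'   absent a constant quality `"I"` is used, as the simulator does not model
#'   base qualities).
#' @param path Output path.
#' @param format `"FASTA"` or `"FASTQ"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("FASTA", "FASTQ")) {
  format <- toupper(match.arg(toupper(format), c("FASTA", "FASTQ")))
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  validate_alphabet(records$sequence, records$id)
  nm <- records$id
  if (!is.null(records$description)) {
    has_desc <- !is.na(records$description) & nzchar(records$description)
    nm[has_desc] <- paste(nm[has_desc], records$description[has_desc])
  }
  if (format == "FASTA") {
    set <- Biostrings::DNAStringSet(records$sequence)
    names(set) <- nm
    Biostrings::writeXStringSet(set, path, format = "fasta", width = 70L)
  } else {
    qual <- records$quality
    if (is.null(qual)) qual <- rep(NA_character_, nrow(records))
    missing_q <- is.na(qual)
    qual[missing_q] <- vapply(
      nchar(records$sequence[missing_q]),
      function(n) strrep("I", n), character(1)
    )
    if (any(nchar(qual) != nchar(records$sequence))) {
      stop("quality length differs from sequence length for read(s): ",
           paste(head(records$id[nchar(qual) != nchar(records$sequence)], 5),
                 collapse = ", "), call. = FALSE)
    }
    set <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(records$sequence),
      Biostrings::PhredQuality(qual)
    ))
    names(set) <- nm
    Biostrings::writeQualityScaledXStringSet(set, path)
  }
  invisible(path)
}

# Record-layout QC ahead of Biostrings decoding: Biostrings silently pads a
# short quality string, so the FASTQ contract (4-line records, '@' and '+'
# markers, quality length == sequence length) is enforced here, with line
# numbers in the error.
validate_fastq_layout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0) {
    stop("FASTQ parse error in '", path, "': truncated record at line ",
         (length(lines) %/% 4) * 4 + 1, call. = FALSE)
  }
  first <- seq(1L, length(lines), by = 4L)
  bad_hdr <- first[!startsWith(lines[first], "@")]
  if (length(bad_hdr)) {
    stop("FASTQ parse error in '", path, "': missing '@' header at line ",
         bad_hdr[1], call. = FALSE)
  }
  bad_sep <- first[!startsWith(lines[first + 2L], "+")]
  if (length(bad_sep)) {
    stop("FASTQ parse error in '", path, "': missing '+' separator at line ",
         bad_sep[1] + 2L, call. = FALSE)
  }
  mism <- first[nchar(lines[first + 1L]) != nchar(lines[first + 3L])]
  if (length(mism)) {
    stop("FASTQ parse error in '", path, "': quality length differs from ",
         "sequence length at line ", mism[1] + 3L, call. = FALSE)
  }
  invisible(TRUE)
}

validate_alphabet <- function(sequences, ids = NULL) {
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    lab <- if (is.null(ids)) which(bad) else ids[bad]
    stop("sequence(s) contain characters outside {A,C,G,T,N}: ",
         paste(head(lab, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read genomic intervals from a BED file
#'
#' BED's 0-based half-open convention is preserved: the returned `start` is
#' 0-based inclusive and `end` exclusive, so `end - start` is the interval
#' length. Strand defaults to `"+"` when the BED file carries none.
#'
#' @param path Path to a BED file (>= 3 columns).
#' @return Data frame with columns `chrom`, `start`, `end`, `name`, `strand`.
#'   An empty file yields a zero-row data frame.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), strand = character(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("BED parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0) return(empty)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, length(gr))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # back to BED 0-based
    end = BiocGenerics::end(gr),
    name = nm,
    strand = strand,
    stringsAsFactors = FALSE
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(intervals) {
  bad <- which(!(intervals$start >= 0 & intervals$start < intervals$end))
  if (length(bad)) {
    stop("invalid interval(s) (need 0 <= start < end) at record index: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write intervals as BED
#'
#' @param intervals Data frame with `chrom`, `start` (0-based), `end`
#'   (exclusive); optional `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  validate_intervals(intervals)
  n <- nrow(intervals)
  bed <- data.frame(
    chrom = intervals$chrom,
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = if (!is.null(intervals$name)) intervals$name else rep(".", n),
    score = if (!is.null(intervals$score)) intervals$score else rep(0L, n),
    strand = if (!is.null(intervals$strand)) intervals$strand else rep("+", n),
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tabular result as TSV (with header, stable column order)
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Shipped repeat consensus amplicon sequences and primers
#'
#' Returns the Alu or LINE-1 consensus amplicon shipped with the package,
#' together with its PCR primer pair. The Alu consensus is in genomic space
#' (cytosines intact); the LINE-1 consensus is a bisulfite-space consensus
#' printed in the orientation of the reverse primer, which
#' [locate_amplicon()] handles by searching both orientations.
#'
#' @param which `"alu"` or `"line1"`.
#' @return A list with elements `consensus` (one-row data frame as from
#'   [read_sequences()]) and `primers` (list with `forward`, `reverse`).
#' @export
consensus_amplicon <- function(which = c("alu", "line1")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_consensus.fasta"),
                      package = "bsmethr", mustWork = TRUE)
  primers <- list(
    alu = list(forward = "GAGGTCGAGGCGGGAGGATCG",
               reverse = "CGTTTAGGTTGGAGTGTAGTGGCGCG"),
    line1 = list(forward = "ATTTTTGTATTTTTATTTGAGGTAT",
                 reverse = "AACTATAATAAACTCCACCCAATTC")
  )[[which]]
  list(consensus = read_sequences(path, "FASTA"), primers = primers)
}
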