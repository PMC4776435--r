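# Coding-sequence filtering, GC computation, isochore binning and
# expression-by-bin testing.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read coding sequences from a FASTA file
#'
#' Sequences are upper-cased; the header token before the first whitespace
#' is taken as the CDS id. Duplicate ids are an error; an empty file yields
#' an empty table with a warning; a file whose first non-blank line is not
#' a header is reported with its line number.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `cds_id`, `sequence`, `length`,
#'   `gc_fraction`.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(data.frame(cds_id = character(0), sequence = character(0),
                      length = integer(0), gc_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA in ", path, ": line ", nonblank[1],
         " is not a header line", call. = FALSE)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate CDS id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  seq_chr <- toupper(as.character(seqs))
  data.frame(
    cds_id = ids,
    sequence = unname(seq_chr),
    length = unname(Biostrings::width(seqs)),
    gc_fraction = gc_fraction(unname(seq_chr)),
    stringsAsFactors = FALSE
  )
}

#' GC fraction of nucleotide sequences
#'
#' (#G + #C) / length, vectorized over a character vector. Ambiguity codes
#' other than G/C count toward the denominator only; intended use is on
#' unambiguous sequences.
#'
#' @param sequence character vector of non-empty nucleotide strings.
#' @return Numeric vector in \[0, 1\].
#' @export
gc_fraction <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(sequence))) {
    stop("empty sequence has no GC fraction", call. = FALSE)
  }
  ss <- Biostrings::DNAStringSet(sequence)
  as.numeric(Biostrings::letterFrequency(ss, "GC")) /
    Biostrings::width(ss)
}

#' Filter coding sequences by the integrity rules
#'
#' A CDS is kept iff it is at least 100 bp long, contains only unambiguous
#' A/C/G/T, starts with ATG, ends with a stop codon (TAA/TAG/TGA) and — by
#' default, as part of start/stop integrity — has a length divisible by 3.
#' Each rejected record carries its first failing rule, checked in the
#' order length, ambiguous, start, stop, frame.
#'
#' @param records data.frame as from [read_cds_fasta()].
#' @param min_length minimum length in bp (default 100).
#' @param enforce_frame require length divisible by 3 (default TRUE).
#' @return list with `kept` (data.frame) and `rejected` (data.frame with a
#'   `reason` column); the two partition the input.
#' @export
filter_cds <- function(records, min_length = 100, enforce_frame = TRUE) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (!n) {
    return(list(kept = records,
                rejected = cbind(records, reason = character(0))))
  }
  seqs <- toupper(records$sequence)
  len <- nchar(seqs)
  reason <- rep(NA_character_, n)
  fail <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  fail(len < min_length, "length")
  fail(grepl("[^ACGT]", seqs), "ambiguous")
  fail(substr(seqs, 1, 3) != "ATG", "start")
  fail(!substr(seqs, len - 2, len) %in% .STOP_CODONS, "stop")
  if (enforce_frame) fail(len %% 3 != 0, "frame")
  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- NULL
  rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Define an isochore GC binning
#'
#' Three ascending GC-percent cutpoints define four half-open intervals
#' \[low, high); the last interval is unbounded above. The default labels
#' follow the light/heavy isochore nomenclature L, H1, H2, H3. No default
#' cutpoints are shipped for real analyses: the class limits of a genome
#' must be supplied by the user.
#'
#' @param cutpoints ascending numeric vector of 3 GC-percent thresholds.
#' @param labels 4 bin names, lightest first.
#' @return An `isochore_binning` list.
#' @export
isochore_binning <- function(cutpoints, labels = c("L", "H1", "H2", "H3")) {
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) != length(labels) - 1L) {
    stop("need exactly ", length(labels) - 1L, " cutpoints for ",
         length(labels), " bins", call. = FALSE)
  }
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    stop("cutpoints must be strictly ascending", call. = FALSE)
  }
  structure(list(cutpoints = cutpoints, labels = labels),
            class = "isochore_binning")
}

#' Assign coding sequences to isochore GC bins
#'
#' Each record's GC percent (gc_fraction * 100) is placed in its half-open
#' interval; a value exactly at a cutpoint falls in the upper bin.
#'
#' @param records data.frame with a `gc_fraction` column.
#' @param binning an [isochore_binning()].
#' @return `records` with a `bin` factor column; bin counts are attached as
#'   attribute `bin_counts`.
#' @export
assign_bins <- function(records, binning) {
  stopifnot(is.data.frame(records), inherits(binning, "isochore_binning"))
  gc_pct <- records$gc_fraction * 100
  records$bin <- cut(gc_pct,
                     breaks = c(-Inf, binning$cutpoints, Inf),
                     labels = binning$labels,
                     right = FALSE)
  attr(records, "bin_counts") <- table(records$bin)
  records
}

#' Test expression differences across isochore bins
#'
#' Kruskal-Wallis test (with tie correction) of the expression level across
#' all non-empty bins, plus a two-sided Mann-Whitney test restricted to the
#' two designated main bins.
#'
#' @param records data.frame with `bin` and `expression` columns; rows with
#'   missing expression are dropped.
#' @param main_bins the two main bins for the pairwise test (default H1,
#'   H2).
#' @param correct continuity correction for the pairwise test; disable to
#'   make the two-group Kruskal-Wallis chi-square equal the squared
#'   Mann-Whitney z.
#' @return list with `kw_h`, `kw_df`, `kw_p`, `pairwise` (a `rank_test`,
#'   or NULL if a main bin is empty), `bin_summary` (data.frame).
#' @export
expression_by_bin <- function(records, main_bins = c("H1", "H2"),
                              correct = TRUE) {
  stopifnot(is.data.frame(records))
  if (is.null(records$bin) || is.null(records$expression)) {
    stop("records need 'bin' and 'expression' columns", call. = FALSE)
  }
  keep <- is.finite(records$expression)
  expr <- records$expression[keep]
  bin <- droplevels(factor(records$bin[keep]))
  if (nlevels(bin) < 2) {
    stop("need at least 2 non-empty bins with expression values",
         call. = FALSE)
  }
  kw <- stats::kruskal.test(expr, bin)
  pairwise <- NULL
  if (all(main_bins %in% levels(bin))) {
    pairwise <- mann_whitney(expr[bin == main_bins[1]],
                             expr[bin == main_bins[2]],
                             alternative = "two_sided", correct = correct)
  }
  bin_summary <- do.call(rbind, lapply(levels(bin), function(b) {
    v <- expr[bin == b]
    data.frame(bin = b, n = length(v), median = stats::median(v),
               mean = mean(v), stringsAsFactors = FALSE)
  }))
  list(
    kw_h = unname(kw$statistic),
    kw_df = unname(kw$parameter),
    kw_p = kw$p.value,
    pairwise = pairwise,
    bin_summary = bin_summary
  )
}
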