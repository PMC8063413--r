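#' Transcript record
#'
#' Container for one transcript sequence with an RNA class label and, for
#' pri-miR transcripts, the location of the pre-miR hairpin within the
#' mature transcript. All coordinates are 0-based, half-open, on the sense
#' strand of the mature transcript.
#'
#' @param id Transcript identifier.
#' @param rna_class One of `"CDS"`, `"UTR5"`, `"UTR3"`, `"lncRNA"`,
#'   `"pri_miR"`.
#' @param sequence Nucleotide string over A/C/G/T (N permitted).
#' @param premir_interval Optional integer vector `c(start, end)` giving the
#'   pre-miR hairpin as a 0-based half-open interval in transcript
#'   coordinates; only meaningful for `rna_class == "pri_miR"`.
#' @param source_coords Optional list `(chrom, start, end, strand)` recording
#'   genomic provenance; not used by any computation.
#' @return An object of class `transcript_record`.
#' @export
transcript_record <- function(id, rna_class, sequence, premir_interval = NULL,
                              source_coords = NULL) {
  rna_class <- match.arg(rna_class, c("CDS", "UTR5", "UTR3", "lncRNA", "pri_miR"))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("transcript '", id, "': empty sequence")
  check_alphabet(sequence)
  n <- nchar(sequence)
  if (!is.null(premir_interval)) {
    premir_interval <- as.integer(premir_interval)
    if (length(premir_interval) != 2L ||
        premir_interval[1] < 0L || premir_interval[2] > n ||
        premir_interval[1] >= premir_interval[2]) {
      stop("transcript '", id, "': premir_interval must lie within [0, ", n, ")")
    }
  }
  structure(
    list(id = as.character(id), rna_class = rna_class, sequence = sequence,
         premir_interval = premir_interval, source_coords = source_coords),
    class = "transcript_record"
  )
}

#' @export
print.transcript_record <- function(x, ...) {
  cat("<transcript_record> ", x$id, " [", x$rna_class, "], ",
      nchar(x$sequence), " nt", sep = "")
  if (!is.null(x$premir_interval)) {
    cat(", pre-miR [", x$premir_interval[1], ", ", x$premir_interval[2], ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

# Error at the first offending offset so malformed FASTA is easy to trace.
check_alphabet <- function(sequence) {
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0) {
    stop("invalid base '", substr(sequence, bad, bad),
         "' at 0-based offset ", bad - 1L)
  }
  invisible(TRUE)
}

as_transcript_list <- function(transcripts) {
  if (inherits(transcripts, "transcript_record")) return(list(transcripts))
  if (!is.list(transcripts) ||
      !all(vapply(transcripts, inherits, logical(1), "transcript_record"))) {
    stop("expected a transcript_record or a list of them")
  }
  transcripts
}
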