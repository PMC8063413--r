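#' Three-frame forward translation
#'
#' Translates a transcript in its three forward frames with the standard
#' nuclear genetic code. Stop codons are rendered `*`; any codon containing
#' N translates to `X`. Each frame also carries its maximal stop-free
#' segments (the only regions a translated peptide can come from).
#'
#' @param sequence Nucleotide string over A/C/G/T/N or a
#'   [transcript_record].
#' @return List of three `frame_translation` objects, one per frame 0/1/2,
#'   each a list with `transcript_id`, `frame`, `peptide_string` and
#'   `segments` (data frame with `aa_offset`, `peptide`).
#' @examples
#' translate3("ATGGCTTAA")[[1]]$peptide_string  # "MA*"
#' @export
translate3 <- function(sequence) {
  transcript_id <- NA_character_
  if (inherits(sequence, "transcript_record")) {
    transcript_id <- sequence$id
    sequence <- sequence$sequence
  }
  sequence <- toupper(as.character(sequence))
  check_alphabet(sequence)
  n <- nchar(sequence)
  if (n < 3L) warning("sequence shorter than one codon; translations are empty")
  lapply(0:2, function(frame) {
    ncod <- max(0L, (n - frame) %/% 3L)
    pep <- if (ncod == 0L) "" else {
      pos <- frame + 3L * (seq_len(ncod) - 1L) + 1L
      translate_codons(substring(sequence, pos, pos + 2L))
    }
    structure(list(transcript_id = transcript_id, frame = frame,
                   peptide_string = pep, segments = stop_free_segments(pep)),
              class = "frame_translation")
  })
}

# Maximal '*'-free substrings with their 0-based aa offsets.
stop_free_segments <- function(peptide_string) {
  if (!nzchar(peptide_string)) {
    return(data.frame(aa_offset = integer(), peptide = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(peptide_string, "*", fixed = TRUE)[[1]]
  lens <- nchar(parts)
  offs <- cumsum(c(0L, lens + 1L))[seq_along(parts)]
  keep <- lens > 0L
  data.frame(aa_offset = offs[keep], peptide = parts[keep],
             stringsAsFactors = FALSE)
}

#' Locate ribo-seq sORF peptides in transcript translations
#'
#' Exact, case-insensitive substring search of each peptide against the
#' three forward-frame translations of each transcript. Every occurrence is
#' reported. A match can never span a stop codon because peptides contain no
#' `*`. Peptides shorter than `min_len` are dropped; peptides with
#' characters outside the 20-residue alphabet (plus X) are rejected with a
#' warning giving their count.
#'
#' @param transcripts A [transcript_record] or list of them (or a
#'   precomputed list of `translate3()` outputs, named by transcript).
#' @param peptides Data frame with columns `peptide_id` and `peptide`, or a
#'   character vector (ids taken from names or generated).
#' @param min_len Minimum peptide length considered (default 7; shorter
#'   sequences match too promiscuously to be informative).
#' @return Data frame of class `peptide_matches`, ordered by
#'   `(transcript_id, frame, aa_offset, peptide_id)`, with columns
#'   `peptide_id`, `peptide`, `transcript_id`, `frame`, `aa_offset`,
#'   `nt_start`, `nt_end` (0-based half-open transcript interval).
#' @export
match_peptides <- function(transcripts, peptides, min_len = 7L) {
  if (is.character(peptides)) {
    ids <- if (!is.null(names(peptides))) names(peptides) else
      sprintf("pep%04d", seq_along(peptides))
    peptides <- data.frame(peptide_id = ids, peptide = unname(peptides),
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("peptide_id", "peptide") %in% names(peptides)))
  peptides$peptide <- toupper(peptides$peptide)
  ok <- !grepl("[^ACDEFGHIKLMNPQRSTVWYX]", peptides$peptide)
  if (any(!ok)) {
    warning("rejected ", sum(!ok), " peptide(s) with invalid residues")
    peptides <- peptides[ok, , drop = FALSE]
  }
  peptides <- peptides[nchar(peptides$peptide) >= min_len, , drop = FALSE]
  if (!nrow(peptides)) return(empty_peptide_matches())

  translations <- as_translation_list(transcripts)
  out <- list()
  for (frames in translations) {
    for (ft in frames) {
      pep_str <- ft$peptide_string
      if (!nzchar(pep_str)) next
      for (i in seq_len(nrow(peptides))) {
        pep <- peptides$peptide[i]
        hit <- gregexpr(pep, pep_str, fixed = TRUE)[[1]]
        if (hit[1] == -1L) next
        aa_off <- as.integer(hit) - 1L
        out[[length(out) + 1L]] <- data.frame(
          peptide_id = peptides$peptide_id[i], peptide = pep,
          transcript_id = ft$transcript_id, frame = ft$frame,
          aa_offset = aa_off,
          nt_start = ft$frame + 3L * aa_off,
          nt_end = ft$frame + 3L * (aa_off + nchar(pep)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_peptide_matches())
  m <- do.call(rbind, out)
  m <- m[order(m$transcript_id, m$frame, m$aa_offset, m$peptide_id), ,
         drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("peptide_matches", "data.frame")
  m
}

empty_peptide_matches <- function() {
  structure(
    data.frame(peptide_id = character(), peptide = character(),
               transcript_id = character(), frame = integer(),
               aa_offset = integer(), nt_start = integer(),
               nt_end = integer(), stringsAsFactors = FALSE),
    class = c("peptide_matches", "data.frame")
  )
}

as_translation_list <- function(transcripts) {
  if (is.list(transcripts) && length(transcripts) &&
      all(vapply(transcripts, function(x)
        is.list(x) && all(vapply(x, inherits, logical(1), "frame_translation")),
        logical(1)))) {
    return(transcripts)
  }
  lapply(as_transcript_list(transcripts), translate3)
}

#' Summarize peptide matches over pri-miR transcripts
#'
#' Restricts matches to transcripts of class `pri_miR` and reports, per
#' pri-miR, the number of match records and of distinct matched peptides
#' (pri-miRs without matches are reported with 0). A peptide matching
#' several pri-miRs is counted once in the global distinct-peptide total and
#' once per transcript in the per-transcript counts; both numbers are
#' reported.
#'
#' @param matches Output of [match_peptides()].
#' @param transcripts List of [transcript_record]s carrying `rna_class`.
#' @return List of class `primir_match_summary` with `per_primir` (data
#'   frame: `transcript_id`, `n_matches`, `n_peptides`), `n_primirs`,
#'   `n_primirs_with_match`, `n_matched_peptides` (distinct),
#'   `n_match_records`.
#' @export
summarize_by_primir <- function(matches, transcripts) {
  transcripts <- as_transcript_list(transcripts)
  primir_ids <- vapply(
    Filter(function(tr) tr$rna_class == "pri_miR", transcripts),
    function(tr) tr$id, character(1))
  m <- matches[matches$transcript_id %in% primir_ids, , drop = FALSE]
  per <- data.frame(
    transcript_id = primir_ids,
    n_matches = vapply(primir_ids, function(id)
      sum(m$transcript_id == id), integer(1)),
    n_peptides = vapply(primir_ids, function(id)
      length(unique(m$peptide_id[m$transcript_id == id])), integer(1)),
    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  structure(list(per_primir = per,
                 n_primirs = length(primir_ids),
                 n_primirs_with_match = sum(per$n_matches > 0L),
                 n_matched_peptides = length(unique(m$peptide_id)),
                 n_match_records = nrow(m)),
            class = "primir_match_summary")
}

#' @export
print.primir_match_summary <- function(x, ...) {
  cat("Ribo-seq peptide matches in pri-miR transcripts\n")
  cat(sprintf("  %d of %d pri-miRs with >= 1 match; %d distinct peptides matched (%d match records)\n",
              x$n_primirs_with_match, x$n_primirs, x$n_matched_peptides,
              x$n_match_records))
  invisible(x)
}
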