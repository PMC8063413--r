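#' Default start-codon context matrix
#'
#' A Cavener-style Drosophila consensus for the initiation context: scored
#' positions are -4..-1 (the four bases before the ATG) and +4 (the first
#' base after it; the A of the ATG is +1). The -3 position carries the
#' highest weight, with A/C as its preferred set. Per-base scores lie in
#' [0, 1]; the position weights control each position's contribution to the
#' weight-normalized score. The favorability call this matrix supports is a
#' heuristic annotation, not a measurement of translation.
#'
#' @param threshold Score at or above which a context may be called
#'   favorable (default 0.5).
#' @return List with `scores` (4 x 5 matrix, rows A/C/G/T, columns
#'   `-4,-3,-2,-1,+4`), `weights`, `preferred_minus3`, `threshold`.
#' @export
kozak_pwm <- function(threshold = 0.5) {
  pos <- c("-4", "-3", "-2", "-1", "+4")
  scores <- matrix(0, nrow = 4, ncol = 5, dimnames = list(c("A", "C", "G", "T"), pos))
  scores["C", "-4"] <- 1.0; scores["A", "-4"] <- 0.5
  scores["A", "-3"] <- 1.0; scores["C", "-3"] <- 0.8
  scores["A", "-2"] <- 1.0; scores["C", "-2"] <- 0.5
  scores["A", "-1"] <- 1.0; scores["C", "-1"] <- 0.5
  scores["A", "+4"] <- 1.0; scores["G", "+4"] <- 0.5
  list(scores = scores,
       weights = c("-4" = 1, "-3" = 3, "-2" = 1, "-1" = 1, "+4" = 1),
       preferred_minus3 = c("A", "C"),
       threshold = threshold)
}

#' Score the translational context of a start codon
#'
#' Weight-normalized match of the bases at positions -4..-1 and +4 around an
#' ATG against a consensus matrix (default [kozak_pwm()]). The context is
#' called favorable when the score reaches the matrix threshold AND the -3
#' base belongs to the preferred set. Windows truncated by the transcript
#' end are scored over the available positions and flagged.
#'
#' @param sequence Nucleotide string or [transcript_record].
#' @param atg_pos 0-based offset of the A of the ATG.
#' @param pwm Consensus description as returned by [kozak_pwm()].
#' @return List of class `context_score` with `score` in [0, 1],
#'   `favorable`, `truncated`, `bases` (the scored bases, NA where outside
#'   the sequence) and `minus3`.
#' @export
context_score <- function(sequence, atg_pos, pwm = kozak_pwm()) {
  if (inherits(sequence, "transcript_record")) sequence <- sequence$sequence
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  atg_pos <- as.integer(atg_pos)
  if (atg_pos < 0L || atg_pos + 3L > n) stop("atg_pos outside sequence")
  if (substr(sequence, atg_pos + 1L, atg_pos + 3L) != "ATG") {
    stop("no ATG at 0-based offset ", atg_pos)
  }
  # 0-based offsets of scored positions -4..-1, +4
  offs <- c(atg_pos - 4L, atg_pos - 3L, atg_pos - 2L, atg_pos - 1L, atg_pos + 3L)
  inside <- offs >= 0L & offs < n
  if (!any(inside)) stop("context window entirely outside sequence")
  bases <- rep(NA_character_, 5L)
  bases[inside] <- substring(sequence, offs[inside] + 1L, offs[inside] + 1L)
  names(bases) <- colnames(pwm$scores)

  w <- pwm$weights[inside]
  b <- bases[inside]
  per_pos <- vapply(seq_along(b), function(i) {
    if (b[i] %in% rownames(pwm$scores)) pwm$scores[b[i], names(w)[i]] else 0
  }, numeric(1))
  score <- sum(w * per_pos) / sum(w)
  minus3 <- bases[["-3"]]
  favorable <- !is.na(minus3) && minus3 %in% pwm$preferred_minus3 &&
    score >= pwm$threshold
  structure(list(score = score, favorable = favorable,
                 truncated = !all(inside), bases = bases, minus3 = minus3),
            class = "context_score")
}

#' Select the candidate miORF of a pri-miR transcript
#'
#' Among ORFs lying wholly 5' of the pre-miR hairpin (stop codon ending at
#' or before the pre-miR start), selects the longest; ties go to the
#' 5'-most (first translated under ribosome scanning). Downstream in-frame
#' ATGs sharing the selected stop are reported as alternative starts
#' (ATG2, ...), and the start-codon context of the selected ATG is scored.
#'
#' @param transcript [transcript_record] of class `pri_miR` with
#'   `premir_interval` set.
#' @param min_aa Minimum peptide length (default 10).
#' @param mode ORF counting mode for candidate selection; alternative
#'   starts are always enumerated from the full in-frame ATG set.
#' @param pwm Context matrix for [context_score()].
#' @return Object of class `miorf_candidate` (list with `transcript_id`,
#'   `orf` one-row [find_orfs()] output, `upstream_of_premir`,
#'   `is_longest_upstream`, `alt_starts` data frame `(start_rank, start_nt,
#'   aa_len)`, `context`), or `NULL` when no ORF qualifies.
#' @export
select_miorf <- function(transcript, min_aa = 10L,
                         mode = c("maximal", "all"), pwm = kozak_pwm()) {
  mode <- match.arg(mode)
  stopifnot(inherits(transcript, "transcript_record"))
  if (transcript$rna_class != "pri_miR") {
    stop("transcript '", transcript$id, "' is not a pri_miR")
  }
  if (is.null(transcript$premir_interval)) {
    stop("transcript '", transcript$id, "' has no premir_interval")
  }
  premir_start <- transcript$premir_interval[1]
  hits <- find_orfs(transcript, min_aa = min_aa, mode = mode)
  up <- hits[hits$end_nt <= premir_start, , drop = FALSE]
  if (!nrow(up)) return(NULL)
  best <- up[order(-up$aa_len, up$start_nt), , drop = FALSE][1, , drop = FALSE]

  all_hits <- find_orfs(transcript, min_aa = 1L, mode = "all")
  alts <- all_hits[all_hits$frame == best$frame &
                     all_hits$end_nt == best$end_nt &
                     all_hits$start_nt > best$start_nt, , drop = FALSE]
  alts <- alts[order(alts$start_nt), , drop = FALSE]
  alt_starts <- data.frame(
    start_rank = best$start_rank + seq_len(nrow(alts)),
    start_nt = alts$start_nt, aa_len = alts$aa_len)

  structure(list(transcript_id = transcript$id, orf = best,
                 upstream_of_premir = TRUE, is_longest_upstream = TRUE,
                 alt_starts = alt_starts,
                 context = context_score(transcript, best$start_nt, pwm = pwm)),
            class = "miorf_candidate")
}

#' @export
print.miorf_candidate <- function(x, ...) {
  cat("<miorf_candidate> ", x$transcript_id, ": ", x$orf$aa_len,
      "-aa ORF at [", x$orf$start_nt, ", ", x$orf$end_nt, ") frame ",
      x$orf$frame, "\n", sep = "")
  cat(sprintf("  context score %.3f (%s); %d alternative in-frame start(s)\n",
              x$context$score,
              if (x$context$favorable) "favorable" else "not favorable",
              nrow(x$alt_starts)))
  invisible(x)
}

#' Apply a single-nucleotide variant to a transcript
#'
#' Substitutes one base after checking the reference allele; all annotation
#' must be recomputed from the returned record.
#'
#' @param transcript [transcript_record].
#' @param variant List or one-row data frame with `position` (0-based),
#'   `ref_base`, `alt_base`.
#' @return A new [transcript_record] with the substituted base.
#' @export
apply_variant <- function(transcript, variant) {
  stopifnot(inherits(transcript, "transcript_record"))
  pos <- as.integer(variant$position)
  seq <- transcript$sequence
  if (pos < 0L || pos >= nchar(seq)) stop("variant position outside transcript")
  obs <- substr(seq, pos + 1L, pos + 1L)
  if (obs != toupper(variant$ref_base)) {
    stop("reference mismatch at position ", pos, ": expected ",
         toupper(variant$ref_base), ", observed ", obs)
  }
  substr(seq, pos + 1L, pos + 1L) <- toupper(variant$alt_base)
  transcript_record(transcript$id, transcript$rna_class, seq,
                    premir_interval = transcript$premir_interval,
                    source_coords = transcript$source_coords)
}

#' Consequence of a variant on the candidate miORF
#'
#' Re-annotates the transcript after applying a variant and classifies the
#' effect on the selected miORF: `"none"` (unchanged), `"truncation"`
#' (same start, shorter peptide; `truncation_aa` = lost C-terminal
#' residues), `"elongation"` (same start, longer), `"start_lost"` (selected
#' start changed), or `"candidate_lost"`/`"candidate_gained"`.
#'
#' @inheritParams select_miorf
#' @param variant See [apply_variant()].
#' @return List of class `miorf_variant_effect` with `original`, `variant`
#'   (both `miorf_candidate` or NULL), `consequence`, `truncation_aa`.
#' @export
miorf_variant_effect <- function(transcript, variant, min_aa = 10L,
                                 mode = c("maximal", "all"), pwm = kozak_pwm()) {
  mode <- match.arg(mode)
  orig <- select_miorf(transcript, min_aa = min_aa, mode = mode, pwm = pwm)
  mutated <- apply_variant(transcript, variant)
  new <- select_miorf(mutated, min_aa = min_aa, mode = mode, pwm = pwm)
  consequence <- if (is.null(orig) && is.null(new)) "none"
    else if (is.null(orig)) "candidate_gained"
    else if (is.null(new)) "candidate_lost"
    else if (new$orf$start_nt != orig$orf$start_nt) "start_lost"
    else if (new$orf$aa_len < orig$orf$aa_len) "truncation"
    else if (new$orf$aa_len > orig$orf$aa_len) "elongation"
    else "none"
  truncation_aa <- if (consequence == "truncation")
    orig$orf$aa_len - new$orf$aa_len else NA_integer_
  structure(list(original = orig, variant = new, consequence = consequence,
                 truncation_aa = truncation_aa),
            class = "miorf_variant_effect")
}

#' Annotate candidate miORFs across a transcript set
#'
#' One row per pri-miR transcript: the selected miORF (if any), its context
#' score, alternative starts, and the number of peptide matches overlapping
#' the candidate's nucleotide interval (translation evidence).
#'
#' @param transcripts List of [transcript_record]s.
#' @param peptide_matches Optional [match_peptides()] output.
#' @inheritParams select_miorf
#' @return Data frame with columns `transcript_id`, `has_candidate`,
#'   `frame`, `start_nt`, `end_nt`, `aa_len`, `context_score`,
#'   `context_favorable`, `n_alt_starts`, `n_peptide_matches`.
#' @export
annotate_all <- function(transcripts, peptide_matches = NULL, min_aa = 10L,
                         mode = c("maximal", "all"), pwm = kozak_pwm()) {
  mode <- match.arg(mode)
  transcripts <- as_transcript_list(transcripts)
  pri <- Filter(function(tr) tr$rna_class == "pri_miR", transcripts)
  rows <- lapply(pri, function(tr) {
    cand <- select_miorf(tr, min_aa = min_aa, mode = mode, pwm = pwm)
    if (is.null(cand)) {
      return(data.frame(transcript_id = tr$id, has_candidate = FALSE,
                        frame = NA_integer_, start_nt = NA_integer_,
                        end_nt = NA_integer_, aa_len = NA_integer_,
                        context_score = NA_real_, context_favorable = NA,
                        n_alt_starts = NA_integer_, n_peptide_matches = 0L,
                        stringsAsFactors = FALSE))
    }
    n_ev <- 0L
    if (!is.null(peptide_matches) && nrow(peptide_matches)) {
      m <- peptide_matches[peptide_matches$transcript_id == tr$id, , drop = FALSE]
      n_ev <- sum(m$nt_start < cand$orf$end_nt & m$nt_end > cand$orf$start_nt)
    }
    data.frame(transcript_id = tr$id, has_candidate = TRUE,
               frame = cand$orf$frame, start_nt = cand$orf$start_nt,
               end_nt = cand$orf$end_nt, aa_len = cand$orf$aa_len,
               context_score = cand$context$score,
               context_favorable = cand$context$favorable,
               n_alt_starts = nrow(cand$alt_starts),
               n_peptide_matches = n_ev, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), has_candidate = logical(),
               frame = integer(), start_nt = integer(), end_nt = integer(),
               aa_len = integer(), context_score = numeric(),
               context_favorable = logical(), n_alt_starts = integer(),
               n_peptide_matches = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
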