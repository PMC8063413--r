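#' Find ATG-initiated open reading frames on the forward strand
#'
#' Scans all three forward frames for ORFs that start at an ATG and run to
#' the first in-frame stop codon (TAA/TAG/TGA). An ORF qualifies when its
#' peptide (excluding the stop) has at least `min_aa` residues. Codons
#' containing N are never treated as start or stop codons.
#'
#' Several in-frame ATGs can share one stop codon. `mode = "maximal"` keeps
#' only the 5'-most (start rank 1) ATG per (frame, stop) pair, i.e. one ORF
#' per stop; `mode = "all"` keeps every qualifying ATG, with `start_rank`
#' recording its 1-based rank among the in-frame ATGs sharing that stop.
#'
#' @param sequence Nucleotide string over A/C/G/T/N, or a
#'   [transcript_record].
#' @param min_aa Minimum peptide length in residues, stop excluded
#'   (default 10).
#' @param mode `"maximal"` (default) or `"all"`; see Details.
#' @param allow_open If `TRUE`, also report ORFs that reach the 3' end of
#'   the sequence without a stop codon (`has_stop = FALSE`); off by default
#'   since an ORF is normally required to code to a stop.
#' @return A data frame of class `orf_hits`, sorted by `(start_nt, frame)`,
#'   with columns `transcript_id`, `frame`, `start_nt`, `end_nt`, `aa_len`,
#'   `peptide`, `start_rank`, `is_maximal`, `has_stop`. Coordinates are
#'   0-based half-open; `end_nt` is just past the stop codon.
#' @examples
#' find_orfs(paste0("ATG", strrep("GCT", 10), "TAA"), min_aa = 10)
#' @export
find_orfs <- function(sequence, min_aa = 10L, mode = c("maximal", "all"),
                      allow_open = FALSE) {
  mode <- match.arg(mode)
  transcript_id <- NA_character_
  if (inherits(sequence, "transcript_record")) {
    transcript_id <- sequence$id
    sequence <- sequence$sequence
  }
  sequence <- toupper(as.character(sequence))
  if (min_aa < 1L) stop("min_aa must be >= 1")
  if (!nzchar(sequence)) return(empty_orf_hits())
  check_alphabet(sequence)

  n <- nchar(sequence)
  out <- vector("list", 3L)
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    pos <- frame + 3L * (seq_len(ncod) - 1L) + 1L           # 1-based codon starts
    codons <- substring(sequence, pos, pos + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    starts <- which(is_start)
    if (!length(starts)) next
    stops <- which(is_stop)
    # index of the first stop codon at or after each start (exclusive of it)
    nxt <- if (length(stops)) {
      stops[findInterval(starts, stops) + 1L]
    } else {
      rep(NA_integer_, length(starts))
    }
    open <- is.na(nxt)
    if (!allow_open && all(open)) next
    keep <- !open
    if (allow_open) keep <- keep | open
    starts <- starts[keep]
    nxt <- nxt[keep]
    open <- open[keep]
    # open ORFs run to the last complete codon
    stop_cod <- ifelse(open, ncod + 1L, nxt)
    aa_len <- stop_cod - starts
    sel <- aa_len >= min_aa
    if (!any(sel)) next
    starts <- starts[sel]; stop_cod <- stop_cod[sel]
    aa_len <- aa_len[sel]; open <- open[sel]
    rank <- stats::ave(starts, stop_cod, FUN = seq_along)
    peptide <- vapply(seq_along(starts), function(i) {
      translate_codons(codons[starts[i]:(stop_cod[i] - 1L)])
    }, character(1))
    out[[frame + 1L]] <- data.frame(
      transcript_id = transcript_id,
      frame = frame,
      start_nt = frame + 3L * (starts - 1L),
      end_nt = frame + 3L * (stop_cod - 1L) + ifelse(open, 0L, 3L),
      aa_len = aa_len,
      peptide = peptide,
      start_rank = as.integer(rank),
      is_maximal = rank == 1L,
      has_stop = !open,
      stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(hits)) return(empty_orf_hits())
  if (mode == "maximal") hits <- hits[hits$is_maximal, , drop = FALSE]
  hits <- hits[order(hits$start_nt, hits$frame), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("orf_hits", "data.frame")
  hits
}

empty_orf_hits <- function() {
  structure(
    data.frame(transcript_id = character(), frame = integer(),
               start_nt = integer(), end_nt = integer(), aa_len = integer(),
               peptide = character(), start_rank = integer(),
               is_maximal = logical(), has_stop = logical(),
               stringsAsFactors = FALSE),
    class = c("orf_hits", "data.frame")
  )
}

# Codon-wise translation with the standard nuclear code; any codon
# containing N translates to X.
translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Per-transcript sORF density
#'
#' Counts qualifying ORFs per transcript and expresses the count per
#' kilobase, the unit used when comparing RNA classes.
#'
#' @param transcripts A [transcript_record] or list of them.
#' @inheritParams find_orfs
#' @return Data frame with one row per transcript: `transcript_id`,
#'   `rna_class`, `n_orfs`, `length_kb`, `orfs_per_kb`.
#' @export
orf_density <- function(transcripts, min_aa = 10L, mode = c("maximal", "all")) {
  mode <- match.arg(mode)
  transcripts <- as_transcript_list(transcripts)
  rows <- lapply(transcripts, function(tr) {
    n_orfs <- nrow(find_orfs(tr, min_aa = min_aa, mode = mode))
    length_kb <- nchar(tr$sequence) / 1000
    data.frame(transcript_id = tr$id, rna_class = tr$rna_class,
               n_orfs = n_orfs, length_kb = length_kb,
               orfs_per_kb = n_orfs / length_kb, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare sORF densities across RNA classes
#'
#' Kruskal-Wallis test across classes on per-transcript ORFs/kb, followed by
#' pairwise two-sided Mann-Whitney tests with Bonferroni correction, plus
#' per-class summaries (n, median, quartiles) and a ranking by median
#' density. Classes with fewer than two transcripts are excluded with a
#' warning. When every observation is identical the global and pairwise
#' p-values are reported as 1 (all-ties convention).
#'
#' @param densities Data frame as returned by [orf_density()].
#' @param alpha Significance level used only for the printed summary.
#' @return Object of class `class_density_test`: list with `summary`
#'   (per-class stats, ranked by median), `kruskal_stat`, `kruskal_p`,
#'   `pairwise` (data frame with raw and Bonferroni-adjusted p-values) and
#'   `alpha`.
#' @export
compare_classes <- function(densities, alpha = 0.05) {
  stopifnot(is.data.frame(densities),
            all(c("rna_class", "orfs_per_kb") %in% names(densities)))
  tab <- table(densities$rna_class)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("excluding class(es) with < 2 transcripts: ",
            paste(small, collapse = ", "))
    densities <- densities[!densities$rna_class %in% small, , drop = FALSE]
  }
  classes <- unique(densities$rna_class)
  if (length(classes) < 2L) stop("need at least 2 classes with >= 2 records")
  x <- densities$orfs_per_kb
  g <- factor(densities$rna_class)

  summary_df <- do.call(rbind, lapply(levels(g), function(cl) {
    v <- x[g == cl]
    data.frame(rna_class = cl, n = length(v), median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  summary_df <- summary_df[order(-summary_df$median), , drop = FALSE]
  summary_df$rank <- seq_len(nrow(summary_df))
  rownames(summary_df) <- NULL

  all_ties <- length(unique(x)) == 1L
  if (all_ties) {
    kw_stat <- 0; kw_p <- 1
  } else {
    kw <- stats::kruskal.test(x, g)
    kw_stat <- unname(kw$statistic); kw_p <- kw$p.value
  }

  prs <- utils::combn(levels(g), 2L)
  pw <- data.frame(class_a = prs[1, ], class_b = prs[2, ],
                   p_raw = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pw))) {
    va <- x[g == pw$class_a[i]]
    vb <- x[g == pw$class_b[i]]
    pw$p_raw[i] <- if (length(unique(c(va, vb))) == 1L) 1 else {
      suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE)$p.value)
    }
  }
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = "bonferroni")

  structure(list(summary = summary_df, kruskal_stat = kw_stat,
                 kruskal_p = kw_p, pairwise = pw, alpha = alpha),
            class = "class_density_test")
}

#' @export
print.class_density_test <- function(x, ...) {
  cat("sORF density comparison across RNA classes\n")
  cat(sprintf("Kruskal-Wallis chi-squared = %.3f, p = %.3g\n",
              x$kruskal_stat, x$kruskal_p))
  cat("\nPer-class densities (ORFs/kb), ranked by median:\n")
  print(x$summary, row.names = FALSE)
  cat("\nPairwise Mann-Whitney (Bonferroni-adjusted):\n")
  pw <- x$pairwise
  pw$signif <- ifelse(pw$p_adj <= x$alpha, "*", "")
  print(pw, row.names = FALSE, digits = 4)
  invisible(x)
}
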