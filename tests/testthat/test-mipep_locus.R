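# deterministic pri-miR with controllable upstream ORFs: stop-rich filler,
# chosen ORFs, hairpin interval at the 3' end
build_primir <- function(orfs, len = 1200, premir_at = 900) {
  filler <- strrep("TAAATAAATAA", ceiling(len / 11))
  seq <- substr(filler, 1, len)
  for (o in orfs) {
    body <- rep("GAA", o$aa - 1)
    if (!is.null(o$atg2_codon)) body[o$atg2_codon - 1] <- "ATG"
    orf_seq <- paste(c("ATG", body, "TAA"), collapse = "")
    substr(seq, o$start + 1, o$start + nchar(orf_seq)) <- orf_seq
  }
  transcript_record("pri_test", "pri_miR", seq,
                    premir_interval = c(premir_at, premir_at + 70))
}

test_that("the longest ORF 5' of the pre-miR is selected, ties to 5'-most", {
  # no upstream ORF at all
  expect_null(select_miorf(build_primir(list())))

  # ORF downstream of the hairpin does not qualify
  tr_down <- build_primir(list(list(aa = 30, start = 1000)), len = 1200,
                          premir_at = 900)
  expect_null(select_miorf(tr_down))

  # two upstream ORFs of 20 and 45 aa: the longer wins
  tr2 <- build_primir(list(list(aa = 20, start = 60),
                           list(aa = 45, start = 300)))
  cand <- select_miorf(tr2)
  expect_equal(cand$orf$aa_len, 45L)
  expect_equal(cand$orf$start_nt, 300L)

  # equal lengths: the 5'-most wins
  tr3 <- build_primir(list(list(aa = 30, start = 60),
                           list(aa = 30, start = 400)))
  expect_equal(select_miorf(tr3)$orf$start_nt, 60L)

  # missing hairpin interval or wrong class errors
  expect_error(select_miorf(transcript_record("x", "pri_miR", "ATGAAATAA")),
               "premir_interval")
  expect_error(select_miorf(transcript_record("x", "lncRNA", "ATGAAATAA")),
               "not a pri_miR")
})

test_that("selection equals max-by-(aa_len, -start) over upstream-filtered scanner output", {
  set.seed(31)
  sim <- simulate_transcriptome(sim_config(
    seed = 31, n_per_class = c(pri_miR = 12L),
    length_range = list(pri_miR = c(800L, 1600L)),
    orf_rate = c(pri_miR = 2.5)))
  for (tr in sim$transcripts) {
    cand <- select_miorf(tr)
    hits <- find_orfs(tr, min_aa = 10, mode = "maximal")
    up <- hits[hits$end_nt <= tr$premir_interval[1], , drop = FALSE]
    if (is.null(cand)) {
      expect_equal(nrow(up), 0L)
    } else {
      best <- up[order(-up$aa_len, up$start_nt), ][1, ]
      expect_equal(cand$orf$start_nt, best$start_nt)
      expect_equal(cand$orf$aa_len, best$aa_len)
    }
  }
})

test_that("the surrogate locus reproduces the 71-aa ORF with ATG2 at codon 15", {
  s <- surrogate_primir8()
  cand <- select_miorf(s$transcript)
  expect_equal(cand$orf$aa_len, 71L)
  expect_true(cand$orf$end_nt <= s$transcript$premir_interval[1])
  # second in-frame start 14 codons in: 71 - 14 = 57 residues
  expect_true(any(cand$alt_starts$start_rank == 2 &
                    cand$alt_starts$aa_len == 57))
  # alt-start lengths strictly decrease with rank
  expect_true(all(diff(cand$alt_starts$aa_len[order(cand$alt_starts$start_rank)]) < 0))
  expect_true(cand$context$favorable)
})

test_that("context scoring matches a direct weighted-sum oracle", {
  pwm <- kozak_pwm()
  # perfect consensus context scores 1 and is favorable
  perfect <- paste0("CAAA", "ATG", "A")
  cs <- context_score(perfect, 4)
  expect_equal(cs$score, 1.0)
  expect_true(cs$favorable)
  # context matching nowhere scores 0
  worst <- paste0("GGGG", "ATG", "T")
  cs0 <- context_score(worst, 4)
  expect_equal(cs0$score, 0.0)
  expect_false(cs0$favorable)

  # random contexts against an independent oracle
  set.seed(41)
  for (i in 1:50) {
    ctx <- paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                 collapse = "")
    plus4 <- sample(c("A", "C", "G", "T"), 1)
    seq <- paste0(ctx, "ATG", plus4, "CT")
    got <- context_score(seq, 4)
    bases <- c(strsplit(ctx, "")[[1]], plus4)
    want <- sum(pwm$weights * vapply(1:5, function(p)
      pwm$scores[bases[p], p], numeric(1))) / sum(pwm$weights)
    expect_equal(got$score, want)
    expect_equal(got$favorable,
                 want >= pwm$threshold && bases[2] %in% pwm$preferred_minus3)
  }
})

test_that("context score ignores bases outside the window and flags truncation", {
  seq1 <- paste0("CAAA", "ATG", "A", "CCCCCC")
  seq2 <- paste0("CAAA", "ATG", "A", "GGGGGG")
  expect_equal(context_score(seq1, 4)$score, context_score(seq2, 4)$score)
  # ATG at the very start: only +4 is scorable
  tr <- context_score("ATGA", 0)
  expect_true(tr$truncated)
  expect_equal(tr$score, 1.0)  # +4 = A matches alone
  expect_error(context_score("ATG", 0), "window")
})

test_that("variants apply with reference checking and recompute annotation", {
  s <- surrogate_primir8()
  # stop-gain at codon 48: 71 -> 47 aa, a 24-residue C-terminal truncation
  eff <- miorf_variant_effect(s$transcript, s$stop_variant)
  expect_equal(eff$consequence, "truncation")
  expect_equal(eff$original$orf$aa_len, 71L)
  expect_equal(eff$variant$orf$aa_len, 47L)
  expect_equal(eff$truncation_aa, 24L)

  # reference mismatch is rejected with both alleles named
  expect_error(apply_variant(s$transcript,
                             list(position = s$stop_variant$position,
                                  ref_base = "G", alt_base = "A")),
               "expected G, observed C")

  # applying the variant then its reverse restores the annotation exactly
  mutated <- apply_variant(s$transcript, s$stop_variant)
  restored <- apply_variant(mutated, list(position = s$stop_variant$position,
                                          ref_base = "A", alt_base = "C"))
  expect_identical(restored$sequence, s$transcript$sequence)
  expect_equal(select_miorf(restored)$orf, select_miorf(s$transcript)$orf)

  # a variant outside every ORF leaves the candidate unchanged
  neutral <- miorf_variant_effect(s$transcript,
                                  list(position = 2L, ref_base = "A",
                                       alt_base = "C"))
  expect_equal(neutral$consequence, "none")
  expect_equal(neutral$variant$orf, neutral$original$orf)

  # destroying ATG1 drops selection to the next qualifying start
  orf_start <- select_miorf(s$transcript)$orf$start_nt
  lost <- miorf_variant_effect(s$transcript,
                               list(position = orf_start, ref_base = "A",
                                    alt_base = "C"))
  expect_equal(lost$consequence, "start_lost")
  expect_equal(lost$variant$orf$aa_len, 57L)   # ATG2 takes over
})

test_that("annotation table joins candidates with peptide evidence", {
  expect_equal(nrow(annotate_all(list(
    transcript_record("l1", "lncRNA", "ATGAAATAA")))), 0L)

  s <- surrogate_primir8()
  cand <- select_miorf(s$transcript)
  pep_in <- substr(cand$orf$peptide, 3, 14)
  peps <- data.frame(peptide_id = c("ev1", "ev2", "out1"),
                     peptide = c(pep_in, substr(cand$orf$peptide, 20, 31),
                                 "WWWWWWWWWW"))
  m <- match_peptides(list(s$transcript), peps)
  ann <- annotate_all(list(s$transcript), peptide_matches = m)
  expect_equal(nrow(ann), 1L)
  expect_true(ann$has_candidate)
  expect_equal(ann$aa_len, 71L)
  expect_equal(ann$n_peptide_matches,
               sum(m$nt_start < ann$end_nt & m$nt_end > ann$start_nt &
                     m$transcript_id == "pri_miR_8_surrogate"))
  expect_gte(ann$n_peptide_matches, 2L)
})

test_that("evidence counts equal an interval-intersection oracle on random layouts", {
  set.seed(51)
  sim <- simulate_transcriptome(sim_config(
    seed = 51, n_per_class = c(pri_miR = 10L),
    length_range = list(pri_miR = c(800L, 1400L)),
    orf_rate = c(pri_miR = 2.0)))
  peps <- simulate_ribopeptides(sim, n_peptides = 60, true_fraction = 0.9)
  m <- match_peptides(sim$transcripts,
                      data.frame(peptide_id = peps$peptide_id,
                                 peptide = peps$peptide))
  ann <- annotate_all(sim$transcripts, peptide_matches = m)
  for (i in seq_len(nrow(ann))) {
    if (!ann$has_candidate[i]) next
    mm <- m[m$transcript_id == ann$transcript_id[i], , drop = FALSE]
    want <- 0L
    for (j in seq_len(nrow(mm))) {
      lo <- max(mm$nt_start[j], ann$start_nt[i])
      hi <- min(mm$nt_end[j], ann$end_nt[i])
      if (lo < hi) want <- want + 1L
    }
    expect_equal(ann$n_peptide_matches[i], want)
  }
})
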