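# Independent brute-force oracles used to validate the fast implementations.
# These deliberately re-derive everything from first principles and share no
# code with R/.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# position-by-position ORF scan: every ATG, walk codons to the first
# in-frame stop, apply the length filter
oracle_find_orfs <- function(seq, min_aa, mode) {
  n <- nchar(seq)
  res <- list()
  for (p in 0:(n - 3)) {
    if (substr(seq, p + 1, p + 3) != "ATG") next
    q <- p
    stop_at <- NA_integer_
    repeat {
      q <- q + 3
      if (q + 3 > n) break
      if (substr(seq, q + 1, q + 3) %in% c("TAA", "TAG", "TGA")) {
        stop_at <- q
        break
      }
    }
    if (is.na(stop_at)) next
    aa_len <- (stop_at - p) / 3
    if (aa_len >= min_aa) {
      res[[length(res) + 1]] <- data.frame(frame = p %% 3, start_nt = p,
                                           end_nt = stop_at + 3,
                                           aa_len = aa_len)
    }
  }
  df <- if (length(res)) do.call(rbind, res) else
    data.frame(frame = integer(), start_nt = integer(),
               end_nt = integer(), aa_len = integer())
  if (mode == "maximal" && nrow(df)) {
    df <- do.call(rbind, lapply(split(df, paste(df$frame, df$end_nt)),
                                function(g) g[which.min(g$start_nt), ]))
  }
  df <- df[order(df$start_nt, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# independent translation route via Biostrings (ACGT-only sequences)
oracle_translate <- function(seq, frame) {
  n <- nchar(seq)
  ncod <- (n - frame) %/% 3
  if (ncod == 0) return("")
  sub <- substr(seq, frame + 1, frame + 3 * ncod)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     no.init.codon = TRUE))
}

# naive all-positions substring matcher
oracle_match <- function(transcripts, peptides) {
  out <- list()
  for (tr in transcripts) {
    for (f in 0:2) {
      pepstr <- oracle_translate(tr$sequence, f)
      np <- nchar(pepstr)
      for (i in seq_len(nrow(peptides))) {
        pep <- peptides$peptide[i]
        L <- nchar(pep)
        if (np < L) next
        for (off in 0:(np - L)) {
          if (substr(pepstr, off + 1, off + L) == pep) {
            out[[length(out) + 1]] <- data.frame(
              peptide_id = peptides$peptide_id[i], transcript_id = tr$id,
              frame = f, aa_offset = off, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(peptide_id = character(), transcript_id = character(),
               frame = integer(), aa_offset = integer(),
               stringsAsFactors = FALSE)
  df[order(df$transcript_id, df$frame, df$aa_offset, df$peptide_id), ,
     drop = FALSE]
}

# step-up FDR adjustment from its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# TMM factor for one library against a fixed reference, recomputed
# literally from the trim-and-weight definition
oracle_tmm_pair <- function(obs, ref) {
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_l <- floor(n * 0.3) + 1; hi_l <- n + 1 - lo_l
  lo_s <- floor(n * 0.05) + 1; hi_s <- n + 1 - lo_s
  keep <- rank(m) >= lo_l & rank(m) <= hi_l &
    rank(a) >= lo_s & rank(a) <= hi_s
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

# 16-cell Punnett enumeration for a two-locus double-heterozygote cross
oracle_punnett_2locus <- function(p1, p2) {
  probs <- list()
  for (a1 in p1[[1]]) for (b1 in p1[[2]]) {
    for (a2 in p2[[1]]) for (b2 in p2[[2]]) {
      g <- paste(paste(sort(c(a1, a2)), collapse = "/"),
                 paste(sort(c(b1, b2)), collapse = "/"), sep = "; ")
      probs[[g]] <- (if (is.null(probs[[g]])) 0 else probs[[g]]) + 1 / 16
    }
  }
  unlist(probs)
}

# two-sided exact binomial p by tail summation over outcome probabilities
oracle_binom_p <- function(x, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= dbinom(x, n, p) * (1 + 1e-7)])
}
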