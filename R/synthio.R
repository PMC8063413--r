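#' Simulation configuration
#'
#' Central parameter set for all synthetic-data generators. Defaults define
#' the study conditions emulated throughout the package: five RNA classes
#' with pri-miR and lncRNA carrying the highest sORF densities and 5'UTRs
#' the lowest; ribo-seq peptide lists that are mostly genuine translation
#' products plus verified decoys; three-condition count matrices (ctrl,
#' miR-like and miPEP-like overexpression, five replicates each) in which
#' 24% of the miPEP-responsive genes are co-regulated with the miR
#' condition; and cross/phenotype generators for the genetics module.
#'
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   outputs.
#' @param n_per_class Named integer vector: transcripts per RNA class.
#' @param length_range Named list of `c(min, max)` transcript lengths (nt)
#'   per class.
#' @param orf_rate Named numeric vector: expected planted ORFs per kb per
#'   class.
#' @param orf_aa_range Planted ORF peptide lengths (residues, stop
#'   excluded).
#' @param n_peptides Number of simulated ribo-seq peptides.
#' @param peptide_true_fraction Fraction of peptides drawn verbatim from
#'   planted ORF translations; the rest are shuffled decoys verified absent
#'   from every three-frame translation.
#' @param peptide_len_range Peptide lengths (residues).
#' @param n_genes,n_reps Genes and replicates per condition for the count
#'   simulator.
#' @param dispersion NB dispersion phi (Var = mu + phi mu^2), genome-wide.
#' @param lib_size_range Expected per-library total counts `c(min, max)`.
#' @param frac_specific_A,frac_specific_B,frac_shared Fractions of genes
#'   planted as miR-specific, miPEP-specific and co-regulated. Defaults put
#'   10% of genes in the miPEP-responsive set with 24% of that set shared.
#' @param effect_logfc Planted absolute log2 fold change.
#' @param progeny_n Total flies per simulated cross.
#' @param phenotype_effect Mean shift of affected phenotype groups, in
#'   within-group standard deviations.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_class = c(CDS = 40L, UTR5 = 40L, UTR3 = 40L,
                                       lncRNA = 40L, pri_miR = 40L),
                       length_range = list(CDS = c(600L, 3000L),
                                           UTR5 = c(300L, 900L),
                                           UTR3 = c(400L, 1500L),
                                           lncRNA = c(600L, 2500L),
                                           pri_miR = c(800L, 2000L)),
                       orf_rate = c(CDS = 1.5, UTR5 = 0.5, UTR3 = 1.0,
                                    lncRNA = 2.0, pri_miR = 2.0),
                       orf_aa_range = c(10L, 60L),
                       n_peptides = 120L,
                       peptide_true_fraction = 0.8,
                       peptide_len_range = c(7L, 17L),
                       n_genes = 2000L,
                       n_reps = 5L,
                       dispersion = 0.1,
                       lib_size_range = c(8e5, 1.2e6),
                       frac_specific_A = 0.076,
                       frac_specific_B = 0.076,
                       frac_shared = 0.024,
                       effect_logfc = 1.5,
                       progeny_n = 200L,
                       phenotype_effect = 1.0) {
  cfg <- list(seed = as.integer(seed), n_per_class = n_per_class,
              length_range = length_range, orf_rate = orf_rate,
              orf_aa_range = as.integer(orf_aa_range),
              n_peptides = as.integer(n_peptides),
              peptide_true_fraction = peptide_true_fraction,
              peptide_len_range = as.integer(peptide_len_range),
              n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
              dispersion = dispersion, lib_size_range = lib_size_range,
              frac_specific_A = frac_specific_A,
              frac_specific_B = frac_specific_B, frac_shared = frac_shared,
              effect_logfc = effect_logfc, progeny_n = as.integer(progeny_n),
              phenotype_effect = phenotype_effect)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (frac_specific_A + frac_specific_B + frac_shared > 1 + 1e-12) {
      stop("planted DE fractions sum above 1")
    }
    if (any(n_per_class < 0) || n_genes <= 0 || n_reps <= 0 ||
        progeny_n <= 0 || n_peptides < 0) {
      stop("counts must be strictly positive")
    }
    if (dispersion <= 0) stop("dispersion must be > 0")
    if (peptide_true_fraction < 0 || peptide_true_fraction > 1) {
      stop("peptide_true_fraction must lie in [0, 1]")
    }
    classes <- names(n_per_class)
    if (!setequal(classes, names(length_range)) ||
        !setequal(classes, names(orf_rate))) {
      stop("n_per_class, length_range and orf_rate must name the same classes")
    }
    # minimal room for a planted ORF: longest span plus background flanks;
    # pri-miR transcripts only plant 5' of the hairpin (~60% of the length)
    max_span <- 3 * (orf_aa_range[2] + 1)
    for (cl in classes) {
      if (orf_rate[[cl]] > 0) {
        usable <- length_range[[cl]][1] * (if (cl == "pri_miR") 0.6 else 1)
        if (usable < max_span + 50) {
          stop("class '", cl, "': minimum length ", length_range[[cl]][1],
               " nt too short to host a planted ORF")
        }
      }
    }
  })
  invisible(cfg)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Stop-rich background: blocks of 10 random bases followed by an 11-nt
# cassette (TAAATAAATAA) carrying a stop codon in every frame, so that any
# unplanted ORF is capped well below 10 residues.
stop_cassette <- "TAAATAAATAA"

make_background <- function(len) {
  n_blocks <- ceiling(len / 21)
  rand <- vapply(seq_len(n_blocks), function(i) {
    paste(sample(c("A", "C", "G", "T"), 10L, replace = TRUE), collapse = "")
  }, character(1))
  substr(paste(paste0(rand, stop_cassette), collapse = ""), 1L, len)
}

non_stop_codons <- function() {
  all_cod <- names(Biostrings::GENETIC_CODE)
  all_cod[Biostrings::GENETIC_CODE != "*"]
}

# Planted-ORF body: random non-stop codons interleaved every few codons
# with the triple CTA-ACT-AAC (Leu-Thr-Asn), whose nucleotide string
# CTAACTAAC carries a TAA in both shifted frames. This keeps the planted
# frame stop-free while capping shifted-frame read-through, so spurious
# >= 10-aa ORFs overlapping planted ones stay rare.
orf_body <- function(n_codons, codons) {
  out <- character(0)
  while (length(out) < n_codons) {
    out <- c(out, sample(codons, min(4L, n_codons - length(out)),
                         replace = TRUE))
    if (length(out) < n_codons) {
      out <- c(out, c("CTA", "ACT", "AAC")[seq_len(min(3L, n_codons - length(out)))])
    }
  }
  out
}

#' Simulate a transcriptome with planted sORFs
#'
#' Generates, per RNA class, transcripts of random length whose background
#' is stop-rich in all three frames, then plants Poisson-many complete ORFs
#' (ATG ... stop, peptide length within `orf_aa_range`) at non-overlapping
#' positions. pri-miR transcripts receive a pre-miR interval in their 3'
#' region and plant all their ORFs (at least one) strictly 5' of it.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_transcriptome`: `transcripts` (list of
#'   [transcript_record]), `truth` (data frame of planted ORFs:
#'   `transcript_id`, `rna_class`, `frame`, `start_nt`, `end_nt`, `aa_len`,
#'   `peptide`), `config`.
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, {
    codons <- non_stop_codons()
    stops <- c("TAA", "TAG", "TGA")
    transcripts <- list()
    truth <- list()
    for (cl in names(config$n_per_class)) {
      rng <- config$length_range[[cl]]
      for (i in seq_len(config$n_per_class[[cl]])) {
        id <- sprintf("%s_%03d", cl, i)
        len <- if (rng[1] == rng[2]) rng[1] else
          sample(rng[1]:rng[2], 1L)
        seq <- make_background(len)
        premir <- NULL
        region_end <- len
        if (cl == "pri_miR") {
          pm_len <- sample(60:100, 1L)
          pm_start <- min(round(len * stats::runif(1, 0.65, 0.8)),
                          len - pm_len)
          premir <- c(pm_start, pm_start + pm_len)
          region_end <- pm_start
        }
        n_orfs <- stats::rpois(1L, config$orf_rate[[cl]] * len / 1000)
        if (cl == "pri_miR" && config$orf_rate[[cl]] > 0) {
          n_orfs <- max(1L, n_orfs)
        }
        placed <- matrix(integer(0), ncol = 2L)
        for (k in seq_len(n_orfs)) {
          aa <- sample(config$orf_aa_range[1]:config$orf_aa_range[2], 1L)
          span <- 3L * (aa + 1L)
          if (region_end < span) next
          ok <- FALSE
          for (try in 1:100) {
            s <- sample.int(region_end - span + 1L, 1L) - 1L
            if (!nrow(placed) ||
                all(s + span <= placed[, 1] | s >= placed[, 2])) {
              ok <- TRUE; break
            }
          }
          if (!ok) next
          body <- orf_body(aa - 1L, codons)
          orf_seq <- paste(c("ATG", body, sample(stops, 1L)), collapse = "")
          substr(seq, s + 1L, s + span) <- orf_seq
          placed <- rbind(placed, c(s, s + span))
          truth[[length(truth) + 1L]] <- data.frame(
            transcript_id = id, rna_class = cl, frame = s %% 3L,
            start_nt = s, end_nt = s + span, aa_len = aa,
            peptide = translate_codons(c("ATG", body)),
            stringsAsFactors = FALSE)
        }
        transcripts[[length(transcripts) + 1L]] <-
          transcript_record(id, cl, seq, premir_interval = premir)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(transcript_id = character(), rna_class = character(),
                 frame = integer(), start_nt = integer(), end_nt = integer(),
                 aa_len = integer(), peptide = character(),
                 stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    structure(list(transcripts = transcripts, truth = truth, config = config),
              class = "sim_transcriptome")
  })
}

#' @export
print.sim_transcriptome <- function(x, ...) {
  cat("<sim_transcriptome>", length(x$transcripts), "transcripts,",
      nrow(x$truth), "planted ORFs (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Simulate a ribo-seq-derived sORF peptide list
#'
#' Draws `peptide_true_fraction` of the peptides as exact substrings of
#' planted ORF peptides and the remainder as residue-shuffled decoys,
#' each verified absent from every three-frame translation of every
#' transcript (so matcher precision against decoys is exactly measurable).
#'
#' @param sim A [simulate_transcriptome()] result.
#' @param n_peptides,true_fraction,len_range Override the corresponding
#'   config fields.
#' @return Data frame of class `sim_peptides`: `peptide_id`, `peptide`,
#'   `label` (`"true"`/`"decoy"`), `source_transcript`.
#' @export
simulate_ribopeptides <- function(sim,
                                  n_peptides = sim$config$n_peptides,
                                  true_fraction = sim$config$peptide_true_fraction,
                                  len_range = sim$config$peptide_len_range) {
  stopifnot(inherits(sim, "sim_transcriptome"))
  truth <- sim$truth
  if (true_fraction > 0 && !nrow(truth)) {
    stop("true peptides requested but the ground-truth ORF table is empty")
  }
  with_seed(sim$config$seed + 1000L, {
    translations <- unlist(lapply(sim$transcripts, function(tr) {
      vapply(translate3(tr), `[[`, character(1), "peptide_string")
    }), use.names = FALSE)
    in_translations <- function(pep) {
      any(vapply(translations, function(s) grepl(pep, s, fixed = TRUE),
                 logical(1)))
    }
    n_true <- round(n_peptides * true_fraction)
    n_decoy <- n_peptides - n_true
    rows <- list()
    if (n_true > 0) {
      src <- truth[sample.int(nrow(truth), n_true, replace = TRUE), ,
                   drop = FALSE]
      for (i in seq_len(n_true)) {
        aa <- src$aa_len[i]
        w <- sample(len_range[1]:min(len_range[2], aa), 1L)
        off <- sample.int(aa - w + 1L, 1L) - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          peptide_id = sprintf("pep%04d", i),
          peptide = substr(src$peptide[i], off + 1L, off + w),
          label = "true", source_transcript = src$transcript_id[i],
          stringsAsFactors = FALSE)
      }
    }
    residues <- strsplit(paste(truth$peptide, collapse = ""), "")[[1]]
    if (!length(residues)) residues <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in seq_len(n_decoy)) {
      w <- sample(len_range[1]:len_range[2], 1L)
      for (try in 1:100) {
        pep <- paste(sample(residues, w, replace = TRUE), collapse = "")
        if (!in_translations(pep)) break
        if (try == 100) stop("could not generate a verified decoy")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = sprintf("pep%04d", n_true + i), peptide = pep,
        label = "decoy", source_transcript = NA_character_,
        stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(peptide_id = character(), peptide = character(),
                 label = character(), source_transcript = character(),
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("sim_peptides", "data.frame")
    out
  })
}

#' Simulate a three-condition RNA-seq count matrix with planted DE
#'
#' Negative-binomial counts (Var = mu + phi mu^2, single genome-wide phi)
#' for ctrl, miR-like and miPEP-like conditions. Baseline relative
#' abundances are log-normal; planted gene sets shift their mean by
#' `effect_logfc` (random sign, the same sign in both conditions for
#' shared genes). Per-sample means are renormalized so each library's
#' expected total equals its drawn library size, so condition-specific
#' shifts appear as composition effects, as in real sequencing.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_counts`: `counts` (matrix, genes x samples),
#'   `conditions`, `labels` (data frame `gene_id`, `set` in
#'   none/A_only/B_only/shared, `sign`), `lib_sizes`, `config`.
#' @export
simulate_counts <- function(config = sim_config()) {
  validate_sim_config(config)
  if (config$n_reps < 2L) stop("n_reps must be >= 2")
  with_seed(config$seed + 2000L, {
    n <- config$n_genes
    reps <- config$n_reps
    conditions <- rep(c("ctrl", "miR_like", "miPEP_like"), each = reps)
    n_samp <- length(conditions)
    gene_id <- sprintf("g%05d", seq_len(n))

    rel <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
    n_sh <- round(config$frac_shared * n)
    n_a <- round(config$frac_specific_A * n)
    n_b <- round(config$frac_specific_B * n)
    pick <- sample.int(n, n_sh + n_a + n_b)
    set <- rep("none", n)
    set[pick[seq_len(n_sh)]] <- "shared"
    set[pick[n_sh + seq_len(n_a)]] <- "A_only"
    set[pick[n_sh + n_a + seq_len(n_b)]] <- "B_only"
    sign <- ifelse(set == "none", 0L, sample(c(-1L, 1L), n, replace = TRUE))

    fc <- 2^(sign * config$effect_logfc)
    rel_by_cond <- cbind(ctrl = rel,
                         miR_like = rel * ifelse(set %in% c("A_only", "shared"),
                                                 fc, 1),
                         miPEP_like = rel * ifelse(set %in% c("B_only", "shared"),
                                                   fc, 1))
    lib <- stats::runif(n_samp, config$lib_size_range[1],
                        config$lib_size_range[2])
    mu <- vapply(seq_len(n_samp), function(j) {
      r <- rel_by_cond[, conditions[j]]
      lib[j] * r / sum(r)
    }, numeric(n))
    counts <- matrix(stats::rnbinom(n * n_samp, mu = mu,
                                    size = 1 / config$dispersion),
                     nrow = n, ncol = n_samp)
    dimnames(counts) <- list(gene_id, sprintf("%s_r%d", conditions,
                                              rep(seq_len(reps), 3L)))
    structure(list(counts = counts, conditions = conditions,
                   labels = data.frame(gene_id = gene_id, set = set,
                                       sign = sign, stringsAsFactors = FALSE),
                   lib_sizes = lib, config = config),
              class = "sim_counts")
  })
}

#' Synthetic surrogate of the pri-miR-8 miORF geometry
#'
#' A fully synthetic pri-miR transcript mirroring the studied locus
#' geometry at desk scale: a 71-codon miORF (ATG1) in a favorable start
#' context, an internal in-frame ATG at codon 15 (ATG2, yielding a 57-aa
#' peptide), a pre-miR interval downstream of the ORF, and a known
#' single-base stop-gain variant at codon 48 (TCA -> TAA) whose
#' application truncates the peptide to 47 residues (a 24-aa C-terminal
#' truncation). The sequence is constructed, not genomic.
#'
#' @return List with `transcript` ([transcript_record]) and `stop_variant`
#'   (list `position`, `ref_base`, `alt_base`).
#' @export
surrogate_primir8 <- function() {
  pad <- function(k) strrep(stop_cassette, k)
  body <- rep("GAA", 70L)
  body[14L] <- "ATG"          # ORF codon 15 = ATG2
  body[47L] <- "TCA"          # ORF codon 48; C->A makes a TAA stop
  orf <- paste(c("ATG", body, "TAA"), collapse = "")
  seq <- paste0(pad(4L), "CAAA", orf, pad(3L))
  orf_start <- nchar(pad(4L)) + 4L
  premir_start <- nchar(seq)
  seq <- paste0(seq, strrep("GC", 35L), pad(1L))
  tr <- transcript_record("pri_miR_8_surrogate", "pri_miR", seq,
                          premir_interval = c(premir_start, premir_start + 70L))
  list(transcript = tr,
       stop_variant = list(position = orf_start + 47L * 3L + 1L,
                           ref_base = "C", alt_base = "A"))
}

#' Simulate progeny counts for a cross
#'
#' Multinomial draw from the cross's expected class fractions, reweighted
#' by per-class relative viability and renormalized.
#'
#' @param scheme A [cross_scheme()].
#' @param n Total progeny (must be positive).
#' @param viability Named per-class relative viabilities (default all 1 =
#'   neutral); 0 removes a class entirely.
#' @param seed Optional seed for reproducible draws.
#' @return Named integer vector of class counts.
#' @export
simulate_progeny <- function(scheme, n, viability = NULL, seed = NULL) {
  if (n <= 0) stop("n must be positive")
  expected <- expected_fractions(scheme)
  w <- expected
  if (!is.null(viability)) {
    v <- rep(1, length(expected))
    names(v) <- names(expected)
    v[names(viability)] <- viability
    w <- expected * v
    if (sum(w) <= 0) stop("all classes have zero viability")
    w <- w / sum(w)
  }
  draw <- function() {
    stats::setNames(as.integer(stats::rmultinom(1L, n, w)), names(w))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate continuous phenotype measurements
#'
#' Per-group measurements (e.g. wing sizes in arbitrary units) from a
#' normal or heavy-tailed (log-normal) distribution, with named groups
#' shifted by `effects` standard deviations.
#'
#' @param groups Character vector of group names.
#' @param n_per_group Measurements per group.
#' @param effects Named numeric vector of mean shifts, in units of the
#'   within-group standard deviation; unnamed groups shift by 0.
#' @param dist `"normal"` or `"lognormal"`.
#' @param baseline,sd_unit Location and scale of the control distribution
#'   (arbitrary units).
#' @param seed Optional seed.
#' @return Data frame with columns `group`, `value`.
#' @export
simulate_phenotypes <- function(groups, n_per_group = 25L,
                                effects = numeric(),
                                dist = c("normal", "lognormal"),
                                baseline = 100, sd_unit = 10, seed = NULL) {
  dist <- match.arg(dist)
  draw <- function() {
    do.call(rbind, lapply(groups, function(g) {
      shift <- if (g %in% names(effects)) effects[[g]] * sd_unit else 0
      v <- if (dist == "normal") {
        stats::rnorm(n_per_group, baseline + shift, sd_unit)
      } else {
        # heavy-tailed: log-normal matched to baseline scale, then shifted
        baseline + shift +
          (stats::rlnorm(n_per_group, 0, 0.6) - exp(0.18)) * sd_unit
      }
      data.frame(group = g, value = v, stringsAsFactors = FALSE)
    }))
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  rownames(out) <- NULL
  out
}
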