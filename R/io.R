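#' Write transcripts to FASTA
#'
#' 60-column-wrapped FASTA, one record per transcript.
#'
#' @param transcripts [transcript_record] list.
#' @param path Output file.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  transcripts <- as_transcript_list(transcripts)
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, character(1),
                                          "sequence"))
  names(seqs) <- vapply(transcripts, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Write transcript class annotations as TSV
#'
#' Columns `transcript_id`, `rna_class`, `premir_start`, `premir_end`
#' (0-based half-open, empty when absent), with `#`-prefixed metadata
#' lines.
#'
#' @inheritParams write_transcripts_fasta
#' @param meta Named character vector written as `# key=value` lines.
#' @export
write_transcript_classes <- function(transcripts, path, meta = character()) {
  transcripts <- as_transcript_list(transcripts)
  df <- do.call(rbind, lapply(transcripts, function(tr) {
    pm <- tr$premir_interval
    data.frame(transcript_id = tr$id, rna_class = tr$rna_class,
               premir_start = if (is.null(pm)) NA_integer_ else pm[1],
               premir_end = if (is.null(pm)) NA_integer_ else pm[2],
               stringsAsFactors = FALSE)
  }))
  write_tsv(df, path, meta = meta)
}

#' Read transcripts from FASTA plus a class annotation table
#'
#' @param fasta Path to the FASTA file.
#' @param classes Path to a [write_transcript_classes()] TSV, or an
#'   equivalent data frame.
#' @return List of [transcript_record].
#' @export
read_transcripts_fasta <- function(fasta, classes) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (is.character(classes)) classes <- read_tsv(classes)
  stopifnot(all(c("transcript_id", "rna_class") %in% names(classes)))
  lapply(seq_along(seqs), function(i) {
    id <- sub("\\s.*$", "", names(seqs)[i])
    row <- classes[classes$transcript_id == id, , drop = FALSE]
    if (!nrow(row)) stop("no class annotation for transcript '", id, "'")
    pm <- NULL
    if ("premir_start" %in% names(row) && !is.na(row$premir_start[1])) {
      pm <- c(row$premir_start[1], row$premir_end[1])
    }
    transcript_record(id, row$rna_class[1], as.character(seqs[[i]]),
                      premir_interval = pm)
  })
}

#' Write transcript features as GFF3
#'
#' One `transcript` feature per record (carrying `rna_class`) and one
#' `pre_miR` feature for each pri-miR hairpin interval, with transcript
#' ids as seqnames. Internal 0-based half-open intervals `[s, e)` are
#' converted to the 1-based closed GFF3 convention `[s + 1, e]`.
#'
#' @inheritParams write_transcripts_fasta
#' @export
write_transcripts_gff3 <- function(transcripts, path) {
  transcripts <- as_transcript_list(transcripts)
  rows <- list()
  for (tr in transcripts) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = tr$id, start = 1L, end = nchar(tr$sequence),
      type = "transcript", rna_class = tr$rna_class,
      ID = tr$id, stringsAsFactors = FALSE)
    if (!is.null(tr$premir_interval)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = tr$id, start = tr$premir_interval[1] + 1L,
        end = tr$premir_interval[2], type = "pre_miR",
        rna_class = tr$rna_class, ID = paste0(tr$id, "_premir"),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = "+", type = df$type, rna_class = df$rna_class, ID = df$ID)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read transcripts from FASTA plus GFF3 annotations
#'
#' Inverse of [write_transcripts_gff3()]: GFF3 1-based closed coordinates
#' are converted back to 0-based half-open.
#'
#' @param fasta Path to the FASTA file.
#' @param gff3 Path to the GFF3 file.
#' @return List of [transcript_record].
#' @export
read_transcripts_gff3 <- function(fasta, gff3) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  gr <- rtracklayer::import(gff3, format = "gff3")
  tr_feat <- gr[gr$type == "transcript"]
  pm_feat <- gr[gr$type == "pre_miR"]
  lapply(seq_along(seqs), function(i) {
    id <- sub("\\s.*$", "", names(seqs)[i])
    feat <- tr_feat[as.character(GenomicRanges::seqnames(tr_feat)) == id]
    if (!length(feat)) stop("no transcript feature for '", id, "'")
    pm_i <- pm_feat[as.character(GenomicRanges::seqnames(pm_feat)) == id]
    pm <- if (length(pm_i)) {
      c(GenomicRanges::start(pm_i)[1] - 1L, GenomicRanges::end(pm_i)[1])
    } else NULL
    transcript_record(id, feat$rna_class[1], as.character(seqs[[i]]),
                      premir_interval = pm)
  })
}

#' Write a data frame as TSV with metadata header lines
#'
#' @param df Data frame.
#' @param path Output file.
#' @param meta Named character vector written as leading `# key=value`
#'   lines.
#' @export
write_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(paste0("# ", names(meta), "=", meta), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' `#`-prefixed lines are treated as comments and returned in the
#' `metadata` attribute.
#'
#' @param path Input file.
#' @return Data frame (with attribute `metadata`).
#' @export
read_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  attr(df, "metadata") <- sub("^#\\s*", "", meta_lines)
  df
}

#' Write a count matrix with condition labels
#'
#' Counts as TSV (`gene_id` column plus one column per sample), plus the
#' seed and config hash in metadata lines; conditions go in a second TSV.
#'
#' @param sim A [simulate_counts()] result.
#' @param counts_path,conditions_path Output files.
#' @export
write_counts_tsv <- function(sim, counts_path, conditions_path) {
  stopifnot(inherits(sim, "sim_counts"))
  meta <- c(seed = as.character(sim$config$seed),
            config_hash = config_hash(sim$config))
  df <- data.frame(gene_id = rownames(sim$counts), sim$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path, meta = meta)
  write_tsv(data.frame(sample_id = colnames(sim$counts),
                       condition = sim$conditions, stringsAsFactors = FALSE),
            conditions_path, meta = meta)
  invisible(counts_path)
}

#' Read a count matrix and condition labels
#'
#' @param counts_path,conditions_path Files written by
#'   [write_counts_tsv()].
#' @return List with `counts` (matrix) and `conditions`.
#' @export
read_counts_tsv <- function(counts_path, conditions_path) {
  df <- read_tsv(counts_path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  cond <- read_tsv(conditions_path)
  counts <- counts[, cond$sample_id, drop = FALSE]
  list(counts = counts, conditions = cond$condition)
}

# Polynomial rolling hash (mod 2^31) over the deparsed object, as a hex
# string; cheap content fingerprint for output metadata.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
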