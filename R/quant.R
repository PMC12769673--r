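#' Parse a FASTQ file into sequence and quality vectors
#'
#' Minimal four-line-record FASTQ reader (plain or gzip). Malformed records
#' (sequence/quality length mismatch, truncated file) raise an error naming
#' the offending record index.
#'
#' @param path FASTQ path, optionally ".gz".
#' @return list with character vectors \code{id}, \code{seq}, \code{qual}.
#' @export
parse_fastq <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  if (length(lines) %% 4 != 0) {
    stop_("%s: truncated FASTQ (%d lines, record %d incomplete)",
          path, length(lines), length(lines) %/% 4 + 1)
  }
  n <- length(lines) %/% 4
  if (n == 0) return(list(id = character(0), seq = character(0),
                          qual = character(0)))
  id <- lines[seq(1, by = 4, length.out = n)]
  sq <- lines[seq(2, by = 4, length.out = n)]
  ql <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad)) {
    stop_("%s: record %d has sequence/quality length mismatch", path, bad[1])
  }
  if (any(substr(id, 1, 1) != "@")) {
    stop_("%s: record %d lacks '@' header", path,
          which(substr(id, 1, 1) != "@")[1])
  }
  list(id = sub("^@", "", id), seq = sq, qual = ql)
}

#' Mean per-base Phred score of reads
#'
#' @param qual Phred+33 encoded quality strings.
#' @return numeric vector of mean Phred scores.
#' @export
mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

#' Quality filter: keep reads whose mean Phred exceeds a threshold
#'
#' Reads pass when their mean base quality is strictly above
#' \code{min_mean_phred} (default 20); a read averaging exactly 20 is
#' discarded. Setting \code{min_base_fraction} additionally requires that
#' fraction of bases to individually exceed the threshold (per-base variant).
#'
#' @param seq,qual equal-length sequence and Phred+33 quality strings.
#' @param min_mean_phred threshold on the mean base Phred score.
#' @param min_base_fraction optional fraction of bases that must each exceed
#'   the threshold; \code{NULL} disables the per-base criterion.
#' @return logical keep vector.
#' @export
filter_quality <- function(seq, qual, min_mean_phred = 20,
                           min_base_fraction = NULL) {
  if (any(nchar(seq) != nchar(qual))) {
    stop_("record %d: sequence and quality lengths differ",
          which(nchar(seq) != nchar(qual))[1])
  }
  keep <- mean_phred(qual) > min_mean_phred
  if (!is.null(min_base_fraction)) {
    frac <- vapply(qual, function(q) mean(utf8ToInt(q) - 33 > min_mean_phred),
                   numeric(1), USE.NAMES = FALSE)
    keep <- keep & frac >= min_base_fraction
  }
  keep
}

#' Extract the protospacer downstream of the vector anchor
#'
#' Locates the leftmost exact occurrence of the anchor (vector prefix) in
#' each read and returns the following \code{k} bases; \code{NA} when the
#' anchor is absent or fewer than \code{k} bases follow it.
#'
#' @param seq read sequences.
#' @param anchor vector prefix immediately 5' of the protospacer.
#' @param k protospacer length (20 for Cas9 sgRNA).
#' @return character vector of protospacers, \code{NA} where unextractable.
#' @export
extract_protospacer <- function(seq, anchor = "ACCG", k = 20L) {
  if (!nzchar(anchor)) stop_("anchor must be a non-empty string")
  pos <- regexpr(anchor, seq, fixed = TRUE)
  start <- ifelse(pos > 0, pos + nchar(anchor), NA_integer_)
  out <- substr(seq, start, start + k - 1L)
  out[is.na(start) | nchar(out) < k] <- NA_character_
  out
}

#' Match extracted protospacers against the guide library
#'
#' Exact hash lookup by default. With \code{max_mismatches = 1}, unmatched
#' spacers are rescued when exactly one library guide lies within one
#' substitution; spacers with several 1-mismatch neighbours stay unmatched
#' (ambiguous).
#'
#' @param spacers character vector of 20-mers (NA = unextractable).
#' @param lib a \code{guide_library}.
#' @param max_mismatches 0 (exact) or 1 (unique-neighbour rescue).
#' @return character vector of guide ids, \code{NA} for unmatched.
#' @export
match_guides <- function(spacers, lib, max_mismatches = 0L) {
  validate_library(lib)
  idx <- match(spacers, lib$protospacer)
  if (max_mismatches >= 1L) {
    lut <- stats::setNames(seq_len(nrow(lib)), lib$protospacer)
    miss <- which(is.na(idx) & !is.na(spacers))
    for (i in miss) {
      hits <- unique(lut[one_mismatch_neighbours(spacers[i])])
      hits <- hits[!is.na(hits)]
      if (length(hits) == 1L) idx[i] <- hits
    }
  }
  lib$guide_id[idx]
}

one_mismatch_neighbours <- function(s) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(s, "")[[1]]
  out <- character(0)
  for (i in seq_along(ch)) {
    for (b in setdiff(bases, ch[i])) {
      v <- ch; v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

#' Quantify guide abundance from per-sample FASTQ files
#'
#' The read-processing pipeline: mean-Phred quality filtering, anchor-based
#' protospacer extraction, library matching, and per-sample accounting. The
#' invariant \code{mapped + filtered_low_quality + unmatched = total_reads}
#' holds for every sample; count columns sum to \code{mapped_reads}. Reads
#' failing extraction or matching count as unmatched. No gene-level
#' expression filter is applied at any stage.
#'
#' @param fastq_files named character vector, names = sample ids, values =
#'   FASTQ paths (one demultiplexed file per sample).
#' @param lib a \code{guide_library}.
#' @param samples sample sheet data.frame (sample, condition, replicate,
#'   timepoint) covering all names of \code{fastq_files}.
#' @param anchor vector prefix used for protospacer extraction.
#' @param min_mean_phred mean-Phred quality threshold (strict >).
#' @param max_mismatches guide-matching stringency (0 or 1).
#' @return a \code{count_table} with per-sample accounting stats.
#' @export
count_fastq <- function(fastq_files, lib, samples,
                        anchor = "ACCG", min_mean_phred = 20,
                        max_mismatches = 0L) {
  validate_library(lib)
  if (is.null(names(fastq_files)) || any(!nzchar(names(fastq_files)))) {
    stop_("fastq_files must be named by sample id")
  }
  counts <- matrix(0L, nrow = nrow(lib), ncol = length(fastq_files),
                   dimnames = list(lib$guide_id, names(fastq_files)))
  stats <- data.frame(sample = names(fastq_files), total_reads = 0L,
                      mapped_reads = 0L, filtered_low_quality = 0L,
                      unmatched = 0L, stringsAsFactors = FALSE)
  for (j in seq_along(fastq_files)) {
    fq <- parse_fastq(fastq_files[[j]])
    total <- length(fq$seq)
    keep <- filter_quality(fq$seq, fq$qual, min_mean_phred)
    spacers <- extract_protospacer(fq$seq[keep], anchor)
    ids <- match_guides(spacers, lib, max_mismatches)
    tab <- table(factor(ids, levels = lib$guide_id))
    counts[, j] <- as.integer(tab)
    mapped <- sum(!is.na(ids))
    stats$total_reads[j] <- total
    stats$mapped_reads[j] <- mapped
    stats$filtered_low_quality[j] <- total - sum(keep)
    stats$unmatched[j] <- sum(keep) - mapped
  }
  count_table(counts, samples, stats)
}
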