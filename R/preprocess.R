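# Demultiplexing by dual sample barcodes (<= 1 mismatch per barcode, ties
# never broken), UMI extraction, and 3' adapter read-through trimming.

#' Read and validate a sample sheet
#'
#' Columns: `sample_name`, `i5_barcode`, `i7_barcode`, `primer_name`.
#' Validates uniqueness of (i5, i7) pairs and barcode lengths, and warns if
#' any two i5 (or two i7) barcodes are closer than Hamming distance 3.
#'
#' @param path CSV path, or a data.frame with the same columns.
#' @return A validated data.frame of class `ue_sheet`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_name", "i5_barcode", "i7_barcode", "primer_name")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sheet$i5_barcode <- toupper(sheet$i5_barcode)
  sheet$i7_barcode <- toupper(sheet$i7_barcode)
  if (anyDuplicated(paste(sheet$i5_barcode, sheet$i7_barcode)))
    stop("duplicate (i5, i7) barcode pairs in sample sheet")
  if (length(unique(nchar(sheet$i5_barcode))) > 1L)
    stop("i5 barcodes must all have the same length")
  if (length(unique(nchar(sheet$i7_barcode))) > 1L)
    stop("i7 barcodes must all have the same length")
  for (col in c("i5_barcode", "i7_barcode")) {
    bc <- unique(sheet[[col]])
    if (length(bc) > 1L) {
      d <- outer(bc, bc, Vectorize(hamming))
      diag(d) <- NA
      if (any(d < 3, na.rm = TRUE))
        warning("some ", col, "s are within Hamming distance 2; ",
                "1-mismatch demultiplexing may leave reads undetermined")
    }
  }
  class(sheet) <- c("ue_sheet", "data.frame")
  sheet
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# vectorised Hamming distance of many observed barcodes vs one candidate
hamming_to <- function(obs, candidate) {
  k <- nchar(candidate)
  d <- integer(length(obs))
  cand <- strsplit(candidate, "")[[1]]
  for (p in seq_len(k))
    d <- d + (substr(obs, p, p) != cand[p])
  d[nchar(obs) != k] <- NA_integer_
  d
}

# unique best candidate within max_mismatch, NA on no-candidate or tie
match_barcode <- function(obs, candidates, max_mismatch = 1L) {
  dmat <- vapply(candidates, function(cb) hamming_to(obs, cb),
                 integer(length(obs)))
  if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = length(obs))
  ok <- dmat <= max_mismatch
  nok <- rowSums(ok, na.rm = TRUE)
  best <- max.col(-replace(dmat, is.na(dmat), 1000L), ties.method = "first")
  # a tie exists when two candidates are both within max_mismatch at the
  # same minimal distance, or simply when more than one candidate qualifies
  # at any distance <= max_mismatch (conservative: never break ties)
  hit <- ifelse(nok == 1L, best, NA_integer_)
  hit
}

parse_header_barcodes <- function(headers) {
  bc <- sub(".*\\bBC:([ACGTN]+)\\+([ACGTN]+).*", "\\1\t\\2", headers)
  miss <- !grepl("\\bBC:", headers)
  i5 <- sub("\t.*", "", bc); i7 <- sub(".*\t", "", bc)
  i5[miss] <- NA_character_; i7[miss] <- NA_character_
  list(i5 = i5, i7 = i7)
}

#' Demultiplex reads by dual barcodes
#'
#' A read is assigned to a sample iff, for i5 and i7 independently, exactly
#' one sheet barcode lies within `max_mismatch`; otherwise (no candidate, or
#' a tie on either index) the read is undetermined. Barcodes are taken from
#' the FASTQ header comment (`BC:i5+i7`) or from index read vectors.
#'
#' @param reads data.frame from [read_fastq_pairs()] (needs `header`), or
#'   any data.frame to which a `sample_name` column should be added when
#'   `i5`/`i7` are given explicitly.
#' @param sheet A sample sheet ([read_sample_sheet()]).
#' @param max_mismatch Maximum mismatches per barcode (default 1).
#' @param i5,i7 Optional explicit observed barcode vectors (index-read
#'   dialect); by default parsed from `reads$header`.
#' @return A list: `reads` (input with `sample_name`, NA = undetermined)
#'   and `counts` (data.frame of per-sample read counts including
#'   `undetermined`).
#' @export
demultiplex <- function(reads, sheet, max_mismatch = 1L, i5 = NULL, i7 = NULL) {
  if (is.null(i5) || is.null(i7)) {
    parsed <- parse_header_barcodes(reads$header)
    i5 <- i5 %||% parsed$i5
    i7 <- i7 %||% parsed$i7
  }
  if (anyNA(i5) || anyNA(i7)) {
    bad <- which(is.na(i5) | is.na(i7))[1]
    stop("missing barcode data for read '", reads$id[bad] %||% bad, "'")
  }
  hit5 <- match_barcode(i5, sheet$i5_barcode, max_mismatch)
  hit7 <- match_barcode(i7, sheet$i7_barcode, max_mismatch)
  # both indices must agree on the same sheet row
  key <- paste(sheet$i5_barcode[hit5], sheet$i7_barcode[hit7])
  row <- match(key, paste(sheet$i5_barcode, sheet$i7_barcode))
  row[is.na(hit5) | is.na(hit7)] <- NA_integer_
  reads$sample_name <- sheet$sample_name[row]
  counts <- as.data.frame(table(
    sample = factor(ifelse(is.na(reads$sample_name), "undetermined",
                           reads$sample_name),
                    levels = c(sheet$sample_name, "undetermined"))),
    stringsAsFactors = FALSE)
  names(counts) <- c("sample", "reads")
  counts$fraction <- counts$reads / max(1L, nrow(reads))
  list(reads = reads, counts = counts)
}

#' Write demultiplexed reads as per-sample paired FASTQ
#'
#' @param dm Result of [demultiplex()] run on reads that carry `r1`, `r2`
#'   (and optionally `q1`, `q2`) columns.
#' @param dir Output directory.
#' @return Named list of written path pairs (one per sample, plus
#'   `undetermined` when present).
#' @export
write_demultiplexed <- function(dm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads <- dm$reads
  grp <- ifelse(is.na(reads$sample_name), "undetermined", reads$sample_name)
  out <- list()
  for (s in unique(grp)) {
    sub <- reads[grp == s, , drop = FALSE]
    p1 <- file.path(dir, paste0(s, "_R1.fastq.gz"))
    p2 <- file.path(dir, paste0(s, "_R2.fastq.gz"))
    write_fastq(sub$header, sub$r1, p1)
    write_fastq(sub$header, sub$r2, p2)
    out[[s]] <- c(r1 = p1, r2 = p2)
  }
  out
}

#' Extract UMIs
#'
#' Reads the UMI from the FASTQ header comment (`UMI:<seq>`) or from a
#' dedicated index-read vector (first `umi_length` bases). UMIs containing
#' N are kept but flagged; reads whose UMI is shorter than configured are
#' discarded with a logged reason.
#'
#' @param reads data.frame with `header` (and any other columns).
#' @param umi_length Expected UMI length (default 10).
#' @param index_seq Optional index-read sequences carrying the UMI.
#' @return A list: `reads` (with `umi` and `umi_has_n` columns; short-UMI
#'   rows removed) and `n_discarded`.
#' @export
extract_umi <- function(reads, umi_length = 10L, index_seq = NULL) {
  if (is.null(index_seq)) {
    umi <- sub(".*\\bUMI:([ACGTN]+).*", "\\1", reads$header)
    umi[!grepl("\\bUMI:", reads$header)] <- ""
  } else {
    umi <- substr(index_seq, 1L, umi_length)
  }
  short <- nchar(umi) < umi_length
  if (any(short))
    message(sum(short), " read(s) discarded: UMI shorter than ", umi_length)
  reads <- reads[!short, , drop = FALSE]
  umi <- substr(umi[!short], 1L, umi_length)
  reads$umi <- umi
  reads$umi_has_n <- grepl("N", umi, fixed = TRUE)
  list(reads = reads, n_discarded = sum(short))
}

#' Trim 3' adapter read-through
#'
#' Removes the longest 3' suffix of each read that aligns to a prefix of the
#' adapter with a mismatch fraction of at most `max_error_rate` and overlap
#' of at least `min_overlap`. No internal trimming; reads with no match are
#' returned unchanged. Qualities are carried through untouched apart from
#' the same truncation.
#'
#' @param seq Character vector of read sequences.
#' @param qual Optional matching quality strings.
#' @param adapter Adapter sequence whose prefix is sought at read 3' ends.
#' @param min_overlap Minimum suffix/prefix overlap (default 3).
#' @param max_error_rate Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return If `qual` is NULL, the trimmed sequences; otherwise a list
#'   `seq`, `qual`.
#' @export
trim_adapter <- function(seq, qual = NULL, adapter, min_overlap = 3L,
                         max_error_rate = 0.1) {
  stopifnot(nzchar(adapter))
  alen <- nchar(adapter)
  keep_len <- nchar(seq)
  maxo <- pmin(keep_len, alen)
  trimmed <- logical(length(seq))
  if (any(maxo >= min_overlap)) {
    # longest qualifying overlap wins: scan from long to short, freeze matches
    for (k in seq(max(maxo), min_overlap)) {
      idx <- which(!trimmed & maxo >= k)
      if (!length(idx)) next
      suffix <- substr(seq[idx], nchar(seq[idx]) - k + 1L, nchar(seq[idx]))
      mism <- hamming_to(suffix, substr(adapter, 1L, k))
      ok <- mism <= floor(max_error_rate * k)
      keep_len[idx[ok]] <- nchar(seq[idx[ok]]) - k
      trimmed[idx[ok]] <- TRUE
    }
  }
  out_seq <- substr(seq, 1L, keep_len)
  if (is.null(qual)) return(out_seq)
  list(seq = out_seq, qual = substr(qual, 1L, keep_len))
}
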