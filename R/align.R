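# Read-pair alignment against the reference amplicon set.
#
# The aligner is "glocal": the read must align end-to-end (read bases
# overhanging the reference are penalized as affine-gap insertions) while
# reference end gaps are free, approximating end-to-end short-read alignment
# stringency.  Traceback is deterministic with tie order MATCH/SUB > DEL > INS.

#' Alignment scoring scheme
#'
#' @param match Match score (> 0). Default +2.
#' @param mismatch Mismatch penalty (< 0). Default -4.
#' @param gap_open Gap opening penalty (< 0), charged once per gap in
#'   addition to the per-base extension. Default -6.
#' @param gap_extend Gap extension penalty (< 0) per gap base. Default -1.
#' @param min_identity Minimum fraction of alignment columns that are
#'   matches for a mate to pass. Default 0.8.
#' @param min_aligned_fraction Minimum fraction of the read aligned.
#'   Default 0.8 (the glocal mode aligns reads end-to-end, so this acts as a
#'   guard for degenerate inputs).
#' @return An object of class `ue_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -4L, gap_open = -6L,
                           gap_extend = -1L, min_identity = 0.8,
                           min_aligned_fraction = 0.8) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            min_identity > 0, min_identity <= 1,
            min_aligned_fraction > 0, min_aligned_fraction <= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_identity = min_identity,
                 min_aligned_fraction = min_aligned_fraction),
            class = "ue_scheme")
}

#' Semi-global alignment of one read against one reference
#'
#' Optimal affine-gap alignment with the read aligned end-to-end and free
#' reference end gaps. All coordinates are 0-based half-open on the
#' reference.
#'
#' @param read Read sequence (character).
#' @param ref Reference sequence (character).
#' @param scheme A [scoring_scheme()].
#' @return A list with `score`, `ref_start`, `ref_end`, `read_start`,
#'   `read_end`, `cigar` (ops `=`, `X`, `I`, `D`), and `edits`: a data.frame
#'   of `op` (MATCH/SUB/INS/DEL), `ref_pos`, `length`.
#' @export
align_semiglobal <- function(read, ref, scheme = scoring_scheme()) {
  stopifnot(nchar(read) > 0, nchar(ref) > 0)
  r <- cpp_align_glocal(read, ref, scheme$match, scheme$mismatch,
                        scheme$gap_open, scheme$gap_extend)
  edits <- parse_cigar(r$cigar, r$ref_start)
  list(score = r$score, ref_start = r$ref_start, ref_end = r$ref_end,
       read_start = 0L, read_end = nchar(read), cigar = r$cigar,
       n_match = r$n_match, n_cols = r$n_cols, edits = edits)
}

#' Parse an extended CIGAR into an edit table
#'
#' @param cigar CIGAR string using ops `=`, `X`, `I`, `D`.
#' @param ref_start 0-based reference start of the alignment.
#' @return data.frame with `op` (MATCH/SUB/INS/DEL), `ref_pos` (0-based),
#'   `length`, `read_pos` (0-based offset in the read).
#' @export
parse_cigar <- function(cigar, ref_start = 0L) {
  if (is.na(cigar) || !nzchar(cigar))
    return(data.frame(op = character(0), ref_pos = integer(0),
                      length = integer(0), read_pos = integer(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[=XID]", cigar))[[1]]
  opname <- c(`=` = "MATCH", X = "SUB", I = "INS", D = "DEL")[ops]
  ref_pos <- integer(length(ops)); read_pos <- integer(length(ops))
  rp <- as.integer(ref_start); qp <- 0L
  for (k in seq_along(ops)) {
    ref_pos[k] <- rp; read_pos[k] <- qp
    if (ops[k] %in% c("=", "X")) { rp <- rp + lens[k]; qp <- qp + lens[k] }
    else if (ops[k] == "D") rp <- rp + lens[k]
    else qp <- qp + lens[k]
  }
  data.frame(op = unname(opname), ref_pos = ref_pos, length = lens,
             read_pos = read_pos, stringsAsFactors = FALSE)
}

# reference intervals consumed by MATCH/SUB without interruption: returns a
# data.frame of contiguous gap-free [start, end) spans on the reference
matched_spans <- function(cigar, ref_start) {
  ed <- parse_cigar(cigar, ref_start)
  if (!nrow(ed)) return(data.frame(start = integer(0), end = integer(0)))
  spans <- list(); cur_start <- NA_integer_; cur_end <- NA_integer_
  for (k in seq_len(nrow(ed))) {
    if (ed$op[k] %in% c("MATCH", "SUB")) {
      if (is.na(cur_start)) cur_start <- ed$ref_pos[k]
      cur_end <- ed$ref_pos[k] + ed$length[k]
    } else {
      if (!is.na(cur_start)) spans[[length(spans) + 1L]] <- c(cur_start, cur_end)
      cur_start <- NA_integer_; cur_end <- NA_integer_
    }
  }
  if (!is.na(cur_start)) spans[[length(spans) + 1L]] <- c(cur_start, cur_end)
  out <- do.call(rbind, spans)
  data.frame(start = out[, 1], end = out[, 2])
}

#' Assign read pairs to their best amplicon
#'
#' Aligns both mates of every pair against every amplicon on both strands
#' and assigns each pair to the amplicon with the highest summed mate score
#' among amplicons where both mates pass the identity and aligned-fraction
#' thresholds. If no amplicon qualifies on both mates, a pair may be
#' assigned on a single passing mate (flagged `single_mate`); otherwise it
#' is `UNASSIGNED` (`amplicon_id` NA). Ties prefer wildtype amplicons, then
#' the lexicographically smaller amplicon id.
#'
#' @param r1,r2 Character vectors of mate sequences (same length).
#' @param amplicons A `ue_amplicons` data.frame.
#' @param scheme A [scoring_scheme()].
#' @return A data.frame with one row per pair: `amplicon_id`, `pair_score`,
#'   `single_mate`, and per-mate columns (`m1_valid`, `m1_strand`,
#'   `m1_score`, `m1_ref_start`, `m1_cigar`, `m1_match`, `m1_cols`, same
#'   for `m2`).
#' @export
assign_amplicons <- function(r1, r2, amplicons, scheme = scoring_scheme()) {
  stopifnot(length(r1) == length(r2), nrow(amplicons) >= 1L)
  ord <- order(amplicons$amplicon_id)
  amp <- amplicons[ord, , drop = FALSE]
  # PCR duplicates are frequently byte-identical pairs: align each distinct
  # pair once and expand (assignment is a pure function of the sequences)
  key <- paste0(r1, "\r", r2)
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  res <- cpp_assign_pairs(
    as.character(r1[uniq]), as.character(r2[uniq]),
    amp$sequence, amp$kind == "WILDTYPE",
    scheme$match, scheme$mismatch, scheme$gap_open, scheme$gap_extend,
    scheme$min_identity, scheme$min_aligned_fraction)
  out <- as.data.frame(res, stringsAsFactors = FALSE)[map, , drop = FALSE]
  rownames(out) <- NULL
  out$amplicon_id <- amp$amplicon_id[out$amp_idx]
  out$amp_idx <- NULL
  out[, c("amplicon_id", setdiff(names(out), "amplicon_id"))]
}

#' Export pair assignments as SAM
#'
#' Writes a minimal SAM file with the amplicons as reference sequences,
#' extended CIGARs (`=`/`X`/`I`/`D`), and the UMI in the `RX` tag.
#'
#' @param assignments Output of [assign_amplicons()].
#' @param r1,r2 The mate sequences that were aligned.
#' @param amplicons The `ue_amplicons` used.
#' @param path Output SAM path.
#' @param read_ids Optional read names.
#' @param umis Optional UMI per pair (written as `RX:Z:`).
#' @return Invisibly, `path`.
#' @export
export_sam <- function(assignments, r1, r2, amplicons, path,
                       read_ids = NULL, umis = NULL) {
  n <- nrow(assignments)
  if (is.null(read_ids)) read_ids <- sprintf("pair%06d", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_len(nrow(amplicons)))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", amplicons$amplicon_id[i],
                       nchar(amplicons$sequence[i])), con)
  recs <- character(0)
  for (i in seq_len(n)) {
    a <- assignments[i, ]
    for (mate in 1:2) {
      seq <- if (mate == 1) r1[i] else r2[i]
      valid <- if (mate == 1) a$m1_valid else a$m2_valid
      strand <- if (mate == 1) a$m1_strand else a$m2_strand
      cig <- if (mate == 1) a$m1_cigar else a$m2_cigar
      pos <- if (mate == 1) a$m1_ref_start else a$m2_ref_start
      flag <- 1L + if (mate == 1) 64L else 128L
      if (is.na(a$amplicon_id) || !isTRUE(valid)) {
        flag <- flag + 4L
        rec <- sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t%s\t*", read_ids[i], flag, seq)
      } else {
        if (strand == "-") { flag <- flag + 16L; seq <- revcomp(seq) }
        rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                       read_ids[i], flag, a$amplicon_id, pos + 1L, cig, seq)
      }
      if (!is.null(umis)) rec <- paste0(rec, "\tRX:Z:", umis[i])
      recs <- c(recs, rec)
    }
  }
  writeLines(recs, con)
  invisible(path)
}
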