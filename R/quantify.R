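# Molecule classification and UMI-based quantification.
#
# A read pair assigned to a junction amplicon supports that junction only if
# it completely covers a window around the junction (default 15 bp each
# side); pairs assigned to a wildtype amplicon are inspected for small
# indels in a window around the cut.  Reads are then collapsed by
# (sample, UMI) to molecules, each molecule taking the majority category of
# its reads, and frequencies are UMI-based.

#' Quantification configuration
#'
#' @param junction_window Bases on each side of a junction that a read must
#'   completely cover to support it (default 15).
#' @param indel_window Bases on each side of the cut inspected for small
#'   indels on wildtype amplicons (default 15).
#' @param umi_collapse `"EXACT"` (default) or `"HAMMING1"` (directional
#'   1-mismatch collapse: a UMI with count c is absorbed by a neighbour
#'   with count >= 2c - 1).
#' @param min_reads_per_umi Minimum reads supporting a molecule
#'   (default 1).
#' @param require_gapfree If TRUE (default), the junction window must be
#'   consumed entirely by match/substitution columns with no gap opening a
#'   hole across it; if FALSE, spanning the window suffices.
#' @return An object of class `ue_quantconfig`.
#' @export
quantify_config <- function(junction_window = 15L, indel_window = 15L,
                            umi_collapse = c("EXACT", "HAMMING1"),
                            min_reads_per_umi = 1L, require_gapfree = TRUE) {
  umi_collapse <- match.arg(umi_collapse)
  stopifnot(junction_window >= 1L, indel_window >= 1L, min_reads_per_umi >= 1L)
  structure(list(junction_window = as.integer(junction_window),
                 indel_window = as.integer(indel_window),
                 umi_collapse = umi_collapse,
                 min_reads_per_umi = as.integer(min_reads_per_umi),
                 require_gapfree = require_gapfree),
            class = "ue_quantconfig")
}

# outcome category group of a junction kind
kind_category <- function(kind, same_locus) {
  ifelse(kind == "WILDTYPE", "WILDTYPE",
  ifelse(kind == "DELETION", "DELETION",
  ifelse(kind %in% c("INVERSION_J1", "INVERSION_J2"), "INVERSION",
  ifelse(kind %in% c("HOMOLOG_LL", "HOMOLOG_RR"), "HOMOLOG_FUSION",
  ifelse(grepl("^FUSION", kind) & !same_locus, "TRANSLOCATION",
  ifelse(grepl("^FUSION", kind), "OTHER_JUNCTION", kind))))))
}

# which rows' I/D ops intersect [lo, hi) (vectors lo/hi per row); returns
# list(hit = logical, desc = character of intersecting ops)
indels_in_window <- function(indstr, lo, hi, interior_ins_only = FALSE) {
  n <- length(indstr)
  hit <- logical(n); desc <- rep(NA_character_, n)
  nz <- which(!is.na(indstr) & nzchar(indstr))
  if (!length(nz)) return(list(hit = hit, desc = desc))
  toks <- strsplit(indstr[nz], ";", fixed = TRUE)
  row <- rep(nz, lengths(toks))
  tok <- unlist(toks)
  parts <- data.table::tstrsplit(tok, ":", fixed = TRUE)
  op <- parts[[1]]; pos <- as.integer(parts[[2]]); len <- as.integer(parts[[3]])
  in_win <- ifelse(op == "D",
                   pos < hi[row] & pos + len > lo[row],
                   if (interior_ins_only) pos > lo[row] & pos < hi[row]
                   else pos >= lo[row] & pos < hi[row])
  if (any(in_win)) {
    dt <- data.table::data.table(row = row[in_win], tok = tok[in_win])
    agg <- dt[, list(d = paste(tok, collapse = ";")), by = row]
    hit[agg$row] <- TRUE
    desc[agg$row] <- agg$d
  }
  list(hit = hit, desc = desc)
}

# vectorised: does a mate completely cover [lo, hi) (gap-free if strict)?
mate_covers <- function(valid, ref_start, ref_end, indels, lo, hi, strict) {
  span <- !is.na(valid) & valid & !is.na(ref_start) &
    ref_start <= lo & ref_end >= hi
  if (!strict) return(span)
  broken <- indels_in_window(ifelse(span, indels, NA_character_),
                             lo, hi, interior_ins_only = TRUE)$hit
  span & !broken
}

#' Does an aligned pair completely cover a junction window?
#'
#' TRUE iff at least one passing mate's aligned reference span contains
#' `[junction_offset - window, junction_offset + window)`; with
#' `require_gapfree` every base of the window must be consumed by
#' match/substitution columns.
#'
#' @param pair One-row data.frame from [assign_amplicons()].
#' @param junction_offset 0-based junction offset on the amplicon.
#' @param window Bases each side (default 15).
#' @param require_gapfree Gap-free coverage required (default TRUE).
#' @return Logical.
#' @export
covers_junction <- function(pair, junction_offset, window = 15L,
                            require_gapfree = TRUE) {
  lo <- rep(junction_offset - window, nrow(pair))
  hi <- rep(junction_offset + window, nrow(pair))
  c1 <- mate_covers(pair$m1_valid, pair$m1_ref_start, pair$m1_ref_end,
                    pair$m1_indels, lo, hi, require_gapfree)
  c2 <- mate_covers(pair$m2_valid, pair$m2_ref_start, pair$m2_ref_end,
                    pair$m2_indels, lo, hi, require_gapfree)
  c1 | c2
}

#' Call a small indel around a cut site
#'
#' For a pair assigned to a wildtype amplicon that spans the cut window,
#' returns the merged descriptor of insertion/deletion edits whose reference
#' interval intersects `[cut - w, cut + w)`, or `NA` if the window is pure
#' match/substitution (wildtype call).
#'
#' @param pair One-row (or many-row) data.frame from [assign_amplicons()].
#' @param cut_offset 0-based cut offset on the wildtype amplicon.
#' @param indel_window Bases each side (default 15).
#' @return Character vector of descriptors (`op:ref_pos:length`, semicolon
#'   separated), `NA` where no indel intersects the window.
#' @export
call_small_indel <- function(pair, cut_offset, indel_window = 15L) {
  lo <- rep(cut_offset - indel_window, nrow(pair))
  hi <- rep(cut_offset + indel_window, nrow(pair))
  h1 <- indels_in_window(pair$m1_indels, lo, hi)
  h2 <- indels_in_window(pair$m2_indels, lo, hi)
  out <- ifelse(h1$hit, h1$desc, NA_character_)
  ifelse(is.na(out) & h2$hit, h2$desc, out)
}

#' Classify aligned read pairs into outcome categories
#'
#' Pairs on junction amplicons are classified by junction-window coverage;
#' pairs on wildtype amplicons by cut-site indel inspection. Pairs that are
#' assigned but do not cover any junction/cut window are `UNINFORMATIVE`;
#' unassigned pairs are `UNASSIGNED`.
#'
#' @param assignments Output of [assign_amplicons()].
#' @param amplicons The `ue_amplicons` aligned against.
#' @param classes The `ue_classes` enumeration (for locus context).
#' @param config A [quantify_config()].
#' @return `assignments` with added columns `category` (group),
#'   `subtype` (class id or `WILDTYPE`/`SMALL_INDEL`), `informative`,
#'   `indel` (descriptor).
#' @export
classify_pairs <- function(assignments, amplicons, classes,
                           config = quantify_config()) {
  n <- nrow(assignments)
  category <- rep("UNASSIGNED", n)
  subtype <- rep(NA_character_, n)
  informative <- rep(FALSE, n)
  indel <- rep(NA_character_, n)

  same_locus <- setNames(classes$end1_locus == classes$end2_locus,
                         classes$class_id)
  ai <- match(assignments$amplicon_id, amplicons$amplicon_id)

  for (a in which(!is.na(match(amplicons$amplicon_id,
                               unique(assignments$amplicon_id))))) {
    rows <- which(!is.na(ai) & ai == a)
    if (!length(rows)) next
    amp <- amplicons[a, ]
    sub <- assignments[rows, , drop = FALSE]
    if (amp$kind == "WILDTYPE") {
      covered <- rep(FALSE, length(rows))
      has_indel <- rep(FALSE, length(rows))
      descr <- rep(NA_character_, length(rows))
      for (off in unlist(amp$junction_offsets)) {
        lo <- rep(off - config$indel_window, length(rows))
        hi <- rep(off + config$indel_window, length(rows))
        # spanning coverage (gaps allowed: an indel inside the window is the
        # signal being called, not a coverage failure)
        c1 <- mate_covers(sub$m1_valid, sub$m1_ref_start, sub$m1_ref_end,
                          sub$m1_indels, lo, hi, strict = FALSE)
        c2 <- mate_covers(sub$m2_valid, sub$m2_ref_start, sub$m2_ref_end,
                          sub$m2_indels, lo, hi, strict = FALSE)
        h1 <- indels_in_window(sub$m1_indels, lo, hi)
        h2 <- indels_in_window(sub$m2_indels, lo, hi)
        cov_off <- c1 | c2
        hit_off <- (c1 & h1$hit) | (c2 & h2$hit)
        d_off <- ifelse(c1 & h1$hit, h1$desc,
                        ifelse(c2 & h2$hit, h2$desc, NA_character_))
        descr <- ifelse(is.na(descr) & hit_off, d_off, descr)
        covered <- covered | cov_off
        has_indel <- has_indel | hit_off
      }
      category[rows] <- ifelse(!covered, "UNINFORMATIVE",
                               ifelse(has_indel, "SMALL_INDEL", "WILDTYPE"))
      subtype[rows] <- ifelse(!covered, NA_character_,
                              ifelse(has_indel, "SMALL_INDEL", "WILDTYPE"))
      informative[rows] <- covered
      indel[rows] <- descr
    } else {
      off <- unlist(amp$junction_offsets)[1]
      cov <- covers_junction(sub, off, config$junction_window,
                             config$require_gapfree)
      lo <- rep(off - config$junction_window, length(rows))
      hi <- rep(off + config$junction_window, length(rows))
      extra <- call_small_indel(sub, off, config$junction_window)
      grp <- kind_category(amp$kind, same_locus[[amp$class_id]])
      category[rows] <- ifelse(cov, grp, "UNINFORMATIVE")
      subtype[rows] <- ifelse(cov, amp$class_id, NA_character_)
      informative[rows] <- cov
      indel[rows] <- ifelse(cov, extra, NA_character_)
    }
  }
  assignments$category <- category
  assignments$subtype <- subtype
  assignments$informative <- informative
  assignments$indel <- indel
  assignments
}

# directional 1-mismatch UMI collapse using masked-position keys; returns a
# representative UMI per input element
collapse_umi_map <- function(umis) {
  cnt <- table(umis)
  u <- names(cnt)
  k <- as.integer(cnt)
  if (length(u) <= 1L) return(setNames(u, u)[umis])
  L <- nchar(u[1])
  parent <- seq_along(u)
  ord <- order(k)  # absorb small into large
  # neighbour candidates: same sequence with one position masked
  neigh <- vector("list", length(u))
  for (p in seq_len(L)) {
    key <- paste0(substr(u, 1L, p - 1L), substr(u, p + 1L, L))
    grp <- split(seq_along(u), key)
    for (g in grp) if (length(g) > 1L)
      for (i in g) neigh[[i]] <- c(neigh[[i]], setdiff(g, i))
  }
  for (i in ord) {
    cand <- unique(neigh[[i]])
    cand <- cand[k[cand] >= 2L * k[i] - 1L & cand != i]
    if (length(cand)) {
      best <- cand[which.max(k[cand])]
      parent[i] <- best
    }
  }
  # resolve chains
  for (i in seq_along(parent)) {
    seen <- integer(0); j <- i
    while (parent[j] != j && !(j %in% seen)) { seen <- c(seen, j); j <- parent[j] }
    parent[i] <- j
  }
  setNames(u[parent], u)[umis]
}

#' Collapse classified reads to molecules by UMI
#'
#' Groups classified read pairs by (sample, UMI) under the configured
#' collapse policy and assigns each molecule the majority category of its
#' informative reads (ties give `AMBIGUOUS`; molecules with no informative
#' read are `UNINFORMATIVE` if aligned, else `UNASSIGNED`).
#'
#' @param classified data.frame with columns `sample_name`, `umi`,
#'   `category`, `subtype`, `indel`, `informative` (e.g.
#'   [classify_pairs()] output joined with read metadata).
#' @param config A [quantify_config()].
#' @return data.frame of molecules: `sample_name`, `umi`, `category`,
#'   `subtype`, `indel`, `supporting_reads`.
#' @export
collapse_umis <- function(classified, config = quantify_config()) {
  dt <- data.table::as.data.table(classified)
  if (config$umi_collapse == "HAMMING1") {
    dt[, umi := collapse_umi_map(umi), by = sample_name]
  }
  # majority vote among informative reads
  votes <- dt[informative == TRUE,
              list(v = .N, subtype = subtype[1],
                   indel = stats::na.omit(indel)[1] %||% NA_character_),
              by = list(sample_name, umi, category)]
  data.table::setorder(votes, sample_name, umi, -v, category)
  top <- votes[, list(category = category[1],
                      subtype = subtype[1], indel = indel[1],
                      tie = .N > 1L && v[2] == v[1]),
               by = list(sample_name, umi)]
  top[tie == TRUE, category := "AMBIGUOUS"]
  grp <- dt[, list(supporting_reads = .N,
                   any_aligned = any(category != "UNASSIGNED")),
            by = list(sample_name, umi)]
  out <- merge(grp, top[, list(sample_name, umi, category, subtype, indel)],
               by = c("sample_name", "umi"), all.x = TRUE)
  out[is.na(category), category := ifelse(any_aligned, "UNINFORMATIVE",
                                          "UNASSIGNED")]
  out[supporting_reads < config$min_reads_per_umi, category := "LOW_SUPPORT"]
  out[, any_aligned := NULL]
  data.table::setDF(out)
  out
}

#' Tally molecules into a frequency table
#'
#' Frequencies are UMI-based: the denominator is the number of molecules in
#' any detectable category including wildtype; `UNASSIGNED`, `AMBIGUOUS`,
#' `UNINFORMATIVE` and `LOW_SUPPORT` molecules are excluded from the
#' denominator and reported in the QC table. Inversion junction subclasses
#' are aggregated (a molecule supporting either junction counts once).
#'
#' @param molecules Output of [collapse_umis()].
#' @param by_sample Tally each sample separately (default TRUE).
#' @return A list of class `ue_freqtable`: `table` (`sample_name`,
#'   `category`, `umi_count`, `read_count`, `frequency`), `qc`
#'   (excluded-category counts), `denominator` (per sample).
#' @export
tally <- function(molecules, by_sample = TRUE) {
  dt <- data.table::as.data.table(molecules)
  if (!nrow(dt)) {
    return(structure(list(
      table = data.frame(sample_name = character(0), category = character(0),
                         umi_count = integer(0), read_count = integer(0),
                         frequency = numeric(0)),
      qc = data.frame(), denominator = integer(0)), class = "ue_freqtable"))
  }
  if (!by_sample) dt[, sample_name := "all"]
  excluded <- c("UNASSIGNED", "AMBIGUOUS", "UNINFORMATIVE", "LOW_SUPPORT")
  inc <- dt[!category %in% excluded]
  tab <- inc[, list(umi_count = .N, read_count = sum(supporting_reads)),
             by = list(sample_name, category)]
  den <- inc[, list(denominator = .N), by = sample_name]
  tab <- merge(tab, den, by = "sample_name")
  tab[, frequency := umi_count / denominator]
  qc <- dt[category %in% excluded,
           list(umi_count = .N, read_count = sum(supporting_reads)),
           by = list(sample_name, category)]
  data.table::setorder(tab, sample_name, -umi_count)
  structure(list(table = data.table::setDF(tab[, list(sample_name, category,
                                                      umi_count, read_count,
                                                      frequency)]),
                 qc = data.table::setDF(qc),
                 denominator = setNames(den$denominator, den$sample_name)),
            class = "ue_freqtable")
}

#' @export
print.ue_freqtable <- function(x, ...) {
  cat("<ue_freqtable>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
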