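# Genomic model: loci, cut sites, free ends, anchor primers, and the
# end-joining outcome classes they can form.
#
# Coordinate convention: 0-based, half-open everywhere.  A cut position p is
# an inter-base coordinate: the cut falls between bases p-1 and p, so the
# LEFT free end is the sequence [0, p) ending at the cut and the RIGHT free
# end is [p, L) starting at it.

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over character vectors, delegating to
#' [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Define a locus
#'
#' A locus is a named stretch of genomic sequence on which cuts are placed.
#' The optional `centromere_side` annotation ("LEFT" or "RIGHT" of the cut
#' region) lets fusion classes be labelled balanced / dicentric / acentric.
#'
#' @param name Identifier, unique within a model.
#' @param sequence Uppercase DNA string (A/C/G/T only).
#' @param chrom_label Free-text chromosome label.
#' @param centromere_side Optional "LEFT" or "RIGHT": on which side of the
#'   edited region the centromere lies.
#' @return An object of class `ue_locus`.
#' @export
locus <- function(name, sequence, chrom_label = name, centromere_side = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGT]+$", sequence))
    stop("locus '", name, "': sequence must contain only A/C/G/T")
  if (!is.null(centromere_side))
    centromere_side <- match.arg(centromere_side, c("LEFT", "RIGHT"))
  structure(
    list(name = name, sequence = sequence, chrom_label = chrom_label,
         centromere_side = centromere_side),
    class = "ue_locus")
}

#' Define a cut site
#'
#' @param locus Locus name (character) or a `ue_locus` object.
#' @param position 0-based inter-base cut coordinate; the cut falls between
#'   bases `position - 1` and `position`. Must satisfy `0 < position < L`.
#' @param guide Guide identifier, unique within a model.
#' @return An object of class `ue_cut`.
#' @export
cut_site <- function(locus, position, guide) {
  locus_name <- if (inherits(locus, "ue_locus")) locus$name else as.character(locus)
  position <- as.integer(position)
  stopifnot(length(position) == 1L, !is.na(position), position > 0L)
  structure(list(locus = locus_name, position = position, guide = guide),
            class = "ue_cut")
}

#' Define an anchor primer
#'
#' An anchor primer anneals on one flank of a cut, with its 3' terminus
#' `distance_to_cut` bases from the cut point, pointing toward the cut. It
#' provides the fixed side of the uni-directional library; a class of
#' junctions is detectable by the primer iff the primer's free end takes part
#' in the junction.
#'
#' @param name Primer identifier.
#' @param guide Guide name of the cut the primer targets.
#' @param side "LEFT" or "RIGHT": the flank (free end) the primer anneals on.
#' @param distance_to_cut Non-negative distance (bp) from the primer 3'
#'   terminus to the cut point.
#' @param sequence Optional primer sequence (simulator realism only).
#' @return An object of class `ue_primer`.
#' @export
anchor_primer <- function(name, guide, side, distance_to_cut, sequence = NULL) {
  side <- match.arg(side, c("LEFT", "RIGHT"))
  distance_to_cut <- as.integer(distance_to_cut)
  stopifnot(distance_to_cut >= 0L)
  structure(list(name = name, guide = guide, side = side,
                 distance_to_cut = distance_to_cut, sequence = sequence),
            class = "ue_primer")
}

#' Assemble an editing model
#'
#' Bundles loci, cut sites and anchor primers and validates all
#' cross-references and coordinate bounds.
#'
#' @param loci List of [locus()] objects.
#' @param cuts List of [cut_site()] objects (1 or more).
#' @param primers List of [anchor_primer()] objects (may be empty).
#' @return An object of class `ue_model` with elements `loci` (named list),
#'   `cuts` (data.frame) and `primers` (data.frame).
#' @export
editing_model <- function(loci, cuts, primers = list()) {
  if (inherits(loci, "ue_locus")) loci <- list(loci)
  if (inherits(cuts, "ue_cut")) cuts <- list(cuts)
  if (inherits(primers, "ue_primer")) primers <- list(primers)
  stopifnot(length(loci) >= 1L, length(cuts) >= 1L)
  lnames <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(lnames)) stop("duplicate locus names")
  names(loci) <- lnames

  cuts_df <- data.frame(
    locus = vapply(cuts, `[[`, character(1), "locus"),
    position = vapply(cuts, `[[`, integer(1), "position"),
    guide = vapply(cuts, function(x) as.character(x$guide), character(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(cuts_df$guide)) stop("duplicate guide names")
  for (i in seq_len(nrow(cuts_df))) {
    ln <- cuts_df$locus[i]
    if (!ln %in% lnames) stop("cut '", cuts_df$guide[i], "': unknown locus '", ln, "'")
    L <- nchar(loci[[ln]]$sequence)
    if (cuts_df$position[i] <= 0L || cuts_df$position[i] >= L)
      stop("cut '", cuts_df$guide[i], "': position must lie strictly inside the locus")
  }

  primers_df <- if (length(primers)) data.frame(
    name = vapply(primers, function(x) as.character(x$name), character(1)),
    guide = vapply(primers, function(x) as.character(x$guide), character(1)),
    side = vapply(primers, `[[`, character(1), "side"),
    distance_to_cut = vapply(primers, `[[`, integer(1), "distance_to_cut"),
    sequence = vapply(primers, function(x) x$sequence %||% NA_character_, character(1)),
    stringsAsFactors = FALSE
  ) else data.frame(name = character(0), guide = character(0), side = character(0),
                    distance_to_cut = integer(0), sequence = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(primers_df) && !all(primers_df$guide %in% cuts_df$guide))
    stop("primer references unknown guide")

  structure(list(loci = loci, cuts = cuts_df, primers = primers_df),
            class = "ue_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ue_model <- function(x, ...) {
  cat("<ue_model> ", length(x$loci), " loci, ", nrow(x$cuts), " cuts, ",
      nrow(x$primers), " primers\n", sep = "")
  for (l in x$loci)
    cat("  locus ", l$name, " (", nchar(l$sequence), " bp)\n", sep = "")
  invisible(x)
}

# --- free ends ---------------------------------------------------------------

# an End is a (locus, position, guide, side) tuple; data.frame row form
model_ends <- function(model) {
  cuts <- model$cuts
  data.frame(
    locus = rep(cuts$locus, each = 2L),
    position = rep(cuts$position, each = 2L),
    guide = rep(cuts$guide, each = 2L),
    side = rep(c("LEFT", "RIGHT"), times = nrow(cuts)),
    stringsAsFactors = FALSE)
}

end_key <- function(end) paste0(end$guide, ".", substr(end$side, 1, 1))

primer_ends <- function(model) {
  p <- model$primers
  if (!nrow(p)) return(character(0))
  cuts <- model$cuts
  paste0(p$guide, ".", substr(p$side, 1, 1))
}

# --- outcome enumeration -----------------------------------------------------

#' Enumerate end-joining outcome classes
#'
#' Given one or two cuts, enumerates every junction that can be formed by
#' joining any two free DNA ends in either relative orientation, and returns
#' the canonical, reverse-complement-deduplicated class set. Two cuts on
#' distinct loci yield exactly 10 classes; one cut yields 3; two cuts on one
#' locus yield 10, with the cross-end pairs taking the DELETION and
#' INVERSION kinds.
#'
#' Canonical orientation puts a LEFT end in the first slot when possible;
#' ties are broken by (locus name, position). The junction sequence of a
#' class is `left_part(end1) + right_part(end2)` where a RIGHT end in slot 1
#' and a LEFT end in slot 2 contribute reverse-complemented flanks; swapping
#' the slots reverse-complements the whole junction, which is why unordered
#' end pairs enumerate the distinct classes.
#'
#' @param model A `ue_model` (its cuts are used), or a list of `ue_cut`.
#' @return A data.frame of class `ue_classes`: one row per junction class
#'   with columns `class_id`, `kind`, `label`, and the two end descriptors
#'   (`end1_locus`, `end1_position`, `end1_guide`, `end1_side`, same for
#'   `end2`).
#' @export
enumerate_outcomes <- function(model) {
  if (!inherits(model, "ue_model")) {
    cuts <- model
    loci <- unique(vapply(cuts, `[[`, character(1), "locus"))
    # sequence-free enumeration still needs a model shell; fabricate loci
    stop("enumerate_outcomes() expects a ue_model; wrap cuts with editing_model()")
  }
  if (nrow(model$cuts) > 2L)
    stop("unsupported configuration: more than 2 simultaneous cuts")
  ends <- model_ends(model)
  n <- nrow(ends)
  rows <- list()
  for (i in seq_len(n)) for (j in i:n) {
    e1 <- ends[i, ]; e2 <- ends[j, ]
    rows[[length(rows) + 1L]] <- canonical_pair(e1, e2, model)
  }
  out <- do.call(rbind, rows)
  out <- out[order(kind_rank(out$kind), out$class_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ue_classes", "data.frame")
  out
}

kind_rank <- function(kind) {
  lv <- c("NHEJ", "DELETION", "INVERSION_J1", "INVERSION_J2",
          "HOMOLOG_LL", "HOMOLOG_RR", "FUSION_LR", "FUSION_RL",
          "FUSION_LL", "FUSION_RR")
  match(kind, lv)
}

# canonicalize an unordered end pair and classify its kind
canonical_pair <- function(e1, e2, model) {
  # ordering: LEFT end first when sides differ; otherwise by (locus, position)
  swap <- FALSE
  if (e1$side != e2$side) {
    if (e1$side == "RIGHT") swap <- TRUE
  } else {
    if (e1$locus > e2$locus ||
        (e1$locus == e2$locus && e1$position > e2$position)) swap <- TRUE
  }
  if (swap) { tmp <- e1; e1 <- e2; e2 <- tmp }

  same_cut <- e1$guide == e2$guide
  same_end <- same_cut && e1$side == e2$side
  same_locus <- e1$locus == e2$locus
  sides <- paste0(substr(e1$side, 1, 1), substr(e2$side, 1, 1))

  kind <- if (same_end) {
    if (e1$side == "LEFT") "HOMOLOG_LL" else "HOMOLOG_RR"
  } else if (same_cut) {
    "NHEJ"
  } else if (same_locus) {
    switch(sides,
      LR = if (e1$position < e2$position) "DELETION" else "FUSION_RL",
      LL = "INVERSION_J1",
      RR = "INVERSION_J2",
      stop("unreachable"))
  } else {
    switch(sides,
      LR = if (e1$locus == min(e1$locus, e2$locus)) "FUSION_LR" else "FUSION_RL",
      LL = "FUSION_LL",
      RR = "FUSION_RR")
  }

  label <- class_label(kind, e1, e2, model)
  data.frame(
    class_id = paste0(kind, "_", end_key(e1), "_", end_key(e2)),
    kind = kind, label = label,
    end1_locus = e1$locus, end1_position = e1$position,
    end1_guide = e1$guide, end1_side = e1$side,
    end2_locus = e2$locus, end2_position = e2$position,
    end2_guide = e2$guide, end2_side = e2$side,
    stringsAsFactors = FALSE)
}

# centromere-aware label for fusion-type classes; descriptive names otherwise
class_label <- function(kind, e1, e2, model) {
  if (kind %in% c("NHEJ", "DELETION", "INVERSION_J1", "INVERSION_J2")) {
    return(switch(kind,
      NHEJ = paste0("religation/indel at ", e1$guide),
      DELETION = "deletion junction",
      INVERSION_J1 = "inversion junction (upstream)",
      INVERSION_J2 = "inversion junction (downstream)"))
  }
  cen1 <- model$loci[[e1$locus]]$centromere_side
  cen2 <- model$loci[[e2$locus]]$centromere_side
  if (is.null(cen1) || is.null(cen2))
    return(tolower(gsub("_", " ", kind)))
  # a fragment carries the centromere iff the centromere lies on the side of
  # the cut that the free end retains
  n_cen <- (cen1 == e1$side) + (cen2 == e2$side)
  c("acentric", "balanced", "dicentric")[n_cen + 1L]
}

#' Which outcome classes can a primer set detect?
#'
#' A junction class is detectable iff at least one primer's free end takes
#' part in the junction (in either slot).
#'
#' @param classes A `ue_classes` data.frame from [enumerate_outcomes()].
#' @param model The `ue_model` holding the primers, or a list of
#'   `ue_primer` objects.
#' @return The detectable subset of `classes`, in canonical order, with a
#'   `detected_by` column of comma-separated primer names.
#' @export
detectable_classes <- function(classes, model) {
  primers <- if (inherits(model, "ue_model")) model$primers else {
    if (inherits(model, "ue_primer")) model <- list(model)
    do.call(rbind, lapply(model, function(p) data.frame(
      name = p$name, guide = p$guide, side = p$side, stringsAsFactors = FALSE)))
  }
  if (is.null(primers) || !nrow(primers)) {
    out <- classes[0, , drop = FALSE]
    out$detected_by <- character(0)
    return(out)
  }
  pkeys <- paste0(primers$guide, ".", substr(primers$side, 1, 1))
  k1 <- paste0(classes$end1_guide, ".", substr(classes$end1_side, 1, 1))
  k2 <- paste0(classes$end2_guide, ".", substr(classes$end2_side, 1, 1))
  det <- vapply(seq_len(nrow(classes)), function(i) {
    hit <- primers$name[pkeys %in% c(k1[i], k2[i])]
    paste(unique(hit), collapse = ",")
  }, character(1))
  keep <- nzchar(det)
  out <- classes[keep, , drop = FALSE]
  out$detected_by <- det[keep]
  rownames(out) <- NULL
  out
}

# --- amplicon construction ---------------------------------------------------

# flank sequences feeding a junction: the part ENDING at the junction (slot 1)
# and the part STARTING at it (slot 2); RIGHT-in-slot-1 and LEFT-in-slot-2
# flanks are reverse-complemented.
flank_left_of_junction <- function(model, locus, pos, side, flank) {
  seq <- model$loci[[locus]]$sequence
  if (side == "LEFT") {
    if (pos < flank) stop("flank ", flank, " exceeds sequence upstream of cut at ",
                          locus, ":", pos)
    substr(seq, pos - flank + 1L, pos)
  } else {
    if (pos + flank > nchar(seq))
      stop("flank ", flank, " exceeds sequence downstream of cut at ", locus, ":", pos)
    revcomp(substr(seq, pos + 1L, pos + flank))
  }
}

flank_right_of_junction <- function(model, locus, pos, side, flank) {
  seq <- model$loci[[locus]]$sequence
  if (side == "RIGHT") {
    if (pos + flank > nchar(seq))
      stop("flank ", flank, " exceeds sequence downstream of cut at ", locus, ":", pos)
    substr(seq, pos + 1L, pos + flank)
  } else {
    if (pos < flank) stop("flank ", flank, " exceeds sequence upstream of cut at ",
                          locus, ":", pos)
    revcomp(substr(seq, pos - flank + 1L, pos))
  }
}

#' Build reference amplicons for junction classes
#'
#' Each junction amplicon is the last `flank` bases of the first end's
#' retained sequence followed by the first `flank` bases of the second end's,
#' with reverse-complementation where the orientation demands; the junction
#' sits at offset `flank` (0-based). Wildtype amplicons span the cut
#' region of each locus, `min(cut) - flank` to `max(cut) + flank`, with
#' every cut offset recorded.
#'
#' @param model A `ue_model`.
#' @param classes A `ue_classes` data.frame (default: all enumerated
#'   outcomes).
#' @param flank Flank length in bp (default 350).
#' @param include_wildtype Also emit one wildtype amplicon per locus that
#'   carries a cut.
#' @return A data.frame of class `ue_amplicons`: `amplicon_id`, `class_id`,
#'   `kind`, `locus` (wildtype only), `sequence`, `junction_offsets`
#'   (list column; the junction offset for junction amplicons, all cut
#'   offsets for wildtype), `flank`.
#' @export
build_amplicons <- function(model, classes = enumerate_outcomes(model),
                            flank = 350L, include_wildtype = TRUE) {
  flank <- as.integer(flank)
  stopifnot(flank >= 1L)
  rows <- list()
  for (i in seq_len(nrow(classes))) {
    cl <- classes[i, ]
    left <- flank_left_of_junction(model, cl$end1_locus, cl$end1_position,
                                   cl$end1_side, flank)
    right <- flank_right_of_junction(model, cl$end2_locus, cl$end2_position,
                                     cl$end2_side, flank)
    rows[[length(rows) + 1L]] <- data.frame(
      amplicon_id = paste0("J_", cl$class_id),
      class_id = cl$class_id, kind = cl$kind, locus = NA_character_,
      sequence = paste0(left, right),
      junction_offsets = I(list(flank)),
      flank = flank, stringsAsFactors = FALSE)
  }
  if (include_wildtype) {
    for (ln in unique(model$cuts$locus)) {
      pos <- sort(model$cuts$position[model$cuts$locus == ln])
      seq <- model$loci[[ln]]$sequence
      start <- min(pos) - flank           # 0-based
      end <- max(pos) + flank             # half-open
      if (start < 0L || end > nchar(seq))
        stop("flank ", flank, " exceeds sequence bounds for wildtype span of '", ln, "'")
      rows[[length(rows) + 1L]] <- data.frame(
        amplicon_id = paste0("WT_", ln),
        class_id = "WILDTYPE", kind = "WILDTYPE", locus = ln,
        sequence = substr(seq, start + 1L, end),
        junction_offsets = I(list(pos - start)),
        flank = flank, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ue_amplicons", "data.frame")
  out
}

#' Reference amplicon set for pipeline alignment
#'
#' The working amplicon set used for read assignment: one wildtype amplicon
#' per cut-bearing locus plus one amplicon per non-NHEJ junction class.
#' Perfect-religation (NHEJ) junctions are sequence-identical to wildtype and
#' are quantified as (indel-free or indel-bearing) wildtype-amplicon
#' molecules, so they are omitted here to keep reference sequences unique.
#'
#' @inheritParams build_amplicons
#' @return A `ue_amplicons` data.frame.
#' @export
reference_amplicons <- function(model, flank = 350L,
                                classes = enumerate_outcomes(model)) {
  build_amplicons(model, classes[classes$kind != "NHEJ", , drop = FALSE],
                  flank = flank, include_wildtype = TRUE)
}

#' Export amplicons as FASTA plus a junction-offset sidecar TSV
#'
#' @param amplicons A `ue_amplicons` data.frame.
#' @param fasta_path Output FASTA path.
#' @param tsv_path Output TSV path (`amplicon_id`, `class_id`, `kind`,
#'   `junction_offset`, one row per offset; offsets are 0-based).
#' @return Invisibly, the two paths.
#' @export
export_amplicons <- function(amplicons, fasta_path, tsv_path) {
  seqs <- Biostrings::DNAStringSet(amplicons$sequence)
  names(seqs) <- amplicons$amplicon_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  off <- do.call(rbind, lapply(seq_len(nrow(amplicons)), function(i) data.frame(
    amplicon_id = amplicons$amplicon_id[i],
    class_id = amplicons$class_id[i],
    kind = amplicons$kind[i],
    junction_offset = unlist(amplicons$junction_offsets[[i]]),
    stringsAsFactors = FALSE)))
  con <- file(tsv_path, "w")
  writeLines("# junction_offset is 0-based; the junction falls between offset-1 and offset", con)
  write.table(off, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(fasta = fasta_path, tsv = tsv_path))
}

# --- model config I/O --------------------------------------------------------

#' Read an editing model from a YAML configuration
#'
#' Expected keys: `loci` (list of `{name, sequence | fasta, chrom_label?,
#' centromere_side?}`), `cuts` (list of `{locus, position, guide}`), and
#' `primers` (list of `{name, guide, side, distance_to_cut, sequence?}`).
#' A locus `fasta` entry is resolved relative to the config file.
#'
#' @param path YAML file path.
#' @return A `ue_model`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  loci <- lapply(cfg$loci, function(l) {
    seq <- l$sequence
    if (is.null(seq) && !is.null(l$fasta)) {
      fa <- Biostrings::readDNAStringSet(file.path(base, l$fasta))
      seq <- as.character(fa[[1]])
    }
    if (is.null(seq)) stop("locus '", l$name, "': no sequence or fasta given")
    locus(l$name, seq, l$chrom_label %||% l$name, l$centromere_side)
  })
  cuts <- lapply(cfg$cuts, function(x) cut_site(x$locus, x$position, x$guide))
  primers <- lapply(cfg$primers %||% list(), function(p)
    anchor_primer(p$name, p$guide, p$side, p$distance_to_cut, p$sequence))
  editing_model(loci, cuts, primers)
}

#' Write an editing model to YAML
#'
#' @param model A `ue_model`.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    loci = lapply(model$loci, function(l) {
      out <- list(name = l$name, sequence = l$sequence, chrom_label = l$chrom_label)
      if (!is.null(l$centromere_side)) out$centromere_side <- l$centromere_side
      out
    }),
    cuts = lapply(seq_len(nrow(model$cuts)), function(i) as.list(model$cuts[i, ])),
    primers = lapply(seq_len(nrow(model$primers)), function(i) {
      p <- as.list(model$primers[i, ])
      if (is.na(p$sequence)) p$sequence <- NULL
      p
    }))
  names(cfg$loci) <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}
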