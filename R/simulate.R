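# Synthetic library simulator: ground-truth-labelled paired reads emulating
# the anchored uni-directional tagmentation architecture.  Each template
# molecule carries a UMI; the fragment runs from the anchor primer's 3'
# terminus to a uniform tagmentation breakpoint; R1 is the primer-side read
# and R2 the transposase-side read (reverse-complemented); PCR duplicates
# share the molecule's UMI and fragment ends and re-draw sequencing errors
# independently.

#' Simulator configuration
#'
#' @param umi_length UMI length in nt (default 10, matching the ten
#'   consecutive ambiguity positions of the custom adapter design).
#' @param i5_barcode,i7_barcode 8-nt sample barcodes.
#' @param read_length Read length in nt (default 150).
#' @param fragment_min,fragment_max Fragment length range, drawn uniformly
#'   (default 150-600 bp).
#' @param duplicate_mean Mean total copies per molecule; copies are
#'   `1 + Geometric`, so the minimum is one copy (default mean 5).
#' @param substitution_error_rate Per-base substitution probability applied
#'   independently to every copy, including barcode and UMI bases
#'   (default 0.001).
#' @param indel_p_del Probability a small indel is a deletion (default 0.5).
#' @param indel_size_geom_p Geometric size parameter for indel length
#'   (default 0.3; sizes are `1 + Geometric(p)`).
#' @param indel_max_size Indel size cap (default 30).
#' @param dropout_prob Per-molecule dropout probability, a simple stand-in
#'   for library process yield (default 0: all molecules survive).
#' @return An object of class `ue_simconfig`.
#' @export
sim_config <- function(umi_length = 10L,
                       i5_barcode = "TAGATCGC", i7_barcode = "AGCGGAAT",
                       read_length = 150L,
                       fragment_min = 150L, fragment_max = 600L,
                       duplicate_mean = 5, substitution_error_rate = 0.001,
                       indel_p_del = 0.5, indel_size_geom_p = 0.3,
                       indel_max_size = 30L, dropout_prob = 0) {
  stopifnot(umi_length >= 1L, read_length >= 20L,
            fragment_min >= 1L, fragment_max >= fragment_min,
            duplicate_mean >= 1, substitution_error_rate >= 0,
            substitution_error_rate < 1, dropout_prob >= 0, dropout_prob < 1)
  structure(list(
    umi_length = as.integer(umi_length),
    i5_barcode = i5_barcode, i7_barcode = i7_barcode,
    read_length = as.integer(read_length),
    fragment_min = as.integer(fragment_min),
    fragment_max = as.integer(fragment_max),
    duplicate_mean = duplicate_mean,
    substitution_error_rate = substitution_error_rate,
    indel_p_del = indel_p_del, indel_size_geom_p = indel_size_geom_p,
    indel_max_size = as.integer(indel_max_size),
    dropout_prob = dropout_prob), class = "ue_simconfig")
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# add substitution errors at `rate` per base; returns mutated strings
add_substitutions <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0L & lens > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1L)
    }
  }
  seqs
}

# resolve a proportion label to a molecule recipe relative to one primer
resolve_outcome_label <- function(label, model, primer, classes) {
  if (label %in% c("WILDTYPE", "SMALL_INDEL"))
    return(list(type = label))
  hit <- classes[classes$class_id == label, , drop = FALSE]
  if (!nrow(hit)) hit <- classes[classes$kind == label, , drop = FALSE]
  if (label == "INVERSION")
    hit <- classes[classes$kind %in% c("INVERSION_J1", "INVERSION_J2"), , drop = FALSE]
  if (label == "INVERSION") {
    if (!nrow(hit)) stop("no inversion junctions enumerable for this model")
    return(list(type = "INVERSION"))
  }
  if (nrow(hit) != 1L)
    stop("outcome label '", label, "' does not resolve to exactly one junction class")
  list(type = "JUNCTION", class = hit)
}

# molecule template: full-length sequence plus the primer anchor
# (j = junction/cut coordinate on the molecule; strand + means the fragment
# extends rightward from the primer 3' end at j - distance)
molecule_template <- function(recipe, model, primer) {
  cuts <- model$cuts
  pc <- cuts[cuts$guide == primer$guide, ]
  lseq <- model$loci[[pc$locus]]$sequence
  if (recipe$type == "WILDTYPE") {
    return(list(seq = lseq, j = pc$position,
                strand = if (primer$side == "LEFT") "+" else "-"))
  }
  if (recipe$type == "INVERSION") {
    same <- cuts[cuts$locus == pc$locus, ]
    if (nrow(same) != 2L) stop("INVERSION requires two cuts on the primer locus")
    p1 <- min(same$position); p2 <- max(same$position)
    seq <- paste0(substr(lseq, 1L, p1),
                  revcomp(substr(lseq, p1 + 1L, p2)),
                  substr(lseq, p2 + 1L, nchar(lseq)))
    inside <- pc$position == p1 && primer$side == "RIGHT" ||
              pc$position == p2 && primer$side == "LEFT"
    if (!inside) {
      j <- if (pc$position == p1) p1 else p2
      strand <- if (primer$side == "LEFT") "+" else "-"
    } else {
      # primer site lies within the inverted segment: reflected and flipped
      j <- if (pc$position == p1) p2 else p1
      strand <- if (primer$side == "RIGHT") "+" else "-"
    }
    return(list(seq = seq, j = j, strand = strand))
  }
  cl <- recipe$class
  l1 <- model$loci[[cl$end1_locus]]$sequence
  l2 <- model$loci[[cl$end2_locus]]$sequence
  fl1 <- if (cl$end1_side == "LEFT") cl$end1_position else nchar(l1) - cl$end1_position
  fl2 <- if (cl$end2_side == "RIGHT") nchar(l2) - cl$end2_position else cl$end2_position
  left <- flank_left_of_junction(model, cl$end1_locus, cl$end1_position,
                                 cl$end1_side, fl1)
  right <- flank_right_of_junction(model, cl$end2_locus, cl$end2_position,
                                   cl$end2_side, fl2)
  pk <- paste0(primer$guide, ".", substr(primer$side, 1, 1))
  k1 <- paste0(cl$end1_guide, ".", substr(cl$end1_side, 1, 1))
  k2 <- paste0(cl$end2_guide, ".", substr(cl$end2_side, 1, 1))
  if (pk == k1) strand <- "+"
  else if (pk == k2) strand <- "-"
  else stop("primer '", primer$name, "' cannot detect class ", cl$class_id)
  list(seq = paste0(left, right), j = nchar(left), strand = strand)
}

# one small indel whose reference interval touches the cut; returns mutated
# molecule, its anchor, and a descriptor string
realize_small_indel <- function(lseq, cutpos, side, config) {
  size <- min(1L + rgeom(1L, config$indel_size_geom_p), config$indel_max_size)
  is_del <- runif(1L) < config$indel_p_del
  if (is_del) {
    start <- cutpos - sample.int(size + 1L, 1L) + 1L  # start in [cut-size, cut]
    start <- max(0L, min(start, nchar(lseq) - size))
    seq <- paste0(substr(lseq, 1L, start), substr(lseq, start + size + 1L, nchar(lseq)))
    # anchor: molecule coordinate whose offset by the primer distance lands on
    # the (unchanged) primer site
    j <- if (side == "LEFT") cutpos else cutpos - size
    desc <- sprintf("DEL:%d:%d", start, size)
  } else {
    ins <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE), collapse = "")
    seq <- paste0(substr(lseq, 1L, cutpos), ins, substr(lseq, cutpos + 1L, nchar(lseq)))
    j <- if (side == "LEFT") cutpos else cutpos + size
    desc <- sprintf("INS:%d:%s", cutpos, ins)
  }
  list(seq = seq, j = j, desc = desc)
}

#' Realize one edited molecule
#'
#' Returns the full-length sequence of a molecule of the requested outcome:
#' wildtype (the unmodified locus of the primer's cut), a small indel
#' touching the cut, a whole-inversion molecule, or any enumerated junction
#' class realized by joining the two ends' full flanks.
#'
#' @param label Outcome label: `"WILDTYPE"`, `"SMALL_INDEL"`,
#'   `"INVERSION"`, a junction `class_id`, or a kind that resolves uniquely
#'   (e.g. `"DELETION"`).
#' @param model A `ue_model`.
#' @param primer_name Name of the anchor primer the molecule is captured by.
#' @param config A [sim_config()] (used for the indel model).
#' @return A list with `seq`, `j` (junction/cut coordinate on the molecule),
#'   `strand` (fragment direction from the primer), and `indel` descriptor
#'   (NA unless a small indel).
#' @export
realize_molecule <- function(label, model, primer_name, config = sim_config()) {
  primer <- as.list(model$primers[model$primers$name == primer_name, ])
  if (!length(primer$name)) stop("unknown primer '", primer_name, "'")
  classes <- enumerate_outcomes(model)
  recipe <- resolve_outcome_label(label, model, primer, classes)
  if (recipe$type == "SMALL_INDEL") {
    pc <- model$cuts[model$cuts$guide == primer$guide, ]
    lseq <- model$loci[[pc$locus]]$sequence
    r <- realize_small_indel(lseq, pc$position, primer$side, config)
    return(list(seq = r$seq, j = r$j,
                strand = if (primer$side == "LEFT") "+" else "-",
                indel = r$desc))
  }
  tpl <- molecule_template(recipe, model, primer)
  list(seq = tpl$seq, j = tpl$j, strand = tpl$strand, indel = NA_character_)
}

#' Simulate a uni-directional tagmentation library
#'
#' Draws `n_molecules` template molecules at the configured outcome
#' proportions, places the anchored fragment (primer 3' end to a uniform
#' tagmentation breakpoint with uniform fragment length), emits paired reads
#' for each PCR copy with independent substitution errors, and returns reads
#' plus a ground-truth table. Fully reproducible from `seed`.
#'
#' @param model A `ue_model`.
#' @param primer_name Anchor primer used for this library.
#' @param proportions Named numeric vector of outcome proportions summing to
#'   1; names as in [realize_molecule()].
#' @param n_molecules Number of template molecules.
#' @param sample_name Sample label recorded in truth and headers.
#' @param config A [sim_config()].
#' @param seed Integer seed (set once at entry).
#' @return A list of class `ue_library`: `reads` (data.frame `id`, `header`,
#'   `r1`, `r2`), `truth` (one row per molecule), `sample_name`, `config`.
#' @export
simulate_library <- function(model, primer_name, proportions, n_molecules,
                             sample_name = "sample1", config = sim_config(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_molecules >= 1L, length(proportions) >= 1L,
            !is.null(names(proportions)))
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("outcome proportions must sum to 1")
  if (any(proportions < 0)) stop("outcome proportions must be >= 0")
  primer <- as.list(model$primers[model$primers$name == primer_name, ])
  if (!length(primer$name)) stop("unknown primer '", primer_name, "'")
  classes <- enumerate_outcomes(model)
  rl <- config$read_length

  labels <- names(proportions)
  true_class <- sample(labels, n_molecules, replace = TRUE, prob = proportions)
  if (config$dropout_prob > 0) {
    keep <- runif(n_molecules) >= config$dropout_prob
    true_class <- true_class[keep]
    n_molecules <- length(true_class)
  }

  # molecule sequences and anchors; non-indel templates are shared per label
  tpl <- lapply(setNames(labels, labels), function(lb) {
    if (lb == "SMALL_INDEL") NULL
    else molecule_template(resolve_outcome_label(lb, model, primer, classes),
                           model, primer)
  })
  mol_seq <- character(n_molecules)
  mol_j <- integer(n_molecules)
  mol_strand <- character(n_molecules)
  mol_indel <- rep(NA_character_, n_molecules)
  pc <- model$cuts[model$cuts$guide == primer$guide, ]
  lseq_primer <- model$loci[[pc$locus]]$sequence
  for (i in seq_len(n_molecules)) {
    lb <- true_class[i]
    if (lb == "SMALL_INDEL") {
      r <- realize_small_indel(lseq_primer, pc$position, primer$side, config)
      mol_seq[i] <- r$seq; mol_j[i] <- r$j
      mol_strand[i] <- if (primer$side == "LEFT") "+" else "-"
      mol_indel[i] <- r$desc
    } else {
      t <- tpl[[lb]]
      mol_seq[i] <- t$seq; mol_j[i] <- t$j; mol_strand[i] <- t$strand
    }
  }

  d <- primer$distance_to_cut
  mol_len <- nchar(mol_seq)
  flen <- config$fragment_min +
    floor(runif(n_molecules) * (config$fragment_max - config$fragment_min + 1L))
  fwd <- mol_strand == "+"
  pstart <- ifelse(fwd, mol_j - d, NA_integer_)      # 0-based fragment start
  pend <- ifelse(fwd, NA_integer_, mol_j + d)        # half-open fragment end
  if (any(fwd & (pstart < 0L)) || any(!fwd & (pend > mol_len)))
    stop("primer distance_to_cut places the primer outside a molecule")
  frag_start <- ifelse(fwd, pstart, pmax(0L, pend - flen))
  frag_end <- ifelse(fwd, pmin(mol_len, pstart + flen), pend)
  flen_act <- frag_end - frag_start
  short <- flen_act < rl
  rle1 <- pmin(rl, flen_act)

  # R1: primer-side; R2: breakpoint-side (reverse-complemented relative to R1)
  r1 <- ifelse(fwd,
               substr(mol_seq, frag_start + 1L, frag_start + rle1),
               revcomp(substr(mol_seq, frag_end - rle1 + 1L, frag_end)))
  r2 <- ifelse(fwd,
               revcomp(substr(mol_seq, frag_end - rle1 + 1L, frag_end)),
               substr(mol_seq, frag_start + 1L, frag_start + rle1))

  umi <- random_dna(n_molecules, config$umi_length)
  ndup <- 1L + rgeom(n_molecules, 1 / config$duplicate_mean)
  molecule_id <- sprintf("%s_mol%06d", sample_name, seq_len(n_molecules))

  # expand to copies and apply per-copy errors
  rep_idx <- rep(seq_len(n_molecules), ndup)
  copy_no <- sequence(ndup)
  ids <- paste0(molecule_id[rep_idx], ":", copy_no)
  er1 <- add_substitutions(r1[rep_idx], config$substitution_error_rate)
  er2 <- add_substitutions(r2[rep_idx], config$substitution_error_rate)
  eumi <- add_substitutions(umi[rep_idx], config$substitution_error_rate)
  ei5 <- add_substitutions(rep(config$i5_barcode, length(rep_idx)),
                           config$substitution_error_rate)
  ei7 <- add_substitutions(rep(config$i7_barcode, length(rep_idx)),
                           config$substitution_error_rate)
  headers <- paste0(ids, " BC:", ei5, "+", ei7, " UMI:", eumi)

  truth <- data.frame(
    molecule_id = molecule_id, sample_name = sample_name, umi = umi,
    true_class = true_class, indel = mol_indel,
    fragment_start = frag_start, fragment_end = frag_end,
    strand = mol_strand, n_duplicates = ndup, short_fragment = short,
    umi_collision = duplicated(umi) | duplicated(umi, fromLast = TRUE),
    stringsAsFactors = FALSE)

  structure(list(
    reads = data.frame(id = ids, header = headers, r1 = er1, r2 = er2,
                       stringsAsFactors = FALSE),
    truth = truth, sample_name = sample_name, primer_name = primer_name,
    config = config, proportions = proportions), class = "ue_library")
}

#' Combine simulated libraries into one run
#'
#' @param ... `ue_library` objects (e.g. one per sample barcode pair).
#' @return A `ue_library` with concatenated reads and truth.
#' @export
combine_libraries <- function(...) {
  libs <- list(...)
  stopifnot(length(libs) >= 1L)
  structure(list(
    reads = do.call(rbind, lapply(libs, `[[`, "reads")),
    truth = do.call(rbind, lapply(libs, `[[`, "truth")),
    sample_name = vapply(libs, `[[`, character(1), "sample_name"),
    primer_name = vapply(libs, `[[`, character(1), "primer_name"),
    config = lapply(libs, `[[`, "config"),
    proportions = lapply(libs, `[[`, "proportions")), class = "ue_library")
}

#' Write a simulated library to disk
#'
#' Emits gzipped R1/R2 FASTQ (UMI and barcodes in the header comment as
#' `BC:i5+i7 UMI:seq`), a ground-truth TSV, and the generating configuration
#' echoed as YAML.
#'
#' @param lib A `ue_library`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default "sim").
#' @param index_fastq Also write index reads: I1 carries the observed i7
#'   barcode, I2 the observed i5 barcode followed by the UMI (default
#'   FALSE; the same information always travels in the header comment).
#' @return Named character vector of the written paths.
#' @export
write_library <- function(lib, dir, prefix = "sim", index_fastq = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_r1 <- file.path(dir, paste0(prefix, "_R1.fastq.gz"))
  p_r2 <- file.path(dir, paste0(prefix, "_R2.fastq.gz"))
  p_truth <- file.path(dir, paste0(prefix, "_truth.tsv"))
  p_cfg <- file.path(dir, paste0(prefix, "_config.yaml"))
  write_fastq(lib$reads$header, lib$reads$r1, p_r1)
  write_fastq(lib$reads$header, lib$reads$r2, p_r2)
  idx_paths <- NULL
  if (index_fastq) {
    bc <- parse_header_barcodes(lib$reads$header)
    umi <- sub(".*\\bUMI:([ACGTN]+).*", "\\1", lib$reads$header)
    p_i1 <- file.path(dir, paste0(prefix, "_I1.fastq.gz"))
    p_i2 <- file.path(dir, paste0(prefix, "_I2.fastq.gz"))
    write_fastq(lib$reads$header, bc$i7, p_i1)
    write_fastq(lib$reads$header, paste0(bc$i5, umi), p_i2)
    idx_paths <- c(i1 = p_i1, i2 = p_i2)
  }
  con <- file(p_truth, "w")
  writeLines("# coordinates are 0-based, half-open (molecule coordinates)", con)
  write.table(lib$truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  cfg <- lib$config
  if (inherits(cfg, "ue_simconfig")) cfg <- list(unclass(cfg))
  else cfg <- lapply(cfg, unclass)
  yaml::write_yaml(list(samples = as.list(lib$sample_name),
                        primers = as.list(lib$primer_name),
                        proportions = if (is.list(lib$proportions))
                          lapply(lib$proportions, as.list) else as.list(lib$proportions),
                        config = cfg), p_cfg)
  c(r1 = p_r1, r2 = p_r2, truth = p_truth, config = p_cfg, idx_paths)
}

write_fastq <- function(headers, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- headers
  qs <- Biostrings::PhredQuality(strrep("I", nchar(seqs)))
  # constructor warns about dropping (empty) metadata columns
  out <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(x, qs))
  Biostrings::writeQualityScaledXStringSet(out, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read paired FASTQ files
#'
#' @param r1_path,r2_path FASTQ paths (optionally gzipped).
#' @return data.frame with `id`, `header`, `r1`, `r2`, `q1`, `q2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  # the reader warns about dropping (empty) metadata columns
  f1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1_path))
  f2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2_path))
  if (length(f1) != length(f2)) stop("R1/R2 read counts differ")
  data.frame(
    id = sub(" .*$", "", names(f1)),
    header = names(f1),
    r1 = as.character(f1), r2 = as.character(f2),
    q1 = as.character(Biostrings::quality(f1)),
    q2 = as.character(Biostrings::quality(f2)),
    stringsAsFactors = FALSE)
}
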