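# Benchmark scenarios on synthetic loci: a dual-guide excision experiment
# (one locus, two cuts ~1.2 kb apart, one anchor primer flanking the
# downstream cut), a dual-RNP two-locus translocation experiment, and the
# titration/assignment-robustness setups used for validation.
#
# The synthetic locus sequences are fixed (internal seed) so the genomic
# model is a constant of the scenario; the caller's seed drives every
# stochastic step (molecule sampling, fragments, duplicates, errors).

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  force(code)
}

fixed_seq <- function(n, seed) {
  with_preserved_rng({
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })
}

#' Synthetic dual-guide excision model
#'
#' One 3,000-bp synthetic locus (a stand-in for a real intronic target; no
#' genomic sequence is embedded) with two cuts 1,176 bp apart and one anchor
#' primer annealing 100 bp downstream of the second cut, reading back across
#' it. The detectable outcomes are cut-site indels, the inter-cut deletion
#' and inversion junctions, and the like-end homolog/sister fusion at the
#' primer-side cut.
#'
#' @return A `ue_model`.
#' @export
synthetic_dual_guide_model <- function() {
  editing_model(
    list(locus("CEPsyn", fixed_seq(3000L, 64323L), chrom_label = "chr12-like",
               centromere_side = "LEFT")),
    list(cut_site("CEPsyn", 1000L, "g64"), cut_site("CEPsyn", 2176L, "g323")),
    list(anchor_primer("p323", "g323", "RIGHT", 100L)))
}

#' Synthetic two-locus translocation model
#'
#' Two 2,500-bp synthetic loci on distinct chromosomes, one cut each, one
#' anchor primer per locus (LEFT flank, 100 bp from the cut), emulating a
#' dual-RNP T-cell editing experiment in which inter-chromosomal fusions are
#' detectable from either side.
#'
#' @return A `ue_model`.
#' @export
synthetic_translocation_model <- function() {
  editing_model(
    list(locus("TRACsyn", fixed_seq(2500L, 60621L), chrom_label = "chr14-like",
               centromere_side = "LEFT"),
         locus("B2Msyn", fixed_seq(2500L, 60622L), chrom_label = "chr15-like",
               centromere_side = "LEFT")),
    list(cut_site("TRACsyn", 1200L, "gT"), cut_site("B2Msyn", 1200L, "gB")),
    list(anchor_primer("pT", "gT", "LEFT", 100L),
         anchor_primer("pB", "gB", "LEFT", 100L)))
}

#' Quantify a simulated library in memory
#'
#' Runs the analysis path (UMI extraction from headers, amplicon
#' construction, pair assignment, classification, UMI collapse, tallying)
#' on a `ue_library` without the FASTQ round trip.
#'
#' @param lib A `ue_library`.
#' @param model The `ue_model` the library was simulated from.
#' @param flank Amplicon flank (default 350).
#' @param scheme A [scoring_scheme()].
#' @param quant A [quantify_config()].
#' @return A list: `frequencies` (`ue_freqtable`), `molecules`,
#'   `classified`.
#' @export
quantify_library <- function(lib, model, flank = 350L,
                             scheme = scoring_scheme(),
                             quant = quantify_config()) {
  classes <- enumerate_outcomes(model)
  amplicons <- reference_amplicons(model, flank = flank, classes = classes)
  um <- extract_umi(lib$reads)
  reads <- um$reads
  sample_of_read <- sub("_mol.*$", "", reads$id)
  classified <- list()
  for (s in unique(sample_of_read)) {
    idx <- sample_of_read == s
    asg <- assign_amplicons(reads$r1[idx], reads$r2[idx], amplicons, scheme)
    cls <- classify_pairs(asg, amplicons, classes, quant)
    cls$sample_name <- s
    cls$umi <- reads$umi[idx]
    classified[[s]] <- cls
  }
  classified <- do.call(rbind, classified)
  molecules <- collapse_umis(classified, quant)
  list(frequencies = tally(molecules), molecules = molecules,
       classified = classified)
}

#' Outcome proportions for the dual-guide excision benchmark
#'
#' The event mix of the bulk dual-guide excision experiment the benchmark
#' emulates: ~17% cut-site indels, ~40% inter-cut deletion junctions, ~18%
#' inversion junctions, ~0.75% homolog/sister fusion junctions, remainder
#' unedited.
#'
#' @return Named numeric vector summing to 1.
#' @export
dual_guide_proportions <- function() {
  c(SMALL_INDEL = 0.17, DELETION = 0.40, INVERSION = 0.18,
    HOMOLOG_RR_g323.R_g323.R = 0.0075, WILDTYPE = 0.2425)
}

#' Run the dual-guide excision benchmark end to end
#'
#' Simulates a UMI-tagged library at [dual_guide_proportions()], writes
#' FASTQ, runs the full file-based pipeline, and reports the measured
#' category frequencies in percent alongside the realized simulation truth.
#'
#' @param n_molecules Number of template molecules (default 30000).
#' @param seed Integer seed.
#' @param dir Working directory (default a temp dir).
#' @return A list with `measured_pct` (named: DELETION, INVERSION,
#'   SMALL_INDEL, HOMOLOG_FUSION, WILDTYPE), `truth_pct`, `denominator`,
#'   `run` (the [run_pipeline()] result).
#' @export
benchmark_dual_guide <- function(n_molecules = 30000L, seed = 1L,
                                 dir = tempfile("dualguide")) {
  model <- synthetic_dual_guide_model()
  cfg <- sim_config(i5_barcode = "TAGATCGC", i7_barcode = "AGCGGAAT")
  lib <- simulate_library(model, "p323", dual_guide_proportions(),
                          n_molecules, "u2os_bulk", cfg, seed = seed)
  paths <- write_library(lib, dir, "dualguide")
  sheet <- data.frame(sample_name = "u2os_bulk", i5_barcode = cfg$i5_barcode,
                      i7_barcode = cfg$i7_barcode, primer_name = "p323")
  run <- run_pipeline(model, paths[["r1"]], paths[["r2"]], sheet,
                      file.path(dir, "out"))
  tab <- run$frequencies$table
  pct <- function(cat) {
    v <- tab$frequency[tab$category == cat]
    if (length(v)) 100 * v else 0
  }
  cats <- c("DELETION", "INVERSION", "SMALL_INDEL", "HOMOLOG_FUSION",
            "WILDTYPE")
  measured <- vapply(cats, pct, numeric(1))
  grp <- c(DELETION = "DELETION", INVERSION = "INVERSION",
           SMALL_INDEL = "SMALL_INDEL", WILDTYPE = "WILDTYPE",
           HOMOLOG_RR_g323.R_g323.R = "HOMOLOG_FUSION")
  tgrp <- grp[lib$truth$true_class]
  truth <- 100 * table(factor(tgrp, levels = cats)) / nrow(lib$truth)
  list(measured_pct = measured, truth_pct = c(truth),
       denominator = run$frequencies$denominator[["u2os_bulk"]], run = run)
}

#' Per-locus outcome proportions for the translocation benchmark
#'
#' Event mixes for the two anchored libraries of the two-locus experiment:
#' ~82% indels at the first locus and ~91% at the second, ~2.5% of
#' molecules carrying an inter-chromosomal fusion junction detectable from
#' that locus's primer (split over the two detectable fusion classes),
#' remainder unedited.
#'
#' @return A list with named proportion vectors `pT` and `pB`.
#' @export
translocation_proportions <- function() {
  list(
    pT = c(SMALL_INDEL = 0.82, FUSION_RL_gT.L_gB.R = 0.0125,
           FUSION_LL_gB.L_gT.L = 0.0125, WILDTYPE = 0.155),
    pB = c(SMALL_INDEL = 0.91, FUSION_LR_gB.L_gT.R = 0.0125,
           FUSION_LL_gB.L_gT.L = 0.0125, WILDTYPE = 0.065))
}

#' Run the two-locus translocation benchmark end to end
#'
#' Simulates one library per anchor primer at
#' [translocation_proportions()], runs the file-based pipeline over both
#' samples, and reports the inter-locus fusion frequency (summed over fusion
#' junction classes, averaged over the two libraries) and the per-locus
#' indel frequencies, in percent.
#'
#' @param n_per_primer Molecules per library (default 20000).
#' @param seed Integer seed.
#' @param dir Working directory.
#' @return A list: `translocation_pct`, `indel_pct` (named by sample),
#'   `table`, `run`.
#' @export
benchmark_translocation <- function(n_per_primer = 20000L, seed = 1L,
                                    dir = tempfile("transloc")) {
  model <- synthetic_translocation_model()
  props <- translocation_proportions()
  cfgT <- sim_config(i5_barcode = "TAGATCGC", i7_barcode = "AGCGGAAT")
  cfgB <- sim_config(i5_barcode = "CTCTCTAT", i7_barcode = "GATCATGC")
  libT <- simulate_library(model, "pT", props$pT, n_per_primer,
                           "tcell_TRAC", cfgT, seed = seed)
  libB <- simulate_library(model, "pB", props$pB, n_per_primer,
                           "tcell_B2M", cfgB, seed = seed + 1L)
  lib <- combine_libraries(libT, libB)
  paths <- write_library(lib, dir, "transloc")
  sheet <- data.frame(
    sample_name = c("tcell_TRAC", "tcell_B2M"),
    i5_barcode = c(cfgT$i5_barcode, cfgB$i5_barcode),
    i7_barcode = c(cfgT$i7_barcode, cfgB$i7_barcode),
    primer_name = c("pT", "pB"))
  run <- run_pipeline(model, paths[["r1"]], paths[["r2"]], sheet,
                      file.path(dir, "out"))
  tab <- run$frequencies$table
  pick <- function(s, cat) {
    v <- tab$frequency[tab$sample_name == s & tab$category == cat]
    if (length(v)) 100 * v else 0
  }
  transloc <- mean(c(pick("tcell_TRAC", "TRANSLOCATION"),
                     pick("tcell_B2M", "TRANSLOCATION")))
  indels <- c(tcell_TRAC = pick("tcell_TRAC", "SMALL_INDEL"),
              tcell_B2M = pick("tcell_B2M", "SMALL_INDEL"))
  list(translocation_pct = transloc, indel_pct = indels, table = tab,
       run = run)
}

#' Assignment robustness benchmark
#'
#' Simulates a mixed outcome population with sequencing errors and reports
#' the percentage of read pairs whose best-amplicon assignment matches their
#' molecule's true class (wildtype and cut-site-indel molecules map to the
#' wildtype amplicon; inversion molecules may hit either junction
#' amplicon).
#'
#' @param n_molecules Number of molecules (default 10000).
#' @param seed Integer seed.
#' @return A list: `correct_pct`, `n_pairs`.
#' @export
benchmark_assignment <- function(n_molecules = 10000L, seed = 1L) {
  model <- synthetic_dual_guide_model()
  lib <- simulate_library(model, "p323", dual_guide_proportions(),
                          n_molecules, "s", sim_config(), seed = seed)
  amplicons <- reference_amplicons(model, flank = 350L)
  asg <- assign_amplicons(lib$reads$r1, lib$reads$r2, amplicons)
  truth <- lib$truth$true_class[match(sub(":.*", "", lib$reads$id),
                                      lib$truth$molecule_id)]
  expected <- list(
    WILDTYPE = "WT_CEPsyn", SMALL_INDEL = "WT_CEPsyn",
    DELETION = "J_DELETION_g64.L_g323.R",
    INVERSION = c("J_INVERSION_J1_g64.L_g323.L",
                  "J_INVERSION_J2_g64.R_g323.R"),
    HOMOLOG_RR_g323.R_g323.R = "J_HOMOLOG_RR_g323.R_g323.R")
  ok <- mapply(function(cl, amp) !is.na(amp) && amp %in% expected[[cl]],
               truth, asg$amplicon_id)
  list(correct_pct = 100 * mean(ok), n_pairs = length(ok))
}

#' Replicated titration benchmark
#'
#' Simulates independently seeded replicate libraries (2,860 unique
#' molecules each, the molecule yield of a standard 50-ng input at ~20%
#' process yield) across a deletion-frequency titration, quantifies each
#' in memory, and reports per-level measured frequencies, the replicate
#' log-scale R-squared, and the detection-rule LLoD.
#'
#' @param levels Titration frequencies (default square-root-of-ten steps
#'   from 50% to 0.1%).
#' @param n_molecules Molecules per library (default 2860).
#' @param n_replicates Replicate libraries per level (default 2).
#' @param seed Integer seed.
#' @return A list: `titration` (data.frame), `r_squared` (first vs second
#'   replicate), `llod`, `linearity` (a `ue_linfit` on positive points).
#' @export
benchmark_titration <- function(levels = 10^seq(log10(0.5), log10(0.001),
                                                length.out = 7),
                                n_molecules = 2860L, n_replicates = 2L,
                                seed = 1L) {
  model <- synthetic_dual_guide_model()
  rows <- list()
  k <- 0L
  for (rep_id in seq_len(n_replicates)) for (f in levels) {
    k <- k + 1L
    props <- c(DELETION = f, WILDTYPE = 1 - f)
    # derived sub-seeds stay within 32-bit integer range
    sub_seed <- (seed %% 100000000L) * 20L + k
    lib <- simulate_library(model, "p323", props, n_molecules, "tit",
                            sim_config(), seed = sub_seed)
    q <- quantify_library(lib, model)
    tab <- q$frequencies$table
    meas <- tab$frequency[tab$category == "DELETION"]
    rows[[k]] <- data.frame(
      expected_frequency = f,
      measured_frequency = if (length(meas)) meas else 0,
      replicate_id = rep_id)
  }
  tit <- do.call(rbind, rows)
  r1 <- tit$measured_frequency[tit$replicate_id == 1]
  r2 <- tit$measured_frequency[tit$replicate_id == 2]
  pos <- tit$measured_frequency > 0
  lin <- fit_linearity(data.frame(expected = tit$expected_frequency[pos],
                                  measured = tit$measured_frequency[pos]))
  list(titration = tit,
       r_squared = replicate_r_squared(r1, r2),
       llod = estimate_llod(tit),
       linearity = lin)
}
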