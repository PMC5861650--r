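# End-to-end orchestration: demultiplex -> UMI extraction -> amplicon
# construction -> alignment/assignment -> classification -> UMI collapse ->
# frequency tables, with a stable on-disk output layout and structured logs.
# All coordinates in output files are 0-based half-open.

#' Run configuration
#'
#' @param flank Amplicon flank length in bp (default 350).
#' @param scheme A [scoring_scheme()].
#' @param quant A [quantify_config()].
#' @param max_mismatch Barcode mismatches allowed per index (default 1).
#' @param adapter Optional 3' adapter to trim before alignment.
#' @param umi_length UMI length (default 10).
#' @param sam_export Write per-sample SAM of assignments (default FALSE).
#' @return An object of class `ue_runconfig`.
#' @export
run_config <- function(flank = 350L, scheme = scoring_scheme(),
                       quant = quantify_config(), max_mismatch = 1L,
                       adapter = NULL, umi_length = 10L, sam_export = FALSE) {
  structure(list(flank = as.integer(flank), scheme = scheme, quant = quant,
                 max_mismatch = as.integer(max_mismatch), adapter = adapter,
                 umi_length = as.integer(umi_length), sam_export = sam_export),
            class = "ue_runconfig")
}

#' Run the full quantification pipeline
#'
#' Executes demultiplexing, UMI extraction, optional adapter trimming,
#' reference amplicon construction, read-pair assignment, molecule
#' classification, UMI collapse and tallying for every sample in the sheet.
#' Identical inputs and configuration give identical outputs. A failing
#' sample is isolated: its error is recorded in the run summary and the
#' remaining samples complete.
#'
#' @param model A `ue_model` (or path to a YAML model config).
#' @param r1_path,r2_path Paired FASTQ paths.
#' @param sample_sheet Sample sheet path or data.frame
#'   ([read_sample_sheet()]).
#' @param out_dir Output directory; created if needed. Written files:
#'   `amplicons.fasta` + `amplicons.tsv`, per-sample
#'   `<sample>_frequencies.tsv` and `<sample>_qc.tsv`, `demux_summary.tsv`,
#'   `run_summary.json`, `run_config.yaml`, `run.log`.
#' @param config A [run_config()].
#' @return Invisibly, a list: `frequencies` (`ue_freqtable`), `molecules`,
#'   `classified`, `demux_counts`, `failures` (named list of errors),
#'   `status` (0 if all samples succeeded).
#' @export
run_pipeline <- function(model, r1_path, r2_path, sample_sheet, out_dir,
                         config = run_config()) {
  if (is.character(model)) model <- read_model_config(model)
  sheet <- read_sample_sheet(sample_sheet)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
    log_lines <<- c(log_lines, line)
  }

  reads <- read_fastq_pairs(r1_path, r2_path)
  log("input: %d read pairs", nrow(reads))

  dm <- demultiplex(reads, sheet, max_mismatch = config$max_mismatch)
  n_assigned <- sum(!is.na(dm$reads$sample_name))
  log("demultiplex: %d assigned + %d undetermined = %d total",
      n_assigned, nrow(reads) - n_assigned, nrow(reads))
  stopifnot(n_assigned + sum(is.na(dm$reads$sample_name)) == nrow(reads))

  um <- extract_umi(dm$reads, umi_length = config$umi_length)
  reads <- um$reads
  log("umi extraction: %d reads kept, %d discarded (short UMI), %d N-flagged",
      nrow(reads), um$n_discarded, sum(reads$umi_has_n))

  if (!is.null(config$adapter)) {
    t1 <- trim_adapter(reads$r1, reads$q1, config$adapter)
    t2 <- trim_adapter(reads$r2, reads$q2, config$adapter)
    reads$r1 <- t1$seq; reads$q1 <- t1$qual
    reads$r2 <- t2$seq; reads$q2 <- t2$qual
    log("adapter trimming done")
  }

  classes <- enumerate_outcomes(model)
  amplicons <- reference_amplicons(model, flank = config$flank,
                                   classes = classes)
  export_amplicons(amplicons, file.path(out_dir, "amplicons.fasta"),
                   file.path(out_dir, "amplicons.tsv"))
  log("amplicons: %d reference sequences (%d junction classes enumerated)",
      nrow(amplicons), nrow(classes))

  classified_all <- list()
  failures <- list()
  for (s in sheet$sample_name) {
    sub <- reads[!is.na(reads$sample_name) & reads$sample_name == s, ,
                 drop = FALSE]
    res <- tryCatch({
      if (nrow(sub) == 0L) {
        log("sample %s: 0 reads", s)
        NULL
      } else {
        asg <- assign_amplicons(sub$r1, sub$r2, amplicons, config$scheme)
        cls <- classify_pairs(asg, amplicons, classes, config$quant)
        cls$sample_name <- s
        cls$umi <- sub$umi
        cls$read_id <- sub$id
        log("sample %s: %d pairs, %d assigned, %d informative", s, nrow(cls),
            sum(!is.na(cls$amplicon_id)), sum(cls$informative))
        if (isTRUE(config$sam_export))
          export_sam(asg, sub$r1, sub$r2, amplicons,
                     file.path(out_dir, paste0(s, ".sam")),
                     read_ids = sub$id, umis = sub$umi)
        cls
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[s]] <- conditionMessage(res)
      log("sample %s: FAILED (%s)", s, conditionMessage(res))
    } else if (!is.null(res)) {
      classified_all[[s]] <- res
    }
  }

  classified <- if (length(classified_all)) do.call(rbind, classified_all)
                else NULL
  molecules <- if (!is.null(classified))
    collapse_umis(classified, config$quant) else data.frame()
  ft <- tally(molecules)
  if (!is.null(classified))
    log("molecules: %d distinct (sample, UMI) groups from %d pairs",
        nrow(molecules), nrow(classified))

  # per-sample outputs (frequencies printed to 6 decimals for stable reruns)
  for (s in unique(ft$table$sample_name)) {
    tab <- ft$table[ft$table$sample_name == s, , drop = FALSE]
    tab$frequency <- sprintf("%.6f", tab$frequency)
    write_tsv_commented(tab, file.path(out_dir, paste0(s, "_frequencies.tsv")),
      "# UMI-based outcome frequencies; denominator = molecules in detectable categories")
    qc <- ft$qc[ft$qc$sample_name == s, , drop = FALSE]
    write_tsv_commented(qc, file.path(out_dir, paste0(s, "_qc.tsv")),
      "# molecules excluded from the frequency denominator")
  }
  write_tsv_commented(dm$counts, file.path(out_dir, "demux_summary.tsv"),
                      "# reads per sample after dual-barcode demultiplexing")

  summary <- list(
    n_read_pairs = nrow(reads),
    samples = as.list(setNames(ft$denominator, names(ft$denominator))),
    failures = failures,
    status = if (length(failures)) 1L else 0L)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cfg_echo <- list(flank = config$flank,
                   scheme = unclass(config$scheme),
                   quant = unclass(config$quant),
                   max_mismatch = config$max_mismatch,
                   adapter = config$adapter %||% NA,
                   umi_length = config$umi_length)
  yaml::write_yaml(cfg_echo, file.path(out_dir, "run_config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(frequencies = ft, molecules = molecules,
                 classified = classified, demux_counts = dm$counts,
                 failures = failures,
                 status = if (length(failures)) 1L else 0L))
}

write_tsv_commented <- function(df, path, comment) {
  con <- file(path, "w")
  writeLines(c(comment, "# coordinates, where present, are 0-based half-open"),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
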