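test_that("realized molecules have the exact expected sequence surgery", {
  md <- dual_cut_model()
  L <- nchar(md$loci$locA$sequence)

  wt <- realize_molecule("WILDTYPE", md, "p64")
  expect_equal(wt$seq, md$loci$locA$sequence)

  # deletion between cuts 1176 bp apart shortens the molecule by exactly 1176
  del <- realize_molecule("DELETION", md, "p64")
  expect_equal(nchar(del$seq), L - 1176L)

  # inversion molecule: same length, inter-cut segment reverse-complemented
  inv <- realize_molecule("INVERSION", md, "p64")
  expect_equal(nchar(inv$seq), L)
  expect_equal(substr(inv$seq, 1001, 2176),
               revcomp(substr(md$loci$locA$sequence, 1001, 2176)))
  expect_equal(substr(inv$seq, 1, 1000), substr(md$loci$locA$sequence, 1, 1000))

  # small indels: length change matches the descriptor, distant flanks intact
  set.seed(40)
  for (i in 1:25) {
    si <- realize_molecule("SMALL_INDEL", md, "p64")
    parts <- strsplit(si$indel, ":")[[1]]
    if (parts[1] == "DEL") {
      size <- as.integer(parts[3])
      expect_equal(nchar(si$seq), L - size)
      # interval touches the cut point
      start <- as.integer(parts[2])
      expect_true(start <= 1000L && start + size >= 1000L)
    } else {
      size <- nchar(parts[3])
      expect_equal(nchar(si$seq), L + size)
    }
    expect_equal(substr(si$seq, 1, 960), substr(md$loci$locA$sequence, 1, 960))
  }

  expect_error(realize_molecule("NOPE", md, "p64"), "does not resolve")
})

test_that("library simulation is seed-reproducible and conserves counts", {
  md <- dual_cut_model()
  props <- c(DELETION = 0.5, WILDTYPE = 0.3, SMALL_INDEL = 0.2)
  lib1 <- simulate_library(md, "p64", props, 100, "s1", sim_config(), seed = 7)
  lib2 <- simulate_library(md, "p64", props, 100, "s1", sim_config(), seed = 7)
  expect_identical(lib1$reads, lib2$reads)
  expect_identical(lib1$truth, lib2$truth)

  expect_equal(nrow(lib1$truth), 100L)
  expect_equal(nrow(lib1$reads), sum(lib1$truth$n_duplicates))
  expect_true(all(nchar(lib1$truth$umi) == 10L))

  # written FASTQ files are byte-identical across reruns
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_library(lib1, d1)
  p2 <- write_library(lib2, d2)
  expect_identical(unname(tools::md5sum(p1[["r1"]])),
                   unname(tools::md5sum(p2[["r1"]])))
  expect_identical(readLines(p1[["truth"]]), readLines(p2[["truth"]]))

  # FASTQ round trip preserves sequences and header dialect
  back <- read_fastq_pairs(p1[["r1"]], p1[["r2"]])
  expect_equal(nrow(back), nrow(lib1$reads))
  expect_equal(back$r1, lib1$reads$r1)
  expect_true(all(grepl("BC:[ACGTN]+\\+[ACGTN]+ UMI:[ACGTN]+", back$header)))

  # index-read dialect: I1 = i7, I2 = i5 + UMI, consistent with the header
  d3 <- withr::local_tempdir()
  p3 <- write_library(lib1, d3, index_fastq = TRUE)
  i2 <- as.character(Biostrings::readDNAStringSet(p3[["i2"]],
                                                  format = "fastq"))
  hdr_umi <- sub(".*UMI:([ACGTN]+).*", "\\1", back$header)
  expect_equal(unname(substr(i2, 9, 18)), hdr_umi)
})

test_that("error-free wildtype reads are exact locus substrings", {
  md <- dual_cut_model()
  lib <- simulate_library(md, "p64", c(WILDTYPE = 1), 50, "s1",
                          sim_config(substitution_error_rate = 0), seed = 3)
  seqA <- md$loci$locA$sequence
  expect_true(all(vapply(lib$reads$r1, grepl, logical(1), x = seqA,
                         fixed = TRUE)))
  # R2 is the reverse-complemented breakpoint-side read
  expect_true(all(vapply(revcomp(lib$reads$r2), grepl, logical(1), x = seqA,
                         fixed = TRUE)))
})

test_that("per-class counts follow the configured multinomial", {
  md <- dual_cut_model()
  props <- c(DELETION = 0.4, WILDTYPE = 0.25, SMALL_INDEL = 0.17,
             INVERSION = 0.18)
  for (seed in c(11, 12, 13)) {
    lib <- simulate_library(md, "p64", props, 3000, "s1", sim_config(),
                            seed = seed)
    obs <- table(factor(lib$truth$true_class, levels = names(props)))
    p <- suppressWarnings(stats::chisq.test(obs, p = props)$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("junction read coverage matches the fragment-length expectation", {
  # with short tagmentation fragments (60-300 bp) the primer-side read is
  # truncated to the fragment, so it reaches the junction window only when
  # the fragment is long enough: probability given directly by the uniform
  # fragment-length law, P(len >= distance_to_cut + window)
  md <- dual_cut_model(primer_dist = 100L)
  cfg <- sim_config(substitution_error_rate = 0, fragment_min = 60L,
                    fragment_max = 300L)
  lib <- simulate_library(md, "p64", c(DELETION = 1), 2000, "s1", cfg, seed = 9)
  need <- 100L + 15L    # distance to cut + window
  p_expect <- (cfg$fragment_max - need + 1) /
    (cfg$fragment_max - cfg$fragment_min + 1)
  # measure on the reads themselves: R1 spans the junction +/- 15 iff the
  # junction amplicon's window sequence is contained in it
  amp <- build_amplicons(md, flank = 175L, include_wildtype = FALSE)
  del <- amp[amp$kind == "DELETION", ]
  win <- substr(del$sequence, 175L - 15L + 1L, 175L + 15L)
  first <- !duplicated(sub(":.*", "", lib$reads$id))
  frac <- mean(grepl(win, lib$reads$r1[first], fixed = TRUE))
  expect_lt(abs(frac - p_expect), 3 * sqrt(p_expect * (1 - p_expect) / 2000))
})

test_that("short fragments are truncated and flagged", {
  md <- dual_cut_model()
  cfg <- sim_config(fragment_min = 60L, fragment_max = 120L,
                    substitution_error_rate = 0)
  lib <- simulate_library(md, "p64", c(WILDTYPE = 1), 50, "s1", cfg, seed = 5)
  expect_true(all(lib$truth$short_fragment))
  expect_true(all(nchar(lib$reads$r1) < 150L))
  expect_equal(nchar(lib$reads$r1[1]),
               lib$truth$fragment_end[1] - lib$truth$fragment_start[1])
})

test_that("dropout thins molecules without touching proportions", {
  md <- dual_cut_model()
  cfg <- sim_config(dropout_prob = 0.8)
  lib <- simulate_library(md, "p64", c(WILDTYPE = 0.5, DELETION = 0.5),
                          2000, "s1", cfg, seed = 13)
  expect_lt(nrow(lib$truth), 600)    # ~20% yield
  frac <- mean(lib$truth$true_class == "DELETION")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(lib$truth)))
})
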