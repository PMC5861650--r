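# build a minimal one-row assignment data.frame by hand
fake_pair <- function(start1, end1, indels1 = "", valid1 = TRUE,
                      start2 = NA, end2 = NA, indels2 = "", valid2 = FALSE) {
  data.frame(amplicon_id = "J_X", pair_score = 0L, single_mate = !valid2,
             m1_valid = valid1, m1_strand = "+", m1_score = 0L,
             m1_ref_start = start1, m1_ref_end = end1, m1_cigar = "",
             m1_indels = indels1, m1_match = 0L, m1_cols = 0L,
             m2_valid = valid2, m2_strand = "-", m2_score = 0L,
             m2_ref_start = start2, m2_ref_end = end2, m2_cigar = "",
             m2_indels = indels2, m2_match = 0L, m2_cols = 0L,
             stringsAsFactors = FALSE)
}

test_that("junction window coverage is half-open, complete and gap-aware", {
  off <- 350L
  # spans offset-20 .. offset+20, all matches: covered
  expect_true(covers_junction(fake_pair(330L, 370L), off, 15L))
  # read ending exactly at offset+14: the half-open right bound is not reached
  expect_false(covers_junction(fake_pair(250L, 364L), off, 15L))
  # ...ending at offset+15 reaches it
  expect_true(covers_junction(fake_pair(250L, 365L), off, 15L))
  # a deletion crossing the junction breaks strict coverage
  expect_false(covers_junction(fake_pair(300L, 403L, "D:348:3"), off, 15L))
  # ...but satisfies the spanning-only reading
  expect_true(covers_junction(fake_pair(300L, 403L, "D:348:3"), off, 15L,
                              require_gapfree = FALSE))
  # an indel outside the window does not interfere
  expect_true(covers_junction(fake_pair(300L, 403L, "D:310:3"), off, 15L))
  # either mate suffices
  expect_true(covers_junction(
    fake_pair(10L, 60L, valid1 = TRUE, start2 = 330L, end2 = 380L,
              valid2 = TRUE), off, 15L))
})

test_that("small indel calls merge window-intersecting edits only", {
  cut <- 350L
  expect_true(is.na(call_small_indel(fake_pair(250L, 400L), cut)))
  got <- call_small_indel(fake_pair(250L, 403L, "D:349:3"), cut)
  expect_equal(got, "D:349:3")
  # insertion exactly at the cut
  expect_equal(call_small_indel(fake_pair(250L, 400L, "I:350:5"), cut),
               "I:350:5")
  # an indel far from the cut is not a cut-site indel
  expect_true(is.na(call_small_indel(fake_pair(250L, 403L, "D:100:3"), cut)))
})

test_that("UMI collapse counts molecules, resolves majorities, flags ties", {
  base <- data.frame(
    sample_name = "s", umi = "AAAAAAAAAA", category = "DELETION",
    subtype = "DELETION", indel = NA_character_, informative = TRUE,
    stringsAsFactors = FALSE)
  # 5 duplicates, same UMI and category: one molecule with 5 supporting reads
  m <- collapse_umis(base[rep(1, 5), ])
  expect_equal(nrow(m), 1L)
  expect_equal(m$supporting_reads, 5L)
  expect_equal(m$category, "DELETION")

  # two distinct UMIs: two molecules
  two <- rbind(base, transform(base, umi = "CCCCCCCCCC"))
  expect_equal(nrow(collapse_umis(two)), 2L)

  # 2 vs 2 split vote is ambiguous; 3 vs 1 resolves
  split <- base[rep(1, 4), ]
  split$category <- c("DELETION", "DELETION", "WILDTYPE", "WILDTYPE")
  expect_equal(collapse_umis(split)$category, "AMBIGUOUS")
  split$category[3] <- "DELETION"
  expect_equal(collapse_umis(split)$category, "DELETION")

  # molecules whose reads never cover a window are uninformative
  un <- transform(base, informative = FALSE, category = "UNINFORMATIVE")
  expect_equal(collapse_umis(un)$category, "UNINFORMATIVE")
})

test_that("directional 1-mismatch UMI collapse absorbs likely errors", {
  reads <- data.frame(
    sample_name = "s",
    umi = c(rep("ACGTACGTAC", 9), "ACGTACGTAT"),
    category = "DELETION", subtype = "DELETION", indel = NA_character_,
    informative = TRUE, stringsAsFactors = FALSE)
  cfg <- quantify_config(umi_collapse = "HAMMING1")
  m <- collapse_umis(reads, cfg)
  expect_equal(nrow(m), 1L)          # 9 >= 2*1 - 1: absorbed
  expect_equal(m$supporting_reads, 10L)

  # equal counts are NOT absorbed (9 < 2*9 - 1)
  reads2 <- transform(reads, umi = rep(c("ACGTACGTAC", "ACGTACGTAT"), 5))
  expect_equal(nrow(collapse_umis(reads2, cfg)), 2L)

  # exact policy keeps both
  expect_equal(nrow(collapse_umis(reads, quantify_config())), 2L)
})

test_that("frequency tables use UMI counts over the detectable denominator", {
  mols <- data.frame(
    sample_name = "s",
    umi = replicate(100, rand_seq(10)),
    category = rep(c("DELETION", "WILDTYPE"), c(40, 60)),
    subtype = NA, indel = NA, supporting_reads = 2L,
    stringsAsFactors = FALSE)
  ft <- tally(mols)
  expect_equal(ft$denominator[["s"]], 100L)
  expect_equal(ft$table$frequency[ft$table$category == "DELETION"], 0.40)
  expect_equal(ft$table$frequency[ft$table$category == "WILDTYPE"], 0.60)
  expect_equal(sum(ft$table$frequency), 1.0)

  # single category: frequency 1
  ft1 <- tally(transform(mols, category = "DELETION"))
  expect_equal(ft1$table$frequency, 1.0)

  # excluded categories leave the denominator and land in QC
  mols$category[1:10] <- "UNASSIGNED"
  ft2 <- tally(mols)
  expect_equal(ft2$denominator[["s"]], 90L)
  expect_equal(ft2$qc$umi_count, 10L)
  # conservation: included + excluded = all molecules
  expect_equal(sum(ft2$table$umi_count) + sum(ft2$qc$umi_count), 100L)

  # empty input: zero rows, no division
  ft0 <- tally(mols[0, ])
  expect_equal(nrow(ft0$table), 0L)
})

test_that("PCR depth cancels out of UMI-based frequencies", {
  md <- dual_cut_model()
  props <- c(DELETION = 0.6, WILDTYPE = 0.4)
  amps <- reference_amplicons(md, flank = 350L)
  classes <- enumerate_outcomes(md)
  run_depth <- function(dup_mean) {
    lib <- simulate_library(md, "p64", props, 150, "s",
                            sim_config(substitution_error_rate = 0,
                                       duplicate_mean = dup_mean), seed = 15)
    asg <- assign_amplicons(lib$reads$r1, lib$reads$r2, amps)
    cls <- classify_pairs(asg, amps, classes)
    cls$sample_name <- "s"
    cls$umi <- lib$truth$umi[match(sub(":.*", "", lib$reads$id),
                                   lib$truth$molecule_id)]
    tally(collapse_umis(cls))
  }
  shallow <- run_depth(1)
  deep <- run_depth(8)
  # same seed draws the same 150 molecules; only duplication depth differs
  expect_equal(shallow$table[c("category", "umi_count", "frequency")],
               deep$table[c("category", "umi_count", "frequency")])
})

test_that("estimated frequencies converge to truth as libraries grow", {
  md <- dual_cut_model()
  props <- c(DELETION = 0.35, WILDTYPE = 0.45, SMALL_INDEL = 0.2)
  amps <- reference_amplicons(md, flank = 350L)
  classes <- enumerate_outcomes(md)
  err <- vapply(c(300, 3000), function(n) {
    lib <- simulate_library(md, "p64", props, n,
                            "s", sim_config(duplicate_mean = 2), seed = 100 + n)
    asg <- assign_amplicons(lib$reads$r1, lib$reads$r2, amps)
    cls <- classify_pairs(asg, amps, classes)
    cls$sample_name <- "s"
    cls$umi <- lib$truth$umi[match(sub(":.*", "", lib$reads$id),
                                   lib$truth$molecule_id)]
    ft <- tally(collapse_umis(cls))
    truth <- table(lib$truth$true_class) / n
    max(abs(ft$table$frequency[match(names(truth), ft$table$category)] -
              as.numeric(truth)))
  }, numeric(1))
  # recovery error within 3 multinomial SDs of zero at each depth
  expect_lt(err[1], 3 * sqrt(0.5 * 0.5 / 300))
  expect_lt(err[2], 3 * sqrt(0.5 * 0.5 / 3000))
  expect_lt(err[2], err[1] + 0.02)   # shrinking with n
})
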