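test_that("outcome enumeration matches the brute-force end-pairing oracle", {
  # two cuts on distinct loci: 10 rc-deduplicated classes
  m2 <- two_locus_model()
  cls2 <- enumerate_outcomes(m2)
  expect_equal(nrow(cls2), 10L)
  expect_equal(length(oracle_enumerate(m2)), 10L)

  # one cut: religation plus the two like-end self fusions
  m1 <- editing_model(list(locus("locA", rand_seq(500, 3))),
                      list(cut_site("locA", 250L, "g1")))
  cls1 <- enumerate_outcomes(m1)
  expect_equal(nrow(cls1), 3L)
  expect_setequal(cls1$kind, c("NHEJ", "HOMOLOG_LL", "HOMOLOG_RR"))
  expect_equal(length(oracle_enumerate(m1)), 3L)

  # two cuts on one locus: one deletion, two inversion junctions
  md <- dual_cut_model()
  clsd <- enumerate_outcomes(md)
  expect_equal(nrow(clsd), 10L)
  expect_equal(sum(clsd$kind == "DELETION"), 1L)
  expect_equal(sum(clsd$kind %in% c("INVERSION_J1", "INVERSION_J2")), 2L)
  expect_equal(length(oracle_enumerate(md)), 10L)

  # junction sequences agree with the oracle's rc-deduplicated set
  for (model in list(m2, md)) {
    amps <- build_amplicons(model, flank = 20L, include_wildtype = FALSE)
    got <- amps$sequence
    want <- oracle_enumerate(model, flank = 20L)
    canon <- function(x) pmin(x, revcomp(x))
    expect_setequal(canon(got), canon(want))
  }

  # involution: enumerating is stable / deterministic
  expect_identical(enumerate_outcomes(m2), enumerate_outcomes(m2))
  expect_error(enumerate_outcomes(editing_model(
    list(locus("l", rand_seq(300, 4))),
    list(cut_site("l", 50, "a"), cut_site("l", 150, "b"), cut_site("l", 250, "c")))),
    "more than 2")
})

test_that("primer detectability follows end membership", {
  m2 <- two_locus_model()   # primers on the LEFT flank of each cut
  cls <- enumerate_outcomes(m2)
  det <- detectable_classes(cls, m2)
  expect_equal(nrow(det), 7L)

  # the three undetected classes involve only RIGHT ends
  undet <- cls[!cls$class_id %in% det$class_id, ]
  expect_setequal(undet$kind, c("FUSION_RR", "HOMOLOG_RR", "HOMOLOG_RR"))
  expect_true(all(undet$end1_side == "RIGHT" & undet$end2_side == "RIGHT"))

  # no primers: nothing detectable
  m0 <- editing_model(m2$loci, list(cut_site("TRACsyn", 1200L, "gT"),
                                    cut_site("B2Msyn", 1200L, "gB")))
  expect_equal(nrow(detectable_classes(cls, m0)), 0L)

  # one primer per free end: everything detectable
  mall <- editing_model(m2$loci,
    list(cut_site("TRACsyn", 1200L, "gT"), cut_site("B2Msyn", 1200L, "gB")),
    list(anchor_primer("p1", "gT", "LEFT", 50), anchor_primer("p2", "gT", "RIGHT", 50),
         anchor_primer("p3", "gB", "LEFT", 50), anchor_primer("p4", "gB", "RIGHT", 50)))
  expect_equal(nrow(detectable_classes(cls, mall)), nrow(cls))
})

test_that("amplicon construction is exact string surgery", {
  md <- dual_cut_model()
  seqA <- md$loci$locA$sequence
  amps <- reference_amplicons(md, flank = 350L)

  # deletion arithmetic: wildtype span exceeds the deletion amplicon by the
  # inter-cut distance
  wt <- amps[amps$kind == "WILDTYPE", ]
  del <- amps[amps$kind == "DELETION", ]
  expect_equal(nchar(wt$sequence) - nchar(del$sequence), 1176L)
  expect_equal(nchar(del$sequence), 700L)

  # NHEJ amplicon on an unedited locus is the plain cut +/- flank slice
  cls <- enumerate_outcomes(md)
  nhej <- build_amplicons(md, cls[cls$kind == "NHEJ" & cls$end1_guide == "g64", ],
                          flank = 300L, include_wildtype = FALSE)
  expect_equal(nhej$sequence, substr(seqA, 1000L - 300L + 1L, 1000L + 300L))

  # inversion J1: right half is the reverse complement of the inter-cut
  # segment's tail-end bases (the segment read back from its far end)
  j1 <- build_amplicons(md, cls[cls$kind == "INVERSION_J1", ], flank = 60L,
                        include_wildtype = FALSE)
  right_half <- substr(j1$sequence, 61L, 120L)
  expect_equal(right_half, revcomp(substr(seqA, 2176L - 60L + 1L, 2176L)))

  # every junction amplicon half matches (or rc-matches) a locus substring
  small <- build_amplicons(md, cls, flank = 40L, include_wildtype = FALSE)
  for (i in seq_len(nrow(small))) {
    halves <- c(substr(small$sequence[i], 1, 40), substr(small$sequence[i], 41, 80))
    for (h in halves)
      expect_true(grepl(h, seqA, fixed = TRUE) ||
                  grepl(revcomp(h), seqA, fixed = TRUE))
    expect_equal(unlist(small$junction_offsets[[i]]), 40L)
  }

  # flank beyond the available sequence is a bounds error
  expect_error(build_amplicons(md, cls, flank = 1500L), "flank")
})

test_that("centromere annotation labels fusions balanced/dicentric/acentric", {
  m <- two_locus_model()   # both centromeres on the LEFT side
  cls <- enumerate_outcomes(m)
  lab <- setNames(cls$label, cls$kind)
  expect_equal(unname(lab["FUSION_LL"]), "dicentric")
  expect_equal(unname(lab["FUSION_RR"]), "acentric")
  expect_true(all(cls$label[cls$kind %in% c("FUSION_LR", "FUSION_RL")] == "balanced"))
})

test_that("model configuration round-trips through YAML", {
  m <- two_locus_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(m, path)
  m2 <- read_model_config(path)
  expect_equal(m2$cuts, m$cuts)
  expect_equal(m2$primers$name, m$primers$name)
  expect_equal(vapply(m2$loci, `[[`, character(1), "sequence"),
               vapply(m$loci, `[[`, character(1), "sequence"))
})

test_that("amplicon export writes FASTA plus 0-based offsets sidecar", {
  md <- dual_cut_model()
  amps <- reference_amplicons(md, flank = 100L)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_amplicons(amps, fa, tsv)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(back), nrow(amps))
  expect_equal(sort(names(back)), sort(amps$amplicon_id))
  off <- read.delim(tsv, comment.char = "#")
  expect_true(all(off$junction_offset[off$kind == "DELETION"] == 100L))
})
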