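# Shared fixtures and independent oracles, all built in code.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# two cuts 1176 bp apart on one locus, anchored primer upstream of the first
dual_cut_model <- function(seed = 1, primer_side = "LEFT", primer_dist = 100L) {
  lA <- locus("locA", rand_seq(3000, seed))
  editing_model(
    list(lA),
    list(cut_site("locA", 1000L, "g64"), cut_site("locA", 2176L, "g323")),
    list(anchor_primer("p64", "g64", primer_side, primer_dist)))
}

# one cut on each of two loci ("different chromosomes"), one primer each
two_locus_model <- function(seed = 2, len = 2500L, cutpos = 1200L) {
  lT <- locus("TRACsyn", rand_seq(len, seed), centromere_side = "LEFT")
  set.seed(seed + 1000)
  lB <- locus("B2Msyn", rand_seq(len), centromere_side = "LEFT")
  editing_model(
    list(lT, lB),
    list(cut_site("TRACsyn", cutpos, "gT"), cut_site("B2Msyn", cutpos, "gB")),
    list(anchor_primer("pT", "gT", "LEFT", 100L),
         anchor_primer("pB", "gB", "LEFT", 100L)))
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", sapply(lapply(strsplit(x, ""), rev), paste, collapse = ""))
}

# ---------------------------------------------------------------------------
# brute-force junction enumeration oracle: join every ordered pair of free
# ends in both orientations, build the junction sequence with a fixed flank,
# and deduplicate by sequence-or-reverse-complement identity
# ---------------------------------------------------------------------------
oracle_enumerate <- function(model, flank = 20L) {
  ends <- list()
  for (i in seq_len(nrow(model$cuts))) {
    cut <- model$cuts[i, ]
    for (side in c("LEFT", "RIGHT"))
      ends[[length(ends) + 1L]] <- list(locus = cut$locus, pos = cut$position,
                                        side = side)
  }
  left_of <- function(e) {
    s <- model$loci[[e$locus]]$sequence
    if (e$side == "LEFT") substr(s, e$pos - flank + 1L, e$pos)
    else oracle_revcomp(substr(s, e$pos + 1L, e$pos + flank))
  }
  right_of <- function(e) {
    s <- model$loci[[e$locus]]$sequence
    if (e$side == "RIGHT") substr(s, e$pos + 1L, e$pos + flank)
    else oracle_revcomp(substr(s, e$pos - flank + 1L, e$pos))
  }
  seqs <- character(0)
  for (e1 in ends) for (e2 in ends) {
    jx <- paste0(left_of(e1), right_of(e2))
    if (!(jx %in% seqs) && !(oracle_revcomp(jx) %in% seqs))
      seqs <- c(seqs, jx)
  }
  seqs
}

# ---------------------------------------------------------------------------
# independent glocal alignment oracle: top-down recursion with memoisation
# over (read position, ref position, state), read aligned end-to-end, free
# reference end gaps, affine gaps
# ---------------------------------------------------------------------------
oracle_glocal_score <- function(read, ref, match = 2, mismatch = -4,
                                gap_open = -6, gap_extend = -1) {
  r <- strsplit(read, "")[[1]]
  f <- strsplit(ref, "")[[1]]
  m <- length(r); n <- length(f)
  memo <- new.env(hash = TRUE)
  # best(i, j, st): best score of aligning read[1..i] ending at ref prefix j
  # in state st (1 = diagonal, 2 = insertion run, 3 = deletion run)
  best <- function(i, j, st) {
    if (i == 0L) {
      if (st == 3L) return(-Inf)            # leading deletions are pointless
      return(if (st == 1L) 0 else -Inf)     # free reference prefix
    }
    key <- paste(i, j, st)
    if (!is.null(v <- memo[[key]])) return(v)
    v <- -Inf
    if (st == 1L) {                         # consumed read[i] and ref[j]
      if (j >= 1L) {
        s <- if (r[i] == f[j]) match else mismatch
        v <- max(best(i - 1L, j - 1L, 1L),
                 best(i - 1L, j - 1L, 2L),
                 best(i - 1L, j - 1L, 3L)) + s
      }
    } else if (st == 2L) {                  # consumed read[i] against a gap
      v <- max(best(i - 1L, j, 1L) + gap_open + gap_extend,
               best(i - 1L, j, 2L) + gap_extend,
               best(i - 1L, j, 3L) + gap_open + gap_extend)
    } else {                                # consumed ref[j] against a gap
      if (j >= 1L)
        v <- max(best(i, j - 1L, 1L) + gap_open + gap_extend,
                 best(i, j - 1L, 3L) + gap_extend,
                 best(i, j - 1L, 2L) + gap_open + gap_extend)
    }
    memo[[key]] <- v
    v
  }
  out <- -Inf
  for (j in 0:n)                            # free reference suffix
    out <- max(out, best(m, j, 1L), best(m, j, 2L))
  out
}

# exhaustive path enumeration for tiny inputs (anchors the memoised oracle)
oracle_glocal_enum <- function(read, ref, match = 2, mismatch = -4,
                               gap_open = -6, gap_extend = -1) {
  r <- strsplit(read, "")[[1]]
  f <- strsplit(ref, "")[[1]]
  m <- length(r); n <- length(f)
  best <- -Inf
  walk <- function(i, j, score, last) {
    if (i > m) {
      best <<- max(best, score)             # remaining ref is a free suffix
      return(invisible())
    }
    if (j <= n) {
      s <- if (r[i] == f[j]) match else mismatch
      walk(i + 1L, j + 1L, score + s, "M")
    }
    walk(i + 1L, j, score + (if (last == "I") gap_extend
                             else gap_open + gap_extend), "I")
    if (j <= n && last != "start")          # no leading deletions
      walk(i, j + 1L, score + (if (last == "D") gap_extend
                               else gap_open + gap_extend), "D")
  }
  for (j0 in 0:n) walk(1L, j0 + 1L, 0, "start")
  best
}

# brute-force exact binomial tail scan for min_trials
oracle_min_trials <- function(k, p, confidence) {
  n <- k
  repeat {
    if (pbinom(k - 1, n, p, lower.tail = FALSE) >= confidence) return(n)
    n <- n + 1L
    if (n > 5e6) stop("oracle scan exceeded bound")
  }
}

# truth-vs-measured helper: realized truth fractions over category groups
truth_fractions <- function(truth, map) {
  grp <- map[truth$true_class]
  grp[is.na(grp)] <- truth$true_class[is.na(grp)]
  table(grp) / nrow(truth)
}
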