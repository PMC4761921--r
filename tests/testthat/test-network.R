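library(GenomicRanges)

test_that("promoter windows extend 5 kb upstream, strand-aware, clipped", {
  tr <- make_transcripts(start0 = c(10000, 10000, 3000),
                         end0 = c(20000, 20000, 9000),
                         strand = c("+", "-", "+"))
  w <- promoter_window(tr)
  # BED coordinates: start = start(gr) - 1, end = end(gr)
  expect_equal(start(w) - 1, c(5000, 10000, 0))
  expect_equal(end(w), c(20000, 25000, 9000))
  # window length = transcript length + min(upstream, available room)
  expect_equal(width(w) - width(tr), c(5000, 5000, 3000))
  expect_error(promoter_window(GRanges("c", IRanges(1, 10), strand = "*")),
               "stranded")
})

test_that("TSS correction statuses and center arithmetic are right", {
  tr <- make_transcripts(10000, 20000, "+")
  h3_at_tss <- make_peaks(9500, 10500)
  pol_at_tss <- make_peaks(9800, 10400)
  both <- correct_tss(tr, h3_at_tss, pol_at_tss)
  expect_equal(both$tss_status, "h3k4me3_and_polii")
  expect_equal(start(both), start(tr))
  only_h3 <- correct_tss(tr, h3_at_tss, make_peaks(5e6, 5e6 + 100))
  expect_equal(only_h3$tss_status, "h3k4me3_only")
  expect_equal(start(only_h3), start(tr))
  # neither mark near the 5' end: move to the center of the nearest
  # H3K4me3 peak; BED peak [7000, 7500) has center 7250
  far_h3 <- make_peaks(7000, 7500)
  fixed <- correct_tss(tr, far_h3, make_peaks(5e6, 5e6 + 100))
  expect_equal(fixed$tss_status, "corrected")
  expect_equal(start(fixed) - 1, 7250)
  expect_equal(end(fixed), end(tr))          # 3' end untouched
  expect_equal(as.character(strand(fixed)), "+")
  # no anchor within reach
  none <- correct_tss(tr, make_peaks(5e6, 5e6 + 100),
                      make_peaks(6e6, 6e6 + 100))
  expect_equal(none$tss_status, "uncorrectable")
  expect_equal(start(none), start(tr))
})

test_that("TSS correction breaks ties upstream and is idempotent", {
  tr <- make_transcripts(10000, 20000, "+")
  # peak centers 3000 bp up- and downstream of the 5' end: upstream wins
  ties <- make_peaks(c(6900, 12900), c(7100, 13100))
  fixed <- correct_tss(tr, ties, GRanges())
  expect_equal(start(fixed) - 1, 7000)
  again <- correct_tss(fixed, ties, GRanges())
  expect_equal(start(again), start(fixed))
  expect_equal(end(again), end(fixed))
  # minus strand: upstream means higher coordinate
  trm <- make_transcripts(10000, 20000, "-")
  tiesm <- make_peaks(c(16800, 22800), c(17199, 23199))
  fixm <- correct_tss(trm, tiesm, GRanges())
  expect_equal(end(fixm), 23000)
})

test_that("TSS correction equals a naive nearest-peak scan on small cases", {
  set.seed(51)
  for (rep in 1:25) {
    s0 <- sample(20000:40000, 1)
    str <- sample(c("+", "-"), 1)
    tr <- make_transcripts(s0, s0 + 8000, str)
    tss0 <- if (str == "+") s0 else s0 + 8000
    np <- sample(1:5, 1)
    ps <- sort(sample(seq(s0 - 15000, s0 + 15000, by = 50), np))
    peaks <- make_peaks(ps, ps + sample(100:400, np, replace = TRUE))
    got <- correct_tss(tr, peaks, GRanges(), tss_flank = 500,
                       max_distance = 10000)
    # naive scan in BED coordinates
    centers <- floor((start(peaks) - 1 + end(peaks)) / 2)
    overl <- (start(peaks) - 1) < (tss0 + 500) & end(peaks) > (tss0 - 500)
    if (any(overl)) {
      expect_equal(got$tss_status, "h3k4me3_only")
      expect_equal(start(got), start(tr))
    } else {
      d <- abs(centers - tss0)
      ok <- d <= 10000
      if (!any(ok)) {
        expect_equal(got$tss_status, "uncorrectable")
      } else {
        best <- centers[ok][d[ok] == min(d[ok])]
        want <- if (str == "+") min(best) else max(best)
        expect_equal(got$tss_status, "corrected")
        expect_equal(if (str == "+") start(got) - 1 else end(got) - 1,
                     want)
      }
    }
  }
})

test_that("regulator assignment enforces the BMAL1 two-dataset rule", {
  tr <- make_transcripts(10000, 20000, "+")
  inside <- make_peaks(6000, 6300, "BMAL1", support = 1L)
  expect_equal(nrow(assign_regulators(tr, inside)), 0L)
  inside2 <- make_peaks(6000, 6300, "BMAL1", support = 2L)
  e <- assign_regulators(tr, inside2)
  expect_equal(e$regulator, "BMAL1")
  expect_equal(e$transcript, "t1")
  # other regulators need a single dataset
  other <- make_peaks(6000, 6300, "PER1", support = 1L)
  expect_equal(nrow(assign_regulators(tr, other)), 1L)
  # strict rule table: unknown regulator is an error
  expect_error(assign_regulators(tr, other, default_support = NA),
               "PER1")
  expect_error(assign_regulators(tr, make_peaks(1, 10, "X", 0L)), ">= 1")
})

test_that("a peak abutting the window does not overlap (half-open)", {
  tr <- make_transcripts(10000, 20000, "+")   # window BED [5000, 20000)
  abut_left <- make_peaks(4800, 5000)         # ends exactly at 5000
  expect_equal(nrow(assign_regulators(tr, abut_left)), 0L)
  abut_right <- make_peaks(20000, 20200)      # starts exactly at 20000
  expect_equal(nrow(assign_regulators(tr, abut_right)), 0L)
  one_bp <- make_peaks(4801, 5001)            # 1 bp inside
  expect_equal(nrow(assign_regulators(tr, one_bp)), 1L)
})

test_that("regulator assignment equals the quadratic overlap oracle", {
  set.seed(52)
  for (rep in 1:15) {
    nt <- sample(3:8, 1)
    s0 <- sort(sample(seq(10000, 4e5, by = 100), nt))
    tr_df <- data.frame(id = paste0("t", seq_len(nt)), start0 = s0,
                        end0 = s0 + sample(2000:20000, nt, replace = TRUE),
                        strand = sample(c("+", "-"), nt, replace = TRUE),
                        stringsAsFactors = FALSE)
    np <- sample(5:25, 1)
    p0 <- sample(seq(1000, 4.5e5, by = 50), np)
    peak_df <- data.frame(
      start0 = p0, end0 = p0 + sample(100:500, np, replace = TRUE),
      regulator = sample(c("BMAL1", "CLOCK", "PER1"), np, replace = TRUE),
      support = sample(1:4, np, replace = TRUE), stringsAsFactors = FALSE)
    tr <- make_transcripts(tr_df$start0, tr_df$end0, tr_df$strand,
                           tr_df$id)
    peaks <- make_peaks(peak_df$start0, peak_df$end0, peak_df$regulator,
                        peak_df$support)
    got <- assign_regulators(tr, peaks)
    want <- quadratic_assign_oracle(tr_df, peak_df)
    expect_equal(got[, c("regulator", "transcript")], want,
                 ignore_attr = TRUE)
  }
})

test_that("binding enrichment degenerates to p = 1 when it must", {
  edges <- data.frame(regulator = "BMAL1", transcript = c("a", "b"))
  allt <- c("a", "b", "c", "d")
  # identical bound fractions
  expect_equal(binding_enrichment(c("a", "c"), allt, edges,
                                  "BMAL1")$p_value, 1)
  # circadian set == all set
  expect_equal(binding_enrichment(allt, allt, edges, "BMAL1")$p_value, 1)
  expect_error(binding_enrichment(character(), allt, edges, "BMAL1"),
               "empty")
  expect_error(binding_enrichment("zz", allt, edges, "BMAL1"), "subset")
})

test_that("motif construction pairs TF sets with target groups", {
  tfe <- data.frame(
    tf = c("BMAL1", "CLOCK", "REV-ERBA", "BMAL1", "REV-ERBB"),
    target = c("Gadd45a", "Gadd45a", "Cdkn1a", "Bcl2", "Bcl2"),
    functional = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  mte <- data.frame(mirna = "miR-378",
                    target = c("Gadd45a", "Cdkn1a", "Bcl2", "Other"))
  grp <- c(Gadd45a = "I", Cdkn1a = "III", Bcl2 = "III", Other = "none")
  m <- build_motifs(tfe, mte, grp)
  expect_equal(m$motif_type, c(1L, 2L, 2L))
  expect_equal(m$target, c("Gadd45a", "Bcl2", "Cdkn1a"))
  expect_equal(m$tfs[1], "BMAL1+CLOCK")
  # a Group III target bound by BMAL1 only makes no motif
  expect_equal(m$tfs[m$target == "Bcl2"], "REV-ERBB")
  # binding without functional evidence is not regulation
  tfe$functional <- FALSE
  expect_equal(nrow(build_motifs(tfe, mte, grp)), 0L)
  expect_equal(nrow(build_motifs(tfe[0, ], mte, grp)), 0L)
  expect_equal(nrow(build_motifs(tfe, mte[0, ], grp)), 0L)
})
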