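test_that("compile_motif validates the alphabet and expands degenerate letters", {
  expect_error(compile_motif("TGAXGT"), "position 4")
  expect_error(compile_motif(""), "non-empty")
  # the TT(G/T)CATCA(G/T) element has exactly these four concrete forms
  expect_setequal(expand_motif("TTKCATCAK"),
                  c("TTGCATCAG", "TTGCATCAT", "TTTCATCAG", "TTTCATCAT"))
  expect_identical(cre_motif()$consensus, "TGACGT")
})

test_that("scan_sequence honours the matching rules", {
  cre <- cre_motif()
  expect_identical(nrow(scan_sequence("", cre)), 0L)
  expect_identical(nrow(scan_sequence("TGACG", cre)), 0L)  # motif > seq

  h <- scan_sequence("TGACGT", cre, strands = "forward")
  expect_identical(h$offset, 0L)
  expect_identical(h$matched, "TGACGT")

  # subject N matches nothing but motif letter N
  expect_identical(nrow(scan_sequence("TGACGN", cre)), 0L)
  expect_identical(scan_sequence("TGACGN", "TGACGN")$strand, "+")

  # overlapping matches are all reported
  expect_identical(scan_sequence("AAAA", "AA", "forward")$offset, 0:2)

  # reverse-strand hit at the 5'-most forward offset, matched in forward
  # orientation
  s <- paste0("CCC", oracle_revcomp("TTGCATCAT"), "GGG")
  h <- scan_sequence(s, atf4_mef_motif())
  expect_identical(h$offset, 3L)
  expect_identical(h$strand, "-")
  expect_identical(oracle_revcomp(h$matched), "TTGCATCAT")

  # ties sort forward before reverse ("AT" is its own reverse complement)
  h <- scan_sequence("AT", "AT")
  expect_identical(h$strand, c("+", "-"))
})

test_that("scan_sequence agrees with the brute-force oracle", {
  withr::local_seed(101)
  for (i in 1:30) {
    s <- random_seq(sample(50:2000, 1))
    for (cons in c("TGACGT", "TTKCATCAK", "RNCGTN")) {
      for (str in c("both", "forward", "reverse")) {
        expect_identical(scan_sequence(s, cons, str), oracle_scan(s, cons, str))
      }
    }
  }
})

test_that("strand involution and hit-count monotonicity hold", {
  withr::local_seed(33)
  for (i in 1:10) {
    s <- random_seq(500)
    m <- atf4_mef_motif()
    h <- scan_sequence(s, m)
    h_rc <- scan_sequence(oracle_revcomp(s), m)
    mirrored <- data.frame(
      offset = nchar(s) - h$offset - m$length,
      strand = as.character(ifelse(h$strand == "+", "-", "+")),
      matched = vapply(h$matched, oracle_revcomp, character(1),
                       USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
    rownames(mirrored) <- NULL
    expect_identical(h_rc, mirrored)
  }
  # planting one extra non-overlapping instance adds exactly one hit
  bg <- generate_background(1L, upstream_bp = 400L, downstream_bp = 100L,
                            seed = 5)
  s0 <- bg$genome[[1]]
  n0 <- nrow(scan_sequence(s0, cre_motif()))
  expect_identical(n0, 0L)
  s1 <- mutate_sequence(s0, lapply(0:5, function(k)
    sub_edit(100 + k, substr("TGACGT", k + 1, k + 1))))
  expect_identical(nrow(scan_sequence(s1, cre_motif())), 1L)

  # every reported hit re-validates against its consensus
  s <- random_seq(3000)
  h <- scan_sequence(s, "TTKCATCAK")
  for (j in seq_len(nrow(h))) {
    w <- if (h$strand[j] == "-") oracle_revcomp(h$matched[j]) else h$matched[j]
    expect_true(w %in% oracle_expansions("TTKCATCAK"))
  }
})

test_that("scan_promoters reports TSS-relative positions and dedups by footprint", {
  bg <- generate_background(2L, upstream_bp = 2000L, downstream_bp = 500L,
                            seed = 9)
  planted <- plant_motifs(bg, data.frame(
    gene_id = "gene_01", motif_name = "CRE", pos_rel_tss = -1500L,
    strand = "+", stringsAsFactors = FALSE), seed = 10)
  w <- extract_promoters(planted$genome, planted$tss)
  res <- scan_promoters(w)
  expect_identical(res$hits$pos_rel_tss, -1500L)
  expect_identical(unname(res$has_site),
                   c(TRUE, FALSE))  # motif-free background gene stays clean

  # two alternative TSSs 100 bp apart: the shared genomic site is one hit
  tss2 <- rbind(planted$tss[1, ],
                transform(planted$tss[1, ], transcript_id = "gene_01.t2",
                          tss = planted$tss$tss[1] + 100L))
  w2 <- extract_promoters(planted$genome, tss2)
  res2 <- scan_promoters(w2)
  expect_identical(nrow(res2$hits), 1L)
})

test_that("mutate_sequence applies edits right-to-left and stays in bounds", {
  s <- paste0("AAAA", "TTGCATCAG", "CCCC")
  expect_identical(mutate_sequence(s, list(del_edit(4, 13))), "AAAACCCC")
  expect_identical(nrow(scan_sequence(mutate_sequence(s, list(del_edit(4, 13))),
                                      atf4_mef_motif())), 0L)

  # two point substitutions inside a planted CRE kill that hit only
  s2 <- paste0("TGACGT", "AAAA", "TGACGT")
  h0 <- scan_sequence(s2, cre_motif(), "forward")
  expect_identical(h0$offset, c(0L, 10L))
  mut <- mutate_sequence(s2, list(sub_edit(11, "C"), sub_edit(13, "A")))
  h1 <- scan_sequence(mut, cre_motif(), "forward")
  expect_identical(h1$offset, 0L)
  expect_identical(s2, paste0("TGACGT", "AAAA", "TGACGT"))  # input untouched

  # a deletion before a substitution: coordinates refer to the input
  expect_identical(mutate_sequence("ACGTAC", list(del_edit(0, 2),
                                                  sub_edit(4, "G"))),
                   "GTGC")

  expect_error(mutate_sequence(s2, list(sub_edit(nchar(s2), "A"))),
               "out of bounds")
  expect_error(mutate_sequence(s2, list(del_edit(0, 4), del_edit(2, 6))),
               "overlapping")
  expect_error(sub_edit(1, "N"), "A/C/G/T")
})
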