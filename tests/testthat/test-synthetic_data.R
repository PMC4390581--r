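# Small windows keep rejection sampling fast in unit tests; the full-size
# (2000/500) geometry is exercised in test-acceptance.R.

test_that("generate_background is motif-free, seeded and strand-alternating", {
  bg <- generate_background(20L, upstream_bp = 300L, downstream_bp = 100L,
                            seed = 1)
  w <- extract_promoters(bg$genome, bg$tss, 300L, 100L)
  expect_identical(nrow(scan_promoters(w)$hits), 0L)
  expect_identical(unique(nchar(w$sequence)), 400L)
  expect_identical(bg$tss$strand, rep(c("+", "-"), 10))

  bg2 <- generate_background(20L, upstream_bp = 300L, downstream_bp = 100L,
                             seed = 1)
  expect_identical(bg$genome, bg2$genome)  # determinism
  bg3 <- generate_background(20L, upstream_bp = 300L, downstream_bp = 100L,
                             seed = 2)
  expect_false(identical(bg$genome, bg3$genome))

  expect_error(generate_background(5L), "seed is mandatory")
})

test_that("background GC content sits inside a 99% binomial interval", {
  n_genes <- 50L; up <- 300L; down <- 100L; gc <- 0.4
  bg <- generate_background(n_genes, up, down, gc_fraction = gc, seed = 3)
  bases <- strsplit(paste(bg$genome, collapse = ""), "")[[1]]
  n <- length(bases)
  gc_obs <- sum(bases %in% c("G", "C"))
  bounds <- qbinom(c(0.005, 0.995), n, gc)
  expect_gte(gc_obs, bounds[1])
  expect_lte(gc_obs, bounds[2])
})

test_that("plant_motifs writes recoverable instances on both strands", {
  bg <- generate_background(4L, upstream_bp = 300L, downstream_bp = 100L,
                            seed = 4)
  pl <- data.frame(
    gene_id = c("gene_01", "gene_02", "gene_02", "gene_03"),
    motif_name = c("CRE", "ATF4_MEF", "CRE", "ATF4_MEF"),
    pos_rel_tss = c(-250L, -120L, 50L, -200L),
    strand = c("+", "-", "+", "+"), stringsAsFactors = FALSE)
  planted <- plant_motifs(bg, pl, seed = 8)
  w <- extract_promoters(planted$genome, planted$tss, 300L, 100L)
  res <- scan_promoters(w)
  got <- res$hits[, c("gene_id", "motif_name", "pos_rel_tss", "strand_rel")]
  want <- pl[order(pl$gene_id, pl$pos_rel_tss), ]
  expect_identical(got$pos_rel_tss, want$pos_rel_tss)
  expect_identical(got$motif_name, want$motif_name)
  expect_identical(got$strand_rel, want$strand)
  expect_identical(unname(res$has_site),
                   c(TRUE, TRUE, TRUE, FALSE))

  # a minus-strand placement stores the reverse complement of an expansion
  hit2 <- res$hits[res$hits$gene_id == "gene_02" &
                     res$hits$strand_rel == "-", ]
  expect_true(oracle_revcomp(hit2$matched) %in% oracle_expansions("TTKCATCAK"))

  expect_error(plant_motifs(bg, transform(pl, pos_rel_tss = 400L), seed = 1),
               "outside the promoter window")
  overlap <- data.frame(gene_id = "gene_01", motif_name = c("CRE", "CRE"),
                        pos_rel_tss = c(-50L, -47L), strand = "+",
                        stringsAsFactors = FALSE)
  expect_error(plant_motifs(bg, overlap, seed = 1), "overlapping placements")
})

test_that("simulate_expression plants fold changes with log-normal noise", {
  truth <- data.frame(gene_id = sprintf("g%d", 1:6),
                      true_fold_change = c(4, 4, 1, 1, 0.25, 8))
  e0 <- simulate_expression(truth, noise_sd_log2 = 0, seed = 6)
  calls <- classify_regulation(e0)
  expect_identical(as.character(calls$label),
                   c("up", "up", "unchanged", "unchanged", "down", "up"))
  expect_equal(calls$fold_change, truth$true_fold_change)

  expect_identical(simulate_expression(truth, noise_sd_log2 = 0.3, seed = 6),
                   simulate_expression(truth, noise_sd_log2 = 0.3, seed = 6))
  expect_false(identical(
    simulate_expression(truth, noise_sd_log2 = 0.3, seed = 6),
    simulate_expression(truth, noise_sd_log2 = 0.3, seed = 7)))
})

test_that("simulate_ct inverts the qPCR model", {
  levels <- data.frame(gene_id = c("Ldh", "Ldh", "Pfk", "Pfk"),
                       condition = c("ctl", "dtt", "ctl", "dtt"),
                       level = c(1, 8, 0.5, 3), stringsAsFactors = FALSE)
  ct <- simulate_ct(levels, ct_noise_sd = 0, seed = 12)
  expect_equal(ct$ct[ct$gene_id == "Ldh" & ct$condition == "dtt"],
               rep(18 - 3, 3))  # log2(8) = 3 cycles below baseline
  ref <- ct[ct$gene_id == "RpL19", ]
  for (g in c("Ldh", "Pfk")) {
    rec <- qpcr_relative(ct[ct$gene_id == g, ], ref)
    want <- levels[levels$gene_id == g, ]
    expect_equal(rec$mean_level[match(want$condition, rec$condition)],
                 want$level, tolerance = 1e-12)
  }
})

test_that("replicate noise propagates as sigma*sqrt(2)/sqrt(n) on log2 scale", {
  sd_ct <- 0.2; n_rep <- 3L
  levels <- data.frame(gene_id = "Ldh", condition = "ctl", level = 4,
                       stringsAsFactors = FALSE)
  log2_means <- vapply(1:400, function(s) {
    ct <- simulate_ct(levels, ct_noise_sd = sd_ct, n_replicates = n_rep,
                      seed = 9000 + s)
    rec <- qpcr_relative(ct[ct$gene_id == "Ldh", ],
                         ct[ct$gene_id == "RpL19", ])
    log2(rec$mean_level)
  }, numeric(1))
  expect_equal(sd(log2_means), sd_ct * sqrt(2) / sqrt(n_rep), tolerance = 0.15)
})

test_that("the default cohort reproduces the 7-up/4-not-up design exactly", {
  co <- make_synthetic_cohort(seed = 77)
  w <- extract_promoters(co$genome, co$tss)
  res <- scan_promoters(w)
  calls <- classify_regulation(co$expression)
  ct <- build_contingency(calls, res$has_site)
  expect_identical(c(ct$a, ct$b, ct$c, ct$d), c(6L, 1L, 1L, 3L))
  expect_identical(as.character(calls$label), co$labels$true_label)
})
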