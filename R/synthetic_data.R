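# All generators are pure functions of (parameters, seed): they seed R's RNG
# locally and restore the caller's RNG state on exit.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

random_dna <- function(n, gc_fraction) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

has_forbidden <- function(seq, forbidden) {
  for (motif in forbidden) {
    if (nrow(scan_sequence(seq, motif, "both")) > 0L) return(TRUE)
  }
  FALSE
}

#' Generate motif-free promoter backgrounds
#'
#' Each gene gets its own contig holding exactly one promoter window
#' (`upstream_bp` + `downstream_bp` bases); genes are placed on + and -
#' strands alternately. Bases are i.i.d. with P(G) = P(C) = gc_fraction/2.
#' Any candidate window containing an occurrence of a forbidden motif on
#' either strand is rejected and resampled, so a subsequent scan is
#' guaranteed to return zero hits. Deterministic for a given seed.
#'
#' @param n_genes number of genes/contigs.
#' @param upstream_bp,downstream_bp window geometry (defaults 2000/500).
#' @param gc_fraction GC content in (0, 1); default 0.43 (fly euchromatin
#'   is ~43% GC).
#' @param forbidden list of `motif_def`s to exclude (default
#'   [default_motifs()]).
#' @param seed mandatory RNG seed.
#' @param max_attempts rejection-sampling cap per gene.
#' @return list with elements genome (named character), tss (TSS table
#'   data.frame), upstream_bp, downstream_bp, gc_fraction, forbidden, seed.
#' @export
generate_background <- function(n_genes, upstream_bp = 2000L,
                                downstream_bp = 500L, gc_fraction = 0.43,
                                forbidden = default_motifs(), seed,
                                max_attempts = 1000L) {
  stopifnot(gc_fraction > 0, gc_fraction < 1, n_genes >= 1L)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  L <- upstream_bp + downstream_bp
  with_seed(seed, {
    gene_ids <- sprintf("gene_%02d", seq_len(n_genes))
    strands <- rep(c("+", "-"), length.out = n_genes)
    promoters <- character(n_genes)
    for (i in seq_len(n_genes)) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        cand <- random_dna(L, gc_fraction)
        if (!has_forbidden(cand, forbidden)) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("could not sample a motif-free window after ", max_attempts,
             " attempts; use shorter windows or fewer forbidden motifs",
             call. = FALSE)
      }
      promoters[i] <- cand
    }
    # contig stores the promoter in genomic orientation
    genome <- ifelse(strands == "+", promoters, revcomp(promoters))
    names(genome) <- paste0("ctg_", gene_ids)
    tss <- data.frame(
      gene_id = gene_ids, transcript_id = paste0(gene_ids, ".t1"),
      chrom = names(genome),
      tss = ifelse(strands == "+", upstream_bp + 1L, downstream_bp),
      strand = strands, stringsAsFactors = FALSE)
    list(genome = genome, tss = tss, upstream_bp = upstream_bp,
         downstream_bp = downstream_bp, gc_fraction = gc_fraction,
         forbidden = forbidden, seed = seed)
  })
}

resolve_consensus <- function(motif) {
  paste(vapply(motif$classes, function(cl) {
    cl <- setdiff(cl, "N")
    cl[sample.int(length(cl), 1L)]
  }, character(1)), collapse = "")
}

#' Plant motif instances into background promoters
#'
#' Placements give (gene_id, motif_name, pos_rel_tss, strand) in promoter
#' coordinates; degenerate consensus letters are resolved uniformly at
#' random (seeded). Planting on strand `-` writes the reverse complement of
#' the resolved instance. After planting, each edited window is rescanned
#' and must yield exactly the planted placements; if the junction between an
#' instance and the background happens to create a spurious occurrence, the
#' degenerate letters (and, failing that, the background window) are
#' resampled. Placements must lie fully inside their window and must not
#' overlap each other.
#'
#' @param background result of [generate_background()].
#' @param placements data.frame with columns gene_id, motif_name,
#'   pos_rel_tss, strand; motif_name must name an entry of
#'   `background$forbidden`.
#' @param seed RNG seed for degenerate-letter resolution.
#' @param max_attempts resampling cap per gene.
#' @return list with elements genome, tss (as in the background) and truth
#'   (placements with an added `instance` column, the planted A/C/G/T word
#'   in promoter orientation).
#' @export
plant_motifs <- function(background, placements, seed, max_attempts = 100L) {
  motifs <- background$forbidden
  up <- background$upstream_bp; down <- background$downstream_bp
  L <- up + down
  stopifnot(all(placements$gene_id %in% background$tss$gene_id),
            all(placements$motif_name %in%
                  vapply(motifs, `[[`, character(1), "name")))
  motif_by_name <- stats::setNames(motifs,
                                   vapply(motifs, `[[`, character(1), "name"))
  genome <- background$genome
  truth_rows <- list()
  with_seed(seed, {
    for (g in unique(placements$gene_id)) {
      pl <- placements[placements$gene_id == g, , drop = FALSE]
      rec <- background$tss[background$tss$gene_id == g, ][1, ]
      mlens <- vapply(pl$motif_name,
                      function(nm) motif_by_name[[nm]]$length, integer(1))
      offs <- up + pl$pos_rel_tss
      if (any(offs < 0L | offs + mlens > L)) {
        stop("placement outside the promoter window for gene ", g,
             call. = FALSE)
      }
      o <- order(offs)
      if (any(offs[o][-1] < (offs[o] + mlens[o])[-length(o)])) {
        stop("overlapping placements for gene ", g, call. = FALSE)
      }
      prom_orig <- if (rec$strand == "+") genome[[rec$chrom]] else
        revcomp(genome[[rec$chrom]])
      planted_ok <- FALSE
      prom <- prom_orig
      for (attempt in seq_len(max_attempts)) {
        instances <- character(nrow(pl))
        cand <- prom
        for (j in seq_len(nrow(pl))) {
          inst <- resolve_consensus(motif_by_name[[pl$motif_name[j]]])
          write_seq <- if (pl$strand[j] == "+") inst else revcomp(inst)
          substr(cand, offs[j] + 1L, offs[j] + mlens[j]) <- write_seq
          instances[j] <- write_seq
        }
        # verify: scanning must recover exactly the planted set
        found <- do.call(rbind, lapply(names(motif_by_name), function(nm) {
          h <- scan_sequence(cand, motif_by_name[[nm]], "both")
          if (nrow(h) == 0L) return(NULL)
          data.frame(motif_name = nm, pos_rel_tss = h$offset - up,
                     strand = h$strand, stringsAsFactors = FALSE)
        }))
        want <- data.frame(motif_name = pl$motif_name,
                           pos_rel_tss = pl$pos_rel_tss, strand = pl$strand,
                           stringsAsFactors = FALSE)
        key <- function(d) sort(paste(d$motif_name, d$pos_rel_tss, d$strand))
        if (!is.null(found) && identical(key(found), key(want))) {
          prom <- cand
          planted_ok <- TRUE
          break
        }
        # junction artefact: resample degenerate letters; periodically
        # resample the background window itself
        if (attempt %% 10L == 0L) {
          repeat {
            prom <- random_dna(L, background$gc_fraction)
            if (!has_forbidden(prom, motifs)) break
          }
        }
      }
      if (!planted_ok) {
        stop("could not plant motifs cleanly for gene ", g, " after ",
             max_attempts, " attempts", call. = FALSE)
      }
      genome[[rec$chrom]] <- if (rec$strand == "+") prom else revcomp(prom)
      truth_rows[[g]] <- cbind(pl, instance = instances,
                               stringsAsFactors = FALSE)
    }
  })
  truth <- if (length(truth_rows) > 0L) do.call(rbind, truth_rows) else
    placements
  rownames(truth) <- NULL
  list(genome = genome, tss = background$tss, truth = truth,
       upstream_bp = up, downstream_bp = down)
}

#' Simulate a control/stress expression table with planted fold changes
#'
#' control = base_level * 2^e1 and stress = base_level * true_fold_change *
#' 2^e2 with e1, e2 ~ Normal(0, noise_sd_log2), independent — i.e.
#' log-normal multiplicative noise, the error structure of array and qPCR
#' levels. Deterministic per seed.
#'
#' @param truth data.frame with columns gene_id, true_fold_change.
#' @param base_level control-level scale (arbitrary units).
#' @param noise_sd_log2 SD of the log2 noise (>= 0); 0 reproduces the
#'   planted labels exactly.
#' @param seed RNG seed.
#' @return data.frame with columns gene_id, control, stress.
#' @export
simulate_expression <- function(truth, base_level = 100, noise_sd_log2 = 0,
                                seed) {
  stopifnot(noise_sd_log2 >= 0, all(truth$true_fold_change > 0))
  with_seed(seed, {
    n <- nrow(truth)
    e1 <- stats::rnorm(n, 0, noise_sd_log2)
    e2 <- stats::rnorm(n, 0, noise_sd_log2)
    data.frame(gene_id = truth$gene_id,
               control = base_level * 2^e1,
               stress = base_level * truth$true_fold_change * 2^e2,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a qPCR Ct table from known relative levels
#'
#' Inverse of the [qpcr_relative()] model: the target Ct is
#' `ct_ref_base - log_efficiency(level) + eta` and the reference gene's Ct
#' is `ct_ref_base + eta`, with eta ~ Normal(0, ct_noise_sd) independent per
#' well. At zero noise, feeding the result back through [qpcr_relative()]
#' recovers the input levels exactly.
#'
#' @param levels data.frame with columns gene_id, condition, level (> 0).
#' @param reference_gene reference gene id added to the table (default
#'   "RpL19").
#' @param efficiency amplification efficiency in (1, 2].
#' @param ct_ref_base reference Ct baseline (cycles).
#' @param n_replicates technical replicates per (gene, condition).
#' @param ct_noise_sd per-well Ct noise SD (cycles).
#' @param seed RNG seed.
#' @return QpcrMeasurement data.frame (gene_id, condition, replicate, ct)
#'   covering all target genes plus the reference gene.
#' @export
simulate_ct <- function(levels, reference_gene = "RpL19", efficiency = 2.0,
                        ct_ref_base = 18, n_replicates = 3L,
                        ct_noise_sd = 0, seed) {
  stopifnot(all(levels$level > 0), efficiency > 1, efficiency <= 2,
            n_replicates >= 1L, ct_noise_sd >= 0)
  with_seed(seed, {
    reps <- sprintf("r%d", seq_len(n_replicates))
    rows <- list()
    for (i in seq_len(nrow(levels))) {
      ct0 <- ct_ref_base - log(levels$level[i]) / log(efficiency)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = levels$gene_id[i], condition = levels$condition[i],
        replicate = reps, ct = ct0 + stats::rnorm(n_replicates, 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
    for (cond in unique(levels$condition)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = reference_gene, condition = cond, replicate = reps,
        ct = ct_ref_base + stats::rnorm(n_replicates, 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Default synthetic cohort mirroring the glycolytic-gene design
#'
#' Eleven genes: seven up-regulated (true fold change `up_fc`, default 4) of
#' which six carry one planted Atf4 site, and four unchanged (fold change 1)
#' of which one carries a site — the 7-up/4-not-up, 6-with-site/1-with-site
#' shape of the motivating analysis, giving the contingency table
#' (6, 1, 1, 3). Sites are a mix of CRE and TTKCATCAK placements on both
#' strands at biologically plausible offsets.
#'
#' @param seed RNG seed.
#' @param noise_sd_log2 expression noise (default 0: labels are exact).
#' @param up_fc planted fold change of up-regulated genes.
#' @param gc_fraction background GC content.
#' @return list with genome, tss, truth (placements), expression
#'   (data.frame), labels (data.frame gene_id, true_label, true_fold_change).
#' @export
make_synthetic_cohort <- function(seed, noise_sd_log2 = 0, up_fc = 4,
                                  gc_fraction = 0.43) {
  bg <- generate_background(11L, gc_fraction = gc_fraction, seed = seed)
  genes <- bg$tss$gene_id
  # genes 1-7 up; sites on 1-6 (up) and 8 (not-up)
  placements <- data.frame(
    gene_id = genes[c(1, 2, 3, 4, 5, 6, 8)],
    motif_name = c("CRE", "CRE", "ATF4_MEF", "CRE", "ATF4_MEF", "CRE",
                   "ATF4_MEF"),
    pos_rel_tss = c(-1500L, -150L, -800L, -1900L, 100L, -60L, -400L),
    strand = c("+", "-", "+", "+", "-", "+", "+"),
    stringsAsFactors = FALSE)
  planted <- plant_motifs(bg, placements, seed = seed + 1L)
  labels <- data.frame(
    gene_id = genes,
    true_label = c(rep("up", 7), rep("unchanged", 4)),
    true_fold_change = c(rep(up_fc, 7), rep(1, 4)),
    stringsAsFactors = FALSE)
  expression <- simulate_expression(labels, noise_sd_log2 = noise_sd_log2,
                                    seed = seed + 2L)
  list(genome = planted$genome, tss = planted$tss, truth = planted$truth,
       expression = expression, labels = labels,
       upstream_bp = bg$upstream_bp, downstream_bp = bg$downstream_bp)
}

#' Write a synthetic cohort to disk as plain-text fixtures
#'
#' Emits FASTA (contigs), TSV (TSS table, expression table) and a JSON
#' truth table into `dir`; used by the pipeline tests and the
#' `make-fixtures` CLI subcommand.
#'
#' @param cohort result of [make_synthetic_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_cohort_fixtures <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "contigs.fa"),
             tss = file.path(dir, "tss.tsv"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.json"))
  writeLines(paste0(">", names(cohort$genome), "\n", cohort$genome),
             paths[["fasta"]])
  utils::write.table(cohort$tss, paths[["tss"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$expression, paths[["expression"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(truth = cohort$truth, labels = cohort$labels),
                       paths[["truth"]], dataframe = "rows", auto_unbox = TRUE)
  paths
}
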