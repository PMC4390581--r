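#' Build a pipeline configuration
#'
#' Defaults are the motivating study's stated parameters: a 2 kb upstream /
#' 0.5 kb downstream promoter window, the CRE and TT(G/T)CATCA(G/T) motifs,
#' fold-change thresholds of 2 (up) and 1.5 (down), and both-strand
#' scanning.
#'
#' @param fasta,tss,expression input paths (FASTA, TSS table, expression
#'   TSV).
#' @param qpcr optional qPCR Ct TSV.
#' @param tss_dialect TSS file dialect ("tsv", "gff3" or "bed").
#' @param reference_gene qPCR reference (housekeeping) gene id.
#' @param upstream_bp,downstream_bp promoter-window geometry.
#' @param motifs named character vector of IUPAC consensi.
#' @param up_threshold,down_threshold fold-change thresholds.
#' @param strands "both", "forward" or "reverse".
#' @param seed RNG seed recorded in the manifest.
#' @param out_dir output directory.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(fasta, tss, expression, qpcr = NULL,
                            tss_dialect = "tsv", reference_gene = "RpL19",
                            upstream_bp = 2000L, downstream_bp = 500L,
                            motifs = c(CRE = "TGACGT", ATF4_MEF = "TTKCATCAK"),
                            up_threshold = 2.0, down_threshold = 1.5,
                            strands = "both", seed = 1L,
                            out_dir = "uprshift_out") {
  cfg <- list(fasta = fasta, tss = tss, expression = expression, qpcr = qpcr,
              tss_dialect = tss_dialect, reference_gene = reference_gene,
              upstream_bp = as.integer(upstream_bp),
              downstream_bp = as.integer(downstream_bp),
              motifs = motifs, up_threshold = up_threshold,
              down_threshold = down_threshold, strands = strands,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips losslessly through [pipeline_config()].
#'
#' @param path YAML file.
#' @return for `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$motifs)) raw$motifs <- unlist(raw$motifs)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$motifs <- as.list(cfg$motifs)  # keep names through YAML
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Reads the genome, TSS annotations and expression table; extracts
#' promoter windows; scans them for the configured motifs; classifies
#' regulation; cross-tabulates motif presence against up-regulation with an
#' exact test; optionally summarises a qPCR Ct table; and writes a report
#' bundle (regulation TSV, hits TSV + BED, text motif map, contingency
#' block, manifest JSON with input checksums) into `config$out_dir`.
#' Genes with expression data but no annotated TSS are excluded from the
#' association table with a warning. Deterministic given (inputs, config).
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with windows, hits, has_site, calls,
#'   contingency, qpcr (or NULL) and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  genome <- read_genome_fasta(config$fasta)
  tss <- read_tss_table(config$tss, dialect = config$tss_dialect)
  expr <- read_expression_table(config$expression)

  orphans <- setdiff(expr$gene_id, tss$gene_id)
  if (length(orphans) > 0L) {
    warning("gene(s) without an annotated TSS excluded from the association: ",
            paste(orphans, collapse = ", "), call. = FALSE)
    expr <- expr[!expr$gene_id %in% orphans, , drop = FALSE]
  }

  windows <- extract_promoters(genome, tss, config$upstream_bp,
                               config$downstream_bp)
  motifs <- lapply(names(config$motifs), function(nm)
    compile_motif(config$motifs[[nm]], name = nm))
  scan <- scan_promoters(windows, motifs, strands = config$strands)
  calls <- classify_regulation(expr, config$up_threshold,
                               config$down_threshold)
  contingency <- build_contingency(calls, scan$has_site)

  qpcr_summary <- NULL
  if (!is.null(config$qpcr)) {
    ct <- read_qpcr_table(config$qpcr)
    ref <- ct[ct$gene_id == config$reference_gene, , drop = FALSE]
    if (nrow(ref) == 0L) {
      stop("qPCR table lacks the reference gene ", config$reference_gene,
           call. = FALSE)
    }
    targets <- setdiff(unique(ct$gene_id), config$reference_gene)
    qpcr_summary <- do.call(rbind, lapply(targets, function(g) {
      qpcr_relative(ct[ct$gene_id == g, , drop = FALSE], ref)
    }))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(regulation = file.path(config$out_dir, "regulation.tsv"),
             hits = file.path(config$out_dir, "motif_hits.tsv"),
             bed = file.path(config$out_dir, "motif_hits.bed"),
             report = file.path(config$out_dir, "report.txt"),
             manifest = file.path(config$out_dir, "manifest.json"))
  utils::write.table(calls, paths[["regulation"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scan$hits, paths[["hits"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_hits_bed(scan$hits, paths[["bed"]])
  if (!is.null(qpcr_summary)) {
    paths <- c(paths, qpcr = file.path(config$out_dir, "qpcr_summary.tsv"))
    utils::write.table(qpcr_summary, paths[["qpcr"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  report <- c("uprshift pipeline report", "",
              sprintf("windows: %d genes, -%d/+%d bp around the TSS",
                      length(unique(windows$gene_id)), config$upstream_bp,
                      config$downstream_bp),
              sprintf("motifs: %s",
                      paste(sprintf("%s (%s)", names(config$motifs),
                                    config$motifs), collapse = ", ")),
              "", "Motif map (| = TSS; letters mark hits, lowercase = reverse):",
              render_motif_map(scan$hits, windows), "",
              format(contingency))
  writeLines(report, paths[["report"]])

  inputs <- c(config$fasta, config$tss, config$expression, config$qpcr)
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("uprshift")),
    r_version = R.version.string,
    input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(windows = windows, hits = scan$hits,
                 has_site = scan$has_site, calls = calls,
                 contingency = contingency, qpcr = qpcr_summary,
                 paths = paths))
}

#' Plot a per-gene motif map
#'
#' Base-graphics rendering of the hit map: one row per gene, arrowheads at
#' hit positions relative to the TSS. Optional (flag-gated in the CLI) so
#' headless environments need no plotting device.
#'
#' @param hits,windows as returned by the scan stage.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plot_motif_map <- function(hits, windows, ...) {
  genes <- unique(windows$gene_id)
  up <- max(windows$tss_offset)
  down <- max(nchar(windows$sequence) - windows$tss_offset)
  graphics::plot(NA, xlim = c(-up, down), ylim = c(0.5, length(genes) + 0.5),
                 xlab = "position relative to TSS (bp)", ylab = "",
                 yaxt = "n", ...)
  graphics::axis(2, at = seq_along(genes), labels = genes, las = 2,
                 cex.axis = 0.7)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  for (i in seq_along(genes)) {
    h <- hits[hits$gene_id == genes[i], , drop = FALSE]
    if (nrow(h) == 0L) next
    pch <- ifelse(h$strand_rel == "+", 24, 25)
    col <- ifelse(h$motif_name == "CRE", "grey60", "black")
    graphics::points(h$pos_rel_tss, rep(i, nrow(h)), pch = pch, bg = col)
  }
  invisible(NULL)
}
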