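# Internal coordinate convention: 0-based, half-open [start, end). All 1-based
# conventions (FASTA positions, GFF3, the `tss` column) are converted at the
# I/O boundary and never used internally.

#' Reverse-complement a DNA string
#'
#' Works on plain character vectors over the alphabet A/C/G/T/N.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TGACGT")  # "ACGTCA"
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s))))
  }, character(1), USE.NAMES = FALSE)
}

# Fold a raw residue string to the working alphabet {A,C,G,T,N}.
# Lowercase is uppercased, U (RNA) becomes T, IUPAC ambiguity codes other
# than N are degraded to N. Any other character is a hard error reported
# with its 1-based position within the record.
normalize_residues <- function(residues, id) {
  s <- chartr("u", "t", toupper(residues))
  s <- chartr("U", "T", s)
  # degrade non-N ambiguity codes
  s <- chartr("RYSWKMBDHV", "NNNNNNNNNN", s)
  bad <- regexpr("[^ACGTN]", s)
  if (bad != -1L) {
    stop(sprintf("sequence '%s': non-IUPAC character '%s' at position %d",
                 id, substr(s, bad, bad), bad), call. = FALSE)
  }
  s
}

#' Read genome or promoter sequences from FASTA
#'
#' Residues are normalised to uppercase A/C/G/T/N (U is mapped to T and
#' ambiguity codes other than N are folded to N). Duplicate record ids,
#' invalid characters and empty files are hard errors.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return named character vector, one element per record; names are record
#'   ids (first whitespace-delimited token of each header).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA record id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  res <- as.character(set)
  names(res) <- ids
  mapply(normalize_residues, res, ids, USE.NAMES = TRUE)
}

validate_tss_table <- function(df) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "tss", "strand") %in%
                  names(df)))
  df$gene_id <- as.character(df$gene_id)
  df$transcript_id <- as.character(df$transcript_id)
  df$chrom <- as.character(df$chrom)
  df$tss <- as.integer(df$tss)
  df$strand <- as.character(df$strand)
  bad_strand <- !df$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("unknown strand symbol(s): ",
         paste(unique(df$strand[bad_strand]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(df$tss) | df$tss < 1L)) {
    stop("TSS coordinates must be 1-based integers >= 1", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read TSS annotations
#'
#' Supported dialects:
#' \describe{
#'   \item{tsv}{header `gene_id, transcript_id, chrom, tss, strand`; `tss`
#'     is 1-based and taken verbatim.}
#'   \item{gff3}{features of `feature_type` (default "mRNA"); the TSS is the
#'     `start` field on `+` and the `end` field on `-` (GFF3 is 1-based
#'     inclusive). `transcript_id` comes from the ID attribute, `gene_id`
#'     from gene_id/Parent when present, else the ID.}
#'   \item{bed}{BED6; TSS = chromStart+1 on `+`, chromEnd on `-` (BED is
#'     0-based half-open); the name column is used for both ids.}
#' }
#'
#' @param path input file.
#' @param dialect one of "tsv", "gff3", "bed".
#' @param feature_type GFF3 feature type carrying transcripts.
#' @return data.frame with columns gene_id, transcript_id, chrom, tss
#'   (1-based), strand.
#' @export
read_tss_table <- function(path, dialect = c("tsv", "gff3", "bed"),
                           feature_type = "mRNA") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("TSS file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    return(validate_tss_table(df))
  }
  gr <- rtracklayer::import(path, format = if (dialect == "bed") "BED" else "GFF3")
  if (dialect == "gff3") {
    gr <- gr[as.character(gr$type) == feature_type]
    if (length(gr) == 0L) {
      stop("no '", feature_type, "' features in ", path, call. = FALSE)
    }
    tid <- as.character(gr$ID)
    gid <- tid
    if (!is.null(gr$gene_id)) {
      gid <- ifelse(is.na(gr$gene_id), tid, as.character(gr$gene_id))
    } else if (!is.null(gr$Parent)) {
      par <- as.character(S4Vectors::unstrsplit(gr$Parent, ","))
      gid <- ifelse(par == "", tid, par)
    }
  } else {
    tid <- gid <- as.character(gr$name)
  }
  str <- as.character(GenomicRanges::strand(gr))
  # GRanges start/end are 1-based inclusive for both formats after import,
  # so TSS = start on + and end on - regardless of the on-disk convention.
  tss <- ifelse(str == "+", GenomicRanges::start(gr), GenomicRanges::end(gr))
  validate_tss_table(data.frame(
    gene_id = gid, transcript_id = tid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = tss, strand = str, stringsAsFactors = FALSE))
}

#' Extract strand-aware promoter windows
#'
#' For each TSS record, returns the window spanning `upstream_bp` bases
#' before the TSS plus `downstream_bp` bases starting at the TSS base
#' itself, oriented 5'->3' in the direction of transcription (minus-strand
#' windows are reverse-complemented). Windows are clipped at contig edges:
#' truncation shifts `tss_offset`, it never pads.
#'
#' @param genome named character vector as from [read_genome_fasta()].
#' @param tss data.frame as from [read_tss_table()].
#' @param upstream_bp bases upstream of the TSS (default 2000, i.e. 2 kb).
#' @param downstream_bp bases from the TSS base onwards (default 500).
#' @return data.frame with columns gene_id, transcript_id, chrom, start, end
#'   (0-based half-open genomic interval), strand, sequence (promoter
#'   orientation), tss_offset (0-based index of the TSS base within
#'   `sequence`).
#' @export
extract_promoters <- function(genome, tss, upstream_bp = 2000L,
                              downstream_bp = 500L) {
  stopifnot(upstream_bp >= 0L, downstream_bp >= 1L)
  missing_chrom <- setdiff(unique(tss$chrom), names(genome))
  if (length(missing_chrom) > 0L) {
    stop("chromosome(s) absent from the sequence set: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  out <- vector("list", nrow(tss))
  for (i in seq_len(nrow(tss))) {
    rec <- tss[i, ]
    contig <- genome[[rec$chrom]]
    L <- nchar(contig)
    tss0 <- rec$tss - 1L              # 0-based TSS position
    if (tss0 < 0L || tss0 >= L) {
      stop(sprintf("TSS of %s (%s:%d) lies outside contig of length %d",
                   rec$transcript_id, rec$chrom, rec$tss, L), call. = FALSE)
    }
    if (rec$strand == "+") {
      gstart <- max(0L, tss0 - upstream_bp)
      gend <- min(L, tss0 + downstream_bp)
      tss_offset <- tss0 - gstart
      seq <- substr(contig, gstart + 1L, gend)
    } else {
      gstart <- max(0L, tss0 - downstream_bp + 1L)
      gend <- min(L, tss0 + upstream_bp + 1L)
      tss_offset <- gend - 1L - tss0
      seq <- revcomp(substr(contig, gstart + 1L, gend))
    }
    out[[i]] <- data.frame(
      gene_id = rec$gene_id, transcript_id = rec$transcript_id,
      chrom = rec$chrom, start = gstart, end = gend, strand = rec$strand,
      sequence = seq, tss_offset = tss_offset, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Extract a single promoter window
#'
#' Single-record convenience wrapper around [extract_promoters()].
#'
#' @inheritParams extract_promoters
#' @param rec one-row data.frame (a TSS record).
#' @return one-row promoter-window data.frame.
#' @export
extract_promoter <- function(genome, rec, upstream_bp = 2000L,
                             downstream_bp = 500L) {
  extract_promoters(genome, rec[1, , drop = FALSE], upstream_bp, downstream_bp)
}

#' Write promoter windows as FASTA
#'
#' Headers follow `gene_id|transcript_id|chrom:start-end(strand)` with the
#' genomic interval printed 0-based half-open.
#'
#' @param windows promoter-window data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(windows, path) {
  headers <- sprintf("%s|%s|%s:%d-%d(%s)", windows$gene_id,
                     windows$transcript_id, windows$chrom, windows$start,
                     windows$end, windows$strand)
  writeLines(paste0(">", headers, "\n", windows$sequence), path)
  invisible(path)
}
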