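# IUPAC nucleotide classes. A motif letter matches a subject base iff the
# base is in the letter's class; subject N matches only motif letter N
# (conservative: an unknown base is never evidence for a site).
IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

#' Compile a degenerate consensus motif
#'
#' Turns an IUPAC consensus string into a matcher object used by the
#' scanning functions. Matching is literal consensus matching (no PWM
#' scores): a window matches iff every position's base belongs to the
#' corresponding IUPAC class.
#'
#' @param consensus IUPAC string, e.g. `"TGACGT"` or `"TTKCATCAK"`.
#' @param name motif name used in reports (defaults to the consensus).
#' @param source free-text provenance tag.
#' @return an object of class `motif_def` with elements name, consensus,
#'   length, classes (per-position allowed-base sets) and regex.
#' @export
#' @examples
#' compile_motif("TTKCATCAK", name = "ATF4_MEF")
compile_motif <- function(consensus, name = consensus, source = "") {
  if (!is.character(consensus) || length(consensus) != 1L ||
      nchar(consensus) == 0L) {
    stop("consensus must be a single non-empty string", call. = FALSE)
  }
  letters <- strsplit(toupper(consensus), "")[[1]]
  bad <- which(!letters %in% names(IUPAC_CLASSES))
  if (length(bad) > 0L) {
    stop(sprintf("illegal motif character '%s' at position %d",
                 letters[bad[1]], bad[1]), call. = FALSE)
  }
  classes <- IUPAC_CLASSES[letters]
  regex <- paste(vapply(classes, function(cl) {
    if (length(cl) == 1L) cl else paste0("[", paste(cl, collapse = ""), "]")
  }, character(1)), collapse = "")
  structure(list(name = name, consensus = toupper(consensus),
                 length = length(letters), classes = classes, regex = regex,
                 source = source),
            class = "motif_def")
}

#' @export
print.motif_def <- function(x, ...) {
  cat(sprintf("<motif_def> %s: %s (%d bp)\n", x$name, x$consensus, x$length))
  invisible(x)
}

#' Built-in Atf4 binding-site motifs
#'
#' `cre_motif()` is the bZIP cAMP-response-element core TGACGT;
#' `atf4_mef_motif()` is the TT(G/T)CATCA(G/T) element reported from Atf4
#' ChIP in mouse embryonic fibroblasts, written in IUPAC as TTKCATCAK.
#'
#' @return a `motif_def`.
#' @export
cre_motif <- function() {
  compile_motif("TGACGT", name = "CRE", source = "bZIP CRE core")
}

#' @rdname cre_motif
#' @export
atf4_mef_motif <- function() {
  compile_motif("TTKCATCAK", name = "ATF4_MEF", source = "Atf4 ChIP motif (MEF)")
}

#' Default motif set used throughout the pipeline
#' @return named list of `motif_def` objects (CRE, ATF4_MEF).
#' @export
default_motifs <- function() {
  list(CRE = cre_motif(), ATF4_MEF = atf4_mef_motif())
}

#' Enumerate the concrete expansions of a consensus
#'
#' @param motif a `motif_def` or IUPAC string.
#' @return character vector of all A/C/G/T words matching the consensus.
#' @export
expand_motif <- function(motif) {
  if (is.character(motif)) motif <- compile_motif(motif)
  cls <- lapply(motif$classes, setdiff, y = "N")
  apply(do.call(expand.grid,
                c(cls, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)),
        1L, paste, collapse = "")
}

# All (0-based) offsets at which `regex` matches `seq`, overlapping matches
# included (zero-width lookahead).
regex_offsets <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan one sequence for a motif
#'
#' Every offset is tested on the requested strand(s); overlapping matches
#' are all reported. Reverse-strand hits are reported at the 5'-most
#' forward-coordinate offset of the matched window, and `matched` is always
#' the forward-orientation subsequence (so for a `-` hit its reverse
#' complement satisfies the consensus).
#'
#' @param seq subject sequence (uppercase A/C/G/T/N).
#' @param motif a `motif_def` or IUPAC string.
#' @param strands "both" (default), "forward" or "reverse".
#' @return data.frame with columns offset (0-based), strand ("+"/"-"),
#'   matched; sorted by offset, forward before reverse at ties. A motif
#'   longer than the sequence yields zero rows.
#' @export
scan_sequence <- function(seq, motif, strands = c("both", "forward", "reverse")) {
  strands <- match.arg(strands)
  if (is.character(motif)) motif <- compile_motif(motif)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      matched = character(0), stringsAsFactors = FALSE)
  n <- nchar(seq)
  m <- motif$length
  if (n < m) return(empty)
  hits <- empty
  if (strands %in% c("both", "forward")) {
    off <- regex_offsets(seq, motif$regex)
    if (length(off) > 0L) {
      hits <- rbind(hits, data.frame(
        offset = off, strand = "+",
        matched = substring(seq, off + 1L, off + m), stringsAsFactors = FALSE))
    }
  }
  if (strands %in% c("both", "reverse")) {
    rc <- revcomp(seq)
    off_rc <- regex_offsets(rc, motif$regex)
    if (length(off_rc) > 0L) {
      off <- n - off_rc - m  # map back to forward coordinates
      hits <- rbind(hits, data.frame(
        offset = off, strand = "-",
        matched = substring(seq, off + 1L, off + m), stringsAsFactors = FALSE))
    }
  }
  hits[order(hits$offset, hits$strand), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Scan promoter windows for a set of motifs
#'
#' Positions are reported relative to the TSS (`pos_rel_tss`: negative =
#' upstream, 0 = the TSS base) and as genomic footprints. Hits duplicated by
#' overlapping windows of the same gene (alternative TSSs) are deduplicated
#' on the genomic footprint (gene, motif, chrom, genomic start, genomic
#' strand).
#'
#' @param windows promoter-window data.frame from [extract_promoters()].
#' @param motifs list of `motif_def` objects (default [default_motifs()]).
#' @param strands passed to [scan_sequence()].
#' @return list with elements `hits` (data.frame: gene_id, transcript_id,
#'   motif_name, pos_rel_tss, strand_rel, matched, chrom, gstart, gend,
#'   gstrand) and `has_site` (named logical over all genes in `windows`).
#' @export
scan_promoters <- function(windows, motifs = default_motifs(),
                           strands = "both") {
  if (nrow(windows) == 0L) stop("no promoter windows supplied", call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    for (motif in motifs) {
      h <- scan_sequence(w$sequence, motif, strands)
      if (nrow(h) == 0L) next
      m <- motif$length
      if (w$strand == "+") {
        gstart <- w$start + h$offset
        gstrand <- ifelse(h$strand == "+", "+", "-")
      } else {
        gstart <- w$end - h$offset - m
        gstrand <- ifelse(h$strand == "+", "-", "+")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = w$gene_id, transcript_id = w$transcript_id,
        motif_name = motif$name, pos_rel_tss = h$offset - w$tss_offset,
        strand_rel = h$strand, matched = h$matched, chrom = w$chrom,
        gstart = gstart, gend = gstart + m, gstrand = gstrand,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene_id = character(0), transcript_id = character(0),
               motif_name = character(0), pos_rel_tss = integer(0),
               strand_rel = character(0), matched = character(0),
               chrom = character(0), gstart = integer(0), gend = integer(0),
               gstrand = character(0), stringsAsFactors = FALSE)
  key <- with(hits, paste(gene_id, motif_name, chrom, gstart, gstrand))
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits <- hits[order(hits$gene_id, hits$pos_rel_tss, hits$strand_rel), ,
               drop = FALSE]
  rownames(hits) <- NULL
  genes <- unique(windows$gene_id)
  has_site <- stats::setNames(genes %in% hits$gene_id, genes)
  list(hits = hits, has_site = has_site)
}

#' Construct sequence edits
#'
#' `sub_edit()` replaces one base; `del_edit()` removes the 0-based
#' half-open interval `[start, end)`.
#'
#' @param pos,start,end 0-based coordinates.
#' @param base replacement base (A/C/G/T).
#' @return an edit object for [mutate_sequence()].
#' @export
sub_edit <- function(pos, base) {
  base <- toupper(base)
  if (!base %in% c("A", "C", "G", "T")) {
    stop("substitution base must be one of A/C/G/T", call. = FALSE)
  }
  structure(list(type = "substitute", pos = as.integer(pos), base = base),
            class = "seq_edit")
}

#' @rdname sub_edit
#' @export
del_edit <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("deletion interval must be non-empty", call. = FALSE)
  structure(list(type = "delete", start = start, end = end),
            class = "seq_edit")
}

#' Apply point mutations and deletions to a sequence
#'
#' Mirrors reporter-construct mutagenesis in silico: point-mutate bases
#' inside a CRE, or delete a motif footprint outright, then rescan. Edits
#' are applied right-to-left so earlier coordinates stay valid; the input
#' is not modified. Out-of-bounds edits and overlapping deletions (or a
#' substitution inside a deleted interval) are errors.
#'
#' @param seq sequence to edit.
#' @param edits list of edits from [sub_edit()] / [del_edit()].
#' @return the edited sequence.
#' @export
#' @examples
#' mutate_sequence("TTGCATCAG", list(sub_edit(2, "A")))
mutate_sequence <- function(seq, edits) {
  n <- nchar(seq)
  if (length(edits) == 0L) return(seq)
  if (inherits(edits, "seq_edit")) edits <- list(edits)
  iv <- lapply(edits, function(e) {
    if (e$type == "delete") c(e$start, e$end) else c(e$pos, e$pos + 1L)
  })
  for (k in seq_along(edits)) {
    if (iv[[k]][1] < 0L || iv[[k]][2] > n) {
      stop(sprintf("edit %d out of bounds for sequence of length %d", k, n),
           call. = FALSE)
    }
  }
  ord <- order(vapply(iv, `[`, integer(1), 1L), decreasing = FALSE)
  for (a in seq_along(ord)[-1]) {
    prev <- iv[[ord[a - 1L]]]; cur <- iv[[ord[a]]]
    overlap <- cur[1] < prev[2] && prev[1] < cur[2]
    if (overlap && !(edits[[ord[a - 1L]]]$type == "substitute" &&
                     edits[[ord[a]]]$type == "substitute")) {
      stop("overlapping edits involving a deletion are not allowed",
           call. = FALSE)
    }
  }
  # right-to-left application
  for (k in rev(ord)) {
    e <- edits[[k]]
    if (e$type == "substitute") {
      substr(seq, e$pos + 1L, e$pos + 1L) <- e$base
    } else {
      seq <- paste0(substr(seq, 1L, e$start), substr(seq, e$end + 1L, nchar(seq)))
    }
  }
  seq
}

#' Write motif hits as BED6
#'
#' One line per hit: chrom, genomic start (0-based), genomic end,
#' `gene|motif`, score 0, genomic strand.
#'
#' @param hits hit data.frame from [scan_promoters()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s", hits$chrom, hits$gstart,
                   hits$gend, hits$gene_id, hits$motif_name, hits$gstrand)
  writeLines(lines, path)
  invisible(path)
}

#' Render a per-gene text diagram of motif hits
#'
#' One row per gene: a fixed-width track spanning the promoter window with
#' the TSS marked `|`; hits are marked with the first letter of the motif
#' name, uppercase for promoter-forward hits and lowercase for reverse.
#'
#' @param hits hit data.frame from [scan_promoters()].
#' @param windows the promoter windows that were scanned.
#' @param width diagram width in characters.
#' @return character vector of diagram lines.
#' @export
render_motif_map <- function(hits, windows, width = 60L) {
  genes <- unique(windows$gene_id)
  lab_w <- max(nchar(genes), 4L)
  out <- character(0)
  for (g in genes) {
    w <- windows[windows$gene_id == g, ][1, ]
    L <- nchar(w$sequence)
    track <- rep("-", width)
    tss_col <- floor(w$tss_offset / L * (width - 1L)) + 1L
    track[tss_col] <- "|"
    h <- hits[hits$gene_id == g, , drop = FALSE]
    for (j in seq_len(nrow(h))) {
      col <- floor((h$pos_rel_tss[j] + w$tss_offset) / L * (width - 1L)) + 1L
      mark <- substr(h$motif_name[j], 1L, 1L)
      if (h$strand_rel[j] == "-") mark <- tolower(mark)
      track[col] <- mark
    }
    out <- c(out, sprintf("%-*s  5'-%s-3'", lab_w, g, paste(track, collapse = "")))
  }
  out
}
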